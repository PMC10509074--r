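#' Fingerprint featurizers
#'
#' Two featurizers feed the baseline random forests:
#'
#' * **Morgan** (ECFP-style): iterative circular-substructure hashing of the
#'   ligand's 2D graph, radius 2 by default. Purely topological — no
#'   coordinates and no protein information enter the vector.
#' * **PLEC-style**: every (ligand atom, synthetic residue) pair closer than
#'   a distance cutoff is hashed into the vector, combining the ligand atom's
#'   circular environment (depths 0..`plec_ligand_depth`) with the residue
#'   identity. Synthetic residues are single unconnected pseudo-atoms, so the
#'   protein depth is 0 and the residue identity is its type.
#'
#' Vectors are binary presence vectors. Identifiers are folded into the bit
#' range with a stable string hash, so fingerprints are identical across
#' sessions and platforms; hash collisions are tolerated as in any hashed
#' fingerprint.
#'
#' @name fingerprints
NULL

#' Featurizer configuration
#'
#' @param morgan_radius Circular-environment radius for Morgan fingerprints.
#' @param morgan_bits Morgan vector length.
#' @param plec_cutoff Distance cutoff in Angstrom for PLEC pair detection
#'   (the `n` of the RF_PLEC_n model naming).
#' @param plec_ligand_depth Ligand environment depth for PLEC.
#' @param plec_protein_depth Protein environment depth (0: residues are
#'   single pseudo-atoms).
#' @param plec_bits PLEC vector length.
#' @return A `featurizer_config` list.
#' @export
featurizer_config <- function(morgan_radius = 2L, morgan_bits = 2048L,
                              plec_cutoff = 4, plec_ligand_depth = 3L,
                              plec_protein_depth = 0L, plec_bits = 16384L) {
  assert_that(morgan_radius >= 0 && plec_ligand_depth >= 0 && plec_protein_depth >= 0,
              "radii/depths must be >= 0")
  assert_that(plec_cutoff > 0, "plec_cutoff must be > 0")
  structure(list(morgan_radius = as.integer(morgan_radius),
                 morgan_bits = as.integer(morgan_bits),
                 plec_cutoff = plec_cutoff,
                 plec_ligand_depth = as.integer(plec_ligand_depth),
                 plec_protein_depth = as.integer(plec_protein_depth),
                 plec_bits = as.integer(plec_bits)),
            class = "featurizer_config")
}

# Per-atom circular environment identifiers for depths 0..radius.
# Returns a list of integer vectors (one per depth, length n_heavy).
# Dummy atoms receive a sentinel identifier: they still perturb their
# neighbours' environments, but environments centred on them are never
# emitted as features.
atom_environments <- function(lig, radius) {
  at <- lig$atoms
  adj <- ligand_adjacency(lig)
  n <- lig$n_heavy
  deg <- vapply(adj$nbrs, length, integer(1))
  ids <- stable_hash(paste("atom", at$element, deg, at$n_h, at$charge))
  ids[at$dummy] <- stable_hash("dummy-atom")
  out <- vector("list", radius + 1L)
  out[[1]] <- ids
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      prev <- out[[r]]
      cur <- integer(n)
      for (i in seq_len(n)) {
        nb <- adj$nbrs[[i]]
        if (length(nb)) {
          parts <- sort(paste0(adj$ords[[i]], ":", prev[nb]))
          cur[i] <- stable_hash(paste(prev[i], paste(parts, collapse = ",")))
        } else {
          cur[i] <- stable_hash(paste(prev[i], "leaf"))
        }
      }
      cur[at$dummy] <- stable_hash(paste("dummy-atom", r))
      out[[r + 1L]] <- cur
    }
  }
  out
}

new_fingerprint <- function(bits, n_bits, tag, params) {
  structure(list(bits = sort(unique(as.integer(bits))),
                 n_bits = as.integer(n_bits), tag = tag, params = params),
            class = "sb_fingerprint")
}

#' @exportS3Method base::print
print.sb_fingerprint <- function(x, ...) {
  cat(sprintf("<sb_fingerprint> %s: %d/%d bits set\n", x$tag,
              length(x$bits), x$n_bits))
  invisible(x)
}

#' Morgan (circular-substructure) fingerprint of a ligand
#'
#' @param ligand An `sb_ligand`.
#' @param config A [featurizer_config()].
#' @return An `sb_fingerprint` (0-based set-bit indices).
#' @export
morgan_fingerprint <- function(ligand, config = featurizer_config()) {
  envs <- atom_environments(ligand, config$morgan_radius)
  keep <- !ligand$atoms$dummy
  feats <- unlist(lapply(envs, function(v) v[keep]), use.names = FALSE)
  new_fingerprint(feats %% config$morgan_bits, config$morgan_bits, "morgan",
                  config[c("morgan_radius", "morgan_bits")])
}

#' PLEC-style interaction fingerprint of a synthetic complex
#'
#' Hashes every (ligand atom, synthetic residue) pair with distance strictly
#' below `plec_cutoff`. The residue contributes its type; the ligand atom
#' contributes its circular environments at depths 0..`plec_ligand_depth`.
#' A complex with no pair inside the cutoff yields the zero vector.
#'
#' @param complex An `sb_complex` (see [generate_complex()]).
#' @param config A [featurizer_config()].
#' @return An `sb_fingerprint`.
#' @export
plec_fingerprint <- function(complex, config = featurizer_config()) {
  lig <- complex$ligand
  res <- complex$protein$residues
  if (!nrow(res)) {
    return(new_fingerprint(integer(0), config$plec_bits, "plec",
                           config[c("plec_cutoff", "plec_ligand_depth",
                                    "plec_protein_depth", "plec_bits")]))
  }
  d <- cross_dist(ligand_coords(lig), as.matrix(res[, c("x", "y", "z")]))
  keep_atom <- !lig$atoms$dummy
  pair_idx <- which(d < config$plec_cutoff & keep_atom, arr.ind = TRUE)
  if (!nrow(pair_idx)) {
    return(new_fingerprint(integer(0), config$plec_bits, "plec",
                           config[c("plec_cutoff", "plec_ligand_depth",
                                    "plec_protein_depth", "plec_bits")]))
  }
  envs <- atom_environments(lig, config$plec_ligand_depth)
  feats <- integer(0)
  for (depth in seq_along(envs)) {
    feats <- c(feats, stable_hash(paste("plec", depth - 1L,
                                        envs[[depth]][pair_idx[, 1]],
                                        res$type[pair_idx[, 2]])))
  }
  new_fingerprint(feats %% config$plec_bits, config$plec_bits, "plec",
                  config[c("plec_cutoff", "plec_ligand_depth",
                           "plec_protein_depth", "plec_bits")])
}

#' Mask a ligand atom with a dummy
#'
#' Replaces the indexed heavy atom by a typeless dummy: it keeps its
#' coordinates and bonds but loses its element identity and pharmacophore
#' types, contributes no Morgan environments, and forms no PLEC pairs. The
#' original object is unmodified.
#'
#' @param x An `sb_ligand` or `sb_complex`.
#' @param atom_index 1-based heavy-atom index.
#' @return Masked copy of `x`.
#' @export
mask_atom <- function(x, atom_index) {
  UseMethod("mask_atom")
}

#' @export
mask_atom.sb_ligand <- function(x, atom_index) {
  assert_that(atom_index >= 1 && atom_index <= x$n_heavy,
              sprintf("atom_index %s out of range 1..%d", atom_index, x$n_heavy))
  x$atoms$dummy[atom_index] <- TRUE
  x
}

#' @export
mask_atom.sb_complex <- function(x, atom_index) {
  x$ligand <- mask_atom(x$ligand, atom_index)
  x
}

# --- fingerprint matrices --------------------------------------------------

#' Stack fingerprints into a sparse binary matrix
#'
#' @param fps List of `sb_fingerprint` objects of equal length and tag.
#' @return A `dgCMatrix` (rows = inputs, columns = bits, named `b0..`).
#' @export
fingerprint_matrix <- function(fps) {
  assert_that(length(fps) >= 1, "no fingerprints given")
  n_bits <- fps[[1]]$n_bits
  tags <- unique(vapply(fps, `[[`, character(1), "tag"))
  assert_that(length(tags) == 1 && all(vapply(fps, `[[`, integer(1), "n_bits") == n_bits),
              "fingerprints must share tag and length")
  ii <- rep(seq_along(fps), vapply(fps, function(f) length(f$bits), integer(1)))
  jj <- unlist(lapply(fps, `[[`, "bits"), use.names = FALSE) + 1L
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(fps), n_bits))
  colnames(m) <- paste0("b", seq_len(n_bits) - 1L)
  m
}

#' Persist / restore a fingerprint matrix as text
#'
#' Writes the sparse matrix as (row, bit) index pairs in a CSV plus a JSON
#' sidecar holding the featurizer parameters.
#'
#' @param m `dgCMatrix` from [fingerprint_matrix()].
#' @param path CSV path (`<path>.json` is written alongside).
#' @param params Featurizer parameter list for the sidecar.
#' @export
write_fingerprint_matrix <- function(m, path, params = list()) {
  tr <- Matrix::mat2triplet(m)
  write.csv(data.frame(row = tr$i, bit = tr$j - 1L), path, row.names = FALSE)
  jsonlite::write_json(c(list(n_rows = nrow(m), n_bits = ncol(m)), params),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fingerprint_matrix
#' @export
read_fingerprint_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  df <- read.csv(path)
  m <- Matrix::sparseMatrix(i = df$row, j = df$bit + 1L, x = 1,
                            dims = c(meta$n_rows, meta$n_bits))
  colnames(m) <- paste0("b", seq_len(ncol(m)) - 1L)
  attr(m, "featurizer") <- meta
  m
}

# --- similarity ------------------------------------------------------------

tanimoto_bits <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Similarity and size filter for candidate ligands
#'
#' Retains candidates with at least `min_heavy` heavy atoms whose maximum
#' Tanimoto similarity (2048-bit Morgan radius-2 fingerprints) to every
#' reference ligand is at most `max_tanimoto`. Order is preserved; the
#' filter is idempotent. With an empty reference set only the size criterion
#' applies (logged).
#'
#' @param candidates,references Ligand-set tibbles.
#' @param max_tanimoto Maximum allowed similarity to any reference.
#' @param min_heavy Minimum heavy-atom count.
#' @return Filtered candidate tibble.
#' @export
similarity_and_size_filter <- function(candidates, references,
                                       max_tanimoto = 0.8, min_heavy = 15L) {
  cfg <- featurizer_config()
  keep_size <- candidates$n_heavy >= min_heavy
  if (is.null(references) || nrow(references) == 0) {
    warn("empty reference set: applying size criterion only")
    return(candidates[keep_size, , drop = FALSE])
  }
  ref_bits <- lapply(references$mol, function(m) morgan_fingerprint(m, cfg)$bits)
  keep_sim <- vapply(candidates$mol, function(m) {
    b <- morgan_fingerprint(m, cfg)$bits
    all(vapply(ref_bits, function(r) tanimoto_bits(b, r), numeric(1)) <= max_tanimoto)
  }, logical(1))
  candidates[keep_size & keep_sim, , drop = FALSE]
}
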