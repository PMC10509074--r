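#' Ligand records and ligand sets
#'
#' A ligand is stored as a heavy-atom molecular graph with (optional) 3D
#' coordinates: a tibble of atoms (element, x/y/z in Angstrom, formal charge,
#' attached-hydrogen count) and a tibble of bonds (atom indices and bond
#' order). Hydrogens are implicit everywhere: explicit hydrogens found in an
#' input file are folded into the `n_h` count of their heavy neighbour and
#' dropped, so all geometry and all indexing is heavy-atom only.
#'
#' Ligand *sets* are tibbles with one row per ligand and a `mol` list-column
#' holding the records, so they compose with dplyr verbs and the pipe.
#'
#' @name ligand
NULL

STANDARD_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

# Total hydrogen count per heavy atom from standard valences: implicit H =
# max(0, valence + charge-adjustment - sum of bond orders). Hypervalent S and
# P (sulfones, phosphates) are handled by never assigning negative counts.
hydrogen_counts <- function(element, charge, bond_sum) {
  val <- unname(STANDARD_VALENCE[element])
  val[is.na(val)] <- 0
  adj <- ifelse(element %in% c("N", "P"), charge,
         ifelse(element %in% c("O", "S"), charge, 0))
  pmax(0L, as.integer(round(val + adj - bond_sum)))
}

bond_order_sums <- function(n_atoms, bonds) {
  bs <- numeric(n_atoms)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bs[bonds$a1[k]] <- bs[bonds$a1[k]] + bonds$order[k]
      bs[bonds$a2[k]] <- bs[bonds$a2[k]] + bonds$order[k]
    }
  }
  bs
}

#' Construct a ligand record
#'
#' @param id Ligand identifier.
#' @param atoms Tibble/data frame with columns `element`, `x`, `y`, `z`,
#'   and optionally `charge` (formal charge, default 0) and `n_h`
#'   (attached hydrogens; computed from standard valences when absent).
#' @param bonds Tibble/data frame with columns `a1`, `a2`, `order`
#'   (1-based heavy-atom indices).
#' @param source Free-text provenance (a SMILES string or file record name).
#' @param has_3d Whether the coordinates are a real 3D conformation.
#' @return An object of class `sb_ligand`.
#' @export
new_ligand <- function(id, atoms, bonds, source = NA_character_, has_3d = FALSE) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  if (!"dummy" %in% names(atoms)) atoms$dummy <- FALSE
  n <- nrow(atoms)
  assert_that(n >= 1, "ligand must have at least one heavy atom")
  assert_that(all(is.finite(atoms$x)) && all(is.finite(atoms$y)) && all(is.finite(atoms$z)),
              sprintf("ligand '%s': non-finite coordinates", id))
  if (nrow(bonds)) {
    assert_that(all(bonds$a1 >= 1 & bonds$a1 <= n & bonds$a2 >= 1 & bonds$a2 <= n),
                sprintf("ligand '%s': bond references an invalid atom index", id))
  }
  if (!"n_h" %in% names(atoms)) {
    atoms$n_h <- hydrogen_counts(atoms$element, atoms$charge, bond_order_sums(n, bonds))
  }
  structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         n_heavy = n, source = source, has_3d = isTRUE(has_3d)),
    class = "sb_ligand"
  )
}

#' @exportS3Method base::print
print.sb_ligand <- function(x, ...) {
  cat(sprintf("<sb_ligand> %s: %d heavy atoms, %d bonds, %s\n",
              x$id, x$n_heavy, nrow(x$bonds),
              if (x$has_3d) "3D" else "no 3D conformation"))
  invisible(x)
}

ligand_coords <- function(lig) {
  as.matrix(lig$atoms[, c("x", "y", "z")])
}

# Heavy-atom adjacency list: for atom i, integer vector of bonded atoms and
# parallel vector of bond orders.
ligand_adjacency <- function(lig) {
  n <- lig$n_heavy
  nbrs <- vector("list", n)
  ords <- vector("list", n)
  b <- lig$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$a1[k]; j <- b$a2[k]; o <- b$order[k]
      nbrs[[i]] <- c(nbrs[[i]], j); ords[[i]] <- c(ords[[i]], o)
      nbrs[[j]] <- c(nbrs[[j]], i); ords[[j]] <- c(ords[[j]], o)
    }
  }
  list(nbrs = nbrs, ords = ords)
}

#' Bundle ligand records into a ligand-set tibble
#'
#' @param mols List of `sb_ligand` records.
#' @return Tibble with columns `id`, `n_heavy`, `has_3d`, `source` and the
#'   list-column `mol`.
#' @export
ligand_set <- function(mols) {
  tibble::tibble(
    id = vapply(mols, function(m) m$id, character(1)),
    n_heavy = vapply(mols, function(m) m$n_heavy, integer(1)),
    has_3d = vapply(mols, function(m) m$has_3d, logical(1)),
    source = vapply(mols, function(m) m$source %||% NA_character_, character(1)),
    mol = mols
  )
}

# --- parsing ---------------------------------------------------------------

sdfset_to_ligands <- function(sdfset, fallback_ids = NULL) {
  mols <- vector("list", length(sdfset))
  keep <- logical(length(sdfset))
  for (i in seq_along(sdfset)) {
    lig <- tryCatch(sdf_to_ligand(sdfset[[i]], fallback_ids[i]),
                    error = function(e) {
                      warn(sprintf("skipping record %d: %s", i, conditionMessage(e)))
                      NULL
                    })
    if (!is.null(lig)) { mols[[i]] <- lig; keep[i] <- TRUE }
  }
  mols[keep]
}

sdf_to_ligand <- function(sdf, fallback_id = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  info <- ChemmineR::bonds(sdf)
  element <- sub("_.*$", "", rownames(ab))
  atoms <- tibble::tibble(
    element = element,
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    charge = as.integer(info$charge)
  )
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
  } else {
    tibble::tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }
  db <- ChemmineR::datablock(sdf)
  # tag names may carry record-number suffixes ("smiles  (1) ")
  names(db) <- sub("\\s.*$", "", names(db))
  # formal charges can arrive as an SD tag (written by the embedding helper,
  # whose molblocks carry charge only in M CHG lines)
  if ("atom_charges" %in% names(db)) {
    ch <- as.integer(strsplit(trimws(db[["atom_charges"]]), "\\s+")[[1]])
    if (length(ch) == nrow(atoms)) atoms$charge <- ch
  }
  # fold explicit hydrogens into their heavy neighbour
  is_h <- atoms$element == "H"
  if (any(is_h)) {
    n_exp_h <- integer(nrow(atoms))
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]
      if (is_h[i] && !is_h[j]) n_exp_h[j] <- n_exp_h[j] + 1L
      if (is_h[j] && !is_h[i]) n_exp_h[i] <- n_exp_h[i] + 1L
    }
    newidx <- cumsum(!is_h)
    bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
    bonds$a1 <- newidx[bonds$a1]; bonds$a2 <- newidx[bonds$a2]
    atoms <- atoms[!is_h, , drop = FALSE]
    bs <- bond_order_sums(nrow(atoms), bonds)
    atoms$n_h <- n_exp_h[!is_h] +
      hydrogen_counts(atoms$element, atoms$charge, bs + n_exp_h[!is_h])
  }
  name <- ChemmineR::header(sdf)[["Molecule_Name"]]
  if (is.null(name) || !nzchar(trimws(name))) name <- fallback_id %||% "mol"
  smi <- if ("smiles" %in% names(db)) db[["smiles"]] else NA_character_
  new_ligand(trimws(name), atoms, bonds, source = smi,
             has_3d = any(abs(atoms$z) > 1e-6))
}

#' Load ligands from a SMILES or SDF file
#'
#' SMILES files hold one record per line (`SMILES` optionally followed by an
#' id, whitespace-separated). Records that fail chemistry parsing are skipped
#' with a warning. Ligands lacking 3D coordinates are flagged
#' (`has_3d = FALSE`) and must pass through [embed_ligands()] before dataset
#' construction.
#'
#' @param path File path.
#' @param format `"smiles"` or `"sdf"`.
#' @return A ligand-set tibble (see [ligand_set()]).
#' @export
load_ligands <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) abort("no records in SMILES file")
    parts <- strsplit(trimws(lines), "\\s+")
    smis <- vapply(parts, `[[`, character(1), 1)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][[2]] else sprintf("mol%d", i)
    }, character(1))
    mols <- parse_smiles(smis, ids)
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    mols <- sdfset_to_ligands(sdfset,
                              fallback_ids = sprintf("mol%d", seq_along(sdfset)))
  }
  if (!length(mols)) abort(sprintf("no valid ligand records in %s", path))
  ligand_set(mols)
}

# SMILES -> ligand records via OpenBabel (ChemmineOB); invalid SMILES are
# skipped with a warning.
parse_smiles <- function(smis, ids) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("ChemmineOB is required to parse SMILES")
  }
  mols <- list()
  # batch conversion; fall back to per-record on failure so one bad SMILES
  # does not sink the batch
  sdfset <- tryCatch(ChemmineR::smiles2sdf(setNames(smis, ids)),
                     error = function(e) NULL)
  if (!is.null(sdfset) && length(sdfset) == length(smis)) {
    for (i in seq_along(sdfset)) {
      lig <- tryCatch(sdf_to_ligand(sdfset[[i]], ids[i]), error = function(e) NULL)
      if (is.null(lig)) { warn(sprintf("skipping unparseable SMILES '%s'", smis[i])); next }
      lig$source <- smis[i]
      mols[[length(mols) + 1L]] <- lig
    }
  } else {
    for (i in seq_along(smis)) {
      one <- tryCatch(ChemmineR::smiles2sdf(setNames(smis[i], ids[i])),
                      error = function(e) NULL)
      lig <- if (!is.null(one)) tryCatch(sdf_to_ligand(one[[1]], ids[i]),
                                         error = function(e) NULL) else NULL
      if (is.null(lig)) { warn(sprintf("skipping unparseable SMILES '%s'", smis[i])); next }
      lig$source <- smis[i]
      mols[[length(mols) + 1L]] <- lig
    }
  }
  mols
}

# --- writing ---------------------------------------------------------------

# V2000 molblock text for a ligand (fixed-column layout). Dummy atoms are
# written with the conventional "*" symbol.
ligand_to_molblock <- function(lig) {
  at <- lig$atoms
  sym <- ifelse(at$dummy, "*", at$element)
  natoms <- nrow(at); nbonds <- nrow(lig$bonds)
  chg_lines <- character(0)
  charged <- which(at$charge != 0 & !at$dummy)
  if (length(charged)) {
    chg_lines <- vapply(charged, function(i) {
      sprintf("M  CHG  1 %3d %3d", i, at$charge[i])
    }, character(1))
  }
  c(
    lig$id,
    "  synthbind",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", natoms, nbonds),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            at$x, at$y, at$z, sym),
    if (nbonds) sprintf("%3d%3d%3d  0  0  0  0",
                        lig$bonds$a1, lig$bonds$a2, lig$bonds$order),
    chg_lines,
    "M  END"
  )
}

#' Write ligands to an SDF file
#'
#' @param ligands Ligand-set tibble.
#' @param path Output path.
#' @param data Optional named list (per ligand) of SD tag vectors.
#' @export
write_ligands_sdf <- function(ligands, path, data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ligands))) {
    lig <- ligands$mol[[i]]
    lines <- ligand_to_molblock(lig)
    tags <- character(0)
    if (!is.na(lig$source %||% NA_character_)) {
      tags <- c(tags, "> <smiles>", lig$source, "")
    }
    if (!is.null(data) && !is.null(data[[i]])) {
      for (nm in names(data[[i]])) {
        tags <- c(tags, sprintf("> <%s>", nm), as.character(data[[i]][[nm]]), "")
      }
    }
    writeLines(c(lines, tags, "$$$$"), con)
  }
  invisible(path)
}
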