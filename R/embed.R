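#' Seeded 3D conformer embedding
#'
#' Generates one 3D conformation per ligand with the ETKDG distance-geometry
#' method (seeded per molecule, so a fixed seed reproduces coordinates
#' exactly). Embedding runs in a single batched subprocess through the
#' bundled helper script; molecules that cannot be embedded are dropped with
#' a warning.
#'
#' @param ligands Ligand-set tibble (needs a SMILES `source` per ligand;
#'   ligands loaded from SMILES files or the fixture generator carry one).
#' @param seed Integer seed; per-molecule seeds are derived from it.
#' @return The ligand-set tibble with 3D `mol` records (`has_3d = TRUE`),
#'   in input order, minus any embedding failures.
#' @export
embed_ligands <- function(ligands, seed) {
  assert_that(nrow(ligands) >= 1, "no ligands to embed")
  smis <- ligands$source
  missing_src <- is.na(smis)
  if (any(missing_src)) {
    abort(sprintf("%d ligand(s) have no SMILES source; cannot embed",
                  sum(missing_src)))
  }
  infile <- tempfile(fileext = ".tsv")
  outfile <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  seeds <- vapply(seq_len(nrow(ligands)),
                  function(i) derive_seed(seed, i, "embed"), integer(1))
  writeLines(paste(ligands$id, smis, seeds, sep = "\t"), infile)
  run_embed_helper(infile, outfile)
  sdfset <- ChemmineR::read.SDFset(outfile)
  mols <- sdfset_to_ligands(sdfset)
  for (i in seq_along(mols)) mols[[i]]$has_3d <- TRUE
  out <- ligand_set(mols)
  n_fail <- nrow(ligands) - nrow(out)
  if (n_fail > 0) {
    warn(sprintf("%d ligand(s) failed 3D embedding and were dropped", n_fail))
  }
  if (!nrow(out)) abort("all ligands failed 3D embedding")
  out
}

#' Embed a single ligand record
#'
#' Convenience wrapper over [embed_ligands()] for one molecule.
#'
#' @param ligand An `sb_ligand` with a SMILES source.
#' @param seed Integer seed.
#' @return The embedded `sb_ligand`.
#' @export
embed_3d <- function(ligand, seed) {
  out <- embed_ligands(ligand_set(list(ligand)), seed)
  out$mol[[1]]
}

run_embed_helper <- function(infile, outfile) {
  script <- system.file("python", "embed_smiles.py", package = "synthbind")
  assert_that(nzchar(script), "embedding helper script not found")
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  assert_that(nzchar(python), "no python interpreter on PATH for 3D embedding")
  status <- system2(python, c(shQuote(script),
                              "--infile", shQuote(infile),
                              "--outfile", shQuote(outfile)),
                    stdout = FALSE, stderr = FALSE)
  assert_that(identical(status, 0L),
              sprintf("3D embedding helper exited with status %s", status))
  invisible(outfile)
}
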