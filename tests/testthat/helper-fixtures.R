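# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A dozen embedded drug-like fixture ligands for unit tests.
small_ligands <- function() {
  memo("small_ligands", function() {
    embed_ligands(generate_fixture_ligands(12, seed = 101), seed = 202)
  })
}

# Parse single molecules from SMILES through the package's reader.
smiles_ligand <- function(smiles, id = "mol") {
  path <- tempfile(fileext = ".smi")
  writeLines(paste(smiles, id), path)
  on.exit(unlink(path))
  load_ligands(path, "smiles")$mol[[1]]
}

ethanol <- function() memo("ethanol", function() smiles_ligand("CCO", "ethanol"))
benzene <- function() memo("benzene", function() smiles_ligand("c1ccccc1", "benzene"))
ethane <- function() memo("ethane", function() smiles_ligand("CC", "ethane"))

# Hand-built ligand with exact coordinates: a 4-atom amide-like fragment
# N-C(=O)-C with known donor (N), acceptor (O) and hydrophobe (terminal C).
toy_ligand <- function() {
  new_ligand(
    id = "toy",
    atoms = tibble::tibble(
      element = c("N", "C", "O", "C"),
      x = c(0, 1.4, 2.0, 2.1),
      y = c(0, 0, 1.0, -1.3),
      z = c(0, 0, 0, 0.2)
    ),
    bonds = tibble::tibble(a1 = c(1, 2, 2), a2 = c(2, 3, 4),
                           order = c(1L, 2L, 1L)),
    source = "NC(=O)C", has_3d = TRUE
  )
}

# Protein with residues at fixed positions (types and coordinates chosen by
# the caller); bypasses sampling for exact-rule tests.
fixed_protein <- function(coords, types, ligand, pad = 5) {
  structure(list(
    residues = tibble::tibble(x = coords[, 1], y = coords[, 2],
                              z = coords[, 3], type = types),
    box = make_box(ligand, pad), n_res_cap = length(types)
  ), class = "sb_protein")
}

toy_complex <- function(coords, types, rule = "polar",
                        config = generation_config(rule), ligand = toy_ligand()) {
  assignment <- assign_pharmacophores(ligand, rule)
  protein <- fixed_protein(matrix(coords, ncol = 3, byrow = TRUE), types, ligand,
                           pad = config$pad)
  synthbind:::build_complex(ligand, assignment, protein, config, seed = 0L)
}

# Brute-force oracles, independent of the package implementations ---------

# pair-concordance Attribution AUC by explicit double loop
oracle_attribution_auc <- function(scores, binder) {
  num <- 0; den <- 0
  for (i in which(binder)) {
    for (j in which(!binder)) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# Polar rule by explicit double loop over residues and atoms
oracle_polar_label <- function(complex) {
  res <- complex$protein$residues
  xyz <- synthbind:::ligand_coords(complex$ligand)
  asg <- complex$assignment
  hits <- 0L
  for (r in seq_len(nrow(res))) {
    for (a in seq_len(nrow(xyz))) {
      d <- sqrt(sum((as.numeric(res[r, c("x", "y", "z")]) - xyz[a, ])^2))
      ok <- (res$type[r] == "HBD" && asg$acceptor[a]) ||
            (res$type[r] == "HBA" && asg$donor[a])
      if (ok && d < complex$config$polar_cutoff) hits <- hits + 1L
    }
  }
  if (hits > 0) "active" else "inactive"
}

# Gamma(4,1) density from first principles (not via dgamma)
oracle_gamma4_pdf <- function(d) d^3 * exp(-d) / factorial(3)
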