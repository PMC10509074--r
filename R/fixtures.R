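#' Offline fixture ligand generation
#'
#' Enumerates small drug-like ligands from an embedded panel of SMILES
#' templates, each carrying two aromatic substitution sites filled from a
#' fixed substituent alphabet. Every template contains at least one hydrogen
#' bond donor or acceptor, so every fixture ligand has `n_lig >= 1` under
#' either binding rule, and the combinations span roughly 10-40 heavy atoms.
#' The panel stands in for the public ligand collections a benchmark would
#' normally draw on, so that every pipeline stage runs offline.
#'
#' @name fixtures
NULL

# Templates: two %s slots on aromatic carbons. Each core is a drug-sized
# two-ring scaffold (16-24 heavy atoms) with built-in polar groups (amides,
# ureas, sulfonamides, acids, phenols), sized like typical screening-library
# molecules so the padded box volumes match drug-like ligands.
FIXTURE_TEMPLATES <- c(
  "CC(=O)Nc1ccc(C(=O)Nc2ccc(%s)cc2%s)cc1",
  "O=C(Nc1ccc(%s)cc1)c1ccc(S(=O)(=O)N2CCOCC2)cc1%s",
  "COc1ccc(CCNC(=O)c2ccc(%s)cc2%s)cc1OC",
  "Oc1ccc(%s)cc1CC(=O)N1CCN(c2ccccc2%s)CC1",
  "NS(=O)(=O)c1ccc(NC(=O)c2ccc(%s)cc2%s)cc1",
  "OC(=O)c1ccc(Oc2ccc(%s)cc2%s)cc1",
  "NC(=O)c1ccc(OCc2ccc(%s)cc2%s)nc1",
  "CN(C)C(=O)c1ccc(NC(=O)c2ccc(%s)cc2%s)cc1",
  "O=C(NCc1ccccc1)Nc1ccc(%s)cc1%s",
  "COc1cc(%s)ccc1NC(=O)c1ccc(CN2CCOCC2)cc1%s",
  "CC(N)C(=O)Nc1ccc(Oc2ccc(%s)cc2%s)cc1",
  "O=S(=O)(N1CCCC1)c1ccc(NC(=O)c2ccc(%s)cc2%s)cc1",
  "Oc1ccc(-c2ccc(NC(=O)c3ccc(%s)cc3%s)cc2)cc1",
  "COC(=O)c1ccc(NC(=O)c2cc(%s)ccc2%s)cc1",
  "O=C(Nc1ccc(CN2CCOCC2)cc1)c1ccc(%s)cc1%s"
)

FIXTURE_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "C(C)C", "CO", "CCO", "OC", "OCC", "O", "N", "NC",
  "F", "Cl", "Br", "C#N", "C(=O)C", "C(=O)OC", "S(=O)(=O)C"
)

fixture_space_size <- function() {
  length(FIXTURE_TEMPLATES) * length(FIXTURE_SUBSTITUENTS)^2
}

fixture_combinations <- function() {
  expand.grid(t = seq_along(FIXTURE_TEMPLATES),
              s1 = seq_along(FIXTURE_SUBSTITUENTS),
              s2 = seq_along(FIXTURE_SUBSTITUENTS), KEEP.OUT.ATTRS = FALSE)
}

#' Generate fixture ligands
#'
#' Draws `n` distinct ligands (seeded, without replacement) from the
#' enumerable template-substituent space. Returned ligands are 2D molecular
#' graphs; pass them through [embed_ligands()] for 3D conformations.
#'
#' @param n Number of ligands (at most [fixture_space_size()]).
#' @param seed Integer seed; same seed reproduces the same set.
#' @return A ligand-set tibble.
#' @export
generate_fixture_ligands <- function(n, seed) {
  assert_that(n >= 1, "n must be >= 1")
  space <- fixture_combinations()
  if (n > nrow(space)) {
    abort(sprintf("n = %d exceeds the enumerable fixture space (maximum %d)",
                  n, nrow(space)))
  }
  pick <- with_seed(derive_seed(seed, 0L, "fixture"),
                    space[sample.int(nrow(space), n), , drop = FALSE])
  smis <- sprintf(FIXTURE_TEMPLATES[pick$t],
                  FIXTURE_SUBSTITUENTS[pick$s1], FIXTURE_SUBSTITUENTS[pick$s2])
  ids <- sprintf("fix_t%02d_s%02d_s%02d", pick$t, pick$s1, pick$s2)
  mols <- parse_smiles(smis, ids)
  assert_that(length(mols) == n, "fixture panel produced unparseable SMILES")
  ligand_set(mols)
}
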