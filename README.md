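# synthbind

Synthetic protein–ligand benchmarks for virtual-screening attribution.

## The problem

Machine-learning virtual-screening models frequently separate actives from
decoys by exploiting ligand-specific dataset biases rather than by
recognising protein–ligand interactions — and on real data there is no
ground truth for which ligand atoms actually matter, so the failure is hard
to measure. `synthbind` builds datasets where that ground truth is exact: it
surrounds each 3D ligand with a randomly sampled point cloud of typed
pharmacophores (a "synthetic protein") and labels the complex with a
deterministic binding rule. The package is for method developers who want to
quantify whether their model's per-atom attributions recover the atoms that
actually drive the label.

Two rules are provided. The **Polar** rule types residues HBA/HBD and calls
a complex active iff any complementary residue/atom pair (HBD residue ↔
Acceptor atom, HBA ↔ Donor) lies strictly within 4 Å. The **Contribution**
rule adds Hydrophobic residues and scores each same-typed pair

    score(pair) = w · f(d),   f = Gamma(4, 1) density,  w = 10 (H-bond) or 3 (hydrophobic),

labelling the complex active iff the summed score exceeds 4; the per-atom
ground truth is the atom's summed score. Residue counts are capped at
`floor(50 / n_lig)` so the number of interaction opportunities does not leak
the ligand's functional-group count.

On top of the generator the package provides Morgan and PLEC-style
fingerprint featurizers, seeded random-forest baselines (`RF_Morgan`,
`RF_PLEC_n`), atom-masking attributions `s_i = score(m) − score(m \ i)`, and
ranking metrics against ground truth: Attribution AUC (binder/non-binder
pair concordance), Spearman's ρ, MATR curves (mean rank of above-threshold
atoms), and RER (MATR relative to the perfect ranking; 1.00 is optimal).

## A worked example

```r
library(synthbind)

ligands <- generate_fixture_ligands(400, seed = 42) |>
  embed_ligands(seed = 7)

polar <- run_dataset_build(ligands, generation_config("polar"), seed = 5)
polar$active_fraction
#> [1] 0.575

# ligand-only baseline vs. a cutoff-matched PLEC model
bench <- run_benchmark(polar$complexes, test_size = 100,
                       cutoffs = c(3, 4, 5), num_trees = 300, seed = 11)
bench[, c("model", "cutoff", "accuracy", "au_prc")]
#>   model       cutoff accuracy au_prc
#> 1 RF_Morgan       NA     0.55   0.64
#> 2 RF_PLEC_3        3     0.71   0.88
#> 3 RF_PLEC_4        4     0.92   0.99
#> 4 RF_PLEC_5        5     0.75   0.83
```

The Morgan forest sees only the ligand and sits near chance — the dataset
carries no ligand signal by construction. The PLEC forest whose distance
cutoff matches the 4 Å binding rule almost recovers the rule; mismatched
cutoffs degrade sharply on both accuracy and attribution quality, which is
the package's central diagnostic. (Numbers above are from a 400-ligand run;
they wobble by a few hundredths across seeds.)

Attributions against ground truth:

```r
m4 <- attr(bench, "models")$RF_PLEC_4
acts <- complex_set(purrr::compact(lapply(seq_len(50), function(i)
  generate_conditioned(ligands$mol[[i]], generation_config("polar"),
                       "active", 100, seed = 1000 + i))))
attrs <- lapply(acts$complex, function(cx) masking_attributions(m4, cx)$s)
glance(metrics_report(attrs, acts))
#> mean_attribution_auc = 0.967: the interacting atoms rank at the top
```

A thin CLI over the same functions lives at
`inst/cli/synthbind.R` (subcommands `generate`, `bias-match`, `testset`,
`benchmark`, `perturb`, `evaluate`).

## Scope

The binding rules are intentionally simple surrogates (point residues, no
directional H-bonds, no solvation): the package benchmarks whether models
can *capture and use spatial information*, not whether they reproduce
physics. Deep-learning scoring models themselves are out of scope — bring
your own model, featurize with the provided fingerprints or your own, and
score its attributions with the metrics here.
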