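test_that("box construction pads the heavy-atom extremes", {
  lig <- new_ligand("boxy",
                    tibble::tibble(element = c("C", "C"),
                                   x = c(1, 4), y = c(0, 3), z = c(-1, 2)),
                    tibble::tibble(a1 = 1L, a2 = 2L, order = 1L),
                    has_3d = TRUE)
  box <- make_box(lig, pad = 5)
  expect_equal(unname(box$lo[1]), -4)
  expect_equal(unname(box$hi[1]), 9)
  expect_equal(box$volume, 13^3)   # 3 A span + 2 * 5 A pad per axis

  box0 <- make_box(lig, pad = 0)
  expect_equal(unname(box0$lo), c(1, 0, -1))
  expect_equal(unname(box0$hi), c(4, 3, 2))

  single <- new_ligand("one", tibble::tibble(element = "C", x = 0, y = 0, z = 0),
                       tibble::tibble(a1 = integer(), a2 = integer(), order = integer()),
                       has_3d = TRUE)
  expect_equal(make_box(single, pad = 5)$volume, 10^3)
})

test_that("protein sampling respects the residue budget and geometry", {
  lig <- small_ligands()$mol[[1]]
  cfg <- generation_config("polar")
  asg <- assign_pharmacophores(lig, "polar")
  prot <- sample_synthetic_protein(lig, asg, cfg, seed = 11)
  expect_lte(nrow(prot$residues), floor(cfg$n_ops / n_lig(asg)))
  expect_true(all(prot$residues$type %in% c("HBA", "HBD")))

  prot2 <- sample_synthetic_protein(lig, asg, cfg, seed = 11)
  expect_identical(prot$residues, prot2$residues)

  # n_lig = 0 ligands are rejected before generation
  asg0 <- assign_pharmacophores(ethane(), "polar")
  e3 <- embed_3d(ethane(), seed = 1)
  expect_error(sample_synthetic_protein(e3, asg0, cfg, seed = 1), "n_lig = 0")
})

test_that("geometry invariants hold across seeds and rules", {
  ligs <- small_ligands()$mol[1:3]
  for (rule in c("polar", "contribution")) {
    cfg <- generation_config(rule)
    for (s in 1:20) {
      lig <- ligs[[(s %% 3) + 1]]
      cx <- generate_complex(lig, cfg, seed = 5000 + s)
      res <- cx$protein$residues
      if (!nrow(res)) next
      rxyz <- as.matrix(res[, c("x", "y", "z")])
      d_lig <- synthbind:::cross_dist(rxyz, synthbind:::ligand_coords(lig))
      expect_gte(min(d_lig), cfg$clash_dist)
      if (nrow(res) > 1) {
        d_rr <- as.matrix(dist(rxyz))
        expect_gte(min(d_rr[upper.tri(d_rr)]), cfg$min_sep)
      }
      box <- cx$protein$box
      expect_true(all(t(rxyz) >= box$lo & t(rxyz) <= box$hi))
    }
  }
})

test_that("interaction score is the weighted Gamma(4,1) density", {
  cfg <- generation_config("contribution")
  # frozen values from the independent density d^3 exp(-d)/3!
  expect_equal(interaction_score("HBond", 3, cfg), 10 * oracle_gamma4_pdf(3),
               tolerance = 1e-12)
  expect_equal(interaction_score("HBond", 3, cfg), 2.240418, tolerance = 1e-6)
  expect_equal(interaction_score("Hydrophobic", 3, cfg), 0.6721254,
               tolerance = 1e-6)

  d <- seq(0.2, 14, by = 0.2)
  expect_equal(interaction_score("HBond", d, cfg) /
                 interaction_score("Hydrophobic", d, cfg),
               rep(10 / 3, length(d)))

  # positive and unimodal with mode at d = 3
  s <- interaction_score("HBond", d, cfg)
  expect_true(all(s > 0))
  rising <- d < 3
  expect_true(all(diff(s[rising]) > 0))
  expect_true(all(diff(s[d >= 3]) < 0))
  expect_error(interaction_score("HBond", 0, cfg), "distance")
})

test_that("polar rule matches its printed examples and strict cutoff", {
  # donor N at origin; HBA residue 2.8 A away -> active
  cx <- toy_complex(c(0, 0, 2.8), "HBA")
  expect_equal(cx$label, "active")
  expect_equal(nrow(cx$records), 1)
  expect_equal(cx$records$atom_idx, 1L)
  expect_equal(cx$contributions, c(1, 0, 0, 0))

  # acceptor O with its nearest HBD residue 4.5 A away -> no record
  cx2 <- toy_complex(c(2.0, 1.0, 4.5), "HBD")
  expect_equal(cx2$label, "inactive")
  expect_equal(nrow(cx2$records), 0)

  # boundary: exactly at the cutoff is excluded (strict <)
  cx3 <- toy_complex(c(0, 0, 4.0), "HBA")
  expect_equal(cx3$label, "inactive")
  cx4 <- toy_complex(c(0, 0, 3.999), "HBA")
  expect_equal(cx4$label, "active")

  # empty protein -> inactive with zero records
  lig <- toy_ligand()
  asg <- assign_pharmacophores(lig, "polar")
  empty <- fixed_protein(matrix(numeric(0), ncol = 3), character(0), lig)
  ev <- evaluate_polar(lig, asg, empty, generation_config("polar"))
  expect_equal(ev$label, "inactive")
  expect_equal(nrow(ev$records), 0)
})

test_that("polar evaluation agrees with a brute-force double loop", {
  ligs <- small_ligands()$mol[1:4]
  cfg <- generation_config("polar")
  for (s in 1:100) {
    cx <- generate_complex(ligs[[(s %% 4) + 1]], cfg, seed = 9000 + s)
    expect_identical(cx$label, oracle_polar_label(cx), label = paste("seed", s))
  }
})

test_that("polar monotonicity: residues only ever add interactions", {
  cfg <- generation_config("polar")
  lig <- small_ligands()$mol[[2]]
  asg <- assign_pharmacophores(lig, "polar")
  for (s in 1:20) {
    cx <- generate_complex(lig, cfg, seed = 300 + s)
    res <- cx$protein$residues
    if (nrow(res) < 2) next
    # deleting a residue never flips inactive -> active
    sub <- fixed_protein(as.matrix(res[-1, c("x", "y", "z")]), res$type[-1], lig)
    ev_sub <- evaluate_polar(lig, asg, sub, cfg)
    if (cx$label == "inactive") expect_equal(ev_sub$label, "inactive")
    # adding a residue never flips active -> inactive
    far <- rbind(as.matrix(res[, c("x", "y", "z")]),
                 matrix(cx$protein$box$hi, ncol = 3))
    sup <- fixed_protein(far, c(res$type, "HBA"), lig)
    ev_sup <- evaluate_polar(lig, asg, sup, cfg)
    if (cx$label == "active") expect_equal(ev_sup$label, "active")
  }
})

test_that("contribution rule scores, conserves, and thresholds correctly", {
  cfg <- generation_config("contribution")
  # a single hydrogen bond at the density mode cannot activate; under the
  # contribution rule HBA residues pair with Acceptor atoms, and the toy
  # ligand's only acceptor is its carbonyl O at (2, 1, 0)
  cx1 <- toy_complex(c(2, 1, 3), "HBA", rule = "contribution", config = cfg)
  expect_equal(nrow(cx1$records), 1)
  expect_equal(cx1$total_score, 2.240418, tolerance = 1e-6)
  expect_equal(cx1$label, "inactive")

  # two such interactions exceed the threshold
  cx2 <- toy_complex(c(2, 1, 3, 2, 1, -3), c("HBA", "HBA"),
                     rule = "contribution", config = cfg)
  expect_equal(cx2$total_score, 4.480836, tolerance = 1e-6)
  expect_equal(cx2$label, "active")

  # mismatched types score zero: hydrophobic residues around polar atoms
  lig <- ethanol() |> embed_3d(seed = 3)
  asg <- assign_pharmacophores(lig, "contribution")
  pos <- synthbind:::ligand_coords(lig)[3, ] + c(0, 0, 3)
  prot <- fixed_protein(matrix(pos, ncol = 3), "Hydrophobic", lig)
  ev <- evaluate_contribution(lig, asg, prot, cfg)
  # ethanol's carbons are hydrophobes, so only pairs with the O are empty;
  # restrict to a purely polar ligand: the toy amide N/O with hydrophobic residue
  toy <- toy_ligand()
  asg_t <- assign_pharmacophores(toy, "contribution")
  prot_t <- fixed_protein(matrix(c(0, 0, 3), ncol = 3), "Hydrophobic", toy)
  ev_t <- evaluate_contribution(toy, asg_t, prot_t, cfg)
  # record exists only for the hydrophobe atom 4, none for N/O
  expect_true(all(ev_t$records$atom_idx == 4))

  # no hard distance cutoff: a remote residue still scores (tiny but nonzero)
  far <- toy_complex(c(2, 1, 14), "HBA", rule = "contribution", config = cfg)
  expect_gt(far$total_score, 0)
  expect_lt(far$total_score, 1e-2)
})

test_that("contribution score conservation holds to 1e-9 relative", {
  cfg <- generation_config("contribution")
  ligs <- small_ligands()$mol
  for (s in 1:30) {
    cx <- generate_complex(ligs[[(s %% 12) + 1]], cfg, seed = 700 + s)
    if (!nrow(cx$records)) next
    expect_equal(cx$total_score, sum(cx$records$score), tolerance = 1e-9)
    expect_equal(cx$total_score, sum(cx$contributions), tolerance = 1e-9)
  }
})

test_that("complex generation is deterministic and rigid-motion invariant", {
  lig <- small_ligands()$mol[[4]]
  cfg <- generation_config("contribution")
  a <- generate_complex(lig, cfg, seed = 77)
  b <- generate_complex(lig, cfg, seed = 77)
  expect_identical(a$label, b$label)
  expect_identical(a$protein$residues, b$protein$residues)
  expect_identical(a$contributions, b$contributions)

  # rotate + translate ligand and protein jointly: label and scores unchanged
  theta <- 0.83
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  shift <- c(5, -2, 9)
  lig2 <- lig
  xyz <- synthbind:::ligand_coords(lig) %*% t(R)
  lig2$atoms$x <- xyz[, 1] + shift[1]
  lig2$atoms$y <- xyz[, 2] + shift[2]
  lig2$atoms$z <- xyz[, 3] + shift[3]
  rxyz <- as.matrix(a$protein$residues[, c("x", "y", "z")]) %*% t(R)
  prot2 <- fixed_protein(sweep(rxyz, 2, shift, "+"), a$protein$residues$type, lig2)
  asg <- assign_pharmacophores(lig2, "contribution")
  ev2 <- evaluate_contribution(lig2, asg, prot2, cfg)
  expect_equal(ev2$label, a$label)
  expect_equal(ev2$contributions, a$contributions, tolerance = 1e-9)

  # polar indicators live only on donor/acceptor atoms
  cfgp <- generation_config("polar")
  for (s in 1:10) {
    cx <- generate_complex(lig, cfgp, seed = 40 + s)
    polar_atoms <- cx$assignment$donor | cx$assignment$acceptor
    expect_true(all(cx$contributions[!polar_atoms] == 0))
  }
})

test_that("conditioned generation returns matches or a discard signal", {
  lig <- small_ligands()$mol[[5]]
  cfg <- generation_config("polar")
  cx <- generate_conditioned(lig, cfg, "active", max_attempts = 100L, seed = 8)
  expect_false(is.null(cx))
  expect_equal(cx$label, "active")
  expect_gte(attr(cx, "attempts"), 1L)

  # an unattainable target: contribution rule with an absurd threshold
  cfg_hard <- generation_config("contribution", score_threshold = 1e9)
  d1 <- generate_conditioned(lig, cfg_hard, "active", max_attempts = 5L, seed = 8)
  expect_null(d1)

  # same seed, same trajectory
  cx2 <- generate_conditioned(lig, cfg, "active", max_attempts = 100L, seed = 8)
  expect_equal(attr(cx2, "attempts"), attr(cx, "attempts"))
  expect_identical(cx2$protein$residues, cx$protein$residues)
  expect_error(generate_conditioned(lig, cfg, "active", max_attempts = 0L),
               "max_attempts")
})

test_that("complex serialization round-trips through SDF/PDB/CSV", {
  lig <- small_ligands()$mol[[6]]
  cfg <- generation_config("contribution")
  cx <- generate_complex(lig, cfg, seed = 55)
  dir <- tempfile("cxio")
  paths <- write_complex(cx, dir)
  expect_true(all(file.exists(paths)))
  n_het <- sum(grepl("^HETATM", readLines(paths[["protein"]])))
  expect_equal(n_het, nrow(cx$protein$residues))

  back <- read_complex(dir, cx$id, cfg)
  expect_equal(back$label, cx$label)
  expect_equal(back$protein$residues$type, cx$protein$residues$type)
  expect_equal(as.matrix(back$protein$residues[, c("x", "y", "z")]),
               as.matrix(cx$protein$residues[, c("x", "y", "z")]),
               tolerance = 5e-4, ignore_attr = TRUE)
  expect_equal(max(abs(synthbind:::ligand_coords(back$ligand) -
                         synthbind:::ligand_coords(cx$ligand))), 0,
               tolerance = 5e-4)

  # empty protein still writes and reads a valid PDB
  toy <- toy_ligand()
  asg <- assign_pharmacophores(toy, "polar")
  empty <- fixed_protein(matrix(numeric(0), ncol = 3), character(0), toy)
  cx0 <- synthbind:::build_complex(toy, asg, empty, generation_config("polar"), 1L)
  p0 <- write_complex(cx0, dir)
  expect_equal(sum(grepl("^HETATM", readLines(p0[["protein"]]))), 0)
  back0 <- read_complex(dir, cx0$id, generation_config("polar"))
  expect_equal(nrow(back0$protein$residues), 0)
  expect_equal(back0$label, "inactive")
})

test_that("generation config round-trips through its key-value file", {
  cfg <- generation_config("contribution", a_coef = 0.07, n_ops = 40L)
  path <- tempfile(fileext = ".cfg")
  write_generation_config(cfg, path)
  back <- read_generation_config(path)
  expect_equal(back$rule, "contribution")
  expect_equal(back$a_coef, 0.07)
  expect_equal(back$n_ops, 40L)
  expect_equal(back$hb_weight, cfg$hb_weight)
})
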