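#' Synthetic protein generation and deterministic binding rules
#'
#' A synthetic protein is a point cloud of typed pseudo-residues
#' \{(x_i, y_i, z_i, t_i)\} sampled uniformly in a padded box around a 3D
#' ligand. Two deterministic rules label the resulting complex:
#'
#' * **Polar rule**: residues are typed HBA or HBD; the complex is active iff
#'   any complementary residue/atom pair (HBD residue with an Acceptor atom,
#'   HBA residue with a Donor atom) lies strictly within the polar cutoff
#'   (4 Angstrom).
#' * **Contribution rule**: residues are typed HBA, HBD or Hydrophobic; each
#'   same-typed residue/atom pair scores `w * f(d)` where `f` is the
#'   Gamma(4, 1) probability density of the pair distance `d` and `w` is 10
#'   for hydrogen bonds and 3 for hydrophobic contacts. The complex is active
#'   iff the summed score exceeds the score threshold (4).
#'
#' Because the rule is known exactly, the ground-truth importance of every
#' ligand atom is known: a binary participates-in-binding indicator under the
#' Polar rule, and the atom's summed interaction score under the Contribution
#' rule.
#'
#' @name synth_generator
NULL

#' Generation configuration
#'
#' @param rule `"polar"` or `"contribution"`.
#' @param pad Box padding beyond the ligand extremes per axis (Angstrom).
#' @param clash_dist Candidate residues strictly closer than this to any
#'   ligand heavy atom are deleted (Angstrom).
#' @param min_sep Minimum allowed residue-residue distance (Angstrom);
#'   enforced greedily in sampling order.
#' @param polar_cutoff Interaction distance threshold of the Polar rule
#'   (Angstrom, strict).
#' @param a_coef Candidate sampling density (residues per cubic Angstrom);
#'   `m = round(a_coef * box volume)` candidates are drawn.
#' @param n_ops Interaction budget: the residue count is capped at
#'   `floor(n_ops / n_lig)` so ligands with many interactable groups do not
#'   receive more interaction opportunities.
#' @param score_threshold Activity threshold on the summed Contribution score.
#' @param hb_weight,hydrophobic_weight Interaction-type weights of the
#'   Contribution score.
#' @param gamma_shape,gamma_rate Parameters of the Gamma density shaping the
#'   distance response (mode at `(shape - 1)/rate` = 3 Angstrom).
#' @param max_retries Internal resampling attempts if every candidate is
#'   filtered away.
#' @return A `generation_config` list.
#' @export
generation_config <- function(rule = c("polar", "contribution"),
                              pad = 5, clash_dist = 2, min_sep = 3,
                              polar_cutoff = 4, a_coef = 0.05, n_ops = 50L,
                              score_threshold = 4, hb_weight = 10,
                              hydrophobic_weight = 3, gamma_shape = 4,
                              gamma_rate = 1, max_retries = 5L) {
  rule <- match.arg(rule)
  assert_that(all(c(pad >= 0, clash_dist > 0, min_sep > 0, polar_cutoff > 0,
                    a_coef > 0)), "distances and density must be positive")
  assert_that(n_ops >= 1, "n_ops must be >= 1")
  assert_that(hb_weight > 0 && hydrophobic_weight > 0, "weights must be > 0")
  structure(list(rule = rule, pad = pad, clash_dist = clash_dist,
                 min_sep = min_sep, polar_cutoff = polar_cutoff,
                 a_coef = a_coef, n_ops = as.integer(n_ops),
                 score_threshold = score_threshold, hb_weight = hb_weight,
                 hydrophobic_weight = hydrophobic_weight,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 max_retries = as.integer(max_retries)),
            class = "generation_config")
}

residue_types_for <- function(rule) {
  if (rule == "polar") c("HBA", "HBD") else c("HBA", "HBD", "Hydrophobic")
}

#' Padded bounding box around a ligand
#'
#' Per-axis closed intervals `[min - pad, max + pad]` over the heavy-atom
#' coordinates, with the box volume.
#'
#' @param ligand An `sb_ligand` with 3D coordinates.
#' @param pad Padding in Angstrom.
#' @return An `sb_box`: list with `lo`, `hi` (length-3) and `volume`.
#' @export
make_box <- function(ligand, pad = 5) {
  xyz <- ligand_coords(ligand)
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  structure(list(lo = lo, hi = hi, volume = prod(hi - lo)), class = "sb_box")
}

#' Sample a synthetic protein around a ligand
#'
#' Implements the generation protocol: sample `m = round(a_coef * volume)`
#' uniform candidate points in the padded box, type each uniformly at random
#' over the rule's type set, delete candidates strictly within `clash_dist`
#' of a ligand heavy atom, greedily (in sampling order) delete candidates
#' strictly within `min_sep` of an already retained candidate, and finally
#' subsample the survivors uniformly down to `n_res = floor(n_ops / n_lig)`
#' if more survive. If nothing survives, resampling is retried with fresh
#' sub-seeds up to `max_retries` times.
#'
#' @param ligand An `sb_ligand` with 3D coordinates.
#' @param assignment Its [assign_pharmacophores()] result (defines `n_lig`).
#' @param config A [generation_config()].
#' @param seed Integer seed; identical seeds give identical proteins.
#' @return An `sb_protein`: list with tibble `residues` (x, y, z, type) and
#'   the generating `box`.
#' @export
sample_synthetic_protein <- function(ligand, assignment, config, seed) {
  nl <- n_lig(assignment)
  if (nl == 0) {
    abort(sprintf("ligand '%s' rejected: no interactable atoms (n_lig = 0)",
                  ligand$id))
  }
  assert_that(ligand$has_3d, sprintf("ligand '%s' has no 3D conformation", ligand$id))
  box <- make_box(ligand, config$pad)
  n_res <- floor(config$n_ops / nl)
  xyz <- ligand_coords(ligand)
  types <- residue_types_for(config$rule)
  m <- max(1L, as.integer(round(config$a_coef * box$volume)))

  for (attempt in seq_len(config$max_retries)) {
    res <- with_seed(derive_seed(seed, attempt, "protein"), {
      cand <- cbind(runif(m, box$lo[1], box$hi[1]),
                    runif(m, box$lo[2], box$hi[2]),
                    runif(m, box$lo[3], box$hi[3]))
      t_i <- sample(types, m, replace = TRUE)
      # clash filter: strictly closer than clash_dist to a ligand atom
      dmin <- apply(cross_dist(cand, xyz), 1, min)
      keep <- dmin >= config$clash_dist
      cand <- cand[keep, , drop = FALSE]
      t_i <- t_i[keep]
      # greedy pairwise-separation filter in sampling order
      if (nrow(cand) > 1) {
        kept <- logical(nrow(cand))
        kept[1] <- TRUE
        for (i in 2:nrow(cand)) {
          dk <- sqrt(colSums((t(cand[kept, , drop = FALSE]) - cand[i, ])^2))
          kept[i] <- all(dk >= config$min_sep)
        }
        cand <- cand[kept, , drop = FALSE]
        t_i <- t_i[kept]
      }
      if (nrow(cand) > n_res) {
        sel <- sample.int(nrow(cand), n_res)
        cand <- cand[sel, , drop = FALSE]
        t_i <- t_i[sel]
      }
      list(cand = cand, t_i = t_i)
    })
    if (nrow(res$cand) > 0 || n_res == 0L) {
      residues <- if (nrow(res$cand)) {
        tibble::tibble(x = res$cand[, 1], y = res$cand[, 2],
                       z = res$cand[, 3], type = res$t_i)
      } else {
        tibble::tibble(x = numeric(0), y = numeric(0),
                       z = numeric(0), type = character(0))
      }
      return(structure(list(residues = residues, box = box, n_res_cap = n_res),
                       class = "sb_protein"))
    }
  }
  abort(sprintf("no residues survived filtering for ligand '%s' after %d attempts",
                ligand$id, config$max_retries))
}

#' Distance-dependent interaction score
#'
#' `w * f(d)` where `f` is the Gamma(4, 1) probability density and `w` is the
#' hydrogen-bond weight (10) or hydrophobic weight (3). The score is positive
#' for all `d > 0`, increases up to the density mode at 3 Angstrom, and
#' decays beyond it. Mismatched-type pairs never reach this function — their
#' score is fixed at 0 by the Contribution rule.
#'
#' @param interaction_type `"HBond"` or `"Hydrophobic"`.
#' @param d Pair distance in Angstrom (> 0); vectorised.
#' @param config A [generation_config()].
#' @return Numeric score(s).
#' @export
interaction_score <- function(interaction_type = c("HBond", "Hydrophobic"), d,
                              config = generation_config("contribution")) {
  interaction_type <- match.arg(interaction_type)
  assert_that(all(d > 0), "distance must be > 0")
  w <- if (interaction_type == "HBond") config$hb_weight else config$hydrophobic_weight
  w * dgamma(d, shape = config$gamma_shape, rate = config$gamma_rate)
}

# (residue, atom) pair table with distances for pairs passing `match_fun`
interaction_pairs <- function(ligand, protein) {
  res <- protein$residues
  d <- cross_dist(as.matrix(res[, c("x", "y", "z")]), ligand_coords(ligand))
  d
}

#' Evaluate the Polar binding rule
#'
#' Emits one interaction record for every complementary (residue, atom) pair
#' strictly within the polar cutoff: HBD residues pair with Acceptor atoms,
#' HBA residues with Donor atoms. The complex is active iff at least one
#' record exists; the per-atom ground truth is a binary indicator of
#' participation in any interaction.
#'
#' @param ligand,assignment,protein,config As in [sample_synthetic_protein()].
#' @return List: `label` ("active"/"inactive"), `records` tibble
#'   (residue_idx, atom_idx, type, distance, score), `contributions`
#'   numeric per-atom indicator vector.
#' @export
evaluate_polar <- function(ligand, assignment, protein, config) {
  assert_that(identical(pharmacophore_rule(assignment), "polar"),
              "assignment must be made with rule = 'polar'")
  res <- protein$residues
  n <- ligand$n_heavy
  records <- tibble::tibble(residue_idx = integer(0), atom_idx = integer(0),
                            type = character(0), distance = numeric(0),
                            score = numeric(0))
  if (nrow(res)) {
    d <- interaction_pairs(ligand, protein)
    comp <- matrix(FALSE, nrow(res), n)
    comp[res$type == "HBD", assignment$acceptor] <- TRUE
    comp[res$type == "HBA", assignment$donor] <- TRUE
    hit <- which(comp & d < config$polar_cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      records <- tibble::tibble(residue_idx = as.integer(hit[, 1]),
                                atom_idx = as.integer(hit[, 2]),
                                type = "HBond",
                                distance = d[hit],
                                score = 0)
    }
  }
  contributions <- as.numeric(seq_len(n) %in% records$atom_idx)
  list(label = if (nrow(records)) "active" else "inactive",
       records = records, contributions = contributions)
}

#' Evaluate the Contribution binding rule
#'
#' Emits one scored record for every same-typed (residue, atom) pair (HBA
#' residue with Acceptor atom, HBD with Donor, Hydrophobic with Hydrophobe);
#' no distance cutoff is applied — the Gamma density decays naturally.
#' The per-atom ground truth is the atom's summed record score; the complex
#' is active iff the total exceeds the score threshold.
#'
#' @inheritParams evaluate_polar
#' @return List: `label`, `records`, `contributions` (per-atom scores),
#'   `total_score`.
#' @export
evaluate_contribution <- function(ligand, assignment, protein, config) {
  assert_that(identical(pharmacophore_rule(assignment), "contribution"),
              "assignment must be made with rule = 'contribution'")
  res <- protein$residues
  n <- ligand$n_heavy
  rec_list <- list()
  if (nrow(res)) {
    d <- interaction_pairs(ligand, protein)
    match_sets <- list(
      list(rtype = "HBA", atoms = assignment$acceptor, itype = "HBond"),
      list(rtype = "HBD", atoms = assignment$donor, itype = "HBond"),
      list(rtype = "Hydrophobic", atoms = assignment$hydrophobe, itype = "Hydrophobic")
    )
    for (ms in match_sets) {
      sel <- matrix(FALSE, nrow(res), n)
      sel[res$type == ms$rtype, ms$atoms] <- TRUE
      hit <- which(sel, arr.ind = TRUE)
      if (nrow(hit)) {
        dist <- d[hit]
        rec_list[[length(rec_list) + 1L]] <- tibble::tibble(
          residue_idx = as.integer(hit[, 1]),
          atom_idx = as.integer(hit[, 2]),
          type = ms$itype,
          distance = dist,
          score = interaction_score(ms$itype, dist, config)
        )
      }
    }
  }
  records <- if (length(rec_list)) dplyr::bind_rows(rec_list) else
    tibble::tibble(residue_idx = integer(0), atom_idx = integer(0),
                   type = character(0), distance = numeric(0), score = numeric(0))
  contributions <- numeric(n)
  if (nrow(records)) {
    agg <- tapply(records$score, records$atom_idx, sum)
    contributions[as.integer(names(agg))] <- as.numeric(agg)
  }
  total <- sum(records$score)
  list(label = if (total > config$score_threshold) "active" else "inactive",
       records = records, contributions = contributions, total_score = total)
}

#' Generate a labelled synthetic complex
#'
#' Samples a typed synthetic protein around the ligand and evaluates the
#' configured binding rule, recording full provenance (config snapshot and
#' seed).
#'
#' @param ligand An `sb_ligand` with a 3D conformation.
#' @param config A [generation_config()].
#' @param seed Integer seed.
#' @return An `sb_complex`: ligand, pharmacophore assignment, protein, rule,
#'   label, per-atom ground-truth `contributions`, interaction `records`,
#'   `total_score` (Contribution rule), `config`, `seed`.
#' @export
generate_complex <- function(ligand, config, seed) {
  assignment <- assign_pharmacophores(ligand, config$rule)
  protein <- sample_synthetic_protein(ligand, assignment, config, seed)
  build_complex(ligand, assignment, protein, config, seed)
}

build_complex <- function(ligand, assignment, protein, config, seed) {
  ev <- if (config$rule == "polar") {
    evaluate_polar(ligand, assignment, protein, config)
  } else {
    evaluate_contribution(ligand, assignment, protein, config)
  }
  structure(list(
    id = sprintf("%s_cx%d", ligand$id, as.integer(seed %% 1000000L)),
    ligand = ligand, assignment = assignment, protein = protein,
    rule = config$rule, label = ev$label, records = ev$records,
    contributions = ev$contributions,
    total_score = ev$total_score %||% NA_real_,
    config = config, seed = as.integer(seed)
  ), class = "sb_complex")
}

#' @exportS3Method base::print
print.sb_complex <- function(x, ...) {
  cat(sprintf("<sb_complex> %s (%s rule): %s, %d residues, %d records%s\n",
              x$id, x$rule, x$label, nrow(x$protein$residues), nrow(x$records),
              if (!is.na(x$total_score)) sprintf(", total score %.3f", x$total_score) else ""))
  invisible(x)
}

#' Generate a complex conditioned on a target label
#'
#' Resamples the synthetic protein (fresh sub-seed each attempt) until the
#' rule label equals `target_label`. After `max_attempts` failures the ligand
#' is discarded: `NULL` is returned with the attempt count in attribute
#' `attempts`. Discarding is a legal, counted outcome, not an error.
#'
#' @param ligand An `sb_ligand` with 3D coordinates.
#' @param config A [generation_config()].
#' @param target_label `"active"` or `"inactive"`.
#' @param max_attempts Maximum number of proteins to try (>= 1).
#' @param seed Integer seed.
#' @return An `sb_complex` with attribute `attempts`, or `NULL` (the discard
#'   signal; the attempt budget was exhausted).
#' @export
generate_conditioned <- function(ligand, config, target_label,
                                 max_attempts = 100L, seed = 1L) {
  assert_that(max_attempts >= 1, "max_attempts must be >= 1")
  assert_that(target_label %in% c("active", "inactive"),
              "target_label must be 'active' or 'inactive'")
  for (attempt in seq_len(max_attempts)) {
    cx <- generate_complex(ligand, config, derive_seed(seed, attempt, "cond"))
    if (identical(cx$label, target_label)) {
      attr(cx, "attempts") <- attempt
      return(cx)
    }
  }
  NULL
}

#' Generate one complex per ligand of a set
#'
#' @param ligands Ligand-set tibble with 3D conformations.
#' @param config A [generation_config()].
#' @param seed Integer seed (per-ligand sub-seeds are derived from it).
#' @return Complex-set tibble: `id`, `ligand_id`, `rule`, `label`,
#'   `total_score`, `n_heavy` and list-column `complex`. Ligands with
#'   `n_lig = 0` are recorded in attribute `rejected` and skipped.
#' @export
generate_complexes <- function(ligands, config, seed) {
  cxs <- vector("list", nrow(ligands))
  rejected <- character(0)
  for (i in seq_len(nrow(ligands))) {
    cx <- tryCatch(
      generate_complex(ligands$mol[[i]], config, derive_seed(seed, i, "set")),
      error = function(e) {
        if (grepl("n_lig = 0", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(cx)) rejected <- c(rejected, ligands$id[i]) else cxs[[i]] <- cx
  }
  cxs <- cxs[!vapply(cxs, is.null, logical(1))]
  out <- complex_set(cxs)
  attr(out, "rejected") <- rejected
  out
}

#' Bundle complexes into a complex-set tibble
#'
#' @param cxs List of `sb_complex` objects.
#' @return Tibble with scalar columns and a `complex` list-column.
#' @export
complex_set <- function(cxs) {
  tibble::tibble(
    id = vapply(cxs, `[[`, character(1), "id"),
    ligand_id = vapply(cxs, function(x) x$ligand$id, character(1)),
    rule = vapply(cxs, `[[`, character(1), "rule"),
    label = vapply(cxs, `[[`, character(1), "label"),
    total_score = vapply(cxs, function(x) x$total_score %||% NA_real_, numeric(1)),
    n_heavy = vapply(cxs, function(x) x$ligand$n_heavy, integer(1)),
    complex = cxs
  )
}
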