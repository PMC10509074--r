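#' Pharmacophore typing of ligand atoms
#'
#' Assigns each heavy atom zero or more pharmacophore types from
#' \{Acceptor, Donor, Hydrophobe\} using rule-based perception on the
#' molecular graph:
#'
#' * **Donor**: N or O carrying at least one hydrogen.
#' * **Acceptor**: any O without positive charge; N without positive charge
#'   that is not part of an amide/amidine motif (bonded to a carbon that is
#'   double-bonded to O or N).
#' * **Hydrophobe**: carbon whose heavy neighbours are all carbon; sulfur
#'   bonded only to carbon; halogens (F, Cl, Br, I) bonded to carbon.
#'
#' These are the standard simplified definitions used by pharmacophore
#' screens; minor differences from any particular toolkit's SMARTS sets are
#' expected and documented. Multi-atom hydrophobic features (aromatic rings,
#' alkyl chains) are represented atom-wise: every member carbon is typed
#' Hydrophobe, since the binding rules need atom-level types.
#'
#' `n_lig` counts atoms able to interact under the active rule: Donor or
#' Acceptor atoms for the polar rule; Donor, Acceptor or Hydrophobe atoms for
#' the contribution rule. An atom with several types counts once.
#'
#' @param ligand An `sb_ligand`.
#' @param rule `"polar"` or `"contribution"`.
#' @return An `sb_pharmacophores` tibble with one row per heavy atom
#'   (`atom`, `element`, `acceptor`, `donor`, `hydrophobe`) and attributes
#'   `rule` and `n_lig`.
#' @export
assign_pharmacophores <- function(ligand, rule = c("polar", "contribution")) {
  rule <- match.arg(rule)
  at <- ligand$atoms
  adj <- ligand_adjacency(ligand)
  n <- ligand$n_heavy
  el <- at$element

  donor <- el %in% c("N", "O") & at$n_h >= 1 & !at$dummy

  # carbon double-bonded to O or N (carbonyl / imine carbon), for the amide
  # exclusion on nitrogen acceptors
  carbonyl_like <- vapply(seq_len(n), function(i) {
    el[i] == "C" && any(adj$ords[[i]] >= 2 & el[adj$nbrs[[i]]] %in% c("O", "N"))
  }, logical(1))

  acceptor <- rep(FALSE, n)
  acceptor[el == "O" & at$charge <= 0] <- TRUE
  for (i in which(el == "N" & at$charge <= 0)) {
    if (!any(carbonyl_like[adj$nbrs[[i]]])) acceptor[i] <- TRUE
  }
  acceptor <- acceptor & !at$dummy

  hydrophobe <- rep(FALSE, n)
  for (i in seq_len(n)) {
    nb <- adj$nbrs[[i]]
    if (el[i] == "C") {
      hydrophobe[i] <- length(nb) == 0L || all(el[nb] == "C")
    } else if (el[i] %in% c("F", "Cl", "Br", "I", "S")) {
      hydrophobe[i] <- length(nb) > 0L && all(el[nb] == "C")
    }
  }
  # sulfone/sulfoxide S is polar, not hydrophobic
  hydrophobe[el == "S" & vapply(seq_len(n), function(i) any(adj$ords[[i]] >= 2), logical(1))] <- FALSE
  hydrophobe <- hydrophobe & !at$dummy

  interacts <- if (rule == "polar") donor | acceptor else donor | acceptor | hydrophobe
  out <- tibble::tibble(
    atom = seq_len(n), element = el,
    acceptor = acceptor, donor = donor, hydrophobe = hydrophobe
  )
  structure(out, rule = rule, n_lig = sum(interacts),
            class = c("sb_pharmacophores", class(out)))
}

#' Number of rule-interactable ligand atoms
#'
#' @param assignment An `sb_pharmacophores` object.
#' @return Integer count (`n_lig`).
#' @export
n_lig <- function(assignment) {
  attr(assignment, "n_lig")
}

pharmacophore_rule <- function(assignment) attr(assignment, "rule")
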