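#' Population labels of the canonical microcircuit
#'
#' The model resolves a cortical column into four interacting populations,
#' in a fixed order: layer-4 spiny stellate cells (\code{SS}), layer-2/3
#' superficial pyramidal cells (\code{SP}), a single trans-laminar
#' inhibitory interneuron population (\code{II}), and layer-5/6 deep
#' pyramidal cells (\code{DP}).
#'
#' @return Character vector \code{c("SS", "SP", "II", "DP")}.
#' @export
cmc_populations <- function() c("SS", "SP", "II", "DP")

#' Intrinsic connectivity graph of the canonical microcircuit
#'
#' Directed, signed edges between the four populations. Each population
#' carries an inhibitory self-modulatory (gain) connection (G1, G4, G7,
#' G10); the interneuron population is reciprocally coupled to each of the
#' three excitatory populations; two non-reciprocal excitatory
#' connections run SS to SP (G8) and SP to DP (G13); and superficial
#' pyramidal cells send an inhibitory-effective feedback to the spiny
#' stellates (G3), as in the classic canonical-microcircuit wiring.
#' G1, G3, G10 and G13 are held fixed during inversion.
#'
#' @return A data.frame with columns \code{label} (\code{"G1"} ...),
#'   \code{source}, \code{target} (population ids) and \code{sign}
#'   (+1 excitatory, -1 inhibitory).
#' @export
cmc_connectivity <- function() {
  data.frame(
    label  = paste0("G", c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13)),
    source = c("SS", "II", "SP", "II", "SS", "DP", "SP", "SS", "II", "DP", "II", "SP", "SP"),
    target = c("SS", "SS", "SS", "II", "II", "II", "SP", "SP", "DP", "DP", "SP", "II", "DP"),
    sign   = c(-1,   -1,   -1,   -1,   +1,   +1,   -1,   +1,   -1,   -1,   -1,   +1,   +1),
    stringsAsFactors = FALSE
  )
}

#' Signed coupling matrix from a parameter set
#'
#' Folds the connectivity graph and the per-edge strengths into a 4 x 4
#' matrix \code{A} with \code{A[target, source]} the summed signed strength
#' of edges source -> target.
#'
#' @param params A \code{cmc_parameters} object.
#' @return 4 x 4 numeric matrix, rows/cols named by population.
#' @export
coupling_matrix <- function(params) {
  stopifnot(inherits(params, "cmc_parameters"))
  pops <- cmc_populations()
  graph <- cmc_connectivity()
  A <- matrix(0, 4, 4, dimnames = list(pops, pops))
  for (k in seq_len(nrow(graph))) {
    g <- params$G[[graph$label[k]]]
    A[graph$target[k], graph$source[k]] <-
      A[graph$target[k], graph$source[k]] + graph$sign[k] * g
  }
  A
}
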