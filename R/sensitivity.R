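#' Spectral features of the model output at a parameter set
#'
#' Beta and gamma peak frequency/amplitude of the predicted (total)
#' spectrum, read off as band argmax peaks. Used by the contribution
#' analysis; evaluated by default on a fine 0.25 Hz grid so that small
#' peak shifts are resolved.
#'
#' @param params A \code{cmc_parameters} object.
#' @param grid Evaluation grid (Hz).
#' @return Named vector \code{beta_freq, beta_amp, gamma_freq, gamma_amp}.
#' @export
model_band_features <- function(params, grid = seq(1, 100, by = 0.25)) {
  out <- predicted_spectrum(params, grid)
  sp <- list(grid = grid, values = out$total)
  beta <- extract_band_peak(sp, c(13, 30), right_open = TRUE)
  gamma <- extract_band_peak(sp, c(30, 80))
  c(beta_freq = beta$freq, beta_amp = beta$amp,
    gamma_freq = gamma$freq, gamma_amp = gamma$amp)
}

#' Effect of one log-scale parameter perturbation on spectral features
#'
#' Regenerates the predicted spectrum with the named parameter scaled by
#' \code{exp(delta)} and returns the change in beta/gamma peak frequency
#' and amplitude relative to the reference.
#'
#' @param ref Reference \code{cmc_parameters} (typically grand-mean
#'   posterior means).
#' @param name Flat parameter key (\code{"G.7"}, \code{"T.II"}, ...).
#' @param delta Log-scale perturbation (default +0.1).
#' @param grid Evaluation grid.
#' @return Named vector of feature deltas (perturbed minus reference).
#' @export
perturb_and_measure <- function(ref, name, delta = 0.1,
                                grid = seq(1, 100, by = 0.25)) {
  f0 <- model_band_features(ref, grid)
  pp <- tryCatch(apply_log_deviations(ref, stats::setNames(delta, name)),
                 error = function(e) stop("perturbation of ", name,
                                          " failed: ", conditionMessage(e)))
  f1 <- tryCatch(model_band_features(pp, grid),
                 error = function(e) stop("model unstable after perturbing ",
                                          name, ": ", conditionMessage(e)))
  f1 - f0
}

#' Contribution (sensitivity) analysis around a reference parameter set
#'
#' Perturbs every free parameter by +/- \code{delta} log-units and
#' tabulates the signed effect on beta/gamma peak frequency and amplitude.
#' Signs are assigned from the +delta direction; effects smaller than the
#' dead-band (0.5 percent of the reference feature value) are recorded as
#' 0. Parameters at which the perturbed model is unstable are marked
#' \code{unstable}.
#'
#' @param ref Reference \code{cmc_parameters}.
#' @param free Character vector of parameters to perturb (default: the
#'   free set of \code{\link{default_priors}} restricted to gains and time
#'   constants).
#' @param delta Log-scale perturbation (default 0.1).
#' @param dead_band Relative dead-band (default 0.005).
#' @param grid Evaluation grid.
#' @return Object of class \code{sensitivity_table}: data.frame with one
#'   row per parameter, signed-effect columns (\code{"+"}, \code{"-"},
#'   \code{"0"} or \code{"unstable"}) and the underlying numeric deltas.
#' @export
contribution_table <- function(ref,
                               free = c("G.2", "G.4", "G.5", "G.6", "G.7",
                                        "G.8", "G.9", "G.11", "G.12",
                                        "T.SP", "T.II", "T.DP"),
                               delta = 0.1, dead_band = 0.005,
                               grid = seq(1, 100, by = 0.25)) {
  f0 <- model_band_features(ref, grid)
  feats <- names(f0)
  rows <- lapply(free, function(nm) {
    dplus <- tryCatch(perturb_and_measure(ref, nm, +delta, grid),
                      error = function(e) NULL)
    dminus <- tryCatch(perturb_and_measure(ref, nm, -delta, grid),
                       error = function(e) NULL)
    if (is.null(dplus)) {
      signs <- rep("unstable", length(feats))
      dplus <- rep(NA_real_, length(feats))
    } else {
      signs <- vapply(feats, function(ft) {
        if (abs(dplus[ft]) <= dead_band * abs(f0[ft])) "0"
        else if (dplus[ft] > 0) "+" else "-"
      }, character(1))
    }
    list(signs = signs, dplus = dplus, dminus = dminus)
  })
  tab <- data.frame(parameter = free,
                    matrix(vapply(rows, `[[`, character(length(feats)), "signs"),
                           nrow = length(free), byrow = TRUE,
                           dimnames = list(NULL, feats)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(table = tab,
                 delta_plus = do.call(rbind, lapply(rows, `[[`, "dplus")),
                 delta_minus = do.call(rbind, lapply(rows, `[[`, "dminus")),
                 reference = ref, reference_features = f0,
                 delta = delta, dead_band = dead_band),
            class = "sensitivity_table")
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("Contribution analysis (delta = %.2g log-units, dead-band %.2g%%)\n",
              x$delta, 100 * x$dead_band))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Reference sign pattern of the contribution analysis
#'
#' Loads the signed-cell fixture shipped with the package: the direction
#' in which each gain/time-constant parameter moves beta and gamma peak
#' frequency and amplitude, as established for this class of microcircuit.
#'
#' @param path TSV file with columns \code{parameter, feature, sign}
#'   (default: the shipped fixture).
#' @return data.frame with character columns.
#' @export
reference_sign_pattern <- function(path = system.file("extdata",
                                                      "reference_signs.tsv",
                                                      package = "cmcssr")) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Compare a sensitivity table with a reference sign pattern
#'
#' @param table A \code{sensitivity_table}.
#' @param pattern data.frame with \code{parameter, feature, sign} rows
#'   (non-empty reference cells); default the shipped fixture.
#' @return List with \code{agreement} (matched / total non-empty cells),
#'   \code{n_cells}, and \code{mismatches} (data.frame).
#' @export
compare_sign_pattern <- function(table, pattern = reference_sign_pattern()) {
  stopifnot(inherits(table, "sensitivity_table"),
            all(c("parameter", "feature", "sign") %in% names(pattern)))
  tab <- table$table
  got <- character(nrow(pattern))
  for (i in seq_len(nrow(pattern))) {
    r <- match(pattern$parameter[i], tab$parameter)
    got[i] <- if (is.na(r)) NA_character_ else tab[r, pattern$feature[i]]
  }
  ok <- !is.na(got) & got == pattern$sign
  mism <- cbind(pattern[!ok, , drop = FALSE], got = got[!ok])
  list(agreement = mean(ok), n_cells = nrow(pattern), mismatches = mism)
}
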