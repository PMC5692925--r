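#' Across-trial and across-subject spectral covariance maps
#'
#' For each subject the frequency-by-frequency covariance of single-trial
#' spectra is computed and averaged over subjects (across-trial map); the
#' across-subject map is the covariance of trial-averaged spectra over
#' subjects. Band correlation profiles (band amplitude vs every
#' frequency) are Fisher z-transformed per subject, averaged, and flagged
#' for significance by a max-statistic permutation test.
#'
#' @param cohort List, one element per subject: numeric matrix
#'   frequencies x trials of per-trial spectra on a common grid.
#' @param grid Frequency grid (Hz).
#' @param bands Named list of band ranges for the correlation profiles.
#' @param n_perm Permutations for the max-statistic correction.
#' @param alpha Family-wise error level.
#' @param seed RNG seed for the permutation draw.
#' @return Object of class \code{covariance_maps}: the two maps, their
#'   correlation versions, and per-band profiles with significance flags.
#' @export
spectral_covariance_maps <- function(cohort, grid,
                                     bands = list(alpha = c(8, 13),
                                                  beta = c(13, 30),
                                                  gamma = c(30, 80)),
                                     n_perm = 1000, alpha = 0.05,
                                     seed = 1) {
  stopifnot(is.list(cohort), length(cohort) >= 3)
  nf <- length(grid)
  lapply(cohort, function(m) stopifnot(is.matrix(m), nrow(m) == nf,
                                       ncol(m) >= 2))
  n_sub <- length(cohort)
  # across-trial: mean over subjects of per-subject trial covariance
  across_trial <- Reduce(`+`, lapply(cohort, function(m) stats::cov(t(m)))) / n_sub
  subj_means <- vapply(cohort, rowMeans, numeric(nf))
  across_subject <- stats::cov(t(subj_means))
  to_cor <- function(S) {
    d <- sqrt(diag(S))
    d[d == 0] <- 1
    S / outer(d, d)
  }
  # band profiles: per-subject across-trial correlation of band mean
  # amplitude with each frequency, Fisher-z averaged over subjects
  profiles <- lapply(bands, function(b) {
    idx <- which(grid >= b[1] & grid <= b[2])
    z <- vapply(cohort, function(m) {
      bandamp <- colMeans(m[idx, , drop = FALSE])
      r <- suppressWarnings(stats::cor(t(m), bandamp))
      r <- pmin(pmax(r, -0.999999), 0.999999)
      atanh(as.numeric(r))
    }, numeric(nf))
    zbar <- rowMeans(z, na.rm = TRUE)
    zse <- apply(z, 1, stats::sd, na.rm = TRUE) / sqrt(n_sub)
    list(z = zbar, se = zse)
  })
  # max-statistic permutation: flip the sign of each subject's z map
  set.seed(seed)
  flags <- lapply(names(bands), function(bn) {
    b <- bands[[bn]]
    idx <- which(grid >= b[1] & grid <= b[2])
    z <- vapply(cohort, function(m) {
      bandamp <- colMeans(m[idx, , drop = FALSE])
      r <- suppressWarnings(stats::cor(t(m), bandamp))
      r <- pmin(pmax(r, -0.999999), 0.999999)
      atanh(as.numeric(r))
    }, numeric(nf))
    tobs <- abs(rowMeans(z)) / (apply(z, 1, stats::sd) / sqrt(n_sub))
    maxnull <- replicate(n_perm, {
      s <- sample(c(-1, 1), n_sub, replace = TRUE)
      zp <- sweep(z, 2, s, `*`)
      max(abs(rowMeans(zp)) / (apply(zp, 1, stats::sd) / sqrt(n_sub)))
    })
    crit <- stats::quantile(maxnull, 1 - alpha, names = FALSE)
    tobs >= crit
  })
  names(flags) <- names(bands)
  structure(list(grid = grid,
                 across_trial = across_trial,
                 across_subject = across_subject,
                 across_trial_cor = to_cor(across_trial),
                 across_subject_cor = to_cor(across_subject),
                 profiles = profiles, significant = flags,
                 n_perm = n_perm, alpha = alpha),
            class = "covariance_maps")
}

#' @export
print.covariance_maps <- function(x, ...) {
  cat(sprintf("Spectral covariance maps: %d frequencies, %d-permutation max-statistic correction\n",
              length(x$grid), x$n_perm))
  invisible(x)
}

#' Bonferroni-corrected parameter-feature correlations
#'
#' Pearson correlation of every (model parameter, spectral feature) pair
#' across subjects, with two-sided p-values and a Bonferroni threshold of
#' \code{alpha / (n_params * n_features)} (a global family over the whole
#' table). Significance tiers mirror the usual starring: * p < 1e-3,
#' ** p < 1e-4, *** p < 1e-5 (all after passing the Bonferroni gate).
#'
#' @param params Numeric matrix subjects x parameters (posterior means).
#' @param features Numeric matrix subjects x features.
#' @param alpha Family-wise level (default 0.05).
#' @return data.frame with one row per pair: r, p, significant, tier.
#' @export
parameter_feature_correlations <- function(params, features, alpha = 0.05) {
  params <- as.matrix(params); features <- as.matrix(features)
  stopifnot(nrow(params) == nrow(features), nrow(params) >= 4)
  thr <- alpha / (ncol(params) * ncol(features))
  out <- list()
  for (j in colnames(features)) for (i in colnames(params)) {
    x <- params[, i]; y <- features[, j]
    keep <- is.finite(x) & is.finite(y)
    if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
      warning("zero-variance column for pair (", i, ", ", j, "); skipped")
      next
    }
    ct <- stats::cor.test(x[keep], y[keep])
    p <- ct$p.value
    out[[length(out) + 1]] <- data.frame(
      parameter = i, feature = j, r = unname(ct$estimate), p = p,
      n = sum(keep), significant = p < thr,
      tier = if (p >= thr) "" else if (p < 1e-5) "***"
             else if (p < 1e-4) "**" else if (p < 1e-3) "*" else ".",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "bonferroni_threshold") <- thr
  res
}

#' Greenhouse-Geisser sphericity estimate
#'
#' Standard epsilon from the double-centred covariance of within-subject
#' level scores: \code{eps = tr(P)^2 / ((k-1) sum(P^2))} with
#' \code{P = H S H}, clipped to [1/(k-1), 1].
#'
#' @param within_cov k x k covariance matrix of the k within-subject
#'   level scores.
#' @return Scalar epsilon.
#' @export
greenhouse_geisser_epsilon <- function(within_cov) {
  S <- as.matrix(within_cov)
  k <- nrow(S)
  stopifnot(k >= 2, ncol(S) == k, max(abs(S - t(S))) < 1e-8 * max(1, max(abs(S))))
  if (!all(is.finite(S)) || all(S == 0)) stop("degenerate covariance")
  H <- diag(k) - matrix(1 / k, k, k)
  P <- H %*% S %*% H
  tr <- sum(diag(P))
  den <- (k - 1) * sum(P^2)
  if (den <= 0) stop("singular double-centred covariance")
  min(max(tr^2 / den, 1 / (k - 1)), 1)
}

# epsilon for an arbitrary within-subject effect given an orthonormal
# contrast basis C (rows) over the cells
gg_epsilon_contrast <- function(S, C) {
  M <- C %*% S %*% t(C)
  d <- nrow(C)
  eps <- sum(diag(M))^2 / (d * sum(M^2))
  min(max(eps, 1 / d), 1)
}

# orthonormal basis of contrasts for a factor with k levels
contrast_basis <- function(k) {
  C <- stats::contr.helmert(k)
  qr.Q(qr(C))
}

#' Two-way repeated-measures ANOVA for the Drug x Time interaction
#'
#' Within-subject ANOVA on a complete subjects x drug(2) x time(4) array.
#' Returns the interaction F with Greenhouse-Geisser-corrected degrees of
#' freedom and p-value, plus paired pre-vs-post contrasts per session in
#' the drug arm.
#'
#' @param values 3-d numeric array, subjects x drug x time (dimension
#'   order respected; \code{dimnames} optional). Subjects with any missing
#'   cell are dropped (complete cases only).
#' @param arm_names,time_names Level labels used for the contrast report.
#' @return Object of class \code{rm_anova}: F, uncorrected dfs, epsilon,
#'   GG-corrected dfs and p, n, and the per-session paired contrasts.
#' @export
rm_anova_drug_time <- function(values,
                               arm_names = c("placebo", "drug"),
                               time_names = c("pre", "1h", "3h", "5h")) {
  stopifnot(length(dim(values)) == 3)
  a <- dim(values)[2]; b <- dim(values)[3]
  complete <- apply(values, 1, function(x) all(is.finite(x)))
  values <- values[complete, , , drop = FALSE]
  n <- dim(values)[1]
  if (n < 3) stop("fewer than 3 subjects with complete data")
  grand <- mean(values)
  A <- apply(values, 2, mean); B <- apply(values, 3, mean)
  S <- apply(values, 1, mean)
  AB <- apply(values, c(2, 3), mean)
  AS <- apply(values, c(1, 2), mean)
  BS <- apply(values, c(1, 3), mean)
  inter <- sweep(sweep(AB, 1, A), 2, B) + grand
  ss_ab <- n * sum(inter^2)
  resid <- values
  for (s in seq_len(n)) for (i in seq_len(a)) for (j in seq_len(b))
    resid[s, i, j] <- values[s, i, j] - AB[i, j] - AS[s, i] - BS[s, j] +
      A[i] + B[j] + S[s] - grand
  ss_err <- sum(resid^2)
  df_ab <- (a - 1) * (b - 1)
  df_err <- (a - 1) * (b - 1) * (n - 1)
  scale2 <- max(ss_ab, ss_err)
  if (scale2 < 1e-300) {
    Fstat <- 0
    eps <- 1
    p <- 1
  } else {
    Fstat <- if (ss_ab == 0) 0 else (ss_ab / df_ab) / (ss_err / df_err)
    # GG epsilon on the interaction contrasts of the flattened cells
    cells <- matrix(aperm(values, c(1, 2, 3)), nrow = n)
    Sc <- stats::cov(cells)
    C <- kronecker(t(contrast_basis(a)), t(contrast_basis(b)))
    eps <- gg_epsilon_contrast(Sc, C)
    p <- stats::pf(Fstat, eps * df_ab, eps * df_err, lower.tail = FALSE)
  }
  # paired drug-arm contrasts vs pre
  contrasts <- NULL
  if (b >= 2) {
    drug <- values[, a, , drop = TRUE]
    contrasts <- do.call(rbind, lapply(2:b, function(j) {
      d <- drug[, j] - drug[, 1]
      tt <- stats::t.test(d)
      data.frame(session = time_names[j], mean_change = mean(d),
                 se = stats::sd(d) / sqrt(n), t = unname(tt$statistic),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }))
  }
  structure(list(F = Fstat, df = c(df_ab, df_err), epsilon = eps,
                 df_gg = eps * c(df_ab, df_err), p = p, n = n,
                 ss = c(interaction = ss_ab, error = ss_err),
                 contrasts = contrasts),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Drug x Time interaction: F(%.2f, %.2f) = %.3f, p = %.4g (GG eps = %.3f, n = %d)\n",
              x$df_gg[1], x$df_gg[2], x$F, x$p, x$epsilon, x$n))
  if (!is.null(x$contrasts)) {
    cat("drug-arm change from pre:\n")
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}
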