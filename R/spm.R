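#' Node-wise mean and SD band of an ensemble of curves
#'
#' @param curves matrix (curves in rows) or list of [waveform()]s on a
#'   common grid, `>= 2` curves.
#' @param template optional [waveform()] supplying grid and metadata when
#'   `curves` is a matrix.
#' @return list with `mean` and `sd` [waveform()]s.
#' @export
ensemble_band <- function(curves, template = NULL) {
  if (is.list(curves) && all(vapply(curves, is_waveform, logical(1)))) {
    template <- curves[[1L]]
    do.call(wf_common_grid, curves)
    curves <- do.call(rbind, lapply(curves, `[[`, "values"))
  }
  curves <- as.matrix(curves)
  if (nrow(curves) < 2L) stop("need at least 2 curves")
  if (is.null(template))
    template <- waveform(seq(0, 100, length.out = ncol(curves)),
                         numeric(ncol(curves)))
  list(mean = wf_with(template, colMeans(curves)),
       sd = wf_with(template, apply(curves, 2L, stats::sd),
                    quantity = paste0(template$quantity, "_sd")))
}

#' Phase-partitioned RMSE report between paired waveform sets
#'
#' For each quantity present in both sets, the RMSE over the full cycle
#' and over each activity phase (per [split_phases()]).
#'
#' @param in_vivo,in_vitro named lists of [waveform()]s on a common
#'   grid; names pair the quantities.
#' @param activity activity name (determines the phase split).
#' @return an `"rmse_report"` data frame with columns `quantity`,
#'   `cycle`, and the two phase labels.
#' @export
rmse_report <- function(in_vivo, in_vitro, activity) {
  if (!all(names(in_vivo) %in% names(in_vitro)))
    stop("unpaired quantity: ",
         paste(setdiff(names(in_vivo), names(in_vitro)), collapse = ", "))
  rows <- lapply(names(in_vivo), function(q) {
    a <- in_vivo[[q]]; b <- in_vitro[[q]]
    wf_common_grid(a, b)
    d <- wf_with(a, a$values - b$values)
    ph <- split_phases(d, activity)
    rmse <- function(v) sqrt(mean(v^2))
    out <- data.frame(quantity = q, cycle = rmse(d$values),
                      p1 = rmse(ph[[1L]]$values), p2 = rmse(ph[[2L]]$values),
                      stringsAsFactors = FALSE)
    names(out)[3:4] <- names(ph)
    out
  })
  report <- do.call(rbind, rows)
  class(report) <- c("rmse_report", "data.frame")
  report
}

as_curve_matrix <- function(group) {
  if (is.list(group) && all(vapply(group, is_waveform, logical(1)))) {
    do.call(wf_common_grid, group)
    group <- do.call(rbind, lapply(group, `[[`, "values"))
  }
  as.matrix(group)
}

# Two-sample pooled-variance t field over cycle nodes.
t_field_2sample <- function(A, B, var_floor = 1e-12) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  ssa <- colSums(sweep(A, 2L, ma)^2)
  ssb <- colSums(sweep(B, 2L, mb)^2)
  df <- na + nb - 2L
  s2 <- (ssa + ssb) / df
  floored <- s2 < var_floor
  s2 <- pmax(s2, var_floor)
  list(t = (ma - mb) / sqrt(s2 * (1 / na + 1 / nb)), df = df,
       floored = any(floored))
}

# FWHM (nodes) of the residual field via the normalized-gradient
# estimator: the gradient variance of a unit-variance smooth Gaussian
# field with kernel FWHM w is 4 log(2) / w^2.
estimate_fwhm <- function(A, B) {
  R <- rbind(sweep(A, 2L, colMeans(A)), sweep(B, 2L, colMeans(B)))
  ssq <- pmax(colSums(R^2), 1e-300)
  D <- R[, -1L, drop = FALSE] - R[, -ncol(R), drop = FALSE]
  v <- colSums(D^2)
  ssq_mid <- (ssq[-1L] + ssq[-length(ssq)]) / 2
  lambda <- mean(v / ssq_mid)
  if (lambda <= 0) return(Inf)
  sqrt(4 * log(2) / lambda)
}

# Expected Euler characteristic of the suprathreshold set of a 1D
# t-distributed random field (Worsley densities): EC(u) = P(T > u) +
# resels * sqrt(4 log 2) / (2 pi) * (1 + u^2/df)^(-(df-1)/2).
rft_expected_ec <- function(u, df, resels) {
  stats::pt(u, df, lower.tail = FALSE) +
    resels * sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

# Two-tailed random-field-theory critical threshold at level alpha.
rft_critical_t <- function(df, resels, alpha) {
  f <- function(u) 2 * rft_expected_ec(u, df, resels) - alpha
  upper <- 50
  if (f(upper) > 0) return(Inf)
  stats::uniroot(f, c(1e-6, upper), tol = 1e-10)$root
}

#' Two-sample 1D statistical parametric mapping t-test
#'
#' Computes the node-wise two-tailed two-sample t statistic over the
#' activity cycle and thresholds it using 1D random field theory: the
#' residual smoothness (FWHM) is estimated from normalized residual
#' gradients, and the critical t solves the expected suprathreshold
#' Euler characteristic equation at the Bonferroni-adjusted level
#' `alpha / n_comparisons` (two-tailed). Maximal runs of
#' `|t| > critical_t` are reported as significant clusters.
#'
#' @param group_a,group_b matrices (curves in rows) or lists of
#'   [waveform()]s on one grid, `>= 2` curves each.
#' @param alpha family-wise error level (default 0.05).
#' @param n_comparisons Bonferroni family size (default 1).
#' @param var_floor variance floor applied at degenerate (zero-variance)
#'   nodes, flagged in the result.
#' @return an `"spm_result"`: `t_field`, `df`, `fwhm` (nodes),
#'   `critical_t`, `clusters` (data frame of start/end percent),
#'   `percent_significant`, `alpha_effective`, `variance_floored`.
#' @export
spm_ttest2_1d <- function(group_a, group_b, alpha = 0.05, n_comparisons = 1L,
                          var_floor = 1e-12) {
  A <- as_curve_matrix(group_a)
  B <- as_curve_matrix(group_b)
  if (ncol(A) != ncol(B)) stop("groups are not on a common grid")
  if (nrow(A) < 2L || nrow(B) < 2L) stop("need >= 2 curves per group")
  tf <- t_field_2sample(A, B, var_floor)
  fwhm <- estimate_fwhm(A, B)
  q <- ncol(A)
  pct <- seq(0, 100, length.out = q)
  alpha_eff <- alpha / n_comparisons
  resels <- (q - 1) / fwhm
  crit <- rft_critical_t(tf$df, resels, alpha_eff)
  supra <- abs(tf$t) > crit
  clusters <- run_intervals(supra, pct)
  structure(list(t_field = tf$t, df = tf$df, fwhm = fwhm,
                 critical_t = crit, clusters = clusters,
                 percent_significant = 100 * sum(supra) / q,
                 alpha = alpha, alpha_effective = alpha_eff,
                 variance_floored = tf$floored),
            class = "spm_result")
}

run_intervals <- function(mask, pct) {
  if (!any(mask))
    return(data.frame(start_percent = numeric(0), end_percent = numeric(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_percent = pct[starts[keep]], end_percent = pct[ends[keep]])
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf(paste0("<spm_result> df = %d, FWHM = %.1f nodes, critical |t| ",
                     "= %.3f (alpha_eff = %.4g); %d cluster(s), %.1f%% of ",
                     "cycle significant\n"),
              x$df, x$fwhm, x$critical_t, x$alpha_effective,
              nrow(x$clusters), x$percent_significant))
  invisible(x)
}

#' Permutation max-|t| null distribution (RFT cross-check)
#'
#' Relabels the pooled curves into two groups, recomputing the maximum
#' absolute t statistic over the cycle for each relabeling; its
#' `1 - alpha` quantile is the permutation counterpart of the
#' random-field-theory threshold.
#'
#' @inheritParams spm_ttest2_1d
#' @param n_perm number of relabelings (warns below 100).
#' @param seed RNG seed.
#' @return list with `max_t` (null distribution), `threshold`,
#'   `observed`, `sampled_with_replacement`.
#' @export
permutation_maxt <- function(group_a, group_b, n_perm = 1000L, alpha = 0.05,
                             seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100: permutation threshold is coarse")
  A <- as_curve_matrix(group_a)
  B <- as_curve_matrix(group_b)
  pool <- rbind(A, B)
  na <- nrow(A)
  n <- nrow(pool)
  replacement <- choose(n, na) < n_perm
  observed <- max(abs(t_field_2sample(A, B)$t))
  max_t <- with_seed(substream_seed(seed, "permutation_maxt"), {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      max(abs(t_field_2sample(pool[idx, , drop = FALSE],
                              pool[-idx, , drop = FALSE])$t))
    }, numeric(1))
  })
  list(max_t = max_t,
       threshold = unname(stats::quantile(max_t, 1 - alpha)),
       observed = observed,
       sampled_with_replacement = replacement)
}

#' Generate smooth Gaussian null curves
#'
#' Zero-mean unit-variance 1D Gaussian fields with approximately the
#' requested smoothness, built by convolving white noise with a Gaussian
#' kernel and renormalizing to unit pointwise variance. Used for the SPM
#' false-positive-rate simulations.
#'
#' @param n_curves curves to generate.
#' @param n_nodes nodes per curve.
#' @param fwhm smoothness in nodes.
#' @return `n_curves` x `n_nodes` matrix.
#' @export
gen_smooth_null_curves <- function(n_curves, n_nodes = 101L, fwhm = 15) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sigma)
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sqrt(sum(kern^2))   # unit output variance
  pad <- n_nodes + 2L * half
  noise <- matrix(stats::rnorm(n_curves * pad), n_curves, pad)
  out <- matrix(0, n_curves, n_nodes)
  for (i in seq_len(n_curves)) {
    sm <- stats::convolve(noise[i, ], rev(kern), type = "filter")
    out[i, ] <- sm[seq_len(n_nodes)]
  }
  out
}
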