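#' Chi-square periodogram of a binned activity trace
#'
#' Sokolove-Bushell periodogram: for each candidate period the trace is
#' folded into `P` columns (nearest-integer number of bins per period) by
#' `K` complete rows, and
#' \deqn{Q_P = K \sum_h (M_h - \bar M)^2 / \mathrm{Var}(x)}
#' with `M_h` the column means, `\bar M` the grand mean of the used bins and
#' `Var(x)` the population variance of the used bins. Under a null of
#' exchangeable bins `Q_P` is approximately chi-square with `P - 1` degrees
#' of freedom; the significance line reports the `1 - alpha` chi-square
#' quantile. The best period is the grid maximum of `Q_P` above its line.
#'
#' @param trace an `activity_trace` (see [simulate_actogram()]) or numeric
#'   vector of counts.
#' @param period_grid candidate periods in hours (default 20 to 28 h in
#'   steps of one bin).
#' @param bin_minutes bin width (minutes), taken from the trace if available.
#' @param alpha significance level for the line (default 0.001, the
#'   conventional stringent line).
#' @param adjust `"bonferroni"` (default) draws the line family-wise over the
#'   tested grid, so a pure-noise trace clears it with probability about
#'   `alpha * grid size / grid correlation`; `"none"` draws the pointwise
#'   line.
#' @return object of class `periodogram`: data frame `grid` (`period_h`,
#'   `Q`, `df`, `sig_line`), `best_period` (NA when no point clears the
#'   line), `alpha`.
#' @export
chi2_periodogram <- function(trace, period_grid = NULL, bin_minutes = NULL,
                             alpha = 0.001,
                             adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  counts <- if (inherits(trace, "activity_trace")) trace$counts else trace
  if (is.null(bin_minutes)) {
    bin_minutes <- if (inherits(trace, "activity_trace")) trace$bin_minutes
                   else stop("bin_minutes required for a bare vector")
  }
  n <- length(counts)
  if (is.null(period_grid)) {
    period_grid <- seq(20, 28, by = bin_minutes / 60)
  }
  bins_per_h <- 60 / bin_minutes
  P_bins <- unique(round(period_grid * bins_per_h))
  P_bins <- P_bins[P_bins >= 2]
  if (n < 2 * max(P_bins)) {
    stop("trace shorter than two cycles of the longest candidate period")
  }
  # fold: matrix(x, nrow = P) has one cycle per column, so phase-bin means
  # across the K cycles are the row means
  alpha_pt <- if (adjust == "bonferroni") alpha / length(P_bins) else alpha
  grid <- do.call(rbind, lapply(P_bins, function(P) {
    K <- n %/% P
    x <- counts[seq_len(K * P)]
    M_h <- rowMeans(matrix(x, nrow = P))
    v <- mean((x - mean(x))^2)
    Q <- if (v > 0) K * sum((M_h - mean(x))^2) / v else 0
    data.frame(period_h = P / bins_per_h, Q = Q, df = P - 1,
               sig_line = stats::qchisq(1 - alpha_pt, P - 1))
  }))
  above <- grid$Q > grid$sig_line
  best <- if (any(above)) grid$period_h[which.max(grid$Q * ifelse(above, 1, NA))]
          else NA_real_
  structure(list(grid = grid, best_period = best, alpha = alpha,
                 bin_minutes = bin_minutes),
            class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("<periodogram> %d candidate periods, best = %s h (alpha = %g)\n",
              nrow(x$grid),
              if (is.na(x$best_period)) "none above line"
              else format(x$best_period), x$alpha))
  invisible(x)
}

#' Compare free-running periods between two groups of animals
#'
#' Two-sample Welch t-test on per-animal period estimates.
#'
#' @param periods_a,periods_b numeric vectors of per-animal periods (h),
#'   >= 2 each.
#' @return list with `delta_min` (mean of group A minus group B, minutes),
#'   `p`, `mean_a`, `mean_b`, `t`.
#' @export
compare_periods <- function(periods_a, periods_b) {
  stopifnot(length(periods_a) >= 2, length(periods_b) >= 2)
  tt <- stats::t.test(periods_a, periods_b)
  list(delta_min = 60 * (mean(periods_a) - mean(periods_b)),
       p = tt$p.value, mean_a = mean(periods_a), mean_b = mean(periods_b),
       t = unname(tt$statistic))
}

#' Per-gene, per-genotype expression phases
#'
#' Fits an unweighted harmonic regression ([harmonic_regression()]) to the
#' log2 expression of every gene within each genotype and tabulates phase,
#' amplitude and rhythmicity p-value, plus the circular phase difference
#' (genotype 2 minus genotype 1, mapped to (-12, 12]) for genes rhythmic
#' (p < `p_cutoff`) in both genotypes.
#'
#' @param expr numeric matrix, genes x samples (expression; log-transformed
#'   internally with `log2(x + 1)` unless `log2_transform = FALSE`).
#' @param meta data frame per sample with `time`, `genotype` (and optionally
#'   `replicate`).
#' @param reference_genotype genotype used as the reference for `delta_phase`
#'   (default: first level); `delta_phase = phase(other) - phase(reference)`
#'   circularly, so a phase-advanced mutant gives negative values.
#' @param p_cutoff rhythmicity cutoff for inclusion in `delta_phase`
#'   summaries (default 0.05 in both genotypes).
#' @param period oscillation period (h).
#' @param log2_transform apply `log2(x+1)` (default TRUE).
#' @return data frame per gene: phase/amplitude/p per genotype (suffixed),
#'   `delta_phase` (NA for genes not rhythmic in both), `rhythmic_both`.
#' @export
expression_phases <- function(expr, meta, reference_genotype = NULL,
                              p_cutoff = 0.05, period = 24,
                              log2_transform = TRUE) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == nrow(meta),
            all(c("time", "genotype") %in% names(meta)))
  gts <- unique(as.character(meta$genotype))
  stopifnot(length(gts) >= 1)
  if (is.null(reference_genotype)) reference_genotype <- gts[1]
  stopifnot(reference_genotype %in% gts)
  if (log2_transform) expr <- log2(expr + 1)
  fits <- lapply(gts, function(g) {
    cols <- which(meta$genotype == g)
    t(apply(expr[, cols, drop = FALSE], 1, function(y) {
      f <- harmonic_regression(y, meta$time[cols], period)
      c(phase = f$phase, amplitude = f$amplitude, p = f$p)
    }))
  })
  names(fits) <- gts
  out <- data.frame(gene = rownames(expr) %||% seq_len(nrow(expr)))
  for (g in gts) {
    out[[paste0("phase_", g)]] <- fits[[g]][, "phase"]
    out[[paste0("amplitude_", g)]] <- fits[[g]][, "amplitude"]
    out[[paste0("p_", g)]] <- fits[[g]][, "p"]
  }
  if (length(gts) == 2) {
    other <- setdiff(gts, reference_genotype)
    rhythmic <- out[[paste0("p_", reference_genotype)]] < p_cutoff &
      out[[paste0("p_", other)]] < p_cutoff
    dp <- circular_diff(out[[paste0("phase_", other)]],
                        out[[paste0("phase_", reference_genotype)]], period)
    dp[!rhythmic] <- NA_real_
    out$delta_phase <- dp
    out$rhythmic_both <- rhythmic
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binomial sign test for a systematic phase shift across a gene set
#'
#' Counts genes with negative (`advanced`) versus positive (`delayed`)
#' circular phase difference and applies an exact two-sided binomial test
#' against 0.5; zero shifts are dropped.
#'
#' @param delta_phase circular phase differences (h), e.g. the
#'   `delta_phase` column of [expression_phases()] restricted to a gene set.
#' @return list with `mean_delta` (h), `n_advanced`, `n_delayed`, `p`.
#' @export
phase_advance_binomial <- function(delta_phase) {
  d <- delta_phase[is.finite(delta_phase)]
  if (length(d) == 0) stop("empty gene set")
  adv <- sum(d < 0); del <- sum(d > 0)
  if (adv + del == 0) stop("all phase differences are exactly zero")
  list(mean_delta = mean(d),
       n_advanced = adv, n_delayed = del,
       p = stats::binom.test(adv, adv + del, 0.5)$p.value)
}

#' Bootstrap test for a nonzero phase difference of one gene
#'
#' Resamples replicates with replacement within each time point and genotype
#' `B` times, recomputes both phases and their circular difference, and
#' reports the two-sided bootstrap p-value
#' `2 * min(frac(delta* >= 0), frac(delta* <= 0))` (capped at 1).
#'
#' @param y expression values of one gene across samples.
#' @param meta data frame per sample with `time`, `genotype`, `replicate`.
#' @param reference_genotype reference for the difference (default first).
#' @param B bootstrap resamples (>= 100 enforced; default 1000).
#' @param period oscillation period (h).
#' @param log2_transform apply `log2(y+1)`.
#' @return list with `delta_phase` (observed), `p`, `B`, vector
#'   `delta_boot`.
#' @export
phase_bootstrap <- function(y, meta, reference_genotype = NULL, B = 1000,
                            period = 24, log2_transform = TRUE) {
  stopifnot(length(y) == nrow(meta),
            all(c("time", "genotype") %in% names(meta)))
  if (B < 100) stop("B must be >= 100 for a usable bootstrap p-value")
  gts <- unique(as.character(meta$genotype))
  stopifnot(length(gts) == 2)
  if (is.null(reference_genotype)) reference_genotype <- gts[1]
  other <- setdiff(gts, reference_genotype)
  if (log2_transform) y <- log2(y + 1)
  cell <- interaction(meta$time, meta$genotype, drop = TRUE)
  if (any(table(cell) < 2)) {
    stop("need >= 2 replicates per time point per genotype")
  }
  phase_of <- function(vals, g) {
    cols <- meta$genotype == g
    harmonic_regression(vals[cols], meta$time[cols], period)$phase
  }
  obs <- circular_diff(phase_of(y, other), phase_of(y, reference_genotype),
                       period)
  cell_idx <- split(seq_along(y), cell)
  boot <- vapply(seq_len(B), function(b) {
    yb <- y
    for (ii in cell_idx) {
      n_i <- length(ii)
      draw <- y[ii[sample.int(n_i, n_i, replace = TRUE)]]
      # resampling within small cells deflates the variance of the cell mean
      # by (n-1)/n, which makes the test anticonservative at 2-3 replicates;
      # rescale the resampled deviations around the original cell mean
      yb[ii] <- mean(y[ii]) + (draw - mean(y[ii])) * sqrt(n_i / (n_i - 1))
    }
    circular_diff(phase_of(yb, other), phase_of(yb, reference_genotype),
                  period)
  }, numeric(1))
  # add-one correction keeps p >= 2/(B+1) when all resamples share a sign
  p <- min(1, 2 * min((sum(boot >= 0) + 1) / (B + 1),
                      (sum(boot <= 0) + 1) / (B + 1)))
  list(delta_phase = obs, p = p, B = B, delta_boot = boot)
}
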