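#' Bin reads into fixed-width intervals and library-normalize
#'
#' Counts reads (by midpoint) into consecutive `bin_size`-bp bins covering
#' `region`, one column per sample, then rescales each sample by
#' `mean(library_sizes) / library_size` so equally sized libraries are left
#' unchanged.
#'
#' @param reads list of numeric vectors, one per sample: read midpoints (bp).
#'   Intervals can be passed as a 2-column matrix per sample, in which case
#'   midpoints are used.
#' @param region length-2 numeric `c(start, end)` in bp (0-based half-open).
#' @param bin_size bin width in bp (default 500).
#' @param library_sizes per-sample library sizes; defaults to the number of
#'   reads supplied per sample.
#' @return object of class `binned_track`: list with `bins` (data frame
#'   `start`, `end`), matrix `counts` (bins x samples, normalized) and
#'   `bin_size`.
#' @export
bin_and_normalize <- function(reads, region, bin_size = 500,
                              library_sizes = NULL) {
  stopifnot(is.list(reads), length(reads) >= 1, length(region) == 2,
            region[2] > region[1], bin_size > 0)
  pos <- lapply(reads, function(r) {
    if (is.matrix(r)) (r[, 1] + r[, 2]) / 2 else as.numeric(r)
  })
  if (any(vapply(pos, length, integer(1)) == 0)) stop("empty sample input")
  if (is.null(library_sizes)) library_sizes <- vapply(pos, length, numeric(1))
  stopifnot(length(library_sizes) == length(pos), all(library_sizes > 0))
  breaks <- seq(region[1], region[2], by = bin_size)
  if (breaks[length(breaks)] < region[2]) breaks <- c(breaks, region[2])
  nb <- length(breaks) - 1L
  counts <- vapply(pos, function(p) {
    p <- p[p >= region[1] & p < region[2]]
    tabulate(findInterval(p, breaks, rightmost.closed = FALSE), nbins = nb)
  }, numeric(nb))
  counts <- sweep(counts, 2, mean(library_sizes) / library_sizes, `*`)
  structure(list(bins = data.frame(start = breaks[-length(breaks)],
                                   end = breaks[-1]),
                 counts = counts, bin_size = bin_size),
            class = "binned_track")
}

#' Running-average smoothing of a binned track
#'
#' Centred moving average over `k` bins (default 7: three upstream, three
#' downstream, one centre). Edge bins average over the bins that exist
#' (shrinking window), so the track keeps its full length.
#'
#' @param x numeric vector or a `binned_track` (each sample column smoothed).
#' @param k window size in bins; must be odd.
#' @export
smooth_track <- function(x, k = 7) {
  stopifnot(k >= 1, k %% 2 == 1)
  smooth_vec <- function(v) {
    n <- length(v)
    h <- (k - 1) / 2
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  if (inherits(x, "binned_track")) {
    x$counts <- apply(x$counts, 2, smooth_vec)
    x$smoothed_k <- k
    x
  } else {
    smooth_vec(x)
  }
}

#' Per-bin 24-h rhythm fit of a smoothed track
#'
#' For every bin, fits an unweighted harmonic regression to the log2 of the
#' (smoothed, normalized) counts across time points and returns amplitude
#' (log2 units), peak phase (h) and p-value (exact F(2, T-3) test; see
#' [harmonic_regression()]). A pseudocount of 1 is added before log2 so
#' empty bins are defined; an all-constant bin gets amplitude 0 and p 1.
#'
#' @param track a `binned_track` whose columns correspond to `times`, or a
#'   numeric matrix (bins x time points) of normalized counts.
#' @param times time point (h) of each column.
#' @param period oscillation period (h, default 24).
#' @param log2_transform take `log2(counts + 1)` first (default TRUE; set
#'   FALSE if the matrix is already on log scale).
#' @return data frame with one row per bin: `amplitude`, `phase`, `p`,
#'   `neg_log10_p`.
#' @export
fit_bin_rhythm <- function(track, times, period = 24, log2_transform = TRUE) {
  m <- if (inherits(track, "binned_track")) track$counts else as.matrix(track)
  stopifnot(ncol(m) == length(times))
  if (length(unique(times %% period)) < 4) {
    stop("need >= 4 distinct time points over the period")
  }
  if (log2_transform) m <- log2(m + 1)
  theta <- 2 * pi * times / period
  X <- cbind(1, cos(theta), sin(theta))
  XtXi <- solve(crossprod(X))
  cf <- m %*% X %*% XtXi            # bins x 3 coefficients
  fitted <- cf %*% t(X)
  rss <- rowSums((m - fitted)^2)
  tss <- rowSums((m - rowMeans(m))^2)
  df2 <- length(times) - 3L
  fstat <- ((tss - rss) / 2) / (rss / df2)
  p <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  const <- tss <= .Machine$double.eps * ncol(m)
  amplitude <- sqrt(cf[, 2]^2 + cf[, 3]^2)
  phase <- (atan2(cf[, 3], cf[, 2]) * period / (2 * pi)) %% period
  amplitude[const] <- 0; phase[const] <- 0; p[const] <- 1
  p[!is.finite(p)] <- 1
  data.frame(amplitude = amplitude, phase = phase, p = p,
             neg_log10_p = -log10(pmax(p, .Machine$double.xmin)))
}

#' Hill function
#'
#' Saturating Hill curve `x^n / (k^n + x^n)`: 0 at `x = 0`, exactly 0.5 at
#' `x = k`, approaching 1 as `x` grows; larger `n` sharpens the threshold.
#'
#' @param x non-negative input.
#' @param k half-saturation threshold.
#' @param n Hill coefficient.
#' @export
hill <- function(x, k, n) {
  stopifnot(all(x >= 0, na.rm = TRUE), k > 0, n > 0)
  x^n / (k^n + x^n)
}

#' HSV phase-colour encoding of bin rhythms
#'
#' Maps each bin's rhythm to a colour: hue encodes the peak phase on a
#' 24-h colour wheel with blue at ZT0 (hue 2/3), advancing through the hue
#' circle as phase increases (phase ZT6 is magenta-red, ZT12 yellow-green);
#' saturation is fixed at 1; value (brightness) is the minimum of two Hill
#' functions of the amplitude `X_a` and the significance `X_p = -log10(p)`,
#' with thresholds `k_a = 1` (log2 units) and `k_p = 4.5` and Hill
#' coefficient `n = 5`. Bins below threshold on either score are (near)
#' black; a bin exactly at threshold on its limiting score has `v = 0.5`.
#'
#' @param amplitude rhythm amplitude `X_a` (log2 units), >= 0.
#' @param neg_log10_p significance `X_p = -log10(p)`, >= 0.
#' @param phase peak phase (h, ZT).
#' @param k_a,k_p Hill thresholds for amplitude and significance.
#' @param n Hill coefficient.
#' @return data frame with `h`, `s`, `v` and hex `rgb`.
#' @export
hsv_encode <- function(amplitude, neg_log10_p, phase,
                       k_a = 1, k_p = 4.5, n = 5) {
  stopifnot(all(amplitude >= 0, na.rm = TRUE),
            all(neg_log10_p >= 0, na.rm = TRUE))
  v <- pmin(hill(amplitude, k_a, n), hill(neg_log10_p, k_p, n))
  h <- (2 / 3 + phase / 24) %% 1
  s <- rep(1, length(v))
  ok <- is.finite(h) & is.finite(v)
  col <- rep(NA_character_, length(v))
  col[ok] <- grDevices::hsv(h[ok], 1, v[ok])
  data.frame(h = h, s = s, v = v, rgb = col, stringsAsFactors = FALSE)
}

#' Write a phase-coloured track as BED9 (itemRgb) for genome browsers
#'
#' @param bins data frame with `start`, `end`.
#' @param colours data frame from [hsv_encode()].
#' @param path output file.
#' @param chrom chromosome name.
#' @export
write_bed9 <- function(bins, colours, path, chrom = "chr1") {
  rgb255 <- t(grDevices::col2rgb(ifelse(is.na(colours$rgb), "#000000",
                                        colours$rgb)))
  item <- apply(rgb255, 1, paste, collapse = ",")
  bed <- data.frame(chrom, bins$start, bins$end, ".", 0, ".",
                    bins$start, bins$end, item)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bed itemRgb=\"On\" name=\"rhythm_phase\"", con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
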