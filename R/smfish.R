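# Image utilities on plain numeric matrices / 3-D arrays (y, x[, z]).
# No external image library is available in this stack, so the handful of
# primitives needed (Laplacian, Gaussian blur, Otsu, connected components,
# distance transform, seeded watershed) are implemented here on small arrays.

shift_mat <- function(m, dy, dx, fill = -Inf) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Discrete Laplacian filter of a 2-D image
#'
#' 4-neighbour Laplacian (kernel 0,1,0 / 1,-4,1 / 0,1,0) with replicated
#' borders. Bright blobs give strongly negative responses at their centres,
#' so spot detection uses the negated response.
#'
#' @param img numeric matrix.
#' @export
laplacian_filter <- function(img) {
  up <- shift_mat(img, -1, 0, NA); dn <- shift_mat(img, 1, 0, NA)
  lf <- shift_mat(img, 0, -1, NA); rt <- shift_mat(img, 0, 1, NA)
  up[is.na(up)] <- img[is.na(up)]; dn[is.na(dn)] <- img[is.na(dn)]
  lf[is.na(lf)] <- img[is.na(lf)]; rt[is.na(rt)] <- img[is.na(rt)]
  up + dn + lf + rt - 4 * img
}

gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  # separable convolution with replicated borders via padding
  pad_rows <- function(m, r) rbind(m[rep(1, r), , drop = FALSE], m,
                                   m[rep(nrow(m), r), , drop = FALSE])
  convolve_cols <- function(m) {
    p <- pad_rows(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * p[i:(i + nrow(m) - 1), , drop = FALSE]
    }
    out
  }
  t(convolve_cols(t(convolve_cols(img))))
}

#' Maximum-intensity projection of a Z-stack
#' @param stack 3-D array (y, x, z) or a matrix (returned unchanged).
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(length(dim(stack)) == 3)
  Reduce(pmax, lapply(seq_len(dim(stack)[3]), function(z) stack[, , z]))
}

#' Detect FISH spots in a Z-stack
#'
#' Applies a Laplacian filter to the maximum-intensity projection, finds
#' local maxima of the negated response above a threshold, and enforces
#' non-maximum suppression within `suppress_radius` pixels (two candidate
#' maxima closer than the radius yield a single call, the brighter one).
#'
#' @param stack 3-D array (y, x, z) or a 2-D matrix.
#' @param threshold response threshold; default `mean + 5 sd` of the filtered
#'   projection.
#' @param suppress_radius minimum spot separation in pixels (default 3).
#' @return data frame of spot calls: `x`, `y` (pixel coordinates),
#'   `response`.
#' @export
detect_spots <- function(stack, threshold = NULL, suppress_radius = 3) {
  proj <- max_project(stack)
  if (max(proj) >= 65535) warning("image may be saturated")
  resp <- -laplacian_filter(proj)
  if (is.null(threshold)) threshold <- mean(resp) + 5 * stats::sd(resp)
  neigh <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  is_max <- resp > threshold
  for (d in neigh) {
    is_max <- is_max & (resp >= shift_mat(resp, d[1], d[2]))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  }
  vals <- resp[idx]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      later <- (i + 1):nrow(idx)
      d2 <- (idx[later, 1] - idx[i, 1])^2 + (idx[later, 2] - idx[i, 2])^2
      keep[later[d2 < suppress_radius^2]] <- FALSE
    }
  }
  data.frame(x = idx[keep, 2], y = idx[keep, 1], response = vals[keep])
}

#' Total transcription-site intensity from the best-focused slices
#'
#' Picks the `n_best` slices with the highest focus score (variance of the
#' per-slice Laplacian, a standard autofocus metric), sum-projects them, and
#' totals the 3x3 pixel block centred on the spot. Spots at the image border
#' use the clipped mask and are flagged.
#'
#' @param stack 3-D array (y, x, z).
#' @param spot list/row with `x`, `y` pixel coordinates.
#' @param n_best number of best-focused slices (default 9; if the stack has
#'   fewer slices all are used, with a warning).
#' @return list with `total_intensity`, `n_slices_used`, `clipped`.
#' @export
site_intensity <- function(stack, spot, n_best = 9) {
  stopifnot(length(dim(stack)) == 3)
  nz <- dim(stack)[3]
  if (nz < n_best) {
    warning(sprintf("stack has %d < %d slices; using all", nz, n_best))
    n_best <- nz
  }
  focus <- vapply(seq_len(nz), function(z)
    stats::var(as.vector(laplacian_filter(stack[, , z]))), numeric(1))
  best <- order(focus, decreasing = TRUE)[seq_len(n_best)]
  proj <- Reduce(`+`, lapply(best, function(z) stack[, , z]))
  x <- round(spot$x); y <- round(spot$y)
  ys <- max(1, y - 1):min(nrow(proj), y + 1)
  xs <- max(1, x - 1):min(ncol(proj), x + 1)
  clipped <- length(ys) < 3 || length(xs) < 3
  if (clipped) warning("spot at image border; mask clipped")
  list(total_intensity = sum(proj[ys, xs]), n_slices_used = n_best,
       clipped = clipped)
}

otsu_threshold <- function(img, n_breaks = 256) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_breaks + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_breaks)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_breaks]
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# connected components of a logical mask (4-connectivity) by iterative
# label-minimization; fine for desk-scale images
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- pmin(shift_mat(lab, -1, 0, Inf), shift_mat(lab, 1, 0, Inf),
               shift_mat(lab, 0, -1, Inf), shift_mat(lab, 0, 1, Inf))
    nb[nb == 0] <- Inf                      # background is not a label
    new <- pmin(lab, nb)
    new[!mask] <- 0
    if (all(new == lab)) break
    lab <- new
  }
  lab[lab == Inf] <- 0
  # compact label ids
  u <- sort(unique(lab[lab > 0]))
  lab[] <- match(lab, c(0L, u)) - 1L
  lab
}

# integer distance-to-background transform by iterative 4-neighbour erosion
distance_transform <- function(mask) {
  dist <- matrix(0L, nrow(mask), ncol(mask))
  cur <- mask
  d <- 0L
  while (any(cur)) {
    d <- d + 1L
    dist[cur] <- d
    er <- cur &
      shift_mat(cur, -1, 0, FALSE) & shift_mat(cur, 1, 0, FALSE) &
      shift_mat(cur, 0, -1, FALSE) & shift_mat(cur, 0, 1, FALSE)
    if (all(er == cur)) {  # plateau (should not happen for finite masks)
      dist[cur] <- d
      break
    }
    cur <- er
  }
  dist
}

# seeded watershed on the negated distance transform: seeds grow outward in
# order of decreasing distance, splitting touching objects at the ridge.
# The integer chamfer distance is smoothed before seed detection so that its
# plateaus do not fragment into many spurious maxima.
watershed_split <- function(mask, dist, min_seed_dist = 2) {
  dsm <- gaussian_blur(dist, 2)
  is_seed <- mask & dist >= min_seed_dist
  for (dy in -3:3) for (dx in -3:3) {
    if (dy == 0 && dx == 0) next
    is_seed <- is_seed & (dsm >= shift_mat(dsm, dy, dx, -Inf))
  }
  seeds <- label_components(is_seed)
  if (max(seeds) == 0) return(label_components(mask))
  lab <- seeds
  for (d in sort(unique(dist[mask]), decreasing = TRUE)) {
    level <- mask & dist >= d
    repeat {
      nb <- pmax(shift_mat(lab, -1, 0, 0L), shift_mat(lab, 1, 0, 0L),
                 shift_mat(lab, 0, -1, 0L), shift_mat(lab, 0, 1, 0L))
      grow <- level & lab == 0 & nb > 0
      if (!any(grow)) break
      lab[grow] <- nb[grow]
    }
  }
  # any unreached pixels (isolated plateaus) keep their own components
  left <- mask & lab == 0
  if (any(left)) {
    extra <- label_components(left)
    extra[extra > 0] <- extra[extra > 0] + max(lab)
    lab <- lab + extra
  }
  lab
}

#' Segment nuclei in a counterstain image
#'
#' Gaussian smoothing, Otsu thresholding, and a distance-transform watershed
#' to split touching nuclei. Diameters are equivalent-circle diameters,
#' `2 sqrt(area/pi)`, converted to micrometres with `pixel_size`.
#'
#' @param img 2-D matrix (e.g. a max-projected DAPI channel).
#' @param pixel_size micrometres per pixel (required metadata).
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param min_area_px minimum object area in pixels (smaller specks are
#'   dropped).
#' @return list with `labels` (integer matrix, 0 = background) and `nuclei`
#'   data frame (`nucleus_id`, `area_px`, `diameter` in um, centroid `x`,
#'   `y`).
#' @export
segment_nuclei <- function(img, pixel_size, smooth_sigma = 2,
                           min_area_px = 25) {
  stopifnot(is.matrix(img), pixel_size > 0)
  sm <- gaussian_blur(img, smooth_sigma)
  if (diff(range(sm)) == 0) {
    return(list(labels = matrix(0L, nrow(img), ncol(img)),
                nuclei = data.frame(nucleus_id = integer(0),
                                    area_px = numeric(0),
                                    diameter = numeric(0),
                                    x = numeric(0), y = numeric(0))))
  }
  mask <- sm > otsu_threshold(sm)
  if (!any(mask)) {
    return(list(labels = matrix(0L, nrow(img), ncol(img)),
                nuclei = data.frame(nucleus_id = integer(0),
                                    area_px = numeric(0),
                                    diameter = numeric(0),
                                    x = numeric(0), y = numeric(0))))
  }
  dist <- distance_transform(mask)
  lab <- watershed_split(mask, dist)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- lapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    data.frame(nucleus_id = id, area_px = nrow(px),
               diameter = 2 * sqrt(nrow(px) / pi) * pixel_size,
               x = mean(px[, 2]), y = mean(px[, 1]))
  })
  nuc <- do.call(rbind, rows)
  nuc <- nuc[nuc$area_px >= min_area_px, , drop = FALSE]
  # relabel dropped specks to background
  lab[!(lab %in% nuc$nucleus_id)] <- 0L
  list(labels = lab, nuclei = nuc)
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Expectation-maximization for a `k`-component univariate Gaussian mixture,
#' initialized from a k-means-style partition of quantile-seeded centres;
#' the best of `restarts` runs by log-likelihood is returned. Component
#' standard deviations are floored at `sd_floor` times the data's standard
#' deviation to avoid degenerate spikes. Components are returned sorted by
#' mean.
#'
#' @param x numeric data (e.g. nucleus diameters, um).
#' @param k number of components (default 4).
#' @param restarts random restarts (default 10).
#' @param max_iter,tol EM iteration controls.
#' @param sd_floor relative sd floor.
#' @return object of class `gaussian_mixture`: list with `mean`, `sd`,
#'   `weight` (each length `k`, sorted by mean), `loglik`, `loglik_trace`
#'   (non-decreasing), `n_iter`, `converged`.
#' @export
fit_gaussian_mixture <- function(x, k = 4, restarts = 10, max_iter = 500,
                                 tol = 1e-8, sd_floor = 1e-3) {
  stopifnot(length(x) >= 2 * k)
  n <- length(x)
  floor_sd <- max(sd_floor * stats::sd(x), 1e-12)
  if (stats::sd(x) == 0) {
    # degenerate input: single effective component at the common value
    return(structure(list(mean = rep(x[1], k), sd = rep(floor_sd, k),
                          weight = c(1, rep(0, k - 1)), loglik = NA_real_,
                          loglik_trace = NA_real_, n_iter = 0L,
                          converged = TRUE),
                     class = "gaussian_mixture"))
  }
  run_em <- function(centres) {
    mu <- sort(centres)
    sg <- rep(stats::sd(x) / k, k)
    pw <- rep(1 / k, k)
    ll_old <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j)
        pw[j] * stats::dnorm(x, mu[j], sg[j]), numeric(n))
      tot <- rowSums(dens)
      tot[tot <= 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      resp <- dens / tot
      nk <- colSums(resp)
      nk[nk < 1e-10] <- 1e-10
      mu <- colSums(resp * x) / nk
      sg <- sqrt(pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk,
                      floor_sd^2))
      pw <- nk / n
      if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) break
      ll_old <- ll
    }
    list(mu = mu, sg = sg, pw = pw, ll = ll, trace = trace, it = it)
  }
  best <- NULL
  qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  for (r in seq_len(restarts)) {
    centres <- if (r == 1) qs else sort(sample(x, k))
    fit <- tryCatch(run_em(centres), error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
  }
  if (is.null(best)) stop("EM failed on all restarts")
  o <- order(best$mu)
  structure(list(mean = best$mu[o], sd = best$sg[o], weight = best$pw[o],
                 loglik = best$ll, loglik_trace = best$trace,
                 n_iter = best$it, converged = best$it < max_iter),
            class = "gaussian_mixture")
}

#' Fit the 4-component ploidy mixture to nucleus diameters
#'
#' Wrapper around [fit_gaussian_mixture()] that records which components
#' correspond to the 2N, 4N and 8N populations (the three smallest means)
#' and which is the outlier class (by convention the component with the
#' largest variance; diameters dominated by it are discarded downstream).
#'
#' @param diameters nucleus diameters (um); >= 200 recommended.
#' @return object of class `ploidy_model`: the mixture plus
#'   `ploidy_components` (indices of the 3 smallest-mean components, in
#'   order 2N, 4N, 8N) and `outlier_component`.
#' @export
fit_ploidy_mixture <- function(diameters) {
  if (length(diameters) < 200) {
    warning("fewer than 200 diameters; mixture fit may be unstable")
  }
  gm <- fit_gaussian_mixture(diameters, k = 4)
  ploidy_comp <- order(gm$mean)[1:3]
  structure(c(unclass(gm),
              list(ploidy_components = ploidy_comp,
                   outlier_component = which.max(gm$sd))),
            class = c("ploidy_model", "gaussian_mixture"))
}

#' Assign ploidy classes from a fitted diameter mixture
#'
#' Computes posterior responsibilities under the mixture and assigns 2N, 4N
#' or 8N when the posterior of one of the three smallest-mean components
#' exceeds `p_min` (default 0.7). Everything else - outlier-dominated or
#' ambiguous nuclei - is discarded (`NA`).
#'
#' @param diameter nucleus diameters (um).
#' @param model a `ploidy_model` from [fit_ploidy_mixture()].
#' @param p_min posterior threshold (default 0.7).
#' @return integer vector in `{2, 4, 8, NA}`.
#' @export
assign_ploidy <- function(diameter, model, p_min = 0.7) {
  stopifnot(inherits(model, "ploidy_model"), p_min > 0, p_min <= 1)
  k <- length(model$mean)
  dens <- vapply(seq_len(k), function(j)
    model$weight[j] * stats::dnorm(diameter, model$mean[j], model$sd[j]),
    numeric(length(diameter)))
  dens <- matrix(dens, ncol = k)
  tot <- rowSums(dens)
  tot[tot <= 0] <- .Machine$double.xmin
  post <- dens / tot
  pc <- model$ploidy_components
  best <- pc[max.col(post[, pc, drop = FALSE])]
  pbest <- post[cbind(seq_along(diameter), best)]
  ploidy <- c(2L, 4L, 8L)[match(best, pc)]
  ploidy[pbest <= p_min] <- NA_integer_
  ploidy
}

#' Burst-fraction and burst-intensity statistics by condition
#'
#' Burst fraction of a nucleus is its number of active transcription sites
#' divided by its (estimated) ploidy; it is proportional to the per-allele
#' burst frequency. Nuclei without an assigned ploidy are excluded; nuclei
#' with more sites than ploidy are retained but flagged. Means and standard
#' errors are over pooled nuclei, and all condition pairs are compared with
#' Welch t-tests (burst fraction, and separately mean site intensity among
#' bursting nuclei).
#'
#' @param nuclei data frame with columns `condition`, `ploidy`,
#'   `n_active_sites` and optionally `mean_site_intensity`.
#' @return list with `summary` (per condition: n, mean/SE of burst fraction,
#'   mean/SE of site intensity) and `tests` (pairwise Welch t-tests).
#' @export
burst_statistics <- function(nuclei) {
  stopifnot(all(c("condition", "ploidy", "n_active_sites") %in% names(nuclei)))
  nuclei <- nuclei[!is.na(nuclei$ploidy), , drop = FALSE]
  conds <- unique(nuclei$condition)
  if (length(conds) < 2) stop("need >= 2 conditions")
  nuclei$burst_fraction <- nuclei$n_active_sites / nuclei$ploidy
  nuclei$flag_excess <- nuclei$burst_fraction > 1
  has_int <- "mean_site_intensity" %in% names(nuclei)
  smry <- do.call(rbind, lapply(conds, function(cd) {
    d <- nuclei[nuclei$condition == cd, ]
    if (nrow(d) < 2) stop(sprintf("condition %s has < 2 nuclei", cd))
    ints <- if (has_int) d$mean_site_intensity[!is.na(d$mean_site_intensity)]
            else numeric(0)
    data.frame(condition = cd, n = nrow(d),
               burst_fraction = mean(d$burst_fraction),
               burst_fraction_se = stats::sd(d$burst_fraction) / sqrt(nrow(d)),
               site_intensity = if (length(ints)) mean(ints) else NA,
               site_intensity_se = if (length(ints) > 1)
                 stats::sd(ints) / sqrt(length(ints)) else NA,
               n_flag_excess = sum(d$flag_excess))
  }))
  # Welch t that tolerates (near-)constant groups: equal constants compare
  # as p = 1, different constants as p = 0
  safe_t <- function(x, y) {
    if (stats::sd(x) + stats::sd(y) < .Machine$double.eps * 10) {
      return(list(p.value = if (mean(x) == mean(y)) 1 else 0))
    }
    stats::t.test(x, y)
  }
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- nuclei[nuclei$condition == pr[1], ]
    b <- nuclei[nuclei$condition == pr[2], ]
    bf <- safe_t(a$burst_fraction, b$burst_fraction)
    pi_ <- if (has_int &&
               sum(!is.na(a$mean_site_intensity)) > 1 &&
               sum(!is.na(b$mean_site_intensity)) > 1) {
      safe_t(a$mean_site_intensity[!is.na(a$mean_site_intensity)],
             b$mean_site_intensity[!is.na(b$mean_site_intensity)])$p.value
    } else NA_real_
    data.frame(condition_a = pr[1], condition_b = pr[2],
               ratio = mean(a$burst_fraction) / mean(b$burst_fraction),
               p_burst_fraction = bf$p.value, p_intensity = pi_)
  }))
  list(summary = smry, tests = tests, nuclei = nuclei)
}

#' Likelihood-ratio tests for a genotype effect on bursting
#'
#' Counts: the number of active sites is regressed on ploidy through the
#' origin with genotype-specific slopes and compared with a shared-slope
#' model (chi-square 1 df LRT) - a genotype-dependent per-allele burst
#' frequency shows up as a slope difference. Intensities: mean site
#' intensity with genotype-specific intercepts versus a single intercept.
#' Gaussian fixed-effects likelihoods; an `animal` column, when present and
#' `animal_covariate = TRUE`, enters both models as a fixed covariate.
#'
#' @param nuclei data frame with `genotype`, `ploidy`, `n_active_sites`, and
#'   optionally `mean_site_intensity`, `animal`.
#' @param animal_covariate include `animal` as fixed covariate if available.
#' @return data frame with rows `counts` and (if intensities are present)
#'   `intensity`: LRT statistic and p-value.
#' @export
lrt_genotype_effect <- function(nuclei, animal_covariate = FALSE) {
  stopifnot(all(c("genotype", "ploidy", "n_active_sites") %in% names(nuclei)))
  nuclei <- nuclei[!is.na(nuclei$ploidy), , drop = FALSE]
  if (length(unique(nuclei$genotype)) != 2) stop("need exactly two genotypes")
  nuclei$genotype <- factor(nuclei$genotype)
  use_animal <- animal_covariate && "animal" %in% names(nuclei)
  lrt_gaussian <- function(full, reduced, data) {
    f1 <- stats::lm(full, data = data)
    f0 <- stats::lm(reduced, data = data)
    n <- nrow(data)
    stat <- n * (log(sum(stats::residuals(f0)^2)) -
                   log(sum(stats::residuals(f1)^2)))
    stat <- max(stat, 0)
    df <- length(stats::coef(f1)) - length(stats::coef(f0))
    c(stat = stat, df = df,
      p = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  an <- if (use_animal) "+ animal" else ""
  counts <- lrt_gaussian(
    stats::as.formula(paste("n_active_sites ~ 0 + ploidy + ploidy:genotype", an)),
    stats::as.formula(paste("n_active_sites ~ 0 + ploidy", an)),
    nuclei)
  out <- data.frame(effect = "counts", statistic = counts["stat"],
                    df = counts["df"], p = counts["p"], row.names = NULL)
  if ("mean_site_intensity" %in% names(nuclei)) {
    d <- nuclei[!is.na(nuclei$mean_site_intensity), , drop = FALSE]
    if (nrow(d) > 5 && length(unique(d$genotype)) == 2) {
      ints <- lrt_gaussian(
        stats::as.formula(paste("mean_site_intensity ~ genotype", an)),
        stats::as.formula(paste("mean_site_intensity ~ 1", an)), d)
      out <- rbind(out, data.frame(effect = "intensity",
                                   statistic = ints["stat"], df = ints["df"],
                                   p = ints["p"], row.names = NULL))
    }
  }
  out
}
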