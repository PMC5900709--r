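#' Configuration for the synthetic 4C-seq generator
#'
#' Describes a single cis chromosome carrying a bait, a power-law contact
#' decay around the bait, and one Gaussian "loop" bump whose mean contact
#' frequency can be modulated along the 24-h cycle. Defaults describe a
#' liver-like design: six time points sampled every 4 h, four biological
#' replicates, an enhancer loop 26 kb downstream of the bait peaking at ZT20
#' with relative amplitude 0.5, and negative-binomial counts with moderate
#' overdispersion and 20% fragment dropout.
#'
#' The per-end mean for a fragment at midpoint `x` and time `t` is
#' \deqn{\mu(x,t) = background + loop(t)\,e^{-(x-x_L)^2/2\sigma_L^2}
#'   + decay\_amp \cdot (\max(|x-x_B|, \bar L)/\bar L)^{-\alpha}}
#' with `loop(t) = loop_base_amp * (1 + rhythm_relamp * cos(2*pi*(t -
#' rhythm_peaktime)/24))`, `x_B` the bait position and `\bar L` the mean
#' fragment length (the decay is truncated at one fragment distance to avoid
#' the singularity at the bait).
#'
#' @param chrom_length chromosome length (bp).
#' @param bait_pos bait position (bp).
#' @param decay_exponent power-law exponent `alpha` (> 0).
#' @param decay_amp mean reads per end at one mean-fragment-length from the
#'   bait (sets the scale of the decay term).
#' @param background_rate flat background mean reads per end.
#' @param loop_center,loop_sigma loop bump centre and width (bp).
#' @param loop_base_amp time-averaged mean reads per end added at the loop
#'   centre.
#' @param rhythm_relamp relative amplitude of the loop oscillation, in [0, 1].
#' @param rhythm_peaktime peak time (h, ZT) of the loop oscillation.
#' @param timepoints sampled times (h); one condition per time point.
#' @param n_replicates biological replicates per condition.
#' @param dropout_prob probability that a fragment x sample is zeroed
#'   (both ends), emulating blind/failed fragments.
#' @param nb_dispersion negative-binomial size parameter; `Inf` gives Poisson.
#' @param mean_fragment_length mean restriction-fragment length (bp); the
#'   expectation for a 4-cutter on random sequence is 256 bp.
#' @param seed integer RNG seed.
#' @return object of class `fourc_sim_config`.
#' @export
fourc_sim_config <- function(chrom_length = 3e6,
                             bait_pos = chrom_length / 2,
                             decay_exponent = 1,
                             decay_amp = 1000,
                             background_rate = 20,
                             loop_center = bait_pos + 26000,
                             loop_sigma = 5000,
                             loop_base_amp = 300,
                             rhythm_relamp = 0.5,
                             rhythm_peaktime = 20,
                             timepoints = c(0, 4, 8, 12, 16, 20),
                             n_replicates = 4,
                             dropout_prob = 0.2,
                             nb_dispersion = 20,
                             mean_fragment_length = 250,
                             seed = 1L) {
  stopifnot(chrom_length > 0, bait_pos > 0, bait_pos < chrom_length,
            decay_exponent > 0, decay_amp >= 0, background_rate >= 0,
            loop_sigma > 0, loop_base_amp >= 0,
            rhythm_relamp >= 0, rhythm_relamp <= 1,
            rhythm_peaktime >= 0, rhythm_peaktime < 24,
            length(timepoints) >= 1, n_replicates >= 1,
            dropout_prob >= 0, dropout_prob < 1,
            nb_dispersion > 0, mean_fragment_length > 0)
  cfg <- as.list(environment())
  class(cfg) <- "fourc_sim_config"
  cfg
}

#' Noiseless 4C mean surface of a simulation config
#'
#' @param config a [fourc_sim_config()].
#' @param x fragment midpoints (bp).
#' @param t time (h); vectorized over `x` for scalar `t`.
#' @return mean reads per end at each `(x, t)`.
#' @export
fourc_mean_surface <- function(config, x, t) {
  loop_amp <- config$loop_base_amp *
    (1 + config$rhythm_relamp * cos(2 * pi * (t - config$rhythm_peaktime) / 24))
  d <- pmax(abs(x - config$bait_pos), config$mean_fragment_length)
  mu <- config$background_rate +
    loop_amp * exp(-(x - config$loop_center)^2 / (2 * config$loop_sigma^2)) +
    config$decay_amp * (d / config$mean_fragment_length)^(-config$decay_exponent)
  if (any(mu < 0)) stop("config produces negative means")
  mu
}

#' Simulate a 4C-seq count matrix with known ground truth
#'
#' Draws a restriction-fragment map (exponential fragment lengths of the
#' configured mean, emulating a 4-cutter digest), then per-fragment, per-end
#' counts from a negative binomial around the config's mean surface, zeroes
#' whole fragment x sample entries with probability `dropout_prob`, and
#' assembles a [fourc_counts] container. The noiseless mean surface per
#' condition is returned alongside, so every simulated dataset labels itself.
#'
#' @param config a [fourc_sim_config()].
#' @return list with `counts` (a `fourc_counts`) and `truth` (list with the
#'   fragment x condition matrix `mean` of per-end means, the `conditions`
#'   data frame and the `config`).
#' @export
simulate_4c <- function(config) {
  stopifnot(inherits(config, "fourc_sim_config"))
  set.seed(config$seed)
  # fragment map: exponential lengths, floored at 20 bp, tiling [0, L)
  n_guess <- ceiling(config$chrom_length / config$mean_fragment_length * 1.4) + 50
  lens <- pmax(20, round(stats::rexp(n_guess, 1 / config$mean_fragment_length)))
  while (sum(lens) < config$chrom_length) {
    lens <- c(lens, pmax(20, round(stats::rexp(1000, 1 / config$mean_fragment_length))))
  }
  ends <- cumsum(lens)
  ends <- ends[ends < config$chrom_length]
  starts <- c(0, ends)
  ends <- c(ends, config$chrom_length)
  frag <- data.frame(
    fragment_id = seq_along(starts),
    chrom = "chrS",
    start = starts, end = ends,
    mid = (starts + ends) / 2
  )
  frag$distance_to_bait <- frag$mid - config$bait_pos

  tp <- config$timepoints
  R <- config$n_replicates
  cond <- sprintf("ZT%02d", tp)
  samples <- data.frame(
    sample_id = paste0(rep(cond, each = R), "_r", seq_len(R)),
    condition = rep(cond, each = R),
    time = rep(tp, each = R),
    genotype = "WT",
    replicate = rep(seq_len(R), times = length(tp)),
    stringsAsFactors = FALSE
  )

  nf <- nrow(frag); ns <- nrow(samples)
  mu_cond <- vapply(tp, function(t) fourc_mean_surface(config, frag$mid, t),
                    numeric(nf))
  colnames(mu_cond) <- cond
  mu_samp <- mu_cond[, samples$condition, drop = FALSE]

  rend <- function() {
    if (is.infinite(config$nb_dispersion)) {
      matrix(stats::rpois(nf * ns, mu_samp), nf, ns)
    } else {
      matrix(stats::rnbinom(nf * ns, size = config$nb_dispersion, mu = mu_samp),
             nf, ns)
    }
  }
  end1 <- rend(); end2 <- rend()
  if (config$dropout_prob > 0) {
    drop <- matrix(stats::runif(nf * ns) < config$dropout_prob, nf, ns)
    end1[drop] <- 0L; end2[drop] <- 0L
  }
  colnames(end1) <- colnames(end2) <- samples$sample_id

  counts <- new_fourc_counts(
    fragments = frag, end1 = end1, end2 = end2, samples = samples,
    bait = list(chrom = "chrS", pos = config$bait_pos)
  )
  list(counts = counts,
       truth = list(mean = mu_cond,
                    conditions = data.frame(condition = cond, time = tp),
                    config = config))
}

#' Configuration for the synthetic smRNA-FISH nucleus generator
#'
#' Nuclei carry a true ploidy drawn from `mixing_props` over (2N, 4N, 8N,
#' outlier); diameters are Gaussian within each class. Default diameter means
#' 7, 9.5, 12.5 and 17 um with sds 0.7, 0.8, 1.0 and 2.5 place the outlier
#' component's mass beyond 15-18 um (these are generator defaults chosen as
#' realistic for liver nuclei, not measured values). Each of the `ploidy`
#' alleles of a nucleus bursts independently with the condition's
#' `burst_prob`, and active-site intensities are log-normal.
#'
#' @param n_nuclei nuclei per condition.
#' @param diameter_means,diameter_sds length-4 numeric (2N, 4N, 8N, outlier),
#'   micrometres.
#' @param mixing_props length-4 mixing proportions summing to 1.
#' @param burst_prob named numeric: per-allele burst probability per condition.
#' @param site_intensity_meanlog,site_intensity_sdlog log-normal parameters of
#'   active-site total intensity (arbitrary fluorescence units).
#' @param pixel_size micrometres per pixel for rendered images.
#' @param psf_sigma spot Gaussian sigma (pixels) when rendering images.
#' @param seed integer RNG seed.
#' @return object of class `fish_sim_config`.
#' @export
fish_sim_config <- function(n_nuclei = 1000,
                            diameter_means = c(7, 9.5, 12.5, 17),
                            diameter_sds = c(0.7, 0.8, 1.0, 2.5),
                            mixing_props = c(0.35, 0.45, 0.15, 0.05),
                            burst_prob = c(WT_ZT08 = 0.1, WT_ZT20 = 0.22),
                            site_intensity_meanlog = log(200),
                            site_intensity_sdlog = 0.5,
                            pixel_size = 0.103,
                            psf_sigma = 1.5,
                            seed = 1L) {
  stopifnot(n_nuclei >= 1,
            length(diameter_means) == 4, length(diameter_sds) == 4,
            all(diameter_sds > 0), length(mixing_props) == 4,
            abs(sum(mixing_props) - 1) <= 1e-9,
            all(burst_prob >= 0 & burst_prob <= 1),
            length(names(burst_prob)) == length(burst_prob),
            pixel_size > 0, psf_sigma > 0)
  cfg <- as.list(environment())
  class(cfg) <- "fish_sim_config"
  cfg
}

#' Simulate smRNA-FISH nuclei (and optional image stacks)
#'
#' @param config a [fish_sim_config()].
#' @param render if `TRUE`, additionally renders one small Z-stack per
#'   condition containing a subset of nuclei (DAPI discs) and their active
#'   transcription sites as 3-D Gaussian spots; intended for exercising the
#'   image-processing path on desk-scale data.
#' @param render_n nuclei per rendered image (kept small; images are
#'   `render_shape` x nz arrays in memory).
#' @param render_shape `c(ny, nx)` pixels of rendered frames.
#' @param nz number of Z slices.
#' @return list with `nuclei` (data frame: condition, nucleus_id, ploidy
#'   (true), diameter, n_active_sites, site intensities summarized) and,
#'   if `render = TRUE`, `images` (named list per condition with elements
#'   `fish` and `dapi`, 3-D arrays, plus ground-truth spot table).
#' @export
simulate_fish_nuclei <- function(config, render = FALSE, render_n = 6,
                                 render_shape = c(192, 192), nz = 12) {
  stopifnot(inherits(config, "fish_sim_config"))
  set.seed(config$seed)
  ploidies <- c(2L, 4L, 8L, NA_integer_)  # NA = outlier class
  out <- list()
  for (cd in names(config$burst_prob)) {
    comp <- sample.int(4L, config$n_nuclei, replace = TRUE,
                       prob = config$mixing_props)
    diam <- stats::rnorm(config$n_nuclei, config$diameter_means[comp],
                         config$diameter_sds[comp])
    diam <- pmax(diam, 1)
    ploidy <- ploidies[comp]
    # outlier nuclei still have alleles; give them 8N alleles for bursting
    alleles <- ifelse(is.na(ploidy), 8L, ploidy)
    p <- config$burst_prob[[cd]]
    nact <- stats::rbinom(config$n_nuclei, alleles, p)
    mean_int <- vapply(nact, function(k) {
      if (k == 0) NA_real_ else mean(stats::rlnorm(k, config$site_intensity_meanlog,
                                                   config$site_intensity_sdlog))
    }, numeric(1))
    out[[cd]] <- data.frame(
      condition = cd,
      nucleus_id = paste0(cd, "_", seq_len(config$n_nuclei)),
      true_ploidy = ploidy, true_component = comp,
      diameter = diam, n_active_sites = nact,
      mean_site_intensity = mean_int,
      stringsAsFactors = FALSE
    )
  }
  nuclei <- do.call(rbind, out)
  rownames(nuclei) <- NULL
  res <- list(nuclei = nuclei, config = config)
  if (render) {
    res$images <- lapply(stats::setNames(names(config$burst_prob),
                                         names(config$burst_prob)),
                         function(cd) {
      render_fish_stack(nuclei[nuclei$condition == cd, ][seq_len(render_n), ],
                        config, render_shape, nz)
    })
  }
  res
}

# Render one synthetic FISH field: DAPI discs on a grid, FISH spots as 3-D
# Gaussians at random positions inside each nucleus for its active sites.
render_fish_stack <- function(nuc, config, shape, nz) {
  ny <- shape[1]; nx <- shape[2]
  dapi <- matrix(0, ny, nx)
  fish <- array(0, dim = c(ny, nx, nz))
  ncols <- ceiling(sqrt(nrow(nuc)))
  cellw <- floor(nx / ncols); cellh <- floor(ny / ncols)
  spots <- NULL
  xs <- seq_len(nx); ys <- seq_len(ny)
  for (i in seq_len(nrow(nuc))) {
    gx <- ((i - 1) %% ncols); gy <- ((i - 1) %/% ncols)
    cx <- gx * cellw + cellw / 2; cy <- gy * cellh + cellh / 2
    r_px <- (nuc$diameter[i] / 2) / config$pixel_size
    r_px <- min(r_px, cellw / 2 - 2, cellh / 2 - 2)
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    dapi <- dapi + 100 * (d2 <= r_px^2)
    k <- nuc$n_active_sites[i]
    if (k > 0) {
      for (s in seq_len(k)) {
        ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0, 0.6 * r_px)
        sx <- cx + rad * cos(ang); sy <- cy + rad * sin(ang)
        sz <- sample.int(nz, 1)
        amp <- stats::rlnorm(1, config$site_intensity_meanlog,
                             config$site_intensity_sdlog)
        g2 <- exp(-(outer((ys - sy)^2, (xs - sx)^2, `+`)) /
                    (2 * config$psf_sigma^2))
        for (z in seq_len(nz)) {
          wz <- exp(-(z - sz)^2 / (2 * 1.2^2))
          fish[, , z] <- fish[, , z] + amp / (2 * pi * config$psf_sigma^2) * wz * g2
        }
        spots <- rbind(spots, data.frame(nucleus_id = nuc$nucleus_id[i],
                                         x = sx, y = sy, z = sz,
                                         intensity = amp))
      }
    }
  }
  # mild Gaussian read noise
  fish <- fish + array(abs(stats::rnorm(length(fish), 0, 0.05)), dim = dim(fish))
  list(fish = fish, dapi = dapi, spots = spots,
       pixel_size = config$pixel_size)
}

#' Configuration for the synthetic actogram generator
#'
#' Square-wave locomotor activity of known free-running period: within every
#' cycle of `true_period` hours the animal is active for `active_fraction` of
#' the cycle (Poisson rate `rate_active`) and quiescent otherwise
#' (`rate_rest`, the "noise" floor). Counts are Poisson per bin.
#'
#' @param true_period free-running period (h); 20-28 recommended.
#' @param n_days recording length in days.
#' @param bin_minutes bin width (minutes; must divide 60). 5-min bins match
#'   passive-infrared recording conventions.
#' @param active_fraction fraction of the cycle spent active.
#' @param rate_active mean counts per bin while active.
#' @param rate_rest mean counts per bin while resting (0 = noiseless).
#' @param seed integer RNG seed.
#' @export
actogram_sim_config <- function(true_period = 23.75, n_days = 21,
                                bin_minutes = 5, active_fraction = 0.5,
                                rate_active = 10, rate_rest = 1,
                                seed = 1L) {
  stopifnot(true_period > 0, n_days >= 1, bin_minutes >= 1,
            60 %% bin_minutes == 0,
            active_fraction > 0, active_fraction < 1,
            rate_active >= 0, rate_rest >= 0)
  if (true_period < 20 || true_period > 28) {
    warning("true_period outside the recommended 20-28 h range")
  }
  cfg <- as.list(environment())
  class(cfg) <- "actogram_sim_config"
  cfg
}

#' Simulate a binned locomotor-activity trace
#'
#' @param config an [actogram_sim_config()].
#' @return object of class `activity_trace`: list with `counts` (integer per
#'   bin), `bin_minutes`, `minutes` (bin start times) and the `config`.
#' @export
simulate_actogram <- function(config) {
  stopifnot(inherits(config, "actogram_sim_config"))
  set.seed(config$seed)
  n_bins <- config$n_days * 24 * 60 / config$bin_minutes
  t_h <- (seq_len(n_bins) - 1) * config$bin_minutes / 60
  phase <- (t_h %% config$true_period) / config$true_period
  active <- phase < config$active_fraction
  rate <- ifelse(active, config$rate_active, config$rate_rest)
  counts <- if (config$rate_rest == 0 && config$rate_active == 0) {
    integer(n_bins)
  } else {
    stats::rpois(n_bins, rate)
  }
  structure(list(counts = counts, bin_minutes = config$bin_minutes,
                 minutes = (seq_len(n_bins) - 1) * config$bin_minutes,
                 config = config),
            class = "activity_trace")
}

#' Write an activity trace as a two-column TSV (minutes, counts)
#' @param trace an `activity_trace`.
#' @param path output file.
#' @export
write_activity_trace <- function(trace, path) {
  stopifnot(inherits(trace, "activity_trace"))
  utils::write.table(data.frame(minutes = trace$minutes, counts = trace$counts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an activity trace from a two-column TSV
#' @param path TSV with columns `minutes`, `counts`.
#' @export
read_activity_trace <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  bw <- if (nrow(d) > 1) diff(d$minutes[1:2]) else 5
  structure(list(counts = d$counts, bin_minutes = bw, minutes = d$minutes,
                 config = NULL),
            class = "activity_trace")
}
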