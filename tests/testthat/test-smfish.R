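# build a Z-stack with Gaussian spots at given (x, y, z, amplitude)
make_spot_stack <- function(spots, shape = c(64, 64), nz = 12,
                            psf = 1.5, noise_sd = 0) {
  ny <- shape[1]; nx <- shape[2]
  stack <- array(0, dim = c(ny, nx, nz))
  ys <- seq_len(ny); xs <- seq_len(nx)
  for (i in seq_len(nrow(spots))) {
    g2 <- exp(-(outer((ys - spots$y[i])^2, (xs - spots$x[i])^2, `+`)) /
                (2 * psf^2))
    for (z in seq_len(nz)) {
      wz <- exp(-(z - spots$z[i])^2 / (2 * 1.2^2))
      stack[, , z] <- stack[, , z] + spots$amp[i] * wz * g2
    }
  }
  if (noise_sd > 0) {
    stack <- stack + array(abs(rnorm(length(stack), 0, noise_sd)),
                           dim = dim(stack))
  }
  stack
}

test_that("spot detection finds isolated spots and suppresses close pairs", {
  expect_equal(nrow(detect_spots(array(0, dim = c(32, 32, 4)))), 0)

  set.seed(2)
  truth <- data.frame(x = c(10, 25, 40, 55, 12, 30, 50, 20, 45, 58),
                      y = c(12, 8, 15, 10, 30, 35, 28, 52, 50, 40),
                      z = sample(3:10, 10, replace = TRUE), amp = 50)
  stack <- make_spot_stack(truth, noise_sd = 0.3)
  calls <- detect_spots(stack)
  expect_equal(nrow(calls), 10)
  for (i in seq_len(10)) {
    d <- sqrt((calls$x - truth$x[i])^2 + (calls$y - truth$y[i])^2)
    expect_lte(min(d), 1)
  }

  # two spots 1 px apart collapse to a single call
  pair <- make_spot_stack(data.frame(x = c(20, 21), y = c(20, 20),
                                     z = c(5, 5), amp = 50))
  expect_equal(nrow(detect_spots(pair)), 1)
})

test_that("site intensity sums a 3x3 mask over the best-focused slices", {
  # uniform stack of value v with 9 slices: total = 9 * 9 * v
  v <- 2.5
  uni <- array(v, dim = c(21, 21, 9))
  si <- site_intensity(uni, list(x = 10, y = 10))
  expect_equal(si$total_intensity, 9 * 9 * v)
  expect_false(si$clipped)

  # single-pixel spot present in 3 slices of a 9-slice stack
  s <- array(0, dim = c(21, 21, 9))
  s[10, 10, c(2, 5, 8)] <- 7
  si2 <- site_intensity(s, list(x = 10, y = 10))
  expect_equal(si2$total_intensity, 3 * 7)

  # fewer than 9 slices warns and uses all; border spot flags clipping
  expect_warning(site_intensity(array(1, dim = c(9, 9, 4)),
                                list(x = 5, y = 5)), "slices")
  expect_warning(
    sib <- site_intensity(array(1, dim = c(15, 15, 9)), list(x = 1, y = 1)),
    "border")
  expect_true(sib$clipped)
})

test_that("site intensities preserve the rank of true spot brightness", {
  set.seed(5)
  truth <- expand.grid(x = seq(8, 56, by = 12), y = seq(8, 56, by = 12))
  truth$z <- sample(3:9, nrow(truth), replace = TRUE)
  truth$amp <- rlnorm(nrow(truth), log(40), 0.5)
  stack <- make_spot_stack(truth, noise_sd = 0.2)
  est <- vapply(seq_len(nrow(truth)), function(i)
    site_intensity(stack, list(x = truth$x[i], y = truth$y[i]))$total_intensity,
    numeric(1))
  expect_gt(cor(est, truth$amp, method = "spearman"), 0.95)
})

test_that("nucleus segmentation measures discs and splits touching pairs", {
  img <- matrix(0, 100, 100)
  img[outer((1:100 - 50)^2, (1:100 - 50)^2, `+`) <= 20^2] <- 100
  seg <- segment_nuclei(img, pixel_size = 1)
  expect_equal(nrow(seg$nuclei), 1)
  expect_lt(abs(seg$nuclei$diameter - 40), 2)

  two <- matrix(0, 80, 80)
  d2a <- outer((1:80 - 40)^2, (1:80 - 25)^2, `+`)
  d2b <- outer((1:80 - 40)^2, (1:80 - 55)^2, `+`)
  two[d2a <= 15^2 | d2b <= 15^2] <- 100
  seg2 <- segment_nuclei(two, pixel_size = 1)
  expect_equal(nrow(seg2$nuclei), 2)

  blank <- segment_nuclei(matrix(0, 50, 50), pixel_size = 1)
  expect_equal(nrow(blank$nuclei), 0)
})

test_that("rendered FISH fields are processed end to end", {
  cfg <- fish_sim_config(n_nuclei = 8, burst_prob = c(A = 0.9), seed = 5)
  sim <- simulate_fish_nuclei(cfg, render = TRUE, render_n = 4)
  img <- sim$images$A
  calls <- detect_spots(img$fish)
  # detection F1 against rendered ground truth
  truth <- img$spots
  matched <- vapply(seq_len(nrow(truth)), function(i)
    any((calls$x - truth$x[i])^2 + (calls$y - truth$y[i])^2 <= 9), logical(1))
  precision_ok <- nrow(calls) <= nrow(truth) + 1
  expect_gt(mean(matched), 0.9)
  expect_true(precision_ok)
  seg <- segment_nuclei(img$dapi, pixel_size = cfg$pixel_size)
  expect_equal(nrow(seg$nuclei), 4)
})

test_that("EM mixture recovers parameters and is well-behaved", {
  cfg <- fish_sim_config(n_nuclei = 1500, burst_prob = c(A = 0.1), seed = 31)
  nuc <- simulate_fish_nuclei(cfg)$nuclei
  gm <- fit_ploidy_mixture(nuc$diameter)
  expect_true(all(diff(gm$mean) > 0))  # sorted by mean
  expect_true(all(diff(gm$loglik_trace) > -1e-6))  # EM monotone
  # the 5% bound is asserted at the 3000-diameter acceptance scale; at
  # n = 1500 the wide outlier component is estimated more loosely
  expect_lt(max(abs(gm$mean - cfg$diameter_means) / cfg$diameter_means), 0.10)
  expect_equal(gm$outlier_component, 4L)

  # degenerate input: identical diameters handled via the sd floor
  deg <- fit_gaussian_mixture(rep(7, 300), k = 4)
  expect_equal(deg$weight[1], 1)

  expect_warning(fit_ploidy_mixture(rnorm(150, 10)), "fewer than 200")
})

test_that("ploidy assignment thresholds posteriors and discards outliers", {
  model <- structure(list(mean = c(5, 9, 30, 60), sd = c(1, 1, 1, 10),
                          weight = c(0.45, 0.45, 0.05, 0.05),
                          ploidy_components = 1:3, outlier_component = 4L),
                     class = c("ploidy_model", "gaussian_mixture"))
  expect_equal(assign_ploidy(c(5, 9, 30), model), c(2L, 4L, 8L))
  # midway between two equal components: posterior 0.5 <= 0.7, discarded
  expect_true(is.na(assign_ploidy(7, model)))
  # far outlier dominated by the wide component
  expect_true(is.na(assign_ploidy(80, model)))
})

test_that("simulated populations are assigned with < 10% error", {
  cfg <- fish_sim_config(n_nuclei = 2000, burst_prob = c(A = 0.1), seed = 13)
  nuc <- simulate_fish_nuclei(cfg)$nuclei
  model <- fit_ploidy_mixture(nuc$diameter)
  assigned <- assign_ploidy(nuc$diameter, model)
  ok <- !is.na(assigned) & !is.na(nuc$true_ploidy)
  expect_lt(mean(assigned[ok] != nuc$true_ploidy[ok]), 0.10)
  # most true outliers are not assigned a ploidy class
  expect_gt(mean(is.na(assigned[is.na(nuc$true_ploidy)])), 0.5)
})

test_that("burst statistics summarize and compare conditions", {
  nuc <- data.frame(condition = rep(c("A", "B"), each = 10),
                    ploidy = 2L, n_active_sites = 1L,
                    mean_site_intensity = rep(c(100, 100), each = 10))
  bs <- burst_statistics(nuc)
  expect_equal(bs$summary$burst_fraction, c(0.5, 0.5))
  expect_equal(bs$summary$burst_fraction_se, c(0, 0))
  # identical distributions: t statistic 0 (p NaN for zero variance is
  # avoided by adding spread)
  nuc2 <- nuc
  set.seed(1)
  nuc2$n_active_sites <- rep(c(0L, 1L, 2L, 1L, 0L), 4)
  bs2 <- burst_statistics(nuc2)
  expect_gt(bs2$tests$p_burst_fraction, 0.99)
  expect_equal(bs2$tests$ratio, 1)
  # nuclei with more sites than ploidy are retained but flagged
  nuc3 <- nuc
  nuc3$n_active_sites[1] <- 5L
  bs3 <- burst_statistics(nuc3)
  expect_equal(sum(bs3$summary$n_flag_excess), 1)
  expect_equal(nrow(bs3$nuclei), 20)
})

test_that("genotype LRT is nested, calibrated, and powered", {
  set.seed(77)
  # nested: statistic >= 0 on arbitrary data
  for (i in 1:5) {
    nuc <- data.frame(genotype = rep(c("WT", "MUT"), each = 50),
                      ploidy = sample(c(2, 4, 8), 100, replace = TRUE),
                      n_active_sites = rpois(100, 1))
    expect_gte(lrt_genotype_effect(nuc)$statistic[1], 0)
  }
  # null calibration: rejection rate at 0.05 over repeated null sims
  pv <- replicate(120, {
    pl <- sample(c(2L, 4L, 8L), 400, replace = TRUE,
                 prob = c(0.4, 0.45, 0.15))
    nuc <- data.frame(genotype = rep(c("WT", "MUT"), each = 200),
                      ploidy = pl, n_active_sites = rbinom(400, pl, 0.15))
    lrt_genotype_effect(nuc)$p[1]
  })
  expect_gt(mean(pv < 0.05), 0.01)
  expect_lt(mean(pv < 0.05), 0.12)
  # power: halving the burst probability is detected at n = 1000/group
  pl <- sample(c(2L, 4L, 8L), 2000, replace = TRUE, prob = c(0.4, 0.45, 0.15))
  gt <- rep(c("WT", "MUT"), each = 1000)
  p_gt <- ifelse(gt == "WT", 0.2, 0.1)
  nuc <- data.frame(genotype = gt, ploidy = pl,
                    n_active_sites = rbinom(2000, pl, p_gt))
  expect_lt(lrt_genotype_effect(nuc)$p[1], 0.01)
})
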