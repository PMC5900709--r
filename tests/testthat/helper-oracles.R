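# Independent oracles used across test files. These deliberately avoid the
# package's solver internals: the LWMR oracle builds the full dense design
# and solves the constrained weighted least-squares problem with a Lagrange
# multiplier; covariances come from dense matrix products.

lwmr_dense_oracle <- function(Y, position, condition, center, sigma_g,
                              nonzero = Y > 0, trunc_sd = 4) {
  condition <- factor(condition)
  keep <- abs(position - center) <= trunc_sd * sigma_g
  Y <- Y[keep]; position <- position[keep]
  condition <- droplevels(condition[keep]); nonzero <- nonzero[keep]
  frag <- factor(position)
  F_ <- nlevels(frag); J <- nlevels(condition)
  fi <- as.integer(frag); ci <- as.integer(condition)
  nnz <- matrix(0, F_, J)
  for (k in seq_along(Y)) {
    nnz[fi[k], ci[k]] <- nnz[fi[k], ci[k]] + nonzero[k]
  }
  wg <- exp(-(as.numeric(levels(frag)) - center)^2 / (2 * sigma_g^2))
  W_obs <- wg[fi] * (nnz[cbind(fi, ci)] + 0.5)
  n <- length(Y)
  X <- matrix(0, n, F_ + J)
  X[cbind(seq_len(n), fi)] <- 1
  X[cbind(seq_len(n), F_ + ci)] <- 1
  g <- c(wg, rep(0, J))
  M <- rbind(cbind(crossprod(X, W_obs * X), g), c(g, 0))
  rhs <- c(crossprod(X, W_obs * Y), 0)
  theta <- solve(M, rhs)[seq_len(F_ + J)]
  a <- theta[seq_len(F_)]; b <- theta[F_ + seq_len(J)]
  # sandwich covariance of the constrained b, via the pinned parameterization
  Xp <- X[, -1, drop = FALSE]
  Minv <- solve(crossprod(Xp, W_obs * Xp))
  M2 <- crossprod(Xp, W_obs^2 * Xp)
  covth <- Minv %*% M2 %*% Minv
  gfull <- wg / sum(wg)
  Tm <- matrix(0, J, ncol(Xp))
  for (j in seq_len(J)) {
    Tm[j, seq_len(F_ - 1)] <- gfull[-1]
    Tm[j, (F_ - 1) + j] <- Tm[j, (F_ - 1) + j] + 1
  }
  rss <- sum(W_obs * (Y - X %*% c(a, b))^2)
  sigma2 <- rss / (sum(W_obs) - sum(diag(Minv %*% M2)))
  list(a = a, b = b, cov_b_unit = Tm %*% covth %*% t(Tm),
       rss = rss, sigma2 = sigma2)
}

# random small LWMR instance for oracle comparisons
random_lwmr_instance <- function(max_frag = 5, max_cond = 3, max_rep = 4) {
  F_ <- sample(2:max_frag, 1)
  J <- sample(1:max_cond, 1)
  R <- sample(2:max_rep, 1)
  pos <- sort(sample(seq(1000, 9000, by = 50), F_))
  obs <- expand.grid(f = seq_len(F_), j = seq_len(J), r = seq_len(R))
  Y <- stats::rnorm(nrow(obs), 0.3, 0.15)
  Y[stats::runif(nrow(obs)) < 0.2] <- 0
  Y <- pmax(Y, 0)
  list(Y = Y, position = pos[obs$f], condition = paste0("c", obs$j),
       center = sample(3000:7000, 1))
}

# circular distance between two clock phases (hours)
phase_err <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# noiseless fourc_counts whose condition effects are an exact shifted cosine:
# Y(condition at time t) = level + cos(2*pi*(t - t0)/period), constant across
# fragments and replicates
cosine_counts <- function(t0, times = c(0, 4, 8, 12, 16, 20), level = 1.5,
                          n_frag = 30, n_rep = 2, P = 500) {
  frag <- data.frame(fragment_id = seq_len(n_frag), chrom = "chrT",
                     start = (seq_len(n_frag) - 1) * 250,
                     end = seq_len(n_frag) * 250)
  cond <- sprintf("ZT%02d", times)
  samples <- data.frame(
    sample_id = paste0(rep(cond, each = n_rep), "_r", seq_len(n_rep)),
    condition = rep(cond, each = n_rep),
    time = rep(times, each = n_rep),
    genotype = "WT", replicate = rep(seq_len(n_rep), length(times)))
  Yj <- level + cos(2 * pi * (times - t0) / 24)
  scores <- matrix(rep(P * (10^Yj - 1), each = n_rep),
                   nrow = n_frag, ncol = nrow(samples), byrow = TRUE)
  cts <- new_fourc_counts(frag, samples = samples,
                          bait = list(chrom = "chrT", pos = 1),
                          scores = scores)
  cts$normalized <- TRUE
  cts
}
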