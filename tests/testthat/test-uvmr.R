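# Univariable estimators against hand arithmetic and independent oracles.

test_that("Wald ratios follow direct division", {
  h <- make_harmonized(bx = 0.1, by = 0.02, sey = 0.1)
  r <- ratio_estimates(h)
  expect_equal(r$ratio, 0.2)
  expect_equal(r$ratio_se, 1.0)

  h0 <- make_harmonized(bx = c(0.1, 0.2, 0.4), by = rep(0, 3),
                        sey = rep(0.05, 3))
  expect_equal(ratio_estimates(h0)$ratio, rep(0, 3))

  h3 <- make_harmonized(bx = c(0.1, -0.2, 0.5), by = c(0.03, -0.08, 0.1),
                        sey = c(0.02, 0.05, 0.01))
  r3 <- ratio_estimates(h3)
  expect_equal(r3$ratio, c(0.3, 0.4, 0.2))
  expect_equal(r3$ratio_se, c(0.2, 0.25, 0.02))

  hz <- make_harmonized(bx = c(0.1, 0), by = c(0.1, 0.1), sey = c(0.1, 0.1))
  expect_error(ratio_estimates(hz), class = "mrpath_error_degenerate",
               regexp = "rs002")
})

test_that("IVW handles degenerate and single-instrument inputs", {
  h <- make_harmonized(bx = c(0.1, 0.1), by = c(0.02, 0.02),
                       sey = c(0.1, 0.1))
  est <- mr_ivw(h, mode = "fixed")
  expect_equal(est$b, 0.2)
  expect_equal(est$q, 0)

  h1 <- make_harmonized(bx = 0.1, by = 0.02, sey = 0.1)
  expect_warning(w <- mr_ivw(h1), class = "mrpath_warning_single_snp")
  expect_equal(w$b, 0.2)
  expect_equal(w$se, 1.0)
})

test_that("IVW equals a weighted through-origin regression oracle", {
  set.seed(11)
  bx <- runif(5, 0.05, 0.3)
  by <- 0.4 * bx + rnorm(5, 0, 0.02)
  sey <- runif(5, 0.01, 0.05)
  h <- make_harmonized(bx, by, sey)
  est <- mr_ivw(h, mode = "fixed")
  fit <- lm(by ~ 0 + bx, weights = 1 / sey^2)
  expect_rel_equal(est$b, unname(coef(fit)))
  # Fixed-effect SE is the model-based (sigma = 1) weighted LS SE.
  se_oracle <- unname(sqrt(diag(vcov(fit)))) / summary(fit)$sigma
  expect_rel_equal(est$se, se_oracle)
})

test_that("random-effects SE inflates by the Q multiplier, floored at one", {
  set.seed(12)
  bx <- runif(8, 0.1, 0.3)
  by <- 0.3 * bx + rnorm(8, 0, 0.1)    # overdispersed
  h <- make_harmonized(bx, by, sey = rep(0.02, 8))
  fixed <- mr_ivw(h, mode = "fixed")
  random <- mr_ivw(h, mode = "random")
  expect_gte(random$se, fixed$se)
  expect_rel_equal(random$se,
                   fixed$se * max(1, sqrt(fixed$q / (nrow(h) - 1))))
  # Homogeneous data: floor applies, random == fixed.
  h2 <- make_harmonized(bx = c(0.1, 0.2, 0.3), by = c(0.03, 0.06, 0.09),
                        sey = rep(0.05, 3))
  expect_equal(mr_ivw(h2, mode = "random")$se, mr_ivw(h2, mode = "fixed")$se)
  # Auto mode picks random effects exactly when Q rejects.
  auto <- mr_ivw(h, mode = "auto")
  expect_equal(auto$method,
               if (fixed$q_p < 0.05) "IVW-random" else "IVW")
})

test_that("Egger recovers an exact line and matches a weighted lm oracle", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  by <- 0.01 + 0.3 * bx
  h <- make_harmonized(bx, by, sey = rep(0.05, 4))
  est <- mr_egger(h)
  expect_equal(est$b, 0.3, tolerance = 1e-12)
  expect_equal(est$egger_intercept, 0.01, tolerance = 1e-12)

  # Exact proportionality: intercept 0, test statistic 0.
  h0 <- make_harmonized(bx, 0.3 * bx, sey = rep(0.05, 4))
  est0 <- mr_egger(h0)
  expect_equal(est0$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(est0$egger_intercept_p, 1, tolerance = 1e-9)

  # Noisy fixture vs lm(): slope, intercept and (overdispersion-floored) SEs.
  set.seed(13)
  bx6 <- runif(6, 0.05, 0.4)
  by6 <- 0.02 + 0.25 * bx6 + rnorm(6, 0, 0.05)
  sey6 <- runif(6, 0.01, 0.04)
  h6 <- make_harmonized(bx6, by6, sey6)
  est6 <- mr_egger(h6)
  fit <- lm(by6 ~ bx6, weights = 1 / sey6^2)
  expect_rel_equal(est6$b, unname(coef(fit)[2]))
  expect_rel_equal(est6$egger_intercept, unname(coef(fit)[1]))
  sigma2 <- summary(fit)$sigma^2
  scale <- sqrt(max(1, sigma2) / sigma2)
  expect_rel_equal(est6$se, unname(sqrt(diag(vcov(fit)))[2]) * scale)
  expect_rel_equal(est6$egger_intercept_se,
                   unname(sqrt(diag(vcov(fit)))[1]) * scale)
})

test_that("Egger orients exposure effects and rejects constant ones", {
  set.seed(14)
  bx <- runif(6, 0.1, 0.4)
  by <- 0.02 + 0.25 * bx + rnorm(6, 0, 0.03)
  h <- make_harmonized(bx, by, sey = rep(0.03, 6))
  flipped <- h
  flipped$beta_exposure[2] <- -flipped$beta_exposure[2]
  flipped$beta_outcome[2] <- -flipped$beta_outcome[2]
  a <- mr_egger(h); b <- mr_egger(flipped)
  expect_equal(a$b, b$b)
  expect_equal(a$egger_intercept, b$egger_intercept)
  hc <- make_harmonized(bx = c(0.2, -0.2, 0.2), by = c(0.1, 0.2, 0.3),
                        sey = rep(0.05, 3))
  expect_error(mr_egger(hc), class = "mrpath_error_collinear")
})

wm_oracle <- function(ratio, weight) {
  # Brute-force interpolation over sorted cumulative weights.
  ord <- order(ratio)
  r <- ratio[ord]; w <- weight[ord] / sum(weight)
  p <- numeric(length(w))
  for (j in seq_along(w)) p[j] <- sum(w[seq_len(j)]) - w[j] / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  j <- max(which(p <= 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

test_that("weighted median interpolates the weight-ordered ratios", {
  # Equal weights on {1,2,3}: the middle ratio sits exactly at p = 0.5.
  h <- make_harmonized(bx = c(1, 1, 1), by = c(1, 2, 3), sey = rep(1, 3))
  est <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(est$b, 2)

  # A dominant weight drags the estimate to its ratio.
  hd <- make_harmonized(bx = c(1, 1, 1), by = c(1, 2, 3),
                        sey = c(0.001, 1, 1))
  estd <- mr_weighted_median(hd, n_boot = 100, seed = 1)
  expect_equal(estd$b, 1, tolerance = 1e-3)

  # Unequal-weight fixture vs the brute-force oracle.
  set.seed(15)
  bx <- runif(5, 0.1, 0.4)
  by <- 0.3 * bx + rnorm(5, 0, 0.05)
  sey <- runif(5, 0.02, 0.1)
  h5 <- make_harmonized(bx, by, sey)
  r <- ratio_estimates(h5)
  expect_rel_equal(mr_weighted_median(h5, n_boot = 100, seed = 2)$b,
                   wm_oracle(r$ratio, 1 / r$ratio_se^2))

  # Estimate always lies inside the ratio range; seed is required.
  expect_true(min(r$ratio) <= mr_weighted_median(h5, 100, seed = 3)$b)
  expect_true(max(r$ratio) >= mr_weighted_median(h5, 100, seed = 3)$b)
  expect_error(mr_weighted_median(h5, 100), class = "mrpath_error_config")
})

test_that("Cochran's Q matches hand arithmetic and its scaling law", {
  h <- make_harmonized(bx = c(0.1, 0.2, 0.4), by = c(0.02, 0.04, 0.08),
                       sey = rep(0.05, 3))
  q <- cochran_q(h)
  expect_equal(q$q, 0)
  expect_equal(q$p, 1)

  h2 <- make_harmonized(bx = c(0.1, 0.2), by = c(0.02, 0.08),
                        sey = c(0.1, 0.1))
  # Hand: w = (1, 4), r = (0.2, 0.4); b = 1.8/5 = 0.36;
  # Q = 1*(0.2-0.36)^2 + 4*(0.4-0.36)^2 = 0.0256 + 0.0064 = 0.032.
  expect_equal(cochran_q(h2)$q, 0.032)

  h2s <- h2
  h2s$se_outcome <- h2$se_outcome * 10
  expect_equal(cochran_q(h2s)$q, 0.032 / 100)
})

test_that("leave-one-out isolates a planted outlier", {
  set.seed(16)
  bx <- runif(8, 0.1, 0.4)
  by <- 0.3 * bx + rnorm(8, 0, 0.005)
  h <- make_harmonized(bx, by, sey = rep(0.02, 8))
  loo <- leave_one_out(h, mode = "fixed")
  expect_equal(nrow(loo), 9)
  full_b <- loo$b[loo$variant_id == "(all)"]
  expect_true(all(abs(loo$b - full_b) < 0.05))

  # Outlier at 10x the common ratio: omitting it moves the estimate most.
  h$beta_outcome[3] <- 3 * h$beta_exposure[3]
  loo2 <- leave_one_out(h, mode = "fixed")
  full2 <- loo2$b[loo2$variant_id == "(all)"]
  departures <- abs(loo2$b[loo2$variant_id != "(all)"] - full2)
  expect_equal(which.max(departures), 3)
})

test_that("odds-ratio conversion reproduces reported rounding", {
  expect_equal(to_odds_ratio(0, 0.1)$or, 1)
  expect_equal(round(to_odds_ratio(0.127, 0.041)$or, 3), 1.135)
  expect_equal(round(to_odds_ratio(0.155, 0.052)$or, 3), 1.168)
  x <- to_odds_ratio(0.5, 0.1)
  expect_lt(x$or_low, x$or)
  expect_gt(x$or_high, x$or)
})

test_that("estimators are invariant to row permutation and per-variant sign flips", {
  set.seed(17)
  bx <- runif(7, 0.05, 0.4)
  by <- 0.3 * bx + rnorm(7, 0, 0.03)
  sey <- runif(7, 0.01, 0.05)
  h <- make_harmonized(bx, by, sey)
  perm <- h[sample(7), ]
  flip <- h
  flip$beta_exposure[4] <- -flip$beta_exposure[4]
  flip$beta_outcome[4] <- -flip$beta_outcome[4]
  for (variant in list(perm, flip)) {
    expect_equal(mr_ivw(variant, "fixed")$b, mr_ivw(h, "fixed")$b)
    expect_equal(mr_egger(variant)$b, mr_egger(h)$b)
    expect_equal(mr_weighted_median(variant, 100, seed = 5)$b,
                 mr_weighted_median(h, 100, seed = 5)$b)
  }
})
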