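test_that("Wald ratios follow the first- and second-order formulas", {
  h <- make_harmonized(0.2, 0.02, 0.1, 0.05)
  r1 <- wald_ratios(h)
  expect_equal(r1$theta, 0.5)
  expect_equal(r1$sigma, 0.25)
  expect_equal(r1$weights, 0.25^-2)
  r2 <- wald_ratios(h, se_order = "second")
  expect_equal(r2$sigma, sqrt(0.05^2 / 0.2^2 + 0.1^2 * 0.02^2 / 0.2^4))
  # null numerator
  h0 <- make_harmonized(0.2, 0.02, 0, 0.05)
  r0 <- wald_ratios(h0)
  expect_equal(r0$theta, 0)
  expect_equal(r0$sigma, 0.05 / 0.2)
  expect_error(wald_ratios(make_harmonized(0, 0.02, 0.1, 0.05)),
               "input error")
})

test_that("second-order ratio SE agrees with a finite-difference delta-method oracle", {
  set.seed(4)
  for (i in 1:20) {
    bx <- runif(1, 0.05, 0.3) * sample(c(-1, 1), 1)
    by <- rnorm(1, 0, 0.1)
    sx <- runif(1, 0.005, 0.05)
    sy <- runif(1, 0.005, 0.05)
    f <- function(x, y) y / x
    eps <- 1e-6
    gx <- (f(bx + eps, by) - f(bx - eps, by)) / (2 * eps)
    gy <- (f(bx, by + eps) - f(bx, by - eps)) / (2 * eps)
    oracle <- sqrt(gx^2 * sx^2 + gy^2 * sy^2)
    got <- wald_ratios(make_harmonized(bx, sx, by, sy),
                       se_order = "second")$sigma
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("IVW reduces to the Wald ratio at J=1 and averages with equal weights", {
  one <- ivw(ratio_estimates("v1", 0.5, 0.25))
  expect_equal(one$theta, 0.5)
  expect_equal(one$se, 0.25)
  two <- ivw(ratio_estimates(c("v1", "v2"), c(0.5, 0.3), c(0.25, 0.25)))
  expect_equal(two$theta, 0.4)
  expect_equal(two$se, 0.25 / sqrt(2))
  # zero heterogeneity: random-effects SE equals fixed SE
  same <- ratio_estimates(paste0("v", 1:3), rep(0.7, 3), c(0.1, 0.2, 0.3))
  expect_equal(ivw(same)$heterogeneity_Q, 0)
  expect_equal(ivw(same, "multiplicative_random")$se, ivw(same)$se)
  expect_equal(ivw(same)$theta, 0.7)
  expect_error(ivw(ratio_estimates(character(0), numeric(0), numeric(0))),
               "analysis error")
})

test_that("IVW equals origin-constrained weighted regression", {
  set.seed(91)
  for (i in 1:20) {
    J <- sample(3:40, 1)
    bx <- runif(J, 0.03, 0.2) * sample(c(-1, 1), J, TRUE)
    by <- 0.25 * bx + rnorm(J, 0, 0.02)
    sy <- runif(J, 0.005, 0.05)
    h <- make_harmonized(bx, 0.01, by, sy)
    est <- ivw(wald_ratios(h))
    fit <- lm(by ~ 0 + bx, weights = sy^-2)
    expect_equal(est$theta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("Egger recovers slope and intercept exactly on exact linear data", {
  bx <- c(0.1, 0.2, 0.3)
  by <- 0.02 + 0.5 * bx
  h <- make_harmonized(bx, 0.01, by, c(0.03, 0.05, 0.02))
  est <- egger(h)
  expect_equal(est$theta, 0.5, tolerance = 1e-10)
  expect_equal(est$intercept, 0.02, tolerance = 1e-10)
  expect_equal(est$heterogeneity_Q, 0, tolerance = 1e-15)
})

test_that("Egger is invariant to flipping a variant's orientation on input", {
  set.seed(8)
  J <- 12
  bx <- runif(J, 0.05, 0.2)
  by <- 0.01 + 0.4 * bx + rnorm(J, 0, 0.01)
  sy <- runif(J, 0.01, 0.03)
  h1 <- make_harmonized(bx, 0.01, by, sy)
  flip <- c(2, 5, 9)
  bx2 <- bx; by2 <- by
  bx2[flip] <- -bx2[flip]; by2[flip] <- -by2[flip]
  h2 <- make_harmonized(bx2, 0.01, by2, sy)
  e1 <- egger(h1); e2 <- egger(h2)
  expect_equal(e1$theta, e2$theta)
  expect_equal(e1$intercept, e2$intercept)
  expect_equal(e1$se, e2$se)
  expect_error(egger(make_harmonized(c(0.1, 0.2), 0.01, c(0.1, 0.2),
                                     c(0.01, 0.01))), "analysis error")
  expect_error(egger(make_harmonized(rep(0.1, 4), 0.01, rep(0.05, 4),
                                     rep(0.01, 4))), "singular")
})

test_that("Egger slope and intercept CIs cover truth under directional pleiotropy (InSIDE)", {
  set.seed(12)
  hits <- c(slope = 0, intercept = 0)
  n_rep <- 40
  for (i in 1:n_rep) {
    J <- 50
    bx <- runif(J, 0.05, 0.2)
    alpha <- rnorm(J, 0.03, 0.01)          # directional pleiotropy, InSIDE
    sy <- runif(J, 0.01, 0.02)
    by <- 0.2 * bx + alpha + rnorm(J, 0, sy)
    est <- egger(make_harmonized(bx, 0.005, by, sy))
    if (est$ci_low <= 0.2 && 0.2 <= est$ci_high) hits["slope"] <- hits["slope"] + 1
    ilo <- est$intercept - 1.96 * est$intercept_se
    ihi <- est$intercept + 1.96 * est$intercept_se
    if (ilo <= 0.03 && 0.03 <= ihi) hits["intercept"] <- hits["intercept"] + 1
  }
  expect_gte(hits[["slope"]] / n_rep, 0.85)
  expect_gte(hits[["intercept"]] / n_rep, 0.85)
})

test_that("weighted median interpolates the percentile formula", {
  r_eq <- ratio_estimates(paste0("v", 1:3), c(0.2, 0.5, 0.9),
                          rep(1, 3))
  expect_equal(weighted_median(r_eq, n_boot = 50, seed = 1)$theta, 0.5)
  # weights proportional to (1, 1, 8): hand-evaluated interpolation
  r_w <- ratio_estimates(paste0("v", 1:3), c(0.2, 0.5, 0.9),
                         c(1, 1, 1 / sqrt(8)))
  est <- weighted_median(r_w, n_boot = 50, seed = 1)
  expect_equal(est$theta, 0.5 + 0.4 * (50 - 15) / (60 - 15),
               tolerance = 1e-9)
  expect_equal(est$theta,
               brute_weighted_median(c(0.2, 0.5, 0.9), c(1, 1, 8)),
               tolerance = 1e-3)
  expect_error(weighted_median(ratio_estimates("v", 0.1, 0.1)),
               "analysis error")
})

test_that("weighted median bootstrap SE is small and seed-stable on degenerate input", {
  r <- ratio_estimates(paste0("v", 1:5), rep(0.4, 5), rep(0.001, 5))
  e1 <- weighted_median(r, n_boot = 200, seed = 3)
  e2 <- weighted_median(r, n_boot = 200, seed = 3)
  expect_equal(e1$se, e2$se)
  expect_equal(e1$theta, 0.4)
  expect_lt(e1$se, 0.01)
  e3 <- weighted_median(r, n_boot = 200, seed = 4)
  expect_lt(abs(e3$se - e1$se) / e1$se, 1)  # stable across seeds
})

test_that("mode-based estimation returns the point mass and resists outliers", {
  r0 <- ratio_estimates(paste0("v", 1:4), rep(0.4, 4), rep(0.05, 4))
  expect_equal(mode_based(r0, n_boot = 50, seed = 1)$theta, 0.4)
  set.seed(6)
  theta <- c(rnorm(28, 0.2, 0.02), 1.5, 1.5)
  sig <- rep(0.05, 30)
  r <- ratio_estimates(sprintf("v%02d", 1:30), theta, sig)
  est <- mode_based(r, n_boot = 100, seed = 2)
  expect_lt(abs(est$theta - 0.2), 0.05)
  expect_gt(abs(mean(theta) - 0.2), 0.05)  # the unweighted mean is pulled
  # dense-grid brute force agrees with the grid argmax
  grid <- mrpipe:::mode_grid(theta, max(sig))
  bw <- 0.9 * min(sd(theta), mad(theta)) * 30^(-1 / 5)
  wn <- r$weights / sum(r$weights)
  dens <- sapply(grid, function(x) sum(wn * dnorm((x - theta) / bw)) / bw)
  expect_equal(est$theta, grid[which.max(dens)])
})

test_that("doubling phi never increases the number of density local maxima", {
  set.seed(26)
  theta <- c(rnorm(15, 0, 0.05), rnorm(15, 1, 0.05))
  w <- rep(1, 30)
  n_modes <- function(phi) {
    bw <- phi * 0.9 * min(sd(theta), mad(theta)) * 30^(-1 / 5)
    grid <- mrpipe:::mode_grid(theta, 0.05)
    d <- sapply(grid, function(x) sum(w * dnorm((x - theta) / bw)) / bw)
    sum(diff(sign(diff(d))) == -2)
  }
  for (phi in c(0.25, 0.5, 1, 2)) {
    expect_gte(n_modes(phi), n_modes(2 * phi))
  }
})

test_that("penalized weights leave consistent variants alone and shrink outliers", {
  r <- ratio_estimates(paste0("v", 1:4), c(0.3, 0.31, 0.29, 0.3),
                       rep(0.1, 4))
  pen <- penalized_weights(r, 0.3)
  expect_equal(pen$weights, r$weights)  # all q_j >= 0.05
  # a variant with q_j = 0.001 gets weight multiplied by 0.02
  q_target <- 0.001
  Qj <- qchisq(q_target, df = 1, lower.tail = FALSE)
  sigma <- 0.1
  theta_out <- 0.3 + sqrt(Qj) * sigma
  r2 <- ratio_estimates(paste0("v", 1:2), c(0.3, theta_out), rep(sigma, 2))
  pen2 <- penalized_weights(r2, 0.3)
  expect_equal(pen2$weights[2] / r2$weights[2], 20 * q_target,
               tolerance = 1e-9)
  expect_error(penalized_weights(r, Inf), "input error")
})

test_that("penalised IVW moves toward the valid variants when an outlier is planted", {
  set.seed(19)
  J <- 30
  theta <- c(rnorm(J - 2, 0.3, 0.01), 1.2, 1.3)
  sig <- c(runif(J - 2, 0.02, 0.05), 0.02, 0.02)
  r <- ratio_estimates(sprintf("v%02d", 1:J), theta, sig)
  plain <- ivw(r)$theta
  pen <- ivw_penalized(r)$theta
  expect_lt(abs(pen - 0.3), abs(plain - 0.3))
})

test_that("estimators are equivariant under outcome rescaling", {
  set.seed(44)
  J <- 25
  bx <- runif(J, 0.05, 0.2) * sample(c(-1, 1), J, TRUE)
  by <- 0.3 * bx + rnorm(J, 0, 0.01)
  sy <- runif(J, 0.01, 0.03)
  h1 <- make_harmonized(bx, 0.005, by, sy)
  cc <- 3.7
  h2 <- make_harmonized(bx, 0.005, cc * by, cc * sy)
  for (fit in list(ivw, function(r) weighted_median(r, 200, seed = 2))) {
    e1 <- fit(wald_ratios(h1)); e2 <- fit(wald_ratios(h2))
    expect_equal(e2$theta, cc * e1$theta, tolerance = 1e-8)
    expect_equal(e2$se, cc * e1$se, tolerance = 1e-8)
  }
  g1 <- egger(h1); g2 <- egger(h2)
  expect_equal(g2$theta, cc * g1$theta, tolerance = 1e-8)
  expect_equal(g2$se, cc * g1$se, tolerance = 1e-8)
})

test_that("estimate p-values match the two-sided normal tail of theta/se", {
  set.seed(3)
  r <- ratio_estimates(paste0("v", 1:10), rnorm(10, 0.2, 0.1),
                       runif(10, 0.05, 0.2))
  for (est in list(ivw(r), ivw(r, "multiplicative_random"),
                   weighted_median(r, 100, seed = 1))) {
    expect_equal(est$pvalue, 2 * pnorm(-abs(est$theta / est$se)),
                 tolerance = 1e-6)
    expect_lte(est$ci_low, est$theta)
    expect_gte(est$ci_high, est$theta)
  }
})

test_that("the mr() battery bundles methods with coef/confint/summary accessors", {
  sim <- simulate_two_sample(truth_record(theta = 0.3, J = 40, seed = 13))
  h <- harmonize(sim$exposures, sim$outcome, sim$instruments,
                 direct_effect_p = 0)
  fit <- mr(h, n_boot = 100, seed = 13)
  expect_s3_class(fit, "mr_fit")
  expect_named(coef(fit), c("ivw", "egger", "weighted_median",
                            "mode_based", "ivw_penalized"))
  ci <- confint(fit)
  expect_equal(nrow(ci), 5L)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  s <- summary(fit)
  expect_equal(s$theta[s$method == "ivw"], fit$estimates$ivw$theta)
  res <- residuals(fit)
  expect_length(res, length(h$variant_ids))
})
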