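#' Per-variant Wald ratios
#'
#' The building block of all univariable two-sample MR estimators: for
#' each instrument j, the ratio estimate theta_j = beta_Yj / beta_Xj of
#' the causal effect, with either the first-order standard error
#' se_Yj / |beta_Xj| (default) or the second-order delta-method error
#' that also propagates the exposure uncertainty.
#'
#' @param h A `harmonized_set`.
#' @param exposure_index Which exposure column to use (default 1).
#' @param se_order `"first"` or `"second"`.
#' @return A `ratio_estimates` object: list with `variant_ids`, `theta`
#'   (ratios), `sigma` (their SEs) and `weights` (= sigma^-2).
#' @export
wald_ratios <- function(h, exposure_index = 1L,
                        se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  bx <- h$beta_exp[, exposure_index]
  sx <- h$se_exp[, exposure_index]
  by <- h$beta_out
  sy <- h$se_out
  if (any(bx == 0)) {
    stop("input error: zero exposure effect for variant(s): ",
         paste(h$variant_ids[bx == 0], collapse = ", "))
  }
  theta <- by / bx
  sigma <- if (se_order == "first") sy / abs(bx)
           else sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  ratio_estimates(h$variant_ids, theta, sigma)
}

#' Construct ratio estimates directly
#'
#' @param variant_ids Character vector.
#' @param theta Per-variant ratio estimates.
#' @param sigma Their positive standard errors.
#' @return A `ratio_estimates` object.
#' @export
ratio_estimates <- function(variant_ids, theta, sigma) {
  stopifnot(length(theta) == length(sigma),
            length(variant_ids) == length(theta))
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("input error: ratio SEs must be positive and finite")
  }
  structure(list(variant_ids = as.character(variant_ids),
                 theta = as.numeric(theta),
                 sigma = as.numeric(sigma),
                 weights = as.numeric(sigma)^-2),
            class = "ratio_estimates")
}

#' @export
print.ratio_estimates <- function(x, ...) {
  cat(sprintf("Wald ratios for %d variants (median theta %.4g)\n",
              length(x$theta), stats::median(x$theta)))
  invisible(x)
}

# assemble an mr_estimate; p-value is the two-sided normal tail of theta/se
mr_estimate <- function(method, theta, se, n_variants,
                        intercept = NA_real_, intercept_se = NA_real_,
                        Q = NA_real_, notes = "", seed = NA_integer_) {
  z <- theta / se
  structure(list(method = method, theta = theta, se = se,
                 ci_low = theta - stats::qnorm(0.975) * se,
                 ci_high = theta + stats::qnorm(0.975) * se,
                 pvalue = 2 * stats::pnorm(-abs(z)),
                 n_variants = n_variants,
                 intercept = intercept, intercept_se = intercept_se,
                 heterogeneity_Q = Q, notes = notes, seed = seed),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: theta = %.4g (SE %.4g, 95%% CI %.4g to %.4g), p = %.3g, %d variants\n",
              x$method, x$theta, x$se, x$ci_low, x$ci_high, x$pvalue,
              x$n_variants))
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept = %.4g (SE %.4g)\n", x$intercept, x$intercept_se))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_variants = x$n_variants,
             theta = x$theta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, pvalue = x$pvalue,
             intercept = x$intercept, intercept_se = x$intercept_se,
             Q = x$heterogeneity_Q, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted MR
#'
#' Precision-weighted mean of the Wald ratios. The fixed-effect model
#' reports SE = (sum of weights)^(-1/2); the multiplicative random-effects
#' model inflates it by max(1, sqrt(Q/(J-1))) where Q is Cochran's
#' heterogeneity statistic.
#'
#' @param r A `ratio_estimates` object.
#' @param model `"fixed"` or `"multiplicative_random"`.
#' @return An `mr_estimate`.
#' @export
ivw <- function(r, model = c("fixed", "multiplicative_random")) {
  model <- match.arg(model)
  J <- length(r$theta)
  if (J < 1L) stop("analysis error: IVW requires at least one variant")
  if (model == "multiplicative_random" && J < 2L) {
    stop("analysis error: random-effects IVW requires J >= 2")
  }
  w <- r$weights
  theta <- sum(w * r$theta) / sum(w)
  se <- sum(w)^-0.5
  Q <- sum(w * (r$theta - theta)^2)
  if (model == "multiplicative_random") {
    se <- se * max(1, sqrt(Q / (J - 1)))
  }
  mr_estimate(if (model == "fixed") "ivw" else "ivw_mre",
              theta, se, J, Q = Q)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept, after orienting every variant so the exposure effect is
#' positive. The slope estimates the causal effect under the InSIDE
#' assumption (instrument strength independent of direct effects); the
#' intercept estimates average directional pleiotropy. Standard errors use
#' multiplicative scaling by max(1, residual standard error).
#'
#' @param h A `harmonized_set` (needs at least 3 variants).
#' @param exposure_index Exposure column.
#' @return An `mr_estimate` with slope as `theta` and the pleiotropy
#'   intercept in `intercept`.
#' @export
egger <- function(h, exposure_index = 1L) {
  bx <- h$beta_exp[, exposure_index]
  by <- h$beta_out
  sy <- h$se_out
  J <- length(bx)
  if (J < 3L) stop("analysis error: MR-Egger requires J >= 3")
  flip <- sign(bx)
  flip[flip == 0] <- 1
  bx <- bx * flip
  by <- by * flip
  if (max(bx) - min(bx) < .Machine$double.eps^0.5 * max(abs(bx), 1)) {
    stop("singular-design error: no spread in exposure effects")
  }
  w <- sy^-2
  fit <- stats::lm(by ~ bx, weights = w)
  sigma <- sqrt(sum(w * fit$residuals^2) / (J - 2L))
  X <- cbind(1, bx)
  se_unscaled <- sqrt(diag(solve(crossprod(X * sqrt(w)))))
  scale <- max(1, sigma)
  mr_estimate("egger", unname(stats::coef(fit)["bx"]),
              se_unscaled[2] * scale, J,
              intercept = unname(stats::coef(fit)["(Intercept)"]),
              intercept_se = se_unscaled[1] * scale,
              Q = sum(w * fit$residuals^2))
}

# weighted-median point estimate on sorted ratios; interpolation of the
# standardized cumulative-weight percentiles at 50
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  S <- cumsum(w)
  p <- 100 * (S - w / 2) / S[length(S)]
  if (p[1] >= 50) return(theta[1])
  if (p[length(p)] <= 50) return(theta[length(theta)])
  stats::approx(p, theta, xout = 50)$y
}

#' Weighted-median MR
#'
#' The median of the inverse-variance-weighted distribution of Wald
#' ratios: consistent when variants contributing at least half the weight
#' are valid instruments, so it tolerates up to 50% invalid variants.
#' The SE comes from a parametric bootstrap (ratios resampled from
#' Normal(theta_j, sigma_j)).
#'
#' @param r A `ratio_estimates` object (J >= 3).
#' @param n_boot Bootstrap replicates for the SE.
#' @param seed Integer seed for the bootstrap (recorded in the output).
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(r, n_boot = 1000L, seed = 1L) {
  J <- length(r$theta)
  if (J < 3L) stop("analysis error: weighted median requires J >= 3")
  est <- weighted_median_point(r$theta, r$weights)
  boots <- with_seed(seed, {
    draws <- matrix(stats::rnorm(J * n_boot, r$theta, r$sigma), nrow = J)
    apply(draws, 2, weighted_median_point, w = r$weights)
  })
  mr_estimate("weighted_median", est, stats::sd(boots), J,
              notes = sprintf("bootstrap n=%d", n_boot), seed = seed)
}

# weighted KDE argmax over a fixed grid; ties go to the smaller grid value
mode_point <- function(theta, w, phi = 1, grid = NULL) {
  h_sil <- 0.9 * min(stats::sd(theta), stats::mad(theta)) * length(theta)^(-1/5)
  bw <- phi * h_sil
  if (!is.finite(bw) || bw <= 0) return(theta[1])  # all ratios identical
  if (is.null(grid)) grid <- mode_grid(theta, max(1 / sqrt(w)))
  wn <- w / sum(w)
  dens <- colSums(wn * stats::dnorm(outer(theta, grid, "-") / bw)) / bw
  grid[which.max(dens)]
}

mode_grid <- function(theta, max_sigma, n = 512L) {
  seq(min(theta) - 3 * max_sigma, max(theta) + 3 * max_sigma, length.out = n)
}

# bootstrap KDE argmaxes for all resamples at once; per-resample
# bandwidth, density evaluated on the point estimate's grid (the argmax
# is unaffected by the per-resample 1/bw and weight normalisation)
mode_boot_argmax <- function(draws, w, phi, grid) {
  J <- nrow(draws); B <- ncol(draws)
  sds <- apply(draws, 2, stats::sd)
  mads <- apply(draws, 2, stats::mad)
  bw <- phi * 0.9 * pmin(sds, mads) * J^(-1 / 5)
  bw[!is.finite(bw) | bw <= 0] <- .Machine$double.eps^0.5
  chunk <- max(1L, floor(2e7 / (J * length(grid))))
  out <- numeric(B)
  for (start in seq(1L, B, by = chunk)) {
    b_idx <- start:min(start + chunk - 1L, B)
    nb <- length(b_idx)
    dev <- outer(as.vector(draws[, b_idx]), grid, "-") /
      bw[rep(b_idx, each = J)]
    K <- exp(-0.5 * dev * dev) * w
    dens <- rowsum(K, group = rep(seq_len(nb), each = J), reorder = FALSE)
    out[b_idx] <- grid[max.col(dens, ties.method = "first")]
  }
  out
}

#' Mode-based MR estimation
#'
#' Estimates the causal effect as the mode of the weighted kernel density
#' of the Wald ratios (normal kernel, bandwidth phi times a modified
#' Silverman rule). Consistent under the zero-modal-pleiotropy assumption:
#' the most common ratio value among instruments is the valid causal
#' effect, even if valid instruments are a minority by weight. The density
#' is maximised over a fixed 512-point grid spanning
#' [min theta - 3 max sigma, max theta + 3 max sigma]; ties at the argmax
#' resolve to the smaller grid value. SE by parametric bootstrap.
#'
#' @param r A `ratio_estimates` object (J >= 3).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return An `mr_estimate`.
#' @export
mode_based <- function(r, phi = 1, n_boot = 1000L, seed = 1L) {
  J <- length(r$theta)
  if (J < 3L) stop("analysis error: mode-based estimation requires J >= 3")
  grid <- mode_grid(r$theta, max(r$sigma))
  est <- mode_point(r$theta, r$weights, phi, grid)
  boots <- with_seed(seed, {
    draws <- matrix(stats::rnorm(J * n_boot, r$theta, r$sigma), nrow = J)
    mode_boot_argmax(draws, r$weights, phi, grid)
  })
  mr_estimate("mode_based", est, stats::sd(boots), J,
              notes = sprintf("phi=%g, bootstrap n=%d", phi, n_boot),
              seed = seed)
}

#' Penalise heterogeneous variants' weights
#'
#' Down-weights variants whose ratio departs from a reference estimate:
#' each variant's heterogeneity contribution Q_j = w_j (theta_j - ref)^2
#' is referred to a chi-square(1) upper tail q_j, and the weight is
#' multiplied by min(1, 20 q_j). Variants consistent with the reference
#' (q_j >= 0.05) keep their weight; strong outliers are suppressed.
#' Feeding the result back to [ivw()] gives the penalised IVW estimator.
#'
#' @param r A `ratio_estimates` object.
#' @param theta_ref Reference causal estimate (typically the IVW value).
#' @return A new `ratio_estimates` with updated weights and SEs.
#' @export
penalized_weights <- function(r, theta_ref) {
  if (!is.finite(theta_ref)) stop("input error: theta_ref must be finite")
  Qj <- r$weights * (r$theta - theta_ref)^2
  qj <- stats::pchisq(Qj, df = 1, lower.tail = FALSE)
  w_new <- r$weights * pmin(1, 20 * qj)
  w_new <- pmax(w_new, .Machine$double.xmin)  # keep sigma finite
  out <- r
  out$weights <- w_new
  out$sigma <- w_new^-0.5
  out
}

#' Penalised IVW
#'
#' IVW re-run on weights penalised around the initial IVW estimate; the
#' standard robust-MR sensitivity companion to the fixed-effect fit.
#'
#' @inheritParams ivw
#' @return An `mr_estimate` with method `"ivw_penalized"`.
#' @export
ivw_penalized <- function(r, model = "fixed") {
  ref <- ivw(r, model = "fixed")$theta
  est <- ivw(penalized_weights(r, ref), model = model)
  est$method <- "ivw_penalized"
  est
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
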