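#' Fit the univariable two-sample MR estimator battery
#'
#' The package's central fitting function: given a harmonized
#' exposure-outcome set, computes the fixed-effect inverse-variance
#' weighted estimate together with the pleiotropy-robust sensitivity
#' estimators (MR-Egger, weighted median, mode-based, penalised IVW).
#' Returns a classed object with `print`, `summary`, `coef`, `confint`
#' and `plot` methods.
#'
#' @param h A `harmonized_set`.
#' @param exposure_index Which exposure column to analyse (default 1).
#' @param methods Character vector of estimators to run, a subset of
#'   `"ivw"`, `"ivw_mre"`, `"egger"`, `"weighted_median"`, `"mode_based"`,
#'   `"ivw_penalized"`.
#' @param se_order Wald-ratio SE order, `"first"` (default) or `"second"`.
#' @param n_boot Bootstrap replicates for the median/mode SEs.
#' @param seed Integer seed for the bootstrap stages.
#' @param phi Mode-based bandwidth multiplier.
#' @return An `mr_fit` object: list with `estimates` (named list of
#'   `mr_estimate`), `ratios`, `exposure`, `outcome`, `seed`.
#' @examples
#' sim <- simulate_two_sample(truth_record(theta = 0.3, J = 50, seed = 7))
#' h <- harmonize(sim$exposures, sim$outcome, sim$instruments)
#' fit <- mr(h, seed = 7)
#' fit
#' coef(fit)
#' @export
mr <- function(h, exposure_index = 1L,
               methods = c("ivw", "egger", "weighted_median",
                           "mode_based", "ivw_penalized"),
               se_order = "first", n_boot = 1000L, seed = 1L, phi = 1) {
  allowed <- c("ivw", "ivw_mre", "egger", "weighted_median",
               "mode_based", "ivw_penalized")
  methods <- match.arg(methods, allowed, several.ok = TRUE)
  r <- wald_ratios(h, exposure_index, se_order = se_order)
  ests <- list()
  for (m in methods) {
    ests[[m]] <- switch(m,
      ivw = ivw(r, "fixed"),
      ivw_mre = ivw(r, "multiplicative_random"),
      egger = egger(h, exposure_index),
      weighted_median = weighted_median(r, n_boot = n_boot, seed = seed),
      mode_based = mode_based(r, phi = phi, n_boot = n_boot, seed = seed),
      ivw_penalized = ivw_penalized(r))
  }
  structure(list(estimates = ests, ratios = r,
                 exposure = h$exposure_names[exposure_index],
                 outcome = h$outcome_name, seed = seed),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d variants)\n",
              x$exposure, x$outcome, length(x$ratios$theta)))
  print(summary(x), ...)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  df <- do.call(rbind, lapply(object$estimates, as.data.frame))
  rownames(df) <- NULL
  df
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "theta")
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  th <- coef(object)
  se <- vapply(object$estimates, `[[`, numeric(1), "se")
  out <- cbind(th - z * se, th + z * se)
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Forest-style plot of an MR fit
#'
#' Point estimates and 95% intervals for each method, base graphics.
#'
#' @param x An `mr_fit`.
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, y, ...) {
  s <- summary(x)
  n <- nrow(s)
  graphics::plot(s$theta, seq_len(n), xlim = range(c(s$ci_low, s$ci_high, 0)),
                 yaxt = "n", ylab = "", pch = 15, col = "steelblue",
                 xlab = sprintf("causal estimate (%s on %s)",
                                x$exposure, x$outcome), ...)
  graphics::segments(s$ci_low, seq_len(n), s$ci_high, seq_len(n),
                     col = "steelblue")
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n), labels = s$method, las = 1)
  invisible(x)
}

#' Residuals of an MR fit
#'
#' Per-variant deviations of the outcome effects from the fitted causal
#' model, beta_Yj - theta_hat * beta_Xj, for the chosen method.
#'
#' @param object An `mr_fit`.
#' @param method Which estimate to use (default `"ivw"`).
#' @param ... Ignored.
#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  est <- object$estimates[[method]]
  if (is.null(est)) stop("input error: method not in fit: ", method)
  r <- object$ratios
  # on the ratio scale: theta_j - theta_hat, standardised by sigma_j
  (r$theta - est$theta) / r$sigma
}
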