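#' Joint multivariable MR
#'
#' Weighted regression of the outcome associations on all K exposures'
#' associations simultaneously, with no intercept and weights
#' se_out^-2. The coefficients are conditional (direct) causal effects of
#' each exposure given the others. Standard errors use multiplicative
#' scaling by max(1, residual standard error). With K = 1 this reduces
#' exactly to fixed-effect IVW on the same variants.
#'
#' @param h A `harmonized_set` with K exposure columns and J > K variants.
#' @return An `mvmr_fit`: list with `exposures`, `theta`, `se`, `pvalues`,
#'   `variant_count`, `approach`.
#' @export
mvmr_joint <- function(h) {
  X <- h$beta_exp
  K <- ncol(X)
  J <- nrow(X)
  if (J <= K) stop("analysis error: MVMR needs more variants than exposures")
  qrX <- qr(X)
  if (qrX$rank < K) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):K]]
    stop("singular-design error: collinear exposure columns: ",
         paste(bad, collapse = ", "))
  }
  w <- h$se_out^-2
  fit <- stats::lm.wfit(X, h$beta_out, w)
  sigma <- sqrt(sum(w * fit$residuals^2) / (J - K))
  XtWXinv <- solve(crossprod(X * sqrt(w)))
  se <- sqrt(diag(XtWXinv)) * max(1, sigma)
  theta <- fit$coefficients
  z <- theta / se
  structure(list(exposures = colnames(X), theta = unname(theta),
                 se = unname(se),
                 pvalues = unname(2 * stats::pnorm(-abs(z))),
                 variant_count = J, approach = "joint",
                 outcome = h$outcome_name),
            class = "mvmr_fit")
}

#' Residualized multivariable MR
#'
#' Two-stage variant of [mvmr_joint()]: the outcome associations are first
#' regressed (weighted, no intercept) on the non-target exposures, and the
#' residuals are used as a new outcome in a through-the-origin weighted
#' regression on the target exposure. With `residualize_target = TRUE` the
#' target column is residualized on the same covariates too, which by the
#' Frisch-Waugh-Lovell identity reproduces the joint coefficient exactly;
#' with `FALSE` (outcome-only residualization) the result differs whenever
#' exposure columns are correlated.
#'
#' @param h A `harmonized_set` (K >= 2).
#' @param target_exposure Index or name of the exposure of interest.
#' @param residualize_target Also residualize the target column
#'   (FWL-exact) rather than only the outcome.
#' @return An `mvmr_fit` for the target exposure only
#'   (`approach = "residualized"`).
#' @export
mvmr_residualized <- function(h, target_exposure = 1L,
                              residualize_target = FALSE) {
  X <- h$beta_exp
  K <- ncol(X)
  if (K < 2L) stop("analysis error: residualized MVMR needs K >= 2")
  if (is.character(target_exposure)) {
    target_exposure <- match(target_exposure, colnames(X))
  }
  J <- nrow(X)
  if (J <= K) stop("analysis error: MVMR needs more variants than exposures")
  w <- h$se_out^-2
  Z <- X[, -target_exposure, drop = FALSE]
  x <- X[, target_exposure]
  if (qr(Z)$rank < ncol(Z)) {
    stop("singular-design error: collinear covariate exposures")
  }
  ry <- stats::lm.wfit(Z, h$beta_out, w)$residuals
  rx <- if (residualize_target) stats::lm.wfit(Z, x, w)$residuals else x
  fit <- stats::lm.wfit(cbind(rx), ry, w)
  theta <- unname(fit$coefficients)
  df <- J - if (residualize_target) K else ncol(Z) + 1L
  sigma <- sqrt(sum(w * fit$residuals^2) / df)
  se <- sqrt(1 / sum(w * rx^2)) * max(1, sigma)
  structure(list(exposures = colnames(X)[target_exposure], theta = theta,
                 se = se, pvalues = 2 * stats::pnorm(-abs(theta / se)),
                 variant_count = J, approach = "residualized",
                 outcome = h$outcome_name),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("Multivariable MR (%s), %d variants -> %s\n", x$approach,
              x$variant_count, x$outcome))
  print(data.frame(exposure = x$exposures, theta = x$theta, se = x$se,
                   pvalue = x$pvalues))
  invisible(x)
}

#' @export
coef.mvmr_fit <- function(object, ...) {
  stats::setNames(object$theta, object$exposures)
}

#' @export
confint.mvmr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$theta - z * object$se, object$theta + z * object$se)
  dimnames(out) <- list(object$exposures,
                        paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               " %"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Mediation decomposition by the difference method
#'
#' Decomposes an exposure's effect on the outcome into direct and
#' mediated components: the total effect (C path) is the univariable IVW
#' estimate; the direct effect (C' path) is the exposure's coefficient in
#' a multivariable MR adjusting for the mediator; the indirect effect is
#' their difference, C - C', and the percent mediated is
#' 100 * indirect / total. The difference qualifies as mediation (rather
#' than mere attenuation) when both legs of the path are themselves
#' supported: the exposure affects the mediator (A path) and the mediator
#' affects the outcome (B path), each at level `alpha` in univariable MR.
#'
#' @param h_exposure_outcome Harmonized set, exposure instruments vs
#'   outcome (gives the total effect).
#' @param h_exposure_mediator Harmonized set, exposure instruments vs
#'   mediator (A path).
#' @param h_joint Harmonized set with exposure and mediator columns vs
#'   outcome (gives the direct effect).
#' @param h_mediator_outcome Optional harmonized set, mediator instruments
#'   vs outcome, for the B path; when absent the B path is estimated from
#'   `h_joint` variants genome-wide significant for the mediator.
#' @param alpha Path-significance level (default 0.05).
#' @return A `mediation_result`: list with `total_effect`,
#'   `direct_effect`, `indirect_effect`, `percent_mediated`,
#'   `a_path_pvalue`, `b_path_pvalue`, `qualifies_as_mediation`, `label`.
#' @export
mediation <- function(h_exposure_outcome, h_exposure_mediator, h_joint,
                      h_mediator_outcome = NULL, alpha = 0.05) {
  if (ncol(h_joint$beta_exp) < 2L) {
    stop("input error: h_joint must contain exposure and mediator columns")
  }
  total_fit <- ivw(wald_ratios(h_exposure_outcome))
  joint <- mvmr_joint(h_joint)
  exposure <- h_exposure_outcome$exposure_names[1]
  mediator <- setdiff(h_joint$exposure_names, exposure)[1]
  k_exp <- match(exposure, h_joint$exposure_names)
  direct <- joint$theta[k_exp]

  a_fit <- ivw(wald_ratios(h_exposure_mediator))
  b_fit <- if (!is.null(h_mediator_outcome)) {
    ivw(wald_ratios(h_mediator_outcome))
  } else {
    k_med <- match(mediator, h_joint$exposure_names)
    zmed <- abs(h_joint$beta_exp[, k_med]) / h_joint$se_exp[, k_med]
    sig <- which(is.finite(zmed) &
                   2 * stats::pnorm(-zmed) < 5e-8)
    if (length(sig) < 1L) {
      stop("analysis error: no mediator-significant variants for the B path; ",
           "supply h_mediator_outcome")
    }
    hb <- subset_harmonized(h_joint, sig)
    ivw(wald_ratios(hb, exposure_index = k_med))
  }

  total <- total_fit$theta
  indirect <- total - direct
  percent <- if (abs(total) > 1e-12) 100 * indirect / total else NA_real_
  qualifies <- (a_fit$pvalue < alpha) && (b_fit$pvalue < alpha)
  structure(list(exposure = exposure, mediator = mediator,
                 outcome = h_exposure_outcome$outcome_name,
                 total_effect = total, direct_effect = direct,
                 indirect_effect = indirect, percent_mediated = percent,
                 a_path_pvalue = a_fit$pvalue, b_path_pvalue = b_fit$pvalue,
                 qualifies_as_mediation = qualifies,
                 label = if (qualifies) "mediation" else "attenuation"),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (difference method): %s -> %s -> %s\n",
              x$exposure, x$mediator, x$outcome))
  cat(sprintf("  total (C) = %.4g, direct (C') = %.4g, indirect = %.4g",
              x$total_effect, x$direct_effect, x$indirect_effect))
  if (!is.na(x$percent_mediated)) {
    cat(sprintf(" (%.1f%% mediated)", x$percent_mediated))
  }
  cat(sprintf("\n  A-path p = %.3g, B-path p = %.3g -> %s\n",
              x$a_path_pvalue, x$b_path_pvalue, x$label))
  invisible(x)
}

#' Attenuation table across adjusted models
#'
#' One row per adjusted model: how the exposure's estimate changes when a
#' covariate (or the full covariate set) is added to the MR model.
#' Differences from the base (univariable) estimate are reported in
#' absolute and percent terms; the percent change is read as the share of
#' the exposure's effect attributable to the added trait when the
#' mediation criteria hold.
#'
#' @param base An `mr_estimate` (univariable fit of the exposure).
#' @param adjusted Named list of `mvmr_fit` objects; each contributes the
#'   base exposure's coefficient from that adjusted model.
#' @param exposure Name of the exposure (matched in each `mvmr_fit`).
#' @param mediation_flags Optional named logical vector (per adjusted
#'   model) from the mediation qualification test.
#' @return Data frame: model, theta, se, pvalue, abs_change, pct_change,
#'   mediation_flag; the base row first, any `"full"` model last.
#' @export
attenuation_table <- function(base, adjusted, exposure,
                              mediation_flags = NULL) {
  rows <- list(data.frame(model = "base", theta = base$theta, se = base$se,
                          pvalue = base$pvalue, abs_change = 0,
                          pct_change = 0, mediation_flag = NA,
                          stringsAsFactors = FALSE))
  nm <- names(adjusted)
  ord <- c(setdiff(seq_along(adjusted), which(nm == "full")),
           which(nm == "full"))
  for (i in ord) {
    fit <- adjusted[[i]]
    k <- match(exposure, fit$exposures)
    if (is.na(k)) stop("input error: exposure '", exposure,
                       "' absent from adjusted model '", nm[i], "'")
    change <- fit$theta[k] - base$theta
    rows[[length(rows) + 1L]] <-
      data.frame(model = nm[i], theta = fit$theta[k], se = fit$se[k],
                 pvalue = fit$pvalues[k], abs_change = change,
                 pct_change = if (abs(base$theta) > 1e-12)
                   -100 * change / base$theta else NA_real_,
                 mediation_flag = if (!is.null(mediation_flags) &&
                                        nm[i] %in% names(mediation_flags))
                   mediation_flags[[nm[i]]] else NA,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
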