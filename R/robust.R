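#' MR-PRESSO-style residual-sum-of-squares outlier test
#'
#' Global and per-variant tests for horizontal pleiotropy. For each
#' variant j the leave-one-out IVW estimate is computed and its squared
#' residual rss_j = (beta_Yj - theta_hat_(-j) beta_Xj)^2 recorded; the
#' global statistic is the sum. Significance is judged against a
#' parametric null: effect estimates are redrawn from their sampling
#' distributions with outcome means set to the leave-one-out fitted
#' values, the statistic recomputed `n_sim` times, and empirical p-values
#' formed with the (r+1)/(n+1) correction. A variant is flagged when its
#' per-variant p-value falls below `outlier_alpha / J` (Bonferroni over
#' variants).
#'
#' @param h A `harmonized_set` (J >= 4).
#' @param exposure_index Exposure column.
#' @param n_sim Null simulations.
#' @param seed Integer seed.
#' @param outlier_alpha Family-wise outlier level before the per-variant
#'   Bonferroni division.
#' @return An `outlier_report`: list with `global_rss`, `global_pvalue`,
#'   `per_variant` (data frame: variant_id, rss, pvalue, flagged),
#'   `n_sim`, `seed`.
#' @export
presso <- function(h, exposure_index = 1L, n_sim = 1000L, seed = 1L,
                   outlier_alpha = 0.05) {
  J <- n_variants(h)
  if (J < 4L) stop("analysis error: presso requires J >= 4")
  bx <- h$beta_exp[, exposure_index]
  sx <- h$se_exp[, exposure_index]
  by <- h$beta_out
  sy <- h$se_out

  loo <- loo_ivw(bx, by, sy)
  rss_obs <- (by - loo * bx)^2
  global_obs <- sum(rss_obs)

  sims <- with_seed(seed, {
    rss_sim <- matrix(0, nrow = n_sim, ncol = J)
    for (s in seq_len(n_sim)) {
      bxs <- stats::rnorm(J, bx, sx)
      bys <- stats::rnorm(J, loo * bx, sy)
      loos <- loo_ivw(bxs, bys, sy)
      rss_sim[s, ] <- (bys - loos * bxs)^2
    }
    rss_sim
  })
  global_sim <- rowSums(sims)
  global_p <- (sum(global_sim >= global_obs) + 1) / (n_sim + 1)
  pv <- (colSums(sims >= rep(rss_obs, each = n_sim)) + 1) / (n_sim + 1)
  flagged <- pv < outlier_alpha / J

  structure(list(global_rss = global_obs, global_pvalue = global_p,
                 per_variant = data.frame(variant_id = h$variant_ids,
                                          rss = rss_obs, pvalue = pv,
                                          flagged = flagged,
                                          stringsAsFactors = FALSE),
                 n_sim = n_sim, seed = seed),
            class = "outlier_report")
}

# leave-one-out fixed-effect IVW estimates, vectorised over variants;
# first-order ratio weights
loo_ivw <- function(bx, by, sy) {
  theta <- by / bx
  w <- (abs(bx) / sy)^2
  sw <- sum(w); swt <- sum(w * theta)
  (swt - w * theta) / (sw - w)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Pleiotropy RSS test: global RSS = %.4g, p = %.4g (%d sims)\n",
              x$global_rss, x$global_pvalue, x$n_sim))
  nf <- sum(x$per_variant$flagged)
  if (nf) {
    cat("  flagged outliers:",
        paste(x$per_variant$variant_id[x$per_variant$flagged],
              collapse = ", "), "\n")
  } else cat("  no outliers flagged\n")
  invisible(x)
}

#' Write an outlier report
#'
#' Per-variant table as TSV plus a JSON summary of the global statistics.
#'
#' @param x An `outlier_report`.
#' @param path Output TSV path; the JSON goes to `<path>.json`.
#' @export
write_outlier_report <- function(x, path) {
  utils::write.table(x$per_variant, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(global_rss = x$global_rss,
                            global_pvalue = x$global_pvalue,
                            n_sim = x$n_sim, seed = x$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Contamination-mixture causal estimate
#'
#' Profiles a two-component mixture over a grid of candidate causal
#' effects: at each candidate theta every variant contributes the larger
#' of its valid-instrument log-likelihood, Normal(theta_j; theta,
#' sigma_j^2), and its invalid log-likelihood, Normal(theta_j; 0,
#' sigma_j^2 + psi^2). The estimate is the grid argmax of the profile
#' log-likelihood; the 95% interval collects grid points within
#' qchisq(0.95, 1)/2 = 1.92 of the maximum (reported as the convex hull,
#' with a flag when the accepted region is disjoint). The argmax
#' assignment yields the set of variants deemed valid.
#'
#' @param r A `ratio_estimates` object (J >= 3).
#' @param psi Invalid-component scale; default 1.5 times the SD of the
#'   ratios.
#' @param grid_points Grid resolution (default 401) over
#'   [min theta - 2 max sigma, max theta + 2 max sigma].
#' @return A `conmix_result`: list with `theta`, `ci_low`, `ci_high`,
#'   `valid_ids`, `psi`, `grid`, `multimodal`.
#' @export
conmix <- function(r, psi = NULL, grid_points = 401L) {
  J <- length(r$theta)
  if (J < 3L) stop("analysis error: conmix requires J >= 3")
  if (is.null(psi)) psi <- 1.5 * stats::sd(r$theta)
  if (!is.finite(psi) || psi <= 0) psi <- 1  # degenerate ratio spread
  span <- max(r$theta) - min(r$theta)
  if (span < .Machine$double.eps^0.5) {
    return(structure(list(theta = r$theta[1], ci_low = r$theta[1],
                          ci_high = r$theta[1], valid_ids = r$variant_ids,
                          psi = psi, grid = r$theta[1], multimodal = FALSE),
                     class = "conmix_result"))
  }
  s <- max(r$sigma)
  grid <- seq(min(r$theta) - 2 * s, max(r$theta) + 2 * s,
              length.out = grid_points)
  ll_invalid <- stats::dnorm(r$theta, 0, sqrt(r$sigma^2 + psi^2), log = TRUE)
  profile <- vapply(grid, function(th) {
    ll_valid <- stats::dnorm(r$theta, th, r$sigma, log = TRUE)
    sum(pmax(ll_valid, ll_invalid))
  }, numeric(1))
  imax <- which.max(profile)
  accepted <- profile >= profile[imax] - stats::qchisq(0.95, 1) / 2
  ll_valid_max <- stats::dnorm(r$theta, grid[imax], r$sigma, log = TRUE)
  valid <- ll_valid_max >= ll_invalid
  runs <- rle(accepted)
  multimodal <- sum(runs$values) > 1L
  structure(list(theta = grid[imax],
                 ci_low = min(grid[accepted]), ci_high = max(grid[accepted]),
                 valid_ids = r$variant_ids[valid], psi = psi,
                 grid = grid, multimodal = multimodal),
            class = "conmix_result")
}

#' @export
print.conmix_result <- function(x, ...) {
  cat(sprintf("Contamination mixture: theta = %.4g (95%% CI %.4g to %.4g)%s\n",
              x$theta, x$ci_low, x$ci_high,
              if (x$multimodal) " [multimodal profile: CI is convex hull]" else ""))
  cat(sprintf("  %d variants assigned valid, psi = %.4g\n",
              length(x$valid_ids), x$psi))
  invisible(x)
}

#' Re-fit the estimator battery after excluding variants
#'
#' Sensitivity re-analysis on an altered instrument set: removes the
#' listed variants (e.g. those flagged by [presso()] or assigned invalid
#' by [conmix()]) and re-runs [mr()] on the remainder, tagging the result
#' with the exclusion provenance.
#'
#' @param h A `harmonized_set`.
#' @param exposure_index Exposure column.
#' @param excluded Character vector of variant ids to drop (must all be
#'   present in `h`); empty vector reproduces the original fit.
#' @param ... Passed to [mr()].
#' @return An `mr_fit` with an `excluded` element.
#' @export
refit_after_exclusion <- function(h, exposure_index = 1L,
                                  excluded = character(0), ...) {
  missing_ids <- setdiff(excluded, h$variant_ids)
  if (length(missing_ids)) {
    stop("input error: excluded variant(s) not in set: ",
         paste(missing_ids, collapse = ", "))
  }
  keep <- !(h$variant_ids %in% excluded)
  if (sum(keep) < 3L) {
    stop("analysis error: fewer than 3 variants remain after exclusion")
  }
  fit <- mr(subset_harmonized(h, which(keep)), exposure_index, ...)
  fit$excluded <- excluded
  fit
}
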