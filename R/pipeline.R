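#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 9)  # 0.00556
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("input error: alpha must be in (0, 1)")
  }
  if (n_tests < 1) stop("input error: n_tests must be >= 1")
  alpha / n_tests
}

#' Power of a two-sample MR analysis
#'
#' Normal-approximation power for detecting a causal effect `theta` (on
#' unit-variance trait scales) with instruments explaining `r2_gx` of the
#' exposure variance in an outcome sample of size `n`:
#' power = Phi(|theta| sqrt(n r2) - z_(1-alpha/2)) +
#'         Phi(-|theta| sqrt(n r2) - z_(1-alpha/2)).
#' At theta = 0 this returns exactly alpha (the test's size).
#'
#' @param theta True causal effect (SD units of outcome per SD exposure).
#' @param r2_gx Variance of the exposure explained by the instruments,
#'   in (0, 1).
#' @param n Outcome sample size.
#' @param alpha Two-sided significance level.
#' @return Power in [0, 1]; vectorised over `theta`, `r2_gx`, `n`.
#' @export
mr_power <- function(theta, r2_gx, n, alpha = 0.05) {
  if (any(r2_gx <= 0 | r2_gx >= 1)) {
    stop("input error: r2_gx must be in (0, 1)")
  }
  if (any(n < 1)) stop("input error: n must be >= 1")
  if (any(alpha <= 0 | alpha >= 1)) {
    stop("input error: alpha must be in (0, 1)")
  }
  zc <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(theta) * sqrt(n * r2_gx)
  stats::pnorm(ncp - zc) + stats::pnorm(-ncp - zc)
}

#' Power table over a parameter grid
#'
#' Expands the grids and tabulates [mr_power()] for each combination.
#'
#' @param theta,r2_gx,n Numeric vectors defining the grid.
#' @param alpha Two-sided level.
#' @return Data frame: theta, r2_gx, n, power.
#' @export
mr_power_table <- function(theta, r2_gx, n, alpha = 0.05) {
  g <- expand.grid(theta = theta, r2_gx = r2_gx, n = n,
                   KEEP.OUT.ATTRS = FALSE)
  g$power <- mr_power(g$theta, g$r2_gx, g$n, alpha)
  g
}

#' Consistency verdict across MR methods
#'
#' An exposure-outcome result counts as consistent when at least two of
#' the supplied methods are nominally significant and all point estimates
#' agree in direction; otherwise it is flagged inconsistent.
#'
#' @param estimates List of `mr_estimate` objects (>= 2).
#' @param alpha Nominal significance level.
#' @return A `consistency_verdict`: list with `n_methods_nominal`,
#'   `directions_agree`, `consistent`.
#' @export
consistency_verdict <- function(estimates, alpha = 0.05) {
  if (length(estimates) < 2L) {
    stop("input error: need at least 2 method estimates")
  }
  p <- vapply(estimates, `[[`, numeric(1), "pvalue")
  th <- vapply(estimates, `[[`, numeric(1), "theta")
  n_nominal <- sum(p < alpha)
  agree <- all(sign(th) == sign(th[1]))
  structure(list(n_methods_nominal = n_nominal,
                 directions_agree = agree,
                 consistent = n_nominal >= 2L && agree),
            class = "consistency_verdict")
}

#' @export
print.consistency_verdict <- function(x, ...) {
  cat(sprintf("Consistency: %d method(s) nominal, directions %s -> %s\n",
              x$n_methods_nominal,
              if (x$directions_agree) "agree" else "disagree",
              if (x$consistent) "CONSISTENT" else "not consistent"))
  invisible(x)
}

#' Read a run configuration file
#'
#' YAML with a trait registry (name -> path/type/n), analysis pairs,
#' method list, thresholds and seeds; defaults fill any missing
#' threshold.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A list with the same structure as the YAML file.
#' @export
as_run_config <- function(cfg) {
  defaults <- list(p_instrument = 5e-8, r2 = 0.2, window_bp = 1e6,
                   direct_effect_p = 5e-8, alpha = 0.05, n_tests = 9,
                   seed = 1L, n_boot = 1000L, n_sim = 1000L)
  cfg$thresholds <- utils::modifyList(defaults, cfg$thresholds %||% list())
  if (is.null(cfg$methods)) {
    cfg$methods <- c("ivw", "egger", "weighted_median", "mode_based",
                     "ivw_penalized")
  }
  for (pair in cfg$pairs %||% list()) {
    if (!all(c(pair$exposure, pair$outcome) %in% names(cfg$traits))) {
      stop("configuration error: pair traits missing from registry: ",
           pair$exposure, " -> ", pair$outcome)
    }
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resolve a trait entry to an in-memory sumstat_table
resolve_trait <- function(cfg, name) {
  entry <- cfg$traits[[name]]
  if (is.null(entry)) stop("configuration error: unknown trait: ", name)
  if (inherits(entry, "sumstat_table")) return(entry)
  if (!is.null(entry$table)) return(entry$table)
  read_sumstats(entry$path, trait_name = name,
                trait_type = entry$type %||% "continuous")
}

#' Run one exposure-outcome analysis end to end
#'
#' Instrument selection (a supplied list, or [clump()] when an LD matrix
#' is in the config), harmonization with the palindromic and
#' direct-effect filters, the univariable estimator battery, the
#' outlier-robust sensitivity stage ([presso()] and [conmix()]), a re-fit
#' on the altered instrument set, and the consistency verdict. All seeds
#' and thresholds are recorded in the returned bundle.
#'
#' @param config A `run_config` (see [read_run_config()]); traits may be
#'   registered as in-memory tables (`list(table = <sumstat_table>)`) or
#'   paths.
#' @param pair List with `exposure`, `outcome` and optionally
#'   `instruments` (character vector; otherwise clumping is attempted).
#' @return An `mr_run` bundle: list with `harmonized`, `fit` (`mr_fit`),
#'   `presso`, `conmix`, `refit`, `verdict`, `pair`, `thresholds`.
#' @export
run_pair <- function(config, pair) {
  th <- config$thresholds
  exposure <- resolve_trait(config, pair$exposure)
  outcome <- resolve_trait(config, pair$outcome)
  instruments <- pair$instruments
  if (is.null(instruments)) {
    if (is.null(config$ld)) {
      stop("configuration error: pair has no instrument list and no LD ",
           "reference is configured for clumping")
    }
    instruments <- clump(exposure, config$ld, p_threshold = th$p_instrument,
                         r2_threshold = th$r2,
                         window_bp = th$window_bp)$variant_id
  }
  h <- harmonize(exposure, outcome, instruments,
                 direct_effect_p = th$direct_effect_p)
  fit <- mr(h, methods = config$methods, n_boot = th$n_boot,
            seed = th$seed)
  pres <- if (n_variants(h) >= 4L) {
    presso(h, n_sim = th$n_sim, seed = th$seed, outlier_alpha = th$alpha)
  }
  cm <- conmix(fit$ratios)
  excluded <- union(
    if (!is.null(pres)) pres$per_variant$variant_id[pres$per_variant$flagged]
    else character(0),
    setdiff(h$variant_ids, cm$valid_ids))
  refit <- if (length(excluded) &&
                 n_variants(h) - length(excluded) >= 3L) {
    refit_after_exclusion(h, excluded = excluded,
                          methods = config$methods, n_boot = th$n_boot,
                          seed = th$seed)
  }
  verdict <- consistency_verdict(fit$estimates, alpha = th$alpha)
  structure(list(pair = pair, harmonized = h, fit = fit, presso = pres,
                 conmix = cm, refit = refit, verdict = verdict,
                 thresholds = th,
                 bonferroni = bonferroni_threshold(th$alpha, th$n_tests)),
            class = "mr_run")
}

#' @export
print.mr_run <- function(x, ...) {
  cat(sprintf("MR run: %s -> %s\n", x$pair$exposure, x$pair$outcome))
  print(x$harmonized)
  print(summary(x$fit))
  print(x$verdict)
  if (!is.null(x$refit)) {
    cat(sprintf("Sensitivity re-fit excluded %d variant(s): %s\n",
                length(x$refit$excluded),
                paste(x$refit$excluded, collapse = ", ")))
  }
  invisible(x)
}

#' Bidirectional MR over a trait pair
#'
#' Runs A -> B with A's instruments and B -> A with B's instruments.
#' Instruments genome-wide significant for the opposite trait are removed
#' by the harmonization direct-effect filter, so a causal signal in one
#' direction does not mechanically produce one in the other.
#'
#' @param config A `run_config`.
#' @param trait_a,trait_b Registry names.
#' @param instruments_a,instruments_b Instrument id vectors for each
#'   direction (optional if clumping is configured).
#' @return List with `forward` and `reverse` `mr_run` bundles.
#' @export
bidirectional <- function(config, trait_a, trait_b,
                          instruments_a = NULL, instruments_b = NULL) {
  forward <- run_pair(config, list(exposure = trait_a, outcome = trait_b,
                                   instruments = instruments_a))
  reverse <- run_pair(config, list(exposure = trait_b, outcome = trait_a,
                                   instruments = instruments_b))
  list(forward = forward, reverse = reverse)
}

#' Write the tidy estimates table of a run
#'
#' One row per method: exposure, outcome, method, n_variants, theta, se,
#' ci_low, ci_high, pvalue, intercept, intercept_se, Q, seed; raw
#' p-values are reported alongside the Bonferroni flag.
#'
#' @param run An `mr_run`.
#' @param path Output TSV path (optional; the data frame is returned
#'   invisibly either way).
#' @export
estimates_table <- function(run, path = NULL) {
  df <- summary(run$fit)
  df <- cbind(exposure = run$pair$exposure, outcome = run$pair$outcome,
              df, seed = run$thresholds$seed,
              below_bonferroni = df$pvalue < run$bonferroni)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(df)
}
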