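#' LD scores from a genotype dosage panel
#'
#' The LD score of variant j is the sum over variants within the window of
#' the adjusted squared correlation r^2 - (1 - r^2)/(n_ref - 2), an
#' unbiased-under-the-null estimator of the population r^2; the self term
#' contributes exactly 1. Zero-variance variants are excluded with a
#' warning.
#'
#' @param panel n_ref x M numeric dosage matrix, columns named by variant
#'   id (n_ref >= 3).
#' @param window_bp Window half-width in base pairs; variants farther
#'   apart (or on different chromosomes) contribute nothing.
#' @param positions Data frame with `variant_id`, `chrom`, `pos` (defaults
#'   to a single chromosome with one variant per bp, i.e. all in window).
#' @return An `ld_score_table`: data frame (`variant_id`, `ld_score`) with
#'   attribute `n_ref`.
#' @export
ld_scores <- function(panel, window_bp = Inf, positions = NULL) {
  n_ref <- nrow(panel)
  if (n_ref < 3L) stop("input error: reference panel needs n_ref >= 3")
  v <- apply(panel, 2, stats::var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance variant(s)")
    panel <- panel[, v > 0, drop = FALSE]
  }
  ids <- colnames(panel)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(panel)))
  M <- ncol(panel)
  if (is.null(positions)) {
    positions <- data.frame(variant_id = ids, chrom = "1", pos = seq_len(M))
    if (!is.infinite(window_bp)) {
      # positions unknown: honour the window only if supplied
      window_bp <- Inf
    }
  }
  pos <- positions$pos[match(ids, positions$variant_id)]
  chrom <- positions$chrom[match(ids, positions$variant_id)]
  r2 <- stats::cor(panel)^2
  adj <- r2 - (1 - r2) / (n_ref - 2)
  if (!is.infinite(window_bp)) {
    inwin <- abs(outer(pos, pos, "-")) <= window_bp &
      outer(chrom, chrom, "==")
    adj[!inwin] <- 0
  }
  diag(adj) <- 1  # self term exactly 1
  structure(data.frame(variant_id = ids, ld_score = colSums(adj),
                       stringsAsFactors = FALSE),
            n_ref = n_ref,
            class = c("ld_score_table", "data.frame"))
}

# weighted regression of y on ld with (optional) fixed intercept; returns
# slope and intercept. weights 1/max(ld,1) unless ols.
ldsc_wls <- function(y, ld, weights = c("inverse_ld", "ols"),
                     fixed_intercept = NULL) {
  weights <- match.arg(weights)
  w <- if (weights == "inverse_ld") 1 / pmax(ld, 1) else rep(1, length(ld))
  if (stats::var(ld) == 0) {
    stop("singular-design error: no variation in LD scores")
  }
  if (is.null(fixed_intercept)) {
    X <- cbind(1, ld)
    b <- stats::lm.wfit(X, y, w)$coefficients
    list(intercept = unname(b[1]), slope = unname(b[2]))
  } else {
    yy <- y - fixed_intercept
    slope <- sum(w * ld * yy) / sum(w * ld^2)
    list(intercept = fixed_intercept, slope = slope)
  }
}

# core two-step univariate fit on (chi2, ld); returns slope and intercept
ldsc_fit_uni <- function(chi2, ld, two_step_cutoff, weights) {
  step1 <- chi2 < two_step_cutoff
  if (sum(step1) < 3L) step1 <- rep(TRUE, length(chi2))
  int <- ldsc_wls(chi2[step1], ld[step1], weights)$intercept
  slope <- ldsc_wls(chi2, ld, weights, fixed_intercept = int)$slope
  list(slope = slope, intercept = int)
}

#' Univariate LD score regression
#'
#' Regresses per-variant chi-square statistics (z^2) on LD scores.
#' Under the polygenic model E[chi2_j] = 1 + n h2 l_j / m, so the slope
#' rescaled by m/n estimates SNP heritability and the intercept captures
#' confounding/overlap inflation. The intercept is estimated in a first
#' step restricted to variants with chi2 below `two_step_cutoff`, then
#' held fixed while the slope is re-estimated on all variants. Standard
#' errors come from a delete-a-block jackknife over `n_blocks` contiguous
#' blocks.
#'
#' @param z Per-variant z-statistics, aligned to `ld`.
#' @param ld An `ld_score_table` or numeric vector of LD scores.
#' @param n GWAS sample size.
#' @param m Number of variants the LD scores sum over (defaults to
#'   `length(z)`).
#' @param two_step_cutoff Chi-square cutoff for the intercept step.
#' @param n_blocks Jackknife blocks.
#' @param weights `"inverse_ld"` (1/max(l,1), default) or `"ols"`.
#' @return List with `h2`, `intercept`, `h2_se`, `intercept_se`, `m`, `n`.
#' @export
univariate_ldsc <- function(z, ld, n, m = length(z), two_step_cutoff = 30,
                            n_blocks = 200L, weights = "inverse_ld") {
  l <- if (is.data.frame(ld)) ld$ld_score else ld
  stopifnot(length(z) == length(l))
  if (length(z) < n_blocks) {
    stop("analysis error: fewer variants than jackknife blocks")
  }
  chi2 <- z^2
  fit <- ldsc_fit_uni(chi2, l, two_step_cutoff, weights)
  jack <- jackknife_blocks(length(z), n_blocks, function(keep) {
    f <- ldsc_fit_uni(chi2[keep], l[keep], two_step_cutoff, weights)
    c(f$slope * m / n, f$intercept)
  })
  list(h2 = fit$slope * m / n, intercept = fit$intercept,
       h2_se = jack$se[1], intercept_se = jack$se[2], m = m, n = n)
}

# delete-a-block jackknife over n contiguous blocks; fun(keep_index) must
# return a numeric vector. Returns list(se = jackknife SEs).
jackknife_blocks <- function(n_items, n_blocks, fun) {
  blocks <- split(seq_len(n_items),
                  cut(seq_len(n_items), n_blocks, labels = FALSE))
  template <- fun(seq_len(n_items))
  ests <- vapply(blocks, function(b) fun(setdiff(seq_len(n_items), b)),
                 template)
  ests <- if (length(template) == 1L) matrix(ests, ncol = 1L) else t(ests)
  nb <- nrow(ests)
  se <- sqrt((nb - 1) / nb * colSums(sweep(ests, 2, colMeans(ests))^2))
  list(se = se, estimates = ests)
}

#' Cross-trait LD score regression
#'
#' Estimates the genetic covariance and correlation of two traits from
#' their summary statistics alone: the product of the two traits'
#' z-statistics is regressed on LD scores; the slope rescaled by
#' m/sqrt(n1 n2) estimates genetic covariance, and the intercept absorbs
#' sample overlap. Genetic correlation rg = gencov / sqrt(h2_1 h2_2) uses
#' univariate fits for the heritabilities. Block-jackknife SEs cover
#' gencov and rg (the whole pipeline is re-run per deleted block).
#'
#' @param z1,z2 Aligned z-statistic vectors.
#' @param ld LD scores (table or vector) aligned to them.
#' @param n1,n2 The two GWAS sample sizes.
#' @param m Number of variants (defaults to `length(z1)`).
#' @param n_blocks Jackknife blocks (default 200).
#' @param two_step_cutoff Univariate intercept-step cutoff.
#' @param weights Regression weights as in [univariate_ldsc()].
#' @return An `ldsc_result`: list with `h2_trait1`, `h2_trait2`, `gencov`,
#'   `rg`, intercepts, jackknife SEs, `m_snps`, `n1`, `n2`, `rg_pvalue`,
#'   `warning` (set when |rg| > 1 or an h2 is non-positive).
#' @export
cross_trait_ldsc <- function(z1, z2, ld, n1, n2, m = length(z1),
                             n_blocks = 200L, two_step_cutoff = 30,
                             weights = "inverse_ld") {
  l <- if (is.data.frame(ld)) ld$ld_score else ld
  stopifnot(length(z1) == length(l), length(z2) == length(l))
  if (length(z1) < n_blocks) {
    stop("analysis error: fewer variants than jackknife blocks")
  }
  chi1 <- z1^2; chi2 <- z2^2; prod12 <- z1 * z2

  point <- function(keep) {
    f1 <- ldsc_fit_uni(chi1[keep], l[keep], two_step_cutoff, weights)
    f2 <- ldsc_fit_uni(chi2[keep], l[keep], two_step_cutoff, weights)
    fb <- ldsc_wls(prod12[keep], l[keep], weights)
    h2_1 <- f1$slope * m / n1
    h2_2 <- f2$slope * m / n2
    gencov <- fb$slope * m / sqrt(n1 * n2)
    rg <- if (h2_1 > 0 && h2_2 > 0) gencov / sqrt(h2_1 * h2_2) else NA_real_
    c(h2_1 = h2_1, h2_2 = h2_2, gencov = gencov, rg = rg,
      int1 = f1$intercept, int2 = f2$intercept, intb = fb$intercept)
  }
  est <- point(seq_along(z1))
  jack <- jackknife_blocks(length(z1), n_blocks, point)

  warn <- NULL
  if (is.na(est["rg"])) warn <- "non-positive heritability: rg undefined"
  else if (abs(est["rg"]) > 1) warn <- "|rg| exceeds 1"
  rg_p <- if (!is.na(est["rg"]) && jack$se[4] > 0) {
    2 * stats::pnorm(-abs(est["rg"] / jack$se[4]))
  } else NA_real_

  structure(list(h2_trait1 = unname(est["h2_1"]),
                 h2_trait2 = unname(est["h2_2"]),
                 gencov = unname(est["gencov"]), rg = unname(est["rg"]),
                 intercept_uni1 = unname(est["int1"]),
                 intercept_uni2 = unname(est["int2"]),
                 intercept_biv = unname(est["intb"]),
                 h2_trait1_se = jack$se[1], h2_trait2_se = jack$se[2],
                 gencov_se = jack$se[3], rg_se = jack$se[4],
                 rg_pvalue = rg_p,
                 m_snps = m, n1 = n1, n2 = n2, warning = warn),
            class = "ldsc_result")
}

#' @export
print.ldsc_result <- function(x, ...) {
  cat("Cross-trait LD score regression\n")
  cat(sprintf("  h2 trait1 = %.4g (SE %.4g), h2 trait2 = %.4g (SE %.4g)\n",
              x$h2_trait1, x$h2_trait1_se, x$h2_trait2, x$h2_trait2_se))
  cat(sprintf("  genetic covariance = %.4g (SE %.4g)\n", x$gencov,
              x$gencov_se))
  if (!is.na(x$rg)) {
    cat(sprintf("  rg = %.4g (SE %.4g, p = %.3g)\n", x$rg, x$rg_se,
                x$rg_pvalue))
  } else cat("  rg: not defined\n")
  cat(sprintf("  intercepts: %.3g / %.3g (uni), %.3g (bivariate)\n",
              x$intercept_uni1, x$intercept_uni2, x$intercept_biv))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' z-statistics from a summary-statistic table
#'
#' Uses beta/se (the usual reconstruction when z is not distributed).
#'
#' @param tab A `sumstat_table`.
#' @return Numeric vector aligned to the table rows.
#' @export
z_from_sumstats <- function(tab) tab$beta / tab$se
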