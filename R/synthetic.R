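#' Ground-truth parameters for a two-sample simulation
#'
#' Encodes the causal diagram and generative settings that
#' [simulate_two_sample()] realises: K exposure traits plus one outcome,
#' a directed acyclic matrix of trait-on-trait effects, per-exposure
#' instrument counts and effect sizes, horizontal pleiotropy acting
#' directly on the outcome, allele frequencies, and the two samples'
#' sizes. The record travels with every simulated dataset so recovery
#' tests can compare estimates against the truth.
#'
#' @param theta Length-K vector of causal effects of each exposure on the
#'   outcome (convenience for the common case; ignored when
#'   `causal_matrix` is supplied).
#' @param causal_matrix Optional (K+1) x (K+1) matrix of direct effects,
#'   entry (i, j) = effect of trait i on trait j; the last trait is the
#'   outcome. Must be acyclic (nilpotent).
#' @param J Instruments per exposure (recycled to length K).
#' @param n_exposure,n_outcome GWAS sample sizes for the exposure and
#'   outcome samples (non-overlapping).
#' @param effect_range Magnitude range for true instrument effects; drawn
#'   uniformly with random sign. The default (0.05, 0.15) gives strong
#'   instruments (per-variant F above ~20 at n = 1e5).
#' @param maf_range Minor-allele-frequency range, default U(0.05, 0.5).
#' @param pleiotropy_frac Fraction of instruments with a direct outcome
#'   effect (horizontal pleiotropy), default 0.
#' @param pleiotropy_mean,pleiotropy_sd Direct-effect distribution for
#'   affected variants; a nonzero mean makes pleiotropy directional.
#' @param palindromic_frac Fraction of variants assigned strand-ambiguous
#'   (A/T or C/G) allele pairs, default 0.
#' @param exposure_names Optional trait names (default X1..XK).
#' @param outcome_name Outcome trait name.
#' @param seed Integer seed.
#' @return A `truth_record` list.
#' @export
truth_record <- function(theta = 0.3, causal_matrix = NULL, J = 100L,
                         n_exposure = 1e5, n_outcome = 1e5,
                         effect_range = c(0.05, 0.15),
                         maf_range = c(0.05, 0.5),
                         pleiotropy_frac = 0, pleiotropy_mean = 0,
                         pleiotropy_sd = 0, palindromic_frac = 0,
                         exposure_names = NULL, outcome_name = "Y",
                         seed = 1L) {
  if (is.null(causal_matrix)) {
    K <- length(theta)
    causal_matrix <- matrix(0, K + 1, K + 1)
    causal_matrix[seq_len(K), K + 1] <- theta
  }
  K <- nrow(causal_matrix) - 1L
  if (K < 1L) stop("configuration error: need at least one exposure")
  check_acyclic(causal_matrix)
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1) {
    stop("configuration error: pleiotropy_frac must be in [0, 1]")
  }
  if (is.null(exposure_names)) exposure_names <- paste0("X", seq_len(K))
  J <- rep(as.integer(J), length.out = K)
  structure(list(causal_matrix = causal_matrix, K = K, J = J,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 effect_range = effect_range, maf_range = maf_range,
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 palindromic_frac = palindromic_frac,
                 exposure_names = exposure_names,
                 outcome_name = outcome_name, seed = as.integer(seed)),
            class = "truth_record")
}

check_acyclic <- function(A) {
  if (nrow(A) != ncol(A)) stop("configuration error: causal matrix not square")
  if (any(diag(A) != 0)) {
    stop("configuration error: causal matrix has self-loops")
  }
  P <- (A != 0) * 1
  for (i in seq_len(nrow(A))) P <- P %*% ((A != 0) * 1)
  if (any(P != 0)) stop("configuration error: causal matrix is cyclic")
  invisible(TRUE)
}

# standard error of a per-allele GWAS beta for a unit-variance trait
gwas_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# allele pair for each variant; palindromic pairs are A/T or C/G
draw_alleles <- function(J, palindromic_frac) {
  pal <- stats::runif(J) < palindromic_frac
  ea <- oa <- character(J)
  pairs_np <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pairs_p <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  for (j in seq_len(J)) {
    p <- if (pal[j]) sample(pairs_p, 1)[[1]] else sample(pairs_np, 1)[[1]]
    ea[j] <- p[1]; oa[j] <- p[2]
  }
  list(ea = ea, oa = oa)
}

#' Simulate two-sample GWAS summary statistics under a causal diagram
#'
#' Realises the generative model a two-sample MR study assumes: each
#' exposure has its own set of unlinked instruments with true per-allele
#' effects; effects propagate through the causal matrix to every
#' downstream trait, so a variant's true marginal effect on the outcome
#' is its instrument effect times the total (path-summed) causal effect,
#' plus any direct (pleiotropic) outcome effect. Observed coefficients
#' add independent sampling noise with the standard GWAS standard error
#' 1/sqrt(2 n maf (1-maf)) on the unit-variance trait scale; exposure and
#' outcome samples are non-overlapping, so their noise is independent.
#'
#' @param truth A `truth_record`.
#' @param noise Multiplier on the sampling noise (0 gives the zero-noise
#'   limit where observed = true; 1 is the default generative model).
#' @return List with `exposures` (list of `sumstat_table`),
#'   `outcome` (`sumstat_table`), `instruments` (list of id vectors per
#'   exposure), and `truth` (the record, with per-variant true effects
#'   attached as `gamma`, `pleiotropy` and `maf`).
#' @export
simulate_two_sample <- function(truth, noise = 1) {
  stopifnot(inherits(truth, "truth_record"))
  with_seed(truth$seed, {
    K <- truth$K
    Jtot <- sum(truth$J)
    owner <- rep(seq_len(K), truth$J)  # which exposure a variant instruments
    ids <- sprintf("rs%05d", seq_len(Jtot))
    chrom <- as.character(rep_len(1:22, Jtot))
    pos <- (seq_len(Jtot) %/% 22L + 1L) * 5e6 + seq_len(Jtot)
    maf <- stats::runif(Jtot, truth$maf_range[1], truth$maf_range[2])
    al <- draw_alleles(Jtot, truth$palindromic_frac)

    # true direct instrument effects: gamma[j, k] nonzero only for owner
    gamma <- matrix(0, Jtot, K)
    mag <- stats::runif(Jtot, truth$effect_range[1], truth$effect_range[2])
    sgn <- sample(c(-1, 1), Jtot, replace = TRUE)
    gamma[cbind(seq_len(Jtot), owner)] <- mag * sgn

    # propagate through the DAG: total effects = (I - A)^(-1)
    A <- truth$causal_matrix
    total <- solve(diag(K + 1) - A)
    gamma_full <- cbind(gamma, 0)          # no direct instrument->outcome
    beta_true <- gamma_full %*% total      # J x (K+1) marginal effects

    # horizontal pleiotropy: direct variant -> outcome effects, defined on
    # the exposure-increasing allele so a nonzero mean is directional in
    # the sense an Egger intercept detects
    plei <- numeric(Jtot)
    if (truth$pleiotropy_frac > 0) {
      hit <- stats::runif(Jtot) < truth$pleiotropy_frac
      plei[hit] <- stats::rnorm(sum(hit), truth$pleiotropy_mean,
                                truth$pleiotropy_sd) * sgn[hit]
    }
    beta_true[, K + 1] <- beta_true[, K + 1] + plei

    se_exp <- gwas_se(truth$n_exposure, maf)
    se_out <- gwas_se(truth$n_outcome, maf)

    make_table <- function(beta_col, se, name) {
      b_obs <- beta_col + noise * stats::rnorm(Jtot, 0, se)
      as_sumstat_table(data.frame(
        variant_id = ids, chrom = chrom, pos = pos,
        effect_allele = al$ea, other_allele = al$oa, eaf = maf,
        beta = b_obs, se = se,
        pvalue = 2 * stats::pnorm(-abs(b_obs / se)),
        n = if (name == truth$outcome_name) truth$n_outcome
            else truth$n_exposure,
        stringsAsFactors = FALSE), trait_name = name)
    }
    exposures <- lapply(seq_len(K), function(k) {
      make_table(beta_true[, k], se_exp, truth$exposure_names[k])
    })
    outcome <- make_table(beta_true[, K + 1], se_out, truth$outcome_name)
    instruments <- lapply(seq_len(K), function(k) ids[owner == k])
    truth$gamma <- gamma
    truth$pleiotropy <- plei
    truth$maf <- maf
    list(exposures = exposures, outcome = outcome,
         instruments = instruments, truth = truth)
  })
}

#' Simulate a three-trait mediation chain
#'
#' Generates summary statistics for the chain X -> M -> Y with an
#' additional direct X -> Y path, so the true total X effect is
#' `theta_xy_direct + theta_xm * theta_my` and the true percent mediated
#' is `100 * theta_xm * theta_my / total`. X and M each get `J` unlinked
#' instruments; the harmonized sets that [mediation()] consumes are
#' returned ready-made.
#'
#' @param theta_xm,theta_my,theta_xy_direct Path coefficients.
#' @param J Instruments per trait (X and M each).
#' @param n GWAS sample size for all three samples.
#' @param seed Integer seed.
#' @param ... Further arguments to [truth_record()].
#' @return List with the four harmonized sets (`h_xy`, `h_xm`, `h_joint`,
#'   `h_my`), the raw simulation (`sim`), and `truth_percent_mediated`.
#' @export
simulate_mediation_chain <- function(theta_xm, theta_my, theta_xy_direct,
                                     J = 150L, n = 1e5, seed = 1L, ...) {
  # traits: X, M, Y (outcome)
  A <- matrix(0, 3, 3)
  A[1, 2] <- theta_xm
  A[2, 3] <- theta_my
  A[1, 3] <- theta_xy_direct
  truth <- truth_record(causal_matrix = A, J = J, n_exposure = n,
                        n_outcome = n, exposure_names = c("X", "M"),
                        outcome_name = "Y", seed = seed, ...)
  sim <- simulate_two_sample(truth)
  x_tab <- sim$exposures[[1]]; m_tab <- sim$exposures[[2]]
  x_ids <- sim$instruments[[1]]; m_ids <- sim$instruments[[2]]
  # direct-effect filtering is disabled inside the chain: by construction
  # every X instrument acts on Y through the modelled paths
  h_xy <- harmonize(x_tab, sim$outcome, x_ids, direct_effect_p = 0)
  h_xm <- harmonize(x_tab, m_tab, x_ids, direct_effect_p = 0)
  h_my <- harmonize(m_tab, sim$outcome, m_ids, direct_effect_p = 0)
  h_joint <- harmonize(list(x_tab, m_tab), sim$outcome,
                       list(x_ids, m_ids), direct_effect_p = 0)
  total_true <- theta_xy_direct + theta_xm * theta_my
  list(h_xy = h_xy, h_xm = h_xm, h_joint = h_joint, h_my = h_my,
       sim = sim,
       truth_percent_mediated = if (abs(total_true) > 0)
         100 * theta_xm * theta_my / total_true else NA_real_)
}

#' Configuration for an LDSC-model z-statistic simulation
#'
#' @param m Number of variants.
#' @param h2 Length-2 vector of SNP heritabilities in [0, 1].
#' @param gencov Genetic covariance, |gencov| <= sqrt(h2_1 h2_2).
#' @param n1,n2 GWAS sample sizes.
#' @param seed Integer seed.
#' @return An `ldsc_sim_config` list.
#' @export
ldsc_sim_config <- function(m = 5000L, h2 = c(0.4, 0.4), gencov = 0.2,
                            n1 = 5e4, n2 = 5e4, seed = 1L) {
  if (any(h2 < 0 | h2 > 1)) stop("configuration error: h2 must be in [0,1]")
  if (abs(gencov) > sqrt(prod(h2)) + 1e-12) {
    stop("configuration error: |gencov| exceeds sqrt(h2_1 h2_2)")
  }
  structure(list(m = as.integer(m), h2 = h2, gencov = gencov,
                 n1 = n1, n2 = n2, seed = as.integer(seed)),
            class = "ldsc_sim_config")
}

#' Simulate z-statistics from the LD score regression model
#'
#' Draws per-variant pairs (z1_j, z2_j) jointly normal with
#' Var(z1_j) = 1 + n1 h2_1 l_j / m, Var(z2_j) analogous, and
#' Cov(z1_j, z2_j) = sqrt(n1 n2) gencov l_j / m (non-overlapping samples:
#' the covariance carries no intercept term while the variances carry 1).
#'
#' @param config An `ldsc_sim_config`.
#' @param ld LD scores (an `ld_score_table` or numeric vector, length m).
#' @return List with `z1`, `z2`.
#' @export
simulate_ldsc_z <- function(config, ld) {
  l <- if (is.data.frame(ld)) ld$ld_score else ld
  stopifnot(length(l) == config$m)
  with_seed(config$seed, {
    v1 <- 1 + config$n1 * config$h2[1] * l / config$m
    v2 <- 1 + config$n2 * config$h2[2] * l / config$m
    cv <- sqrt(config$n1 * config$n2) * config$gencov * l / config$m
    resid_var <- v2 - cv^2 / v1
    if (any(resid_var < -1e-12)) {
      stop("configuration error: implied z covariance not positive ",
           "semidefinite at some variants")
    }
    resid_var <- pmax(resid_var, 0)
    u1 <- stats::rnorm(config$m)
    u2 <- stats::rnorm(config$m)
    z1 <- sqrt(v1) * u1
    z2 <- (cv / sqrt(v1)) * u1 + sqrt(resid_var) * u2
    list(z1 = z1, z2 = z2)
  })
}

#' Simulate a block-structured LD reference panel
#'
#' Small genotype-dosage stand-in for an LD reference: variants come in
#' blocks of `block_size`; within a block, dosages share a latent factor
#' giving pairwise correlation about `rho`; across blocks variants are
#' independent. Used to exercise clumping and LD score computation.
#'
#' @param n_ref Panel size (rows).
#' @param m Number of variants.
#' @param block_size Variants per LD block.
#' @param rho Target within-block dosage correlation.
#' @param seed Integer seed.
#' @return List with `dosages` (n_ref x m), `positions` (variant_id,
#'   chrom, pos; blocks are 10 kb apart, within-block spacing 100 bp).
#' @export
simulate_ld_panel <- function(n_ref = 200L, m = 60L, block_size = 5L,
                              rho = 0.8, seed = 1L) {
  with_seed(seed, {
    blocks <- ceiling(m / block_size)
    dos <- matrix(0, n_ref, m)
    for (b in seq_len(blocks)) {
      cols <- ((b - 1L) * block_size + 1L):min(b * block_size, m)
      f <- stats::rnorm(n_ref)
      for (cc in cols) {
        dos[, cc] <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n_ref)
      }
    }
    ids <- sprintf("ld%04d", seq_len(m))
    colnames(dos) <- ids
    block_of <- (seq_len(m) - 1L) %/% block_size
    within <- (seq_len(m) - 1L) %% block_size
    positions <- data.frame(variant_id = ids, chrom = "1",
                            pos = 1e4L + block_of * 1e4L + within * 100L,
                            stringsAsFactors = FALSE)
    list(dosages = dos, positions = positions)
  })
}
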