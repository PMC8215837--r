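# small in-memory fixtures shared across test files

make_table <- function(ids, beta, se, ea = "A", oa = "G",
                       pvalue = 2 * pnorm(-abs(beta / se)),
                       chrom = "1", pos = seq_along(ids) * 1000L,
                       eaf = 0.3, n = 1e5, name = "trait") {
  as_sumstat_table(data.frame(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pvalue = pvalue, n = n,
    stringsAsFactors = FALSE), trait_name = name)
}

# harmonized set built directly, bypassing allele logic, for estimator tests
make_harmonized <- function(bx, sx, by, sy, ids = NULL,
                            exposure = "X", outcome = "Y") {
  bx <- as.matrix(bx)
  sx <- if (length(sx) == 1L) matrix(sx, nrow(bx), ncol(bx)) else as.matrix(sx)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(nrow(bx)))
  if (is.null(colnames(bx))) {
    colnames(bx) <- if (ncol(bx) == 1L) exposure
                    else paste0(exposure, seq_len(ncol(bx)))
  }
  colnames(sx) <- colnames(bx)
  structure(list(exposure_names = colnames(bx), outcome_name = outcome,
                 variant_ids = ids, beta_exp = bx, se_exp = sx,
                 beta_out = as.numeric(by), se_out = as.numeric(sy),
                 dropped = data.frame(variant_id = character(0),
                                      reason = character(0))),
            class = "harmonized_set")
}

# brute-force greedy clump following the definition literally; used as the
# oracle for the fast implementation on small instances
brute_clump <- function(candidates, ld, p_threshold = 5e-8,
                        r2_threshold = 0.2, window_bp = 1e6) {
  d <- as.data.frame(candidates)
  d <- d[d$pvalue < p_threshold, ]
  d <- d[order(d$pvalue, d$chrom, d$pos, d$variant_id), ]
  kept <- character(0)
  while (nrow(d) > 0) {
    top <- d[1, ]
    kept <- c(kept, top$variant_id)
    d <- d[-1, , drop = FALSE]
    if (nrow(d) == 0) break
    r2 <- vapply(d$variant_id, function(id) {
      i <- match(top$variant_id, ld$variant_ids)
      j <- match(id, ld$variant_ids)
      if (is.na(i) || is.na(j)) 0 else ld$r[i, j]^2
    }, numeric(1))
    pruned <- d$chrom == top$chrom & abs(d$pos - top$pos) <= window_bp &
      r2 >= r2_threshold
    d <- d[!pruned, , drop = FALSE]
  }
  kept
}

# brute-force weighted-median oracle: dense scan over the percentile
# interpolation instead of the closed-form lookup
brute_weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  S <- cumsum(w)
  p <- 100 * (S - w / 2) / S[length(S)]
  grid <- seq(min(theta), max(theta), length.out = 200001)
  pg <- approx(theta, p, xout = grid)$y
  grid[which.min(abs(pg - 50))]
}
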