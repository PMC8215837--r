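#' Construct an LD matrix object
#'
#' Pairwise allelic correlations (r, not r-squared) among candidate
#' variants, with genomic positions, standing in for a reference-panel
#' lookup during clumping.
#'
#' @param r Square symmetric matrix of correlations with unit diagonal,
#'   dimnames set to variant ids.
#' @param positions Data frame with columns `variant_id`, `chrom`, `pos`.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(r, positions) {
  r <- as.matrix(r)
  if (is.null(rownames(r))) stop("input error: r needs variant ids as dimnames")
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8))) {
    stop("input error: r must be symmetric")
  }
  if (any(abs(diag(r) - 1) > 1e-8)) stop("input error: diagonal of r must be 1")
  if (any(abs(r) > 1 + 1e-8)) stop("input error: |r| must be <= 1")
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(positions)))
  positions <- positions[match(rownames(r), positions$variant_id), ]
  if (anyNA(positions$variant_id)) {
    stop("input error: positions missing for some LD-matrix variants")
  }
  structure(list(variant_ids = rownames(r), r = r, positions = positions),
            class = "ld_matrix")
}

#' Read an LD matrix from disk
#'
#' Accepts either a square tab-delimited matrix (variant ids as header and
#' first column) or a long-format triplet file with columns `id1`, `id2`,
#' `r`; absent pairs in the triplet form are treated as r = 0.
#'
#' @param path Path to the matrix or triplet file.
#' @param positions Data frame of `variant_id`, `chrom`, `pos`.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, positions) {
  header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (identical(tolower(header[1:2]), c("id1", "id2"))) {
    long <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    ids <- sort(unique(c(long$id1, long$id2)))
    r <- diag(1, length(ids)); dimnames(r) <- list(ids, ids)
    i <- match(long$id1, ids); j <- match(long$id2, ids)
    r[cbind(i, j)] <- long$r
    r[cbind(j, i)] <- long$r
    diag(r) <- 1
  } else {
    m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
    r <- as.matrix(m)
  }
  ld_matrix(r, positions)
}

#' Compute an LD matrix from a genotype dosage panel
#'
#' @param dosages n_ref x M numeric matrix (columns named by variant id).
#' @param positions Data frame of `variant_id`, `chrom`, `pos`.
#' @return An `ld_matrix`.
#' @export
ld_from_dosages <- function(dosages, positions) {
  r <- stats::cor(dosages)
  ld_matrix(r, positions)
}

#' Greedy LD clumping
#'
#' Selects an approximately independent instrument set: candidates with
#' p-value below `p_threshold` are ranked by p-value; the best remaining
#' variant is retained and all remaining variants on the same chromosome
#' within `window_bp` of it with squared correlation at or above
#' `r2_threshold` are removed; repeat until exhausted. Ties on p-value are
#' broken by (chrom, pos), then variant id, so the retained set does not
#' depend on input row order. The window is centred on the index variant
#' (+/- `window_bp`); set `one_sided = TRUE` for a downstream-only window.
#'
#' @param candidates A `sumstat_table` with positions and p-values.
#' @param ld An `ld_matrix`; candidates absent from it are treated as
#'   unlinked, with a warning.
#' @param p_threshold Selection p-value threshold (default 5e-8).
#' @param r2_threshold Squared-correlation pruning threshold (default 0.2,
#'   variants with r^2 >= threshold are pruned).
#' @param window_bp Window half-width in base pairs (default 1e6).
#' @param one_sided If `TRUE`, prune only variants with position greater
#'   than the index variant's, within `window_bp`.
#' @return An `instrument_set`: data frame of `variant_id`, `pvalue`, `F`
#'   with attribute `exposure_name`.
#' @export
clump <- function(candidates, ld, p_threshold = 5e-8, r2_threshold = 0.2,
                  window_bp = 1e6, one_sided = FALSE) {
  p <- candidates$pvalue
  if (anyNA(p)) {
    p[is.na(p)] <- 2 * stats::pnorm(-abs(candidates$beta / candidates$se))[is.na(p)]
  }
  sig <- which(p < p_threshold)
  if (length(sig) == 0L) {
    stop("analysis error: no candidate variant passes p < ", p_threshold)
  }
  d <- candidates[sig, , drop = FALSE]
  d$pvalue <- p[sig]
  missing_ld <- setdiff(d$variant_id, ld$variant_ids)
  if (length(missing_ld)) {
    warning("variant(s) absent from LD matrix treated as unlinked: ",
            paste(missing_ld, collapse = ", "))
  }
  ord <- order(d$pvalue, d$chrom, d$pos, d$variant_id)
  d <- d[ord, , drop = FALSE]

  retained <- integer(0)
  alive <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    retained <- c(retained, i)
    remaining <- which(alive & seq_len(nrow(d)) > i)
    if (!length(remaining)) next
    same_chr <- d$chrom[remaining] == d$chrom[i]
    dist <- d$pos[remaining] - d$pos[i]
    in_win <- if (one_sided) dist > 0 & dist <= window_bp
              else abs(dist) <= window_bp
    r2 <- vapply(remaining, function(j) {
      ii <- match(d$variant_id[i], ld$variant_ids)
      jj <- match(d$variant_id[j], ld$variant_ids)
      if (is.na(ii) || is.na(jj)) 0 else ld$r[ii, jj]^2
    }, numeric(1))
    prune <- same_chr & in_win & r2 >= r2_threshold
    alive[remaining[prune]] <- FALSE
  }
  out <- d[retained, , drop = FALSE]
  res <- data.frame(variant_id = out$variant_id,
                    pvalue = out$pvalue,
                    F = f_statistic(out$beta, out$se),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, exposure_name = attr(candidates, "trait_name"),
            class = c("instrument_set", "data.frame"))
}

#' Per-variant instrument strength (F-statistic)
#'
#' Large-sample approximation by the squared z-statistic, `(beta/se)^2`.
#' Values above 10 conventionally indicate adequate instrument strength.
#'
#' @param beta,se Effect estimate and its standard error (vectorised).
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("input error: se must be positive")
  }
  (beta / se)^2
}

#' Flag instruments associated with multiple traits
#'
#' Looks every instrument up in every supplied trait table and reports
#' which traits reach genome-wide significance for it, plus the fraction
#' of instruments significant for more than one trait (the pleiotropy
#' yardstick reported alongside instrument tables).
#'
#' @param instrument_sets List of `instrument_set` objects (or character
#'   vectors of ids).
#' @param all_tables List of `sumstat_table`s to scan.
#' @param p_threshold Significance threshold (default 5e-8).
#' @return List with `flags` (data frame: variant_id, n_traits, traits)
#'   and `multi_trait_fraction` (NA when there are no instruments).
#' @export
cross_trait_flags <- function(instrument_sets, all_tables,
                              p_threshold = 5e-8) {
  ids <- unique(unlist(lapply(instrument_sets, function(s) {
    if (is.character(s)) s else s$variant_id
  })))
  if (length(ids) == 0L) {
    return(list(flags = data.frame(variant_id = character(0),
                                   n_traits = integer(0),
                                   traits = character(0)),
                multi_trait_fraction = NA_real_))
  }
  trait_names <- vapply(all_tables, function(t) attr(t, "trait_name"), "")
  hits <- lapply(ids, function(id) {
    sig <- vapply(all_tables, function(tab) {
      i <- match(id, tab$variant_id)
      if (is.na(i)) return(FALSE)
      p <- tab$pvalue[i]
      if (is.na(p)) p <- 2 * stats::pnorm(-abs(tab$beta[i] / tab$se[i]))
      p < p_threshold
    }, TRUE)
    trait_names[sig]
  })
  n_traits <- lengths(hits)
  flags <- data.frame(variant_id = ids, n_traits = n_traits,
                      traits = vapply(hits, paste, "", collapse = ","),
                      stringsAsFactors = FALSE)
  list(flags = flags,
       multi_trait_fraction = mean(n_traits > 1L))
}
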