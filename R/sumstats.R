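#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file of per-variant association records into a
#' `sumstat_table`. The delimiter is auto-detected among tab, comma and
#' whitespace. Alleles are upper-cased on ingestion; rows with a
#' non-positive standard error or an unparsable effect estimate are dropped
#' and counted in the `n_dropped` attribute. Missing effect-allele
#' frequency or sample size is stored as `NA`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping standard field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n`) to column names in the file.
#'   Defaults follow the common GWAS dialect (`SNP`, `CHR`, `BP`, `A1`,
#'   `A2`, `EAF`, `BETA`, `SE`, `P`, `N`).
#' @param trait_name Trait label; defaults to the file name sans extension.
#' @param trait_type `"continuous"` or `"binary"` (log-odds scale betas).
#'
#' @return A `sumstat_table`: a data frame with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`, plus attributes `trait_name`, `trait_type`,
#'   `n_dropped`.
#' @export
read_sumstats <- function(path,
                          column_map = default_column_map(),
                          trait_name = NULL,
                          trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(trimws(header))) {
    stop("input error: empty file: ", path)
  }
  sep <- detect_delimiter(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"",
                          strip.white = TRUE)
  if (nrow(df) == 0L) stop("input error: no data rows in ", path)
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  as_sumstat_table(df, column_map = column_map, trait_name = trait_name,
                   trait_type = trait_type)
}

default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "A1", other_allele = "A2", eaf = "EAF",
    beta = "BETA", se = "SE", pvalue = "P", n = "N")
}

detect_delimiter <- function(header) {
  if (grepl("\t", header)) "\t"
  else if (grepl(",", header)) ","
  else ""
}

#' Build a summary-statistic table from a data frame
#'
#' In-memory constructor used by [read_sumstats()] and the synthetic-data
#' generator. Applies the same validation: mandatory columns must be
#' present, alleles are upper-cased, rows with `se <= 0` or non-finite
#' `beta` are dropped and counted.
#'
#' @param df Data frame of per-variant records.
#' @inheritParams read_sumstats
#' @return A `sumstat_table`.
#' @export
as_sumstat_table <- function(df, column_map = default_column_map(),
                             trait_name = "trait",
                             trait_type = "continuous") {
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  std <- names(default_column_map())
  # accept either standard names directly or via the column map
  out <- vector("list", 0L)
  for (field in std) {
    col <- if (field %in% names(df)) field else unname(column_map[field])
    if (!is.null(col) && !is.na(col) && col %in% names(df)) {
      out[[field]] <- df[[col]]
    } else if (field %in% mandatory) {
      stop("configuration error: mandatory column for field '", field,
           "' (mapped to '", col, "') not found")
    } else {
      out[[field]] <- rep(NA, nrow(df))
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out$variant_id <- as.character(out$variant_id)
  out$chrom <- as.character(out$chrom)
  out$pos <- suppressWarnings(as.integer(out$pos))
  out$effect_allele <- toupper(as.character(out$effect_allele))
  out$other_allele <- toupper(as.character(out$other_allele))
  for (num in c("eaf", "beta", "se", "pvalue", "n")) {
    out[[num]] <- suppressWarnings(as.numeric(out[[num]]))
  }
  bad <- !is.finite(out$beta) | !is.finite(out$se) | out$se <= 0
  n_dropped <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  if (anyDuplicated(out$variant_id)) {
    stop("input error: duplicate variant_id in table '", trait_name, "'")
  }
  rownames(out) <- NULL
  structure(out,
            trait_name = trait_name, trait_type = trait_type,
            n_dropped = n_dropped,
            class = c("sumstat_table", "data.frame"))
}

#' @export
print.sumstat_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants, %d rows dropped on read\n",
              attr(x, "trait_name"), attr(x, "trait_type"),
              nrow(x), attr(x, "n_dropped")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Write a summary-statistic table
#'
#' Always tab-delimited, standard column names.
#'
#' @param x A `sumstat_table`.
#' @param path Output path.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs are strand-ambiguous: the same pair read from the
#' opposite strand is indistinguishable, so the effect allele cannot be
#' resolved between two studies from the alleles alone. Such variants are
#' excluded from harmonization unconditionally.
#'
#' @param effect_allele,other_allele Single-base alleles (A, C, G or T);
#'   vectorised.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a1 <- toupper(effect_allele)
  a2 <- toupper(other_allele)
  ok <- a1 %in% c("A", "C", "G", "T") & a2 %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    stop("input error: invalid allele symbol: ",
         paste(unique(c(a1[!ok & !a1 %in% c("A","C","G","T")],
                        a2[!ok])), collapse = ", "))
  }
  a2 == allele_complement(a1)
}

allele_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every instrument to the exposure's
#' effect allele, producing the matched (beta_exp, se_exp, beta_out,
#' se_out) rows that the MR estimators consume. Matching precedence per
#' variant: exact allele match; swapped alleles (outcome beta sign
#' flipped); strand complement; swapped complement (sign flipped).
#' Palindromic variants are dropped unconditionally, as are instruments
#' with a genome-wide significant direct association with the outcome
#' (default P < 5e-8) and variants missing from the outcome table or with
#' irreconcilable alleles. Every exclusion is logged with a reason.
#'
#' @param exposures A `sumstat_table` or list of them (one per exposure).
#' @param outcome A `sumstat_table`.
#' @param instrument_ids Character vector of instrument variant ids, or a
#'   list of such vectors (one per exposure); the union is harmonized and
#'   the exposure beta matrix carries one column per exposure.
#' @param direct_effect_p Outcome p-value threshold below which an
#'   instrument is considered to act on the outcome directly and is
#'   excluded. Set to 0 to disable.
#' @return A `harmonized_set`: list with `exposure_names`, `outcome_name`,
#'   `variant_ids`, `beta_exp` (J x K matrix), `se_exp`, `beta_out`,
#'   `se_out`, `dropped` (data frame of variant_id, reason).
#' @export
harmonize <- function(exposures, outcome, instrument_ids,
                      direct_effect_p = 5e-8) {
  if (inherits(exposures, "sumstat_table")) exposures <- list(exposures)
  if (!is.list(instrument_ids)) instrument_ids <- list(instrument_ids)
  if (length(instrument_ids) == 1L && length(exposures) > 1L) {
    instrument_ids <- rep(instrument_ids, length(exposures))
  }
  stopifnot(length(instrument_ids) == length(exposures))
  exposure_names <- vapply(exposures, function(e) attr(e, "trait_name"), "")
  outcome_name <- attr(outcome, "trait_name")

  ids <- unique(unlist(instrument_ids))
  for (k in seq_along(exposures)) {
    missing_exp <- setdiff(instrument_ids[[k]], exposures[[k]]$variant_id)
    if (length(missing_exp)) {
      stop("input error: instrument(s) absent from exposure '",
           exposure_names[k], "': ", paste(missing_exp, collapse = ", "))
    }
  }

  out_idx <- match(ids, outcome$variant_id)
  dropped <- data.frame(variant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(id, reason) {
    rbind(dropped, data.frame(variant_id = id, reason = reason,
                              stringsAsFactors = FALSE))
  }

  K <- length(exposures)
  keep_ids <- character(0)
  beta_out <- se_out <- numeric(0)
  rows_exp <- list()

  # reference orientation comes from the first exposure carrying the variant
  for (i in seq_along(ids)) {
    id <- ids[i]
    k_ref <- which(vapply(instrument_ids, function(v) id %in% v, TRUE))[1]
    e_row <- exposures[[k_ref]][exposures[[k_ref]]$variant_id == id, ]
    if (is.na(out_idx[i])) { dropped <- drop(id, "missing_in_outcome"); next }
    if (is_palindromic(e_row$effect_allele, e_row$other_allele)) {
      dropped <- drop(id, "palindromic"); next
    }
    o_row <- outcome[out_idx[i], ]
    al <- match_alleles(e_row$effect_allele, e_row$other_allele,
                        o_row$effect_allele, o_row$other_allele)
    if (is.na(al)) { dropped <- drop(id, "allele_mismatch"); next }
    b_out <- if (al == "flip") -o_row$beta else o_row$beta
    p_out <- o_row$pvalue
    if (is.na(p_out)) {
      p_out <- 2 * stats::pnorm(-abs(o_row$beta / o_row$se))
    }
    if (direct_effect_p > 0 && p_out < direct_effect_p) {
      dropped <- drop(id, "direct_effect"); next
    }
    # align every exposure carrying this instrument to the same allele
    be <- se <- rep(NA_real_, K)
    mismatch <- FALSE
    for (k in seq_len(K)) {
      if (!(id %in% exposures[[k]]$variant_id)) { be[k] <- 0; se[k] <- NA; next }
      ek <- exposures[[k]][exposures[[k]]$variant_id == id, ]
      alk <- match_alleles(e_row$effect_allele, e_row$other_allele,
                           ek$effect_allele, ek$other_allele)
      if (is.na(alk)) { mismatch <- TRUE; break }
      be[k] <- if (alk == "flip") -ek$beta else ek$beta
      se[k] <- ek$se
    }
    if (mismatch) { dropped <- drop(id, "allele_mismatch"); next }
    keep_ids <- c(keep_ids, id)
    beta_out <- c(beta_out, b_out)
    se_out <- c(se_out, o_row$se)
    rows_exp[[length(rows_exp) + 1L]] <- list(be = be, se = se)
  }

  if (length(keep_ids) == 0L) {
    stop("analysis error: no variants retained after harmonization; drops: ",
         paste(sprintf("%s=%d", names(table(dropped$reason)),
                       table(dropped$reason)), collapse = ", "))
  }

  beta_exp <- do.call(rbind, lapply(rows_exp, `[[`, "be"))
  se_exp <- do.call(rbind, lapply(rows_exp, `[[`, "se"))
  colnames(beta_exp) <- colnames(se_exp) <- exposure_names

  structure(list(exposure_names = exposure_names,
                 outcome_name = outcome_name,
                 variant_ids = keep_ids,
                 beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = beta_out, se_out = se_out,
                 dropped = dropped),
            class = "harmonized_set")
}

# returns "same", "flip", or NA for irreconcilable pairs; precedence:
# exact, swapped, strand complement, swapped complement
match_alleles <- function(ref_ea, ref_oa, ea, oa) {
  if (ea == ref_ea && oa == ref_oa) return("same")
  if (ea == ref_oa && oa == ref_ea) return("flip")
  cea <- allele_complement(ea); coa <- allele_complement(oa)
  if (cea == ref_ea && coa == ref_oa) return("same")
  if (cea == ref_oa && coa == ref_ea) return("flip")
  NA_character_
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s\n",
              paste(x$exposure_names, collapse = " + "), x$outcome_name))
  cat(sprintf("  %d variants retained, %d dropped", length(x$variant_ids),
              nrow(x$dropped)))
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.harmonized_set <- function(x, ...) {
  K <- length(x$exposure_names)
  df <- data.frame(variant_id = x$variant_ids, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    df[[paste0("beta_", x$exposure_names[k])]] <- x$beta_exp[, k]
    df[[paste0("se_", x$exposure_names[k])]] <- x$se_exp[, k]
  }
  df$beta_out <- x$beta_out
  df$se_out <- x$se_out
  df
}

#' Write a harmonized set and its drop log
#'
#' Writes the aligned table (tab-delimited) and a companion drop-log TSV
#' (`<path>.drops.tsv`) of excluded variants and reasons.
#'
#' @param x A `harmonized_set`.
#' @param path Output path for the harmonized table.
#' @export
write_harmonized <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$dropped, paste0(path, ".drops.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# number of variants in a harmonized set
n_variants <- function(h) length(h$variant_ids)

# subset a harmonized set by variant id or logical/integer index
subset_harmonized <- function(h, keep) {
  if (is.character(keep)) keep <- match(keep, h$variant_ids)
  h$variant_ids <- h$variant_ids[keep]
  h$beta_exp <- h$beta_exp[keep, , drop = FALSE]
  h$se_exp <- h$se_exp[keep, , drop = FALSE]
  h$beta_out <- h$beta_out[keep]
  h$se_out <- h$se_out[keep]
  h
}
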