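#' Log2 fold change from mean delta-CT values
#'
#' FC = -(deltaCT_end - deltaCT_onset), the negated delta-delta-CT. Negative
#' values indicate downregulation after induction chemotherapy (a rise in CT
#' is a drop in expression).
#'
#' @param mean_dct_onset,mean_dct_end mean delta-CT values (log2 units).
#' @return log2 fold change (vectorized).
#' @export
fold_change <- function(mean_dct_onset, mean_dct_end) {
  stopifnot(all(is.finite(mean_dct_onset)), all(is.finite(mean_dct_end)))
  -(mean_dct_end - mean_dct_onset)
}

#' Relative quantity from delta-CT
#'
#' RQ = 2^(-deltaCT): linear-scale expression relative to the sample's
#' global-mean reference; strictly decreasing in delta-CT.
#'
#' @param delta_ct delta-CT value(s) in log2 units.
#' @return relative quantity (dimensionless, > 0).
#' @export
relative_quantity <- function(delta_ct) {
  stopifnot(all(is.finite(delta_ct)))
  2^(-delta_ct)
}

#' Per-miRNA paired t-test between timepoints
#'
#' Two-sided t-test on the per-patient difference deltaCT(end) -
#' deltaCT(onset). Patients missing either timepoint are excluded per miRNA.
#' When all differences are identical (zero variance) the test is undefined
#' and p = 1 is reported with a flag; assays with fewer than 3 complete pairs
#' get `NA` with a warning. With `paired = FALSE` an unpaired Welch test on
#' the two timepoint groups is used instead.
#'
#' @param norm a `normalized_matrix`.
#' @param paired paired across patients (default) or unpaired.
#' @return data.frame with columns `mirna`, `p_raw`, `n_pairs`,
#'   `zero_variance`.
#' @export
paired_test <- function(norm, paired = TRUE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  d <- norm$delta_ct
  info <- sample_info(norm)
  onset <- d[, info$timepoint == "onset", drop = FALSE]
  end <- d[, info$timepoint == "end", drop = FALSE]
  colnames(onset) <- info$patient_id[info$timepoint == "onset"]
  colnames(end) <- info$patient_id[info$timepoint == "end"]
  common <- intersect(colnames(onset), colnames(end))
  if (length(common) < 3) stop("need >= 3 patients with both timepoints")
  onset <- onset[, common, drop = FALSE]
  end <- end[, common, drop = FALSE]

  out <- data.frame(mirna = rownames(d), p_raw = NA_real_, n_pairs = 0L,
                    zero_variance = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(d))) {
    ok <- !is.na(onset[i, ]) & !is.na(end[i, ])
    out$n_pairs[i] <- sum(ok)
    if (sum(ok) < 3) next
    if (paired) {
      diffs <- end[i, ok] - onset[i, ok]
      if (stats::sd(diffs) == 0) {
        out$p_raw[i] <- 1
        out$zero_variance[i] <- TRUE
      } else {
        out$p_raw[i] <- stats::t.test(diffs)$p.value
      }
    } else {
      a <- end[i, ok]; b <- onset[i, ok]
      if (stats::sd(c(a, b)) == 0) {
        out$p_raw[i] <- 1
        out$zero_variance[i] <- TRUE
      } else {
        out$p_raw[i] <- stats::t.test(a, b)$p.value
      }
    }
  }
  if (anyNA(out$p_raw))
    warning(sum(is.na(out$p_raw)),
            " miRNA(s) with < 3 complete pairs: p reported as NA")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p values (monotone, capped at 1).
#' `NA` entries are passed through.
#'
#' @param p_raw vector of raw p values in [0, 1].
#' @return adjusted p values.
#' @export
bh_adjust <- function(p_raw) {
  ok <- !is.na(p_raw)
  if (any(p_raw[ok] < 0 | p_raw[ok] > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = "BH")
}

#' Differential expression between onset and end of induction
#'
#' Builds the per-miRNA differential-expression table: mean delta-CT per
#' timepoint (over all samples with data at that timepoint), relative
#' quantities RQ = 2^(-mean deltaCT), fold change -(deltaCT_end -
#' deltaCT_onset), raw and BH-adjusted paired t-test p values.
#'
#' @param norm a complete `normalized_matrix` (after imputation).
#' @param paired see [paired_test()].
#' @return data.frame of class `diffexpr_table` with columns `mirna`,
#'   `mean_dct_onset`, `mean_dct_end`, `rq_onset`, `rq_end`, `fold_change`,
#'   `p_raw`, `p_adj`.
#' @export
diff_expression <- function(norm, paired = TRUE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  d <- norm$delta_ct
  info <- sample_info(norm)
  mu_on <- rowMeans(d[, info$timepoint == "onset", drop = FALSE], na.rm = TRUE)
  mu_en <- rowMeans(d[, info$timepoint == "end", drop = FALSE], na.rm = TRUE)
  tt <- paired_test(norm, paired = paired)
  out <- data.frame(mirna = rownames(d),
                    mean_dct_onset = mu_on, mean_dct_end = mu_en,
                    rq_onset = relative_quantity(mu_on),
                    rq_end = relative_quantity(mu_en),
                    fold_change = fold_change(mu_on, mu_en),
                    p_raw = tt$p_raw,
                    p_adj = bh_adjust(tt$p_raw),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- unique(c("diffexpr_table", class(out)))
  out
}

#' Filter a differential-expression table for significant modulation
#'
#' Keeps miRNAs with |log2 fold change| at or above `fc_threshold_log2`
#' (0.58 = log2 of a linear 1.5-fold change, inclusive) and adjusted p below
#' `alpha`, and records the modulation direction.
#'
#' @param table a data.frame with columns `fold_change` and `p_adj` (e.g.
#'   from [diff_expression()]).
#' @param fc_threshold_log2 minimum |log2 FC|.
#' @param alpha maximum adjusted p value (exclusive).
#' @return the filtered table with an added `direction` column
#'   (`"up"`/`"down"`).
#' @export
significance_filter <- function(table, fc_threshold_log2 = 0.58, alpha = 0.05) {
  stopifnot(all(c("fold_change", "p_adj") %in% names(table)))
  keep <- !is.na(table$p_adj) &
    abs(table$fold_change) >= fc_threshold_log2 & table$p_adj < alpha
  out <- table[keep, , drop = FALSE]
  out$direction <- ifelse(out$fold_change > 0, "up", "down")
  out
}
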