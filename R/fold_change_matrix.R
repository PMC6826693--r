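#' Per-patient fold-change matrix
#'
#' For every patient with both timepoints, the per-miRNA log2 fold change
#' -(deltaCT_end - deltaCT_onset). Entries where either timepoint is missing
#' are `NA`. Patients lacking a timepoint entirely are excluded with a
#' warning.
#'
#' @param norm a `normalized_matrix`.
#' @return numeric matrix, patients x miRNAs.
#' @export
patient_fold_changes <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  d <- norm$delta_ct
  info <- sample_info(norm)
  onset <- d[, info$timepoint == "onset", drop = FALSE]
  end <- d[, info$timepoint == "end", drop = FALSE]
  colnames(onset) <- info$patient_id[info$timepoint == "onset"]
  colnames(end) <- info$patient_id[info$timepoint == "end"]
  common <- intersect(colnames(onset), colnames(end))
  all_pat <- unique(info$patient_id)
  if (length(common) < length(all_pat))
    warning("patient(s) excluded for a missing timepoint: ",
            paste(setdiff(all_pat, common), collapse = ", "))
  if (!length(common)) stop("no patient has both timepoints")
  t(-(end[, common, drop = FALSE] - onset[, common, drop = FALSE]))
}
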