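#' Mark unreliable CT values as missing
#'
#' CT values above `ct_max`, below `ct_min`, or from failed wells carry no
#' reliable quantitative signal and are replaced by `NA`. The window is
#' inclusive: CT values exactly at either bound are kept.
#'
#' @param ct a [ct_matrix()].
#' @param ct_min,ct_max reliable CT window (cycles).
#' @return a `ct_matrix` with out-of-window entries set to missing.
#' @export
filter_reliable_ct <- function(ct, ct_min = 14, ct_max = 32) {
  stopifnot(inherits(ct, "ct_matrix"), ct_min < ct_max)
  m <- unclass(ct)
  m[!is.na(m) & (m > ct_max | m < ct_min)] <- NA_real_
  structure(m, class = class(ct))
}

#' Global-mean delta-CT normalization
#'
#' For each sample, the mean CT of its detected assays (CT strictly below
#' `detection_ceiling`) is subtracted from every raw CT, yielding delta-CT
#' values in log2 units (lower = more expressed). The global mean acts as the
#' per-sample reference, removing additive technical offsets (input amount,
#' reverse-transcription efficiency) exactly; it replaces an endogenous
#' control such as U6, which is unstable in plasma.
#'
#' @param ct a [ct_matrix()], normally after [filter_reliable_ct()].
#' @param detection_ceiling CT ceiling for an assay to count as detected.
#' @return a `normalized_matrix`: list with `delta_ct` (matrix), `detected`
#'   (logical matrix, CT < ceiling) and `imputed` (logical matrix, all `FALSE`
#'   until [impute_missing()]).
#' @export
normalize_global_mean <- function(ct, detection_ceiling = 32) {
  stopifnot(inherits(ct, "ct_matrix"))
  m <- unclass(ct)
  detected <- !is.na(m) & m < detection_ceiling
  n_det <- colSums(detected)
  if (any(n_det < 2))
    stop("global mean undefined for sample(s) with < 2 detected miRNAs: ",
         paste(colnames(m)[n_det < 2], collapse = ", "))
  gm <- colSums(m * detected, na.rm = TRUE) / n_det
  delta <- sweep(m, 2, gm, `-`)
  new_normalized_matrix(delta, detected)
}

new_normalized_matrix <- function(delta_ct, detected,
                                  imputed = array(FALSE, dim(delta_ct),
                                                  dimnames(delta_ct))) {
  stopifnot(all(dim(delta_ct) == dim(detected)),
            all(dim(delta_ct) == dim(imputed)),
            !any(imputed & detected))
  structure(list(delta_ct = delta_ct, detected = detected, imputed = imputed),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(paste0("normalized_matrix: %d miRNAs x %d samples, ",
                     "%.1f%% detected, %d imputed entries\n"),
              nrow(x$delta_ct), ncol(x$delta_ct),
              100 * mean(x$detected), sum(x$imputed)))
  invisible(x)
}

#' Per-sample detected-assay counts
#'
#' Counts, per sample, the assays detected below the CT ceiling and summarizes
#' the counts per timepoint (mean and SD across samples). On real cohorts the
#' onset mean exceeds the end-of-induction mean, reflecting the global
#' suppression of circulating exosomal miRNAs by chemotherapy.
#'
#' @param norm a `normalized_matrix`.
#' @return list with `per_sample` (data.frame: `sample_id`, `patient_id`,
#'   `timepoint`, `n_detected`) and `per_timepoint` (data.frame: `timepoint`,
#'   `mean`, `sd`, `n_samples`).
#' @export
count_detected <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  info <- sample_info(norm)
  info$n_detected <- as.integer(colSums(norm$detected))
  by_tp <- lapply(split(info$n_detected, info$timepoint), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n_samples = length(v)))
  per_tp <- do.call(rbind, by_tp)
  per_tp <- data.frame(timepoint = rownames(per_tp), per_tp, row.names = NULL)
  list(per_sample = info, per_timepoint = per_tp)
}

#' Drop assays detected in too few samples
#'
#' Keeps miRNAs detected in at least `detection_fraction` of all samples
#' (both timepoints pooled); the boundary is inclusive. Restricting
#' imputation to assays with few missing wells bounds the bias the
#' worst-case imputation rule can introduce.
#'
#' @param norm a `normalized_matrix`.
#' @param detection_fraction minimum detected fraction, in (0, 1].
#' @return the reduced `normalized_matrix`; dropped assay names are available
#'   via `attr(, "dropped")`.
#' @export
detection_filter <- function(norm, detection_fraction = 0.80) {
  stopifnot(inherits(norm, "normalized_matrix"),
            detection_fraction > 0, detection_fraction <= 1)
  frac <- rowMeans(norm$detected)
  keep <- frac >= detection_fraction
  out <- new_normalized_matrix(norm$delta_ct[keep, , drop = FALSE],
                               norm$detected[keep, , drop = FALSE],
                               norm$imputed[keep, , drop = FALSE])
  attr(out, "dropped") <- rownames(norm$delta_ct)[!keep]
  out
}

#' Impute missing delta-CT values at the assay's worst observed expression
#'
#' Each missing entry is set to the maximum observed delta-CT of its miRNA
#' across all samples plus one log2 unit, i.e. one CT cycle above the highest
#' CT ever recorded for that assay: an undetected well is treated as the
#' lowest plausible expression, never as more expressed than any observed
#' well.
#'
#' @param norm a `normalized_matrix` (after [detection_filter()]).
#' @return a complete `normalized_matrix` with the `imputed` mask set.
#' @export
impute_missing <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  d <- norm$delta_ct
  n_obs <- rowSums(!is.na(d))
  if (any(n_obs == 0))
    stop("miRNA(s) with zero observed values (run detection_filter first): ",
         paste(rownames(d)[n_obs == 0], collapse = ", "))
  fill <- apply(d, 1, max, na.rm = TRUE) + 1
  miss <- is.na(d)
  d[miss] <- fill[row(d)[miss]]
  new_normalized_matrix(d, norm$detected, imputed = miss)
}

#' Per-assay coefficient of variation
#'
#' CV = sample standard deviation / |mean| per miRNA over its observed
#' entries, computed on the values as given. Assays with fewer than two
#' observed values, or a mean of zero, yield `NA` with a warning.
#'
#' @param x numeric matrix (miRNAs x samples), a [ct_matrix()], or a
#'   `normalized_matrix` (its `delta_ct` is used).
#' @return named numeric vector of CVs.
#' @export
mirna_cv <- function(x) {
  m <- if (inherits(x, "normalized_matrix")) x$delta_ct else unclass(x)
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, stats::sd, na.rm = TRUE)
  cv <- s / abs(mu)
  und <- is.na(s) | mu == 0
  if (any(und[!is.na(und)])) {
    warning("CV undefined for ", sum(und, na.rm = TRUE),
            " miRNA(s) (zero mean or < 2 observed values)")
    cv[und] <- NA_real_
  }
  cv
}

#' Technical-variability diagnostic: CV before vs. after normalization
#'
#' Compares the dispersion of each assay across samples before and after
#' global-mean normalization. CVs are computed on the linear
#' relative-quantity scale (RQ = 2^-CT and 2^-deltaCT), where the lognormal
#' CV depends only on the log-scale spread, so removing per-sample offsets
#' shows up directly as a drop in CV. A two-sample Kolmogorov-Smirnov test
#' compares the raw and normalized CV distributions.
#'
#' @param raw a [ct_matrix()] (after [filter_reliable_ct()]).
#' @param norm the corresponding `normalized_matrix`.
#' @return list with `cv_raw`, `cv_normalized` (per-assay CVs on the linear
#'   scale), `median_raw`, `median_normalized`, and `ks` (the
#'   [stats::ks.test()] result).
#' @export
cv_reduction <- function(raw, norm) {
  stopifnot(inherits(raw, "ct_matrix"), inherits(norm, "normalized_matrix"))
  cv_raw <- suppressWarnings(mirna_cv(2^(-unclass(raw))))
  cv_nrm <- suppressWarnings(mirna_cv(2^(-norm$delta_ct)))
  ks <- suppressWarnings(
    stats::ks.test(cv_raw[is.finite(cv_raw)], cv_nrm[is.finite(cv_nrm)]))
  list(cv_raw = cv_raw, cv_normalized = cv_nrm,
       median_raw = stats::median(cv_raw, na.rm = TRUE),
       median_normalized = stats::median(cv_nrm, na.rm = TRUE),
       ks = ks)
}
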