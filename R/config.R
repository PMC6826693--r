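#' Analysis configuration
#'
#' Central collection of the pipeline's tunable thresholds. Defaults follow
#' the array-card manufacturer's reliability window (CT in [14, 32]), an 80%
#' detection-rate inclusion rule, a linear fold-change cutoff of 1.5
#' (|log2 FC| >= 0.58), a 5% significance level, elastic-net mixing 0.7 and a
#' 5% weighted-average-proportion-variance (WAPV) ceiling for a negligible
#' batch effect.
#'
#' @param ct_min lower bound of the reliable CT window (cycles).
#' @param ct_max upper bound of the reliable CT window (cycles); values above
#'   it are unreliable, and detection additionally requires CT strictly below
#'   this ceiling.
#' @param detection_fraction minimum fraction of samples in which an assay
#'   must be detected to be retained (in (0, 1]).
#' @param fc_threshold_log2 minimum |log2 fold change| called significant.
#' @param alpha significance level for adjusted p values.
#' @param elasticnet_mixing elastic-net mixing parameter (1 = lasso).
#' @param wapv_batch_threshold WAPV above (or at) which the batch effect is
#'   classified significant.
#' @param kmeans_k number of patient clusters.
#' @param paired whether the differential-expression t-test is paired across
#'   patients (the samples are longitudinal per patient).
#' @param pc_variance_target cumulative variance fraction retained by PVCA.
#' @param random_seed seed recorded in run manifests and used for k-means
#'   restarts.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(ct_min = 14, ct_max = 32,
                            detection_fraction = 0.80,
                            fc_threshold_log2 = 0.58,
                            alpha = 0.05,
                            elasticnet_mixing = 0.7,
                            wapv_batch_threshold = 0.05,
                            kmeans_k = 2,
                            paired = TRUE,
                            pc_variance_target = 0.6,
                            random_seed = 1L) {
  stopifnot(ct_min < ct_max, ct_min > 0,
            detection_fraction > 0, detection_fraction <= 1,
            fc_threshold_log2 > 0, alpha > 0, alpha < 1,
            elasticnet_mixing > 0, elasticnet_mixing <= 1,
            wapv_batch_threshold > 0, kmeans_k >= 1,
            pc_variance_target > 0, pc_variance_target <= 1)
  structure(list(ct_min = ct_min, ct_max = ct_max,
                 detection_fraction = detection_fraction,
                 fc_threshold_log2 = fc_threshold_log2, alpha = alpha,
                 elasticnet_mixing = elasticnet_mixing,
                 wapv_batch_threshold = wapv_batch_threshold,
                 kmeans_k = kmeans_k, paired = paired,
                 pc_variance_target = pc_variance_target,
                 random_seed = as.integer(random_seed)),
            class = "analysis_config")
}
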