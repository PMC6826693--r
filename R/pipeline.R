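#' Run the full analysis pipeline
#'
#' Executes the fixed stage order: CT reliability filter, global-mean
#' normalization, detection counting, detection-rate filter, PVCA batch
#' verdict, imputation, paired differential expression with BH correction and
#' significance filtering, optional elastic-net signature selection,
#' chemoresistance-index computation, k-means stratification, cluster
#' association tests and the three-year EFS log-rank comparison.
#'
#' The pipeline applies no batch correction; if the PVCA verdict is
#' `"significant"` it aborts unless `override_batch = TRUE`, so a material
#' batch effect is an explicit stop condition rather than a silent hazard.
#'
#' @param ct a [ct_matrix()].
#' @param clinical a [clinical_table()].
#' @param chemo_list a [chemoresistance_list()].
#' @param config an [analysis_config()].
#' @param signature_groups two response levels for signature selection, or
#'   `NULL` to skip the stage.
#' @param override_batch proceed despite a significant batch verdict.
#' @param out_dir optional directory; when given, every intermediate table is
#'   written as TSV and the run manifest as JSON.
#' @return list of class `pipeline_result` with elements `normalized`,
#'   `detected_counts`, `pvca`, `batch_verdict`, `diffexpr`, `significant`,
#'   `signature` (or `NULL`), `ci`, `clusters`, `associations`, `survival`,
#'   `manifest`.
#' @export
run_pipeline <- function(ct, clinical, chemo_list,
                         config = analysis_config(),
                         signature_groups = c("MR", "VGPR"),
                         override_batch = FALSE, out_dir = NULL) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(config, "analysis_config"))
  clinical <- clinical_table(as.data.frame(clinical))
  chemo_list <- chemoresistance_list(as.data.frame(chemo_list))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  manifest <- list(config = unclass(config),
                   seed = config$random_seed,
                   n_input_mirnas = nrow(ct), n_samples = ncol(ct),
                   stages = character(0))
  note <- function(nm, ...) {
    manifest$stages <<- c(manifest$stages, nm)
    manifest[[nm]] <<- list(...)
  }

  reliable <- stage("reliability_filter",
                    filter_reliable_ct(ct, config$ct_min, config$ct_max))
  note("reliability_filter", n_unreliable = sum(is.na(reliable)) - sum(is.na(ct)))
  norm <- stage("normalization",
                normalize_global_mean(reliable, config$ct_max))
  note("normalization", n_samples = ncol(norm$delta_ct))
  counts <- stage("detection_counts", count_detected(norm))
  note("detection_counts",
       per_timepoint = counts$per_timepoint)
  norm <- stage("detection_filter",
                detection_filter(norm, config$detection_fraction))
  note("detection_filter", n_kept = nrow(norm$delta_ct),
       n_dropped = length(attr(norm, "dropped")))
  if (nrow(norm$delta_ct) < 2)
    stop("[detection_filter] fewer than 2 assays pass the detection filter")

  imputed <- stage("imputation", impute_missing(norm))
  note("imputation", n_imputed = sum(imputed$imputed))

  pvca <- stage("pvca", run_pvca(imputed, clinical,
                                 pc_variance_target = config$pc_variance_target))
  verdict <- assess_batch_effect(pvca, config$wapv_batch_threshold)
  note("pvca", wapv = as.list(pvca$wapv), verdict = as.character(verdict))
  if (verdict == "significant" && !override_batch)
    stop(sprintf(paste0("[pvca] batch effect significant (WAPV(%s) = %.3f ",
                        ">= %.3f); no correction is applied - rerun with ",
                        "override_batch = TRUE to proceed regardless"),
                 pvca$batch_factor, attr(verdict, "wapv"),
                 config$wapv_batch_threshold), call. = FALSE)

  de <- stage("diffexpr", diff_expression(imputed, paired = config$paired))
  sig_table <- significance_filter(de, config$fc_threshold_log2, config$alpha)
  note("diffexpr", n_tested = nrow(de), n_significant = nrow(sig_table))

  signature <- NULL
  if (!is.null(signature_groups)) {
    signature <- stage("signature", {
      des <- build_design(imputed, clinical, signature_groups)
      fit_elastic_net_loocv(des$x, des$y, mixing = config$elasticnet_mixing)
    })
    note("signature", n_selected = length(signature$selected_mirnas),
         penalty = signature$chosen_penalty)
  }

  dirs <- stage("modulation", modulation_directions(imputed))
  note("modulation", n_patients = nrow(dirs))
  ci <- stage("chemoresistance_index", chemoresistance_index(dirs, chemo_list))
  note("chemoresistance_index", drugs = colnames(ci$ci),
       excluded = ci$excluded_drugs)
  clusters <- stage("stratification",
                    kmeans_stratify(ci, k = config$kmeans_k,
                                    seed = config$random_seed))
  note("stratification", sizes = as.list(table(clusters$cluster)))
  assoc <- stage("association", association_tests(clusters, clinical))
  surv <- stage("survival", logrank_efs(clusters, clinical))
  note("association", efs_p = assoc$p[assoc$covariate == "efs_event"])
  note("survival", logrank_p = surv$p)

  result <- structure(list(normalized = imputed, detected_counts = counts,
                           pvca = pvca, batch_verdict = verdict,
                           diffexpr = de, significant = sig_table,
                           signature = signature, ci = ci,
                           clusters = clusters, associations = assoc,
                           survival = surv, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  d <- result$normalized$delta_ct
  write_tsv(data.frame(mirna = rownames(d), d, check.names = FALSE),
            p("normalized_delta_ct.tsv"))
  write_tsv(result$detected_counts$per_sample, p("detected_counts.tsv"))
  write_tsv(data.frame(factor = names(result$pvca$wapv),
                       wapv = unname(result$pvca$wapv)), p("pvca_wapv.tsv"))
  write_tsv(as.data.frame(result$diffexpr), p("diffexpr.tsv"))
  write_tsv(as.data.frame(result$significant), p("diffexpr_significant.tsv"))
  if (!is.null(result$signature))
    write_tsv(data.frame(mirna = result$signature$selected_mirnas,
                         coefficient = unname(result$signature$coefficients)),
              p("signature.tsv"))
  write_tsv(data.frame(patient_id = rownames(result$ci$ci), result$ci$ci,
                       check.names = FALSE), p("chemoresistance_index.tsv"))
  write_tsv(data.frame(patient_id = names(result$clusters$cluster),
                       cluster = unname(result$clusters$cluster)),
            p("clusters.tsv"))
  write_tsv(result$associations, p("associations.tsv"))
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  assays kept: %d, significant: %d\n",
              nrow(x$diffexpr), nrow(x$significant)))
  cat(sprintf("  batch verdict: %s (WAPV %.3f)\n",
              x$batch_verdict, attr(x$batch_verdict, "wapv")))
  if (!is.null(x$signature))
    cat(sprintf("  signature: %s\n",
                paste(x$signature$selected_mirnas, collapse = ", ")))
  cat(sprintf("  clusters: %s; log-rank p = %.4g\n",
              paste(table(x$clusters$cluster), collapse = "/"), x$survival$p))
  invisible(x)
}
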