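#' Per-patient modulation direction of each miRNA
#'
#' The sign of the per-patient -(delta-delta-CT): `"up"` when expression rose
#' after induction chemotherapy, `"down"` when it fell, `"none"` when the
#' contrast is exactly zero or unevaluable. No magnitude threshold is applied
#' by default (an exact zero has measure zero under continuous noise); set
#' `min_abs_fc` for a strict mode that also calls `"none"` below a |log2 FC|
#' cutoff.
#'
#' @param norm a `normalized_matrix`.
#' @param min_abs_fc optional minimum |log2 FC| for a direction call.
#' @return character matrix (patients x miRNAs) with values
#'   `"up"`/`"down"`/`"none"`.
#' @export
modulation_directions <- function(norm, min_abs_fc = 0) {
  fc <- patient_fold_changes(norm)
  dir <- matrix("none", nrow(fc), ncol(fc), dimnames = dimnames(fc))
  dir[!is.na(fc) & fc > 0 & abs(fc) >= min_abs_fc] <- "up"
  dir[!is.na(fc) & fc < 0 & abs(fc) >= min_abs_fc] <- "down"
  dir
}

#' Laplace-smoothed chemoresistance index
#'
#' For each patient and drug, counts the listed miRNAs whose observed
#' modulation direction matches the literature-reported resistance direction
#' (m concordant out of M listed) and estimates the probability of
#' chemoresistance with add-one (Laplace) smoothing: CI = (m + 1) / (M + 2).
#' Smoothing keeps the estimate strictly inside (0, 1) and robust to drugs
#' with few listed miRNAs. Listed miRNAs absent from the expression matrix
#' are excluded from both m and M and reported; drugs with no evaluable
#' miRNAs (M = 0) are excluded from the matrix (their smoothed value would be
#' an uninformative 0.5) and reported separately.
#'
#' @param directions matrix from [modulation_directions()].
#' @param chemo_list a [chemoresistance_list()].
#' @return object of class `ci_matrix`: `ci` (patients x drugs probabilities),
#'   `m`, `M` (count matrices), `excluded_drugs`, `unmatched_mirnas`.
#' @export
chemoresistance_index <- function(directions, chemo_list) {
  stopifnot(inherits(chemo_list, "chemoresistance_list"))
  if (!nrow(chemo_list)) stop("chemoresistance list is empty")
  key <- canonical_mirna(colnames(directions))
  hit <- match(canonical_mirna(chemo_list$mirna), key)
  unmatched <- unique(chemo_list$mirna[is.na(hit)])
  lst <- chemo_list[!is.na(hit), , drop = FALSE]
  col <- hit[!is.na(hit)]

  drugs <- unique(chemo_list$drug)
  pats <- rownames(directions)
  m <- M <- matrix(0L, length(pats), length(drugs),
                   dimnames = list(pats, drugs))
  for (j in seq_along(drugs)) {
    sel <- lst$drug == drugs[j]
    if (!any(sel)) next
    dsub <- directions[, col[sel], drop = FALSE]
    want <- matrix(lst$direction[sel], nrow(dsub), sum(sel), byrow = TRUE)
    m[, j] <- as.integer(rowSums(dsub == want))
    M[, j] <- as.integer(sum(sel))
  }
  ci <- (m + 1) / (M + 2)
  informative <- colSums(M) > 0
  structure(list(ci = ci[, informative, drop = FALSE],
                 m = m[, informative, drop = FALSE],
                 M = M[, informative, drop = FALSE],
                 excluded_drugs = drugs[!informative],
                 unmatched_mirnas = unmatched),
            class = "ci_matrix")
}

#' @export
print.ci_matrix <- function(x, ...) {
  cat(sprintf("ci_matrix: %d patients x %d drugs\n", nrow(x$ci), ncol(x$ci)))
  print(round(utils::head(x$ci, 4), 3))
  if (length(x$excluded_drugs))
    cat("excluded (no listed miRNAs):",
        paste(x$excluded_drugs, collapse = ", "), "\n")
  invisible(x)
}

# Drugs whose high chemoresistance index marks the poor-responder-like
# cluster (platinum compounds and doxorubicin).
.poor_response_drugs <- c("carboplatin", "cisplatin", "doxorubicin")

#' Stratify patients by k-means on the chemoresistance index
#'
#' Euclidean k-means on the patient x drug CI profiles (already on a common
#' (0,1) probability scale, so no re-standardization), with `n_restarts`
#' random initializations at a fixed seed. With k = 2 the clusters are
#' relabeled so that cluster 1 is the one with the higher mean CI over the
#' carboplatin/cisplatin/doxorubicin columns (the "poor-responder-like"
#' profile).
#'
#' @param ci a `ci_matrix`.
#' @param k number of clusters.
#' @param seed RNG seed for the restarts.
#' @param n_restarts number of random initializations.
#' @return object of class `cluster_assignment`: `cluster` (named integer
#'   vector), `centers` (k x drugs), `inertia` (total within-cluster sum of
#'   squares), `poor_responder_cluster` (1, or NA when undeterminable).
#' @export
kmeans_stratify <- function(ci, k = 2, seed = 1L, n_restarts = 50) {
  stopifnot(inherits(ci, "ci_matrix"))
  x <- ci$ci
  if (k > nrow(x)) stop("k exceeds the number of patients")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
  cl <- km$cluster
  poor <- NA_integer_
  anchor <- intersect(.poor_response_drugs, colnames(x))
  if (k == 2 && length(anchor)) {
    sev <- rowMeans(km$centers[, anchor, drop = FALSE])
    ord <- order(-sev)                 # cluster 1 = higher anchor-drug CI
    relab <- match(seq_len(k), ord)
    cl <- relab[cl]
    km$centers <- km$centers[ord, , drop = FALSE]
    rownames(km$centers) <- seq_len(k)
    poor <- 1L
  }
  structure(list(cluster = stats::setNames(cl, rownames(x)),
                 centers = km$centers, inertia = km$tot.withinss,
                 poor_responder_cluster = poor, k = k, seed = seed),
            class = "cluster_assignment")
}

# Two-proportion z-test with pooled variance; exact-test fallback when the
# pooled proportion is degenerate (0 or 1).
two_proportion_test <- function(x1, n1, x2, n2) {
  p_pool <- (x1 + x2) / (n1 + n2)
  if (p_pool %in% c(0, 1)) {
    if (x1 / n1 == x2 / n2)
      return(list(z = 0, p = 1, method = "degenerate"))
    p <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2))$p.value
    return(list(z = NA_real_, p = p, method = "fisher"))
  }
  z <- (x1 / n1 - x2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), method = "z")
}

#' Cluster-covariate association tests
#'
#' Two-proportion z-tests (pooled variance) comparing the two clusters on
#' dichotomized clinical covariates: INSS stage 4 vs. other, MYCN amplified
#' vs. not (NA dropped), induction response MR vs. PR/VGPR (NA dropped), and
#' EFS event within the horizon vs. event-free. Degenerate tables fall back
#' to Fisher's exact test, flagged in the `method` column.
#'
#' @param assign a `cluster_assignment` with k = 2.
#' @param clinical a [clinical_table()].
#' @param horizon_months horizon for the EFS dichotomy.
#' @return data.frame with columns `covariate`, `prop_cluster1`,
#'   `prop_cluster2`, `z`, `p`, `method`.
#' @export
association_tests <- function(assign, clinical, horizon_months = 36) {
  stopifnot(inherits(assign, "cluster_assignment"))
  if (assign$k != 2) stop("association tests require exactly 2 clusters")
  cl <- assign$cluster
  if (min(table(cl)) < 2) stop("each cluster needs >= 2 patients")
  idx <- match(names(cl), clinical$patient_id)
  if (anyNA(idx)) stop("clustered patient(s) absent from clinical table")
  cln <- clinical[idx, , drop = FALSE]
  covs <- list(
    inss_stage4 = cln$inss_stage == "4",
    mycn_ampl = ifelse(is.na(cln$mycn) | cln$mycn == "NA", NA,
                       cln$mycn == "AMPL"),
    response_mr = ifelse(is.na(cln$induction_response), NA,
                         cln$induction_response == "MR"),
    efs_event = cln$efs_event == 1 & cln$efs_time <= horizon_months)
  rows <- lapply(names(covs), function(nm) {
    v <- covs[[nm]]
    ok <- !is.na(v)
    n1 <- sum(ok & cl == 1); n2 <- sum(ok & cl == 2)
    x1 <- sum(v[ok & cl == 1]); x2 <- sum(v[ok & cl == 2])
    tst <- two_proportion_test(x1, n1, x2, n2)
    data.frame(covariate = nm, prop_cluster1 = x1 / n1,
               prop_cluster2 = x2 / n2, z = tst$z, p = tst$p,
               method = tst$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Log-rank comparison of event-free survival between clusters
#'
#' Kaplan-Meier EFS curves per cluster, administratively censored at
#' `horizon_months` (default three years), compared with the standard
#' log-rank test (hypergeometric variance). Events are relapse, progression
#' or death.
#'
#' @param assign a `cluster_assignment`.
#' @param clinical a [clinical_table()].
#' @param horizon_months follow-up horizon in months.
#' @return object of class `survival_result`: `logrank_chisq`, `p`, `df`,
#'   `km` (a [survival::survfit] object), `table` (per-cluster n, events).
#' @export
logrank_efs <- function(assign, clinical, horizon_months = 36) {
  stopifnot(inherits(assign, "cluster_assignment"))
  cl <- assign$cluster
  idx <- match(names(cl), clinical$patient_id)
  if (anyNA(idx)) stop("clustered patient(s) absent from clinical table")
  time <- pmin(clinical$efs_time[idx], horizon_months)
  event <- as.integer(clinical$efs_event[idx] == 1 &
                        clinical$efs_time[idx] <= horizon_months)
  if (any(tapply(event, cl, sum) == 0 & tapply(time, cl, max) == 0))
    stop("a cluster has zero events and zero follow-up")
  df <- data.frame(time = time, event = event, cluster = factor(cl))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ cluster, data = df)
  p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  km <- survival::survfit(survival::Surv(time, event) ~ cluster, data = df)
  structure(list(logrank_chisq = unname(sd_$chisq), p = p,
                 df = length(sd_$n) - 1, km = km,
                 table = data.frame(cluster = sub("cluster=", "", names(sd_$n)),
                                    n = as.vector(sd_$n),
                                    events = as.vector(sd_$obs))),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("log-rank chisq = %.3f (df %d), p = %.4g\n",
              x$logrank_chisq, x$df, x$p))
  print(x$table, row.names = FALSE)
  invisible(x)
}
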