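#' Principal component analysis of a normalized matrix
#'
#' Projects samples onto the principal components of the column-centered
#' delta-CT matrix. The matrix must be complete (run [impute_missing()]
#' first).
#'
#' @param norm a complete `normalized_matrix`.
#' @return list with `scores` (samples x PCs), `eigenvalues` (nonincreasing)
#'   and `center` (per-miRNA means).
#' @export
run_pca <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (anyNA(norm$delta_ct))
    stop("matrix contains missing values; run impute_missing() first")
  x <- t(norm$delta_ct)                 # samples x miRNAs
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(scores = pc$x, eigenvalues = pc$sdev^2, center = pc$center)
}

# Per-sample factor data frame for the variance-component fits. Clinical
# covariates are patient-level; both samples of a patient share them. Numeric
# covariates (age) are binned into tertiles; missing levels become an explicit
# "NA" stratum so no sample is dropped.
pvca_factor_frame <- function(norm, clinical, factors) {
  info <- sample_info(norm)
  idx <- match(info$patient_id, clinical$patient_id)
  if (anyNA(idx))
    stop("sample patient(s) absent from clinical table: ",
         paste(unique(info$patient_id[is.na(idx)]), collapse = ", "))
  out <- info["sample_id"]
  for (f in factors) {
    if (!f %in% names(clinical)) stop("factor not in clinical table: ", f)
    v <- clinical[[f]][idx]
    if (is.numeric(v)) {
      br <- unique(stats::quantile(v, c(0, 1 / 3, 2 / 3, 1), na.rm = TRUE))
      v <- if (length(br) > 1) cut(v, br, include.lowest = TRUE) else rep("all", length(v))
    }
    v <- as.character(v)
    v[is.na(v)] <- "NA"
    out[[f]] <- factor(v)
  }
  out
}

# REML variance components for one PC score; independent random intercepts
# per factor (and eligible pairwise interactions). Returns proportions of
# variance (factors + residual). Falls back to a method-of-moments (one-way
# ANOVA) estimate when the mixed model cannot be fitted.
pvca_components_one_pc <- function(score, fct, terms) {
  df <- fct
  df$.score <- score
  form <- stats::as.formula(paste(".score ~",
    paste(sprintf("(1|`%s`)", terms), collapse = " + ")))
  res <- tryCatch({
    fit <- suppressWarnings(suppressMessages(lme4::lmer(
      form, data = df, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- stats::setNames(vc$vcov, vc$grp)
    comp <- pmax(v[terms], 0)
    names(comp) <- terms
    comp[is.na(comp)] <- 0
    c(comp, resid = unname(v["Residual"]))
  }, error = function(e) NULL)
  if (is.null(res)) {               # method-of-moments fallback, flagged
    comp <- vapply(terms, function(tm) {
      g <- fct[[tm]]
      a <- stats::anova(stats::lm(score ~ g))
      msb <- a[["Mean Sq"]][1]; msw <- a[["Mean Sq"]][2]
      n0 <- (length(score) - sum(table(g)^2) / length(score)) /
        (nlevels(droplevels(g)) - 1)
      max(0, (msb - msw) / n0)
    }, 0)
    res <- c(comp, resid = stats::var(score))
    attr(res, "mom") <- TRUE
  }
  res / sum(res)
}

#' Principal variance component analysis (PVCA)
#'
#' Quantifies how much of the expression variance is attributable to a batch
#' factor (center of origin) versus biological covariates. PCA scores of the
#' retained components are each decomposed by a mixed model with every factor
#' (and eligible pairwise interactions) as an independent random effect; the
#' per-PC variance proportions are then averaged with eigenvalue weights and
#' renormalized, giving one weighted average proportion variance (WAPV) per
#' factor plus a residual.
#'
#' Components are retained up to `pc_variance_target` cumulative variance. The
#' default 0.6 follows the published PVCA screening convention; to *estimate*
#' a total-variance fraction (rather than screen for structure) a high target
#' such as 0.9 is preferable, since truncation renormalizes away unstructured
#' variance and inflates structured proportions.
#'
#' @param norm a complete `normalized_matrix`.
#' @param clinical a [clinical_table()].
#' @param batch_factor clinical column treated as the batch variable.
#' @param bio_factors clinical columns treated as biological covariates;
#'   numeric ones (age) are binned into tertiles.
#' @param pc_variance_target cumulative variance fraction of retained PCs.
#' @param interactions include pairwise interactions of factors that both
#'   have >= 2 levels and whose crossing has >= 2 observed cells.
#' @return object of class `pvca_result`: `wapv` (named, sums to 1),
#'   `per_pc` (proportions per retained PC), `eigenvalues`, `n_components`,
#'   `retained_variance_fraction`, `batch_factor`, and `mom_pcs` (indices of
#'   PCs where the method-of-moments fallback was used).
#' @export
run_pvca <- function(norm, clinical, batch_factor = "origin",
                     bio_factors = c("age", "inss_stage", "mycn"),
                     pc_variance_target = 0.6, interactions = TRUE) {
  stopifnot(pc_variance_target > 0, pc_variance_target <= 1)
  bio_factors <- intersect(bio_factors, names(clinical))
  factors <- c(batch_factor, bio_factors)
  fct <- pvca_factor_frame(norm, clinical, factors)

  single <- factors[vapply(factors, function(f) nlevels(fct[[f]]) < 2, NA)]
  if (length(single))
    warning("factor(s) with a single level get a zero component: ",
            paste(single, collapse = ", "))
  active <- setdiff(factors, single)
  terms <- active
  if (interactions && length(active) > 1) {
    for (pair in utils::combn(active, 2, simplify = FALSE)) {
      cross <- interaction(fct[[pair[1]]], fct[[pair[2]]], drop = TRUE)
      if (nlevels(cross) >= 2) {
        nm <- paste(pair, collapse = ":")
        fct[[nm]] <- cross
        terms <- c(terms, nm)
      }
    }
  }
  if (!length(terms)) stop("no factor with >= 2 levels")

  pca <- run_pca(norm)
  ev <- pca$eigenvalues
  ev <- ev[ev > 1e-12 * sum(ev)]
  k <- which(cumsum(ev) / sum(pca$eigenvalues) >= pc_variance_target)[1]
  if (is.na(k)) k <- length(ev)
  k <- max(k, 1L)

  props <- matrix(0, k, length(terms) + 1,
                  dimnames = list(NULL, c(terms, "resid")))
  mom <- integer(0)
  for (i in seq_len(k)) {
    p <- pvca_components_one_pc(pca$scores[, i], fct, terms)
    if (isTRUE(attr(p, "mom"))) mom <- c(mom, i)
    props[i, names(p)] <- p
  }
  w <- ev[seq_len(k)] / sum(ev[seq_len(k)])
  wapv <- colSums(props * w)
  # zero-level factors appear with a fixed 0 component
  for (f in single) wapv[f] <- 0
  wapv <- wapv / sum(wapv)
  structure(list(wapv = wapv, per_pc = props, eigenvalues = pca$eigenvalues,
                 n_components = k,
                 retained_variance_fraction =
                   sum(ev[seq_len(k)]) / sum(pca$eigenvalues),
                 batch_factor = batch_factor, mom_pcs = mom),
            class = "pvca_result")
}

#' @export
print.pvca_result <- function(x, ...) {
  cat(sprintf("PVCA over %d PCs (%.1f%% of variance)\n", x$n_components,
              100 * x$retained_variance_fraction))
  print(round(sort(x$wapv, decreasing = TRUE), 4))
  invisible(x)
}

#' Classify the batch effect from a PVCA result
#'
#' The batch effect is negligible when the batch factor's WAPV is strictly
#' below `threshold` (default 5%); at or above the threshold it is
#' significant, and downstream differential analysis should not proceed
#' without an explicit override (this pipeline applies no batch correction).
#'
#' @param result a `pvca_result`.
#' @param threshold WAPV boundary (a proportion).
#' @return `"negligible"` or `"significant"`, with attribute `wapv`.
#' @export
assess_batch_effect <- function(result, threshold = 0.05) {
  stopifnot(inherits(result, "pvca_result"))
  w <- result$wapv[result$batch_factor]
  if (is.na(w)) stop("batch factor absent from PVCA result: ",
                     result$batch_factor)
  verdict <- if (w < threshold) "negligible" else "significant"
  structure(verdict, wapv = unname(w))
}
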