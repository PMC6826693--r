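#' Design matrix for response-signature selection
#'
#' One row per patient with both timepoints and a response label in `groups`;
#' features are the per-miRNA log2 fold changes (the longitudinal contrast is
#' what separates responders), standardized to zero mean and unit variance
#' with the scaling stored. Constant features are dropped with a warning.
#' Labels are binary: 1 for `groups[1]` (the poor-response class), 0 for
#' `groups[2]`.
#'
#' @param norm a complete `normalized_matrix`.
#' @param clinical a [clinical_table()].
#' @param groups two response levels to contrast, default `c("MR", "VGPR")`.
#' @return list with `x` (standardized patients x miRNAs matrix), `y`
#'   (named 0/1 vector), `center`, `scale`, `dropped` (constant features).
#' @export
build_design <- function(norm, clinical, groups = c("MR", "VGPR")) {
  stopifnot(length(groups) == 2)
  fc <- patient_fold_changes(norm)
  resp <- clinical$induction_response[match(rownames(fc), clinical$patient_id)]
  keep <- !is.na(resp) & resp %in% groups
  fc <- fc[keep, , drop = FALSE]
  resp <- resp[keep]
  n_per <- table(factor(resp, levels = groups))
  if (any(n_per < 2))
    stop("each group needs >= 2 patients with both timepoints; got ",
         paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", "))
  if (anyNA(fc)) stop("fold-change matrix incomplete; impute first")
  sds <- apply(fc, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature(s): ",
            paste(utils::head(colnames(fc)[const], 5), collapse = ", "))
    fc <- fc[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  ctr <- colMeans(fc)
  x <- scale(fc, center = ctr, scale = sds)
  y <- stats::setNames(as.integer(resp == groups[1]), rownames(fc))
  list(x = x, y = y, center = ctr, scale = sds,
       dropped = names(const)[const])
}

#' Elastic-net signature selection with leave-one-out cross-validation
#'
#' Fits elastic-net-penalized linear regressions (squared-error loss on the
#' 0/1 labels; penalty lambda * (mixing * L1 + (1 - mixing)/2 * L2)) over a
#' log-spaced penalty grid, choosing the penalty that minimizes the
#' leave-one-out cross-validated mean squared prediction error. Ties are
#' broken toward the larger (sparser) penalty. The model is then refit on all
#' data at the chosen penalty; features with nonzero coefficients form the
#' signature.
#'
#' @param x standardized feature matrix (patients x miRNAs).
#' @param y numeric 0/1 labels.
#' @param mixing elastic-net mixing parameter in (0, 1]; 1 = lasso.
#' @param penalty_grid optional decreasing penalty grid; by default 100
#'   log-spaced values from the smallest penalty that zeroes every
#'   coefficient down four orders of magnitude.
#' @param nlambda grid size when `penalty_grid` is `NULL`.
#' @return object of class `signature_result`: `selected_mirnas`,
#'   `coefficients` (named, nonzero only), `intercept`, `chosen_penalty`,
#'   `penalty_grid`, `loocv_mse_per_penalty`, `mixing`.
#' @export
fit_elastic_net_loocv <- function(x, y, mixing = 0.7, penalty_grid = NULL,
                                  nlambda = 100) {
  n <- nrow(x)
  stopifnot(n >= 4, length(y) == n, mixing > 0, mixing <= 1)
  if (length(unique(y)) < 2) stop("labels are all identical")
  if (!is.null(penalty_grid) && !length(penalty_grid))
    stop("empty penalty grid")
  if (is.null(penalty_grid)) {
    lmax <- max(abs(crossprod(x, y - mean(y)))) / (n * mixing)
    penalty_grid <- 10^seq(log10(lmax), log10(lmax) - 4, length.out = nlambda)
  }
  penalty_grid <- sort(penalty_grid, decreasing = TRUE)

  sqerr <- matrix(NA_real_, n, length(penalty_grid))
  for (i in seq_len(n)) {
    fit <- glmnet::glmnet(x[-i, , drop = FALSE], y[-i], family = "gaussian",
                          alpha = mixing, lambda = penalty_grid,
                          standardize = FALSE, thresh = 1e-10)
    pred <- stats::predict(fit, newx = x[i, , drop = FALSE],
                           s = penalty_grid, exact = FALSE)
    sqerr[i, ] <- (y[i] - as.numeric(pred))^2
  }
  mse <- colMeans(sqerr)
  # ties toward the larger penalty: grid is decreasing, take the first
  chosen <- which(mse <= min(mse) + 1e-12)[1]
  lam <- penalty_grid[chosen]

  full <- glmnet::glmnet(x, y, family = "gaussian", alpha = mixing,
                         lambda = penalty_grid, standardize = FALSE,
                         thresh = 1e-10)
  beta <- as.numeric(stats::coef(full, s = lam))
  names(beta) <- c("(Intercept)", colnames(x))
  nz <- beta[-1][beta[-1] != 0]
  structure(list(selected_mirnas = names(nz), coefficients = nz,
                 intercept = unname(beta[1]), chosen_penalty = lam,
                 penalty_grid = penalty_grid, loocv_mse_per_penalty = mse,
                 mixing = mixing),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("elastic net (mixing %.2f): penalty %.4g, %d miRNA(s) selected\n",
              x$mixing, x$chosen_penalty, length(x$selected_mirnas)))
  if (length(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

#' Assess how well a signature separates two patient groups
#'
#' Restricts the per-patient fold-change matrix to the signature miRNAs,
#' projects patients onto its principal components, and reports per-group
#' means on PC1 together with a standardized separation statistic
#' (|difference of group means| / pooled SD on PC1), per-miRNA group medians,
#' and per-miRNA Mann-Whitney (Wilcoxon rank-sum) p values between the
#' groups. The same Mann-Whitney machinery serves to test each signature
#' miRNA against event-free-survival groups.
#'
#' @param norm a complete `normalized_matrix`.
#' @param clinical a [clinical_table()].
#' @param signature character vector of miRNA names (matched via
#'   [canonical_mirna()]).
#' @param groups two response levels, or a named list mapping
#'   `"event"`/`"event_free"` if `by = "efs"`.
#' @param by `"response"` (INRC classes) or `"efs"` (event within horizon vs.
#'   event-free).
#' @param horizon_months EFS horizon when `by = "efs"`.
#' @return list with `scores` (patients x PCs), `group` (factor),
#'   `separation`, `group_means_pc1`, `medians` (miRNAs x groups),
#'   `mann_whitney_p` (per miRNA).
#' @export
evaluate_signature_separation <- function(norm, clinical, signature,
                                          groups = c("MR", "VGPR"),
                                          by = c("response", "efs"),
                                          horizon_months = 36) {
  by <- match.arg(by)
  stopifnot(length(signature) >= 1)
  fc <- patient_fold_changes(norm)
  hit <- match(canonical_mirna(signature), canonical_mirna(colnames(fc)))
  if (anyNA(hit))
    stop("signature miRNA(s) absent from matrix: ",
         paste(signature[is.na(hit)], collapse = ", "))
  fc <- fc[, hit, drop = FALSE]
  colnames(fc) <- signature
  idx <- match(rownames(fc), clinical$patient_id)
  grp <- if (by == "response") {
    g <- clinical$induction_response[idx]
    g[!g %in% groups] <- NA
    factor(g, levels = groups)
  } else {
    ev <- clinical$efs_event[idx] == 1 & clinical$efs_time[idx] <= horizon_months
    factor(ifelse(ev, "event", "event_free"), levels = c("event", "event_free"))
  }
  keep <- !is.na(grp) & !apply(fc, 1, anyNA)
  fc <- fc[keep, , drop = FALSE]
  grp <- droplevels(grp[keep])
  if (nlevels(grp) < 2) stop("need two non-empty groups")

  pc <- stats::prcomp(fc, center = TRUE, scale. = FALSE)
  s1 <- pc$x[, 1]
  mu <- tapply(s1, grp, mean)
  sp <- sqrt(mean(tapply(s1, grp, stats::var), na.rm = TRUE))
  sep <- if (is.na(sp) || sp == 0) 0 else abs(diff(mu)) / sp
  med <- apply(fc, 2, function(v) tapply(v, grp, stats::median))
  mw <- apply(fc, 2, function(v)
    tryCatch(suppressWarnings(
      stats::wilcox.test(v ~ grp)$p.value), error = function(e) NA_real_))
  list(scores = pc$x, group = grp, separation = unname(sep),
       group_means_pc1 = mu, medians = t(med), mann_whitney_p = mw)
}
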