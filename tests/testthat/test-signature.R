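# Two-timepoint matrix with per-patient planted fold changes.
design_cohort <- function(fc_by_patient, seed = 1) {
  # fc_by_patient: patients x miRNAs planted log2 FCs (end minus onset = -FC)
  set.seed(seed)
  pats <- rownames(fc_by_patient)
  n_mir <- ncol(fc_by_patient)
  onset <- matrix(rnorm(n_mir * length(pats), 0, 0.1), n_mir, length(pats),
                  dimnames = list(colnames(fc_by_patient),
                                  paste0(pats, ":onset")))
  end <- onset - t(fc_by_patient)
  colnames(end) <- paste0(pats, ":end")
  make_norm(cbind(onset, end))
}

test_that("design matrix keeps the contrasted groups, standardized", {
  pats <- sprintf("P%02d", 1:20)
  fc <- matrix(rnorm(20 * 6), 20, 6,
               dimnames = list(pats, sprintf("m%d", 1:6)))
  fc[, 6] <- 0                          # constant feature
  norm <- design_cohort(fc)
  cl <- make_clinical(pats, induction_response =
                        c(rep("MR", 6), rep("VGPR", 8), rep("PR", 4),
                          NA, NA))
  expect_warning(des <- build_design(norm, cl), "constant")
  expect_equal(nrow(des$x), 14L)        # 6 MR + 8 VGPR, PR/NA excluded
  expect_equal(sum(des$y), 6L)
  expect_equal(unname(colMeans(des$x)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(des$x, 2, sd)), rep(1, 5), tolerance = 1e-12)

  too_few <- make_clinical(pats, induction_response =
                             c("MR", rep("VGPR", 8), rep("PR", 11)))
  expect_error(suppressWarnings(build_design(norm, too_few)), ">= 2 patients")
})

test_that("LOOCV elastic net honors definitional and limiting behavior", {
  set.seed(13)
  n <- 14; p <- 30
  y <- c(rep(1, 6), rep(0, 8))
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  x[, 1:2] <- x[, 1:2] + outer(ifelse(y == 1, 2, -2), c(1, 1))
  fit <- fit_elastic_net_loocv(scale(x), y, mixing = 0.7)
  # chosen penalty attains the LOOCV minimum
  expect_equal(fit$loocv_mse_per_penalty[match(fit$chosen_penalty,
                                               fit$penalty_grid)],
               min(fit$loocv_mse_per_penalty), tolerance = 1e-12)
  expect_true(all(c("f01", "f02") %in% fit$selected_mirnas))

  # infinite penalty selects nothing
  huge <- fit_elastic_net_loocv(scale(x), y, mixing = 0.7,
                                penalty_grid = c(1e6, 1e5))
  expect_length(huge$selected_mirnas, 0)

  expect_error(fit_elastic_net_loocv(scale(x), rep(1, n), mixing = 0.7),
               "identical")
  expect_error(fit_elastic_net_loocv(scale(x), y, penalty_grid = numeric(0)),
               "empty")
})

test_that("vanishing penalty reproduces least squares on orthonormal designs", {
  set.seed(17)
  n <- 12; p <- 4
  raw <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  x <- qr.Q(qr(raw))                    # centered orthonormal columns
  colnames(x) <- sprintf("f%d", 1:p)
  y <- as.numeric(x %*% c(1, -2, 0.5, 0) + rnorm(n, 0, 0.05))
  fit <- glmnet::glmnet(x, y, alpha = 0.7, lambda = 1e-9,
                        standardize = FALSE, thresh = 1e-14)
  ols <- coef(lm(y ~ x))
  expect_equal(as.numeric(coef(fit))[-1], unname(ols[-1]), tolerance = 1e-6)

  # lasso route: soft-thresholding oracle at n*lambda
  lam <- 0.02
  fit1 <- glmnet::glmnet(x, y, alpha = 1, lambda = lam,
                         standardize = FALSE, thresh = 1e-14)
  oracle <- soft_threshold(crossprod(x, y - mean(y)), n * lam)
  expect_equal(as.numeric(coef(fit1))[-1], as.numeric(oracle),
               tolerance = 1e-6)

  # near-zero mixing approaches the ridge solution; the solver applies its
  # quadratic penalty per unit response sd, so the closed form uses lam/sd(y)
  fit0 <- glmnet::glmnet(x, y, alpha = 1e-4, lambda = lam,
                         standardize = FALSE, thresh = 1e-14)
  sy <- sqrt(mean((y - mean(y))^2))
  ridge <- solve(crossprod(x) + diag(n * lam * (1 - 1e-4) / sy, p),
                 crossprod(x, y - mean(y)))
  expect_equal(as.numeric(coef(fit0))[-1], as.numeric(ridge),
               tolerance = 1e-3)
})

test_that("selection is invariant to per-miRNA affine rescaling of inputs", {
  set.seed(19)
  pats <- sprintf("P%02d", 1:14)
  fc <- matrix(rnorm(14 * 20), 14, 20,
               dimnames = list(pats, sprintf("m%02d", 1:20)))
  fc[, 1] <- fc[, 1] + c(rep(3, 6), rep(-3, 8))
  norm <- design_cohort(fc)
  cl <- make_clinical(pats, induction_response =
                        c(rep("MR", 6), rep("VGPR", 8)))
  d1 <- build_design(norm, cl)
  # rescale one assay by an affine map before normalization of features
  fc2 <- fc
  fc2[, 1] <- 10 * fc[, 1] + 4
  d2 <- build_design(design_cohort(fc2), cl)
  f1 <- fit_elastic_net_loocv(d1$x, d1$y, mixing = 0.7)
  f2 <- fit_elastic_net_loocv(d2$x, d2$y, mixing = 0.7)
  expect_setequal(f1$selected_mirnas, f2$selected_mirnas)
})

test_that("signature separation reports planted group medians", {
  pats <- sprintf("P%02d", 1:14)
  grp <- c(rep("MR", 6), rep("VGPR", 8))
  fc <- matrix(0, 14, 3, dimnames = list(pats, c("hsa-miR-29c",
                                                 "hsa-let-7b", "noise")))
  fc[, "hsa-miR-29c"] <- ifelse(grp == "MR", -6.52, -1.57)
  fc[, "hsa-let-7b"] <- ifelse(grp == "MR", -3.31, 0.005)
  norm <- design_cohort(fc, seed = 23)
  cl <- make_clinical(pats, induction_response = grp)
  sep <- evaluate_signature_separation(norm, cl,
                                       c("hsa-miR-29c", "hsa-let-7b"))
  expect_equal(sep$medians["hsa-miR-29c", "MR"], -6.52, tolerance = 0.15)
  expect_equal(sep$medians["hsa-miR-29c", "VGPR"], -1.57, tolerance = 0.15)
  expect_equal(sep$medians["hsa-let-7b", "MR"], -3.31, tolerance = 0.15)
  expect_gt(sep$separation, 2)
  expect_true(all(sep$mann_whitney_p < 0.05))

  # identical groups: separation collapses
  same <- matrix(rnorm(14 * 2, 0, 1), 14, 2,
                 dimnames = list(pats, c("a", "b")))
  sep0 <- evaluate_signature_separation(design_cohort(same, seed = 29), cl,
                                        c("a", "b"))
  expect_lt(sep0$separation, 1.5)

  # EFS grouping mode is available for the same machinery
  cl2 <- make_clinical(pats, induction_response = grp,
                       efs_time = rep(c(10, 40), 7),
                       efs_event = rep(c(1, 0), 7))
  sep_efs <- evaluate_signature_separation(norm, cl2, c("hsa-miR-29c"),
                                           by = "efs")
  expect_true(is.finite(sep_efs$mann_whitney_p[1]))
})
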