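# Small in-code fixtures and independent oracles shared across tests.

# CT matrix from a named list of per-sample CT vectors.
make_ct <- function(..., mirnas = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  rownames(m) <- if (is.null(mirnas)) sprintf("miR-%02d", seq_len(nrow(m))) else mirnas
  ct_matrix(m)
}

# normalized_matrix straight from a delta-CT matrix (detected = non-missing).
make_norm <- function(delta, detected = !is.na(delta)) {
  exopipe:::new_normalized_matrix(delta, detected)
}

# Minimal clinical table; defaults give valid columns for n patients.
make_clinical <- function(patient_id,
                          inss_stage = rep("4", length(patient_id)),
                          mycn = rep("NO AMPL", length(patient_id)),
                          induction_response = rep("PR", length(patient_id)),
                          efs_time = rep(36, length(patient_id)),
                          efs_event = rep(0, length(patient_id)),
                          origin = rep("ITA", length(patient_id)),
                          age = NULL) {
  df <- data.frame(patient_id = patient_id, inss_stage = inss_stage,
                   mycn = mycn, induction_response = induction_response,
                   relapse = ifelse(efs_event == 1, "yes", "no"),
                   efs_time = efs_time, efs_event = efs_event,
                   origin = origin, stringsAsFactors = FALSE)
  if (!is.null(age)) df$age <- age
  clinical_table(df)
}

chemo_fixture <- function() read_chemoresistance_list(packaged_chemoresistance_path())

# --- independent oracles -------------------------------------------------

# Benjamini-Hochberg step-up from its definition (independent of p.adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, m * p[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Log-rank chi-square by summing observed-minus-expected over event times.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2)
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Sign-flip permutation p value for a paired t statistic.
signflip_p <- function(diffs, B = 20000) {
  tstat <- function(d) mean(d) / (sd(d) / sqrt(length(d)))
  t0 <- abs(tstat(diffs))
  hits <- sum(replicate(B, {
    s <- sample(c(-1, 1), length(diffs), replace = TRUE)
    abs(tstat(s * diffs)) >= t0
  }))
  (hits + 1) / (B + 1)
}

# Lasso on centered orthonormal columns: soft thresholding of x_j'y at n*lambda.
soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
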