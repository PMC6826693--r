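#' Simulation configuration for a two-timepoint exo-miRNA cohort
#'
#' Defines a synthetic cohort with the statistical structure every pipeline
#' stage assumes: per-miRNA normal CT baselines spanning the reliable window,
#' per-patient and per-sample additive technical offsets (removed by
#' global-mean normalization), per-center-by-miRNA batch shifts, a global
#' end-of-induction CT increase (driving the drop in detected assays),
#' response-signature effects planted in minor-response (MR) patients, a
#' latent chemoresistance status modulating the platinum/anthracycline-listed
#' miRNAs concordantly, detection censoring at the CT ceiling, and
#' exponential event-free-survival (EFS) times whose hazard is multiplied for
#' latent-resistant patients.
#'
#' Defaults emulate the study conditions: 52 patients sampled at onset and
#' end of induction (104 samples), 381 assays, measurement noise 0.5 CT,
#' patient intercept 0.5 CT, sample offset 1 CT, near-negligible batch shifts
#' (sd 0.05 CT per center x miRNA), response mix 6/33/8/5
#' (MR/PR/VGPR/unknown), MR signature effects equal to the reported MR median
#' fold changes (miR-29c 6.52, miR-342-3p 2.83, let-7b 3.31 CT units), a 50%
#' prevalence of latent resistance shifting the listed miRNAs by 1 CT, EFS
#' base hazard 0.012/month with hazard ratio 3 for resistant patients
#' (about a 50% three-year event rate overall) and censoring hazard
#' 0.003/month.
#'
#' @param n_patients number of patients (two samples each).
#' @param n_mirnas number of assays on the card.
#' @param mirna_names assay names; defaults to the packaged chemoresistance
#'   list plus the signature miRNAs, padded with `sim-miR-*` fillers.
#' @param baseline_ct_range per-miRNA baseline means drawn uniformly from
#'   this CT range.
#' @param noise_sd per-well measurement noise (CT).
#' @param patient_sd patient random intercept (CT), shared by both samples.
#' @param sample_offset_sd per-sample technical offset (CT); what
#'   normalization must remove.
#' @param detection_ceiling CT above which wells are censored to missing.
#' @param failure_rate probability of a random well failure (missing).
#' @param global_downregulation_shift CT added to every end-timepoint well.
#' @param batch_levels,batch_probs center labels and sampling probabilities.
#' @param batch_sd sd of the per-center-by-miRNA additive shift (CT).
#' @param response_probs named probabilities for MR/PR/VGPR/NA.
#' @param signature_mirnas,signature_effect miRNAs and end-timepoint CT
#'   increases planted only in MR patients.
#' @param resistance_drugs drugs whose listed miRNAs the latent-resistant
#'   subgroup modulates concordantly.
#' @param resistance_prevalence probability a patient is latent-resistant.
#' @param resistance_exact if `TRUE`, exactly `round(n_patients *
#'   resistance_prevalence)` patients are resistant (a randomly chosen
#'   subset), giving fixed group sizes for power studies.
#' @param resistance_effect CT shift magnitude of the concordant modulation.
#' @param efs_base_hazard baseline EFS event hazard per month.
#' @param hazard_ratio_resistant multiplicative hazard for resistant patients.
#' @param censoring_rate independent right-censoring hazard per month.
#' @param cor_rank,cor_sd optional low-rank miRNA-miRNA correlation term
#'   (`cor_rank` latent factors with loading sd `cor_sd`); off by default.
#' @param seed mandatory RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 52, n_mirnas = 381, mirna_names = NULL,
                       baseline_ct_range = c(18, 30),
                       noise_sd = 0.5, patient_sd = 0.5, sample_offset_sd = 1,
                       detection_ceiling = 32, failure_rate = 0.01,
                       global_downregulation_shift = 1,
                       batch_levels = c("ITA", "ESP", "GBR", "FRA"),
                       batch_probs = c(0.7, 0.1, 0.1, 0.1),
                       batch_sd = 0.05,
                       response_probs = c(MR = 6, PR = 33, VGPR = 8,
                                          "NA" = 5) / 52,
                       signature_mirnas = c("hsa-miR-29c", "hsa-miR-342-3p",
                                            "hsa-let-7b"),
                       signature_effect = c(6.52, 2.83, 3.31),
                       resistance_drugs = c("carboplatin", "cisplatin",
                                            "doxorubicin"),
                       resistance_prevalence = 0.5,
                       resistance_exact = FALSE,
                       resistance_effect = 1,
                       efs_base_hazard = 0.012,
                       hazard_ratio_resistant = 3,
                       censoring_rate = 0.003,
                       cor_rank = 0, cor_sd = 0,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(n_patients >= 2, n_mirnas >= 2,
            noise_sd >= 0, patient_sd >= 0, sample_offset_sd >= 0,
            batch_sd >= 0, failure_rate >= 0, failure_rate < 1,
            length(batch_levels) == length(batch_probs),
            length(signature_mirnas) == length(signature_effect),
            resistance_prevalence >= 0, resistance_prevalence <= 1,
            efs_base_hazard > 0, hazard_ratio_resistant > 0,
            censoring_rate >= 0, cor_rank >= 0, cor_sd >= 0)
  if (abs(sum(response_probs) - 1) > 1e-8)
    stop("response_probs must sum to 1")
  if (abs(sum(batch_probs) - 1) > 1e-8)
    stop("batch_probs must sum to 1")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

default_mirna_names <- function(cfg) {
  base <- unique(c(packaged_chemoresistance_list()$mirna, cfg$signature_mirnas))
  n_fill <- cfg$n_mirnas - length(base)
  if (n_fill < 0) return(base[seq_len(cfg$n_mirnas)])
  c(base, sprintf("sim-miR-%03d", seq_len(n_fill)))
}

packaged_chemoresistance_list <- function() {
  read_chemoresistance_list(system.file("extdata", "chemoresistance_mirnas.tsv",
                                        package = "exopipe", mustWork = TRUE))
}

# Net resistance direction per miRNA over the drugs in `drugs`: +1 when the
# listed entries are predominantly "up", -1 when "down", 0 on a tie.
resistance_net_direction <- function(chemo_list, drugs) {
  sub <- chemo_list[chemo_list$drug %in% drugs, , drop = FALSE]
  sgn <- ifelse(sub$direction == "up", 1L, -1L)
  net <- tapply(sgn, canonical_mirna(sub$mirna), sum)
  sign(net)
}

#' Simulate a two-timepoint exosomal-miRNA cohort
#'
#' Draws raw CT values, clinical annotations and EFS outcomes under the
#' generative model of [sim_config()], and returns the planted ground truth
#' alongside. The same seed always reproduces the identical cohort.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort`: `ct` (a [ct_matrix()]),
#'   `clinical` (a [clinical_table()]), `truth` (latent labels and planted
#'   effects), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  mirnas <- if (is.null(cfg$mirna_names)) default_mirna_names(cfg) else cfg$mirna_names
  stopifnot(length(mirnas) == cfg$n_mirnas)
  pats <- sprintf("P%03d", seq_len(cfg$n_patients))

  origin <- sample(cfg$batch_levels, cfg$n_patients, TRUE, cfg$batch_probs)
  response <- sample(names(cfg$response_probs), cfg$n_patients, TRUE,
                     cfg$response_probs)
  response[response == "NA"] <- NA
  inss <- sample(c("4", "3", "4S"), cfg$n_patients, TRUE, c(47, 4, 1) / 52)
  mycn <- sample(c("AMPL", "NO AMPL", "NA"), cfg$n_patients, TRUE,
                 c(22, 25, 5) / 52)
  age <- round(stats::runif(cfg$n_patients, 6, 60))
  resistant <- if (isTRUE(cfg$resistance_exact)) {
    n_res <- round(cfg$n_patients * cfg$resistance_prevalence)
    seq_len(cfg$n_patients) %in% sample(cfg$n_patients, n_res)
  } else {
    stats::rbinom(cfg$n_patients, 1, cfg$resistance_prevalence) == 1
  }

  baseline <- stats::runif(cfg$n_mirnas, cfg$baseline_ct_range[1],
                           cfg$baseline_ct_range[2])
  batch_shift <- matrix(stats::rnorm(length(cfg$batch_levels) * cfg$n_mirnas,
                                     0, cfg$batch_sd),
                        length(cfg$batch_levels), cfg$n_mirnas,
                        dimnames = list(cfg$batch_levels, mirnas))
  loadings <- if (cfg$cor_rank > 0)
    matrix(stats::rnorm(cfg$n_mirnas * cfg$cor_rank, 0, cfg$cor_sd),
           cfg$n_mirnas, cfg$cor_rank) else NULL

  key <- canonical_mirna(mirnas)
  sig_idx <- match(canonical_mirna(cfg$signature_mirnas), key)
  sig_eff <- stats::setNames(cfg$signature_effect, cfg$signature_mirnas)
  net <- resistance_net_direction(packaged_chemoresistance_list(),
                                  cfg$resistance_drugs)
  res_delta <- numeric(cfg$n_mirnas)           # CT shift at end if resistant
  hit <- match(names(net), key)
  # upregulation in resistance = lower CT at end
  res_delta[hit[!is.na(hit)]] <- -as.numeric(net[!is.na(hit)]) *
    cfg$resistance_effect

  pat_int <- stats::rnorm(cfg$n_patients, 0, cfg$patient_sd)
  samples <- c(paste0(pats, ":onset"), paste0(pats, ":end"))
  tp_end <- rep(c(FALSE, TRUE), each = cfg$n_patients)
  pat_of_sample <- rep(seq_len(cfg$n_patients), 2)

  ct <- matrix(NA_real_, cfg$n_mirnas, length(samples),
               dimnames = list(mirnas, samples))
  for (s in seq_along(samples)) {
    p <- pat_of_sample[s]
    mu <- baseline + pat_int[p] + stats::rnorm(1, 0, cfg$sample_offset_sd) +
      batch_shift[origin[p], ]
    if (tp_end[s]) {
      mu <- mu + cfg$global_downregulation_shift
      if (!is.na(response[p]) && response[p] == "MR" && any(!is.na(sig_idx)))
        mu[sig_idx[!is.na(sig_idx)]] <- mu[sig_idx[!is.na(sig_idx)]] +
          sig_eff[!is.na(sig_idx)]
      if (resistant[p]) mu <- mu + res_delta
    }
    well <- mu + stats::rnorm(cfg$n_mirnas, 0, cfg$noise_sd)
    if (!is.null(loadings))
      well <- well + as.numeric(loadings %*% stats::rnorm(cfg$cor_rank))
    well[well > cfg$detection_ceiling] <- NA       # censored above ceiling
    if (cfg$failure_rate > 0)
      well[stats::runif(cfg$n_mirnas) < cfg$failure_rate] <- NA
    ct[, s] <- well
  }

  haz <- cfg$efs_base_hazard *
    ifelse(resistant, cfg$hazard_ratio_resistant, 1)
  t_event <- stats::rexp(cfg$n_patients, haz)
  t_cens <- if (cfg$censoring_rate > 0)
    stats::rexp(cfg$n_patients, cfg$censoring_rate) else rep(Inf, cfg$n_patients)
  efs_time <- round(pmin(t_event, t_cens), 2)
  efs_event <- as.integer(t_event <= t_cens)

  clinical <- clinical_table(data.frame(
    patient_id = pats, inss_stage = inss, mycn = mycn,
    induction_response = response,
    relapse = ifelse(efs_event == 1, "yes", "no"),
    efs_time = efs_time, efs_event = efs_event,
    origin = origin, age = age, stringsAsFactors = FALSE))

  truth <- list(
    resistant = stats::setNames(resistant, pats),
    response = stats::setNames(response, pats),
    signature_mirnas = cfg$signature_mirnas,
    signature_effect = sig_eff,
    resistance_delta_ct = stats::setNames(res_delta, mirnas),
    batch_variance = cfg$batch_sd^2,
    noise_variance = cfg$noise_sd^2,
    injected_batch_fraction =
      cfg$batch_sd^2 / (cfg$batch_sd^2 + cfg$noise_sd^2),
    hazard = stats::setNames(haz, pats))

  structure(list(ct = ct_matrix(ct), clinical = clinical, truth = truth,
                 config = cfg),
            class = "synthetic_cohort")
}

#' Ground-truth tables of a synthetic cohort
#'
#' Emits the latent labels and planted effect sizes that recovery tests
#' compare against.
#'
#' @param cohort a `synthetic_cohort`.
#' @return list with `patients` (data.frame of latent labels and hazards),
#'   `signature` (data.frame of planted signature effects),
#'   `resistance` (data.frame of per-miRNA planted CT shifts), and
#'   `injected_batch_fraction`.
#' @export
planted_truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tr <- cohort$truth
  list(
    patients = data.frame(patient_id = names(tr$resistant),
                          resistant = unname(tr$resistant),
                          response = unname(tr$response),
                          hazard = unname(tr$hazard),
                          stringsAsFactors = FALSE),
    signature = data.frame(mirna = names(tr$signature_effect),
                           end_ct_shift_mr = unname(tr$signature_effect),
                           stringsAsFactors = FALSE),
    resistance = data.frame(
      mirna = names(tr$resistance_delta_ct),
      end_ct_shift_resistant = unname(tr$resistance_delta_ct),
      stringsAsFactors = FALSE)[tr$resistance_delta_ct != 0, ],
    injected_batch_fraction = tr$injected_batch_fraction)
}
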