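#' Validate a clinical annotation table
#'
#' One row per patient with staging, biology, response and event-free-survival
#' (EFS) outcome. Expected columns: `patient_id`, `inss_stage` (3, 4 or 4S),
#' `mycn` (`AMPL`, `NO AMPL` or `NA`), `induction_response` (`MR`, `PR`,
#' `VGPR` or `NA`), `relapse` (`yes`/`no`), `efs_time` (months), `efs_event`
#' (0/1; relapse, progression or death), `origin` (center/country label) and
#' optionally `age` (months).
#'
#' @param df data.frame of clinical annotations.
#' @return the validated data.frame, with class `clinical_table` prepended.
#' @export
clinical_table <- function(df) {
  need <- c("patient_id", "inss_stage", "mycn", "induction_response",
            "relapse", "efs_time", "efs_event", "origin")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  df$inss_stage <- as.character(df$inss_stage)
  bad <- !df$inss_stage %in% c("3", "4", "4S")
  if (any(bad)) stop("inss_stage must be one of 3, 4, 4S")
  df$induction_response <- as.character(df$induction_response)
  bad <- !(df$induction_response %in% c("MR", "PR", "VGPR") |
             is.na(df$induction_response))
  if (any(bad)) stop("induction_response must be MR, PR, VGPR or NA")
  if (any(!is.finite(df$efs_time)) || any(df$efs_time < 0))
    stop("efs_time must be nonnegative and finite")
  if (any(!df$efs_event %in% c(0, 1)))
    stop("efs_event must be 0 or 1")
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' Read a clinical table from TSV
#'
#' @param path path to a UTF-8 TSV with the columns listed in
#'   [clinical_table()].
#' @return a validated `clinical_table`.
#' @export
read_clinical <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  clinical_table(df)
}

#' Write a clinical table as TSV
#'
#' @param df a `clinical_table`.
#' @param path output path.
#' @export
write_clinical <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
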