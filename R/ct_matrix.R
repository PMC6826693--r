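#' CT matrix of raw threshold-cycle values
#'
#' A `ct_matrix` stores raw RT-qPCR threshold cycles (CT) for a two-timepoint
#' cohort: one column per sample, one row per miRNA assay. Sample identifiers
#' follow the convention `"<patient_id>:<timepoint>"` with timepoint either
#' `"onset"` or `"end"` (before vs. end of induction chemotherapy). Failed or
#' undetermined wells are stored as `NA`.
#'
#' @param ct numeric matrix, rows = miRNA assays, columns = samples. Row names
#'   are assay names (e.g. `"hsa-miR-376a"`); column names are sample ids.
#' @return An object of class `ct_matrix` (a validated numeric matrix).
#' @export
ct_matrix <- function(ct) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (miRNAs x samples)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have miRNA row names and sample column names")
  validate_ct_matrix(structure(ct, class = c("ct_matrix", "matrix")))
}

validate_ct_matrix <- function(x) {
  ids <- colnames(x)
  if (anyDuplicated(ids))
    stop("duplicate sample identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(rownames(x)))
    stop("duplicate miRNA assay names: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  info <- parse_sample_ids(ids)
  bad <- !info$timepoint %in% c("onset", "end")
  if (any(bad))
    stop("unknown timepoint label in sample id(s): ",
         paste(ids[bad], collapse = ", "),
         " (expected \"<patient>:onset\" or \"<patient>:end\")")
  v <- x[is.finite(x)]
  if (any(x[!is.na(x)] == Inf | x[!is.na(x)] == -Inf) || any(v <= 0))
    stop("present CT values must be finite and positive")
  x
}

parse_sample_ids <- function(ids) {
  parts <- regmatches(ids, regexpr(":", ids), invert = TRUE)
  ok <- lengths(parts) == 2
  if (!all(ok))
    stop("sample id(s) not of the form \"<patient>:<timepoint>\": ",
         paste(ids[!ok], collapse = ", "))
  data.frame(sample_id = ids,
             patient_id = vapply(parts, `[`, "", 1),
             timepoint = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Sample annotation of a CT or normalized matrix
#'
#' @param x a `ct_matrix` or `normalized_matrix`.
#' @return data.frame with columns `sample_id`, `patient_id`, `timepoint`.
#' @export
sample_info <- function(x) {
  ids <- if (inherits(x, "normalized_matrix")) colnames(x$delta_ct) else colnames(x)
  parse_sample_ids(ids)
}

#' @export
print.ct_matrix <- function(x, ...) {
  info <- sample_info(x)
  cat(sprintf("ct_matrix: %d miRNAs x %d samples (%d onset, %d end), %d missing wells\n",
              nrow(x), ncol(x), sum(info$timepoint == "onset"),
              sum(info$timepoint == "end"), sum(is.na(x))))
  invisible(x)
}

# Both "NA" and "Undetermined" mark failed wells in instrument exports.
.na_strings <- c("NA", "Undetermined", "undetermined", "")

#' Read a CT matrix from a tab-separated file
#'
#' Two dialects are supported. `wide`: first column holds miRNA assay names,
#' remaining columns are samples named `"<patient>:<timepoint>"`. `long`: one
#' row per well, with columns `sample` (patient id), `mirna`, `timepoint`, and
#' `ct`. `"Undetermined"` and `"NA"` cells are parsed as missing.
#'
#' @param path path to a UTF-8 TSV file.
#' @param layout `"wide"` or `"long"`.
#' @return a [ct_matrix()].
#' @export
read_ct_matrix <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, check.names = FALSE, na.strings = .na_strings,
                          stringsAsFactors = FALSE)
  if (layout == "wide") {
    mirnas <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- mirnas
    if (anyDuplicated(mirnas))
      stop("duplicate (sample, miRNA) entries for miRNA(s): ",
           paste(unique(mirnas[duplicated(mirnas)]), collapse = ", "))
    return(ct_matrix(m))
  }
  need <- c("sample", "mirna", "timepoint", "ct")
  if (!all(need %in% names(df)))
    stop("long layout requires columns: ", paste(need, collapse = ", "))
  bad_tp <- !df$timepoint %in% c("onset", "end")
  if (any(bad_tp))
    stop("unknown timepoint label: ",
         paste(unique(df$timepoint[bad_tp]), collapse = ", "))
  sid <- paste0(df$sample, ":", df$timepoint)
  key <- paste(sid, df$mirna, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (sample, miRNA) entry: ", sub("\r", " / ", d, fixed = TRUE))
  }
  mirnas <- unique(df$mirna)
  samples <- unique(sid)
  m <- matrix(NA_real_, length(mirnas), length(samples),
              dimnames = list(mirnas, samples))
  m[cbind(match(df$mirna, mirnas), match(sid, samples))] <- as.numeric(df$ct)
  ct_matrix(m)
}

#' Write a CT matrix as a wide TSV
#'
#' Missing wells are written as `"NA"`; [read_ct_matrix()] round-trips them.
#'
#' @param x a [ct_matrix()].
#' @param path output path.
#' @export
write_ct_matrix <- function(x, path) {
  df <- data.frame(mirna = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Canonical miRNA assay name
#'
#' Assay names are matched case-insensitively with an optional `"hsa-"` prefix,
#' so `"hsa-miR-150"`, `"miR-150"` and `"HSA-MIR-150"` all refer to the same
#' assay.
#'
#' @param x character vector of assay names.
#' @return canonical lower-case names without the species prefix.
#' @export
canonical_mirna <- function(x) {
  sub("^hsa-", "", tolower(trimws(x)))
}
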