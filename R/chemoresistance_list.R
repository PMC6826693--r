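#' Drugs of the high-risk neuroblastoma induction protocol
#'
#' The six chemotherapeutics combined in induction regimens (Rapid-COJEC /
#' modified N7): cisplatin (CDDP), etoposide (VP-16), doxorubicin (DOXO),
#' vincristine (VCR), carboplatin (CBDCA) and cyclophosphamide (CPM).
#'
#' @export
induction_drugs <- c("cisplatin", "etoposide", "doxorubicin",
                     "vincristine", "carboplatin", "cyclophosphamide")

#' Chemoresistance miRNA list
#'
#' A curated literature mapping of miRNAs whose up- or downregulation promotes
#' resistance to a specific induction drug. Each entry is a
#' (miRNA, drug, direction) triple with direction `"up"` or `"down"`; a
#' `(mirna, drug)` pair appears at most once.
#'
#' @param df data.frame with columns `mirna`, `drug`, `direction`.
#' @return validated data.frame of class `chemoresistance_list`.
#' @export
chemoresistance_list <- function(df) {
  need <- c("mirna", "drug", "direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("chemoresistance list missing column(s): ",
                         paste(miss, collapse = ", "))
  df$drug <- tolower(as.character(df$drug))
  bad <- !df$drug %in% induction_drugs
  if (any(bad)) stop("unknown drug name(s): ",
                     paste(unique(df$drug[bad]), collapse = ", "))
  df$direction <- tolower(as.character(df$direction))
  bad <- !df$direction %in% c("up", "down")
  if (any(bad)) stop("direction must be \"up\" or \"down\"")
  key <- paste(canonical_mirna(df$mirna), df$drug)
  if (anyDuplicated(key))
    stop("duplicate (mirna, drug) pair: ", key[duplicated(key)][1])
  class(df) <- unique(c("chemoresistance_list", class(df)))
  df
}

#' Read a chemoresistance miRNA list from TSV
#'
#' An empty file with only the header yields a valid empty list. The packaged
#' literature-curated list is available via
#' `system.file("extdata", "chemoresistance_mirnas.tsv", package = "exopipe")`.
#'
#' @param path path to a TSV with columns `mirna`, `drug`, `direction`.
#' @return a validated `chemoresistance_list`.
#' @export
read_chemoresistance_list <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  chemoresistance_list(df)
}

#' Count resistance-associated miRNAs per drug
#'
#' Tallies, for every induction drug, how many listed miRNAs promote
#' resistance when upregulated (`n_up`) or downregulated (`n_down`). Drugs
#' with no entries are reported with zero counts.
#'
#' @param x a [chemoresistance_list()].
#' @return data.frame with columns `drug`, `n_up`, `n_down`.
#' @export
summarize_list_by_drug <- function(x) {
  stopifnot(inherits(x, "chemoresistance_list"))
  out <- data.frame(drug = induction_drugs,
                    n_up = 0L, n_down = 0L, stringsAsFactors = FALSE)
  if (nrow(x)) {
    up <- table(factor(x$drug[x$direction == "up"], levels = induction_drugs))
    dn <- table(factor(x$drug[x$direction == "down"], levels = induction_drugs))
    out$n_up <- as.integer(up)
    out$n_down <- as.integer(dn)
  }
  out
}
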