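#' Packaged reference tables
#'
#' `published_diffexpr_summary()` loads the packaged reference summary of the
#' 62 plasma exo-miRNAs reported as significantly downregulated after
#' induction chemotherapy in high-risk neuroblastoma (mean delta-CT per
#' timepoint, relative quantities, fold change and BH-adjusted p values, as
#' printed). `packaged_chemoresistance_path()` returns the path of the
#' literature-curated chemoresistance miRNA list shipped with the package.
#'
#' @return `published_diffexpr_summary()`: a data.frame with columns `mirna`,
#'   `mean_dct_end`, `mean_dct_onset`, `rq_end`, `rq_onset`, `fold_change`,
#'   `p_adj`.
#' @export
published_diffexpr_summary <- function() {
  path <- system.file("extdata", "published_diffexpr_summary.tsv",
                      package = "exopipe", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname published_diffexpr_summary
#' @export
packaged_chemoresistance_path <- function() {
  system.file("extdata", "chemoresistance_mirnas.tsv",
              package = "exopipe", mustWork = TRUE)
}
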