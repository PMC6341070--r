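# Bundled worked example: published per-cohort regression statistics of
# PIP4K2A (the seed kinase gene) against 11 transcription-factor probes in
# eight public pediatric B-ALL microarray cohorts (GEO series, n = 99-575).

#' Published seed-vs-TF association statistics in eight B-ALL cohorts
#'
#' Regression statistics (p, slope, se, adjusted r2, cohort n) of the seed
#' gene PIP4K2A against 11 transcription-factor probes (10 genes; NCOA1 is
#' represented by two probes) in eight pediatric B-ALL cohorts. Useful as a
#' small real-data input for the tier filters.
#'
#' @return data.frame in long format: `feature_id`, `gene`, `cohort_id`,
#'   `n`, `p_value`, `coefficient`, `se`, `adjusted_r2`.
#' @export
ball_seed_tf_stats <- function() {
  path <- system.file("extdata", "ball_seed_tf_associations.tsv",
                      package = "coexscreen", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$n <- as.integer(df$n)
  df
}

#' The worked example as per-cohort association tables
#'
#' @return list with `tables` (one `association_table` per cohort) and
#'   `probe_map` (probe -> gene, all flagged as transcription factors).
#' @export
ball_seed_tf_tables <- function() {
  df <- ball_seed_tf_stats()
  pm <- unique(df[c("feature_id", "gene")])
  pm$tf <- TRUE
  rownames(pm) <- NULL
  tables <- lapply(split(df, df$cohort_id),
                   as_association_table, seed_id = "PIP4K2A")
  list(tables = unname(tables), probe_map = pm)
}
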