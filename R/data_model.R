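# Readers/writers and the in-memory containers shared by the whole pipeline.
# All tabular inputs are plain TSV (UTF-8, "." decimal); read.delim opens
# gzip-compressed files transparently, so every reader accepts .gz too.

MISSING_TOKENS <- c("", "NA", "na", "N/A")

#' Construct an expression cohort
#'
#' Bundles one cohort's features x samples log-scale expression matrix with
#' optional per-sample annotations (group, subtype, tissue, pair_id, ...).
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique row and column names. `NA` marks a missing cell (handled
#'   pairwise-complete downstream); `NaN`/`Inf` are rejected.
#' @param cohort_id cohort identifier.
#' @param sample_annotations optional data.frame with a `sample_id` column;
#'   rows for unknown samples are kept but ignored by analyses.
#' @return an object of class `expression_cohort`: a list with elements
#'   `cohort_id`, `values`, `features`, `samples`, `sample_annotations`.
#' @export
expression_cohort <- function(values, cohort_id, sample_annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_coex("format_error", "expression values must be a numeric matrix")
  feats <- rownames(values); samps <- colnames(values)
  if (is.null(feats) || is.null(samps))
    stop_coex("format_error", "expression matrix must have feature and sample names")
  if (anyDuplicated(feats))
    stop_coex("format_error", "duplicate feature id: %s", feats[duplicated(feats)][1])
  if (anyDuplicated(samps))
    stop_coex("format_error", "duplicate sample id: %s", samps[duplicated(samps)][1])
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad))
    stop_coex("domain_error", "non-finite expression value for feature %s",
              feats[which(bad, arr.ind = TRUE)[1, 1]])
  if (!is.null(sample_annotations)) {
    if (!is.data.frame(sample_annotations) || !"sample_id" %in% names(sample_annotations))
      stop_coex("format_error", "sample annotations need a sample_id column")
    if (anyDuplicated(sample_annotations$sample_id))
      stop_coex("format_error", "duplicated sample_id in annotations")
  }
  structure(
    list(cohort_id = as.character(cohort_id), values = values,
         features = feats, samples = samps,
         sample_annotations = sample_annotations),
    class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort '%s': %d features x %d samples%s>\n",
              x$cohort_id, length(x$features), length(x$samples),
              if (is.null(x$sample_annotations)) "" else ", annotated"))
  invisible(x)
}

.read_tsv_char <- function(path) {
  if (!file.exists(path)) stop_coex("io_error", "file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE)
}

#' Read a tab-delimited expression matrix
#'
#' First column is the feature id, header row holds sample ids. Cells may be
#' empty or `NA` for missing; any other non-numeric token is a format error
#' naming the offending row and column. Features missing in more than
#' `max_missing_frac` of samples are dropped (remaining missing cells are
#' handled pairwise-complete by the regressions).
#'
#' @param path TSV file (optionally gzip-compressed).
#' @param transform `"none"` (values already log-scale) or `"log2_offset"`,
#'   which applies `log2(x + 0.001)` to non-negative raw values, the transform
#'   conventionally applied to TPM matrices.
#' @param cohort_id cohort identifier; defaults to the file name sans extension.
#' @param max_missing_frac per-feature missingness above which the feature is
#'   dropped (default 0.2).
#' @return an [expression_cohort()].
#' @export
read_expression_matrix <- function(path, transform = c("none", "log2_offset"),
                                   cohort_id = NULL, max_missing_frac = 0.2) {
  transform <- match.arg(transform)
  df <- .read_tsv_char(path)
  if (ncol(df) < 2)
    stop_coex("format_error", "expression matrix needs a feature column and >=1 sample: %s", path)
  feats <- df[[1]]
  samps <- colnames(df)[-1]          # before subsetting: `[.data.frame`
  if (anyDuplicated(samps))          # silently deduplicates names
    stop_coex("format_error", "duplicate sample id: %s",
              samps[duplicated(samps)][1])
  if (anyDuplicated(feats))
    stop_coex("format_error", "duplicate feature id: %s",
              feats[duplicated(feats)][1])
  raw <- as.matrix(df[, -1, drop = FALSE])
  colnames(raw) <- samps
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  is_missing <- is.na(raw) | raw %in% MISSING_TOKENS
  dim(is_missing) <- dim(raw)
  bad <- is.na(num) & !is_missing
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop_coex("format_error", "unparseable cell '%s' at feature %s, sample %s",
              raw[ij[1], ij[2]], feats[ij[1]], colnames(raw)[ij[2]])
  }
  if (transform == "log2_offset") {
    if (any(num < 0, na.rm = TRUE))
      stop_coex("domain_error", "negative raw value incompatible with log2_offset")
    num <- log2(num + 0.001)
  }
  dimnames(num) <- list(feats, colnames(raw))
  keep <- rowMeans(is.na(num)) <= max_missing_frac
  if (!all(keep))
    message(sprintf("dropping %d feature(s) with > %.0f%% missing values",
                    sum(!keep), 100 * max_missing_frac))
  cid <- cohort_id %||% sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  expression_cohort(num[keep, , drop = FALSE], cid)
}

#' Read a sample metadata table
#'
#' TSV with a mandatory `sample_id` column; `group`, `subtype`, `tissue` and
#' `pair_id` are recognised downstream, any further columns are carried
#' through untouched. Empty cells become `NA`, not empty strings.
#'
#' @param path TSV file (optionally gzip-compressed).
#' @return data.frame keyed by `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  df <- .read_tsv_char(path)
  if (!"sample_id" %in% names(df))
    stop_coex("format_error", "metadata lacks a sample_id column: %s", path)
  if (anyDuplicated(df$sample_id))
    stop_coex("format_error", "duplicated sample_id '%s' in %s",
              df$sample_id[duplicated(df$sample_id)][1], path)
  for (col in names(df)) df[[col]][df[[col]] %in% MISSING_TOKENS] <- NA
  df
}

#' Attach sample metadata to a cohort
#'
#' Matches by exact `sample_id` equality; annotation rows for samples absent
#' from the expression matrix are reported and ignored.
#'
#' @param cohort an [expression_cohort()].
#' @param metadata data.frame from [read_sample_metadata()].
#' @return the cohort with `sample_annotations` set.
#' @export
annotate_cohort <- function(cohort, metadata) {
  stopifnot(inherits(cohort, "expression_cohort"))
  unmatched <- setdiff(metadata$sample_id, cohort$samples)
  if (length(unmatched))
    message(sprintf("%d metadata sample(s) not in cohort '%s' (ignored)",
                    length(unmatched), cohort$cohort_id))
  cohort$sample_annotations <- metadata
  cohort
}

#' Read a probe-to-gene map
#'
#' TSV with columns `feature_id`, `gene` and optionally `tf` (TRUE/FALSE or
#' 1/0, flags transcription-factor annotation). Several feature ids may map
#' to the same gene symbol; a feature id may appear only once.
#'
#' @param path TSV file (optionally gzip-compressed).
#' @return data.frame with columns `feature_id`, `gene`, `tf` (logical).
#' @export
read_probe_map <- function(path) {
  df <- .read_tsv_char(path)
  if (!all(c("feature_id", "gene") %in% names(df)))
    stop_coex("format_error", "probe map needs feature_id and gene columns: %s", path)
  if (anyDuplicated(df$feature_id))
    stop_coex("format_error", "feature id mapped twice: %s",
              df$feature_id[duplicated(df$feature_id)][1])
  tf <- if ("tf" %in% names(df)) toupper(df$tf) %in% c("TRUE", "T", "1")
        else rep(FALSE, nrow(df))
  data.frame(feature_id = df$feature_id, gene = df$gene, tf = tf,
             stringsAsFactors = FALSE)
}

#' Map feature ids to gene symbols
#'
#' Unmapped features contribute their own id, so every feature always has a
#' gene-level label.
#'
#' @param features character vector of feature ids.
#' @param probe_map data.frame from [read_probe_map()], or `NULL`.
#' @return character vector of gene symbols, same length as `features`.
#' @export
map_genes <- function(features, probe_map = NULL) {
  if (is.null(probe_map) || length(features) == 0) return(features)
  idx <- match(features, probe_map$feature_id)
  ifelse(is.na(idx), features, probe_map$gene[idx])
}

#' Read a survival table
#'
#' TSV with columns `sample_id`, `time` (non-negative, days) and `event`
#' (1/0/true/false; TRUE = death or event observed, FALSE = censored).
#'
#' @param path TSV file (optionally gzip-compressed).
#' @return data.frame with columns `sample_id`, `time` (numeric), `event`
#'   (logical).
#' @export
read_survival <- function(path) {
  df <- .read_tsv_char(path)
  if (!all(c("sample_id", "time", "event") %in% names(df)))
    stop_coex("format_error", "survival table needs sample_id, time, event: %s", path)
  if (anyDuplicated(df$sample_id))
    stop_coex("format_error", "duplicated sample_id in survival table: %s", path)
  time <- suppressWarnings(as.numeric(df$time))
  if (anyNA(time))
    stop_coex("format_error", "unparseable time for sample %s",
              df$sample_id[which(is.na(time))[1]])
  if (any(time < 0))
    stop_coex("domain_error", "negative survival time for sample %s",
              df$sample_id[which(time < 0)[1]])
  ev_tok <- tolower(df$event)
  if (!all(ev_tok %in% c("0", "1", "true", "false")))
    stop_coex("format_error", "event must be 0/1/true/false; got '%s'",
              df$event[which(!ev_tok %in% c("0", "1", "true", "false"))[1]])
  data.frame(sample_id = df$sample_id, time = time,
             event = ev_tok %in% c("1", "true"), stringsAsFactors = FALSE)
}

ASSOC_COLUMNS <- c("feature_id", "gene", "cohort_id", "n", "coefficient",
                   "se", "t", "p_value", "r2", "adjusted_r2", "direction",
                   "p_bh")

#' Write an association table to TSV
#'
#' One row per (feature, cohort) with all regression statistics at 12
#' significant digits, so a write/read round trip preserves values to better
#' than 1e-9 relative. The seed feature id is recorded in a `# seed=` header
#' line.
#'
#' @param table an [association_table].
#' @param path output path.
#' @param probe_map optional probe map supplying the `gene` column.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path, probe_map = NULL) {
  stopifnot(inherits(table, "association_table"))
  res <- table$results
  if (is.null(res) || nrow(res) == 0)
    stop_coex("domain_error", "refusing to write an empty association table")
  out <- data.frame(feature_id = res$feature_id,
                    gene = map_genes(res$feature_id, probe_map),
                    cohort_id = res$cohort_id,
                    stringsAsFactors = FALSE)
  for (col in setdiff(ASSOC_COLUMNS, names(out)))
    out[[col]] <- sprintf("%.12g", res[[col]])
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_coex("io_error", "cannot write %s", path))
  on.exit(close(con))
  writeLines(paste0("# seed=", table$seed_id), con)
  utils::write.table(out[ASSOC_COLUMNS], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an association table written by [write_association_table()]
#'
#' @param path TSV file.
#' @return an [association_table].
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) stop_coex("io_error", "file not found: %s", path)
  first <- readLines(path, n = 1L)
  seed_id <- if (startsWith(first, "# seed=")) sub("^# seed=", "", first) else NA_character_
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  num_cols <- setdiff(ASSOC_COLUMNS, c("feature_id", "gene", "cohort_id"))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(df$n)
  df$direction <- as.integer(df$direction)
  new_association_table(df[setdiff(ASSOC_COLUMNS, "gene")], seed_id)
}
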