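# Replication of a discovery candidate set in new patient groups, and
# tumor-vs-normal association-specificity classification.

.candidate_features <- function(candidates) {
  if (inherits(candidates, "candidate_set")) candidates$features
  else as.character(candidates)
}

#' Replication / direction-consistency report for one validation group
#'
#' Counts, among the discovery candidates, those significantly associated
#' with the seed in the validation group, split by agreement of the slope
#' sign with the discovery direction. Candidates unmeasured in the group stay
#' in the denominator but can never be significant (they are flagged in
#' `n_unmeasured`). The consistent rate is
#' n_significant_same_direction / n_candidates; the opposite-direction rate
#' is n_opposite_among_significant / n_significant_total (0 when no candidate
#' is significant).
#'
#' @param candidates a `candidate_set` or character vector of feature ids.
#' @param reference_direction named vector of +1/-1 discovery directions
#'   covering every candidate (see [discovery_directions()]).
#' @param group_table `association_table` for the validation group.
#' @param alpha per-feature significance level (default 0.05).
#' @param group_id label for the report.
#' @return a `consistency_report` with counts, rates and their two-decimal
#'   percent renderings.
#' @export
replication_report <- function(candidates, reference_direction, group_table,
                               alpha = 0.05, group_id = NULL) {
  feats <- .candidate_features(candidates)
  if (!length(feats)) stop_coex("domain_error", "empty candidate set")
  if (!(alpha > 0 && alpha < 1)) stop_coex("config_error", "alpha must be in (0,1)")
  miss <- setdiff(feats, names(reference_direction))
  if (length(miss))
    stop_coex("config_error", "no reference direction for: %s",
              paste(utils::head(miss, 3), collapse = ", "))
  stopifnot(inherits(group_table, "association_table"))
  res <- group_table$results
  idx <- match(feats, res$feature_id)
  measured <- !is.na(idx)
  p <- ifelse(measured, res$p_value[idx], NA_real_)
  dir <- ifelse(measured, res$direction[idx], NA_integer_)
  ref <- as.integer(reference_direction[feats])
  sig <- measured & p <= alpha
  same <- sig & dir == ref
  opp <- sig & dir == -ref
  n_sig <- sum(sig)
  structure(list(
    group_id = group_id %||% res$cohort_id[1] %||% "group",
    n_candidates = length(feats),
    n_unmeasured = sum(!measured),
    n_significant_total = n_sig,
    n_significant_same_direction = sum(same),
    n_opposite_among_significant = sum(opp),
    consistent_rate = sum(same) / length(feats),
    opposite_rate = if (n_sig > 0) sum(opp) / n_sig else 0,
    consistent_rate_pct = format_percent(sum(same), length(feats)),
    opposite_rate_pct = if (n_sig > 0) format_percent(sum(opp), n_sig) else "0.00%",
    features_same = feats[same],
    features_opposite = feats[opp]),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "<consistency '%s': %d/%d significant same-direction (%s); %d/%d opposite among significant (%s)%s>\n",
    x$group_id, x$n_significant_same_direction, x$n_candidates,
    x$consistent_rate_pct, x$n_opposite_among_significant,
    x$n_significant_total, x$opposite_rate_pct,
    if (x$n_unmeasured > 0) sprintf("; %d unmeasured", x$n_unmeasured) else ""))
  invisible(x)
}

#' Candidates replicating in every molecular subtype
#'
#' Intersection over subtypes of the candidates with p <= alpha, with an
#' identical slope sign across all subtypes. Per-subtype
#' [replication_report()]s are returned alongside.
#'
#' @param candidates a `candidate_set` or character vector of feature ids.
#' @param subtype_tables named list (>= 2) of `association_table`s, one per
#'   subtype.
#' @param alpha per-feature significance level.
#' @param reference_direction optional named direction vector for the side
#'   reports; defaults to the consensus sign across subtypes.
#' @param min_samples subtypes whose regressions used fewer samples than this
#'   are excluded up front (default 30), so small groups cannot destabilise
#'   the intersection.
#' @return list with `features` (the shared set), `reports` (named list of
#'   `consistency_report`s) and `excluded_subtypes`.
#' @export
subtype_screen <- function(candidates, subtype_tables, alpha = 0.05,
                           reference_direction = NULL, min_samples = 30) {
  feats <- .candidate_features(candidates)
  stopifnot(!is.null(names(subtype_tables)))
  size_of <- vapply(subtype_tables, function(tb)
    if (nrow(tb$results)) as.numeric(max(tb$results$n)) else 0, numeric(1))
  excluded <- names(subtype_tables)[size_of < min_samples]
  if (length(excluded)) {
    message("excluding small subtype(s): ", paste(excluded, collapse = ", "))
    subtype_tables <- subtype_tables[size_of >= min_samples]
  }
  if (length(subtype_tables) < 2)
    stop_coex("config_error", "need >= 2 subtypes with >= %d samples", min_samples)
  for (nm in names(subtype_tables)) {
    res <- subtype_tables[[nm]]$results
    if (!any(feats %in% res$feature_id))
      stop_coex("config_error", "subtype '%s' shares no features with the candidates", nm)
  }
  per <- lapply(subtype_tables, function(tb) {
    idx <- match(feats, tb$results$feature_id)
    list(measured = !is.na(idx),
         sig = !is.na(idx) & tb$results$p_value[idx] <= alpha,
         dir = ifelse(is.na(idx), NA_integer_, tb$results$direction[idx]))
  })
  sig_all <- Reduce(`&`, lapply(per, `[[`, "sig"))
  dirs <- do.call(cbind, lapply(per, `[[`, "dir"))
  same_dir <- apply(dirs, 1, function(d) {
    d <- d[!is.na(d)]
    length(d) > 0 && all(d == d[1]) && d[1] != 0
  })
  shared <- feats[sig_all & same_dir]
  if (is.null(reference_direction)) {
    consensus <- apply(dirs, 1, function(d) as.integer(sign(sum(d, na.rm = TRUE))))
    reference_direction <- stats::setNames(consensus, feats)
  }
  reports <- lapply(names(subtype_tables), function(nm)
    replication_report(feats, reference_direction, subtype_tables[[nm]],
                       alpha = alpha, group_id = nm))
  names(reports) <- names(subtype_tables)
  list(features = shared, reports = reports, excluded_subtypes = excluded)
}

SPECIFICITY_CALLS <- c("consistent", "tumor_specific", "normal_specific",
                       "opposite", "neither")

#' Classify tumor-vs-normal association specificity
#'
#' For one feature measured in both tissues of a cancer type:
#' `consistent` if both associations reach alpha with the same slope sign,
#' `opposite` if both reach alpha with differing sign, `tumor_specific` /
#' `normal_specific` if only that tissue reaches alpha, `neither` otherwise.
#' The five calls partition the decision space.
#'
#' @param tumor,normal `association_result`s for the same feature.
#' @param alpha significance level.
#' @param cancer_type optional label.
#' @return a `specificity_call`: list with `feature_id`, `cancer_type`,
#'   `call`, `tumor_result`, `normal_result`.
#' @export
classify_specificity <- function(tumor, normal, alpha = 0.05,
                                 cancer_type = NA_character_) {
  if (!identical(tumor$feature_id, normal$feature_id))
    stop_coex("domain_error", "feature mismatch: %s vs %s",
              tumor$feature_id, normal$feature_id)
  ts <- tumor$p_value <= alpha
  ns <- normal$p_value <= alpha
  call <- if (ts && ns) {
    if (tumor$direction == normal$direction) "consistent" else "opposite"
  } else if (ts) "tumor_specific"
  else if (ns) "normal_specific"
  else "neither"
  structure(list(feature_id = tumor$feature_id, cancer_type = cancer_type,
                 call = call, tumor_result = tumor, normal_result = normal),
            class = "specificity_call")
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(sprintf("<specificity %s%s: %s (tumor p=%.3g, normal p=%.3g)>\n",
              x$feature_id,
              if (is.na(x$cancer_type)) "" else paste0(" @ ", x$cancer_type),
              x$call, x$tumor_result$p_value, x$normal_result$p_value))
  invisible(x)
}

#' Specificity calls for every shared feature of two association tables
#'
#' @param tumor_table,normal_table `association_table`s computed in tumor and
#'   matched normal samples of one cancer type.
#' @param alpha significance level.
#' @param cancer_type optional label.
#' @return data.frame with columns `feature_id`, `cancer_type`, `call`,
#'   `tumor_p`, `normal_p`, `tumor_direction`, `normal_direction`.
#' @export
classify_specificity_table <- function(tumor_table, normal_table, alpha = 0.05,
                                       cancer_type = NA_character_) {
  tr <- tumor_table$results; nr <- normal_table$results
  shared <- intersect(tr$feature_id, nr$feature_id)
  ti <- match(shared, tr$feature_id); ni <- match(shared, nr$feature_id)
  ts <- tr$p_value[ti] <= alpha; ns <- nr$p_value[ni] <= alpha
  call <- ifelse(ts & ns,
                 ifelse(tr$direction[ti] == nr$direction[ni], "consistent", "opposite"),
                 ifelse(ts, "tumor_specific", ifelse(ns, "normal_specific", "neither")))
  data.frame(feature_id = shared, cancer_type = cancer_type, call = call,
             tumor_p = tr$p_value[ti], normal_p = nr$p_value[ni],
             tumor_direction = tr$direction[ti],
             normal_direction = nr$direction[ni],
             stringsAsFactors = FALSE)
}

#' Frequency of up-/down-regulation across matched tumor/normal pairs
#'
#' Computes, over complete tumor/normal pairs linked by `pair_id`, the
#' fraction of pairs with tumor - normal expression at or above
#' `log_fc_threshold` (up) and at or below its negative (down). Expression is
#' assumed log-scale, so the default threshold 1 corresponds to a two-fold
#' change.
#'
#' @param cohort an [expression_cohort()] whose annotations carry `tissue`
#'   (tumor/normal) and `pair_id`.
#' @param feature_id feature to evaluate.
#' @param log_fc_threshold log-fold-change cutoff (default 1).
#' @return list with `up_fraction`, `down_fraction`, `n_pairs`.
#' @export
paired_regulation_frequency <- function(cohort, feature_id,
                                        log_fc_threshold = 1) {
  ann <- cohort$sample_annotations
  if (is.null(ann) || !all(c("tissue", "pair_id") %in% names(ann)))
    stop_coex("config_error", "cohort annotations need tissue and pair_id")
  vals <- .get_feature(cohort, feature_id)
  ann <- ann[ann$sample_id %in% cohort$samples & !is.na(ann$pair_id), ]
  tum <- ann[ann$tissue == "tumor", ]
  nor <- ann[ann$tissue == "normal", ]
  pairs <- intersect(tum$pair_id, nor$pair_id)
  n_unpaired <- nrow(ann) - 2 * length(pairs)
  if (!length(pairs)) stop_coex("domain_error", "no complete tumor/normal pairs")
  if (n_unpaired > 0)
    warning(sprintf("%d unpaired sample(s) ignored", n_unpaired))
  d <- vals[tum$sample_id[match(pairs, tum$pair_id)]] -
       vals[nor$sample_id[match(pairs, nor$pair_id)]]
  d <- d[!is.na(d)]
  if (!length(d)) stop_coex("domain_error", "no complete pairs with expression")
  list(up_fraction = mean(d >= log_fc_threshold),
       down_fraction = mean(d <= -log_fc_threshold),
       n_pairs = length(d))
}
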