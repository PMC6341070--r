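# Tiered, direction-consistent multi-cohort candidate filters.
#
# Three tiers ship as defaults, mirroring the screening design the package
# implements: a relaxed tier (p <= 0.05 in every cohort, same slope sign
# everywhere), a strict tier (p <= 2e-6 AND adjusted r2 >= 0.1 in at least
# five cohorts), and a heatmap tier (additionally adjusted r2 >= 0.3 in at
# least one cohort). Tiers are applied sequentially, each narrowing the
# previous tier's survivors. All r2 thresholds act on adjusted r2, the
# statistic reported per cohort.

#' Define a filter tier
#'
#' @param name tier label.
#' @param p_max per-cohort significance threshold (0 < p_max <= 1).
#' @param r2_min adjusted-r2 floor a cohort must reach to count toward
#'   `min_cohorts` (0 disables).
#' @param min_cohorts number of cohorts that must individually satisfy
#'   `p_max` and `r2_min`.
#' @param require_all_cohorts_significant if TRUE, the feature must be
#'   measured in every cohort and reach `p_max` in all of them.
#' @param require_same_direction if TRUE, the slope sign must be identical in
#'   every cohort where the feature is measured (a zero slope counts as a
#'   mismatch).
#' @param r2_min_any adjusted-r2 threshold that at least one cohort must
#'   reach (0 disables).
#' @return a `filter_tier` object.
#' @export
filter_tier <- function(name, p_max = 0.05, r2_min = 0, min_cohorts = 1,
                        require_all_cohorts_significant = FALSE,
                        require_same_direction = FALSE, r2_min_any = 0) {
  if (!(p_max > 0 && p_max <= 1)) stop_coex("config_error", "p_max must be in (0,1]")
  if (r2_min < 0 || r2_min > 1) stop_coex("config_error", "r2_min must be in [0,1]")
  if (min_cohorts < 1) stop_coex("config_error", "min_cohorts must be >= 1")
  structure(list(name = name, p_max = p_max, r2_min = r2_min,
                 min_cohorts = as.integer(min_cohorts),
                 require_all_cohorts_significant = isTRUE(require_all_cohorts_significant),
                 require_same_direction = isTRUE(require_same_direction),
                 r2_min_any = r2_min_any),
            class = "filter_tier")
}

#' @export
print.filter_tier <- function(x, ...) {
  cat(sprintf(
    "<tier '%s': p<=%g, r2>=%g in >=%d cohort(s)%s%s%s>\n",
    x$name, x$p_max, x$r2_min, x$min_cohorts,
    if (x$require_all_cohorts_significant) ", significant in all cohorts" else "",
    if (x$require_same_direction) ", same direction" else "",
    if (x$r2_min_any > 0) sprintf(", r2>=%g in >=1 cohort", x$r2_min_any) else ""))
  invisible(x)
}

#' The default three-tier screen
#'
#' @return named list of [filter_tier()] objects `relaxed`, `strict`,
#'   `heatmap`.
#' @export
default_tiers <- function() {
  list(
    relaxed = filter_tier("relaxed", p_max = 0.05,
                          require_all_cohorts_significant = TRUE,
                          require_same_direction = TRUE),
    strict = filter_tier("strict", p_max = 2e-6, r2_min = 0.1, min_cohorts = 5),
    heatmap = filter_tier("heatmap", p_max = 1, min_cohorts = 1,
                          r2_min_any = 0.3)
  )
}

# Accept a single (possibly multi-cohort) association_table or a list of
# them; return one combined results data.frame plus the seed and cohort set.
.combine_tables <- function(tables) {
  if (inherits(tables, "association_table")) tables <- list(tables)
  if (!length(tables)) stop_coex("config_error", "no association tables given")
  stopifnot(all(vapply(tables, inherits, logical(1), "association_table")))
  seeds <- unique(vapply(tables, `[[`, character(1), "seed_id"))
  if (length(seeds) > 1)
    stop_coex("config_error", "association tables disagree on the seed: %s",
              paste(seeds, collapse = ", "))
  res <- do.call(rbind, lapply(tables, `[[`, "results"))
  cohorts <- sort(unique(unlist(lapply(tables, `[[`, "cohorts"))))
  if (anyDuplicated(res[c("feature_id", "cohort_id")]))
    stop_coex("config_error", "more than one result per (feature, cohort)")
  list(results = res, seed_id = seeds, cohorts = cohorts)
}

new_candidate_set <- function(tier_name, features, probe_map, evidence) {
  structure(list(tier_name = tier_name,
                 features = features,
                 genes = sort(unique(map_genes(features, probe_map))),
                 evidence = evidence),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set '%s': %d feature(s), %d gene(s)>\n",
              x$tier_name, length(x$features), length(x$genes)))
  invisible(x)
}

#' Apply one filter tier across cohorts
#'
#' A feature passes when all enabled conditions hold: (a) with
#' `require_all_cohorts_significant`, it is measured in every cohort and has
#' p <= p_max in each; (b) at least `min_cohorts` cohorts reach both p_max
#' and r2_min; (c) with `require_same_direction`, the slope sign is identical
#' wherever measured; (d) with `r2_min_any` > 0, the best cohort adjusted r2
#' reaches it. The result is deterministic and independent of cohort or
#' feature ordering.
#'
#' @param tables one `association_table` or a list of them (one per cohort),
#'   all sharing the same seed.
#' @param tier a [filter_tier()].
#' @param probe_map optional probe map for the gene-level view.
#' @return a `candidate_set`: `tier_name`, sorted `features`, `genes`, and an
#'   `evidence` data.frame with one row per (feature, cohort) holding
#'   `measured` and `passed` flags.
#' @export
apply_tier <- function(tables, tier, probe_map = NULL) {
  stopifnot(inherits(tier, "filter_tier"))
  comb <- .combine_tables(tables)
  res <- comb$results
  cohorts <- comb$cohorts
  if (tier$min_cohorts > length(cohorts))
    stop_coex("config_error", "tier '%s' needs %d cohorts, only %d given",
              tier$name, tier$min_cohorts, length(cohorts))
  if (nrow(res) == 0) {
    return(new_candidate_set(tier$name, character(0), probe_map,
                             data.frame(feature_id = character(),
                                        cohort_id = character(),
                                        measured = logical(), passed = logical(),
                                        stringsAsFactors = FALSE)))
  }
  sig <- res$p_value <= tier$p_max
  qual <- sig & res$adjusted_r2 >= tier$r2_min
  idx <- split(seq_len(nrow(res)), res$feature_id)
  pass <- vapply(idx, function(i) {
    m <- length(i)                                   # cohorts where measured
    if (tier$require_all_cohorts_significant &&
        (m < length(cohorts) || !all(sig[i]))) return(FALSE)
    if (sum(qual[i]) < tier$min_cohorts) return(FALSE)
    if (tier$require_same_direction) {
      d <- res$direction[i]
      if (any(d == 0) || length(unique(d)) > 1) return(FALSE)
    }
    if (tier$r2_min_any > 0 && max(res$adjusted_r2[i]) < tier$r2_min_any)
      return(FALSE)
    TRUE
  }, logical(1))
  members <- sort(names(idx)[pass])
  evidence <- expand.grid(feature_id = members, cohort_id = cohorts,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(res$feature_id, res$cohort_id, sep = "\r")
  hit <- match(paste(evidence$feature_id, evidence$cohort_id, sep = "\r"), key)
  evidence$measured <- !is.na(hit)
  evidence$passed <- !is.na(hit) & qual[ifelse(is.na(hit), 1L, hit)]
  evidence <- evidence[order(evidence$feature_id, evidence$cohort_id), ]
  rownames(evidence) <- NULL
  new_candidate_set(tier$name, members, probe_map, evidence)
}

#' Run the sequential tiered screen
#'
#' Applies the tiers in order, each restricted to the previous tier's
#' survivors, so the candidate sets are nested (heatmap within strict within
#' relaxed). Set `sequential = FALSE` to evaluate every tier independently on
#' the full tables.
#'
#' @param tables one `association_table` or a list of them (>= 2 cohorts).
#' @param probe_map optional probe map.
#' @param tiers named list of [filter_tier()]s, applied in list order;
#'   defaults to [default_tiers()].
#' @param sequential narrow sequentially (default) or apply independently.
#' @return list with `candidates` (named list of `candidate_set`s) and
#'   `funnel` (data.frame of per-tier feature and gene counts).
#' @export
run_tiered_screen <- function(tables, probe_map = NULL, tiers = default_tiers(),
                              sequential = TRUE) {
  comb <- .combine_tables(tables)
  if (length(comb$cohorts) < 2)
    stop_coex("config_error", "tiered screening needs >= 2 cohorts")
  if (inherits(tables, "association_table")) tables <- list(tables)
  current <- tables
  out <- list()
  for (nm in names(tiers)) {
    cs <- apply_tier(current, tiers[[nm]], probe_map)
    out[[nm]] <- cs
    if (sequential) {
      current <- lapply(current, function(tb) {
        tb$results <- tb$results[tb$results$feature_id %in% cs$features, ,
                                 drop = FALSE]
        tb
      })
    }
  }
  funnel <- data.frame(
    tier = names(out),
    n_features = vapply(out, function(cs) length(cs$features), integer(1)),
    n_genes = vapply(out, function(cs) length(cs$genes), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(candidates = out, funnel = funnel)
}

#' Collapse a candidate set to distinct gene symbols
#'
#' @param candidates a `candidate_set`.
#' @param probe_map optional probe map; unmapped features keep their own id.
#' @return character vector of distinct gene symbols.
#' @export
collapse_to_genes <- function(candidates, probe_map = NULL) {
  stopifnot(inherits(candidates, "candidate_set"))
  sort(unique(map_genes(candidates$features, probe_map)))
}

#' Discovery direction of each candidate
#'
#' The (unanimous, when the relaxed tier enforced it) slope sign of each
#' candidate across the discovery cohorts; used as the reference direction
#' for replication reports. Where cohorts disagree, the sign of the summed
#' directions is used.
#'
#' @param candidates a `candidate_set` or character vector of feature ids.
#' @param tables discovery association table(s).
#' @return named integer vector of +1/-1/0 per candidate.
#' @export
discovery_directions <- function(candidates, tables) {
  feats <- if (inherits(candidates, "candidate_set")) candidates$features
           else as.character(candidates)
  res <- .combine_tables(tables)$results
  vapply(feats, function(f) {
    d <- res$direction[res$feature_id == f]
    if (!length(d)) return(0L)
    as.integer(sign(sum(d)))
  }, integer(1))
}
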