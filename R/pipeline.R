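# End-to-end orchestration: simulate -> associate -> screen -> validate ->
# survive from one configuration, with a machine-readable manifest.
#
# Every stage writes plain TSV/JSON under the output directory; the manifest
# lists relative paths, md5 checksums and candidate-set sizes, so two runs
# with identical inputs and rng_seed produce byte-identical manifests.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write synthetic cohorts (and optional survival data) to a directory
#'
#' Materialises a [generate_cohorts()] draw as the TSV files the pipeline
#' readers consume: one expression matrix and one metadata table per cohort,
#' a ground-truth JSON, and — when `survival_spec` is configured — a survival
#' table for the first cohort driven by its first planted feature.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return list with `cohort_files` (data.frame id/expr/meta), `ground_truth`
#'   and optional `survival_file`, invisibly usable as pipeline input.
#' @export
simulate_to_dir <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_cohorts(config)
  files <- lapply(gen$cohorts, function(co) {
    expr <- file.path(dir, paste0(co$cohort_id, "_expr.tsv"))
    .write_tsv(data.frame(feature_id = co$features,
                          signif(co$values, 12), check.names = FALSE), expr)
    meta <- file.path(dir, paste0(co$cohort_id, "_meta.tsv"))
    .write_tsv(co$sample_annotations %||%
                 data.frame(sample_id = co$samples), meta)
    data.frame(id = co$cohort_id, expr = expr, meta = meta,
               stringsAsFactors = FALSE)
  })
  out <- list(cohort_files = do.call(rbind, files),
              ground_truth = gen$ground_truth)
  if (!is.null(config$survival_spec)) {
    co <- gen$cohorts[[1]]
    feat <- if (length(gen$ground_truth$planted_features))
      gen$ground_truth$planted_features[1] else config$seed_id
    surv <- generate_survival(co$values[feat, ], config$survival_spec,
                              rng_seed = config$rng_seed + 1000L)
    surv$event <- as.integer(surv$event)
    out$survival_file <- .write_tsv(surv, file.path(dir, "survival.tsv"))
    out$survival_feature <- feat
  }
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gen$ground_truth, gt_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out$ground_truth_file <- gt_path
  invisible(out)
}

.pipeline_stage <- function(out_dir, stage, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop_coex("config_error", "pipeline stage '%s' failed: %s", stage,
              conditionMessage(e))
  })
}

.tiers_from_config <- function(tiers) {
  if (is.null(tiers)) return(default_tiers())
  out <- lapply(names(tiers), function(nm)
    do.call(filter_tier, c(list(name = nm), tiers[[nm]])))
  names(out) <- names(tiers)
  out
}

#' Run the full screening pipeline from one configuration
#'
#' Stages, in order: per-cohort genome-wide association with the seed,
#' tiered candidate screening, optional replication in validation groups,
#' optional expression-dichotomized survival screening. Each stage's output
#' is written under `out_dir`; a failing stage leaves a `FAILED` marker
#' naming itself and keeps earlier outputs.
#'
#' @param config a named list or path to a YAML file with fields:
#'   `out_dir`; `seed_feature`; `cohorts` (list of `id`/`expr`/optional
#'   `meta`/optional `transform`); optional `tiers` (named list of
#'   [filter_tier()] arguments), `probe_map` (path), `alpha`,
#'   `validation_groups` (list of `id`/`expr`), `survival` (list of `surv`
#'   path, optional `cohort` id, optional `features` = "relaxed"/"strict"/
#'   "heatmap" or explicit ids), `rng_seed`.
#' @return the manifest (also written to `manifest.json`): output paths
#'   relative to `out_dir`, md5 checksums, per-tier set sizes.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop_coex("config_error", "out_dir missing")
  if (is.null(config$seed_feature)) stop_coex("config_error", "seed_feature missing")
  if (!length(config$cohorts)) stop_coex("config_error", "no cohorts configured")
  paths <- c(vapply(config$cohorts, `[[`, character(1), "expr"),
             unlist(lapply(config$cohorts, `[[`, "meta")),
             unlist(lapply(config$validation_groups, `[[`, "expr")),
             config$probe_map, config$survival$surv)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_coex("io_error", "input file not found: %s", missing[1])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))
  alpha <- config$alpha %||% 0.05
  probe_map <- if (!is.null(config$probe_map)) read_probe_map(config$probe_map)
  outputs <- character(0)

  # -- associate ------------------------------------------------------------
  cohorts <- list(); tables <- list()
  .pipeline_stage(out_dir, "associate", {
    for (cc in config$cohorts) {
      co <- read_expression_matrix(cc$expr, transform = cc$transform %||% "none",
                                   cohort_id = cc$id)
      if (!is.null(cc$meta)) co <- annotate_cohort(co, read_sample_metadata(cc$meta))
      tb <- associate_all(co, config$seed_feature)
      f <- file.path(out_dir, sprintf("assoc_%s.tsv", cc$id))
      write_association_table(tb, f, probe_map)
      outputs <- c(outputs, f)
      cohorts[[cc$id]] <- co; tables[[cc$id]] <- tb
    }
  })

  # -- screen ---------------------------------------------------------------
  screen <- .pipeline_stage(out_dir, "screen", {
    sc <- run_tiered_screen(tables, probe_map,
                            tiers = .tiers_from_config(config$tiers),
                            sequential = !isFALSE(config$sequential))
    for (nm in names(sc$candidates)) {
      cs <- sc$candidates[[nm]]
      f <- file.path(out_dir, sprintf("candidates_%s.tsv", nm))
      wide <- if (nrow(cs$evidence)) {
        stats::reshape(cs$evidence[c("feature_id", "cohort_id", "passed")],
                       idvar = "feature_id", timevar = "cohort_id",
                       direction = "wide")
      } else data.frame(feature_id = character(0))
      wide <- cbind(wide[1], gene = map_genes(wide$feature_id, probe_map),
                    wide[-1])
      .write_tsv(wide, f)
      outputs <- c(outputs, f)
    }
    f <- file.path(out_dir, "screen_summary.json")
    jsonlite::write_json(sc$funnel, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs <- c(outputs, f)
    sc
  })

  # -- validate (optional) --------------------------------------------------
  if (!is.null(config$validation_groups)) {
    .pipeline_stage(out_dir, "validate", {
      relaxed <- screen$candidates[[1]]
      refdir <- discovery_directions(relaxed, tables)
      reports <- lapply(config$validation_groups, function(vg) {
        co <- read_expression_matrix(vg$expr, transform = vg$transform %||% "none",
                                     cohort_id = vg$id)
        rep <- replication_report(relaxed, refdir,
                                  associate_all(co, config$seed_feature),
                                  alpha = alpha, group_id = vg$id)
        data.frame(group_id = rep$group_id, n_candidates = rep$n_candidates,
                   n_significant_total = rep$n_significant_total,
                   n_significant_same_direction = rep$n_significant_same_direction,
                   n_opposite_among_significant = rep$n_opposite_among_significant,
                   consistent_rate = rep$consistent_rate,
                   consistent_rate_pct = rep$consistent_rate_pct,
                   opposite_rate = rep$opposite_rate,
                   opposite_rate_pct = rep$opposite_rate_pct,
                   n_unmeasured = rep$n_unmeasured, stringsAsFactors = FALSE)
      })
      f <- .write_tsv(do.call(rbind, reports),
                      file.path(out_dir, "validation_reports.tsv"))
      outputs <- c(outputs, f)
    })
  }

  # -- survive (optional) ---------------------------------------------------
  if (!is.null(config$survival)) {
    .pipeline_stage(out_dir, "survive", {
      sv <- config$survival
      co <- cohorts[[sv$cohort %||% names(cohorts)[1]]]
      recs <- read_survival(sv$surv)
      feats <- sv$features %||% "relaxed"
      if (length(feats) == 1 && feats %in% names(screen$candidates))
        feats <- screen$candidates[[feats]]$features
      tab <- survival_screen(co, recs, features = feats,
                             min_group_frac = sv$min_group_frac %||% 0.1,
                             alpha = alpha)
      f <- .write_tsv(tab, file.path(out_dir, "survival_screen.tsv"))
      outputs <- c(outputs, f)
    })
  }

  # -- manifest -------------------------------------------------------------
  rel <- sort(vapply(outputs, function(p)
    sub("^/", "", substring(p, nchar(out_dir) + 1L)), character(1),
    USE.NAMES = FALSE))
  sums <- unname(tools::md5sum(file.path(out_dir, rel)))
  manifest <- list(
    pipeline = "coexscreen",
    seed_feature = config$seed_feature,
    rng_seed = config$rng_seed %||% NA,
    alpha = alpha,
    set_sizes = stats::setNames(as.list(screen$funnel$n_features),
                                screen$funnel$tier),
    outputs = stats::setNames(as.list(sums), rel))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
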