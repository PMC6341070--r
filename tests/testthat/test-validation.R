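ref_dir <- function(feats) setNames(rep(1L, length(feats)), feats)

test_that("replication counts split significant candidates by direction", {
  feats <- sprintf("f%02d", 1:10)
  # 6 significant same direction, 2 significant opposite, 2 non-significant
  tb <- stats_table(feats, c(rep(0.01, 8), 0.5, 0.9),
                    direction = c(rep(1, 6), -1, -1, 1, 1))
  rep <- replication_report(feats, ref_dir(feats), tb, alpha = 0.05,
                            group_id = "G")
  expect_identical(rep$n_candidates, 10L)
  expect_identical(rep$n_significant_total, 8L)
  expect_identical(rep$n_significant_same_direction, 6L)
  expect_identical(rep$n_opposite_among_significant, 2L)
  expect_equal(rep$consistent_rate, 0.6)
  expect_equal(rep$opposite_rate, 0.25)
  expect_lte(rep$n_significant_same_direction + rep$n_opposite_among_significant,
             rep$n_significant_total)
})

test_that("printed-count arithmetic reproduces the reported percentage renderings", {
  expect_identical(format_percent(212, 214), "99.07%")
  expect_identical(format_percent(206, 214), "96.26%")
  expect_identical(format_percent(106, 214), "49.53%")
  expect_identical(format_percent(2, 206), "0.97%")
})

test_that("unmeasured candidates stay in the denominator but never count", {
  feats <- c("f1", "f2", "f3", "f4")
  tb <- stats_table(c("f1", "f2"), c(0.01, 0.01))
  rep <- replication_report(feats, ref_dir(feats), tb)
  expect_identical(rep$n_unmeasured, 2L)
  expect_identical(rep$n_candidates, 4L)
  expect_equal(rep$consistent_rate, 0.5)
})

test_that("fully consistent groups give rate 1 and opposite rate 0", {
  feats <- c("a", "b", "c")
  tb <- stats_table(feats, rep(1e-4, 3))
  rep <- replication_report(feats, ref_dir(feats), tb)
  expect_equal(rep$consistent_rate, 1)
  expect_equal(rep$opposite_rate, 0)
  expect_error(replication_report(character(0), ref_dir(feats), tb),
               class = "coex_domain_error")
})

test_that("rates are unchanged when every candidate is duplicated", {
  feats <- sprintf("f%02d", 1:6)
  p <- c(0.01, 0.01, 0.01, 0.2, 0.01, 0.6)
  dir <- c(1, 1, -1, 1, 1, 1)
  tb1 <- stats_table(feats, p, direction = dir)
  r1 <- replication_report(feats, ref_dir(feats), tb1)
  feats2 <- c(feats, paste0(feats, "_dup"))
  tb2 <- stats_table(feats2, rep(p, 2), direction = rep(dir, 2))
  r2 <- replication_report(feats2, ref_dir(feats2), tb2)
  expect_equal(r1$consistent_rate, r2$consistent_rate)
  expect_equal(r1$opposite_rate, r2$opposite_rate)
})

test_that("subtype screen keeps only candidates replicating in every subtype", {
  feats <- c("f1", "f2", "f3")
  tabs <- list(
    hyperdiploid = stats_table(feats, c(0.01, 0.01, 0.01), cohort_id = "hd"),
    etv6 = stats_table(feats, c(0.01, 0.4, 0.01), cohort_id = "et"),   # f2 null here
    tcf3 = stats_table(feats, c(0.01, 0.01, 0.01), direction = c(1, 1, -1),
                       cohort_id = "tc"))                               # f3 flips
  out <- subtype_screen(feats, tabs, alpha = 0.05)
  expect_identical(out$features, "f1")
  expect_named(out$reports, c("hyperdiploid", "etv6", "tcf3"))

  tabs$empty <- stats_table("other_feature", 0.01, cohort_id = "em")
  expect_error(subtype_screen(feats, tabs), class = "coex_config_error")
  expect_error(subtype_screen(feats, tabs["hyperdiploid"]),
               class = "coex_config_error")
})

test_that("undersized subtypes are excluded before the intersection", {
  feats <- c("f1", "f2")
  tabs <- list(big1 = stats_table(feats, c(0.01, 0.01), cohort_id = "b1"),
               big2 = stats_table(feats, c(0.01, 0.01), cohort_id = "b2"),
               tiny = stats_table(feats, c(0.9, 0.9), cohort_id = "t", n = 12))
  expect_message(out <- subtype_screen(feats, tabs), "tiny")
  expect_identical(out$excluded_subtypes, "tiny")
  expect_setequal(out$features, feats)      # tiny group no longer vetoes
  expect_named(out$reports, c("big1", "big2"))
})

test_that("specificity calls follow the definition and partition the space", {
  mk <- function(p, dir) structure(list(feature_id = "f", p_value = p,
                                        direction = dir),
                                   class = "association_result")
  expect_identical(classify_specificity(mk(1e-5, 1), mk(0.4, 1))$call,
                   "tumor_specific")
  expect_identical(classify_specificity(mk(0.4, 1), mk(1e-5, 1))$call,
                   "normal_specific")
  expect_identical(classify_specificity(mk(0.01, 1), mk(0.01, -1))$call,
                   "opposite")
  expect_identical(classify_specificity(mk(0.01, -1), mk(0.01, -1))$call,
                   "consistent")
  expect_identical(classify_specificity(mk(0.2, 1), mk(0.2, 1))$call, "neither")
  expect_error(classify_specificity(mk(0.2, 1),
                                    structure(list(feature_id = "g",
                                                   p_value = 0.2, direction = 1),
                                              class = "association_result")),
               class = "coex_domain_error")

  # partition over a grid: exactly one call per (p_tumor, p_normal, dirs) cell
  grid <- expand.grid(pt = c(0.001, 0.049, 0.051, 0.9),
                      pn = c(0.001, 0.049, 0.051, 0.9),
                      dt = c(-1L, 1L), dn = c(-1L, 1L))
  calls <- apply(grid, 1, function(g)
    classify_specificity(mk(g[["pt"]], g[["dt"]]), mk(g[["pn"]], g[["dn"]]))$call)
  expect_true(all(calls %in% c("consistent", "tumor_specific",
                               "normal_specific", "opposite", "neither")))
  expect_length(calls, nrow(grid))
})

test_that("paired regulation frequencies count threshold exceedances", {
  n <- 10
  normal <- rnorm(n, 8, 0.001)
  delta <- c(1.5, 2, 3, -1.5, -2, rep(0, 5))   # 3 up, 2 down at threshold 1
  vals <- matrix(c(normal + delta, normal), nrow = 1,
                 dimnames = list("F", c(sprintf("P%02d_T", 1:n),
                                        sprintf("P%02d_N", 1:n))))
  ann <- data.frame(sample_id = colnames(vals),
                    tissue = rep(c("tumor", "normal"), each = n),
                    pair_id = rep(sprintf("P%02d", 1:n), 2))
  co <- expression_cohort(vals, "paired", sample_annotations = ann)
  fr <- paired_regulation_frequency(co, "F", log_fc_threshold = 1)
  expect_equal(fr$up_fraction, 0.3)
  expect_equal(fr$down_fraction, 0.2)

  # identical tumor/normal values -> (0, 0)
  vals0 <- matrix(rep(normal, 2), nrow = 1, dimnames = dimnames(vals))
  co0 <- expression_cohort(vals0, "paired", sample_annotations = ann)
  fr0 <- paired_regulation_frequency(co0, "F")
  expect_equal(fr0$up_fraction, 0)
  expect_equal(fr0$down_fraction, 0)

  # all tumors shifted +10 log2 units -> (1, 0)
  vals10 <- matrix(c(normal + 10, normal), nrow = 1, dimnames = dimnames(vals))
  co10 <- expression_cohort(vals10, "paired", sample_annotations = ann)
  fr10 <- paired_regulation_frequency(co10, "F", log_fc_threshold = 1)
  expect_equal(fr10$up_fraction, 1)
  expect_equal(fr10$down_fraction, 0)

  # unpaired samples are ignored with a warning; no pairs at all errors
  ann2 <- ann; ann2$pair_id[1] <- "P99"
  co2 <- expression_cohort(vals, "paired", sample_annotations = ann2)
  expect_warning(paired_regulation_frequency(co2, "F"), "unpaired")
  ann3 <- ann; ann3$tissue <- "tumor"
  co3 <- expression_cohort(vals, "paired", sample_annotations = ann3)
  expect_error(paired_regulation_frequency(co3, "F"),
               class = "coex_domain_error")
})

test_that("replication on the discovery cohorts themselves is fully consistent", {
  ex <- ball_seed_tf_tables()
  relaxed <- apply_tier(ex$tables, default_tiers()$relaxed)
  refdir <- discovery_directions(relaxed, ex$tables)
  for (tb in ex$tables[1:2]) {
    rep <- replication_report(relaxed, refdir, tb, alpha = 0.05)
    expect_equal(rep$consistent_rate, 1)
    expect_equal(rep$opposite_rate, 0)
  }
})
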