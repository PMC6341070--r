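# Per-feature simple linear regression against the seed feature.
#
# The regression engine is a closed-form OLS kernel (normal equations on
# pairwise-complete observations) shared by fit_seed_association() and
# associate_all(), so looping the single-pair fit reproduces the full screen
# exactly. The seed is the predictor; p and r2 are orientation-invariant for
# one predictor, so every screening decision is unaffected by that choice.

# Closed-form OLS of y on x with intercept; pairwise-complete cases.
.ols_stats <- function(x, y, what = "feature") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4)
    stop_coex("insufficient_samples", "only %d complete pairs (need >= 4)", n)
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  sxx <- sum(dx * dx); syy <- sum(dy * dy); sxy <- sum(dx * dy)
  if (sxx <= 0) stop_coex("constant_feature", "seed feature is constant")
  if (syy <= 0) stop_coex("constant_feature", "%s is constant", what)
  beta <- sxy / sxx
  r2 <- (sxy * sxy) / (sxx * syy)
  rss <- syy - beta * sxy
  collinear <- rss <= 1e-12 * syy
  se <- sqrt(max(rss, 0) / ((n - 2) * sxx))
  tval <- if (se > 0) beta / se else sign(beta) * Inf
  if (collinear) {
    r2 <- 1; p <- 0            # exact linear dependence
  } else {
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(n = n, coefficient = beta, se = se, t = tval, p_value = p,
       r2 = r2, adjusted_r2 = adj, direction = as.integer(sign(beta)))
}

.get_feature <- function(cohort, id) {
  if (!id %in% cohort$features)
    stop_coex("key_not_found", "feature '%s' not in cohort '%s'", id, cohort$cohort_id)
  cohort$values[id, ]
}

#' Regress one feature's expression on the seed feature
#'
#' Ordinary least squares of `target` on `seed` with intercept, on
#' pairwise-complete samples: t = beta/se on n - 2 degrees of freedom,
#' two-sided p, r2 = squared Pearson correlation, adjusted
#' r2 = 1 - (1 - r2)(n - 1)/(n - 2). Exactly collinear pairs report
#' p = 0 and r2 = 1.
#'
#' @param cohort an [expression_cohort()].
#' @param seed_id feature id of the seed gene (the predictor).
#' @param target_id feature id of the response.
#' @return an `association_result`: list with `feature_id`, `cohort_id`, `n`,
#'   `coefficient`, `se`, `t`, `p_value`, `r2`, `adjusted_r2`, `direction`.
#' @export
fit_seed_association <- function(cohort, seed_id, target_id) {
  x <- .get_feature(cohort, seed_id)
  y <- .get_feature(cohort, target_id)
  st <- .ols_stats(x, y, what = sprintf("target '%s'", target_id))
  structure(c(list(feature_id = target_id, cohort_id = cohort$cohort_id), st),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association %s @ %s: n=%d beta=%.4g (se %.3g) p=%.3g adj.r2=%.3f dir=%+d>\n",
    x$feature_id, x$cohort_id, x$n, x$coefficient, x$se, x$p_value,
    x$adjusted_r2, x$direction))
  invisible(x)
}

new_association_table <- function(results, seed_id, skipped = NULL) {
  structure(list(results = results, seed_id = seed_id,
                 cohorts = unique(results$cohort_id),
                 skipped = skipped %||%
                   data.frame(feature_id = character(), reason = character(),
                              stringsAsFactors = FALSE)),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table seed=%s: %d results, %d cohort(s), %d skipped>\n",
              x$seed_id, nrow(x$results), length(x$cohorts), nrow(x$skipped)))
  invisible(x)
}

#' Genome-wide association of every feature with the seed
#'
#' Applies [fit_seed_association()]'s kernel to every non-seed feature of the
#' cohort. Features failing the preconditions (constant, too few complete
#' pairs) are recorded in the `skipped` table with a reason rather than
#' aborting the screen. A Benjamini-Hochberg adjusted p column (`p_bh`) is
#' emitted for convenience; the tier filters operate on raw p only.
#'
#' @param cohort an [expression_cohort()].
#' @param seed_id feature id of the seed gene.
#' @return an `association_table`: list with `results` (data.frame, one row
#'   per feature), `seed_id`, `cohorts`, `skipped`.
#' @export
associate_all <- function(cohort, seed_id) {
  x <- .get_feature(cohort, seed_id)
  targets <- setdiff(cohort$features, seed_id)
  rows <- vector("list", length(targets))
  skip <- list()
  for (i in seq_along(targets)) {
    st <- tryCatch(.ols_stats(x, cohort$values[targets[i], ], what = targets[i]),
                   coex_error = function(e) e)
    if (inherits(st, "coex_error")) {
      skip[[length(skip) + 1L]] <-
        data.frame(feature_id = targets[i],
                   reason = class(st)[1], stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- st
    }
  }
  kept <- !vapply(rows, is.null, logical(1))
  res <- if (any(kept)) {
    data.frame(feature_id = targets[kept],
               cohort_id = cohort$cohort_id,
               n = vapply(rows[kept], `[[`, integer(1), "n"),
               coefficient = vapply(rows[kept], `[[`, numeric(1), "coefficient"),
               se = vapply(rows[kept], `[[`, numeric(1), "se"),
               t = vapply(rows[kept], `[[`, numeric(1), "t"),
               p_value = vapply(rows[kept], `[[`, numeric(1), "p_value"),
               r2 = vapply(rows[kept], `[[`, numeric(1), "r2"),
               adjusted_r2 = vapply(rows[kept], `[[`, numeric(1), "adjusted_r2"),
               direction = vapply(rows[kept], `[[`, integer(1), "direction"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(feature_id = character(), cohort_id = character(),
               n = integer(), coefficient = numeric(), se = numeric(),
               t = numeric(), p_value = numeric(), r2 = numeric(),
               adjusted_r2 = numeric(), direction = integer(),
               stringsAsFactors = FALSE)
  }
  res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  tb <- new_association_table(res, seed_id,
                              skipped = if (length(skip)) do.call(rbind, skip) else NULL)
  tb$cohorts <- cohort$cohort_id
  tb
}

#' Permutation p-value for the seed-target slope
#'
#' Two-sided permutation test of the regression slope: the target vector is
#' permuted `n_perm` times, and the p-value is
#' (1 + #{|beta_perm| >= |beta_obs|}) / (n_perm + 1). Used as a
#' distribution-free cross-check of the parametric p-value.
#'
#' @param cohort an [expression_cohort()].
#' @param seed_id,target_id feature ids.
#' @param n_perm number of permutations (>= 1000).
#' @param rng_seed integer seed; the global RNG stream is left untouched.
#' @return permutation p-value (numeric scalar).
#' @export
permutation_p <- function(cohort, seed_id, target_id, n_perm = 10000,
                          rng_seed = 1) {
  if (n_perm < 1000) stop_coex("config_error", "n_perm must be >= 1000")
  x <- .get_feature(cohort, seed_id)
  y <- .get_feature(cohort, target_id)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  .ols_stats(x, y)                       # validate preconditions
  dx <- x - mean(x)
  sxx <- sum(dx * dx)
  b_obs <- sum(dx * (y - mean(y))) / sxx
  count <- with_seed(rng_seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      yp <- y[sample.int(length(y))]
      bp <- sum(dx * (yp - mean(yp))) / sxx
      if (abs(bp) >= abs(b_obs) * (1 - 1e-12)) hits <- hits + 1L
    }
    hits
  })
  (count + 1) / (n_perm + 1)
}

#' Build an association table from precomputed statistics
#'
#' Accepts published or externally computed regression statistics (for
#' example, a transcribed results table) with at least `feature_id`,
#' `cohort_id`, `p_value`, `coefficient` and `adjusted_r2` columns; `n` and
#' `se` are used to derive `r2` and `t` when present.
#'
#' @param df data.frame of statistics.
#' @param seed_id seed feature id the statistics refer to.
#' @return an `association_table`.
#' @export
as_association_table <- function(df, seed_id) {
  need <- c("feature_id", "cohort_id", "p_value", "coefficient", "adjusted_r2")
  if (!all(need %in% names(df)))
    stop_coex("format_error", "missing columns: %s",
              paste(setdiff(need, names(df)), collapse = ", "))
  df$direction <- as.integer(sign(df$coefficient))
  if (!"n" %in% names(df)) df$n <- NA_integer_
  if (!"se" %in% names(df)) df$se <- NA_real_
  df$t <- ifelse(df$se > 0, df$coefficient / df$se, NA_real_)
  # invert adjusted r2 given n: r2 = 1 - (1 - adj)(n - 2)/(n - 1)
  df$r2 <- ifelse(is.na(df$n), df$adjusted_r2,
                  1 - (1 - df$adjusted_r2) * (df$n - 2) / (df$n - 1))
  keep <- intersect(c(setdiff(ASSOC_COLUMNS, c("gene", "p_bh"))), names(df))
  new_association_table(df[keep], seed_id)
}
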