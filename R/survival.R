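# Expression-dichotomized overall-survival screening.
#
# Samples are split into high/low expression groups at the antimode of a
# kernel density estimate (the "low point of the histogram" between the two
# dominant modes); unimodal features fall back to a median split. Group
# survival is compared with the standard two-group log-rank test; the
# Kaplan-Meier estimator and log-rank machinery stand on the survival
# package, with restricted-mean survival deciding which group benefits.

#' Antimode expression dichotomization
#'
#' Gaussian KDE (Silverman rule-of-thumb bandwidth) on the expression values.
#' Local density maxima are kept as modes only if prominent (height at least
#' `min_peak_frac` of the global maximum); when two or more modes survive,
#' the threshold is the density minimum between the two highest modes,
#' provided that dip sits at least `min_dip_frac` below the lower of the two
#' (guarding against grid-level micro-wiggles). Otherwise — or when the
#' antimode split would leave a group below `min_group_frac` of the samples —
#' the sample median is used (`method = "median_fallback"`).
#'
#' @param values numeric expression values (>= 20, non-constant), optionally
#'   named by sample id.
#' @param feature_id label carried into the result.
#' @param bandwidth KDE bandwidth selector or value (default `"nrd0"`,
#'   Silverman's rule).
#' @param min_group_frac minimum fraction of samples per group (default 0.1).
#' @param min_peak_frac,min_dip_frac mode-prominence guards (defaults 0.2 and
#'   0.1): a secondary mode must reach `min_peak_frac` of the primary mode's
#'   density, and the valley must dip at least `min_dip_frac` below the lower
#'   mode, before the split counts as bimodal.
#' @return a `dichotomy_result`: `feature_id`, `threshold`, `method`
#'   (`"antimode"` or `"median_fallback"`), `group_of` (named character
#'   vector, `"high"`/`"low"`), `group_sizes` (`n_low`, `n_high`).
#' @export
antimode_threshold <- function(values, feature_id = NA_character_,
                               bandwidth = "nrd0", min_group_frac = 0.1,
                               min_peak_frac = 0.2, min_dip_frac = 0.1) {
  values <- values[!is.na(values)]
  if (length(values) < 20)
    stop_coex("insufficient_samples", "need >= 20 values, got %d", length(values))
  if (stats::sd(values) == 0)
    stop_coex("constant_feature", "constant expression cannot be dichotomized")
  d <- stats::density(values, bw = bandwidth, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L      # interior local maxima
  peaks <- peaks[y[peaks] >= min_peak_frac * max(y)]
  threshold <- NA_real_
  method <- "median_fallback"
  if (length(peaks) >= 2) {
    top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
    between <- top2[1]:top2[2]
    dip <- between[which.min(y[between])]
    if (y[dip] <= (1 - min_dip_frac) * min(y[top2])) {
      cand <- d$x[dip]
      n_low <- sum(values <= cand)
      if (min(n_low, length(values) - n_low) >= min_group_frac * length(values) &&
          cand > min(values) && cand < max(values)) {
        threshold <- cand
        method <- "antimode"
      }
    }
  }
  if (method == "median_fallback") {
    threshold <- stats::median(values)
    if (threshold >= max(values)) threshold <- mean(range(values))
  }
  grp <- ifelse(values > threshold, "high", "low")
  if (!is.null(names(values))) names(grp) <- names(values)
  structure(list(feature_id = feature_id, threshold = threshold,
                 method = method, group_of = grp,
                 group_sizes = c(n_low = sum(grp == "low"),
                                 n_high = sum(grp == "high"))),
            class = "dichotomy_result")
}

#' @export
print.dichotomy_result <- function(x, ...) {
  cat(sprintf("<dichotomy %s: threshold %.4g (%s), n_low=%d n_high=%d>\n",
              x$feature_id, x$threshold, x$method,
              x$group_sizes["n_low"], x$group_sizes["n_high"]))
  invisible(x)
}

.check_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "time", "event") %in% names(records)))
  if (nrow(records) == 0) stop_coex("domain_error", "no survival records")
  if (any(records$time < 0)) stop_coex("domain_error", "negative survival time")
  records
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate: right-continuous, non-increasing, S(0) = 1. Ties
#' between events and censorings at the same time follow the standard
#' events-first convention.
#'
#' @param records data.frame with `sample_id`, `time`, `event` columns.
#' @return a `km_curve`: list with step-function knots `time` (starting at
#'   0), `surv`, plus `n_risk`, `n_event` per knot and the sample size `n`.
#' @export
km_curve <- function(records) {
  records <- .check_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  structure(list(time = c(0, fit$time), surv = c(1, fit$surv),
                 n_risk = c(nrow(records), fit$n.risk),
                 n_event = c(0, fit$n.event), n = nrow(records)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve: n=%d, %d knot(s), final S=%.3f>\n",
              x$n, length(x$time) - 1L, x$surv[length(x$surv)]))
  invisible(x)
}

#' Evaluate a KM curve at given times
#'
#' @param curve a [km_curve()].
#' @param t times.
#' @return survival probabilities S(t) (right-continuous step function).
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  curve$surv[pmax(idx, 1L)]
}

#' Restricted-mean survival time
#'
#' Area under the KM curve up to `tau` (default: last observed time).
#'
#' @param curve a [km_curve()].
#' @param tau truncation time.
#' @return restricted mean survival (same units as `time`).
#' @export
km_restricted_mean <- function(curve, tau = max(curve$time)) {
  knots <- c(curve$time[curve$time < tau], tau)
  s <- km_survival_at(curve, utils::head(knots, -1))
  sum(s * diff(knots))
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of the high- and low-expression groups: at
#' each distinct event time the expected events per group come from the
#' hypergeometric model, and the chi-squared statistic (1 df) is
#' (O1 - E1)^2 / V with the summed variance.
#'
#' @param records data.frame with `sample_id`, `time`, `event`.
#' @param group_of named vector mapping every `sample_id` to one of two group
#'   labels (e.g. `"high"`/`"low"`).
#' @return a `logrank_result`: `statistic`, `p_value`, `n` per group,
#'   `observed_events`, `expected_events` (both named by group).
#' @export
logrank_test <- function(records, group_of) {
  records <- .check_records(records)
  grp <- group_of[records$sample_id]
  if (anyNA(grp))
    stop_coex("domain_error", "unassigned sample(s): %s",
              records$sample_id[which(is.na(grp))[1]])
  grp <- factor(as.character(grp))
  if (nlevels(grp) != 2 || any(table(grp) == 0))
    stop_coex("domain_error", "log-rank needs exactly two non-empty groups")
  if (sum(records$event) == 0)
    stop_coex("domain_error", "no observed events")
  dat <- data.frame(time = records$time, event = records$event, grp = grp)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
  stat <- sd$chisq
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 n = stats::setNames(as.integer(table(grp)), levels(grp)),
                 observed_events = stats::setNames(sd$obs, levels(grp)),
                 expected_events = stats::setNames(sd$exp, levels(grp))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank: chisq=%.4g (1 df), p=%.3g; O=(%s) E=(%s)>\n",
              x$statistic, x$p_value,
              paste(sprintf("%.3g", x$observed_events), collapse = ", "),
              paste(sprintf("%.3g", x$expected_events), collapse = ", ")))
  invisible(x)
}

#' Expression-dichotomized survival screen
#'
#' For each feature: samples with both expression and survival data are split
#' at the antimode threshold, the two groups are compared by log-rank, and
#' `direction_of_benefit` records which group has the longer restricted-mean
#' survival (up to the last observed time).
#'
#' @param cohort an [expression_cohort()].
#' @param survival_records data.frame from [read_survival()].
#' @param features feature ids to screen (default: all).
#' @param min_group_frac forwarded to [antimode_threshold()].
#' @param alpha significance level used only for the `significant` flag.
#' @return data.frame with one row per screened feature: `feature_id`,
#'   `threshold`, `method`, `n_low`, `n_high`, `statistic`, `p_value`,
#'   `direction_of_benefit`, `significant`.
#' @export
survival_screen <- function(cohort, survival_records, features = NULL,
                            min_group_frac = 0.1, alpha = 0.05) {
  survival_records <- .check_records(survival_records)
  features <- features %||% cohort$features
  linked <- intersect(cohort$samples, survival_records$sample_id)
  if (length(linked) < 20)
    stop_coex("insufficient_samples",
              "only %d samples with both expression and survival (need >= 20)",
              length(linked))
  recs <- survival_records[match(linked, survival_records$sample_id), ]
  rows <- lapply(features, function(f) {
    vals <- cohort$values[f, linked]
    keep <- !is.na(vals)
    if (sum(keep) < 20) return(NULL)
    dich <- antimode_threshold(vals[keep], feature_id = f,
                               min_group_frac = min_group_frac)
    sub <- recs[keep, ]
    lr <- logrank_test(sub, dich$group_of)
    rm_low <- km_restricted_mean(km_curve(sub[dich$group_of[sub$sample_id] == "low", ]),
                                 tau = max(sub$time))
    rm_high <- km_restricted_mean(km_curve(sub[dich$group_of[sub$sample_id] == "high", ]),
                                  tau = max(sub$time))
    data.frame(feature_id = f, threshold = dich$threshold,
               method = dich$method,
               n_low = unname(dich$group_sizes["n_low"]),
               n_high = unname(dich$group_sizes["n_high"]),
               statistic = lr$statistic, p_value = lr$p_value,
               direction_of_benefit = if (rm_low >= rm_high) "low" else "high",
               significant = lr$p_value <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
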