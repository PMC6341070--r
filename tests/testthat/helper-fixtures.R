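# Shared helpers: small in-code fixtures written to temp files on demand.

toy_matrix <- function(n_feat = 3, n_samp = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(round(rnorm(n_feat * n_samp, 8, 2), 3), n_feat, n_samp,
              dimnames = list(paste0("g", seq_len(n_feat)),
                              paste0("s", seq_len(n_samp))))
  m
}

write_expr_tsv <- function(m, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# cohort with a seed feature, `n_corr` features at correlation rho and
# `n_null` independent features
corr_cohort <- function(n = 100, n_corr = 3, n_null = 3, rho = 0.6,
                        cohort_id = "c1", seed = 1) {
  set.seed(seed)
  s <- rnorm(n)
  vals <- rbind(SEED = s)
  if (n_corr > 0) {
    cm <- matrix(rho * rep(s, each = n_corr) + sqrt(1 - rho^2) * rnorm(n_corr * n),
                 n_corr, n, dimnames = list(paste0("corr", seq_len(n_corr)), NULL))
    vals <- rbind(vals, cm)
  }
  if (n_null > 0) {
    nm <- matrix(rnorm(n_null * n), n_null, n,
                 dimnames = list(paste0("null", seq_len(n_null)), NULL))
    vals <- rbind(vals, nm)
  }
  colnames(vals) <- sprintf("%s_s%03d", cohort_id, seq_len(n))
  expression_cohort(vals, cohort_id)
}

# association_table built directly from given stats (one cohort)
stats_table <- function(feature_id, p_value, direction = 1L,
                        adjusted_r2 = 0.2, cohort_id = "g1",
                        seed_id = "SEED", n = 100) {
  k <- length(feature_id)
  as_association_table(
    data.frame(feature_id = feature_id, cohort_id = cohort_id, n = n,
               p_value = p_value,
               coefficient = rep_len(direction, k) * 0.5,
               se = 0.1, adjusted_r2 = rep_len(adjusted_r2, k),
               stringsAsFactors = FALSE),
    seed_id = seed_id)
}

surv_records <- function(time, event, ids = sprintf("s%03d", seq_along(time))) {
  data.frame(sample_id = ids, time = time, event = as.logical(event),
             stringsAsFactors = FALSE)
}
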