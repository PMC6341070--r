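`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded operations never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Render a fraction as a percentage string
#'
#' Formats `numerator / denominator` as a percentage with two decimals, the
#' rendering used throughout consistency reports (e.g. 212/214 -> "99.07%").
#'
#' @param numerator,denominator counts.
#' @return character scalar like "99.07%"; "NA%" if the denominator is 0.
#' @examples
#' format_percent(212, 214)
#' @export
format_percent <- function(numerator, denominator) {
  if (denominator == 0) return("NA%")
  sprintf("%.2f%%", round(100 * numerator / denominator, 2))
}
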