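#' @keywords internal
"_PACKAGE"

# Seconds per (Julian) year; used to convert tabulated diffusivities
# from cm2/s to m2/yr.
SECONDS_PER_YEAR <- 365.25 * 86400

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never leak into (or depend on) global
#' state.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round to significant figures as printed
#'
#' Rounds `x` to `digits` significant figures. Used to compare computed
#' fluxes with values printed at 1 or 2 significant figures, so tests
#' compare like with like.
#'
#' @param x Numeric vector.
#' @param digits Significant figures (1 or 2 for all printed ledger values).
#' @return Numeric vector rounded to `digits` significant figures.
#' @export
#' @examples
#' round_sig(2.47e12, 2)  # 2.5e12
round_sig <- function(x, digits) {
  stopifnot(digits >= 1)
  signif(x, digits)
}

# Internal: stop() with call.=FALSE for cleaner messages
abort <- function(...) stop(..., call. = FALSE)
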