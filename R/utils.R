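#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package internals
#' do not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)   # force now: a random `seed` argument must be
                             # drawn before the caller's state is captured
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
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

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

stopifnot_prob_open <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop(sprintf("'%s' must lie in the open interval (0, 1)", name),
         call. = FALSE)
  invisible(as.numeric(x))
}

#' Round a fraction to an integer percentage
#'
#' Standard half-up rounding used in all percentage reports, so that branch
#' occupancies such as 4658/11930 and 7272/11930 print as 39% and 61%.
#'
#' @param frac numeric vector of fractions in \[0, 1\].
#' @return integer percentage vector.
#' @keywords internal
#' @noRd
pct_round <- function(frac) as.integer(floor(100 * frac + 0.5))
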