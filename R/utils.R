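# Internal helpers: seed management, validation, logging.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers never perturb the
#' caller's RNG stream. `seed = NULL` leaves the stream untouched.
#'
#' @param seed integer seed or NULL
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Counter-based split: the i-th child stream depends only on (seed, i), so
#' adding lineages/strains/stages never perturbs earlier ones. Result is kept
#' in [1, 2^31 - 2].
#'
#' @param seed master seed (integer)
#' @param index counter (integer >= 0); may be a vector
#' @return integer seed(s)
#' @keywords internal
split_seed <- function(seed, index) {
  m <- 2147483647               # 2^31 - 1, Mersenne prime modulus
  s <- (as.double(seed) %% m + 1)
  ((s * 48271 + as.double(index) * 16807) %% (m - 1)) + 1
}

# fail-fast scalar checks -----------------------------------------------------

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %s", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}

#' Stage-labelled message to stderr
#' @keywords internal
am_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
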