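#' Derive child seeds from a master seed
#'
#' Every stochastic routine in the package takes an integer seed. When one
#' routine must perform several independent stochastic sub-steps (e.g. an
#' ensemble of samples), it derives one child seed per sub-step with this
#' helper so that a single master seed reproduces the whole run.
#'
#' @param seed integer master seed.
#' @param n number of child seeds to derive.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package routines do
#' not disturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the stream alone.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# canonical "a|b" key for an unordered pair of word ids
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
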