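#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; the tabulated percentages and
#' true-positive rates in this package use commercial rounding (half away
#' from zero), e.g. `100 * 649 / 3138 = 20.681...` prints as `20.68` and
#' `22/26 = 0.84615...` prints as `0.85`.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Path to a fixture shipped with the package
#'
#' @param file file name under `extdata/`.
#' @return absolute path.
#' @export
jamunet_extdata <- function(file) {
  p <- system.file("extdata", file, package = "jamunet", mustWork = FALSE)
  if (!nzchar(p)) stop("no such fixture: ", file)
  p
}
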