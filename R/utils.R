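#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (0.005 -> 0.01), as used for all
#' percentage reporting in this package. Base \code{round()} rounds half to
#' even, which does not reproduce conventionally printed table percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to \code{digits} places.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by a few ulp so that values like 45.095 stored as 45.094999..9
  # (a pure representation artifact) still round up
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# coerce a single sequence argument to an upper-case character string
as_seq_chr <- function(x) {
  if (is(x, "DNAString") || is(x, "BString")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

stop_input <- function(...) stop(..., call. = FALSE)
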