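# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so 0.15 -> 0.2 at one
#' decimal), matching how percentages are conventionally printed in ecological
#' survey tables. Base [round()] uses round-half-to-even instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(10.215, -10.215, 16.523), 1)
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  m <- 10^digits
  # nudge by an epsilon scaled to the value so that numbers intended to be
  # exact ties (but stored just below .5 in binary) still round up
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# stop() with a consistent error class for input validation problems
stop_validation <- function(...) {
  stop(structure(class = c("parascreen_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("parascreen_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
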