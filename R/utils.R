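`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-component seed from a global seed
#'
#' One global seed is expanded deterministically into independent seeds for
#' training, simulation and hierarchy randomisation, so a single `--seed`
#' reproduces a whole run. The result always fits a 32-bit integer.
#'
#' @param seed integer global seed.
#' @param index integer component index (any small integer).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  s <- (abs(as.double(seed)) %% 2147480000) * 69069 + as.double(index) * 1013904223
  as.integer(s %% 2147483629)
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

row_norms <- function(x) sqrt(rowSums(x * x))

l2_normalize_rows <- function(x) {
  n <- row_norms(x)
  if (any(n == 0)) stop("cannot L2-normalise rows with zero norm (rows: ",
                        paste(which(n == 0), collapse = ", "), ")")
  x / n
}

# dense integer ids in order of first appearance, for reproducible reports
densify_ids <- function(x) match(x, unique(x))

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number")
  invisible(x)
}
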