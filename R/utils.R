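#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize gene/TF symbols
#'
#' All identifiers are matched case-sensitively after a single upper-casing
#' pass at load time, so `Pax5`, `PAX5` and `pax5` refer to the same gene.
#'
#' @param x character vector of symbols.
#' @return upper-cased, whitespace-trimmed character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# stop() with sprintf-style formatting, no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    abort("'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}
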