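#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor lm coef confint rnorm rgamma predict sd aggregate
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed from a master seed and a sample key
#'
#' Stable string hash (FNV-1a style, folded into 31 bits) so that every
#' (treatment, replicate, day) gets its own reproducible RNG stream and
#' different master seeds give unrelated streams.
#'
#' @param seed master seed (integer).
#' @param ... key components (coerced to character).
#' @return an integer in [0, 2^31 - 1].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  as.integer(h %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x > 0
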