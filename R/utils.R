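`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One RNG stream per operation: a sub-seed derived from (seed, label) so each
# generator output is individually reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, what) {
  u <- utf8ToInt(what)
  h <- sum(u * seq_along(u) * 1009)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483646) + 1L
}

#' Parse a size string with K/M/G suffix
#'
#' Accepts a plain number (bytes) or a number with a binary suffix, e.g.
#' `"500M"` = 500 * 2^20 bytes.
#'
#' @param x Size as a number or string such as `"64M"`.
#' @return Size in bytes (numeric scalar).
#' @examples
#' parse_size("1K")
#' parse_size("500M") / 2^20
#' @export
parse_size <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^\\s*([0-9.]+)\\s*([KkMmGg]?)[Bb]?\\s*$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse size '", x, "'")
  mult <- switch(toupper(m[3]), K = 2^10, M = 2^20, G = 2^30, 1)
  as.numeric(m[2]) * mult
}
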