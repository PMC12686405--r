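#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm pt qt rnorm rpois rbinom rlnorm runif sd
#'   quantile pnorm
#' @importFrom utils read.delim write.table head
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators never perturb each other.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive an independent 31-bit stream seed from a base seed and a stream
# name, so each generated table has its own reproducible stream.
stream_seed <- function(seed, stream) {
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 31 + b) %% 2147483647L
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

# FNV-1a style hash of a deparsed object; used to stamp derived tables with
# a short provenance id for the configuration that produced them.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single non-missing number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stopf("`%s` = %g is outside its allowed range %s%g, %g%s", name, x,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]")
  }
  invisible(x)
}
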