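#' @importFrom rlang %||% .data
#' @importFrom stats rbinom rpois runif qlnorm plnorm
#' @importFrom utils head
NULL

# Percent rounded half-up to one decimal, matching how clinical validation
# studies usually print proportions (plain round() would round half to even).
pct1 <- function(p) {
  sign(p) * floor(abs(p) * 1000 + 0.5) / 10
}

# Derive an independent 32-bit seed for a named RNG stream from a global
# seed, so that e.g. toggling deletion injection does not perturb the
# patient or event streams.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483562) + 1L
}

# Run code under a stream-specific seed without disturbing the caller's RNG.
with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  force(code)
}

# Random Date vector drawn uniformly within [from, to].
runif_date <- function(n, from, to) {
  from <- as.Date(from)
  to <- as.Date(to)
  from + floor(runif(n, 0, as.numeric(to - from) + 1))
}

norm_code <- function(x) toupper(trimws(x))

# Whitespace/number normalization used when comparing field values in the
# congruity audit ("coherence").
norm_field <- function(x) {
  if (is.numeric(x)) {
    return(format(round(as.numeric(x), 6), trim = TRUE, scientific = FALSE))
  }
  gsub("\\s+", " ", trimws(as.character(x)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
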