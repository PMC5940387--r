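#' Derive independent child seeds from a single master seed
#'
#' Pipeline stages each receive their own seed so a stage can be re-run in
#' isolation and still reproduce its output. The derivation is a fixed
#' function of the master seed only.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    .stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

.check_frac <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && x <= hi
  if (!ok) .stopf("'%s' must be in %s%g, %g]", name, if (lo_open) "(" else "[", lo, hi)
  as.numeric(x)
}
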