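#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats setNames rbinom runif rnorm
NULL

DNA_BASES <- c("A", "C", "G", "T")

stop_param <- function(msg, ...) {
  abort(msg, class = c("satlib_param_error", "satlib_error"), ...)
}

stop_data <- function(msg, stage = NULL, ...) {
  abort(msg, class = c("satlib_data_error", "satlib_error"), stage = stage, ...)
}

assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  if (length(x) == 0L || any(is.na(x)) || any(nchar(x) == 0L)) {
    stop_param(sprintf("every %s must be a non-empty DNA string", what))
  }
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop_param(sprintf(
      "%s contains characters outside the %s alphabet",
      what, if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}"
    ))
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  assert_dna(x)
  rev_each <- vapply(strsplit(x, "", fixed = TRUE),
                     function(s) paste(rev(s), collapse = ""), character(1))
  chartr("ACGTN", "TGCAN", rev_each)
}

#' Random DNA strings
#'
#' @param n Number of strings.
#' @param length Length of each string.
#' @param seed Optional integer seed.
#' @return Character vector of `n` DNA strings.
#' @export
random_dna <- function(n, length, seed = NULL) {
  if (n < 0 || length < 1) stop_param("n must be >= 0 and length >= 1")
  draw <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

## Stage seeds are derived from one master seed by fixed offsets so that a
## single integer reproduces a whole pipeline run. Kept well below 2^31.
derive_seed <- function(master, stage) {
  offsets <- c(
    library = 11L, amplify = 23L, array = 37L, reads = 53L,
    subsample = 71L, pipeline = 97L
  )
  off <- offsets[[stage]] %||% stop_param(sprintf("unknown stage '%s'", stage))
  as.integer((as.numeric(master) * 1000003 + off * 10007) %% 2147483545) + 1L
}

rotate_string <- function(x, k) {
  L <- nchar(x)
  k <- ((k %% L) + L) %% L
  if (k == 0L) return(x)
  paste0(substr(x, k + 1L, L), substr(x, 1L, k))
}

all_rotations <- function(x) {
  L <- nchar(x)
  y <- paste0(x, x)
  substring(y, seq_len(L), seq_len(L) + L - 1L)
}

## Reporting convention for diversity statistics: published tables truncate
## (not round) at the printed precision, e.g. Hd = 0.6667 is printed as 0.66
## and 0.9883 as 0.98. trunc_digits() reproduces that convention.
#' Truncate a value at a fixed number of decimals
#'
#' Truncates (rounds toward zero) rather than rounds, matching the convention
#' used in published satellite-DNA diversity tables where e.g. a haplotype
#' diversity of 2/3 is reported as 0.66.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places kept.
#' @return Numeric vector truncated at `digits` decimals.
#' @export
#' @examples
#' trunc_digits(2 / 3, 2) # 0.66
trunc_digits <- function(x, digits = 2) {
  scale <- 10^digits
  trunc(x * scale + sign(x) * 1e-9) / scale
}
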