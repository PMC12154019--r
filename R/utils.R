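## small shared helpers; nothing here is exported

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported ranges in this package
#' use the convention that -1.085 rounds to -1.09 (half away from zero),
#' so ties are resolved away from zero.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_away(-1.085, 2)  # -1.09
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## evaluate `code` under set.seed(seed) without disturbing the caller's RNG
## state; seed = NULL leaves the RNG alone entirely
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## nucleotide bitmasks: A=1 C=2 G=4 T=8; IUPAC codes are unions.
## Two bases are compatible iff their masks intersect.
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

seq_to_bits <- function(x) {
  b <- IUPAC_BITS[strsplit(toupper(x), "", fixed = TRUE)[[1]]]
  if (anyNA(b)) stop("sequence contains non-IUPAC characters", call. = FALSE)
  unname(b)
}

#' Reverse complement of a nucleotide string
#'
#' Accepts IUPAC ambiguity codes (needed for degenerate primers).
#'
#' @param x a single nucleotide string.
#' @return the reverse complement as a string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

assert_acgt <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
  if (grepl("[^ACGTacgt]", x))
    stop(what, " contains characters other than A/C/G/T", call. = FALSE)
  invisible(toupper(x))
}

## coerce DNAStringSet / character to character, keeping names
as_named_chr <- function(x) {
  if (is.character(x)) return(x)
  stats::setNames(as.character(x), names(x))
}

## collapse a character vector of flags to a single ';'-joined string
join_flags <- function(flags) {
  if (length(flags) == 0L) "" else paste(unique(flags), collapse = ";")
}
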