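#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rbinom rnbinom rlnorm runif sd p.adjust t.test
#'   aggregate ave quantile setNames
#' @importFrom utils read.delim write.table head packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Display rounding for percentages: `round()` in R rounds half to even
#' (62.5 -> 62), whereas summary lines in proteomics reports conventionally
#' round half up (62.5 -> 63).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

assert_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop(what, " must be a single non-empty character string", call. = FALSE)
  }
  bad <- setdiff(strsplit(sequence, "")[[1]], STANDARD_AA)
  if (length(bad) > 0L) {
    stop(what, " contains non-standard residues: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(name, " must be an integer >= ", min, call. = FALSE)
  }
  invisible(x)
}

# Derived per-stage RNG seeds keep stages independently reproducible while a
# single top-level seed governs the whole run. Offsets are fixed per stage;
# the modulus keeps seeds inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 99991) %% 2147483647)
}
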