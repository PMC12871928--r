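# Internal helpers shared across modules.

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Smallest exact period of a string
#'
#' Returns the smallest p such that `s` is (a prefix of) a repetition of its
#' first p characters. Used to reduce repeat units to their primitive period
#' and to derive amino-acid unit lengths for planted repeats.
#'
#' @param s A single character string.
#' @return Integer period, between 1 and `nchar(s)`.
#' @keywords internal
#' @noRd
.exactPeriod <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n <= 1L) return(max(n, 1L))
  for (p in seq_len(n - 1L)) {
    if (all(ch[(p + 1L):n] == ch[seq_len(n - p)])) return(p)
  }
  n
}

# TRUE if the string is a whole-number repetition of a shorter string
# (i.e. the repeat unit is reducible). Only proper divisors of the length
# qualify: "LKL" is primitive even though it has weak period 2.
.isStringPeriodic <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(FALSE)
  for (d in seq_len(n %/% 2L)) {
    if (n %% d != 0L) next
    if (identical(strrep(substr(s, 1L, d), n %/% d), s)) return(TRUE)
  }
  FALSE
}

.lcm <- function(a, b) {
  g <- function(x, y) if (y == 0L) x else g(y, x %% y)
  as.integer(a / g(a, b) * b)
}

# stopifnot with a formatted message
.check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# Split a string into a character vector of single letters.
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# Coerce a DNAStringSet or character vector to a named character vector
# (plain as.character() would strip the names of a character vector).
.namedSeqs <- function(x) {
  if (is.character(x)) x else stats::setNames(as.character(x), names(x))
}

# Majority letter with alphabetical tie-break.
.majorityLetter <- function(letters) {
  tab <- table(letters)
  cand <- names(tab)[tab == max(tab)]
  sort(cand)[1L]
}
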