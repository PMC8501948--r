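# Internal string/DNA helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors (ACGT only).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(if (is.na(s)) NA_character_ else "")
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
  }, "", USE.NAMES = FALSE)
}

is_dna <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) && grepl("^[ACGT]*$", x)
}

assert_dna <- function(x, what, allow_empty = FALSE) {
  if (!is_dna(x)) {
    stop_pegkit(sprintf("%s must be a DNA string over {A,C,G,T}, got %s",
                        what, deparse(substr(as.character(x)[1], 1, 30))),
                "pegkit_validation_error")
  }
  if (!allow_empty && nchar(x) == 0L) {
    stop_pegkit(sprintf("%s must be non-empty", what), "pegkit_validation_error")
  }
  invisible(x)
}

assert_scalar_int <- function(x, what, min = -Inf, max = Inf) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != round(x) ||
      x < min || x > max) {
    stop_pegkit(sprintf("%s must be a single integer in [%s, %s]", what, min, max),
                "pegkit_validation_error")
  }
  invisible(as.integer(x))
}

# Classed condition so callers can branch on error type.
stop_pegkit <- function(msg, class) {
  stop(structure(
    class = c(class, "pegkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

warn_pegkit <- function(msg, class) {
  warning(structure(
    class = c(class, "pegkit_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# substring with 0-based half-open coordinates [from, to)
substr0 <- function(x, from, to) {
  if (to <= from) return("")
  substr(x, from + 1L, to)
}

# sample one element from a vector, safe for length-1 vectors
sample1 <- function(v) v[sample.int(length(v), 1L)]
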