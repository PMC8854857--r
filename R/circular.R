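# Circular coordinate helpers. All user-facing coordinates are 1-based
# inclusive; wrapping intervals are always represented by splitting, never by
# coordinates outside [1, L].

#' Map an arbitrary integer offset onto the circle
#'
#' @param pos integer vector of (possibly out-of-range) 1-based positions.
#' @param len genome length in bp.
#' @return positions folded into `[1, len]`.
#' @keywords internal
circ_pos <- function(pos, len) {
  ((pos - 1L) %% len) + 1L
}

#' Extract a (possibly wrapping) interval from a circular sequence
#'
#' @param seq nucleotide string.
#' @param start,end 1-based inclusive bounds; `end < start` means the
#'   interval wraps through the origin.
#' @return the interval as a character scalar.
#' @keywords internal
circ_substr <- function(seq, start, end) {
  len <- nchar(seq)
  stopifnot(start >= 1L, start <= len, end >= 1L, end <= len)
  if (end >= start) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, len), substr(seq, 1L, end))
  }
}

#' Rotate a circular sequence so that `new_start` becomes position 1
#' @keywords internal
rotate_seq <- function(seq, new_start) {
  len <- nchar(seq)
  new_start <- circ_pos(new_start, len)
  if (new_start == 1L) return(seq)
  paste0(substr(seq, new_start, len), substr(seq, 1L, new_start - 1L))
}

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that keeps the
#' character-vector interface used throughout the package.
#' @param seq nucleotide string (IUPAC codes accepted).
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Split a possibly wrapping circular interval into linear pieces
#'
#' @return a matrix with columns `start`, `end`; one row for a non-wrapping
#'   interval, two rows when the interval crosses the origin.
#' @keywords internal
split_wrap <- function(start, end, len) {
  if (end >= start) {
    cbind(start = start, end = end)
  } else {
    cbind(start = c(start, 1L), end = c(len, end))
  }
}

#' Length of a circular interval
#' @keywords internal
circ_len <- function(start, end, len) {
  if (end >= start) end - start + 1L else len - start + 1L + end
}

#' Circular midpoint of an interval given its start and length
#' @keywords internal
circ_mid <- function(start, span_len, len) {
  circ_pos(start + (span_len - 1L) %/% 2L, len)
}
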