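#' Canonical unordered interaction keys
#'
#' A protein pair is stored under a single canonical key so that evidence for
#' (x, y) and (y, x) accumulates on the same interaction. Keys are the two
#' accessions in lexicographic order joined by `"|"`. Self-pairs (x == x) are
#' legal and can be detected with [is_self_key()]; downstream analyses may
#' filter them but the integration layer never silently drops evidence.
#'
#' @param x,y Character vectors of protein identifiers (recycled to a common
#'   length). Identifiers must be non-empty and contain no whitespace or `"|"`.
#' @return For `canonical_pair()`, a character vector of canonical keys.
#' @examples
#' canonical_pair("Q1", "P1")            # "P1|Q1"
#' canonical_pair("P1", "Q1")            # identical key
#' is_self_key(canonical_pair("P1", "P1"))
#' @export
canonical_pair <- function(x, y) {
  x <- as.character(x)
  y <- as.character(y)
  if (length(x) != length(y)) {
    n <- max(length(x), length(y))
    x <- rep_len(x, n)
    y <- rep_len(y, n)
  }
  check_protein_id(c(x, y))
  ifelse(x <= y, paste(x, y, sep = "|"), paste(y, x, sep = "|"))
}

check_protein_id <- function(id) {
  bad <- is.na(id) | !nzchar(id) | grepl("[[:space:]|]", id)
  if (any(bad)) {
    stop("invalid protein identifier(s): must be non-empty, without ",
         "whitespace or '|' (first offender: ",
         deparse(id[bad][1]), ")", call. = FALSE)
  }
  invisible(id)
}

#' @rdname canonical_pair
#' @param key Character vector of canonical keys.
#' @return For `is_self_key()`, a logical vector flagging self-interactions;
#'   for `key_parts()`, a data frame with columns `a`, `b` and `self`.
#' @export
is_self_key <- function(key) {
  p <- key_parts(key)
  p$self
}

#' @rdname canonical_pair
#' @export
key_parts <- function(key) {
  parts <- strsplit(as.character(key), "|", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (!all(ok)) {
    stop("malformed interaction key: ", deparse(key[!ok][1]), call. = FALSE)
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  data.frame(a = a, b = b, self = a == b, stringsAsFactors = FALSE)
}

#' Proteins participating in a set of interaction keys
#'
#' @param keys Character vector of canonical keys.
#' @return Sorted character vector of distinct protein accessions.
#' @export
key_proteins <- function(keys) {
  if (length(keys) == 0L) return(character(0))
  p <- key_parts(keys)
  sort(unique(c(p$a, p$b)))
}
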