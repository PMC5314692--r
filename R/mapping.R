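#' Identifier mapping to canonical reviewed accessions
#'
#' Raw tokens (gene symbols, secondary accessions, vendor identifiers) are
#' resolved to one canonical reviewed accession each. Only rows flagged as
#' reviewed are kept, and raw tokens that still resolve to more than one
#' accession are dropped as ambiguous (their count is retained on the
#' returned object). Matching is exact first, then case-insensitive, so gene
#' symbols in mixed case resolve while accessions keep exact semantics.
#'
#' @param path Path to a tab-separated mapping file with columns `raw_id`,
#'   `canonical_accession` and `reviewed` (Y/N). Lines starting with `#` are
#'   comments.
#' @return An object of class `id_mapping`: a lookup environment plus
#'   bookkeeping (`n_ambiguous` dropped tokens).
#' @export
read_mapping <- function(path) {
  tab <- read_tsv_raw(path, c("raw_id", "canonical_accession", "reviewed"))
  id_mapping(tab)
}

#' @rdname read_mapping
#' @param table Data frame with the three mapping columns (alternative to a
#'   file path).
#' @export
id_mapping <- function(table) {
  stopifnot(all(c("raw_id", "canonical_accession", "reviewed") %in%
                  names(table)))
  tab <- table[toupper(trimws(table$reviewed)) == "Y", , drop = FALSE]
  tab$raw_id <- trimws(tab$raw_id)
  tab$canonical_accession <- trimws(tab$canonical_accession)
  tab <- unique(tab[, c("raw_id", "canonical_accession")])
  n_raw <- table(tab$raw_id)
  ambiguous <- names(n_raw)[n_raw > 1L]
  tab <- tab[!(tab$raw_id %in% ambiguous), , drop = FALSE]
  lut <- new.env(parent = emptyenv(), size = max(16L, nrow(tab)))
  for (i in seq_len(nrow(tab))) {
    assign(tab$raw_id[i], tab$canonical_accession[i], envir = lut)
  }
  lut_upper <- new.env(parent = emptyenv(), size = max(16L, nrow(tab)))
  # case-insensitive fallback: skip raw tokens whose upper-casing collides
  up <- toupper(tab$raw_id)
  keep <- up %in% names(which(table(up) == 1L))
  for (i in which(keep)) {
    assign(up[i], tab$canonical_accession[i], envir = lut_upper)
  }
  structure(
    list(exact = lut, upper = lut_upper, n_ambiguous = length(ambiguous)),
    class = "id_mapping"
  )
}

#' Map raw identifiers to canonical accessions
#'
#' @param raw Character vector of raw tokens.
#' @param mapping An `id_mapping` object.
#' @return Character vector of canonical accessions, `NA` where the token is
#'   unmapped. Absence is a value, not an error; callers tally `NA`s for
#'   reporting.
#' @export
map_identifier <- function(raw, mapping) {
  stopifnot(inherits(mapping, "id_mapping"))
  raw <- trimws(as.character(raw))
  out <- rep(NA_character_, length(raw))
  for (i in seq_along(raw)) {
    hit <- get0(raw[i], envir = mapping$exact, inherits = FALSE)
    if (is.null(hit)) {
      hit <- get0(toupper(raw[i]), envir = mapping$upper, inherits = FALSE)
    }
    if (!is.null(hit)) out[i] <- hit
  }
  out
}

#' A mapping that passes identifiers through unchanged
#'
#' Convenience for fixtures whose identifiers are already canonical.
#'
#' @param ids Character vector of accessions to accept.
#' @return An `id_mapping`.
#' @export
identity_mapping <- function(ids) {
  id_mapping(data.frame(raw_id = ids, canonical_accession = ids,
                        reviewed = "Y", stringsAsFactors = FALSE))
}

#' @export
print.id_mapping <- function(x, ...) {
  cat("<id_mapping> ", length(ls(x$exact)), " reviewed tokens; ",
      x$n_ambiguous, " ambiguous tokens dropped\n", sep = "")
  invisible(x)
}
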