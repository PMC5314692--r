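#' Merge evidence sources into one interactome
#'
#' Union semantics: every distinct canonical key present in any source is
#' kept, annotated with the set of sources contributing it.
#'
#' @param tables List of `source_table` objects.
#' @return Data frame with columns `key` and `sources` (semicolon-joined,
#'   sorted source names), one row per distinct key, sorted by key.
#' @export
merge_sources <- function(tables) {
  if (inherits(tables, "source_table")) tables <- list(tables)
  ev <- do.call(rbind, lapply(tables, function(t)
    as.data.frame(t)[, c("key", "source"), drop = FALSE]))
  if (is.null(ev) || nrow(ev) == 0L) {
    return(data.frame(key = character(0), sources = character(0),
                      stringsAsFactors = FALSE))
  }
  srcs <- tapply(ev$source, ev$key, function(s)
    paste(sort(unique(s)), collapse = ";"))
  data.frame(key = names(srcs), sources = as.character(srcs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise coverage overlap ratios between sources
#'
#' For sources i and j with distinct-pair sets of sizes `N_i`, `N_j` and
#' overlap count `O_ij`, the coverage overlap ratio is
#' \deqn{r_{i,j} = 100 \cdot O_{i,j} / N_i}
#' i.e. the percentage of source i's pairs also present in source j. The
#' matrix is asymmetric (rows are normalized by the row source's size); the
#' diagonal is 100 for non-empty sources. An empty source yields `NA` ratios
#' rather than a division by zero.
#'
#' @param tables List of `source_table` objects.
#' @return An `overlap_matrix` object: list with `sources`, integer matrices
#'   `counts` (O_ij) and `sizes` (N_i), and the percentage matrix `ratios`.
#' @export
overlap_ratio_matrix <- function(tables) {
  if (inherits(tables, "source_table")) tables <- list(tables)
  key_sets <- lapply(tables, function(t) unique(as.data.frame(t)$key))
  src <- vapply(tables, function(t) attr(t, "source_name"), character(1))
  n <- length(key_sets)
  sizes <- vapply(key_sets, length, integer(1))
  counts <- matrix(0L, n, n, dimnames = list(src, src))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      counts[i, j] <- length(intersect(key_sets[[i]], key_sets[[j]]))
    }
  }
  ratios <- 100 * counts / sizes  # divides row i by N_i (column recycling ok)
  ratios <- matrix(ratios, n, n, dimnames = list(src, src))
  ratios[sizes == 0L, ] <- NA_real_
  structure(list(sources = src, sizes = setNames(sizes, src),
                 counts = counts, ratios = ratios),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, digits = 2, ...) {
  cat("<overlap_matrix> coverage overlap (%), rows normalized by row size\n")
  print(round(x$ratios, digits))
  invisible(x)
}

#' Global data quality score against a gold standard
#'
#' The q-score of a database is the plain overlap count between its pair set
#' and the gold-standard pair set.
#'
#' @param db Character vector of canonical keys (the database).
#' @param gold Character vector of canonical keys (the gold standard).
#' @return Integer overlap count.
#' @export
q_score <- function(db, gold) {
  length(intersect(unique(db), unique(gold)))
}
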