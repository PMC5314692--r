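## Readers and writers for the flat-file dialects the toolkit consumes:
## evidence TSVs, pair lists, GMT gene sets, GAF-lite annotations with a DAG
## edge list, and the scored-interaction table. The dialect is deliberately
## plain: UTF-8, tab-separated, '#' comment lines, no quoting.

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

read_tsv_raw <- function(path, col_names) {
  lf <- read_tsv_lines(path)
  if (length(lf$lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(col_names)),
                                  col_names), stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lf$lines, "\t", fixed = TRUE)
  short <- lengths(fields) < length(col_names)
  if (any(short)) {
    stop("malformed row at line ", lf$lineno[short][1], " of '", path,
         "': expected at least ", length(col_names), " columns", call. = FALSE)
  }
  out <- lapply(seq_along(col_names),
                function(j) vapply(fields, `[[`, character(1), j))
  names(out) <- col_names
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Reliability configuration for evidence platforms
#'
#' Each experimental or computational platform carries a reliability index in
#' [0, 1]: the configured probability that an interaction reported by that
#' platform alone reflects a direct physical interaction. The shipped
#' defaults are illustrative, ordered the way the field usually ranks
#' platform trustworthiness; they are configuration, not estimates.
#'
#' @param values Named numeric vector, platform token to reliability in
#'   [0, 1].
#' @param fallback Reliability used for platforms absent from `values`.
#' @return A `reliability_config` object.
#' @export
reliability_config <- function(values = default_reliability(),
                               fallback = 0.2) {
  values <- unlist(values)
  if (length(values) && (is.null(names(values)) || any(!nzchar(names(values)))))
    stop("reliability values must be named by platform", call. = FALSE)
  if (any(values < 0 | values > 1) || fallback < 0 || fallback > 1)
    stop("reliability indices must lie in [0, 1]", call. = FALSE)
  structure(list(values = values, fallback = fallback),
            class = "reliability_config")
}

#' @rdname reliability_config
#' @export
default_reliability <- function() {
  c(curated_literature   = 0.90,
    affinity_purification = 0.70,
    yeast_two_hybrid     = 0.50,
    co_expression        = 0.30,
    text_mining          = 0.20)
}

#' @rdname reliability_config
#' @param platform Character vector of platform tokens.
#' @param config A `reliability_config`.
#' @export
platform_reliability <- function(platform, config) {
  stopifnot(inherits(config, "reliability_config"))
  out <- unname(config$values[platform])
  out[is.na(out)] <- config$fallback
  out
}

#' @rdname reliability_config
#' @param path `key=value` text file (or JSON object) mapping platform to
#'   reliability; an optional `fallback` key sets the default.
#' @export
read_reliability_config <- function(path, fallback = 0.2) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("^\\s*\\{", first)) {
    vals <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    lf <- read_tsv_lines(path)
    kv <- strsplit(lf$lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("malformed reliability line ", lf$lineno[bad][1],
                       " in '", path, "'", call. = FALSE)
    vals <- setNames(as.numeric(trimws(vapply(kv, `[[`, character(1), 2L))),
                     trimws(vapply(kv, `[[`, character(1), 1L)))
  }
  if ("fallback" %in% names(vals)) {
    fallback <- unname(vals[["fallback"]])
    vals <- vals[names(vals) != "fallback"]
  }
  reliability_config(vals, fallback = fallback)
}

#' Read one source's evidence table
#'
#' Accepts a TSV with at least two identifier columns, optionally a platform
#' column and a per-platform score column (in that order). Rows whose
#' identifiers both map become evidence records; rows with unmappable
#' identifiers are counted and skipped. A missing score column falls back to
#' the configured platform reliability; a missing platform column labels all
#' rows with the source name.
#'
#' @param path TSV file path.
#' @param source_name Token naming the source database.
#' @param mapping An `id_mapping` (see [read_mapping()]).
#' @param reliability A `reliability_config` used when the file has no score
#'   column.
#' @return A `source_table`: data frame with columns `key`, `a`, `b`,
#'   `source`, `platform`, `s_i`, plus attributes `source_name` and
#'   `n_unmapped`.
#' @export
read_source_table <- function(path, source_name, mapping,
                              reliability = reliability_config()) {
  lf <- read_tsv_lines(path)
  fields <- strsplit(lf$lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 2L
  if (any(short)) {
    stop("malformed row at line ", lf$lineno[short][1], " of '", path,
         "': expected at least 2 columns", call. = FALSE)
  }
  raw_a <- vapply(fields, `[[`, character(1), 1L)
  raw_b <- vapply(fields, `[[`, character(1), 2L)
  platform <- vapply(fields, function(f)
    if (length(f) >= 3L && nzchar(f[3])) f[3] else source_name, character(1))
  score <- vapply(fields, function(f)
    if (length(f) >= 4L && nzchar(f[4])) as.numeric(f[4]) else NA_real_,
    numeric(1))
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    stop("score outside [0, 1] in '", path, "'", call. = FALSE)
  }
  a <- map_identifier(raw_a, mapping)
  b <- map_identifier(raw_b, mapping)
  ok <- !is.na(a) & !is.na(b)
  s_i <- ifelse(is.na(score), platform_reliability(platform, reliability),
                score)
  source_table(
    data.frame(key = canonical_pair(a[ok], b[ok]),
               a = pmin(a[ok], b[ok]), b = pmax(a[ok], b[ok]),
               source = source_name, platform = platform[ok],
               s_i = s_i[ok], stringsAsFactors = FALSE),
    source_name = source_name, n_unmapped = sum(!ok)
  )
}

#' @rdname read_source_table
#' @param records Data frame of evidence records (columns `key`, `a`, `b`,
#'   `source`, `platform`, `s_i`).
#' @param n_unmapped Count of skipped rows with unmappable identifiers.
#' @export
source_table <- function(records, source_name, n_unmapped = 0L) {
  need <- c("key", "a", "b", "source", "platform", "s_i")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) && any(records$s_i < 0 | records$s_i > 1))
    stop("evidence scores must lie in [0, 1]", call. = FALSE)
  if (nrow(records)) records$source <- source_name
  structure(records[, need, drop = FALSE], source_name = source_name,
            n_unmapped = as.integer(n_unmapped),
            class = c("source_table", "data.frame"))
}

#' @export
print.source_table <- function(x, ...) {
  cat("<source_table> '", attr(x, "source_name"), "': ", nrow(x),
      " evidence records over ", length(unique(x$key)), " pairs (",
      attr(x, "n_unmapped"), " unmapped rows skipped)\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  invisible(x)
}

#' Read a reference pair list (gold standard or negative set)
#'
#' @inheritParams read_source_table
#' @return Sorted character vector of distinct canonical keys.
#' @export
read_pair_list <- function(path, mapping) {
  lf <- read_tsv_lines(path)
  if (length(lf$lines) == 0L) return(character(0))
  fields <- strsplit(lf$lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 2L
  if (any(short)) {
    stop("malformed row at line ", lf$lineno[short][1], " of '", path,
         "': expected 2 columns", call. = FALSE)
  }
  a <- map_identifier(vapply(fields, `[[`, character(1), 1L), mapping)
  b <- map_identifier(vapply(fields, `[[`, character(1), 2L), mapping)
  ok <- !is.na(a) & !is.na(b)
  sort(unique(canonical_pair(a[ok], b[ok])))
}

write_pair_list <- function(keys, path) {
  p <- key_parts(keys)
  writeLines(paste(p$a, p$b, sep = "\t"), path)
  invisible(path)
}

#' Read curated gene sets in GMT format
#'
#' Standard MSigDB-style GMT: one set per line, `name<TAB>description<TAB>`
#' members. Members are deduplicated within a line.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set members).
#' @export
read_gmt <- function(path) {
  lf <- read_tsv_lines(path)
  fields <- strsplit(lf$lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("malformed GMT line ", lf$lineno[short][1], " of '", path,
         "': expected name, description and at least one member",
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

write_gmt <- function(sets, path, description = "synthetic") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a functional annotation corpus (GAF-lite plus ontology DAG)
#'
#' The annotation file is a two-column gene-to-term TSV; the DAG file lists
#' `child<TAB>parent<TAB>namespace` edges (namespaces such as BP and MF form
#' disjoint sub-ontologies). Annotations are propagated to all ancestors at
#' load time and each term's information content is precomputed as
#' `-log(f)`, `f` being the fraction of annotated genes carrying the term
#' after propagation.
#'
#' @param gaf_path Gene-to-term TSV path.
#' @param dag_path DAG edge-list TSV path.
#' @return A `go_corpus`: per-namespace gene term sets (direct and
#'   propagated), ancestor closures, and IC values.
#' @export
read_annotations <- function(gaf_path, dag_path) {
  gaf <- read_tsv_raw(gaf_path, c("gene", "term"))
  dag <- read_tsv_raw(dag_path, c("child", "parent", "namespace"))
  build_corpus(gaf, dag)
}

#' @rdname read_annotations
#' @param gaf Data frame with columns `gene`, `term`.
#' @param dag Data frame with columns `child`, `parent`, `namespace`.
#' @export
build_corpus <- function(gaf, dag) {
  namespaces <- sort(unique(dag$namespace))
  out <- list()
  for (ns in namespaces) {
    edges <- dag[dag$namespace == ns, c("child", "parent"), drop = FALSE]
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    if (!igraph::is_dag(g)) {
      stop("ontology namespace '", ns, "' contains a cycle", call. = FALSE)
    }
    terms <- igraph::V(g)$name
    # ancestor closure includes the term itself
    anc <- lapply(seq_along(terms), function(i)
      terms[as.integer(igraph::subcomponent(g, i, mode = "out"))])
    names(anc) <- terms
    ann <- gaf[gaf$term %in% terms, , drop = FALSE]
    direct <- split(ann$term, ann$gene)
    direct <- lapply(direct, unique)
    propagated <- lapply(direct, function(ts)
      unique(unlist(anc[ts], use.names = FALSE)))
    n_genes <- length(propagated)
    freq <- table(unlist(propagated, use.names = FALSE))
    ic <- setNames(rep(NA_real_, length(terms)), terms)
    if (n_genes > 0L) {
      ic[names(freq)] <- -log(as.numeric(freq) / n_genes)
    }
    out[[ns]] <- list(direct = direct, propagated = propagated,
                      ancestors = anc, ic = ic)
  }
  miss <- unique(gaf$term[!(gaf$term %in% dag$child | gaf$term %in% dag$parent)])
  if (length(miss)) {
    message(length(miss), " annotated term(s) absent from the DAG; skipped")
  }
  structure(list(namespaces = out), class = "go_corpus")
}

#' @export
print.go_corpus <- function(x, ...) {
  for (ns in names(x$namespaces)) {
    nsd <- x$namespaces[[ns]]
    cat("<go_corpus> ", ns, ": ", length(nsd$ic), " terms, ",
        length(nsd$direct), " annotated genes\n", sep = "")
  }
  invisible(x)
}

#' Write and read the scored-interaction table
#'
#' Columns: `a`, `b`, `p_prev`, `p_new`, `p_final`, `star`, `sources`
#' (semicolon-joined), sorted by `p_final` descending then by key.
#'
#' @param interactions A `scored_interactions` data frame (see
#'   [score_database()]).
#' @param path Output TSV path.
#' @export
write_scored_table <- function(interactions, path) {
  df <- as.data.frame(interactions)
  ord <- order(-df$p_final, df$key)
  df <- df[ord, , drop = FALSE]
  lines <- c(paste(c("#a", "b", "p_prev", "p_new", "p_final", "star",
                     "sources"), collapse = "\t"),
             if (nrow(df)) paste(df$a, df$b,
                                 format_num(df$p_prev), format_num(df$p_new),
                                 format_num(df$p_final), df$star,
                                 df$sources, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 15, format = "g")

#' @rdname write_scored_table
#' @export
read_scored_table <- function(path) {
  tab <- read_tsv_raw(path, c("a", "b", "p_prev", "p_new", "p_final",
                              "star", "sources"))
  scored_interactions(data.frame(
    key = if (nrow(tab)) canonical_pair(tab$a, tab$b) else character(0),
    a = tab$a, b = tab$b,
    p_prev = as.numeric(tab$p_prev), p_new = as.numeric(tab$p_new),
    p_final = as.numeric(tab$p_final), star = as.integer(tab$star),
    sources = tab$sources, stringsAsFactors = FALSE))
}
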