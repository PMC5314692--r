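#' Noisy-OR combination of per-platform reliability scores
#'
#' Evidence platforms are treated as independent detectors: the combined
#' confidence that at least one of them is right is
#' \deqn{P = 1 - \prod_i (1 - S_i)}
#' over the platform scores \eqn{S_i}. The empty product gives 0, a single
#' score passes through unchanged, and the result is order-invariant and
#' monotone non-decreasing in every score and in the number of scores.
#'
#' @param scores Numeric vector of platform scores in [0, 1].
#' @return Combined confidence in [0, 1].
#' @examples
#' combine_platform_scores(c(0.5, 0.5))      # 0.75
#' combine_platform_scores(c(0.3, 0.4, 0.2)) # 0.664
#' @export
combine_platform_scores <- function(scores) {
  scores <- as.numeric(scores)
  if (any(is.na(scores)) || any(scores < 0 | scores > 1)) {
    stop("platform scores must lie in [0, 1]", call. = FALSE)
  }
  clamp01(1 - prod(1 - scores))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Fuse confidence scores across database releases
#'
#' A pair's score from the previous release (`p_prev`) and the score computed
#' for the current release (`p_new`) are combined with the same noisy-OR
#' form, `1 - (1 - p_prev) * (1 - p_new)`. Pairs unique to the current
#' release take the default `p_prev = 0`, so re-scoring a release perturbs
#' legacy scores only upward and only where new evidence exists.
#'
#' @param p_prev,p_new Numeric vectors in [0, 1] (recycled).
#' @return Fused confidence, symmetric in its arguments and never below
#'   either.
#' @export
combine_releases <- function(p_prev, p_new) {
  p_prev <- as.numeric(p_prev)
  p_new <- as.numeric(p_new)
  if (any(is.na(p_prev)) || any(is.na(p_new)) ||
      any(p_prev < 0 | p_prev > 1) || any(p_new < 0 | p_new > 1)) {
    stop("release scores must lie in [0, 1]", call. = FALSE)
  }
  clamp01(1 - (1 - p_prev) * (1 - p_new))
}

#' Five-tier star rating of a confidence score
#'
#' Fixed thresholds partition [0, 1] into five confidence categories:
#' \tabular{lll}{
#'   1-star \tab ultra-low  \tab P < 0.25 \cr
#'   2-star \tab low        \tab 0.25 <= P < 0.45 \cr
#'   3-star \tab medium     \tab 0.45 <= P < 0.75 \cr
#'   4-star \tab high       \tab 0.75 <= P < 0.90 \cr
#'   5-star \tab ultra-high \tab 0.90 <= P <= 1 \cr
#' }
#' Lower bounds are inclusive, so every score maps to exactly one tier.
#'
#' @param p Numeric vector of confidence scores in [0, 1].
#' @return Integer vector of star ratings in 1..5.
#' @export
assign_star <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("confidence scores must lie in [0, 1]", call. = FALSE)
  }
  findInterval(p, c(0, 0.25, 0.45, 0.75, 0.90), rightmost.closed = FALSE)
}

#' @rdname assign_star
#' @export
star_thresholds <- function() c(0, 0.25, 0.45, 0.75, 0.90, 1)

#' Score an integrated interactome from per-source evidence
#'
#' Pools all evidence records across the input source tables per canonical
#' interaction key, collapses duplicate evidence from the same platform for
#' the same pair to the maximum score (repeated rows from one platform must
#' not inflate confidence — the noisy-OR product is indexed over platforms,
#' not rows), combines per-platform scores with the noisy-OR model, fuses
#' with the previous-release score where one exists (default 0), and assigns
#' the star tier.
#'
#' @param tables List of `source_table` objects (see [read_source_table()]).
#' @param prior Optional named numeric vector of previous-release scores,
#'   names being canonical keys.
#' @return A `scored_interactions` data frame: one row per distinct key with
#'   columns `key`, `a`, `b`, `p_prev`, `p_new`, `p_final`, `star`, `sources`
#'   (semicolon-joined, sorted).
#' @export
score_database <- function(tables, prior = NULL) {
  if (inherits(tables, "source_table")) tables <- list(tables)
  if (length(tables) == 0L) stop("at least one source table required",
                                 call. = FALSE)
  ev <- do.call(rbind, lapply(tables, as.data.frame))
  if (nrow(ev) == 0L && is.null(prior)) {
    return(scored_interactions(empty_scored()))
  }
  if (nrow(ev)) {
    if (any(ev$s_i < 0 | ev$s_i > 1)) {
      stop("evidence scores must lie in [0, 1]", call. = FALSE)
    }
    # collapse duplicate (key, platform) evidence to the max score
    kp <- paste(ev$key, ev$platform, sep = "\r")
    s_kp <- tapply(ev$s_i, kp, max)
    key_of_kp <- sub("\r.*$", "", names(s_kp))
    p_new <- tapply(1 - as.numeric(s_kp), key_of_kp,
                    function(q) clamp01(1 - prod(q)))
    srcs <- tapply(ev$source, ev$key, function(s)
      paste(sort(unique(s)), collapse = ";"))
  } else {
    p_new <- numeric(0)
    srcs <- character(0)
  }
  keys <- names(p_new)
  if (!is.null(prior)) {
    extra <- setdiff(names(prior), keys)
    keys <- c(keys, extra)
  }
  keys <- sort(keys)
  p_new_v <- setNames(rep(0, length(keys)), keys)
  p_new_v[names(p_new)] <- as.numeric(p_new)
  src_v <- setNames(rep("", length(keys)), keys)
  src_v[names(srcs)] <- as.character(srcs)
  p_prev_v <- setNames(rep(0, length(keys)), keys)
  if (!is.null(prior)) {
    if (any(prior < 0 | prior > 1)) {
      stop("prior scores must lie in [0, 1]", call. = FALSE)
    }
    hit <- intersect(names(prior), keys)
    p_prev_v[hit] <- unname(prior[hit])
  }
  p_final <- combine_releases(p_prev_v, p_new_v)
  parts <- key_parts(keys)
  scored_interactions(data.frame(
    key = keys, a = parts$a, b = parts$b,
    p_prev = unname(p_prev_v), p_new = unname(p_new_v),
    p_final = unname(p_final), star = assign_star(p_final),
    sources = unname(src_v), stringsAsFactors = FALSE, row.names = NULL))
}

empty_scored <- function() {
  data.frame(key = character(0), a = character(0), b = character(0),
             p_prev = numeric(0), p_new = numeric(0), p_final = numeric(0),
             star = integer(0), sources = character(0),
             stringsAsFactors = FALSE)
}

#' @rdname score_database
#' @param df Data frame with the scored-interaction columns.
#' @export
scored_interactions <- function(df) {
  need <- c("key", "a", "b", "p_prev", "p_new", "p_final", "star", "sources")
  stopifnot(all(need %in% names(df)))
  if (nrow(df)) {
    resid <- abs(df$p_final - combine_releases(df$p_prev, df$p_new))
    if (any(resid > 1e-12)) {
      stop("p_final inconsistent with release fusion of p_prev and p_new",
           call. = FALSE)
    }
    if (any(df$star != assign_star(df$p_final))) {
      stop("star tier inconsistent with p_final thresholds", call. = FALSE)
    }
  }
  structure(df[, need, drop = FALSE],
            class = c("scored_interactions", "data.frame"))
}

#' @export
print.scored_interactions <- function(x, ...) {
  cat("<scored_interactions> ", nrow(x), " interactions; star tiers: ",
      paste(sprintf("%d*:%d", 1:5, tabulate(x$star, 5L)), collapse = " "),
      "\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  invisible(x)
}
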