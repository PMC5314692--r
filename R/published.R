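#' Published release statistics shipped with the package
#'
#' Small tables of headline numbers printed in the release notes of a large
#' integrated human interactome: per-tier interaction counts for two
#' releases (with the printed integer-percent increase ratios), overlap
#' counts of several databases with a curated negative reference, and a few
#' summary quantities. They serve as inputs to the arithmetic consistency
#' checks in [release_consistency()]; the package never uses them as model
#' parameters.
#'
#' @return A list with data frames `tiers`, `negatives` and `summary`.
#' @export
published_counts <- function() {
  d <- function(f, cols) {
    path <- system.file("extdata", f, package = "ppintegrate",
                        mustWork = TRUE)
    read_tsv_raw(path, cols)
  }
  tiers <- d("published_tier_counts.tsv",
             c("tier", "v1", "v2", "printed_increase_pct"))
  tiers$v1 <- as.numeric(tiers$v1)
  tiers$v2 <- as.numeric(tiers$v2)
  tiers$printed_increase_pct <- as.numeric(tiers$printed_increase_pct)
  neg <- d("published_negative_overlap.tsv",
           c("db", "overlap", "db_size", "negative_set_size"))
  neg$overlap <- as.numeric(neg$overlap)
  neg$db_size <- as.numeric(neg$db_size)
  neg$negative_set_size <- as.numeric(neg$negative_set_size)
  summ <- d("published_summary.tsv", c("quantity", "value"))
  summ$value <- as.numeric(summ$value)
  list(tiers = tiers, negatives = neg, summary = summ)
}

#' Arithmetic consistency of the published release statistics
#'
#' Recomputes, from the printed per-tier counts: the all-interaction totals
#' (sum of the five tiers), the per-tier increase ratios in percent, the
#' medium-and-above (3/4/5-star) totals, and the negative-reference shares
#' and false-positive ratios. Printed integer percentages are reproduced to
#' within one percent unit, since the printed table mixes rounding and
#' truncation of the exact ratios.
#'
#' @param counts Output of [published_counts()].
#' @return List of recomputed quantities.
#' @export
release_consistency <- function(counts = published_counts()) {
  t <- counts$tiers
  stars <- t[t$tier != "all", , drop = FALSE]
  all_row <- t[t$tier == "all", , drop = FALSE]
  ratio_pct <- 100 * t$v2 / t$v1
  med <- stars$tier %in% c("3", "4", "5")
  neg <- counts$negatives
  list(
    tier_sum_v1 = sum(stars$v1),
    tier_sum_v2 = sum(stars$v2),
    printed_total_v1 = all_row$v1,
    printed_total_v2 = all_row$v2,
    increase_pct = setNames(ratio_pct, t$tier),
    printed_increase_pct = setNames(t$printed_increase_pct, t$tier),
    medium_and_above_v1 = sum(stars$v1[med]),
    medium_and_above_v2 = sum(stars$v2[med]),
    negative_share_pct = setNames(
      100 * neg$overlap / neg$negative_set_size, neg$db),
    false_positive_ratio = setNames(neg$overlap / neg$db_size, neg$db)
  )
}
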