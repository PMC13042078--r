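#' Pairwise mismatch rate between two pseudohaploid rows
#'
#' The fraction of overlapping (both non-missing) SNPs where the two
#' single-allele calls disagree, with a block-jackknife standard error.
#' For an unrelated pair the expectation is the background rate
#' b = mean 2p(1-p); relatedness depresses it toward b/2 for two calls
#' from the same diploid genome.
#'
#' @param g1,g2 pseudohaploid genotype rows (codes in 0/2/9).
#' @param blocks a [assign_blocks()] result.
#' @return one-row tibble `pmr`, `overlap`, `se`; `NA` row when the
#'   overlap is empty.
#' @export
pairwise_mismatch <- function(g1, g2, blocks) {
  stopifnot(all(g1 %in% c(0L, 2L, 9L)), all(g2 %in% c(0L, 2L, 9L)))
  both <- g1 != 9L & g2 != 9L
  if (!any(both))
    return(tibble::tibble(pmr = NA_real_, overlap = 0L, se = NA_real_))
  vals <- ifelse(both, as.numeric(g1 != g2), NA_real_)
  jk <- block_jackknife(vals, blocks)
  tibble::tibble(pmr = jk$estimate, overlap = sum(both), se = jk$se)
}

#' Classify the degree of a pair from its mismatch rate
#'
#' The relatedness coefficient estimate is r = 2(1 - pmr/b) with b the
#' unrelated-pair baseline, so r = 1 for two calls of the same genome,
#' 0.5 for a first-degree pair, and 0 for unrelated. Class boundaries sit
#' at the midpoints of the expected r values (0.75, 0.375, 0.1875,
#' 0.0625), giving symmetric misclassification risk; pairs with too little
#' overlap or whose confidence interval straddles a boundary are
#' "insufficient".
#'
#' @param pmr,se,overlap from [pairwise_mismatch()].
#' @param baseline the unrelated-pair mismatch baseline b (> 0), typically
#'   [kin_baseline()].
#' @param min_overlap minimum overlapping SNPs (default 3000).
#' @param ci_z half-width multiplier of the SE interval used for the
#'   straddle rule (default 1.96).
#' @return one-row tibble `r_hat`, `degree` (one of "identical", "first",
#'   "second", "third", "unrelated", "insufficient").
#' @export
classify_pair <- function(pmr, se, overlap, baseline,
                          min_overlap = 3000, ci_z = 1.96) {
  if (is.na(baseline) || baseline <= 0) stop("baseline must be positive")
  bounds <- c(0.75, 0.375, 0.1875, 0.0625)
  classes <- c("identical", "first", "second", "third", "unrelated")
  r_hat <- 2 * (1 - pmr / baseline)
  if (is.na(pmr) || overlap < min_overlap)
    return(tibble::tibble(r_hat = r_hat, degree = "insufficient"))
  se_r <- 2 * se / baseline
  band <- r_hat + c(-1, 1) * ci_z * se_r
  cls <- function(r) classes[findInterval(-r, -bounds) + 1]
  degree <- cls(r_hat)
  if (is.finite(se_r) && cls(band[1]) != cls(band[2]))
    degree <- "insufficient"
  tibble::tibble(r_hat = r_hat, degree = degree)
}

#' Unrelated-pair mismatch baseline
#'
#' The median mismatch rate of within-group pairs with sufficient overlap;
#' the median is robust to a few genuinely related pairs in the
#' background.
#'
#' @param pairs tibble of pair results with `group1`, `group2`, `pmr`,
#'   `overlap` columns.
#' @param min_overlap minimum overlap for a pair to inform the baseline
#'   (default 10000).
#' @return named numeric of per-group baselines.
#' @export
kin_baseline <- function(pairs, min_overlap = 10000) {
  within <- pairs[pairs$group1 == pairs$group2 &
                    pairs$overlap >= min_overlap, ]
  if (nrow(within) == 0) stop("no within-group pairs with enough overlap")
  tapply(within$pmr, within$group1, stats::median)
}

#' All-pairs kinship screen on a dataset
#'
#' Computes the pairwise mismatch rate for every pair of pseudohaploid
#' individuals, derives per-group baselines, and classifies each
#' within-group pair's degree.
#'
#' @param ds a [paleo_dataset()] of pseudohaploid individuals.
#' @param blocks a [assign_blocks()] result.
#' @param min_overlap_baseline overlap gate for baseline pairs.
#' @return tibble with one row per pair.
#' @export
pairwise_kin <- function(ds, blocks, min_overlap_baseline = 10000) {
  n <- nrow(ds$ind)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mm <- pairwise_mismatch(ds$geno[i, ], ds$geno[j, ], blocks)
    rows[[length(rows) + 1]] <- dplyr::mutate(
      mm, id1 = ds$ind$id[i], id2 = ds$ind$id[j],
      group1 = ds$ind$group[i], group2 = ds$ind$group[j], .before = 1)
  }
  pairs <- dplyr::bind_rows(rows)
  base <- kin_baseline(pairs, min_overlap_baseline)
  cls <- purrr::pmap(pairs, function(pmr, se, overlap, group1, group2, ...) {
    if (group1 == group2 && group1 %in% names(base))
      classify_pair(pmr, se, overlap, base[[group1]])
    else tibble::tibble(r_hat = NA_real_, degree = NA_character_)
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(cls))
}
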