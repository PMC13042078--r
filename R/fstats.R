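#' Per-population allele counts
#'
#' Computes, for each population label, the per-SNP alternative-allele count
#' and the number of haploid observations. Pseudohaploid individuals
#' contribute one observation per covered SNP, diploid individuals two, so
#' mixed panels use total haploid counts.
#' @noRd
pop_counts <- function(ds, pops) {
  pl <- dataset_ploidy(ds)
  out <- vector("list", length(pops))
  names(out) <- pops
  for (p in pops) {
    rows <- which(ds$ind$group == p)
    if (length(rows) == 0) stop("unknown population label: ", p)
    G <- ds$geno[rows, , drop = FALSE]
    miss <- G == 9L
    plr <- pl[rows]
    n <- colSums((!miss) * plr)
    alt <- sweep(ifelse(miss, 0, G), 1, ifelse(plr == 2L, 1, 0.5), `*`)
    x <- colSums(alt)
    n_ind <- colSums(!miss)
    out[[p]] <- list(x = x, n = n, n_ind = n_ind)
  }
  out
}

# sampling-heterozygosity correction h = p(1-p)/(n-1); n is the number of
# individuals with data ("inbreed" mode, required for pseudohaploid panels)
# or the number of alleles (outbred mode). Skipped (0) when n < 2.
het_correction <- function(ct, inbreed) {
  n_corr <- if (inbreed) ct$n_ind else ct$n
  p <- ifelse(ct$n > 0, ct$x / ct$n, NA_real_)
  h <- ifelse(n_corr >= 2, p * (1 - p) / (n_corr - 1), 0)
  ifelse(is.na(p), NA_real_, h)
}

#' Per-SNP contributions to an f-statistic
#'
#' Returns the per-SNP terms whose weighted mean is the unbiased f2/f3/f4
#' estimate on pseudohaploid or diploid data. With sample frequencies
#' \eqn{\hat a,\hat b,\hat c,\hat d}: the f4 term is
#' \eqn{(\hat a-\hat b)(\hat c-\hat d)}; the f3(A,B; X) term is
#' \eqn{(\hat x-\hat a)(\hat x-\hat b) - h_x}; the f2(A,B) term is
#' \eqn{(\hat a-\hat b)^2 - h_a - h_b}; where \eqn{h} is the
#' sampling-heterozygosity correction \eqn{\hat p(1-\hat p)/(n-1)} (skipped
#' at n = 1). SNPs where any required population is fully missing are `NA`
#' (masked); masks are per-statistic, never a global intersection, so each
#' statistic uses all SNPs available to it.
#'
#' @param ds a [paleo_dataset()].
#' @param kind `"f2"`, `"f3"` or `"f4"`.
#' @param pops population labels: `c(A, B)` for f2; `c(A, B, X)` for
#'   f3(A, B; X) with X the target whose heterozygosity is corrected;
#'   `c(A, B, C, D)` for f4.
#' @param inbreed logical; `TRUE` (default) computes corrections on
#'   individual (haploid-observation) counts as required for pseudohaploid
#'   data, `FALSE` on allele counts.
#' @return list with `values` (per-SNP terms, `NA` where masked) and `mask`.
#' @export
per_snp_contributions <- function(ds, kind = c("f2", "f3", "f4"), pops,
                                  inbreed = TRUE) {
  kind <- match.arg(kind)
  need <- c(f2 = 2L, f3 = 3L, f4 = 4L)[[kind]]
  if (length(pops) != need) stop(kind, " needs ", need, " population labels")
  ct <- pop_counts(ds, unique(pops))
  freq <- function(p) {
    cc <- ct[[p]]
    ifelse(cc$n > 0, cc$x / cc$n, NA_real_)
  }
  if (kind == "f4") {
    v <- (freq(pops[1]) - freq(pops[2])) * (freq(pops[3]) - freq(pops[4]))
  } else if (kind == "f3") {
    x <- freq(pops[3])
    v <- (x - freq(pops[1])) * (x - freq(pops[2])) -
      het_correction(ct[[pops[3]]], inbreed)
  } else {
    v <- (freq(pops[1]) - freq(pops[2]))^2 -
      het_correction(ct[[pops[1]]], inbreed) -
      het_correction(ct[[pops[2]]], inbreed)
  }
  v <- unname(v)
  mask <- !is.na(v)
  if (sum(mask) < 1) stop("no usable SNP for ", kind, "(",
                          paste(pops, collapse = ","), ")")
  list(values = v, mask = mask)
}

#' f-statistics with block jackknife standard errors
#'
#' `fstat()` computes one f2/f3/f4 statistic; `f2()`, `f3()` and `f4()` are
#' convenience wrappers. Estimates are SNP-weighted means of the per-SNP
#' contributions; standard errors come from the weighted delete-one-block
#' jackknife over contiguous map blocks (conventionally 5 cM).
#'
#' @inheritParams per_snp_contributions
#' @param blocks a [assign_blocks()] result for `ds$snp`.
#' @return A one-row tibble: `kind`, `pops`, `estimate`, `se`, `z`,
#'   `n_snps`, `n_blocks`.
#' @export
fstat <- function(ds, kind, pops, blocks, inbreed = TRUE) {
  contrib <- per_snp_contributions(ds, kind, pops, inbreed = inbreed)
  jk <- block_jackknife(ifelse(contrib$mask, contrib$values, NA_real_), blocks)
  tibble::tibble(kind = kind, pops = paste(pops, collapse = ","),
                 estimate = jk$estimate, se = jk$se, z = jk$z,
                 n_snps = jk$n_snps, n_blocks = jk$n_blocks)
}

#' @rdname fstat
#' @param a,b,c,d,target population labels.
#' @export
f2 <- function(ds, a, b, blocks, inbreed = TRUE)
  fstat(ds, "f2", c(a, b), blocks, inbreed)

#' @rdname fstat
#' @export
f3 <- function(ds, a, b, target, blocks, inbreed = TRUE)
  fstat(ds, "f3", c(a, b, target), blocks, inbreed)

#' @rdname fstat
#' @export
f4 <- function(ds, a, b, c, d, blocks, inbreed = TRUE)
  fstat(ds, "f4", c(a, b, c, d), blocks, inbreed)

#' Run a battery of configured f-statistics
#'
#' Computes one row per configured statistic and flags `|Z| > 3` as
#' significant, the conventional threshold for treating an f4 asymmetry as
#' real.
#'
#' @param ds a [paleo_dataset()].
#' @param spec tibble with columns `kind` and `pop1`..`pop4` (`pop3`/`pop4`
#'   may be `NA` for f2/f3).
#' @param blocks a [assign_blocks()] result.
#' @param inbreed see [per_snp_contributions()].
#' @return tibble of results with a `significant` column.
#' @export
run_battery <- function(ds, spec, blocks, inbreed = TRUE) {
  if (nrow(spec) == 0)
    return(tibble::tibble(kind = character(), pops = character(),
                          estimate = double(), se = double(), z = double(),
                          n_snps = double(), n_blocks = integer(),
                          significant = logical()))
  labels <- unique(stats::na.omit(unlist(spec[paste0("pop", 1:4)])))
  unknown <- setdiff(labels, ds$ind$group)
  if (length(unknown)) stop("unresolvable label(s): ",
                            paste(unknown, collapse = ", "))
  rows <- purrr::pmap(spec, function(kind, pop1, pop2, pop3 = NA, pop4 = NA, ...) {
    pops <- stats::na.omit(c(pop1, pop2, pop3, pop4))
    fstat(ds, kind, as.character(pops), blocks, inbreed)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = abs(.data$z) > 3)
}
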