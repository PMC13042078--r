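#' Expected ROH segment counts under the geometric-coalescent model
#'
#' A diploid's two copies of a locus coalesce t generations back with
#' probability (1/2Ne)(1 - 1/2Ne)^(t-1); a coalescence at generation t
#' leaves homozygous segments whose lengths are approximately exponential
#' with rate 2t per Morgan, at density 4 t^2 L e^(-2 t l) segments of
#' length l over a genome of map length L. The expected count in a length
#' bin (l1, l2) is the geometric mixture of the closed-form integral
#' 2 t L (e^(-2 t l1) - e^(-2 t l2)), truncated at `t_max` generations.
#'
#' @param two_ne the 2Ne parameter (> 2).
#' @param genome_l total genome map length in Morgans.
#' @param bins_cm ordered bin edges in centimorgans (k+1 edges give k bins).
#' @param t_max truncation of the geometric mixture (default 3000; the
#'   truncated tail is negligible for 2Ne well below t_max).
#' @return tibble with `l1_cm`, `l2_cm`, `expected`.
#' @export
expected_roh_counts <- function(two_ne, genome_l, bins_cm, t_max = 3000) {
  stopifnot(two_ne > 2, !is.unsorted(bins_cm), length(bins_cm) >= 2)
  t <- seq_len(t_max)
  pt <- (1 / two_ne) * (1 - 1 / two_ne)^(t - 1)
  l <- bins_cm / 100
  k <- length(l) - 1
  expected <- vapply(seq_len(k), function(b) {
    sum(pt * 2 * t * genome_l * (exp(-2 * t * l[b]) - exp(-2 * t * l[b + 1])))
  }, 0)
  tibble::tibble(l1_cm = bins_cm[-length(bins_cm)], l2_cm = bins_cm[-1],
                 expected = expected)
}

#' Call runs of homozygosity in one diploid genotype row
#'
#' A windowed heterozygosity caller for synthetic diploid data: the genome
#' is cut into non-overlapping windows of `window_snps` markers; windows
#' with at most `max_het` heterozygous calls are marked; adjacent marked
#' windows merge into candidate runs; runs shorter than `min_cm` are
#' discarded. Coordinates are in Morgans, lengths in centimorgans.
#'
#' @param geno diploid genotype row (codes 0/1/2/9).
#' @param snp SNP tibble with `chrom` and `gpos` (Morgans).
#' @param window_snps window size in markers (default 50).
#' @param max_het maximum heterozygous calls per marked window (default 1).
#' @param min_cm minimum reported run length in cM (default 4).
#' @return tibble `chrom`, `start`, `end` (Morgans), `length_cm`,
#'   `n_windows`; empty for an all-missing row. The attribute `degenerate`
#'   is `TRUE` when no heterozygote was seen anywhere (the row is then
#'   indistinguishable from one long ROH).
#' @export
call_roh <- function(geno, snp, window_snps = 50, max_het = 1, min_cm = 4.0) {
  stopifnot(length(geno) == nrow(snp))
  out <- list()
  any_data <- any(geno != 9L)
  for (ch in unique(snp$chrom)) {
    idx <- which(snp$chrom == ch)
    g <- geno[idx]
    if (all(g == 9L)) next
    pos <- snp$gpos[idx]
    nw <- floor(length(idx) / window_snps)
    if (nw == 0) next
    wid <- rep(seq_len(nw), each = window_snps)
    use <- seq_len(nw * window_snps)
    het <- tapply(g[use] == 1L, wid, sum)
    marked <- het <= max_het
    r <- rle(as.vector(marked))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      w0 <- starts[k]; w1 <- ends[k]
      i0 <- (w0 - 1) * window_snps + 1
      i1 <- w1 * window_snps
      seg_start <- pos[i0]
      seg_end <- pos[i1]
      if ((seg_end - seg_start) * 100 >= min_cm)
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = ch, start = seg_start, end = seg_end,
          length_cm = (seg_end - seg_start) * 100,
          n_windows = w1 - w0 + 1)
    }
  }
  segs <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(chrom = character(), start = double(), end = double(),
                   length_cm = double(), n_windows = integer())
  structure(segs, degenerate = any_data && !any(geno == 1L),
            class = class(segs))
}

#' Summarize ROH segments into length-class sums and flags
#'
#' Computes the conventional class sums (total cM of ROH longer than 4, 8,
#' 12 and 20 cM), flags individuals whose sum of ROH > 20 cM exceeds 50 cM
#' (the signature of a close-kin union, which excludes them from
#' population-size fitting), and marks individuals below the SNP-coverage
#' gate ineligible.
#'
#' @param segments a segment tibble (from [call_roh()] or simulation
#'   truth) with `length_cm`.
#' @param snps_covered SNPs covered for this individual; `NULL` skips the
#'   gate.
#' @param min_snps coverage gate (default 300000).
#' @return one-row tibble of class sums and flags.
#' @export
summarize_roh <- function(segments, snps_covered = NULL, min_snps = 300000) {
  s <- function(th) sum(segments$length_cm[segments$length_cm > th])
  tibble::tibble(
    sum_gt4 = s(4), sum_gt8 = s(8), sum_gt12 = s(12), sum_gt20 = s(20),
    n_segments = nrow(segments),
    long_roh_excess = s(20) > 50,
    eligible = if (is.null(snps_covered)) TRUE else snps_covered >= min_snps)
}

#' Fit 2Ne by Poisson likelihood over ROH length bins
#'
#' Composite Poisson log-likelihood of per-individual segment counts in the
#' conventional length bins against [expected_roh_counts()], maximized over
#' a log-spaced 2Ne grid with golden-section refinement. The 95% confidence
#' interval is the likelihood profile set
#' \{2Ne : logL >= logL_max - 1.92\}; the reported effective size is
#' Ne = 2Ne / 2. Individuals flagged `long_roh_excess` or ineligible are
#' excluded from the likelihood.
#'
#' @param segments segment tibble with `ind` and `length_cm` columns (one
#'   row per ROH segment over all individuals).
#' @param n_ind number of individuals the segments were called in
#'   (individuals with zero segments still inform the likelihood).
#' @param genome_l total genome map length in Morgans.
#' @param bins_cm bin edges in cM (default `c(4, 8, 12, 20, 300)`).
#' @param exclude ids to drop (close-kin or coverage-ineligible).
#' @param grid_range,grid_points 2Ne search grid (log-spaced, default
#'   20..20000 with 400 points).
#' @return An object of class `ne_fit`.
#' @export
fit_ne <- function(segments, n_ind, genome_l,
                   bins_cm = c(4, 8, 12, 20, 300),
                   exclude = character(0),
                   grid_range = c(20, 20000), grid_points = 400) {
  segments <- segments[!(segments$ind %in% exclude), , drop = FALSE]
  n_eff <- n_ind - length(exclude)
  if (n_eff < 1) stop("need at least one eligible individual")
  k <- length(bins_cm) - 1
  obs <- if (nrow(segments) > 0) {
    b <- findInterval(segments$length_cm, bins_cm,
                      rightmost.closed = TRUE)
    tabulate(b[b >= 1 & b <= k], nbins = k)
  } else rep(0L, k)

  loglik <- function(two_ne) {
    e <- n_eff * expected_roh_counts(two_ne, genome_l, bins_cm)$expected
    sum(obs * log(pmax(e, 1e-300)) - e)
  }
  grid <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                  length.out = grid_points))
  ll <- vapply(grid, loglik, 0)
  i_max <- which.max(ll)
  # golden-section refinement around the grid optimum
  lo <- grid[max(i_max - 1, 1)]
  hi <- grid[min(i_max + 1, grid_points)]
  opt <- stats::optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-4)
  mle <- opt$maximum
  ll_max <- opt$objective
  inside <- ll >= ll_max - 1.92
  ci_lo <- if (inside[1]) grid_range[1] else {
    i <- min(which(inside))
    stats::uniroot(function(x) loglik(x) - (ll_max - 1.92),
                   c(grid[i - 1], grid[i]))$root
  }
  ci_hi <- if (inside[grid_points]) Inf else {
    i <- max(which(inside))
    stats::uniroot(function(x) loglik(x) - (ll_max - 1.92),
                   c(grid[i], grid[i + 1]))$root
  }
  structure(list(
    grid = tibble::tibble(two_ne = grid, loglik = ll),
    two_ne = mle, ne = mle / 2,
    ci_two_ne = c(ci_lo, ci_hi), ci_ne = c(ci_lo, ci_hi) / 2,
    open_upper = !is.finite(ci_hi),
    n_ind = n_eff, obs_counts = obs, bins_cm = bins_cm,
    genome_l = genome_l),
    class = "ne_fit")
}

#' @export
print.ne_fit <- function(x, ...) {
  cat(sprintf("<ne_fit> Ne = %.0f (95%% profile CI %.0f-%s), %d individuals\n",
              x$ne, x$ci_ne[1],
              if (x$open_upper) "open" else sprintf("%.0f", x$ci_ne[2]),
              x$n_ind))
  invisible(x)
}
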