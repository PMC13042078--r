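#' Ancestry-informative SNP weights
#'
#' The signed source allele-frequency difference a - b, the weight that
#' makes the pairwise covariance statistic proportional to the squared
#' ancestry-informativeness of each SNP pair. SNPs where both sources are
#' missing are dropped downstream.
#'
#' @param freq_a,freq_b per-SNP allele frequencies of the two sources
#'   (`NA` allowed).
#' @return numeric vector of weights (`NA` where both sources missing).
#' @export
snp_weights <- function(freq_a, freq_b) {
  stopifnot(length(freq_a) == length(freq_b))
  w <- freq_a - freq_b
  if (all(is.na(w))) stop("no SNP with both source frequencies")
  w
}

#' Weighted ancestry-covariance decay curve
#'
#' For every intra-chromosome SNP pair (i, j) at genetic distance
#' d <= `maxdis`, accumulates weight_i x weight_j x cov(residual genotypes
#' across individuals) into the bin ceiling(d / `binsize`), where the
#' residual is genotype - 2 x pooled sample frequency. In an admixed cohort
#' the expected bin value is proportional to w(1-w) exp(-t d): the
#' exponential decay whose rate is the age of admixture in generations.
#' Per-chromosome sums are retained for the chromosome jackknife.
#'
#' @param ds a [paleo_dataset()] of 2 or more target individuals (diploid
#'   or pseudohaploid).
#' @param weights per-SNP weights from [snp_weights()].
#' @param binsize bin width in Morgans (default 0.001).
#' @param maxdis maximum pair distance in Morgans (default 0.20).
#' @return An object of class `decay_curve`: tibble `bin`, `mid` (Morgans),
#'   `value`, `n_pairs`, plus per-chromosome sum/count matrices as
#'   attributes.
#' @export
covariance_curve <- function(ds, weights, binsize = 0.001, maxdis = 0.20) {
  if (nrow(ds$ind) < 2) stop("covariance needs at least 2 individuals")
  stopifnot(length(weights) == nrow(ds$snp))
  n_bins <- ceiling(maxdis / binsize)
  chrs <- unique(ds$snp$chrom)
  sums <- matrix(0, nrow = length(chrs), ncol = n_bins,
                 dimnames = list(chrs, NULL))
  counts <- matrix(0, nrow = length(chrs), ncol = n_bins,
                   dimnames = list(chrs, NULL))
  G <- ds$geno
  G[G == 9L] <- NA_integer_
  n_ind <- nrow(G)
  for (ch in chrs) {
    idx <- which(ds$snp$chrom == ch & !is.na(weights))
    if (length(idx) < 2) next
    pos <- ds$snp$gpos[idx]
    wch <- weights[idx]
    R <- G[, idx, drop = FALSE]
    mu <- colMeans(R, na.rm = TRUE)
    R <- sweep(R, 2, mu)
    R[is.na(R)] <- 0
    C <- crossprod(R) / (n_ind - 1)
    WC <- C * tcrossprod(wch)
    # chunked accumulation over the upper triangle
    chunk <- 512L
    nloc <- length(idx)
    for (j0 in seq(1L, nloc, by = chunk)) {
      j1 <- min(j0 + chunk - 1L, nloc)
      cols <- j0:j1
      D <- abs(outer(pos, pos[cols], `-`))
      upper <- outer(seq_len(nloc), cols, `<`)
      sel <- upper & D > 0 & D <= maxdis
      if (!any(sel)) next
      b <- ceiling(D[sel] / binsize)
      v <- WC[, cols, drop = FALSE][sel]
      agg <- rowsum(v, b)
      present <- as.integer(rownames(agg))
      sums[ch, present] <- sums[ch, present] + agg[, 1]
      counts[ch, ] <- counts[ch, ] + tabulate(b, nbins = n_bins)
    }
  }
  total_counts <- colSums(counts)
  value <- ifelse(total_counts > 0, colSums(sums) / total_counts, NA_real_)
  curve <- tibble::tibble(bin = seq_len(n_bins),
                          mid = (seq_len(n_bins) - 0.5) * binsize,
                          value = value, n_pairs = total_counts)
  structure(curve, chrom_sums = sums, chrom_counts = counts,
            binsize = binsize, maxdis = maxdis,
            class = c("decay_curve", class(curve)))
}

#' Fit an exponential to a decay curve
#'
#' Nonlinear least squares of y(d) = A exp(-t d) + c over bins in
#' \[`fit_min`, `fit_max`\]: t is the admixture age in generations (the
#' decay exponent is t per Morgan, with no +1 convention adjustment). The
#' jackknife refits the curve with each chromosome's pair contributions
#' removed, weighting chromosomes by pair counts. Years are obtained by a
#' configurable generation time.
#'
#' @param curve a [covariance_curve()] result.
#' @param fit_min,fit_max fit range in Morgans; the default lower cut of
#'   0.005 excludes the shortest bins, where background linkage
#'   disequilibrium contaminates the admixture signal.
#' @param generation_time years per generation for the calendar conversion
#'   (default 28.9).
#' @return An object of class `date_fit`: amplitude `A`, generations `t`,
#'   offset `c`, `se` and `z` of t, `years`, `years_se`, `signal`
#'   (FALSE when the curve carries no decay), `converged`.
#' @export
fit_decay <- function(curve, fit_min = 0.005, fit_max = 0.20,
                      generation_time = 28.9) {
  sel <- !is.na(curve$value) & curve$mid >= fit_min & curve$mid <= fit_max
  if (sum(sel) < 10) stop("need >= 10 bins in the fit range")
  d <- curve$mid[sel]
  fit1 <- function(y) {
    if (all(abs(y) < 1e-300) || stats::sd(y) == 0)
      return(list(A = 0, t = NA_real_, c = 0, ok = FALSE))
    c0 <- mean(y[d > stats::quantile(d, 0.8)])
    pos <- y - c0 > 1e-12 * max(abs(y))
    t0 <- 50
    if (sum(pos) > 3) {
      lf <- stats::lm(log(y[pos] - c0) ~ d[pos])
      slope <- -stats::coef(lf)[2]
      if (is.finite(slope) && slope > 0) t0 <- min(max(slope, 1), 2000)
    }
    A0 <- max(y[1] - c0, 1e-8)
    ft <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t * d) + c,
                        start = list(A = A0, t = t0, c = c0),
                        lower = c(-Inf, 1e-3, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(ft)) return(list(A = NA_real_, t = NA_real_, c = NA_real_,
                                 ok = FALSE))
    cf <- stats::coef(ft)
    list(A = unname(cf["A"]), t = unname(cf["t"]), c = unname(cf["c"]),
         ok = TRUE)
  }
  full <- fit1(curve$value[sel])
  if (!full$ok) {
    flat <- identical(full$A, 0) # no-signal curve, not a convergence failure
    return(structure(list(A = if (flat) 0 else NA_real_, t = NA_real_,
                          c = if (flat) 0 else NA_real_, se = NA_real_,
                          z = NA_real_, years = NA_real_,
                          years_se = NA_real_, signal = FALSE,
                          converged = flat,
                          fit_range = c(fit_min, fit_max),
                          generation_time = generation_time),
                     class = "date_fit"))
  }
  sums <- attr(curve, "chrom_sums")[, sel, drop = FALSE]
  counts <- attr(curve, "chrom_counts")[, sel, drop = FALSE]
  tot_s <- colSums(sums)
  tot_c <- colSums(counts)
  chrs <- rownames(sums)
  loo_t <- rep(NA_real_, length(chrs))
  wts <- rowSums(attr(curve, "chrom_counts"))
  for (k in seq_along(chrs)) {
    cs <- tot_s - sums[k, ]
    cc <- tot_c - counts[k, ]
    yk <- ifelse(cc > 0, cs / cc, NA)
    ok <- !is.na(yk)
    if (sum(ok) < 10) next
    fk <- fit1(ifelse(ok, yk, mean(yk, na.rm = TRUE)))
    loo_t[k] <- fk$t
  }
  usable <- is.finite(loo_t) & wts > 0
  se <- if (sum(usable) >= 2 && is.finite(full$t))
    jackknife_from_loo(full$t, loo_t[usable], wts[usable])$se else NA_real_
  structure(list(A = full$A, t = full$t, c = full$c, se = se,
                 z = if (isTRUE(se > 0)) full$t / se else NA_real_,
                 years = full$t * generation_time,
                 years_se = se * generation_time,
                 signal = isTRUE(abs(full$A) > 0),
                 converged = full$ok,
                 fit_range = c(fit_min, fit_max),
                 generation_time = generation_time),
            class = "date_fit")
}

#' @export
print.date_fit <- function(x, ...) {
  if (!x$signal) {
    cat("<date_fit> no decay signal (A = 0)\n")
    return(invisible(x))
  }
  cat(sprintf("<date_fit> t = %.1f +/- %.1f generations (Z = %.1f); %.0f +/- %.0f years\n",
              x$t, x$se, x$z, x$years, x$years_se))
  invisible(x)
}
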