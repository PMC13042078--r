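#' Weighted delete-one-block jackknife
#'
#' Computes the point estimate (SNP-weighted mean of per-SNP terms) and its
#' standard error by the weighted delete-one-block jackknife, with block
#' weights equal to the number of valid SNPs per block. Blocks are typically
#' contiguous 5 cM map segments so that the SE is robust to linkage. With
#' equal block weights the formula reduces to the classic unweighted
#' delete-one jackknife.
#'
#' @param values numeric per-SNP terms (`NA` for masked SNPs).
#' @param blocks a [assign_blocks()] result, or an integer block index per SNP.
#' @return A list of class `jackknife_estimate` with `estimate`, `se`, `z`,
#'   `loo` (leave-one-out estimates for non-empty blocks), `weights` (valid
#'   SNP counts per retained block), `n_snps`, `n_blocks`.
#' @export
block_jackknife <- function(values, blocks) {
  idx <- if (inherits(blocks, "block_assignment")) blocks$block else as.integer(blocks)
  stopifnot(length(idx) == length(values))
  ok <- !is.na(values)
  m <- tapply(ok, idx, sum)                     # valid SNPs per block
  s <- tapply(ifelse(ok, values, 0), idx, sum)  # block sums
  keep <- m > 0
  m <- as.numeric(m[keep]); s <- as.numeric(s[keep])
  g <- length(m)
  if (g < 2) stop("need at least 2 non-empty blocks")
  n <- sum(m)
  total <- sum(s)
  est <- total / n
  loo <- (total - s) / (n - m)
  jackknife_from_loo(est, loo, m, n_snps = n)
}

# Busing-style weighted jackknife variance from leave-one-out estimates.
# est: full estimate; loo: delete-one estimates; m: block weights.
jackknife_from_loo <- function(est, loo, m, n_snps = sum(m)) {
  g <- length(loo)
  n <- sum(m)
  h <- n / m
  theta_j <- g * est - sum((1 - m / n) * loo)
  tau <- h * est - (h - 1) * loo
  v <- sum((tau - theta_j)^2 / (h - 1)) / g
  se <- sqrt(v)
  structure(list(estimate = est, se = se,
                 z = if (se > 0) est / se else NA_real_,
                 loo = loo, weights = m,
                 n_snps = n_snps, n_blocks = g),
            class = "jackknife_estimate")
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat(sprintf("<jackknife_estimate> %.6g +/- %.3g (Z = %.2f; %d SNPs, %d blocks)\n",
              x$estimate, x$se, x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

#' @rdname block_jackknife
#' @param x a `jackknife_estimate`.
#' @param ... unused.
#' @method tidy jackknife_estimate
#' @export
tidy.jackknife_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, se = x$se, z = x$z,
                 n_snps = x$n_snps, n_blocks = x$n_blocks)
}
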