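#' Fit PCA on reference individuals
#'
#' Genotypes are normalized per SNP by subtracting the reference mean and
#' dividing by sqrt(p(1-p)) with p the reference allele frequency, the
#' standard scaling that equalizes drift variance across frequencies. SNPs
#' with any reference missingness or monomorphic in the reference set are
#' dropped. The eigenvector sign is fixed by making each vector's
#' largest-magnitude entry positive, so results are deterministic across
#' runs.
#'
#' @param ds a [paleo_dataset()].
#' @param ref_ids individual ids used to build the axes.
#' @param k number of components (at most one less than the reference
#'   count).
#' @return An object of class `pca_basis`: SNP ids/means/norms, eigenvector
#'   matrix (SNPs x k), eigenvalues, and a tibble of fitted reference
#'   scores. Reference scores are reported as fitted (not projected); no
#'   shrinkage remapping is applied, so projected ancients and fitted
#'   references are not directly co-visualizable.
#' @export
fit_pca <- function(ds, ref_ids, k) {
  rows <- match(ref_ids, ds$ind$id)
  if (anyNA(rows)) stop("unknown reference id(s)")
  if (k > length(rows) - 1) stop("k must be <= reference count - 1")
  G <- ds$geno[rows, , drop = FALSE]
  G[G == 9L] <- NA_integer_
  keep <- colSums(is.na(G)) == 0
  G <- G[, keep, drop = FALSE]
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  norms <- sqrt(p * (1 - p))
  M <- sweep(sweep(G, 2, 2 * p), 2, norms, `/`)
  sv <- svd(M, nu = k, nv = k)
  V <- sv$v
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  V <- sweep(V, 2, flip, `*`)
  U <- sweep(sv$u, 2, flip, `*`)
  scores <- sweep(U, 2, sv$d[seq_len(k)], `*`)
  structure(list(
    snp_id = ds$snp$id[keep][poly],
    means = 2 * p, norms = norms,
    vectors = V, eigenvalues = sv$d[seq_len(k)]^2 / nrow(M),
    ref_scores = tibble::as_tibble(stats::setNames(
      as.data.frame(scores), paste0("PC", seq_len(k)))) |>
      dplyr::mutate(id = ref_ids, .before = 1)),
    class = "pca_basis")
}

#' Least-squares projection of a sample onto fitted axes
#'
#' Projects a (possibly very incomplete) genotype row onto the PCA basis by
#' least squares over the sample's non-missing normalized entries, the
#' device used to place low-coverage ancient individuals on reference axes
#' without imputing missing genotypes. For a fully observed sample this
#' reduces to inner products with the (orthonormal) eigenvectors.
#'
#' @param basis a [fit_pca()] result.
#' @param geno genotype row (codes 0/1/2/9) aligned to `snp_ids`.
#' @param snp_ids SNP ids aligned to `geno` (default: the basis SNPs).
#' @return Numeric vector of k coordinates.
#' @export
lsq_project <- function(basis, geno, snp_ids = basis$snp_id) {
  pos <- match(basis$snp_id, snp_ids)
  g <- rep(9L, length(basis$snp_id))
  g[!is.na(pos)] <- geno[pos[!is.na(pos)]]
  obs <- g != 9L
  k <- ncol(basis$vectors)
  if (sum(obs) < k) stop("fewer non-missing SNPs (", sum(obs),
                         ") than components (", k, ")")
  z <- (g[obs] - basis$means[obs]) / basis$norms[obs]
  V <- basis$vectors[obs, , drop = FALSE]
  as.numeric(solve(crossprod(V), crossprod(V, z)))
}

#' Project many individuals
#'
#' @param basis a [fit_pca()] result.
#' @param ds a [paleo_dataset()].
#' @param ids individuals to project (default: all).
#' @return tibble of `id` and PC coordinates.
#' @export
project_individuals <- function(basis, ds, ids = ds$ind$id) {
  rows <- match(ids, ds$ind$id)
  if (anyNA(rows)) stop("unknown individual id(s)")
  coords <- t(vapply(rows, function(i)
    lsq_project(basis, ds$geno[i, ], ds$snp$id),
    numeric(ncol(basis$vectors))))
  out <- tibble::as_tibble(stats::setNames(as.data.frame(coords),
                                           paste0("PC", seq_len(ncol(coords)))))
  dplyr::mutate(out, id = ids, .before = 1)
}
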