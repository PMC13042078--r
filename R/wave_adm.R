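#' Build a matrix of f4-statistics with jackknife covariance
#'
#' Computes X\[i, j\] = f4(left_i, left_1; right_j, right_1) for i, j >= 2
#' together with the block-jackknife covariance of the stacked entries.
#' This is the statistic family behind rank (cladality) tests and
#' admixture-weight estimation: each row profiles one left population's
#' allele sharing with the differentially related right (reference)
#' populations. Masks are per-entry ("allsnps" semantics); the covariance
#' uses the intersection mask's block weights.
#'
#' @param ds a [paleo_dataset()].
#' @param left,right ordered population labels; the first of each is the
#'   base subtracted from the others.
#' @param blocks a [assign_blocks()] result.
#' @return list of class `f4_matrix`: `x` ((|left|-1) x (|right|-1) matrix),
#'   `cov` (covariance of `c(x)`), `left`, `right`, `n_snps`, `n_blocks`,
#'   `degenerate` (logical matrix flagging zero-variance entries).
#' @export
build_f4_matrix <- function(ds, left, right, blocks) {
  if (length(left) < 2 || length(right) < 2)
    stop("need at least 2 left and 2 right populations")
  ct <- pop_counts(ds, unique(c(left, right)))
  fr <- lapply(ct, function(cc) ifelse(cc$n > 0, cc$x / cc$n, NA_real_))
  p <- length(left) - 1
  q <- length(right) - 1
  n_snp <- nrow(ds$snp)
  terms <- array(NA_real_, dim = c(n_snp, p, q))
  for (i in seq_len(p)) for (j in seq_len(q)) {
    terms[, i, j] <- (fr[[left[i + 1]]] - fr[[left[1]]]) *
      (fr[[right[j + 1]]] - fr[[right[1]]])
  }
  idx <- blocks$block
  inter <- rowSums(is.na(terms[, , , drop = FALSE])) == 0

  # per-entry estimates on their own masks
  x <- matrix(0, p, q)
  for (i in seq_len(p)) for (j in seq_len(q))
    x[i, j] <- mean(terms[, i, j], na.rm = TRUE)

  # delete-one-block estimates on the intersection mask
  tm <- matrix(terms, nrow = n_snp)      # n_snp x (p*q)
  tm[!inter, ] <- NA
  m <- tapply(inter, idx, sum)
  keep <- !is.na(m) & m > 0
  ublocks <- as.integer(names(m))[keep]
  m <- as.numeric(m[keep])
  g <- length(ublocks)
  if (g < 2) stop("need at least 2 non-empty blocks")
  sums <- rowsum(ifelse(is.na(tm), 0, tm), idx)
  sums <- sums[match(as.character(ublocks), rownames(sums)), , drop = FALSE]
  tot <- colSums(sums)
  n <- sum(m)
  est_int <- tot / n
  loo <- sweep(-sums, 2, tot, `+`) / (n - m)    # g x (p*q)
  h <- n / m
  # weighted jackknife covariance from pseudovalues:
  # tau_b = h_b * est - (h_b - 1) * loo_b; cov = mean_b outer(tau_b - theta_J)/(h_b - 1)
  tau <- outer(h, est_int) - sweep(loo, 1, h - 1, `*`)
  theta_j <- g * est_int - colSums(sweep(loo, 1, (1 - m / n), `*`))
  centered <- sweep(tau, 2, theta_j)
  cov <- crossprod(centered / sqrt(h - 1)) / g
  degenerate <- matrix(diag(cov) < 1e-18, p, q)
  structure(list(x = x, cov = cov, left = left, right = right,
                 n_snps = n, n_blocks = g,
                 block_sums = sums, block_weights = m,
                 degenerate = degenerate),
            class = "f4_matrix")
}

# ridge-regularized inverse for near-singular jackknife covariances
robust_inverse <- function(sigma, ridge_rel = 1e-6, cond_max = 1e12) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_max) {
    warning("near-singular covariance; applying relative ridge")
    lambda <- ridge_rel * mean(diag(sigma))
    if (!isTRUE(lambda > 0)) lambda <- ridge_rel
    sigma <- sigma + diag(lambda, nrow(sigma))
    while (inherits(tryCatch(solve(sigma), error = identity), "error")) {
      lambda <- lambda * 100
      sigma <- sigma + diag(lambda, nrow(sigma))
    }
  }
  solve(sigma)
}

#' Rank test on an f4 matrix (qpWave-style)
#'
#' Tests whether the f4 matrix is consistent with rank r by minimizing the
#' covariance-weighted quadratic form over rank-r approximations
#' (alternating generalized least squares on the two factors). Rank 0
#' reduces to Q = x' Sigma^-1 x on the stacked entries and is the pairwise
#' cladality test: two left populations form a clade relative to the
#' references when rank 0 is not rejected.
#'
#' @param m an [build_f4_matrix()] result.
#' @param r tested rank (0 <= r < min(dim)).
#' @return tibble with `chi2`, `df`, `p`, `rank`.
#' @export
rank_test <- function(m, r = 0) {
  p <- nrow(m$x); q <- ncol(m$x)
  if (r >= min(p, q) + 1) stop("rank too large")
  W <- robust_inverse(m$cov)
  fit <- rank_fit(m$x, W, r)
  df <- (p - r) * (q - r)
  tibble::tibble(chi2 = fit$chi2, df = df,
                 p = stats::pchisq(fit$chi2, df, lower.tail = FALSE),
                 rank = r)
}

# GLS best rank-r approximation of a p x q matrix by alternating least
# squares on the factors A (p x r) and B (r x q); W weights vec residuals.
rank_fit <- function(xmat, W, r) {
  p <- nrow(xmat); q <- ncol(xmat)
  x <- c(xmat)
  if (r == 0)
    return(list(chi2 = drop(t(x) %*% W %*% x), A = NULL, B = NULL))
  sv <- svd(xmat)
  A <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  B <- t(sv$v[, seq_len(r), drop = FALSE])
  obj <- function(A, B) {
    res <- x - c(A %*% B)
    drop(t(res) %*% W %*% res)
  }
  prev <- Inf
  for (it in seq_len(500)) {
    # vec(AB) = (t(B) %x% I_p) vec(A): GLS for vec(A), then for vec(B)
    Ja <- t(B) %x% diag(p)
    A <- matrix(solve(t(Ja) %*% W %*% Ja, t(Ja) %*% W %*% x), p, r)
    Jb <- diag(q) %x% A
    B <- matrix(solve(t(Jb) %*% W %*% Jb, t(Jb) %*% W %*% x), r, q)
    cur <- obj(A, B)
    if (abs(prev - cur) < 1e-12 * (1 + abs(cur))) break
    prev <- cur
  }
  list(chi2 = obj(A, B), A = A, B = B)
}

#' Pairwise cladality test between two groups
#'
#' Convenience wrapper: rank-0 test of the 1 x (|right|-1) f4 matrix with
#' the pair as the left set.
#'
#' @param ds a [paleo_dataset()].
#' @param a,b the two left labels.
#' @param right reference labels.
#' @param blocks a [assign_blocks()] result.
#' @return tibble row from [rank_test()].
#' @export
qpwave_pair <- function(ds, a, b, right, blocks) {
  m <- build_f4_matrix(ds, c(a, b), right, blocks)
  rank_test(m, 0)
}

#' Group individuals by pairwise cladality
#'
#' Runs the rank-0 cladality test for every pair, links pairs with
#' p > alpha, and reports connected components as groups. An individual
#' whose removal splits its neighbors into two or more disconnected
#' components bridges otherwise-separate groups; such individuals are
#' flagged ambiguous and left ungrouped, mirroring the practice of
#' excluding samples with ambiguous pairwise model fits.
#'
#' @param ds a [paleo_dataset()]; the tested units are individuals, used as
#'   singleton groups.
#' @param individuals ids to group.
#' @param right reference labels.
#' @param blocks a [assign_blocks()] result.
#' @param alpha cladality threshold (default 0.05).
#' @return tibble `id`, `group` (integer; NA for ambiguous), `ambiguous`.
#' @export
group_by_cladality <- function(ds, individuals, right, blocks, alpha = 0.05) {
  n <- length(individuals)
  if (n < 1) stop("need at least one individual")
  ds2 <- ds
  rows <- match(individuals, ds2$ind$id)
  ds2$ind$group[rows] <- ds2$ind$id[rows]
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pv <- qpwave_pair(ds2, individuals[i], individuals[j], right, blocks)$p
      adj[i, j] <- adj[j, i] <- pv > alpha
    }
  }
  comp_of <- function(A) {
    nn <- nrow(A)
    comp <- rep(NA_integer_, nn)
    cur <- 0L
    for (s in seq_len(nn)) {
      if (!is.na(comp[s])) next
      cur <- cur + 1L
      stack <- s
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (!is.na(comp[v])) next
        comp[v] <- cur
        stack <- c(stack, which(A[v, ] & is.na(comp)))
      }
    }
    comp
  }
  ambiguous <- rep(FALSE, n)
  if (n > 2) {
    for (v in seq_len(n)) {
      nb <- which(adj[v, ])
      if (length(nb) < 2) next
      sub <- adj[-v, -v, drop = FALSE]
      comp_sub <- comp_of(sub)
      nb_sub <- match(nb, setdiff(seq_len(n), v))
      if (length(unique(comp_sub[nb_sub])) > 1) ambiguous[v] <- TRUE
    }
  }
  keep <- which(!ambiguous)
  comp_keep <- comp_of(adj[keep, keep, drop = FALSE])
  group <- rep(NA_integer_, n)
  group[keep] <- comp_keep
  tibble::tibble(id = individuals, group = group, ambiguous = ambiguous)
}

#' qpAdm-style admixture-weight estimation
#'
#' Models the target as a mixture of the source populations: weights w
#' (summing to 1) minimize the covariance-weighted quadratic form of
#' sum_i w_i f4(S_i, T; r_j, r_1) over the reference profile, which is zero
#' in expectation when T is the w-mixture of the sources. Standard errors
#' come from a delete-one-block jackknife of the whole fit; the model
#' p-value is the rank test at r = |sources| - 1 on the full left set,
#' with p > 0.05 conventionally read as consistent with the data. Weights
#' outside \[0, 1\] are reported but flagged infeasible.
#'
#' @param ds a [paleo_dataset()].
#' @param target target label.
#' @param sources source labels (>= 2).
#' @param references reference labels (at least |sources| + 1).
#' @param blocks a [assign_blocks()] result.
#' @return An object of class `qpadm_fit`.
#' @export
qpadm_fit <- function(ds, target, sources, references, blocks) {
  k <- length(sources)
  if (length(references) < k + 1)
    stop("need at least ", k + 1, " references for ", k, " sources")
  # Rows of the f4 matrix (base = target) are z_i = x_{S_i} - x_T; if the
  # target is the w-mixture of the sources with sum(w) = 1 then
  # sum_i w_i z_i = 0, i.e. the matrix has rank k - 1 and the weights are
  # the left null vector of its best rank-(k-1) GLS approximation.
  m <- build_f4_matrix(ds, c(target, sources), references, blocks)
  W <- robust_inverse(m$cov)
  p <- k; q <- length(references) - 1

  weights_of <- function(xmat) {
    if (k == 1) return(1)
    fit <- rank_fit(xmat, W, k - 1)
    if (any(!is.finite(fit$A))) stop("collinear sources: ",
                                     paste(sources, collapse = ", "))
    nv <- qr.Q(qr(fit$A), complete = TRUE)[, k] # orthogonal complement of span(A)
    if (abs(sum(nv)) < 1e-10) stop("collinear sources: ",
                                   paste(sources, collapse = ", "))
    nv / sum(nv)
  }
  w <- weights_of(m$x)

  # delete-one-block jackknife of the whole fit (covariance held fixed)
  sums <- m$block_sums
  mwt <- m$block_weights
  tot <- colSums(sums)
  n <- sum(mwt)
  g <- length(mwt)
  loo_w <- matrix(NA_real_, g, k)
  for (b in seq_len(g)) {
    xb <- matrix((tot - sums[b, ]) / (n - mwt[b]), p, q)
    loo_w[b, ] <- weights_of(xb)
  }
  se <- vapply(seq_len(k), function(i)
    jackknife_from_loo(w[i], loo_w[, i], mwt)$se, 0)

  rt <- rank_test(m, r = if (k == 1) 0 else k - 1)
  structure(list(
    target = target, sources = sources, references = references,
    weights = tibble::tibble(source = sources, weight = w, se = se),
    chi2 = rt$chi2, df = rt$df, p = rt$p,
    feasible = all(w >= 0 & w <= 1),
    n_snps = m$n_snps, n_blocks = m$n_blocks, f4 = m),
    class = "qpadm_fit")
}

#' @export
print.qpadm_fit <- function(x, ...) {
  cat("<qpadm_fit> ", x$target, " ~ ",
      paste(x$sources, collapse = " + "), "\n", sep = "")
  for (i in seq_len(nrow(x$weights)))
    cat(sprintf("  %-20s %6.3f +/- %.3f\n", x$weights$source[i],
                x$weights$weight[i], x$weights$se[i]))
  cat(sprintf("  model p = %.3g (chi2 = %.2f, df = %d)%s\n", x$p, x$chi2,
              x$df, if (x$feasible) "" else "  [infeasible weights]"))
  invisible(x)
}
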