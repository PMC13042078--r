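# Shared fixtures and independent oracles used across the suite.

# A small two-population drift graph with one outgroup.
simple_graph <- function(fa = 0.05, fb = 0.05, fo = 0.1) {
  drift_graph(data.frame(parent = c("R", "R", "N", "N"),
                         child = c("O", "N", "A", "B"),
                         f = c(fo, 0.02, fa, fb)))
}

# Construct a dataset with exact sample allele frequencies: one population
# per column of `counts`, each a list(alt = alt haploid count, n = haploids).
exact_pop_dataset <- function(freq_list, snp = NULL) {
  pops <- names(freq_list)
  n_snp <- length(freq_list[[1]]$alt[[1]])
  if (is.null(snp))
    snp <- tibble::tibble(id = paste0("s", seq_len(n_snp)), chrom = "1",
                          gpos = seq(0, 0.5, length.out = n_snp),
                          ppos = seq_len(n_snp), ref = "A", alt = "G")
  geno <- NULL
  ind <- NULL
  for (p in pops) {
    alt <- freq_list[[p]]$alt[[1]]
    n <- freq_list[[p]]$n
    g <- matrix(0L, nrow = n, ncol = n_snp)
    for (j in seq_len(n_snp)) if (alt[j] > 0) g[seq_len(alt[j]), j] <- 2L
    geno <- rbind(geno, g)
    ind <- dplyr::bind_rows(ind, tibble::tibble(
      id = sprintf("%s_%d", p, seq_len(n)), sex = "U", group = p,
      ploidy = "haploid"))
  }
  paleo_dataset(geno, snp, ind)
}

# Independent brute-force f-statistic oracle: plain loops over SNPs and
# individuals, no shared code with the package implementation.
oracle_fstat <- function(ds, kind, pops, inbreed = TRUE) {
  ploidy <- ifelse(!is.null(ds$ind$ploidy) & ds$ind$ploidy == "diploid", 2, 1)
  freq_n <- function(pop, j) {
    rows <- which(ds$ind$group == pop)
    x <- 0; n <- 0; n_ind <- 0
    for (i in rows) {
      g <- ds$geno[i, j]
      if (g == 9) next
      if (ploidy[i] == 2) { x <- x + g; n <- n + 2 }
      else { x <- x + g / 2; n <- n + 1 }
      n_ind <- n_ind + 1
    }
    list(p = if (n > 0) x / n else NA, n = n, n_ind = n_ind)
  }
  hcorr <- function(fr) {
    nc <- if (inbreed) fr$n_ind else fr$n
    if (nc < 2) return(0)
    fr$p * (1 - fr$p) / (nc - 1)
  }
  vals <- rep(NA_real_, nrow(ds$snp))
  for (j in seq_len(nrow(ds$snp))) {
    fr <- lapply(pops, freq_n, j = j)
    if (any(vapply(fr, function(f) is.na(f$p), TRUE))) next
    vals[j] <- switch(kind,
      f2 = (fr[[1]]$p - fr[[2]]$p)^2 - hcorr(fr[[1]]) - hcorr(fr[[2]]),
      f3 = (fr[[3]]$p - fr[[1]]$p) * (fr[[3]]$p - fr[[2]]$p) - hcorr(fr[[3]]),
      f4 = (fr[[1]]$p - fr[[2]]$p) * (fr[[3]]$p - fr[[4]]$p))
  }
  mean(vals, na.rm = TRUE)
}

# Textbook unweighted delete-one jackknife SE for equal-size blocks.
oracle_unweighted_jackknife <- function(values, block) {
  blocks <- sort(unique(block))
  g <- length(blocks)
  loo <- vapply(blocks, function(b) mean(values[block != b]), 0)
  sqrt((g - 1) / g * sum((loo - mean(loo))^2))
}

# Simulate a pseudohaploid parent/offspring pair plus an unrelated
# individual at given allele frequencies; returns 0/2 coded rows.
sim_trio_rows <- function(p) {
  n <- length(p)
  mom <- stats::rbinom(n, 1, p) + stats::rbinom(n, 1, p)
  dad <- stats::rbinom(n, 1, p) + stats::rbinom(n, 1, p)
  kid <- stats::rbinom(n, 1, mom / 2) + stats::rbinom(n, 1, dad / 2)
  unrel <- stats::rbinom(n, 1, p) + stats::rbinom(n, 1, p)
  ph <- function(g) 2L * stats::rbinom(n, 1, g / 2)
  list(mom = ph(mom), kid = ph(kid), unrel = ph(unrel))
}

# Build a cohort dataset for cladality / qpAdm tests: samples each listed
# population from a shared frequency panel.
sample_cohort <- function(panel, spec, seed0 = 1000) {
  sets <- lapply(seq_len(nrow(spec)), function(k)
    sample_pseudohaploid(panel, spec$pop[k], spec$n[k],
                         missing_rate = spec$miss[k], seed = seed0 + k))
  Reduce(bind_datasets, sets)
}
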