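# Self-contained simulation studies used by the test suite and by
# scripts/acceptance.R. Each runs the whole pipeline stage on synthetic
# data with known ground truth and returns the fitted object.

# Drift graph for admixture-weight recovery: two diverged sources A and B
# at the ends of two drifted branches, eight outgroups hanging off both
# sides of the split so their f4 profiles distinguish the sources, and a
# target formed as the w-mixture of A and B plus post-admixture drift.
two_source_graph <- function(w, target_drift = 0.01) {
  ed <- data.frame(
    parent = c("R", "R", "S0", "S0", "S0", "L1", "L1", "L2", "L2",
               "L3", "L3", "R1", "R1", "R2", "R2", "R3", "R3", "Mix"),
    child = c("O1", "S0", "L1", "R1", "O8", "O2", "L2", "O3", "L3",
              "O4", "A", "O5", "R2", "O6", "R3", "O7", "B", "T"),
    f = c(0.10, 0.02, 0.02, 0.02, 0.08, 0.06, 0.02, 0.06, 0.02,
          0.06, 0.03, 0.06, 0.02, 0.06, 0.02, 0.06, 0.03, target_drift))
  adm <- data.frame(child = "Mix", parent_a = "A", parent_b = "B", w = w)
  drift_graph(ed, adm)
}

#' Admixture-weight recovery study
#'
#' Simulates a two-way admixed target cohort on a drift graph with eight
#' differentially related outgroups and re-estimates the mixture weights
#' with the rank-based admixture model fit. Defaults follow the study
#' design under test: truth 53.9% from the first source, 30 pseudohaploid
#' targets at 200k SNPs with 10% missingness.
#'
#' @param seed integer seed for all randomness.
#' @param w_true true proportion from source A.
#' @param n_snps,n_target,missing simulation size knobs.
#' @return A [qpadm_fit()] object.
#' @export
scenario_admixture_weights <- function(seed, w_true = 0.539,
                                       n_snps = 200000, n_target = 30,
                                       missing = 0.1) {
  pf <- simulate_freq_graph(two_source_graph(w_true), n_snps, seed = seed,
                            chrom_lengths = rep(1, 20))
  pops <- c("T", "A", "B", paste0("O", 1:8))
  ns <- c(n_target, 12, 12, rep(8, 8))
  miss <- c(missing, rep(0, 10))
  ds <- Reduce(bind_datasets, lapply(seq_along(pops), function(k)
    sample_pseudohaploid(pf, pops[k], ns[k], miss[k], seed = seed + 7 * k)))
  bl <- assign_blocks(ds$snp)
  qpadm_fit(ds, "T", c("A", "B"), paste0("O", 1:8), bl)
}

#' Admixture-date recovery study
#'
#' Simulates mosaic diploid chromosomes with a known admixture age and
#' refits it from the decay of weighted ancestry covariance. Defaults
#' follow the study design under test: truth 137 generations, mixture
#' 0.6/0.4, 100 diploids, 100k SNPs on 20 chromosomes of 1 Morgan,
#' source panels diverged at Fst ~ 0.05.
#'
#' @param seed integer seed.
#' @param t_true true admixture age in generations.
#' @param w mixture proportion from source A.
#' @param n_snps,n_ind,n_chrom simulation size knobs.
#' @return A [fit_decay()] object.
#' @export
scenario_admixture_date <- function(seed, t_true = 137, w = 0.6,
                                    n_snps = 100000, n_ind = 100,
                                    n_chrom = 20) {
  g <- drift_graph(data.frame(parent = c("A0", "A0"), child = c("A", "B"),
                              f = c(0.025, 0.025)))
  pf <- simulate_freq_graph(g, n_snps, seed = seed,
                            chrom_lengths = rep(1, n_chrom))
  ds <- simulate_admixed_cohort(pf$freqs["A", ], pf$freqs["B", ], pf$snp,
                                w = w, t_gens = t_true, n_ind = n_ind,
                                seed = seed + 1)
  wts <- snp_weights(pf$freqs["A", ], pf$freqs["B", ])
  cv <- covariance_curve(ds, wts, binsize = 0.001, maxdis = 0.20)
  fit_decay(cv, fit_min = 0.005, fit_max = 0.20)
}

#' Null calibration of the pairwise cladality test
#'
#' Repeatedly samples two groups from the same population and runs the
#' rank-0 test; returns the rejection rate at the given alpha, which
#' should be close to (and not exceed about twice) the nominal level.
#'
#' @param n_rep replicates.
#' @param seed integer seed.
#' @param n_snps SNPs per replicate.
#' @param alpha nominal level.
#' @return rejection fraction.
#' @export
qpwave_null_rejection <- function(n_rep, seed, n_snps = 5000, alpha = 0.05) {
  g <- drift_graph(data.frame(
    parent = c("R", "R", "N", "N", "N2", "N2"),
    child = c("O1", "N", "O2", "N2", "O3", "P"),
    f = c(0.1, 0.03, 0.08, 0.03, 0.08, 0.02)))
  rej <- vapply(seq_len(n_rep), function(r) {
    s <- seed + 13 * r
    pf <- simulate_freq_graph(g, n_snps, seed = s, chrom_lengths = rep(1, 5))
    ds <- Reduce(bind_datasets, list(
      sample_pseudohaploid(pf, "P", 5, 0, seed = s + 1, group = "P1",
                           id_prefix = "P1"),
      sample_pseudohaploid(pf, "P", 5, 0, seed = s + 2, group = "P2",
                           id_prefix = "P2"),
      sample_pseudohaploid(pf, "O1", 8, 0, seed = s + 3),
      sample_pseudohaploid(pf, "O2", 8, 0, seed = s + 4),
      sample_pseudohaploid(pf, "O3", 8, 0, seed = s + 5)))
    bl <- assign_blocks(ds$snp)
    qpwave_pair(ds, "P1", "P2", c("O1", "O2", "O3"), bl)$p < alpha
  }, TRUE)
  mean(rej)
}

#' Post-filter error of the adaptive caller
#'
#' Simulates pileups whose terminal strata carry damage far above the
#' reliability threshold and whose central strata sit below it, fits the
#' stratified error model on flagged monomorphic sites, calls genotypes,
#' and measures the achieved error of the calls against the simulated
#' truth.
#'
#' @param seed integer seed.
#' @param n_poly,n_mono site counts; `n_ind` individuals; `depth` mean
#'   coverage.
#' @param n_ind,depth see above.
#' @return list with `error` (fraction of calls disagreeing with truth)
#'   and `n_called`.
#' @export
caller_error_rate <- function(seed, n_poly = 800, n_mono = 800, n_ind = 5,
                              depth = 2) {
  g <- drift_graph(data.frame(parent = "R", child = "P", f = 0.05))
  pf <- simulate_freq_graph(g, n_poly + n_mono, seed = seed,
                            chrom_lengths = rep(1, 4))
  truth <- sample_pseudohaploid(pf, "P", n_ind, 0, seed = seed + 1)
  truth$snp$monomorphic <- seq_len(nrow(truth$snp)) <= n_mono
  dmg <- data.frame(from = c("C", "G", "A", "T", "C", "G"),
                    to = c("T", "A", "G", "C", "A", "T"),
                    terminal = c(TRUE, TRUE, NA, NA, NA, NA),
                    rate = c(0.12, 0.12, 0.004, 0.004, 0.004, 0.004))
  pu <- simulate_pileups(truth, depth, damage = dmg, seed = seed + 2)
  em <- fit_error_model(pu)
  called <- call_genotypes(pu, em, threshold = 0.02, seed = seed + 3)
  poly_idx <- which(!truth$snp$monomorphic)
  truth_poly <- truth$geno[, poly_idx]
  ok <- called$geno != 9L
  list(error = mean((called$geno != truth_poly)[ok]), n_called = sum(ok))
}

#' First-degree kinship classification accuracy
#'
#' Simulates parent-offspring pseudohaploid pairs at 100k overlapping
#' SNPs and reports the fraction classified as first degree against the
#' analytic unrelated baseline.
#'
#' @param n_rep replicates.
#' @param seed integer seed.
#' @param n_snps overlapping SNPs per replicate.
#' @return fraction of replicates classified "first".
#' @export
kin_classification_accuracy <- function(n_rep, seed, n_snps = 100000) {
  g <- drift_graph(data.frame(parent = "R", child = "P", f = 0.05))
  pf <- simulate_freq_graph(g, n_snps, seed = seed, chrom_lengths = rep(1, 20))
  p <- pf$freqs["P", ]
  bl <- assign_blocks(pf$snp)
  b <- mean(2 * p * (1 - p))
  hits <- vapply(seq_len(n_rep), function(r) {
    trio <- simulate_trio(p, seed = seed + 31 * r)
    mm <- pairwise_mismatch(trio$parent, trio$child, bl)
    classify_pair(mm$pmr, mm$se, mm$overlap, b)$degree == "first"
  }, TRUE)
  mean(hits)
}
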