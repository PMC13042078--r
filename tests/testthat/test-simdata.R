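test_that("drift graph validation rejects malformed specifications", {
  expect_error(drift_graph(data.frame(parent = "R", child = "A", f = 1.2)),
               "strictly in")
  expect_error(drift_graph(data.frame(parent = c("R", "B"),
                                      child = c("A", "A"),
                                      f = c(0.1, 0.1))),
               "more than one incoming")
  expect_error(drift_graph(data.frame(parent = c("A", "B"),
                                      child = c("B", "A"),
                                      f = c(0.1, 0.1))),
               "root|cyclic")
})

test_that("frequency simulation is a pure function of (spec, seed)", {
  g <- simple_graph()
  p1 <- simulate_freq_graph(g, 200, seed = 11)
  p2 <- simulate_freq_graph(g, 200, seed = 11)
  expect_identical(p1, p2)
  p3 <- simulate_freq_graph(g, 200, seed = 12)
  expect_false(identical(p1$freqs, p3$freqs))
})

test_that("Balding-Nichols drift preserves the mean and vanishes at F -> 0", {
  g0 <- drift_graph(data.frame(parent = "R", child = "A", f = 1e-6))
  pf0 <- simulate_freq_graph(g0, 5000, seed = 3)
  rms <- sqrt(mean((pf0$freqs["A", ] - pf0$freqs["R", ])^2))
  expect_lt(rms, 1e-2)

  gg <- drift_graph(data.frame(parent = "R", child = "A", f = 0.1))
  pf <- simulate_freq_graph(gg, 1e5, seed = 4)
  # E[child] = parent: mean difference ~ 0 at Monte-Carlo precision
  expect_lt(abs(mean(pf$freqs["A", ] - pf$freqs["R", ])), 3 * 0.15 / sqrt(1e5))
})

test_that("f2 between parent and child grows with drift F", {
  f2_at <- function(f) {
    g <- drift_graph(data.frame(parent = "R", child = "A", f = f))
    pf <- simulate_freq_graph(g, 3e4, seed = 21)
    mean((pf$freqs["A", ] - pf$freqs["R", ])^2)
  }
  v <- vapply(c(0.01, 0.05, 0.2), f2_at, 0)
  expect_true(all(diff(v) > 0))
})

test_that("pseudohaploid sampling matches panel frequencies and missingness", {
  g <- simple_graph()
  pf <- simulate_freq_graph(g, 400, seed = 2)
  pf$freqs["A", 1] <- 1.0
  ds <- sample_pseudohaploid(pf, "A", 1000, missing_rate = 0, seed = 6)
  expect_true(all(ds$geno[, 1] == 2L))

  j <- 17
  p <- pf$freqs["A", j]
  obs <- mean(ds$geno[, j] == 2L)
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 1000))

  ds2 <- sample_pseudohaploid(pf, "A", 50, missing_rate = 0.2, seed = 7)
  n_cell <- length(ds2$geno)
  expect_lt(abs(mean(ds2$geno == 9L) - 0.2), 3 * sqrt(0.2 * 0.8 / n_cell))
  expect_error(sample_pseudohaploid(pf, "Nope", 5, seed = 1), "unknown")
})

test_that("pileup simulation is seeded and damage-free when rates are zero", {
  g <- simple_graph()
  pf <- simulate_freq_graph(g, 100, seed = 2)
  truth <- sample_pseudohaploid(pf, "A", 3, 0, seed = 5)
  truth$snp$monomorphic <- rep(c(TRUE, FALSE), length.out = 100)
  pu1 <- simulate_pileups(truth, 2, damage = NULL, seed = 9)
  pu2 <- simulate_pileups(truth, 2, damage = NULL, seed = 9)
  expect_identical(as.data.frame(pu1), as.data.frame(pu2))

  # with no damage every read base equals the truth allele
  poly <- truth$snp[!truth$snp$monomorphic, ]
  rd <- pu1[pu1$site_id %in% poly$id & pu1$ind == "A_001", ]
  j <- match(rd$site_id, truth$snp$id)
  expected <- ifelse(truth$geno[1, j] == 0L, truth$snp$ref[j],
                     truth$snp$alt[j])
  expect_equal(rd$base, unname(expected))
})

test_that("terminal C->T damage is recovered at its simulated rate", {
  g <- simple_graph()
  pf <- simulate_freq_graph(g, 600, seed = 2)
  truth <- sample_pseudohaploid(pf, "A", 5, 0, seed = 5)
  truth$snp$monomorphic <- TRUE
  dmg <- data.frame(from = "C", to = "T", terminal = TRUE, rate = 0.10)
  pu <- simulate_pileups(truth, 4, damage = dmg, seed = 31)
  cs <- truth$snp$id[truth$snp$ref == "C"]
  term <- pu[pu$site_id %in% cs & pu$terminal, ]
  n <- nrow(term)
  expect_gt(n, 200)
  expect_lt(abs(mean(term$base == "T") - 0.10), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("admixed cohorts degenerate to the pure source at w = 1", {
  g <- simple_graph(fa = 0.2, fb = 0.2)
  pf <- simulate_freq_graph(g, 2000, seed = 8, chrom_lengths = rep(1, 4))
  ds <- simulate_admixed_cohort(pf$freqs["A", ], pf$freqs["B", ], pf$snp,
                                w = 1, t_gens = 10, n_ind = 200, seed = 3)
  j <- 101
  pa <- pf$freqs["A", j]
  obs <- mean(ds$geno[, j]) / 2
  expect_lt(abs(obs - pa), 3 * sqrt(pa * (1 - pa) / (2 * 200)))
  expect_error(simulate_admixed_cohort(pf$freqs["A", ], pf$freqs["B", ],
                                       pf$snp, w = 0.5, t_gens = 0,
                                       n_ind = 2, seed = 1),
               "positive")
  ds2 <- simulate_admixed_cohort(pf$freqs["A", ], pf$freqs["B", ], pf$snp,
                                 w = 0.5, t_gens = 5, n_ind = 3, seed = 4)
  ds3 <- simulate_admixed_cohort(pf$freqs["A", ], pf$freqs["B", ], pf$snp,
                                 w = 0.5, t_gens = 5, n_ind = 3, seed = 4)
  expect_identical(ds2$geno, ds3$geno)
})

test_that("ancestry covariance decays faster for older admixture", {
  g <- simple_graph(fa = 0.1, fb = 0.1)
  pf <- simulate_freq_graph(g, 8000, seed = 8, chrom_lengths = rep(1, 8))
  w <- snp_weights(pf$freqs["A", ], pf$freqs["B", ])
  slope_at <- function(t_gens, seed) {
    ds <- simulate_admixed_cohort(pf$freqs["A", ], pf$freqs["B", ], pf$snp,
                                  w = 0.5, t_gens = t_gens, n_ind = 40,
                                  seed = seed)
    cv <- covariance_curve(ds, w, binsize = 0.005, maxdis = 0.15)
    fit_decay(cv, fit_min = 0.005, fit_max = 0.15)$t
  }
  t_small <- slope_at(15, 51)
  t_large <- slope_at(60, 52)
  expect_lt(t_small, t_large)
})

test_that("ROH simulation matches the segment-count model and is seeded", {
  sim1 <- simulate_roh_genome(240, rep(1.75, 20), 0.2, 5, seed = 77,
                              geno = FALSE)
  sim2 <- simulate_roh_genome(240, rep(1.75, 20), 0.2, 5, seed = 77,
                              geno = FALSE)
  expect_identical(sim1$segments, sim2$segments)

  big <- simulate_roh_genome(240, rep(1.75, 20), 0.2, 200, seed = 78,
                             geno = FALSE)
  e20 <- expected_roh_counts(240, 35, c(20, 300))$expected
  obs <- sum(big$segments$length_cm > 20) / 200
  expect_lt(abs(obs - e20), 3 * sqrt(e20 / 200))
})

test_that("het_rate = 0 genomes are flagged degenerate by the caller", {
  sim <- simulate_roh_genome(100, c(1, 1), 0, 1, seed = 5)
  segs <- call_roh(sim$dataset$geno[1, ], sim$dataset$snp)
  expect_true(attr(segs, "degenerate"))
  expect_equal(nrow(segs), 2L) # one full-length run per chromosome
})

test_that("QC table construction yields exactly the requested composition", {
  tbl <- simulate_qc_table(5, list(c("snps_covered", 14999),
                                   c("sex_ratio", 0.2)), seed = 1)
  res <- apply_qc(tbl)
  expect_length(res$pass, 5)
  expect_equal(res$fail$reasons, c("coverage", "sex_ratio"))

  tbl2 <- simulate_qc_table(4, list(), seed = 2)
  expect_length(apply_qc(tbl2)$pass, 4)
  expect_error(simulate_qc_table(2, list(c("snps_covered", 20000)), seed = 3),
               "does not violate")
})
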