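# A drift graph whose references straddle the A/B split, so the f4
# profiles of the two sources differ (identifiable admixture weights).
qpadm_graph <- function(w = 0.6, target_drift = 0.01) {
  ed <- data.frame(
    parent = c("R", "R", "S0", "S0", "L1", "L1", "L2", "L2",
               "R1", "R1", "R2", "R2"),
    child = c("O1", "S0", "L1", "R1", "O2", "L2", "O3", "A",
              "O4", "R2", "O5", "B"),
    f = c(0.10, 0.02, 0.02, 0.02, 0.06, 0.02, 0.06, 0.03,
          0.06, 0.02, 0.06, 0.03))
  adm <- data.frame(child = "Mix", parent_a = "A", parent_b = "B", w = w)
  ed2 <- rbind(ed, data.frame(parent = "Mix", child = "T", f = target_drift))
  drift_graph(ed2, adm)
}

qpadm_cohort <- function(pf, n_target = 20, seed0 = 500, miss = 0.1) {
  spec <- tibble::tibble(
    pop = c("T", "A", "B", "O1", "O2", "O3", "O4", "O5"),
    n = c(n_target, 10, 10, 8, 8, 8, 8, 8),
    miss = c(miss, rep(0, 7)))
  sample_cohort(pf, spec, seed0 = seed0)
}

test_that("f4 matrix entries vanish for duplicated left populations and
           agree with the fstats module", {
  pf <- simulate_freq_graph(qpadm_graph(), 8000, seed = 3,
                            chrom_lengths = rep(1, 10))
  ds <- qpadm_cohort(pf, seed0 = 700)
  bl <- assign_blocks(ds$snp)
  m_dup <- build_f4_matrix(ds, c("A", "A"), c("O1", "O2", "O3"), bl)
  expect_equal(unname(m_dup$x), matrix(0, 1, 2))

  m <- build_f4_matrix(ds, c("T", "A", "B"), c("O1", "O2", "O3"), bl)
  for (i in 1:2) for (j in 1:2) {
    ref <- f4(ds, c("A", "B")[i], "T", c("O2", "O3")[j], "O1", bl)
    expect_equal(m$x[i, j], ref$estimate, tolerance = 1e-12)
  }
})

test_that("jackknife covariance diagonal matches a direct block-resampling
           oracle", {
  pf <- simulate_freq_graph(qpadm_graph(), 4000, seed = 5,
                            chrom_lengths = rep(1, 8))
  ds <- qpadm_cohort(pf, seed0 = 900, miss = 0)
  bl <- assign_blocks(ds$snp)
  m <- build_f4_matrix(ds, c("T", "A", "B"), c("O1", "O2", "O3"), bl)
  # oracle: per-entry jackknife SE computed independently via block_jackknife
  ent <- 0
  for (j in 1:2) for (i in 1:2) { # column-major like c(x)
    ent <- ent + 1
    v <- per_snp_contributions(ds, "f4",
                               c(c("A", "B")[i], "T", c("O2", "O3")[j], "O1"))
    jk <- block_jackknife(v$values, bl)
    expect_equal(sqrt(m$cov[ent, ent]), jk$se, tolerance = 1e-8)
  }
})

test_that("rank-0 chi2 is zero with zero entries and symmetric in the pair", {
  m0 <- structure(list(x = matrix(0, 1, 3), cov = diag(3) * 1e-6,
                       left = c("a", "b"), right = c("r0", "r1", "r2", "r3"),
                       n_snps = 1000, n_blocks = 50),
                  class = "f4_matrix")
  rt <- rank_test(m0, 0)
  expect_equal(rt$chi2, 0)
  expect_equal(rt$p, 1)

  pf <- simulate_freq_graph(qpadm_graph(), 4000, seed = 6,
                            chrom_lengths = rep(1, 8))
  ds <- qpadm_cohort(pf, seed0 = 300, miss = 0)
  bl <- assign_blocks(ds$snp)
  r_ab <- rank_test(build_f4_matrix(ds, c("A", "B"),
                                    c("O1", "O2", "O3"), bl), 0)
  r_ba <- rank_test(build_f4_matrix(ds, c("B", "A"),
                                    c("O1", "O2", "O3"), bl), 0)
  expect_equal(r_ab$chi2, r_ba$chi2, tolerance = 1e-9)
})

test_that("cladality grouping separates true populations", {
  pf <- simulate_freq_graph(qpadm_graph(), 20000, seed = 8,
                            chrom_lengths = rep(1, 10))
  dsA <- sample_pseudohaploid(pf, "A", 4, 0, seed = 21)
  dsB <- sample_pseudohaploid(pf, "B", 4, 0, seed = 22)
  refs <- Reduce(bind_datasets, lapply(1:3, function(k)
    sample_pseudohaploid(pf, c("O1", "O2", "O3")[k], 8, 0, seed = 30 + k)))
  ds <- Reduce(bind_datasets, list(dsA, dsB, refs))
  bl <- assign_blocks(ds$snp)
  ids <- c(dsA$ind$id, dsB$ind$id)
  grp <- group_by_cladality(ds, ids, c("O1", "O2", "O3"), bl)
  ga <- grp$group[1:4]
  gb <- grp$group[5:8]
  expect_equal(length(unique(ga)), 1L)
  expect_equal(length(unique(gb)), 1L)
  expect_false(unique(ga) == unique(gb))

  single <- group_by_cladality(ds, ids[1], c("O1", "O2", "O3"), bl)
  expect_equal(single$group, 1L)
  expect_false(single$ambiguous)
})

test_that("qpAdm recovers a degenerate one-source target", {
  gg <- qpadm_graph(w = 1, target_drift = 0.005)
  pf <- simulate_freq_graph(gg, 40000, seed = 12, chrom_lengths = rep(1, 10))
  ds <- qpadm_cohort(pf, seed0 = 110)
  bl <- assign_blocks(ds$snp)
  fit <- qpadm_fit(ds, "T", c("A", "B"), c("O1", "O2", "O3", "O4", "O5"), bl)
  expect_lt(abs(fit$weights$weight[1] - 1), 2 * fit$weights$se[1] + 0.02)
  expect_lt(abs(fit$weights$weight[2] - 0), 2 * fit$weights$se[2] + 0.02)
  expect_equal(sum(fit$weights$weight), 1)
})

test_that("qpAdm weights are equivariant to source order and recover 50/50", {
  pf <- simulate_freq_graph(qpadm_graph(w = 0.5), 40000, seed = 13,
                            chrom_lengths = rep(1, 10))
  ds <- qpadm_cohort(pf, seed0 = 120)
  bl <- assign_blocks(ds$snp)
  refs <- c("O1", "O2", "O3", "O4", "O5")
  fit <- qpadm_fit(ds, "T", c("A", "B"), refs, bl)
  expect_lt(abs(fit$weights$weight[1] - 0.5), 2 * fit$weights$se[1])
  fit_rev <- qpadm_fit(ds, "T", c("B", "A"), refs, bl)
  expect_equal(fit$weights$weight[1], fit_rev$weights$weight[2],
               tolerance = 1e-6)
  expect_gt(fit$p, 0.05)
})

test_that("one-source models of a two-source target are rejected", {
  pf <- simulate_freq_graph(qpadm_graph(w = 0.5), 40000, seed = 14,
                            chrom_lengths = rep(1, 10))
  ds <- qpadm_cohort(pf, seed0 = 130)
  bl <- assign_blocks(ds$snp)
  fit1 <- qpadm_fit(ds, "T", "A", c("O1", "O2", "O3", "O4", "O5"), bl)
  expect_lt(fit1$p, 0.05)
})

test_that("results are invariant to the choice of right base population", {
  pf <- simulate_freq_graph(qpadm_graph(w = 0.5), 20000, seed = 17,
                            chrom_lengths = rep(1, 10))
  ds <- qpadm_cohort(pf, seed0 = 140, miss = 0)
  bl <- assign_blocks(ds$snp)
  refs1 <- c("O1", "O2", "O3", "O4", "O5")
  refs2 <- c("O3", "O1", "O2", "O4", "O5") # different base, same set
  r1 <- rank_test(build_f4_matrix(ds, c("A", "B"), refs1, bl), 0)
  r2 <- rank_test(build_f4_matrix(ds, c("A", "B"), refs2, bl), 0)
  expect_equal(r1$chi2, r2$chi2, tolerance = 1e-6)
  f1 <- qpadm_fit(ds, "T", c("A", "B"), refs1, bl)
  f2 <- qpadm_fit(ds, "T", c("A", "B"), refs2, bl)
  expect_equal(f1$weights$weight, f2$weights$weight, tolerance = 1e-4)
})
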