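test_that("f4 hand example: two SNPs with exact sample frequencies", {
  # a = (.5, .2), b = (.1, .4), c = (.9, .1), d = (.3, .5)
  ds <- exact_pop_dataset(list(
    A = list(alt = list(c(5, 2)), n = 10),
    B = list(alt = list(c(1, 4)), n = 10),
    C = list(alt = list(c(9, 1)), n = 10),
    D = list(alt = list(c(3, 5)), n = 10)))
  contrib <- per_snp_contributions(ds, "f4", c("A", "B", "C", "D"))
  expect_equal(contrib$values, c(0.24, 0.08))
  expect_equal(mean(contrib$values), 0.16)
})

test_that("f4 with identical third and fourth populations is zero", {
  ds <- exact_pop_dataset(list(
    A = list(alt = list(c(5, 2, 7)), n = 10),
    B = list(alt = list(c(1, 4, 2)), n = 10),
    C = list(alt = list(c(9, 1, 5)), n = 10)))
  contrib <- per_snp_contributions(ds, "f4", c("A", "B", "C", "C"))
  expect_equal(contrib$values, c(0, 0, 0))
})

test_that("estimates match the brute-force oracle on random datasets", {
  g <- simple_graph()
  withr::with_seed(31, {
    for (rep in 1:3) {
      pf <- simulate_freq_graph(g, 150, seed = 100 + rep,
                                chrom_lengths = c(1, 1))
      ds <- Reduce(bind_datasets, list(
        sample_pseudohaploid(pf, "A", 4, 0.2, seed = rep),
        sample_pseudohaploid(pf, "B", 3, 0.1, seed = rep + 10),
        sample_diploid(pf, "O", 3, 0.1, seed = rep + 20),
        sample_pseudohaploid(pf, "N", 2, 0, seed = rep + 30)))
      for (inb in c(TRUE, FALSE)) {
        for (cfg in list(list("f2", c("A", "B")),
                         list("f3", c("A", "B", "O")),
                         list("f4", c("A", "B", "O", "N")))) {
          got <- per_snp_contributions(ds, cfg[[1]], cfg[[2]], inbreed = inb)
          expect_equal(mean(got$values, na.rm = TRUE),
                       oracle_fstat(ds, cfg[[1]], cfg[[2]], inbreed = inb),
                       tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("f4 is additive in its third slot on shared masks", {
  g <- drift_graph(data.frame(parent = c("R", "R", "R", "R", "R"),
                              child = c("A", "B", "C", "D", "E"),
                              f = rep(0.1, 5)))
  pf <- simulate_freq_graph(g, 500, seed = 9, chrom_lengths = c(1, 1))
  ds <- Reduce(bind_datasets, lapply(seq_along(c("A", "B", "C", "D", "E")),
    function(k) sample_pseudohaploid(pf, c("A", "B", "C", "D", "E")[k],
                                     5, 0, seed = k)))
  v_cd <- per_snp_contributions(ds, "f4", c("A", "B", "C", "D"))$values
  v_ce <- per_snp_contributions(ds, "f4", c("A", "B", "C", "E"))$values
  v_ed <- per_snp_contributions(ds, "f4", c("A", "B", "E", "D"))$values
  expect_equal(v_cd, v_ce + v_ed, tolerance = 1e-12)
})

test_that("f3(A, A; X) equals f2(X, A) when corrections are skipped (n = 1)", {
  g <- simple_graph()
  pf <- simulate_freq_graph(g, 300, seed = 10)
  ds <- bind_datasets(sample_pseudohaploid(pf, "A", 1, 0, seed = 1),
                      sample_pseudohaploid(pf, "O", 1, 0, seed = 2))
  v3 <- per_snp_contributions(ds, "f3", c("A", "A", "O"))$values
  v2 <- per_snp_contributions(ds, "f2", c("O", "A"))$values
  expect_equal(v3, v2, tolerance = 1e-14)
})

test_that("weighted jackknife reduces to the textbook formula, SE 0 when flat", {
  withr::with_seed(5, {
    vals <- rnorm(200)
    block <- rep(1:10, each = 20)
    jk <- block_jackknife(vals, block)
    expect_equal(jk$estimate, mean(vals))
    expect_equal(jk$se, oracle_unweighted_jackknife(vals, block),
                 tolerance = 1e-10)
  })
  # all per-block means equal -> SE exactly 0
  jk0 <- block_jackknife(rep(c(1, 2), 50), rep(1:5, each = 20))
  expect_equal(jk0$se, 0)
  # an empty (fully masked) block leaves the estimate unchanged
  vals <- c(rnorm(40), rep(NA, 10))
  block <- rep(1:5, each = 10)
  jk1 <- block_jackknife(vals, block)
  expect_equal(jk1$estimate, mean(vals, na.rm = TRUE))
  expect_equal(jk1$n_blocks, 4L)
  expect_error(block_jackknife(rep(NA_real_, 10), rep(1, 10)), "2 non-empty")
})

test_that("batteries flag |Z| > 3 under gene flow but not under the null", {
  # null clade: C and D split from the same node, Test symmetric
  gnull <- drift_graph(data.frame(
    parent = c("R", "R", "N", "N", "N2", "N2"),
    child = c("O", "N", "Test", "N2", "CladeA", "CladeB"),
    f = c(0.1, 0.05, 0.05, 0.02, 0.02, 0.02)))
  pf <- simulate_freq_graph(gnull, 20000, seed = 61, chrom_lengths = rep(1, 10))
  ds <- Reduce(bind_datasets, lapply(
    list(c("O", 1), c("Test", 2), c("CladeA", 3), c("CladeB", 4)),
    function(x) sample_pseudohaploid(pf, x[1], 8, 0, seed = as.integer(x[2]))))
  bl <- assign_blocks(ds$snp)
  spec <- tibble::tibble(kind = "f4", pop1 = "O", pop2 = "Test",
                         pop3 = "CladeA", pop4 = "CladeB")
  out <- run_battery(ds, spec, bl)
  expect_false(out$significant[1])

  # alternative: Test receives gene flow from CladeA's ancestor
  galt <- drift_graph(
    data.frame(parent = c("R", "R", "N", "N2", "N2", "Mix"),
               child = c("O", "N", "N2", "CladeA", "CladeB", "Test"),
               f = c(0.1, 0.05, 0.02, 0.02, 0.02, 0.02)),
    admixtures = data.frame(child = "Mix", parent_a = "CladeA",
                            parent_b = "N", w = 0.5))
  pf2 <- simulate_freq_graph(galt, 20000, seed = 62, chrom_lengths = rep(1, 10))
  ds2 <- Reduce(bind_datasets, lapply(
    list(c("O", 1), c("Test", 2), c("CladeA", 3), c("CladeB", 4)),
    function(x) sample_pseudohaploid(pf2, x[1], 8, 0, seed = as.integer(x[2]))))
  out2 <- run_battery(ds2, spec, assign_blocks(ds2$snp))
  expect_true(out2$significant[1])

  expect_equal(nrow(run_battery(ds, spec[0, ], bl)), 0L)
  expect_error(run_battery(ds, dplyr::mutate(spec, pop1 = "Nope"), bl),
               "Nope")
})
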