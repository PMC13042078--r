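mk_stratum <- function() list(lib = "lib1", terminal = TRUE, strand = "+",
                              mq_bin = "mq_hi", bq_bin = "bq_hi")

mk_model <- function(rates, prior = 0.001) {
  # rates: named list like list("C>T" = 0.01, "T>C" = 0.03)
  rows <- lapply(names(rates), function(k) {
    ab <- strsplit(k, ">")[[1]]
    tibble::tibble(lib = "lib1", terminal = TRUE, strand = "+",
                   mq_bin = "mq_hi", bq_bin = "bq_hi",
                   from = ab[1], to = ab[2], rate = rates[[k]], n_obs = 1000L)
  })
  structure(dplyr::bind_rows(rows), prior = prior,
            class = c("error_model", "tbl_df", "tbl", "data.frame"))
}

mk_reads <- function(bases, terminal = TRUE) {
  tibble::tibble(base = bases, strand = "+", terminal = terminal,
                 mq = 37L, bq = 37L, lib = "lib1")
}

test_that("error rates are mismatch fractions with exact arithmetic", {
  # 12 mismatching reads out of 1000 in one stratum -> rate 0.012
  n <- 1000
  snp <- tibble::tibble(id = "m1", chrom = "1", gpos = 0.01, ppos = 1,
                        ref = "C", alt = "T", monomorphic = TRUE)
  reads <- tibble::tibble(ind = "i1", site_id = "m1",
                          base = c(rep("T", 12), rep("C", n - 12)),
                          strand = "+", terminal = TRUE, mq = 37L, bq = 37L,
                          lib = "lib1", udg = TRUE)
  pu <- structure(reads, snp = snp, class = class(tibble::tibble()))
  attr(pu, "snp") <- snp
  em <- fit_error_model(pu)
  ct <- em[em$from == "C" & em$to == "T", ]
  expect_equal(ct$rate, 0.012)
  expect_equal(ct$n_obs, 1000L)
  # zero-mismatch direction has rate exactly 0
  cg <- em[em$from == "C" & em$to == "G", ]
  expect_equal(cg$rate, 0)
})

test_that("reliability S is the symmetric max of directional errors", {
  st <- mk_stratum()
  em <- mk_model(list("C>T" = 0.01, "T>C" = 0.03))
  expect_equal(reliability_s(em, "C", "T", st), 0.03)
  expect_equal(reliability_s(em, "T", "C", st), 0.03)
  em2 <- mk_model(list("C>T" = 0.02, "T>C" = 0.02))
  expect_equal(reliability_s(em2, "C", "T", st), 0.02)
  withr::with_seed(8, {
    for (k in 1:10) {
      r1 <- runif(1, 0, 0.2); r2 <- runif(1, 0, 0.2)
      emk <- mk_model(list("A>G" = r1, "G>A" = r2))
      expect_equal(reliability_s(emk, "A", "G", mk_stratum()),
                   reliability_s(emk, "G", "A", mk_stratum()))
    }
  })
})

test_that("fitted rates recover simulated stratum truth", {
  g <- simple_graph()
  pf <- simulate_freq_graph(g, 800, seed = 2)
  truth <- sample_pseudohaploid(pf, "A", 6, 0, seed = 5)
  truth$snp$monomorphic <- TRUE
  dmg <- data.frame(from = "C", to = "T", terminal = TRUE, rate = 0.08)
  pu <- simulate_pileups(truth, 4, damage = dmg, seed = 13)
  em <- fit_error_model(pu)
  hits <- em[em$from == "C" & em$to == "T" & em$terminal, ]
  for (k in seq_len(nrow(hits))) {
    tol <- 3 * sqrt(0.08 * 0.92 / hits$n_obs[k])
    expect_lt(abs(hits$rate[k] - 0.08), tol + 1e-9)
  }
})

test_that("site calling filters unreliable strata and draws uniformly", {
  em <- mk_model(list("C>T" = 0.005, "T>C" = 0.005))
  # 3 reliable ref reads, no alt: deterministic ref call
  expect_equal(call_site(mk_reads(c("C", "C", "C")), em, "C", "T", "s1"), 0L)
  # empty pileup is missing
  expect_equal(call_site(mk_reads(character(0)), em, "C", "T", "s1"), 9L)
  # all reads in strata at or above the threshold are discarded
  em_bad <- mk_model(list("C>T" = 0.05, "T>C" = 0.05))
  expect_equal(call_site(mk_reads(c("C", "T", "C")), em_bad, "C", "T", "s1"),
               9L)
  # bases matching neither allele are dropped before the draw
  expect_equal(call_site(mk_reads(c("G", "G", "C")), em, "C", "T", "s1"), 0L)

  # 2 ref + 1 alt: ref called in ~2/3 of independent seeded draws
  reads <- mk_reads(c("C", "C", "T"))
  n_draw <- 10000
  calls <- vapply(seq_len(n_draw), function(s)
    call_site(reads, em, "C", "T", "s1", seed = s), 0L)
  frac_ref <- mean(calls == 0L)
  expect_lt(abs(frac_ref - 2 / 3), 3 * sqrt(2 / 9 / n_draw))
})

test_that("calls are reproducible and independent of read order", {
  em <- mk_model(list("C>T" = 0.005, "T>C" = 0.005))
  reads <- mk_reads(c("C", "T", "C", "T", "C"))
  a <- call_site(reads, em, "C", "T", "siteX", seed = 7)
  b <- call_site(reads[c(4, 1, 5, 3, 2), ], em, "C", "T", "siteX", seed = 7)
  expect_identical(a, b)
})

test_that("library metrics compute damage and sex ratio conventions", {
  g <- simple_graph()
  pf <- simulate_freq_graph(g, 500, seed = 2)
  truth <- sample_pseudohaploid(pf, "A", 4, 0, seed = 5)
  truth$snp$monomorphic <- TRUE
  dmg <- data.frame(from = "C", to = "T", terminal = TRUE, rate = 0.10)
  pu <- simulate_pileups(truth, 4, damage = dmg, seed = 19)
  m <- library_metrics(pu, x_reads = 1000, y_reads = 0)
  expect_equal(m$sex_ratio, 0)
  n_term <- sum(pu$site_id %in% truth$snp$id[truth$snp$ref == "C"] &
                  pu$terminal)
  expect_lt(abs(m$damage_rate - 0.10), 3 * sqrt(0.1 * 0.9 / n_term))
  expect_equal(library_metrics(pu, 500, 500)$sex_ratio, 0.5)
  expect_true(is.na(library_metrics(pu, 0, 0)$sex_ratio))
})

test_that("QC boundaries are strict inequalities and reasons accumulate", {
  tbl <- simulate_qc_table(1, list(), seed = 4)
  tbl$snps_covered[1] <- 15000L  # exactly at threshold: passes
  tbl$sex_ratio[1] <- 0.05       # boundary of the open interval: passes
  expect_length(apply_qc(tbl)$pass, 1)
  tbl$sex_ratio[1] <- 0.3
  expect_length(apply_qc(tbl)$pass, 1)

  tbl$snps_covered[1] <- 14999L
  tbl$contam_lower_bound[1] <- 0.02
  res <- apply_qc(tbl)
  expect_equal(res$fail$reasons, "coverage;contamination")

  tbl$contam_lower_bound[1] <- NA_real_
  expect_equal(apply_qc(tbl)$fail$reasons, "incomplete")
})

test_that("first-degree pruning keeps the higher-coverage member", {
  tbl <- simulate_qc_table(4, list(), seed = 6)
  rel <- tibble::tibble(id1 = tbl$id[1], id2 = tbl$id[2])
  res <- apply_qc(tbl, relatives = rel)
  dropped <- tbl$id[which.min(tbl$snps_covered[1:2])]
  expect_false(dropped %in% res$pass)
  expect_true(dropped %in% res$pass_individual)
  expect_equal(res$fail$reasons[res$fail$id == dropped], "relative_of_passer")
})
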