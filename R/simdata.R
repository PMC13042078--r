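#' Specify a drift/admixture graph
#'
#' A drift graph describes how population allele frequencies diverge from a
#' common root: each edge carries a drift parameter F in (0, 1) and each
#' admixture event mixes two parent nodes with weight `w`. Frequencies drift
#' along edges under the Balding-Nichols model, which keeps the expected
#' frequency equal to the parent frequency while inflating its variance by
#' F p(1-p).
#'
#' @param edges tibble/data.frame with columns `parent`, `child`, `f`
#'   (drift, strictly in (0,1)).
#' @param admixtures optional tibble with columns `child`, `parent_a`,
#'   `parent_b`, `w` (proportion from `parent_a`, in \[0,1\]).
#' @param root_freq length-2 numeric range for the uniform law of root
#'   allele frequencies (default `c(0.05, 0.95)`).
#' @return An object of class `drift_graph`.
#' @export
drift_graph <- function(edges, admixtures = NULL, root_freq = c(0.05, 0.95)) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("parent", "child", "f") %in% names(edges)))
  if (any(edges$f <= 0 | edges$f >= 1)) stop("drift F must lie strictly in (0,1)")
  if (!is.null(admixtures)) {
    admixtures <- tibble::as_tibble(admixtures)
    stopifnot(all(c("child", "parent_a", "parent_b", "w") %in% names(admixtures)))
    if (any(admixtures$w < 0 | admixtures$w > 1)) stop("admixture weight must be in [0,1]")
  } else {
    admixtures <- tibble::tibble(child = character(), parent_a = character(),
                                 parent_b = character(), w = double())
  }
  children <- c(edges$child, admixtures$child)
  if (anyDuplicated(children))
    stop("node(s) with more than one incoming edge/event: ",
         paste(unique(children[duplicated(children)]), collapse = ", "))
  parents <- c(edges$parent, admixtures$parent_a, admixtures$parent_b)
  nodes <- unique(c(parents, children))
  roots <- setdiff(nodes, children)
  if (length(roots) != 1) stop("graph must have exactly one root, found: ",
                               paste(roots, collapse = ", "))
  g <- structure(list(edges = edges, admixtures = admixtures,
                      nodes = nodes, root = roots, root_freq = root_freq),
                 class = "drift_graph")
  topo_order(g) # errors if cyclic
  g
}

# Kahn topological sort; errors on cycles.
topo_order <- function(g) {
  deps <- c(stats::setNames(as.list(g$edges$parent), g$edges$child),
            stats::setNames(purrr::map2(g$admixtures$parent_a,
                                        g$admixtures$parent_b, c),
                            g$admixtures$child))
  order <- g$root
  remaining <- setdiff(g$nodes, order)
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining,
                              function(n) all(deps[[n]] %in% order), TRUE)]
    if (length(ready) == 0) stop("drift graph is cyclic")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Build a genetic map of evenly covered chromosomes
#'
#' SNP genetic positions are uniform on each chromosome and sorted; physical
#' positions assume 1 cM per Mb. Used by all simulators.
#'
#' @param n_snps total number of SNPs.
#' @param chrom_lengths per-chromosome map lengths in Morgans.
#' @return SNP tibble (`id`, `chrom`, `gpos`, `ppos`, `ref`, `alt`).
#' @keywords internal
sim_snp_table <- function(n_snps, chrom_lengths) {
  n_chr <- length(chrom_lengths)
  chr_of <- sort(sample.int(n_chr, n_snps, replace = TRUE,
                            prob = chrom_lengths / sum(chrom_lengths)))
  gpos <- unlist(lapply(seq_len(n_chr), function(ch) {
    sort(stats::runif(sum(chr_of == ch), 0, chrom_lengths[ch]))
  }))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  tibble::tibble(id = sprintf("rs%06d", seq_len(n_snps)),
                 chrom = as.character(chr_of),
                 gpos = gpos,
                 ppos = as.integer(round(gpos * 1e8) + 1),
                 ref = ref, alt = unname(alt))
}

#' Simulate per-population allele frequencies on a drift graph
#'
#' Root frequencies are uniform on the configured range; each child's
#' frequency is drawn from the Balding-Nichols beta law
#' Beta(p(1-F)/F, (1-p)(1-F)/F) given the parent frequency p, so
#' E\[child\] = parent and Var = F p(1-p). Admixed nodes take the weighted
#' mean of their parents before any further drift.
#'
#' @param graph a [drift_graph()].
#' @param n_snps number of SNPs.
#' @param seed integer seed; identical inputs give identical panels.
#' @param chrom_lengths per-chromosome map lengths in Morgans
#'   (default 20 chromosomes of 1 Morgan).
#' @return An object of class `panel_freqs`: list with `freqs`
#'   (populations x SNPs matrix) and `snp` (SNP tibble).
#' @export
simulate_freq_graph <- function(graph, n_snps, seed,
                                chrom_lengths = rep(1, 20)) {
  stopifnot(inherits(graph, "drift_graph"), n_snps >= 1)
  withr::with_seed(seed, {
    snp <- sim_snp_table(n_snps, chrom_lengths)
    order <- topo_order(graph)
    freqs <- matrix(NA_real_, nrow = length(order), ncol = n_snps,
                    dimnames = list(order, snp$id))
    freqs[graph$root, ] <- stats::runif(n_snps, graph$root_freq[1],
                                        graph$root_freq[2])
    for (node in order[-1]) {
      ei <- match(node, graph$edges$child)
      if (!is.na(ei)) {
        p <- freqs[graph$edges$parent[ei], ]
        f <- graph$edges$f[ei]
        interior <- p > 0 & p < 1
        drifted <- p
        drifted[interior] <- stats::rbeta(sum(interior),
                                          p[interior] * (1 - f) / f,
                                          (1 - p[interior]) * (1 - f) / f)
        freqs[node, ] <- drifted
      } else {
        ai <- match(node, graph$admixtures$child)
        w <- graph$admixtures$w[ai]
        freqs[node, ] <- w * freqs[graph$admixtures$parent_a[ai], ] +
          (1 - w) * freqs[graph$admixtures$parent_b[ai], ]
      }
    }
    structure(list(freqs = freqs, snp = snp), class = "panel_freqs")
  })
}

#' @export
print.panel_freqs <- function(x, ...) {
  cat("<panel_freqs> ", nrow(x$freqs), " populations x ", ncol(x$freqs),
      " SNPs\n", sep = "")
  invisible(x)
}

#' Sample pseudohaploid individuals from a frequency panel
#'
#' Draws one haploid allele per individual per SNP (Bernoulli in the panel
#' frequency), coded 0/2 with 9 for missing; missingness is independent per
#' cell. This emulates the output of random-base pseudohaploid calling on
#' low-coverage ancient samples.
#'
#' @param panel a `panel_freqs`.
#' @param pop population row of the panel to sample from.
#' @param n_ind number of individuals.
#' @param missing_rate per-cell missingness probability in \[0,1).
#' @param seed integer seed.
#' @param group group label for the individual table (default `pop`).
#' @param id_prefix prefix for individual ids.
#' @return A [paleo_dataset()] of pseudohaploid individuals.
#' @export
sample_pseudohaploid <- function(panel, pop, n_ind, missing_rate = 0, seed,
                                 group = pop, id_prefix = pop) {
  if (!pop %in% rownames(panel$freqs)) stop("unknown population: ", pop)
  stopifnot(missing_rate >= 0, missing_rate < 1)
  withr::with_seed(seed, {
    p <- panel$freqs[pop, ]
    n_snp <- length(p)
    g <- matrix(2L * stats::rbinom(n_ind * n_snp, 1L, rep(p, each = n_ind)),
                nrow = n_ind)
    if (missing_rate > 0)
      g[stats::runif(length(g)) < missing_rate] <- 9L
    ind <- tibble::tibble(id = sprintf("%s_%03d", id_prefix, seq_len(n_ind)),
                          sex = "U", group = group, ploidy = "haploid")
    paleo_dataset(g, panel$snp, ind)
  })
}

#' Sample diploid individuals from a frequency panel
#'
#' Two independent alleles per individual per SNP under Hardy-Weinberg.
#'
#' @inheritParams sample_pseudohaploid
#' @return A [paleo_dataset()] of diploid individuals.
#' @export
sample_diploid <- function(panel, pop, n_ind, missing_rate = 0, seed,
                           group = pop, id_prefix = pop) {
  if (!pop %in% rownames(panel$freqs)) stop("unknown population: ", pop)
  withr::with_seed(seed, {
    p <- panel$freqs[pop, ]
    n_snp <- length(p)
    g <- matrix(stats::rbinom(n_ind * n_snp, 2L, rep(p, each = n_ind)),
                nrow = n_ind)
    if (missing_rate > 0)
      g[stats::runif(length(g)) < missing_rate] <- 9L
    ind <- tibble::tibble(id = sprintf("%s_%03d", id_prefix, seq_len(n_ind)),
                          sex = "U", group = group, ploidy = "diploid")
    paleo_dataset(g, panel$snp, ind)
  })
}

#' Simulate a cohort of admixed mosaic diploids
#'
#' Each haplotype is an ancestry mosaic along the genetic map: the ancestry
#' state starts Bernoulli(w) and is redrawn at the points of a Poisson
#' process of rate `t_gens` per Morgan, the standard approximation in which
#' the covariance of ancestry between two loci at distance d Morgans decays
#' as w(1-w) exp(-t d). Alleles are drawn from the local ancestry's source
#' frequency; the diploid genotype is the sum of two independent haplotypes.
#'
#' @param pa,pb per-SNP allele frequencies of source A and source B.
#' @param snp shared SNP tibble (with `chrom` and `gpos` in Morgans).
#' @param w proportion of ancestry from source A, in \[0,1\].
#' @param t_gens generations since admixture (positive integer).
#' @param n_ind number of diploid individuals.
#' @param seed integer seed.
#' @param group group label.
#' @return A [paleo_dataset()] of diploid individuals.
#' @export
simulate_admixed_cohort <- function(pa, pb, snp, w, t_gens, n_ind, seed,
                                    group = "Admixed") {
  if (t_gens < 1) stop("t_gens must be a positive integer")
  stopifnot(length(pa) == nrow(snp), length(pb) == nrow(snp),
            w >= 0, w <= 1)
  withr::with_seed(seed, {
    n_snp <- nrow(snp)
    chrs <- unique(snp$chrom)
    geno <- matrix(0L, nrow = n_ind, ncol = n_snp)
    for (hap in 1:2) {
      anc <- matrix(NA, nrow = n_ind, ncol = n_snp) # TRUE = source A
      for (ch in chrs) {
        idx <- which(snp$chrom == ch)
        pos <- snp$gpos[idx]
        len <- max(pos)
        for (i in seq_len(n_ind)) {
          n_sw <- stats::rpois(1, t_gens * len)
          breaks <- sort(stats::runif(n_sw, 0, len))
          states <- stats::runif(n_sw + 1) < w
          anc[i, idx] <- states[findInterval(pos, breaks) + 1]
        }
      }
      pmat <- ifelse(anc, rep(pa, each = n_ind), rep(pb, each = n_ind))
      geno <- geno + matrix(stats::rbinom(n_ind * n_snp, 1L, pmat),
                            nrow = n_ind)
    }
    ind <- tibble::tibble(id = sprintf("%s_%03d", group, seq_len(n_ind)),
                          sex = "U", group = group, ploidy = "diploid")
    paleo_dataset(geno, snp, ind)
  })
}

#' Simulate per-read pileups with stratified base errors
#'
#' Generates per-site read stacks for every individual in `truth`:
#' per-site read depth is Poisson(`depth_mean`); each read carries a strand,
#' a terminal flag (within 10 bases of a read end versus central), mapping
#' and base qualities, and a library id. The read's base starts from the
#' individual's true allele (the reference base at monomorphic
#' error-training sites, marked by a `monomorphic` flag in the SNP table)
#' and is substituted according to the first matching damage rule.
#'
#' @param truth a [paleo_dataset()]; SNP table may carry a logical
#'   `monomorphic` column flagging error-training sites (treated as fixed
#'   for the reference base).
#' @param depth_mean mean reads per site per individual.
#' @param damage tibble of substitution rules with columns `from`, `to`,
#'   `rate` (in \[0, 0.5)) and optional `terminal` (logical), `strand`
#'   (`"+"`/`"-"`), `lib`; `NA`/absent fields match any read.
#' @param seed integer seed.
#' @param p_terminal probability a read observes the site within 10 bases
#'   of one of its ends (default 0.3).
#' @param libs library ids to assign reads to, round-robin over individuals.
#' @param udg named logical: UDG treatment status per library.
#' @return An object of class `pileup_set`: a tibble of reads with
#'   attributes `snp` (site table) and `ind`.
#' @export
simulate_pileups <- function(truth, depth_mean, damage = NULL, seed,
                             p_terminal = 0.3, libs = "lib1",
                             udg = stats::setNames(rep(TRUE, length(libs)), libs)) {
  if (!is.null(damage) && any(damage$rate < 0 | damage$rate >= 0.5))
    stop("damage rates must lie in [0, 0.5)")
  withr::with_seed(seed, {
    snp <- truth$snp
    if (is.null(snp$monomorphic)) snp$monomorphic <- FALSE
    reads <- vector("list", nrow(truth$ind))
    for (i in seq_len(nrow(truth$ind))) {
      depth <- stats::rpois(nrow(snp), depth_mean)
      site_of <- rep(seq_len(nrow(snp)), depth)
      n <- length(site_of)
      if (n == 0) next
      g <- truth$geno[i, site_of]
      true_base <- ifelse(snp$monomorphic[site_of], snp$ref[site_of],
                   ifelse(g == 0L, snp$ref[site_of],
                   ifelse(g == 2L, snp$alt[site_of],
                   ifelse(stats::runif(n) < 0.5, snp$ref[site_of],
                          snp$alt[site_of]))))
      lib <- libs[(i - 1L) %% length(libs) + 1L]
      rd <- tibble::tibble(
        ind = truth$ind$id[i],
        site_id = snp$id[site_of],
        base = true_base,
        strand = ifelse(stats::runif(n) < 0.5, "+", "-"),
        terminal = stats::runif(n) < p_terminal,
        mq = sample(c(20L, 37L), n, replace = TRUE, prob = c(0.2, 0.8)),
        bq = sample(c(25L, 37L), n, replace = TRUE, prob = c(0.2, 0.8)),
        lib = lib,
        udg = unname(udg[lib]))
      if (!is.null(damage) && nrow(damage) > 0) {
        for (k in seq_len(nrow(damage))) {
          rule <- damage[k, ]
          hit <- rd$base == rule$from
          if (!is.null(rule$terminal) && !is.na(rule$terminal))
            hit <- hit & rd$terminal == rule$terminal
          if (!is.null(rule$strand) && !is.na(rule$strand))
            hit <- hit & rd$strand == rule$strand
          if (!is.null(rule$lib) && !is.na(rule$lib))
            hit <- hit & rd$lib == rule$lib
          flip <- hit & stats::runif(n) < rule$rate
          rd$base[flip] <- rule$to
        }
      }
      reads[[i]] <- rd
    }
    structure(dplyr::bind_rows(reads),
              snp = snp, ind = truth$ind, class = c("pileup_set", class(tibble::tibble())))
  })
}

#' Write / read pileups as TSV
#'
#' @param pu a `pileup_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileups <- function(pu, path) {
  utils::write.table(as.data.frame(pu), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate diploid genomes carrying runs of homozygosity
#'
#' Places ROH segments under the geometric-coalescent segment model of
#' [expected_roh_counts()]: per-length-bin segment counts are Poisson with
#' the model expectation at `two_ne`, lengths are drawn from the within-bin
#' density, and positions are uniform without overlap (segments are
#' truncated at chromosome ends). Heterozygous sites occur at rate
#' `het_rate` per SNP outside ROH and never inside.
#'
#' @param two_ne the 2Ne parameter (> 2).
#' @param chrom_lengths per-chromosome map lengths in Morgans.
#' @param het_rate per-SNP heterozygosity outside ROH.
#' @param n_ind number of individuals.
#' @param seed integer seed.
#' @param snps_per_morgan marker density for the genotype matrix.
#' @param min_cm shortest simulated segment length in cM (default 2).
#' @param geno if `FALSE`, skip genotype generation and return only the true
#'   segment table (fast path for count-level studies).
#' @return list of class `roh_sim` with `dataset` (or `NULL`) and
#'   `segments` (tibble: `ind`, `chrom`, `start`, `end` in Morgans,
#'   `length_cm`).
#' @export
simulate_roh_genome <- function(two_ne, chrom_lengths, het_rate, n_ind, seed,
                                snps_per_morgan = 5000, min_cm = 2,
                                geno = TRUE) {
  stopifnot(two_ne > 2)
  withr::with_seed(seed, {
    L <- sum(chrom_lengths)
    # fine length grid for Poisson counts and within-bin length sampling
    grid <- seq(min_cm / 100, 3, by = 0.005)
    edges_cm <- grid * 100
    ev <- expected_roh_counts(two_ne, L, edges_cm)$expected
    segs <- vector("list", n_ind)
    for (i in seq_len(n_ind)) {
      counts <- stats::rpois(length(ev), ev)
      lens <- rep((grid[-length(grid)] + grid[-1]) / 2, counts) +
        stats::runif(sum(counts), -0.0025, 0.0025)
      placed <- place_segments(lens, chrom_lengths)
      if (nrow(placed) > 0) placed$ind <- sprintf("roh_%03d", i)
      segs[[i]] <- placed
    }
    segments <- dplyr::bind_rows(segs)
    if (nrow(segments) > 0)
      segments <- segments |>
        dplyr::mutate(length_cm = (.data$end - .data$start) * 100) |>
        dplyr::select("ind", "chrom", "start", "end", "length_cm")
    dataset <- NULL
    if (geno) {
      snp <- sim_snp_table(round(L * snps_per_morgan), chrom_lengths)
      gmat <- matrix(0L, nrow = n_ind, ncol = nrow(snp))
      hom <- sample(c(0L, 2L), length(gmat), replace = TRUE)
      het <- stats::runif(length(gmat)) < het_rate
      gmat[] <- ifelse(het, 1L, hom)
      for (i in seq_len(n_ind)) {
        id <- sprintf("roh_%03d", i)
        ss <- segments[segments$ind == id, ]
        for (k in seq_len(nrow(ss))) {
          inside <- snp$chrom == ss$chrom[k] &
            snp$gpos >= ss$start[k] & snp$gpos <= ss$end[k]
          gmat[i, inside & gmat[i, ] == 1L] <-
            sample(c(0L, 2L), sum(inside & gmat[i, ] == 1L), replace = TRUE)
        }
      }
      ind <- tibble::tibble(id = sprintf("roh_%03d", seq_len(n_ind)),
                            sex = "U", group = "ROHSim", ploidy = "diploid")
      dataset <- paleo_dataset(gmat, snp, ind)
    }
    structure(list(dataset = dataset, segments = segments,
                   two_ne = two_ne, chrom_lengths = chrom_lengths),
              class = "roh_sim")
  })
}

# uniform placement without overlap, each segment wholly within one
# chromosome so that realized lengths keep the model's bin counts;
# bounded retries per segment.
place_segments <- function(lens, chrom_lengths, max_tries = 200) {
  n_chr <- length(chrom_lengths)
  out <- list()
  occupied <- lapply(seq_len(n_chr), function(i) matrix(numeric(0), ncol = 2))
  for (l in sort(lens, decreasing = TRUE)) {
    placed <- FALSE
    fits <- chrom_lengths > l
    if (!any(fits)) fits <- chrom_lengths == max(chrom_lengths)
    for (try in seq_len(max_tries)) {
      ch <- sample(which(fits), 1, prob = chrom_lengths[fits])
      start <- stats::runif(1, 0, max(chrom_lengths[ch] - l, 0))
      end <- min(start + l, chrom_lengths[ch])
      occ <- occupied[[ch]]
      if (nrow(occ) == 0 || all(end <= occ[, 1] | start >= occ[, 2])) {
        occupied[[ch]] <- rbind(occ, c(start, end))
        out[[length(out) + 1]] <- tibble::tibble(chrom = as.character(ch),
                                                 start = start, end = end)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place ROH segment after ", max_tries, " tries")
  }
  dplyr::bind_rows(out)
}

#' Simulate a per-individual QC metrics table with known composition
#'
#' Builds a table in which exactly `n_pass` rows satisfy all authenticity
#' thresholds (coverage >= 15,000 SNPs; terminal damage >= 3% for UDG /
#' >= 10% for non-UDG libraries; contamination lower bound <= 0.01; mtDNA
#' match >= 0.90; sex ratio outside the open interval (0.05, 0.3)) and each
#' entry of `fail_specs` produces one row violating exactly the named rule.
#'
#' @param n_pass number of passing rows.
#' @param fail_specs list of `c(metric, value)` pairs; `metric` one of
#'   `snps_covered`, `damage_rate`, `contam_lower_bound`,
#'   `mt_match_upper_bound`, `sex_ratio`, or `"date"` (the row passes all
#'   thresholds but its id is added to the date-exclusion list).
#' @param seed integer seed.
#' @return A tibble of class `qc_metrics` with attribute `date_excluded`.
#' @export
simulate_qc_table <- function(n_pass, fail_specs = list(), seed) {
  withr::with_seed(seed, {
    n_fail <- length(fail_specs)
    n <- n_pass + n_fail
    udg <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tbl <- tibble::tibble(
      id = sprintf("I%05d", seq_len(n)),
      snps_covered = sample(20000:1200000, n, replace = TRUE),
      udg_flag = udg,
      damage_rate = ifelse(udg, stats::runif(n, 0.03, 0.08),
                           stats::runif(n, 0.10, 0.30)),
      contam_lower_bound = stats::runif(n, 0, 0.01),
      mt_match_upper_bound = stats::runif(n, 0.92, 1.0),
      sex_ratio = ifelse(stats::runif(n) < 0.5,
                         stats::runif(n, 0, 0.05), stats::runif(n, 0.3, 0.5)))
    date_excluded <- character(0)
    for (k in seq_along(fail_specs)) {
      spec <- fail_specs[[k]]
      row <- n_pass + k
      metric <- spec[[1]]
      if (metric == "date") {
        date_excluded <- c(date_excluded, tbl$id[row])
        next
      }
      value <- as.numeric(spec[[2]])
      violates <- switch(metric,
        snps_covered = value < 15000,
        damage_rate = value < ifelse(tbl$udg_flag[row], 0.03, 0.10),
        contam_lower_bound = value > 0.01,
        mt_match_upper_bound = value < 0.90,
        sex_ratio = value > 0.05 && value < 0.3,
        stop("unknown metric: ", metric))
      if (!violates) stop("fail_spec for ", metric, " = ", value,
                          " does not violate its threshold")
      tbl[[metric]][row] <- value
    }
    structure(tbl, date_excluded = date_excluded,
              class = c("qc_metrics", class(tbl)))
  })
}

#' Simulate a pseudohaploid parent-offspring trio with an unrelated control
#'
#' Draws two diploid parents at the panel frequencies, one child inheriting
#' one allele from each, and one unrelated diploid; all four are reduced to
#' pseudohaploid calls (one random allele per site, coded 0/2). The
#' expected pairwise mismatch rates are b = mean 2p(1-p) for unrelated
#' pairs and 3b/4 for parent-offspring.
#'
#' @param p per-SNP allele frequencies.
#' @param seed integer seed.
#' @return list of pseudohaploid rows `parent`, `child`, `unrelated` and
#'   the diploid truth.
#' @export
simulate_trio <- function(p, seed) {
  withr::with_seed(seed, {
    n <- length(p)
    mom <- stats::rbinom(n, 1, p) + stats::rbinom(n, 1, p)
    dad <- stats::rbinom(n, 1, p) + stats::rbinom(n, 1, p)
    kid <- stats::rbinom(n, 1, mom / 2) + stats::rbinom(n, 1, dad / 2)
    unrel <- stats::rbinom(n, 1, p) + stats::rbinom(n, 1, p)
    ph <- function(g) 2L * stats::rbinom(n, 1, g / 2)
    list(parent = ph(mom), child = ph(kid), unrelated = ph(unrel),
         diploid = list(parent = mom, child = kid, unrelated = unrel))
  })
}
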