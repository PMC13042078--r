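# Stratification used throughout the error model: library, read-terminal
# versus central position (more than 10 bp from either read end), strand,
# and two mapping-/base-quality bins. Published aDNA pipelines do not
# state their bin edges; 30 is the conventional confident-quality cut.
MQ_EDGE <- 30L
BQ_EDGE <- 30L

stratum_cols <- c("lib", "terminal", "strand", "mq_bin", "bq_bin")

add_quality_bins <- function(reads) {
  reads$mq_bin <- ifelse(reads$mq >= MQ_EDGE, "mq_hi", "mq_lo")
  reads$bq_bin <- ifelse(reads$bq >= BQ_EDGE, "bq_hi", "bq_lo")
  reads
}

#' Fit the stratified empirical error model
#'
#' Estimates per-stratum substitution error rates from reads at flagged
#' monomorphic sites, whose true base is taken to be the reference base:
#' for a stratum and ordered base pair a->b, the rate is the fraction of
#' reads with true base a observed as b. Strata are keyed by library,
#' terminal-versus-central read position, strand, and binary mapping- and
#' base-quality bins. Strata with no observations fall back to a
#' configurable pseudo-rate rather than zero, so that unseen strata are
#' never certified reliable.
#'
#' @param pileups a `pileup_set` from [simulate_pileups()] or equivalent,
#'   whose site table carries a logical `monomorphic` column.
#' @param prior fallback error rate for unobserved strata (default 0.001).
#' @return An object of class `error_model`: tibble of `lib`, `terminal`,
#'   `strand`, `mq_bin`, `bq_bin`, `from`, `to`, `rate`, `n_obs` with the
#'   prior stored as an attribute.
#' @export
fit_error_model <- function(pileups, prior = 0.001) {
  snp <- attr(pileups, "snp")
  if (is.null(snp$monomorphic) || !any(snp$monomorphic))
    stop("no monomorphic error-training sites in pileup site table")
  mono <- snp[snp$monomorphic, ]
  reads <- pileups[pileups$site_id %in% mono$id, , drop = FALSE]
  if (nrow(reads) == 0) stop("no reads at monomorphic sites")
  reads <- add_quality_bins(tibble::as_tibble(reads))
  reads$true_base <- mono$ref[match(reads$site_id, mono$id)]

  totals <- reads |>
    dplyr::count(dplyr::across(dplyr::all_of(c(stratum_cols, "true_base"))),
                 name = "n_total")
  errors <- reads |>
    dplyr::filter(.data$base != .data$true_base) |>
    dplyr::count(dplyr::across(dplyr::all_of(c(stratum_cols, "true_base", "base"))),
                 name = "n_err")
  # every observed (stratum, true base) pair yields rates to each other base
  others <- function(b) setdiff(c("A", "C", "G", "T"), b)
  grid <- totals |>
    dplyr::rowwise() |>
    dplyr::mutate(to = list(others(.data$true_base))) |>
    tidyr::unnest("to") |>
    dplyr::ungroup()
  model <- grid |>
    dplyr::left_join(errors,
                     by = c(stratum_cols, "true_base", to = "base")) |>
    dplyr::mutate(n_err = dplyr::coalesce(.data$n_err, 0L),
                  rate = .data$n_err / .data$n_total) |>
    dplyr::rename(from = "true_base", n_obs = "n_total") |>
    dplyr::select(dplyr::all_of(stratum_cols), "from", "to", "rate", "n_obs")
  structure(model, prior = prior, class = c("error_model", class(model)))
}

# directional error E(a -> b) for one stratum; prior when unobserved
error_rate <- function(model, stratum, from, to) {
  hit <- model
  for (col in stratum_cols) hit <- hit[hit[[col]] == stratum[[col]], , drop = FALSE]
  hit <- hit[hit$from == from & hit$to == to, , drop = FALSE]
  if (nrow(hit) == 0) attr(model, "prior") else hit$rate[1]
}

#' Symmetric reliability score S
#'
#' For an allele pair (a, b) in a given stratum, the reliability score is
#' the maximum of the two directional error rates,
#' S = max(E(a->b), E(b->a)), so that a read is only trusted when both
#' miscall directions are rare. Missing strata use the model's prior.
#'
#' @param model an [fit_error_model()] result.
#' @param a,b the two alleles of the SNP.
#' @param stratum named list/row with `lib`, `terminal`, `strand`,
#'   `mq_bin`, `bq_bin`.
#' @return The reliability score S (a single error-rate bound).
#' @export
reliability_s <- function(model, a, b, stratum) {
  max(error_rate(model, stratum, a, b), error_rate(model, stratum, b, a))
}

# deterministic per-site random stream: one global seed expanded by a hash
# of the site id, so calls do not depend on iteration order.
site_seed <- function(seed, site_id) {
  h <- sum(utf8ToInt(site_id) * seq_len(nchar(site_id)) * 131)
  (as.integer(seed) + (h %% 2000000011)) %% .Machine$integer.max
}

#' Call one pseudohaploid genotype from a read pileup
#'
#' Reads whose stratum reliability S is at or above `threshold` are
#' discarded, as are bases matching neither allele; if no reliable read
#' remains the call is missing (9), otherwise one base is drawn uniformly
#' at random from the reliable pileup and coded 0 (reference) or 2
#' (alternative). Because S bounds the error of every contributing base,
#' the achieved call error is below the threshold.
#'
#' @param reads tibble of reads at one site (`base`, `strand`, `terminal`,
#'   `mq`, `bq`, `lib`); may be empty.
#' @param model an [fit_error_model()] result.
#' @param ref,alt the site's two alleles.
#' @param site_id site identifier (keys the per-site random stream).
#' @param threshold reliability cutoff (default 0.02).
#' @param seed global integer seed.
#' @return genotype code 0, 2 or 9.
#' @export
call_site <- function(reads, model, ref, alt, site_id, threshold = 0.02,
                      seed = 1) {
  if (nrow(reads) == 0) return(9L)
  reads <- add_quality_bins(tibble::as_tibble(reads))
  s <- vapply(seq_len(nrow(reads)), function(k)
    reliability_s(model, ref, alt, reads[k, ]), 0)
  keep <- s < threshold & reads$base %in% c(ref, alt)
  if (!any(keep)) return(9L)
  bases <- sort(reads$base[keep]) # canonical order: calls don't depend on read order
  pick <- withr::with_seed(site_seed(seed, site_id),
                           bases[sample.int(length(bases), 1)])
  if (pick == ref) 0L else 2L
}

#' Call pseudohaploid genotypes for a whole pileup set
#'
#' Applies [call_site()] to every (individual, polymorphic site) pair.
#'
#' @param pileups a `pileup_set`.
#' @param model an [fit_error_model()] result.
#' @param threshold reliability cutoff (default 0.02).
#' @param seed global integer seed.
#' @return A [paleo_dataset()] of pseudohaploid calls at the non-flagged
#'   (polymorphic) sites.
#' @export
call_genotypes <- function(pileups, model, threshold = 0.02, seed = 1) {
  snp <- attr(pileups, "snp")
  ind <- attr(pileups, "ind")
  if (is.null(snp$monomorphic)) snp$monomorphic <- FALSE
  sites <- snp[!snp$monomorphic, ]
  geno <- matrix(9L, nrow = nrow(ind), ncol = nrow(sites))
  by_cell <- split(seq_len(nrow(pileups)),
                   list(pileups$ind, pileups$site_id), drop = TRUE)
  for (key in names(by_cell)) {
    rows <- by_cell[[key]]
    ind_id <- pileups$ind[rows[1]]
    site_id <- pileups$site_id[rows[1]]
    j <- match(site_id, sites$id)
    if (is.na(j)) next
    i <- match(ind_id, ind$id)
    geno[i, j] <- call_site(pileups[rows, ], model,
                            sites$ref[j], sites$alt[j], site_id,
                            threshold = threshold, seed = seed)
  }
  ind2 <- ind
  ind2$ploidy <- "haploid"
  paleo_dataset(geno, sites, ind2)
}

#' Library damage rate and sex ratio
#'
#' The damage rate is the terminal C->T mismatch fraction at flagged
#' monomorphic C sites (the residual deamination signal used as an
#' authenticity check); the sex ratio is Y/(X+Y) over aligned read counts.
#'
#' @param pileups a `pileup_set` with monomorphic-flagged sites.
#' @param x_reads,y_reads aligned read counts on X and Y.
#' @return tibble with `damage_rate`, `sex_ratio` (NA, flagged, when
#'   X+Y = 0) and `sex_ratio_defined`.
#' @export
library_metrics <- function(pileups, x_reads, y_reads) {
  snp <- attr(pileups, "snp")
  mono_c <- snp$id[snp$monomorphic & snp$ref == "C"]
  term <- pileups[pileups$site_id %in% mono_c & pileups$terminal, ]
  damage <- if (nrow(term) == 0) NA_real_ else mean(term$base == "T")
  defined <- (x_reads + y_reads) > 0
  tibble::tibble(damage_rate = damage,
                 sex_ratio = ifelse(defined, y_reads / (x_reads + y_reads),
                                    NA_real_),
                 sex_ratio_defined = defined)
}

#' Apply authenticity and QC filters to a metrics table
#'
#' Implements the study-design thresholds with strict inequalities, so
#' exact-threshold values pass: an individual fails when covered at fewer
#' than 15,000 SNPs; when its terminal damage rate is below 3% (UDG-treated)
#' or 10% (non-UDG); when the contamination lower bound exceeds 0.01; when
#' the mtDNA consensus match upper bound is below 0.90; when the sex ratio
#' is strictly between 0.05 and 0.3; or when its id is date-excluded.
#' Among passers, the lower-coverage member of each first-degree pair is
#' dropped for grouped analyses with a distinct reason code. Every failure
#' lists all triggered reasons; rows with missing metrics fail as
#' "incomplete".
#'
#' @param metrics a QC tibble (`id`, `snps_covered`, `damage_rate`,
#'   `udg_flag`, `contam_lower_bound`, `mt_match_upper_bound`, `sex_ratio`).
#' @param relatives optional tibble of first-degree pairs (`id1`, `id2`).
#' @param date_excluded ids excluded on radiocarbon-date inconsistency;
#'   defaults to the table's own `date_excluded` attribute if present.
#' @return list with `pass` (ids passing all filters, relative-pruned for
#'   grouped analyses), `pass_individual` (ids passing before relative
#'   pruning) and `fail` (tibble `id`, `reasons`).
#' @export
apply_qc <- function(metrics, relatives = NULL,
                     date_excluded = attr(metrics, "date_excluded")) {
  if (is.null(date_excluded)) date_excluded <- character(0)
  required <- c("snps_covered", "damage_rate", "udg_flag",
                "contam_lower_bound", "mt_match_upper_bound", "sex_ratio")
  miss <- setdiff(required, names(metrics))
  if (length(miss)) stop("metrics table lacks column(s): ",
                         paste(miss, collapse = ", "))
  reasons <- vector("list", nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    m <- metrics[i, ]
    r <- character(0)
    if (anyNA(m[required])) {
      r <- "incomplete"
    } else {
      if (m$snps_covered < 15000) r <- c(r, "coverage")
      dmin <- if (m$udg_flag) 0.03 else 0.10
      if (m$damage_rate < dmin) r <- c(r, "damage")
      if (m$contam_lower_bound > 0.01) r <- c(r, "contamination")
      if (m$mt_match_upper_bound < 0.90) r <- c(r, "mt_match")
      if (m$sex_ratio > 0.05 && m$sex_ratio < 0.3) r <- c(r, "sex_ratio")
    }
    if (m$id %in% date_excluded) r <- c(r, "date")
    reasons[[i]] <- r
  }
  failed <- lengths(reasons) > 0
  pass_individual <- metrics$id[!failed]
  pass <- pass_individual
  rel_drop <- character(0)
  if (!is.null(relatives) && nrow(relatives) > 0) {
    for (k in seq_len(nrow(relatives))) {
      a <- relatives$id1[k]; b <- relatives$id2[k]
      if (a %in% pass && b %in% pass) {
        cov_a <- metrics$snps_covered[metrics$id == a]
        cov_b <- metrics$snps_covered[metrics$id == b]
        rel_drop <- c(rel_drop, if (cov_a < cov_b) a else b)
      }
    }
    pass <- setdiff(pass, rel_drop)
  }
  fail <- tibble::tibble(
    id = c(metrics$id[failed], rel_drop),
    reasons = c(vapply(reasons[failed], paste, "", collapse = ";"),
                rep("relative_of_passer", length(rel_drop))))
  list(pass = pass, pass_individual = pass_individual, fail = fail)
}
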