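#' Genotype dataset container
#'
#' A `paleo_dataset` bundles a genotype matrix (individuals in rows, SNPs in
#' columns, coded 0/1/2 as the count of the alternative allele with 9 for
#' missing) with a SNP table and an individual table. Pseudohaploid
#' individuals carry only codes in `{0, 2, 9}`: a single randomly drawn
#' allele represented as a homozygote, the standard representation for
#' low-coverage ancient samples.
#'
#' @param geno integer matrix, individuals x SNPs, entries in `{0,1,2,9}`.
#' @param snp tibble with columns `id`, `chrom`, `gpos` (genetic position in
#'   Morgans), `ppos` (1-based physical position), `ref`, `alt`; extra
#'   columns (e.g. a `monomorphic` flag on error-training sites) are kept.
#' @param ind tibble with columns `id`, `sex` (one of `"M"`, `"F"`, `"U"`),
#'   `group`; an optional `ploidy` column (`"haploid"`/`"diploid"`) records
#'   how many allele observations each individual contributes to allele
#'   frequencies. When absent, ploidy is inferred: individuals with at least
#'   one heterozygous call are treated as diploid.
#'
#' @return An object of class `paleo_dataset`.
#' @export
paleo_dataset <- function(geno, snp, ind) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  snp <- tibble::as_tibble(snp)
  ind <- tibble::as_tibble(ind)
  rownames(geno) <- ind$id
  colnames(geno) <- snp$id
  ds <- structure(list(geno = geno, snp = snp, ind = ind),
                  class = "paleo_dataset")
  validate_dataset(ds)
}

validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "paleo_dataset"))
  if (nrow(ds$geno) != nrow(ds$ind))
    stop("genotype rows (", nrow(ds$geno), ") != individuals (", nrow(ds$ind), ")")
  if (ncol(ds$geno) != nrow(ds$snp))
    stop("genotype columns (", ncol(ds$geno), ") != SNPs (", nrow(ds$snp), ")")
  bad <- !(ds$geno %in% c(0L, 1L, 2L, 9L))
  if (any(bad)) stop("illegal genotype code(s): ",
                     paste(unique(ds$geno[bad]), collapse = ", "))
  unsorted <- ds$snp |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$gpos)) |>
    dplyr::filter(!.data$ok)
  if (nrow(unsorted) > 0)
    stop("genetic positions not sorted on chromosome(s): ",
         paste(unsorted$chrom, collapse = ", "))
  ds
}

#' @export
print.paleo_dataset <- function(x, ...) {
  cat("<paleo_dataset> ", nrow(x$ind), " individuals x ", nrow(x$snp),
      " SNPs on ", length(unique(x$snp$chrom)), " chromosome(s)\n", sep = "")
  cat("  groups: ", paste(unique(x$ind$group), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# one haploid observation per pseudohaploid individual, two per diploid
dataset_ploidy <- function(ds) {
  if (!is.null(ds$ind$ploidy)) {
    p <- ds$ind$ploidy
    stopifnot(all(p %in% c("haploid", "diploid")))
    return(ifelse(p == "diploid", 2L, 1L))
  }
  het <- apply(ds$geno == 1L, 1, any)
  ifelse(het, 2L, 1L)
}

#' Subset a dataset by individuals and/or SNPs
#'
#' @param ds a [paleo_dataset()].
#' @param ind_ids,snp_idx individual ids / SNP column indices to keep;
#'   `NULL` keeps all.
#' @return A `paleo_dataset`.
#' @export
subset_dataset <- function(ds, ind_ids = NULL, snp_idx = NULL) {
  keep_i <- if (is.null(ind_ids)) seq_len(nrow(ds$ind)) else match(ind_ids, ds$ind$id)
  if (anyNA(keep_i)) stop("unknown individual id(s): ",
                          paste(ind_ids[is.na(keep_i)], collapse = ", "))
  keep_j <- if (is.null(snp_idx)) seq_len(nrow(ds$snp)) else snp_idx
  paleo_dataset(ds$geno[keep_i, keep_j, drop = FALSE],
                ds$snp[keep_j, ], ds$ind[keep_i, ])
}

#' Combine two datasets sharing the same SNP table
#'
#' @param a,b `paleo_dataset` objects with identical SNP tables.
#' @return A `paleo_dataset` with the individuals of both.
#' @export
bind_datasets <- function(a, b) {
  if (!identical(a$snp$id, b$snp$id)) stop("SNP tables differ")
  paleo_dataset(rbind(a$geno, b$geno), a$snp, dplyr::bind_rows(a$ind, b$ind))
}
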