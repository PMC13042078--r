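#' Read an EIGENSTRAT genotype triplet
#'
#' Parses the plain-text EIGENSTRAT dialect: a `.geno` file with one line per
#' SNP and one digit per individual, a six-column `.snp` file (id,
#' chromosome, genetic position, physical position, ref, alt) and a
#' three-column `.ind` file (id, sex in M/F/U, group label). Genetic
#' positions are stored in Morgans; files whose positions are evidently in
#' centimorgans (any per-chromosome span of 4 or more) are converted with a
#' warning.
#'
#' @param prefix path prefix; `<prefix>.geno`, `.snp`, `.ind` must exist.
#' @return A [paleo_dataset()].
#' @export
read_eigenstrat <- function(prefix) {
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "))

  snp <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "chrom", "gpos", "ppos", "ref", "alt"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  snp <- tibble::as_tibble(snp)
  ind <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "sex", "group"))
  ind <- tibble::as_tibble(ind)
  if (!all(ind$sex %in% c("M", "F", "U")))
    stop(".ind: sex codes must be M, F or U")

  lines <- readLines(paths[1])
  if (length(lines) != nrow(snp))
    stop(".geno has ", length(lines), " lines but .snp has ", nrow(snp), " rows")
  nch <- nchar(lines)
  if (any(nch != nrow(ind)))
    stop(".geno line ", which(nch != nrow(ind))[1], ": expected ",
         nrow(ind), " genotype digits, found ", nch[which(nch != nrow(ind))[1]])
  digits <- lapply(lines, function(l) as.integer(strsplit(l, "")[[1]]))
  geno <- do.call(cbind, digits) # individuals x SNPs
  bad_line <- which(vapply(digits, function(d) any(!(d %in% c(0L, 1L, 2L, 9L))), TRUE))
  if (length(bad_line))
    stop(".geno line ", bad_line[1], ": illegal genotype digit")

  # auto-detect centimorgan positions (Morgan spans are < 4 per chromosome)
  span <- tapply(snp$gpos, snp$chrom, function(g) max(g) - min(g))
  if (any(span >= 4)) {
    warning("genetic positions look like centimorgans; converting to Morgans")
    snp$gpos <- snp$gpos / 100
  }
  ds <- paleo_dataset(geno, snp, ind)
  ds
}

#' Write a dataset as an EIGENSTRAT triplet
#'
#' Emits the dialect [read_eigenstrat()] accepts; genetic positions are
#' written in Morgans with 8 decimals so they round-trip numerically.
#'
#' @param ds a [paleo_dataset()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(ds, prefix) {
  validate_dataset(ds)
  writeLines(apply(ds$geno, 2, paste0, collapse = ""), paste0(prefix, ".geno"))
  snp_lines <- sprintf("%s\t%s\t%.8f\t%d\t%s\t%s",
                       ds$snp$id, as.character(ds$snp$chrom), ds$snp$gpos,
                       ds$snp$ppos, ds$snp$ref, ds$snp$alt)
  writeLines(snp_lines, paste0(prefix, ".snp"))
  writeLines(sprintf("%s\t%s\t%s", ds$ind$id, ds$ind$sex, ds$ind$group),
             paste0(prefix, ".ind"))
  invisible(prefix)
}

#' Assign contiguous jackknife blocks from the genetic map
#'
#' Greedy segmentation used for the weighted block jackknife: a new block
#' starts at every chromosome start and whenever the current SNP lies at
#' least `block_cm`/100 Morgans beyond the first SNP of the current block.
#' Blocks never span chromosomes.
#'
#' @param snp SNP table with `chrom` and `gpos` (Morgans) columns, sorted by
#'   position within chromosome.
#' @param block_cm block extent in centimorgans (default 5).
#' @return A list of class `block_assignment` with `block` (1-based integer
#'   per SNP) and `n_snps` (per-block SNP counts).
#' @export
assign_blocks <- function(snp, block_cm = 5.0) {
  n <- nrow(snp)
  if (n == 0)
    return(structure(list(block = integer(0), n_snps = integer(0)),
                     class = "block_assignment"))
  size_m <- block_cm / 100
  block <- integer(n)
  cur <- 0L
  for (ch in unique(snp$chrom)) {
    idx <- which(snp$chrom == ch)
    start_pos <- -Inf
    for (i in idx) {
      if (snp$gpos[i] - start_pos >= size_m) {
        cur <- cur + 1L
        start_pos <- snp$gpos[i]
      }
      block[i] <- cur
    }
  }
  structure(list(block = block, n_snps = tabulate(block)),
            class = "block_assignment")
}

#' @export
print.block_assignment <- function(x, ...) {
  cat("<block_assignment> ", length(x$n_snps), " blocks over ",
      length(x$block), " SNPs\n", sep = "")
  invisible(x)
}
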