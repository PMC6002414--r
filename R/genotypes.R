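#' Genotype matrix
#'
#' In-memory representation of a filtered multi-sample biallelic SNP callset.
#' Coordinates are converted to 0-based at ingest and all downstream
#' arithmetic is 0-based half-open (BED convention); `pos` stores the 0-based
#' coordinate of each site.  The two allele columns `a1`/`a2` hold the first
#' and second allele of each genotype as written in the VCF (0 = REF,
#' 1 = ALT, NA = missing); `phased` records whether the separator was `|`.
#' Haplotype-level access is permitted where `phased` is TRUE or where the
#' genotype is homozygous (phase is then immaterial).
#'
#' @param contig character vector, one entry per site; sites must be grouped
#'   by contig.
#' @param pos integer vector of 0-based positions, strictly increasing within
#'   each contig.
#' @param ref,alt single-base allele strings per site.
#' @param a1,a2 integer matrices (sites x samples) in \{0, 1, NA\}; both NA
#'   when the genotype is missing.
#' @param phased logical matrix (sites x samples).
#' @param samples ordered character vector of sample ids.
#' @param contig_lengths optional named numeric vector of contig lengths (bp).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(contig, pos, ref, alt, a1, a2, phased, samples,
                            contig_lengths = NULL) {
  n <- length(pos)
  stopifnot(length(contig) == n, length(ref) == n, length(alt) == n)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2); phased <- as.matrix(phased)
  stopifnot(nrow(a1) == n || n == 0L, ncol(a1) == length(samples),
            all(dim(a1) == dim(a2)), all(dim(a1) == dim(phased)))
  if (anyNA(contig)) .stopf("contig ids must not be NA")
  ord <- rle(contig)
  if (anyDuplicated(ord$values)) .stopf("sites must be grouped by contig")
  for (ct in ord$values) {
    p <- pos[contig == ct]
    if (is.unsorted(p, strictly = TRUE))
      .stopf("positions not strictly increasing on contig '%s'", ct)
  }
  # genotype missing <=> both alleles missing
  stopifnot(identical(is.na(a1), is.na(a2)))
  colnames(a1) <- colnames(a2) <- colnames(phased) <- samples
  structure(list(contig = as.character(contig), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 a1 = a1, a2 = a2, phased = phased,
                 samples = as.character(samples),
                 contig_lengths = contig_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on %d contig(s)\n",
              n_sites(x), length(x$samples), length(unique(x$contig))))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm a [genotype_matrix()].
#' @export
n_sites <- function(gm) length(gm$pos)

#' Alt-allele dosage matrix
#'
#' @param gm a [genotype_matrix()].
#' @return integer matrix (sites x samples) of alt-allele counts in
#'   \{0, 1, 2\}, NA where the genotype is missing.
#' @export
dosages <- function(gm) gm$a1 + gm$a2

#' Subset a genotype matrix by site index
#'
#' @param gm a [genotype_matrix()].
#' @param idx integer or logical site index (order preserved).
#' @export
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$contig[idx], gm$pos[idx], gm$ref[idx], gm$alt[idx],
                  gm$a1[idx, , drop = FALSE], gm$a2[idx, , drop = FALSE],
                  gm$phased[idx, , drop = FALSE], gm$samples,
                  gm$contig_lengths)
}

#' Haplotype allele matrix
#'
#' Extracts per-haplotype alleles for a set of samples.  A haplotype allele
#' is defined where the site is phased for that sample or the genotype is
#' homozygous; it is NA otherwise.
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids (default: all).
#' @return integer matrix (sites x 2*length(samples)) with columns named by
#'   [hap_ids()].
#' @export
hap_alleles <- function(gm, samples = gm$samples) {
  miss <- setdiff(samples, gm$samples)
  if (length(miss)) .stopf("unknown sample(s): %s", paste(miss, collapse = ", "))
  a1 <- gm$a1[, samples, drop = FALSE]
  a2 <- gm$a2[, samples, drop = FALSE]
  ok <- gm$phased[, samples, drop = FALSE] | (a1 == a2)
  a1[!ok | is.na(ok)] <- NA_integer_
  a2[!ok | is.na(ok)] <- NA_integer_
  out <- matrix(NA_integer_, nrow = n_sites(gm), ncol = 2L * length(samples))
  out[, seq(1L, by = 2L, length.out = length(samples))] <- a1
  out[, seq(2L, by = 2L, length.out = length(samples))] <- a2
  colnames(out) <- hap_ids(samples)
  out
}

.parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+)(?::([0-9,]+)-([0-9,]+))?$", region))[[1]]
  if (length(m) == 0L) .stopf("cannot parse region '%s'", region)
  list(contig = m[2],
       start = if (nzchar(m[3])) as.numeric(gsub(",", "", m[3])) else NA,
       end = if (nzchar(m[4])) as.numeric(gsub(",", "", m[4])) else NA)
}

#' Read a VCF into a genotype matrix
#'
#' Multi-allelic and non-SNP records are dropped (with a message giving the
#' count), as are records whose genotypes are not diploid GT calls.
#' Coordinates are converted to 0-based.  Contig lengths are taken from
#' `##contig` header lines when present.
#'
#' @param path path to a VCF (optionally bgzipped).
#' @param region optional region string `"contig"` or `"contig:start-end"`
#'   (1-based inclusive, as in samtools).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2L)
    .stopf("VCF '%s' has no genotype columns", path)
  fmt <- v@gt[, "FORMAT"]
  if (nrow(v@gt) > 0L && !all(grepl("(^|:)GT(:|$)", fmt)))
    .stopf("VCF '%s' is missing the GT FORMAT field", path)
  fix <- v@fix
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  snp <- !is.na(ref) & !is.na(alt) & ref %in% bases & alt %in% bases
  if (sum(!snp) > 0L)
    .msg(sum(!snp), " multi-allelic or non-SNP record(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  contig <- fix[snp, "CHROM"]
  pos1 <- as.integer(fix[snp, "POS"])
  ref <- ref[snp]; alt <- alt[snp]

  ok_dip <- is.na(gt) | grepl("^[0-9.]([|/])[0-9.]$", gt)
  bad <- which(!apply(ok_dip, 1L, all))
  if (length(bad)) {
    .msg(length(bad), " record(s) with non-diploid genotypes dropped")
    keep <- setdiff(seq_len(nrow(gt)), bad)
    gt <- gt[keep, , drop = FALSE]
    contig <- contig[keep]; pos1 <- pos1[keep]; ref <- ref[keep]; alt <- alt[keep]
  }

  s1 <- substr(gt, 1L, 1L); s2 <- substr(gt, 3L, 3L)
  a1 <- suppressWarnings(matrix(as.integer(s1), nrow = nrow(gt)))
  a2 <- suppressWarnings(matrix(as.integer(s2), nrow = nrow(gt)))
  mis <- is.na(a1) | is.na(a2)
  a1[mis] <- NA_integer_; a2[mis] <- NA_integer_
  phased <- matrix(substr(gt, 2L, 2L) == "|", nrow = nrow(gt))
  phased[is.na(phased)] <- FALSE

  # drop duplicated positions (keeps positions strictly increasing)
  dup <- duplicated(paste(contig, pos1))
  if (any(dup)) .msg(sum(dup), " duplicated position(s) dropped")
  keep <- !dup
  samples <- colnames(v@gt)[-1L]

  lens <- NULL
  hd <- grep("^##contig=", v@meta, value = TRUE)
  if (length(hd)) {
    id <- sub(".*ID=([^,>]+).*", "\\1", hd)
    ln <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", hd)))
    if (!anyNA(ln)) lens <- stats::setNames(ln, id)
  }

  gm <- genotype_matrix(contig[keep], pos1[keep] - 1L, ref[keep], alt[keep],
                        a1[keep, , drop = FALSE], a2[keep, , drop = FALSE],
                        phased[keep, , drop = FALSE], samples, lens)
  if (!is.null(region)) {
    r <- .parse_region(region)
    sel <- gm$contig == r$contig
    if (!is.na(r$start)) sel <- sel & gm$pos >= r$start - 1L & gm$pos <= r$end - 1L
    gm <- subset_sites(gm, sel)
  }
  gm
}

#' Write a genotype matrix as VCF
#'
#' Plain-text VCF 4.2 with a GT-only FORMAT field; positions are written back
#' 1-based.  Intended for round-tripping and for saving simulated callsets.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(gm$contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(gm$contig_lengths),
                       as.integer(gm$contig_lengths)), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  if (n_sites(gm) > 0L) {
    sep <- ifelse(gm$phased, "|", "/")
    g <- matrix(paste0(gm$a1, sep, gm$a2), nrow = n_sites(gm))
    g[is.na(gm$a1)] <- "./."
    lines <- paste(gm$contig, gm$pos + 1L, ".", gm$ref, gm$alt, ".", ".", ".",
                   "GT", apply(g, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Filter sites on missingness and minor-allele count
#'
#' A site is removed when its fraction of missing genotypes exceeds
#' `max_missing_frac`, or (if `min_mac` is given) when its minor-allele count
#' over observed allele copies is below `min_mac`.  Site order is preserved.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_frac maximum tolerated missing-genotype fraction in
#'   \[0, 1\].
#' @param min_mac optional minimum minor-allele count.
#' @return the filtered [genotype_matrix()].
#' @export
filter_sites <- function(gm, max_missing_frac = 1, min_mac = NULL) {
  stopifnot(.is_prob(max_missing_frac))
  dos <- dosages(gm)
  mf <- rowMeans(is.na(dos))
  keep <- mf <= max_missing_frac
  if (!is.null(min_mac)) {
    stopifnot(.is_count(min_mac))
    ac <- rowSums(dos, na.rm = TRUE)
    an <- 2L * rowSums(!is.na(dos))
    keep <- keep & (pmin(ac, an - ac) >= min_mac)
  }
  if (!any(keep)) warning("all sites removed by filter_sites()", call. = FALSE)
  subset_sites(gm, keep)
}

#' Read contig lengths from a two-column TSV
#'
#' @param path TSV with columns contig, length (no header).
#' @return named numeric vector.
#' @export
read_contig_lengths <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("contig", "length"),
                         colClasses = c("character", "numeric"))
  stats::setNames(d$length, d$contig)
}
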