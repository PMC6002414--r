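`%||%` <- function(a, b) if (is.null(a)) b else a

.msg <- function(...) message("introscan: ", ...)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

#' Haplotype identifiers for a set of samples
#'
#' Haplotypes are named `<sample>.1` and `<sample>.2` throughout the package
#' (first and second allele of the diploid genotype as written in the VCF).
#'
#' @param samples character vector of sample ids.
#' @return character vector of haplotype ids, interleaved per sample.
#' @export
hap_ids <- function(samples) {
  as.vector(rbind(paste0(samples, ".1"), paste0(samples, ".2")))
}

#' @rdname hap_ids
#' @param haps character vector of haplotype ids.
#' @return `hap_sample()`: the sample id each haplotype belongs to.
#' @export
hap_sample <- function(haps) sub("\\.[12]$", "", haps)
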