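#' Genome layout
#'
#' An ordered set of chromosome names and lengths defining the physical
#' coordinate frame (1-based bp) that marker tables, simulations and scans
#' share.
#'
#' @param chrom Character vector of unique chromosome names, in order.
#' @param length Positive integer vector of chromosome lengths in bp.
#'
#' @return An object of class `genome_layout`: a data.frame with columns
#'   `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    stop("'chrom' and 'length' must have the same length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Default S. cerevisiae genome layout
#'
#' The 16 nuclear chromosomes of the S288c reference assembly (R64-1-1),
#' ~12.07 Mb in total. Override with [genome_layout()] for small test
#' genomes.
#'
#' @return A `genome_layout` with 16 chromosomes.
#' @examples
#' sum(sc_genome()$length)
#' @export
sc_genome <- function() {
  genome_layout(
    chrom = c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrVI",
              "chrVII", "chrVIII", "chrIX", "chrX", "chrXI", "chrXII",
              "chrXIII", "chrXIV", "chrXV", "chrXVI"),
    length = c(230218, 813184, 316620, 1531933, 576874, 270161,
               1090940, 562643, 439888, 745751, 666816, 1078177,
               924431, 784333, 1091291, 948066)
  )
}

#' Total genome length of a layout
#' @param layout A `genome_layout`.
#' @return Total length in bp.
#' @export
genome_length <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$length)
}
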