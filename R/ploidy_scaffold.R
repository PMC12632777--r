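# Copy-number calling from relative marker-site depth, and the ~2 kb
# scaffolding marker subset.

#' Normalized per-chromosome sequencing depth
#'
#' For each strain and chromosome, the mean total allele count per marker,
#' divided by the strain's genome-wide median chromosome depth. Euploid
#' chromosomes are expected near 1, disomic chromosomes near 2.
#'
#' @param counts An [allele_counts()] (markers x strains).
#' @param markers The matching `marker_table`.
#' @return Numeric matrix (strains x chromosomes); strains with zero reads
#'   get NA rows and are listed in attribute `"unsequenced"`.
#' @export
normalized_depths <- function(counts, markers) {
  stopifnot(inherits(counts, "allele_counts"))
  if (nrow(counts$ref) != nrow(markers)) {
    stop("dimension mismatch between counts and markers")
  }
  tot <- counts$ref + counts$alt
  chroms <- unique(markers$chrom)
  depth <- sapply(chroms, function(ch) {
    idx <- markers$chrom == ch
    colMeans(tot[idx, , drop = FALSE])
  })
  if (is.null(dim(depth))) depth <- matrix(depth, nrow = 1)
  dimnames(depth) <- list(counts$strains, chroms)
  med <- apply(depth, 1, stats::median)
  bad <- which(!is.finite(med) | med == 0)
  med[med == 0] <- NA
  out <- depth / med
  attr(out, "unsequenced") <- counts$strains[bad]
  out
}

#' Call chromosome copy number from normalized depth
#'
#' @param depths Matrix from [normalized_depths()].
#' @param threshold Copy number 2 is called when normalized depth is at or
#'   above this (default 1.5, midpoint of the expected euploid and disome
#'   depths); must lie in (1, 2).
#' @return Integer matrix (strains x chromosomes) of copy numbers 1/2,
#'   class `ploidy_table`, with the input depths in attribute `"depths"`.
#' @export
call_ploidy <- function(depths, threshold = 1.5) {
  if (threshold <= 1 || threshold >= 2) stop("threshold must be in (1, 2)")
  cn <- ifelse(depths >= threshold, 2L, 1L)
  storage.mode(cn) <- "integer"
  structure(cn, depths = depths,
            unsequenced = attr(depths, "unsequenced"),
            class = c("ploidy_table", class(cn)))
}

#' Select the scaffolding marker subset
#'
#' Greedy per-chromosome selection: start with the first marker on each
#' chromosome, take the first marker whose position is at least `spacing`
#' bp away (inclusive difference), and repeat to the end of the
#' chromosome. Deterministic and idempotent.
#'
#' @param markers A `marker_table`.
#' @param spacing Minimum spacing in bp (default 2000).
#' @return Sorted integer vector of selected marker row indices, class
#'   `scaffold_set` with attribute `"spacing"`.
#' @export
select_scaffold <- function(markers, spacing = 2000) {
  if (spacing <= 0) stop("spacing must be > 0")
  sel <- integer(0)
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    if (length(idx) == 0) next
    pos <- markers$pos[idx]
    keep <- 1L
    last <- pos[1]
    for (k in seq_along(pos)[-1]) {
      if (pos[k] - last >= spacing) {
        keep <- c(keep, k)
        last <- pos[k]
      }
    }
    sel <- c(sel, idx[keep])
  }
  structure(sort(sel), spacing = spacing, class = "scaffold_set")
}

#' Fraction of the genome within a radius of a scaffolding marker
#'
#' The denominator is the per-chromosome span from the first to the last
#' marker of the full table (telomeric regions beyond them are excluded);
#' chromosomes whose span is zero (a single marker) are excluded.
#'
#' @param scaffold Indices from [select_scaffold()].
#' @param markers The full `marker_table`.
#' @param radius Radius in bp (default 2000).
#' @return Fraction in [0, 1].
#' @export
scaffold_coverage <- function(scaffold, markers, radius = 2000) {
  if (radius <= 0) stop("radius must be > 0")
  covered <- 0; span <- 0
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    pos <- markers$pos[idx]
    lo <- min(pos); hi <- max(pos)
    if (hi == lo) next
    span <- span + (hi - lo)
    sp <- sort(markers$pos[intersect(scaffold, idx)])
    if (length(sp) == 0) next
    s <- pmax(sp - radius, lo); e <- pmin(sp + radius, hi)
    # merge overlapping intervals
    cs <- s[1]; ce <- e[1]
    for (k in seq_along(sp)[-1]) {
      if (s[k] <= ce) ce <- max(ce, e[k])
      else { covered <- covered + (ce - cs); cs <- s[k]; ce <- e[k] }
    }
    covered <- covered + (ce - cs)
  }
  if (span == 0) stop("no chromosome with a positive marker span")
  covered / span
}

#' Read / write a scaffold marker list
#'
#' Two-column TSV (`chrom`, `pos`) identifying the selected markers;
#' reading resolves them back to row indices of the marker table.
#'
#' @param scaffold Indices from [select_scaffold()].
#' @param markers The matching `marker_table`.
#' @param path File path.
#' @return `read_scaffold` returns the marker row indices.
#' @export
write_scaffold <- function(scaffold, markers, path) {
  out <- markers[as.integer(scaffold), c("chrom", "pos")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaffold
#' @export
read_scaffold <- function(path, markers) {
  tab <- utils::read.delim(path, colClasses = list(chrom = "character"))
  idx <- match(paste(tab$chrom, tab$pos),
               paste(markers$chrom, markers$pos))
  if (anyNA(idx)) {
    stop("scaffold row ", which(is.na(idx))[1],
         " not found in the marker table")
  }
  structure(idx, class = "scaffold_set")
}

#' Read / write a ploidy table
#'
#' TSV with a `strain` column followed by one copy-number column per
#' chromosome.
#'
#' @param ploidy A `ploidy_table` (strains x chromosomes) from
#'   [call_ploidy()], or any integer matrix of copy numbers.
#' @param path File path.
#' @return `read_ploidy_table` returns an integer matrix with strain
#'   rownames.
#' @export
write_ploidy_table <- function(ploidy, path) {
  out <- data.frame(strain = rownames(ploidy),
                    unclass(ploidy)[, , drop = FALSE],
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ploidy_table
#' @export
read_ploidy_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[-1])
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% 1:2)) stop("copy numbers must be 1 or 2")
  rownames(m) <- tab$strain
  m
}
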