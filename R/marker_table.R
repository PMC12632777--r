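#' Marker table: founder alleles at biallelic SNVs
#'
#' A marker table holds, per marker, a chromosome, a 1-based position, the
#' two allele labels and an 8-vector of founder allele indicators
#' (0 = reference allele, 1 = alternative). Every marker must be biallelic
#' among the eight founders (both 0 and 1 present), positions must be
#' strictly increasing within each chromosome, and no founder call may be
#' missing.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Allele labels (single characters, e.g. bases).
#' @param founders Integer matrix (n markers x 8) of 0/1 founder calls.
#'
#' @return An object of class `marker_table`: a data.frame with columns
#'   `chrom`, `pos`, `ref`, `alt`, `founder1`..`founder8`.
#' @export
marker_table <- function(chrom, pos, ref, alt, founders) {
  founders <- as.matrix(founders)
  if (ncol(founders) != 8) stop("'founders' must have 8 columns")
  tab <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    stringsAsFactors = FALSE)
  colnames(founders) <- paste0("founder", 1:8)
  tab <- cbind(tab, as.data.frame(founders))
  validate_marker_table(tab)
  structure(tab, class = c("marker_table", "data.frame"))
}

founder_cols <- function(tab) as.matrix(tab[paste0("founder", 1:8)])

validate_marker_table <- function(tab) {
  fo <- founder_cols(tab)
  if (anyNA(fo) || anyNA(tab$pos) || anyNA(tab$chrom)) {
    bad <- which(rowSums(is.na(cbind(fo, tab$pos))) > 0 | is.na(tab$chrom))[1]
    stop("missing values in marker table at row ", bad)
  }
  if (!all(fo %in% c(0L, 1L))) {
    bad <- which(rowSums(!(fo == 0 | fo == 1)) > 0)[1]
    stop("founder calls must be 0/1; offending row ", bad)
  }
  rs <- rowSums(fo)
  if (any(rs == 0 | rs == 8)) {
    bad <- which(rs == 0 | rs == 8)[1]
    stop("marker not biallelic among founders at row ", bad)
  }
  for (ch in unique(tab$chrom)) {
    p <- tab$pos[tab$chrom == ch]
    if (any(diff(p) <= 0)) {
      bad <- which(tab$chrom == ch)[which(diff(p) <= 0)[1] + 1]
      stop("positions not strictly increasing on ", ch, " at row ", bad)
    }
  }
  invisible(tab)
}

#' Read / write a marker table
#'
#' Tab-separated with header columns `chrom`, `pos`, `ref`, `alt`,
#' `founder1`..`founder8`. Invariants (biallelic markers, sorted positions,
#' complete founder calls) are enforced on read; violations are rejected
#' with the offending row number. Write then read is the identity.
#'
#' @param path File path.
#' @return `read_marker_table` returns a `marker_table`.
#' @export
read_marker_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = list(chrom = "character",
                                             ref = "character",
                                             alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", paste0("founder", 1:8))
  if (!all(need %in% names(tab))) {
    stop("marker table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab <- tab[need]
  tab$pos <- as.integer(tab$pos)
  validate_marker_table(tab)
  structure(tab, class = c("marker_table", "data.frame"))
}

#' @param table A `marker_table`.
#' @rdname read_marker_table
#' @export
write_marker_table <- function(table, path) {
  stopifnot(inherits(table, "marker_table"))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Founder allele carried by a haplotype at given markers
#'
#' Maps founder-of-origin codes to 0/1 biallelic genotypes through the
#' founder allele table.
#'
#' @param hap Integer vector/matrix of haplotype codes 1..8 (NA allowed).
#' @param table A `marker_table`.
#' @param marker Marker row indices, one per column of `hap` (or one per
#'   element if `hap` is a vector).
#' @return 0/1 genotypes with the shape of `hap`.
#' @export
founder_genotype <- function(hap, table, marker) {
  fo <- founder_cols(table)
  if (is.matrix(hap)) {
    if (length(marker) != ncol(hap)) stop("one marker per haplotype column")
    out <- hap
    for (j in seq_len(ncol(hap))) {
      out[, j] <- ifelse(is.na(hap[, j]), NA, fo[marker[j], ][hap[, j]])
    }
    out
  } else {
    if (length(marker) == 1) marker <- rep(marker, length(hap))
    ifelse(is.na(hap), NA, fo[cbind(marker, hap)])
  }
}
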