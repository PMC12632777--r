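#' Haplotype matrix: founder-of-origin codes per strain and marker
#'
#' Rows are strains, columns markers. Monosomic cells hold a single code in
#' 1..8; disomic cells hold an unordered pair \{i,j\}; missing cells are NA
#' (encoded 0 in files). Internally stored as two integer matrices `hap1`
#' and `hap2`: monosomic cells have `hap2 = NA`; disomic cells satisfy
#' `hap1 <= hap2`.
#'
#' @param hap1 Integer matrix (strains x markers), codes 1..8 or NA.
#' @param hap2 Optional second-homolog matrix (same shape); NA where
#'   monosomic.
#' @param strains Strain labels (default rownames of `hap1`).
#'
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(hap1, hap2 = NULL, strains = rownames(hap1)) {
  hap1 <- as.matrix(hap1)
  storage.mode(hap1) <- "integer"
  if (is.null(strains)) strains <- paste0("strain", seq_len(nrow(hap1)))
  check_codes <- function(m, nm) {
    bad <- which(!is.na(m) & !(m %in% 1:8), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop("haplotype code outside 1..8 in ", nm, " at strain ",
           bad[1, 1], ", marker ", bad[1, 2])
    }
  }
  check_codes(hap1, "hap1")
  if (!is.null(hap2)) {
    hap2 <- as.matrix(hap2)
    storage.mode(hap2) <- "integer"
    if (!all(dim(hap2) == dim(hap1))) stop("hap1/hap2 dimension mismatch")
    check_codes(hap2, "hap2")
    sw <- !is.na(hap2) & !is.na(hap1) & hap2 < hap1
    if (any(sw)) {  # normalize unordered pairs to hap1 <= hap2
      tmp <- hap1[sw]; hap1[sw] <- hap2[sw]; hap2[sw] <- tmp
    }
  }
  rownames(hap1) <- strains
  if (!is.null(hap2)) rownames(hap2) <- strains
  structure(list(hap1 = hap1, hap2 = hap2, strains = strains),
            class = "hap_matrix")
}

#' @export
dim.hap_matrix <- function(x) dim(x$hap1)

#' @export
print.hap_matrix <- function(x, ...) {
  cat("hap_matrix:", nrow(x$hap1), "strains x", ncol(x$hap1), "markers")
  if (!is.null(x$hap2) && any(!is.na(x$hap2))) {
    cat(" (", sum(!is.na(x$hap2)), "disomic cells )")
  }
  cat("\n")
  invisible(x)
}

#' Coerce to a plain monosomic code matrix
#'
#' Disomic cells (if any) are set to NA; use the `hap1`/`hap2` components
#' directly to work with disomes.
#'
#' @param x A `hap_matrix` or integer matrix.
#' @return Integer matrix of codes 1..8 with NA for missing/disomic cells.
#' @export
hap_codes <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    return(x)
  }
  stopifnot(inherits(x, "hap_matrix"))
  h <- x$hap1
  if (!is.null(x$hap2)) h[!is.na(x$hap2)] <- NA_integer_
  h
}

#' Read / write a haplotype matrix
#'
#' Tab-separated with header; first column `strain`, remaining columns one
#' per marker. Monosomic cells are written as the code (1..8), disomic
#' cells as "i/j", and missing cells as the sentinel 0. Write then read is
#' the identity.
#'
#' @param path File path.
#' @return `read_haplotype_matrix` returns a `hap_matrix`.
#' @export
read_haplotype_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (names(tab)[1] != "strain") stop("first column must be 'strain'")
  strains <- tab$strain
  cells <- as.matrix(tab[-1])
  n <- nrow(cells); m <- ncol(cells)
  hap1 <- matrix(NA_integer_, n, m)
  hap2 <- matrix(NA_integer_, n, m)
  pair <- grepl("/", cells, fixed = TRUE)
  if (any(pair)) {
    parts <- strsplit(cells[pair], "/", fixed = TRUE)
    hap1[pair] <- as.integer(vapply(parts, `[`, "", 1))
    hap2[pair] <- as.integer(vapply(parts, `[`, "", 2))
  }
  single <- !pair
  v <- suppressWarnings(as.integer(cells[single]))
  if (anyNA(v)) {
    bad <- which(single)[which(is.na(v))[1]]
    stop("unparseable haplotype cell at strain ",
         (bad - 1) %% n + 1, ", marker ", (bad - 1) %/% n + 1)
  }
  v[v == 0L] <- NA_integer_  # file sentinel for missing
  hap1[single] <- v
  bad <- which((!is.na(hap1) & !(hap1 %in% 1:8)) |
                 (!is.na(hap2) & !(hap2 %in% 1:8)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("haplotype code outside 1..8 at strain ", bad[1, 1],
         ", marker ", bad[1, 2])
  }
  if (all(is.na(hap2))) hap2 <- NULL
  hm <- hap_matrix(hap1, hap2, strains = strains)
  colnames(hm$hap1) <- colnames(cells)
  if (!is.null(hm$hap2)) colnames(hm$hap2) <- colnames(cells)
  hm
}

#' @param matrix A `hap_matrix` (or plain integer matrix of codes).
#' @rdname read_haplotype_matrix
#' @export
write_haplotype_matrix <- function(matrix, path) {
  if (!inherits(matrix, "hap_matrix")) matrix <- hap_matrix(matrix)
  h1 <- matrix$hap1; h2 <- matrix$hap2
  cells <- ifelse(is.na(h1), "0", as.character(h1))
  if (!is.null(h2)) {
    dis <- !is.na(h2)
    cells[dis] <- paste0(h1[dis], "/", h2[dis])
  }
  mk <- colnames(h1)
  if (is.null(mk)) mk <- paste0("m", seq_len(ncol(h1)))
  out <- data.frame(strain = matrix$strains, cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("strain", mk)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
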