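#' Binary genotype matrices
#'
#' The observed data is a matrix of mutation calls: cells in rows, somatic
#' variant sites in columns, entries 0 (unmutated), 1 (mutated) or `NA`
#' (unknown, e.g. no coverage or allele dropout of both alleles at a
#' heterozygous site).
#'
#' @param x matrix coercible to integer with entries in `{0, 1, NA}`;
#'   rownames are cell identifiers, colnames are site identifiers (defaults
#'   `cell1..n` / `site1..m` are supplied when missing)
#' @return an integer matrix of class `genotype_matrix`
#' @export
genotype_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("a genotype matrix needs at least one cell and one site")
  bad <- which(!is.na(x) & x != 0L & x != 1L)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(x))
    stop("genotype entries must be 0, 1 or NA; found ", x[bad[1L]],
         " at cell ", i[1L], ", site ", i[2L])
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("cell", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("site", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate cell identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate site identifiers")
  all_na <- colSums(!is.na(x)) == 0L
  if (any(all_na))
    warning(sum(all_na), " site(s) have no observed entries: ",
            paste(utils::head(colnames(x)[all_na], 5L), collapse = ", "))
  structure(x, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x), " cells x ", ncol(x), " sites; ",
      sum(is.na(x)), " missing (",
      round(100 * mean(is.na(x)), 1), "%), ",
      sum(x == 1L, na.rm = TRUE), " mutated calls\n", sep = "")
  invisible(x)
}

.na_tokens <- c("NA", "na", "", "?", "3")

#' Read a genotype matrix from delimited text
#'
#' TSV or CSV (chosen by file extension, `.csv` means comma) with one
#' header row and one leading identifier column. The common interchange
#' layout puts sites in rows and cells in columns; the matrix is always
#' returned cells-in-rows internally. Accepted missing-value tokens are
#' `NA`, `na`, the empty string, `?` and `3`.
#'
#' @param path input file
#' @param orientation `"sites-as-rows"` (default) or `"cells-as-rows"`
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path,
                           orientation = c("sites-as-rows", "cells-as-rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, comment.char = "",
                          quote = "\"")
  m <- as.matrix(df)
  vals <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  vals[m == "0"] <- 0L
  vals[m == "1"] <- 1L
  bad <- which(is.na(vals) & !(trimws(m) %in% .na_tokens))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop("unparseable genotype entry '", m[bad[1L]], "' at row '",
         rownames(m)[i[1L]], "', column '", colnames(m)[i[2L]], "'")
  }
  if (orientation == "sites-as-rows") vals <- t(vals)
  genotype_matrix(vals)
}

#' Write a genotype matrix as delimited text
#'
#' Inverse of [read_genotypes()]: `NA` is always written as the token
#' `NA`, and the round trip through disk is lossless.
#'
#' @param G a [genotype_matrix()]
#' @param path output file (`.csv` writes comma-separated)
#' @param orientation file layout, as in [read_genotypes()]
#' @export
write_genotypes <- function(G, path,
                            orientation = c("sites-as-rows", "cells-as-rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- unclass(G)
  if (orientation == "sites-as-rows") m <- t(m)
  df <- as.data.frame(m, check.names = FALSE)
  df <- cbind(id = rownames(m), df)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Binarize three-state genotype calls
#'
#' Collapses diploid genotype calls to mutation presence: homozygous
#' reference becomes 0, heterozygous and homozygous alternative both
#' become 1 (a homozygous mutant call still demonstrates the mutation),
#' missing stays missing. Input coding is 0/1/2/NA or the literal strings
#' `"hom-ref"`, `"het"`, `"hom-alt"`.
#'
#' @param raw matrix with entries in `{0, 1, 2, NA}` or the string codes
#' @return a [genotype_matrix()]
#' @export
binarize <- function(raw) {
  m <- as.matrix(raw)
  if (is.character(m)) {
    conv <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
    conv[m == "hom-ref"] <- 0L
    conv[m == "het"] <- 1L
    conv[m == "hom-alt"] <- 2L
    bad <- which(is.na(conv) & !(m %in% c(.na_tokens[-5L], NA)))
    if (length(bad))
      stop("unknown genotype code '", m[bad[1L]], "'")
    m <- conv
  } else {
    storage.mode(m) <- "integer"
    if (any(!is.na(m) & !(m %in% c(0L, 1L, 2L))))
      stop("numeric genotype codes must be 0 (hom-ref), 1 (het), 2 (hom-alt) or NA")
  }
  m[!is.na(m) & m == 2L] <- 1L
  genotype_matrix(m)
}
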