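# NCBI-format substitution matrices. The package ships the standard
# BLOSUM62 file (inst/extdata/BLOSUM62.txt); scores for 'X' come from the
# file's X row.

#' Read a substitution matrix in NCBI text format
#'
#' The format is a whitespace-delimited square matrix: \code{#} comment
#' lines, a header row of residue letters, then one row per residue with
#' its letter followed by integer scores.
#'
#' @param file path to the matrix file, or a character vector of lines
#' @param name matrix name stored on the result
#' @return an integer matrix of class \code{substitution_matrix} with
#'   residue letters as dimnames
#' @export
read_substitution_matrix <- function(file, name = NULL) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  if (is.null(name)) name <- if (length(file) == 1L && file.exists(file))
    sub("\\.[^.]*$", "", basename(file)) else "matrix"
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("substitution matrix input too short")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  if (length(body) != length(header))
    stop("matrix is not square: ", length(header), " columns, ",
         length(body), " rows")
  rlab <- vapply(body, `[`, "", 1)
  sc <- t(vapply(body, function(b) as.integer(b[-1]), integer(length(header))))
  if (anyNA(sc)) stop("non-integer score entries in matrix")
  dimnames(sc) <- list(rlab, header)
  sc <- sc[, rlab, drop = FALSE]  # align column order to row order
  if (!isTRUE(all.equal(sc, t(sc))))
    stop("asymmetric substitution matrix entries")
  missing <- setdiff(amino_acids(), rlab)
  if (length(missing))
    stop("matrix lacks standard residues: ", paste(missing, collapse = ", "))
  structure(sc, name = name, class = c("substitution_matrix", class(sc)))
}

#' The packaged BLOSUM62 matrix
#'
#' Reads the NCBI-format BLOSUM62 file shipped with the package.
#'
#' @return a \code{substitution_matrix}
#' @export
blosum62 <- function() {
  read_substitution_matrix(
    system.file("extdata", "BLOSUM62.txt", package = "paradiv",
                mustWork = TRUE), name = "BLOSUM62")
}

#' Look up substitution scores
#'
#' @param matrix a \code{substitution_matrix}
#' @param a,b residue letters (vectorized)
#' @return integer score vector
#' @export
sub_score <- function(matrix, a, b) {
  bad <- setdiff(unique(c(a, b)), rownames(matrix))
  if (length(bad))
    stop("residues absent from matrix: ", paste(bad, collapse = ", "))
  matrix[cbind(a, b)]
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("substitution_matrix '%s': %d x %d residues\n",
              attr(x, "name"), nrow(x), ncol(x)))
  invisible(x)
}
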