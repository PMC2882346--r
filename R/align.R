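# Global pairwise alignment with affine gap costs, and percent identity.
# A gap of length L costs gap_open + (L - 1) * gap_extend. The gap-open
# default follows the "gap penalty of 10" convention for BLOSUM62 protein
# alignment; the extension default is the ClustalW-style 0.5.

#' Alignment parameters
#'
#' @param matrix a \code{substitution_matrix} (default packaged BLOSUM62)
#' @param gap_open non-negative cost of the first residue of a gap
#' @param gap_extend non-negative cost of each further gap residue;
#'   must not exceed \code{gap_open}
#' @return an \code{alignment_params} list
#' @export
alignment_params <- function(matrix = blosum62(), gap_open = 10,
                             gap_extend = 0.5) {
  stopifnot(inherits(matrix, "substitution_matrix"),
            gap_open >= gap_extend, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_params")
}

#' Globally align two protein sequences
#'
#' Needleman-Wunsch with affine gaps (Gotoh). The optimum maximizes the sum
#' of substitution scores minus affine gap costs. Traceback ties are broken
#' deterministically: substitution is preferred over a gap in the second
#' sequence, which is preferred over a gap in the first.
#'
#' @param s1,s2 ungapped residue strings, or single rows of a
#'   \code{protein_set}
#' @param params an \code{\link{alignment_params}}
#' @return list with \code{msa} (2-row \code{\link{protein_msa}}) and
#'   \code{score}
#' @export
pairwise_align <- function(s1, s2, params = alignment_params()) {
  n1 <- seq_name(s1, "s1"); n2 <- seq_name(s2, "s2")
  s1 <- seq_residues(s1); s2 <- seq_residues(s2)
  c1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  S <- matrix(0, length(c1), length(c2))
  if (length(c1) && length(c2))
    S[] <- sub_score(params$matrix,
                     rep(c1, times = length(c2)),
                     rep(c2, each = length(c1)))
  al <- .gotoh_align(S, params$gap_open, params$gap_extend)
  r1 <- ifelse(al$i1 == 0, "-", c1[pmax(al$i1, 1)])
  r2 <- ifelse(al$i2 == 0, "-", c2[pmax(al$i2, 1)])
  gapped <- c(paste(r1, collapse = ""), paste(r2, collapse = ""))
  names(gapped) <- make.unique(c(n1, n2))
  list(msa = protein_msa(gapped), score = al$score)
}

seq_name <- function(s, default) {
  if (inherits(s, "protein_set") || is.data.frame(s)) s$id[1]
  else if (!is.null(names(s)) && nzchar(names(s)[1])) names(s)[1]
  else default
}
seq_residues <- function(s) {
  if (inherits(s, "protein_set") || is.data.frame(s)) toupper(s$residues[1])
  else toupper(unname(s[1]))
}

#' Percent identity between two aligned rows
#'
#' 100 x (columns where both rows carry the identical non-gap residue) /
#' (columns where both rows are non-gap). If no column is comparable the
#' result is 0 with a warning.
#'
#' @param row1,row2 gapped strings of equal length
#' @return percentage in [0, 100]
#' @export
percent_identity <- function(row1, row2) {
  a <- strsplit(row1, "", fixed = TRUE)[[1]]
  b <- strsplit(row2, "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("aligned rows differ in length (", length(a), " vs ", length(b), ")")
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) {
    warning("no comparable (both non-gap) columns; returning 0")
    return(0)
  }
  100 * sum(a == b & comparable) / sum(comparable)
}
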