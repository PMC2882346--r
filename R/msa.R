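# Progressive multiple alignment: NJ guide tree (midpoint-rooted for the
# merge order), profile-profile alignment bottom-up. The profile-profile
# column score is the mean over all cross-row pairs of the substitution
# score, a gap-vs-residue pair contributing -gap_extend and gap-vs-gap 0.
# Existing gaps are never removed ("once a gap, always a gap").

#' Progressive multiple sequence alignment
#'
#' @param seqs a \code{\link{protein_set}} with at least 2 sequences
#' @param params an \code{\link{alignment_params}}
#' @return a \code{\link{protein_msa}} with rows in input order
#' @export
progressive_msa <- function(seqs, params = alignment_params()) {
  n <- nrow(seqs)
  if (n < 2) stop("need at least 2 sequences")
  if (n == 2) return(pairwise_align(seqs[1, ], seqs[2, ], params)$msa)

  guide <- nj_tree(build_distance_matrix(seqs, params))
  guide <- tryCatch(phangorn::midpoint(guide), error = function(e) guide)

  align_node <- function(node) {
    if (node <= length(guide$tip.label)) {
      id <- guide$tip.label[node]
      s <- seqs$residues[match(id, escape_newick(seqs$id))]
      m <- matrix(strsplit(s, "", fixed = TRUE)[[1]], nrow = 1)
      rownames(m) <- id
      return(m)
    }
    children <- guide$edge[guide$edge[, 1] == node, 2]
    Reduce(function(p1, p2) align_profiles(p1, p2, params),
           lapply(children, align_node))
  }
  root <- setdiff(guide$edge[, 1], guide$edge[, 2])[1]
  m <- align_node(root)
  m <- m[match(escape_newick(seqs$id), rownames(m)), , drop = FALSE]
  rownames(m) <- seqs$id
  protein_msa(msa_strings(structure(m, class = c("protein_msa", "matrix"))))
}

# align two profiles (character matrices); returns the merged matrix
align_profiles <- function(p1, p2, params) {
  S <- profile_score_matrix(p1, p2, params)
  al <- .gotoh_align(S, params$gap_open, params$gap_extend)
  expand <- function(p, idx) {
    out <- matrix("-", nrow(p), length(idx), dimnames = list(rownames(p)))
    out[, idx != 0] <- p[, idx[idx != 0], drop = FALSE]
    out
  }
  rbind(expand(p1, al$i1), expand(p2, al$i2))
}

# column-by-column mean cross-pair score between two profiles
profile_score_matrix <- function(p1, p2, params) {
  alph <- rownames(params$matrix)
  Sfull <- rbind(cbind(params$matrix, -params$gap_extend),
                 c(rep(-params$gap_extend, ncol(params$matrix)), 0))
  counts <- function(p) {
    lev <- c(alph, "-")
    m <- matrix(0L, length(lev), ncol(p))
    for (j in seq_len(ncol(p)))
      m[, j] <- tabulate(match(p[, j], lev), length(lev))
    m
  }
  c1 <- counts(p1); c2 <- counts(p2)
  (t(c1) %*% Sfull %*% c2) / (nrow(p1) * nrow(p2))
}

#' Write an alignment in Clustal format
#'
#' @param msa a \code{\link{protein_msa}}
#' @param file output path
#' @param width block width
#' @return \code{file}, invisibly
#' @export
write_clustal <- function(msa, file, width = 60L) {
  s <- msa_strings(msa)
  ids <- formatC(names(s), width = max(nchar(names(s))) + 3, flag = "-")
  out <- "CLUSTAL format alignment"
  for (start in seq(1, nchar(s[1]), width)) {
    block <- substr(s, start, min(start + width - 1L, nchar(s[1])))
    out <- c(out, "", paste0(ids, block))
  }
  writeLines(out, file)
  invisible(file)
}
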