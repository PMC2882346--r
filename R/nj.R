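# Saitou-Nei neighbor joining with a deterministic tie-break. Written here
# (rather than delegated) so that pair selection, tie-breaking and
# negative-branch clamping are fixed contracts; trees are returned as ape
# "phylo" objects.

#' Neighbor-joining tree from a distance matrix
#'
#' Iteratively joins the pair (i, j) minimizing
#' Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k); ties are
#' broken by the lexicographically smallest active-index pair. Branch
#' lengths follow the standard formulas; negative estimates are clamped to
#' zero (with a message). The final three clusters are resolved by the
#' closed-form star resolution.
#'
#' @param d symmetric numeric distance matrix (zero diagonal, taxa as
#'   dimnames), at least 3 taxa
#' @param outgroup optional taxon label; if given, the returned tree is
#'   rooted on the outgroup's pendant branch
#' @return an \code{ape} \code{phylo} tree
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  taxa <- rownames(d)
  if (is.null(taxa)) stop("distance matrix must carry taxon names")
  if (!is.null(outgroup) && !outgroup %in% taxa)
    stop("outgroup '", outgroup, "' not among taxa")

  lab <- escape_newick(taxa)  # newick fragments for each active cluster
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    best <- NULL; bestq <- Inf
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      q <- (n - 2) * d[i, j] - r[i] - r[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - li)
    newlab <- sprintf("(%s:%.10g,%s:%.10g)", lab[i], li, lab[j], lj)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    lab <- c(lab[keep], newlab)
    rownames(d2) <- colnames(d2) <- lab
    d <- d2
  }
  la <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 lab[1], la, lab[2], lb, lab[3], lc)
  tree <- ape::read.tree(text = nwk)
  if (clamped) {
    message("negative branch length estimate(s) clamped to 0")
    attr(tree, "clamped") <- TRUE
  }
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = escape_newick(outgroup),
                      resolve.root = TRUE)
  tree
}

escape_newick <- function(x) gsub("[(),:; ]", "_", x)

#' Write a tree in Newick format with an optional comment header
#'
#' @param tree a \code{phylo}
#' @param file output path
#' @param header optional \code{"#"}-prefixed comment lines
#' @return \code{file}, invisibly
#' @export
write_newick <- function(tree, file, header = NULL) {
  out <- c(if (length(header)) paste0("# ", header),
           ape::write.tree(tree))
  writeLines(out, file)
  invisible(file)
}
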