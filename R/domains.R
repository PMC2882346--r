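# Domain partitions (N-terminal / middle / C-terminal ranges per protein),
# the domain-wise percent-identity cross-comparison, and the full-length
# distance matrix feeding the neighbor-joining tree.

#' Construct a domain partition table
#'
#' One row per (sequence, domain) with 1-based inclusive residue ranges.
#' Ranges of each sequence must be contiguous, non-overlapping, start at 1,
#' and appear in order.
#'
#' @param id sequence id
#' @param domain domain label, conventionally \code{"N"}, \code{"M"},
#'   \code{"C"}
#' @param start,end 1-based inclusive residue range
#' @return a \code{domain_partition} data.frame
#' @export
domain_partition <- function(id, domain, start, end) {
  dp <- data.frame(id = as.character(id), domain = as.character(domain),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  for (s in unique(dp$id)) {
    r <- dp[dp$id == s, , drop = FALSE]
    if (r$start[1] != 1L || any(r$end < r$start) ||
        (nrow(r) > 1 && any(r$start[-1] != r$end[-nrow(r)] + 1L)))
      stop("ranges for '", s, "' must be contiguous, in order, starting at 1")
  }
  class(dp) <- c("domain_partition", "data.frame")
  dp
}

#' Default Tup-protein domain partitions
#'
#' The published N/M/C boundaries for Saccharomyces cerevisiae Tup1 and the
#' fission-yeast Tup11/Tup12 proteins (S. pombe, S. octosporus,
#' S. japonicus). Tup1's C-terminal WD40 domain spans residues 318-713.
#'
#' @return a \code{\link{domain_partition}}
#' @export
default_domain_partitions <- function() {
  tab <- list(
    Sc_Tup1  = c(89, 317, 713),
    Sp_Tup11 = c(87, 286, 614),
    So_Tup11 = c(87, 271, 601),
    Sj_Tup11 = c(87, 303, 630),
    Sp_Tup12 = c(104, 259, 586),
    So_Tup12 = c(88, 228, 555),
    Sj_Tup12 = c(88, 249, 576))
  rows <- lapply(names(tab), function(id) {
    e <- tab[[id]]
    data.frame(id = id, domain = c("N", "M", "C"),
               start = c(1L, e[1] + 1L, e[2] + 1L), end = e)
  })
  do.call(domain_partition, do.call(rbind, rows))
}

#' Domain-wise percent-identity cross-comparison
#'
#' For every protein pair and every domain label, the two domain
#' sub-sequences are extracted, globally aligned, and their percent
#' identity reported. Symmetric by construction with a diagonal of 100.
#'
#' @param seqs a \code{\link{protein_set}}
#' @param partitions a \code{\link{domain_partition}} covering every id in
#'   \code{seqs}
#' @param params an \code{\link{alignment_params}}
#' @return a \code{domain_identity} object: named list of symmetric
#'   percent-identity matrices, one per domain label
#' @export
domain_identity_matrix <- function(seqs, partitions,
                                   params = alignment_params()) {
  miss <- setdiff(seqs$id, partitions$id)
  if (length(miss))
    stop("no domain partition for: ", paste(miss, collapse = ", "))
  for (k in seq_len(nrow(seqs))) {
    last <- max(partitions$end[partitions$id == seqs$id[k]])
    if (last != nchar(seqs$residues[k]))
      stop("partition of '", seqs$id[k], "' ends at ", last,
           " but sequence has ", nchar(seqs$residues[k]), " residues")
  }
  domains <- unique(partitions$domain)
  n <- nrow(seqs)
  out <- lapply(domains, function(d) {
    m <- diag(100, n)
    dimnames(m) <- list(seqs$id, seqs$id)
    m
  })
  names(out) <- domains
  sub_seq <- function(i, d) {
    r <- partitions[partitions$id == seqs$id[i] & partitions$domain == d, ]
    substr(seqs$residues[i], r$start, r$end)
  }
  for (d in domains)
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      al <- pairwise_align(sub_seq(i, d), sub_seq(j, d), params)
      g <- msa_strings(al$msa)
      out[[d]][i, j] <- out[[d]][j, i] <- percent_identity(g[1], g[2])
    }
  structure(out, class = "domain_identity")
}

#' @export
print.domain_identity <- function(x, digits = 1, ...) {
  for (d in names(x)) {
    cat("domain", d, "(% identity):\n")
    print(round(unclass(x)[[d]], digits))
  }
  invisible(x)
}

#' Export a domain identity comparison as TSV
#'
#' One row per (protein pair, domain), upper triangle only.
#'
#' @param x a \code{domain_identity}
#' @param file output path
#' @param header optional \code{"#"}-prefixed comment lines
#' @return \code{file}, invisibly
#' @export
write_domain_identity <- function(x, file, header = NULL) {
  rows <- do.call(rbind, lapply(names(x), function(d) {
    m <- unclass(x)[[d]]
    idx <- which(upper.tri(m, diag = FALSE), arr.ind = TRUE)
    data.frame(protein1 = rownames(m)[idx[, 1]],
               protein2 = colnames(m)[idx[, 2]],
               domain = d, percent_identity = m[idx])
  }))
  write_tsv(rows, file, header)
}

# shared TSV writer: optional '#' comment header + tab-separated body
write_tsv <- function(df, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_tsv <- function(file) {
  read.table(file, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Full-length pairwise distance matrix
#'
#' d(i, j) = 1 - identity/100 from a global alignment of the full-length
#' sequences; optionally Poisson-corrected, d = -log(identity fraction).
#'
#' @param seqs a \code{\link{protein_set}} with at least 3 sequences
#' @param params an \code{\link{alignment_params}}
#' @param correction \code{"none"} (default) or \code{"poisson"}
#' @return symmetric numeric matrix with zero diagonal, ids as dimnames
#' @export
build_distance_matrix <- function(seqs, params = alignment_params(),
                                  correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  n <- nrow(seqs)
  if (n < 3) stop("need at least 3 sequences for a distance matrix")
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    al <- pairwise_align(seqs[i, ], seqs[j, ], params)
    g <- msa_strings(al$msa)
    p <- percent_identity(g[1], g[2]) / 100
    d[i, j] <- d[j, i] <- if (correction == "poisson") {
      if (p <= 0) stop("Poisson correction undefined at 0% identity")
      -log(p)
    } else 1 - p
  }
  d
}
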