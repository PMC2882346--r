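# Sequence IO: FASTA reading/writing and the protein_set container.
#
# A protein_set is a data.frame with columns id, species, group, residues
# (one ungapped sequence per row). FASTA headers may carry the species and
# group as "key=value;" annotations after the id token:
#   >Sp_Tup11 species=S. pombe;group=Tup11

#' Construct a protein sequence set
#'
#' @param id character vector of unique sequence identifiers
#' @param residues character vector of ungapped sequences over the 20
#'   standard amino-acid letters plus \code{X}
#' @param species,group optional per-sequence labels (default \code{NA})
#' @return a \code{protein_set} data.frame with columns
#'   \code{id}, \code{species}, \code{group}, \code{residues}
#' @export
protein_set <- function(id, residues, species = NA_character_,
                        group = NA_character_) {
  stopifnot(length(id) == length(residues))
  ps <- data.frame(id = as.character(id),
                   species = rep_len(as.character(species), length(id)),
                   group = rep_len(as.character(group), length(id)),
                   residues = toupper(as.character(residues)),
                   stringsAsFactors = FALSE)
  validate_protein_set(ps)
  class(ps) <- c("protein_set", "data.frame")
  ps
}

validate_protein_set <- function(ps) {
  if (anyDuplicated(ps$id))
    stop("duplicate sequence ids: ",
         paste(unique(ps$id[duplicated(ps$id)]), collapse = ", "))
  if (any(!nzchar(ps$residues)))
    stop("empty sequence for id: ",
         paste(ps$id[!nzchar(ps$residues)], collapse = ", "))
  ok <- c(amino_acids(with_x = TRUE))
  for (k in seq_len(nrow(ps))) {
    ch <- strsplit(ps$residues[k], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% ok)
    if (length(bad))
      stop(sprintf("illegal residue '%s' at position %d in sequence '%s'",
                   ch[bad[1]], bad[1], ps$id[k]))
  }
  invisible(ps)
}

#' Read protein sequences from a FASTA file
#'
#' Multi-line records are concatenated; lowercase input is uppercased;
#' lines starting with \code{;} or \code{#} are skipped. Header lines are
#' \code{>id} optionally followed by whitespace and
#' \code{species=...;group=...} annotations.
#'
#' @param file path to a FASTA file, or a character vector of lines
#' @return a \code{\link{protein_set}}
#' @export
read_fasta <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[!grepl("^[;#]", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA input")
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA input does not start with a '>' header")
  rec <- cumsum(hdr)
  ids <- species <- groups <- character(max(rec))
  seqs <- character(max(rec))
  for (r in seq_len(max(rec))) {
    block <- lines[rec == r]
    h <- sub("^>", "", block[1])
    ids[r] <- sub("\\s.*$", "", h)
    rest <- sub("^\\S+\\s*", "", h)
    species[r] <- fasta_annot(rest, "species")
    groups[r] <- fasta_annot(rest, "group")
    seqs[r] <- toupper(paste(gsub("\\s", "", block[-1]), collapse = ""))
  }
  protein_set(ids, seqs, species = species, group = groups)
}

fasta_annot <- function(text, key) {
  m <- regmatches(text, regexec(paste0(key, "=([^;]*)"), text))[[1]]
  if (length(m) == 2) trimws(m[2]) else NA_character_
}

#' Write a protein set (or gapped alignment rows) to FASTA
#'
#' @param x a \code{protein_set}, or a named character vector of (possibly
#'   gapped) sequences
#' @param file output path
#' @param header optional character vector of comment lines written first,
#'   each prefixed with \code{";"}
#' @param width line-wrap width
#' @return \code{file}, invisibly
#' @export
write_fasta <- function(x, file, header = NULL, width = 60L) {
  if (inherits(x, "protein_set")) {
    annot <- ifelse(is.na(x$species) & is.na(x$group), "",
                    paste0(" species=", ifelse(is.na(x$species), "", x$species),
                           ";group=", ifelse(is.na(x$group), "", x$group)))
    ids <- paste0(x$id, annot)
    seqs <- x$residues
  } else {
    ids <- names(x)
    seqs <- unname(x)
  }
  out <- character(0)
  if (length(header)) out <- paste0("; ", header)
  for (k in seq_along(seqs)) {
    body <- substring(seqs[k], seq(1, nchar(seqs[k]), width),
                      pmin(seq(1, nchar(seqs[k]), width) + width - 1L,
                           nchar(seqs[k])))
    out <- c(out, paste0(">", ids[k]), body)
  }
  writeLines(out, file)
  invisible(file)
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("protein_set: %d sequences (%d-%d residues)\n", nrow(x),
              min(nchar(x$residues)), max(nchar(x$residues))))
  print.data.frame(data.frame(id = x$id, species = x$species, group = x$group,
                              length = nchar(x$residues)), row.names = FALSE)
  invisible(x)
}

# ---- multiple alignments -------------------------------------------------

#' Construct a multiple alignment from gapped strings
#'
#' Columns are 1-based; the only gap character is \code{"-"} (\code{"."} is
#' rejected). The object is a character matrix (rows = sequences, one
#' residue or gap per cell) with sequence ids as row names.
#'
#' @param gapped named character vector of equal-length gapped strings
#' @return a \code{protein_msa} character matrix
#' @export
protein_msa <- function(gapped) {
  if (is.null(names(gapped)) || any(!nzchar(names(gapped))))
    stop("alignment rows must be named by sequence id")
  n <- unique(nchar(gapped))
  if (length(n) != 1) stop("alignment rows differ in length")
  if (any(grepl(".", gapped, fixed = TRUE)))
    stop("'.' is not an accepted gap character; use '-'")
  m <- do.call(rbind, strsplit(toupper(gapped), "", fixed = TRUE))
  rownames(m) <- names(gapped)
  class(m) <- c("protein_msa", class(m))
  m
}

#' Collapse an alignment back to gapped strings
#' @param msa a \code{protein_msa}
#' @return named character vector of gapped strings
#' @export
msa_strings <- function(msa) {
  apply(unclass(msa), 1, paste, collapse = "")
}

#' Remove gaps from alignment rows
#' @param msa a \code{protein_msa}
#' @return named character vector of ungapped sequences
#' @export
msa_ungap <- function(msa) {
  gsub("-", "", msa_strings(msa), fixed = TRUE)
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("protein_msa: %d sequences x %d columns\n", nrow(x), ncol(x)))
  s <- msa_strings(x)
  shown <- substr(s, 1, 60)
  cat(sprintf(" %-15s %s%s\n", names(s), shown,
              ifelse(nchar(s) > 60, "...", "")), sep = "")
  invisible(x)
}
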