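# Reference-structure handling. Coordinates come from PDB-format ATOM
# records (parsed with bio3d); only CA atoms are retained, one point per
# residue. Residue numbers use the author numbering of the intact reference
# protein verbatim. Residues expected in the sequence span but absent from
# the coordinate records are kept as disordered records without coordinates.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Read CA coordinates for one chain of a PDB file
#'
#' @param file path to a PDB file, or a character vector of ATOM-record lines
#' @param chain chain identifier to extract
#' @param seq_span integer vector (or \code{c(first, last)} range) of author
#'   residue numbers expected for the domain; numbers without a CA record
#'   are marked disordered
#' @param source label stored on the model (defaults to file name + chain)
#' @return a \code{structure_model}: list with \code{source} and a
#'   \code{residues} data.frame (\code{number}, \code{aa}, \code{x},
#'   \code{y}, \code{z}, \code{disordered})
#' @export
read_structure <- function(file, chain, seq_span, source = NULL) {
  if (length(seq_span) == 2L && seq_span[2] >= seq_span[1] + 1L)
    seq_span <- seq.int(seq_span[1], seq_span[2])
  seq_span <- as.integer(seq_span)
  path <- file
  if (!(length(file) == 1L && file.exists(file))) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(file, path)
  }
  if (is.null(source))
    source <- paste0(if (length(file) == 1L && file.exists(file))
      basename(file) else "pdb-text", ":", chain)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA" & at$chain == chain, ,
           drop = FALSE]
  if (!nrow(at)) stop("chain not found: ", chain)
  # first-listed alternate conformer only
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]
  bad <- setdiff(unique(at$resid), names(AA3TO1))
  if (length(bad))
    stop("non-standard residues in chain ", chain, ": ",
         paste(bad, collapse = ", "))
  if (is.unsorted(at$resno, strictly = TRUE))
    stop("non-monotonic residue numbering in chain ", chain)
  resolved <- data.frame(number = at$resno,
                         aa = unname(AA3TO1[at$resid]),
                         x = at$x, y = at$y, z = at$z,
                         stringsAsFactors = FALSE)
  resolved <- resolved[resolved$number %in% seq_span, , drop = FALSE]
  missing <- setdiff(seq_span, resolved$number)
  res <- rbind(cbind(resolved, disordered = FALSE),
               if (length(missing))
                 data.frame(number = missing, aa = "X", x = NA_real_,
                            y = NA_real_, z = NA_real_, disordered = TRUE))
  res <- res[order(res$number), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(source = source, residues = res),
            class = "structure_model")
}

#' Residue-number span covered by a structure model
#' @param model a \code{structure_model}
#' @return integer vector of residue numbers
#' @export
structure_span <- function(model) model$residues$number

#' CA coordinates of resolved residues
#' @param model a \code{structure_model}
#' @return numeric matrix (x, y, z) with residue numbers as row names
#' @export
structure_coords <- function(model) {
  r <- model$residues[!model$residues$disordered, , drop = FALSE]
  m <- as.matrix(r[, c("x", "y", "z")])
  rownames(m) <- r$number
  m
}

#' @export
print.structure_model <- function(x, ...) {
  r <- x$residues
  cat(sprintf("structure_model [%s]: residues %d-%d, %d resolved, %d disordered\n",
              x$source, min(r$number), max(r$number), sum(!r$disordered),
              sum(r$disordered)))
  invisible(x)
}

#' Write a per-residue attribute file for molecular viewers
#'
#' Tab-separated, one data line per residue, with a one-line header naming
#' the attribute. Duplicate residues with conflicting categories are an
#' error; consistent duplicates are collapsed.
#'
#' @param sites data.frame with columns \code{resno} and \code{category}
#'   (or a two-column data.frame in that order)
#' @param file output path
#' @param attribute attribute name written in the header
#' @param header optional extra comment lines (prefixed \code{"#"})
#' @return \code{file}, invisibly
#' @export
write_attribute_map <- function(sites, file,
                                attribute = "divergence_category",
                                header = NULL) {
  if (nrow(sites)) {
    resno <- as.integer(sites[[if ("resno" %in% names(sites)) "resno" else 1]])
    category <- as.character(
      sites[[if ("category" %in% names(sites)) "category" else 2]])
    u <- !duplicated(paste(resno, category))
    resno <- resno[u]; category <- category[u]
    if (anyDuplicated(resno))
      stop("conflicting categories for residue(s): ",
           paste(unique(resno[duplicated(resno)]), collapse = ", "))
    o <- order(resno)
    body <- paste(resno[o], category[o], sep = "\t")
  } else body <- character(0)
  out <- c(if (length(header)) paste0("# ", header),
           paste("residue", attribute, sep = "\t"), body)
  writeLines(out, file)
  invisible(file)
}
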