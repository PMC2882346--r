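# Group-diagnostic divergent-residue detection. An alignment column is
# reported when (1) all criterion-species rows of group A carry one non-gap
# residue r_a, (2) likewise group B gives r_b, (3) r_a != r_b, and (4) the
# pair has significantly different properties: a negative substitution
# score or opposite net charge. Reported sites are then polarized against
# an outgroup row: which group (if either) retains the outgroup residue.

#' Side-chain charge of a residue
#'
#' Fixed table: D and E are negative, K and R positive, everything else
#' (including H, whose charge is pH-dependent, and X) neutral. Set
#' \code{h_positive = TRUE} to count histidine as positive.
#'
#' @param aa vector of one-letter residue codes
#' @param h_positive treat H as +1?
#' @return integer vector in \{-1, 0, +1\}
#' @export
residue_charge <- function(aa, h_positive = FALSE) {
  aa <- toupper(aa)
  bad <- setdiff(unique(aa), amino_acids(with_x = TRUE))
  if (length(bad))
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "))
  ch <- integer(length(aa))
  ch[aa %in% c("D", "E")] <- -1L
  ch[aa %in% c("K", "R")] <- 1L
  if (h_positive) ch[aa == "H"] <- 1L
  ch
}

#' Is a residue pair significantly different?
#'
#' TRUE iff the substitution score is negative or the two residues carry
#' opposite net charge. Identical residues are outside the predicate's
#' domain and raise an error; callers must pre-filter.
#'
#' @param r1,r2 distinct residue letters
#' @param matrix a \code{substitution_matrix}
#' @param h_positive passed to \code{\link{residue_charge}}
#' @return list with \code{significant} (logical) and \code{reasons}
#'   (subset of \code{"blosum_negative"}, \code{"opposite_charge"})
#' @export
is_significant_pair <- function(r1, r2, matrix = blosum62(),
                                h_positive = FALSE) {
  if (r1 == r2) stop("identical residues are never divergent: ", r1)
  reasons <- character(0)
  if (sub_score(matrix, r1, r2) < 0) reasons <- "blosum_negative"
  if (residue_charge(r1, h_positive) * residue_charge(r2, h_positive) == -1L)
    reasons <- c(reasons, "opposite_charge")
  list(significant = length(reasons) > 0, reasons = reasons)
}

#' Specify the two paralog groups and the outgroup
#'
#' @param group_a,group_b lists with \code{label} (string) and
#'   \code{members}: a character vector of sequence ids named by species
#' @param outgroup_id sequence id of the outgroup row, or \code{NULL}
#' @param criterion_species species whose rows must be conserved within
#'   each group; default: all species present in both groups
#' @return a \code{group_spec} list
#' @export
group_spec <- function(group_a, group_b, outgroup_id = NULL,
                       criterion_species = NULL) {
  for (g in list(group_a, group_b))
    if (is.null(g$label) || is.null(names(g$members)) ||
        any(!nzchar(names(g$members))))
      stop("each group needs a label and members named by species")
  if (length(intersect(group_a$members, group_b$members)))
    stop("groups share sequence ids")
  if (is.null(criterion_species))
    criterion_species <- intersect(names(group_a$members),
                                   names(group_b$members))
  if (!length(criterion_species)) stop("criterion species set is empty")
  for (g in list(group_a, group_b)) {
    miss <- setdiff(criterion_species, names(g$members))
    if (length(miss))
      stop("criterion species absent from group '", g$label, "': ",
           paste(miss, collapse = ", "))
  }
  if (!is.null(outgroup_id) &&
      outgroup_id %in% c(group_a$members, group_b$members))
    stop("outgroup must not be a member of either group")
  structure(list(group_a = group_a, group_b = group_b,
                 outgroup_id = outgroup_id,
                 criterion_species = criterion_species),
            class = "group_spec")
}

#' Find group-diagnostic divergent sites in an alignment
#'
#' Columns where any criterion-species row is gapped or carries \code{X}
#' are skipped (identity cannot be certified). Output is sorted by column.
#'
#' @param msa a \code{\link{protein_msa}}
#' @param spec a \code{\link{group_spec}}; all member ids must be rows of
#'   \code{msa}
#' @param matrix a \code{substitution_matrix}
#' @param h_positive passed to \code{\link{residue_charge}}
#' @return a \code{divergent_sites} data.frame with columns \code{column},
#'   \code{residue_a}, \code{residue_b}, \code{blosum_score},
#'   \code{charge_a}, \code{charge_b}, \code{blosum_negative},
#'   \code{opposite_charge}, \code{category} (\code{NA} until
#'   \code{\link{classify_vs_outgroup}})
#' @export
find_divergent_sites <- function(msa, spec, matrix = blosum62(),
                                 h_positive = FALSE) {
  ids_a <- spec$group_a$members[spec$criterion_species]
  ids_b <- spec$group_b$members[spec$criterion_species]
  miss <- setdiff(c(ids_a, ids_b), rownames(msa))
  if (length(miss))
    stop("ids absent from alignment: ", paste(miss, collapse = ", "))
  m <- unclass(msa)
  hits <- list()
  for (col in seq_len(ncol(m))) {
    ra <- unique(m[ids_a, col])
    rb <- unique(m[ids_b, col])
    if (length(ra) != 1 || length(rb) != 1) next
    if (ra %in% c("-", "X") || rb %in% c("-", "X")) next
    if (ra == rb) next
    sig <- is_significant_pair(ra, rb, matrix, h_positive)
    if (!sig$significant) next
    hits[[length(hits) + 1]] <- data.frame(
      column = col, residue_a = ra, residue_b = rb,
      blosum_score = as.integer(sub_score(matrix, ra, rb)),
      charge_a = residue_charge(ra, h_positive),
      charge_b = residue_charge(rb, h_positive),
      blosum_negative = "blosum_negative" %in% sig$reasons,
      opposite_charge = "opposite_charge" %in% sig$reasons,
      category = NA_character_, stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(column = integer(0), residue_a = character(0),
               residue_b = character(0), blosum_score = integer(0),
               charge_a = integer(0), charge_b = integer(0),
               blosum_negative = logical(0), opposite_charge = logical(0),
               category = character(0), stringsAsFactors = FALSE)
  class(out) <- c("divergent_sites", "data.frame")
  out
}

#' Polarize divergent sites against the outgroup row
#'
#' Per site, with r_o the outgroup residue at the column:
#' r_o == residue_a gives \code{"A_matches_outgroup"}; r_o == residue_b
#' gives \code{"B_matches_outgroup"}; any other non-gap r_o gives
#' \code{"both_differ"}; a gap gives \code{"unclassified"}.
#'
#' @param sites a \code{divergent_sites} table
#' @param msa the alignment the sites came from
#' @param outgroup_id id of the outgroup row
#' @return \code{sites} with \code{category} and \code{residue_outgroup}
#'   filled in
#' @export
classify_vs_outgroup <- function(sites, msa, outgroup_id) {
  if (!outgroup_id %in% rownames(msa))
    stop("outgroup id absent from alignment: ", outgroup_id)
  ro <- unclass(msa)[outgroup_id, sites$column]
  sites$residue_outgroup <- as.character(ro)
  sites$category <- ifelse(ro == "-", "unclassified",
                    ifelse(ro == sites$residue_a, "A_matches_outgroup",
                    ifelse(ro == sites$residue_b, "B_matches_outgroup",
                           "both_differ")))
  if (!nrow(sites)) sites$category <- character(0)
  sites
}

#' @export
print.divergent_sites <- function(x, ...) {
  cat(sprintf("divergent_sites: %d group-diagnostic columns\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 20), row.names = FALSE)
  if (nrow(x) > 20) cat("...\n")
  invisible(x)
}

#' Export a divergent-site table as TSV
#'
#' @param sites a \code{divergent_sites} table (optionally with the mapped
#'   structure columns added by \code{\link{map_sites_to_structure}})
#' @param file output path
#' @param header optional \code{"#"}-prefixed comment lines
#' @return \code{file}, invisibly
#' @export
write_site_table <- function(sites, file, header = NULL) {
  write_tsv(as.data.frame(sites), file, header)
}
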