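# Mapping alignment columns onto reference-structure residue numbers,
# beta-propeller blade annotation, per-blade occupancy, and a permutation
# test for spatial clustering of mapped sites.

#' Construct a blade annotation table
#'
#' One row per (blade, strand) residue range in reference numbering.
#' Ranges must not overlap and blade indices must be contiguous from 1.
#'
#' @param blade integer blade index
#' @param strand strand label (conventionally \code{"A"}-\code{"D"})
#' @param start,end inclusive residue-number range
#' @return a \code{blade_annotation} data.frame
#' @export
blade_annotation <- function(blade, strand, start, end) {
  ba <- data.frame(blade = as.integer(blade), strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(ba$end < ba$start)) stop("range end before start")
  if (!identical(sort(unique(ba$blade)), seq_len(max(ba$blade))))
    stop("blade indices must be contiguous from 1")
  covered <- unlist(Map(seq.int, ba$start, ba$end))
  if (anyDuplicated(covered)) stop("overlapping blade/strand ranges")
  class(ba) <- c("blade_annotation", "data.frame")
  ba
}

#' Read / write blade annotations as TSV (columns blade, strand, start, end)
#' @param file path
#' @return a \code{\link{blade_annotation}}
#' @export
read_blade_annotation <- function(file) {
  x <- read_tsv(file)
  blade_annotation(x$blade, x$strand, x$start, x$end)
}

#' @rdname read_blade_annotation
#' @param annotation a \code{blade_annotation}
#' @param header optional \code{"#"}-prefixed comment lines
#' @export
write_blade_annotation <- function(annotation, file, header = NULL) {
  write_tsv(as.data.frame(annotation), file, header)
}

#' Default blade annotation (toy seven-bladed propeller)
#'
#' The WD40 fold is a seven-bladed propeller; real blade/strand boundaries
#' must be curated from a crystal structure and supplied by the user. This
#' default is the annotation of the package's toy structure
#' (\code{\link{make_toy_structure}}): seven blades of one 10-residue
#' strand each, starting at residue 301.
#'
#' @return a \code{\link{blade_annotation}} with seven blades
#' @export
default_blade_annotation <- function() {
  make_toy_structure()$annotation
}

#' Map alignment columns to reference residue numbers
#'
#' The k-th non-gap position of the reference row maps to residue number
#' \code{ref_start + k - 1}; columns where the reference row is gapped are
#' absent from the map. The disordered flag is copied from the structure.
#'
#' @param msa a \code{\link{protein_msa}} containing the reference row
#' @param ref_id row id of the reference sequence
#' @param ref_start reference-protein number of the first non-gap residue
#'   of the reference row
#' @param structure a \code{\link{read_structure}} model covering all
#'   mapped numbers
#' @return a \code{column_residue_map} data.frame (\code{column},
#'   \code{resno}, \code{disordered})
#' @export
map_alignment_to_structure <- function(msa, ref_id, ref_start, structure) {
  if (!ref_id %in% rownames(msa))
    stop("reference id absent from alignment: ", ref_id)
  row <- unclass(msa)[ref_id, ]
  cols <- which(row != "-")
  resno <- ref_start + seq_along(cols) - 1L
  span <- structure_span(structure)
  out <- setdiff(resno, span)
  if (length(out))
    stop("mapped residue number(s) outside structure span: ",
         paste(head(out, 5), collapse = ", "))
  map <- data.frame(column = cols, resno = as.integer(resno),
                    disordered = structure$residues$disordered[
                      match(resno, structure$residues$number)])
  class(map) <- c("column_residue_map", "data.frame")
  map
}

#' Attach structure residue numbers and blades to a site table
#'
#' @param sites a \code{divergent_sites} table
#' @param map a \code{column_residue_map}
#' @param annotation a \code{\link{blade_annotation}} (optional)
#' @return \code{sites} with \code{resno}, \code{disordered} and (if an
#'   annotation is given) \code{blade} columns; unmapped columns get
#'   \code{NA} resno, sites outside every blade get \code{NA} blade
#' @export
map_sites_to_structure <- function(sites, map, annotation = NULL) {
  k <- match(sites$column, map$column)
  sites$resno <- map$resno[k]
  sites$disordered <- map$disordered[k]
  if (!is.null(annotation))
    sites$blade <- assign_blades(sites$resno, annotation)
  sites
}

assign_blades <- function(resno, annotation) {
  blade <- rep(NA_integer_, length(resno))
  for (r in seq_len(nrow(annotation))) {
    inside <- !is.na(resno) & resno >= annotation$start[r] &
      resno <= annotation$end[r]
    blade[inside] <- annotation$blade[r]
  }
  blade
}

#' Per-blade occupancy of mapped sites
#'
#' @param resno integer vector of mapped site residue numbers
#' @param annotation a \code{\link{blade_annotation}}
#' @return named integer vector: one count per blade plus
#'   \code{"unassigned"} (sites in loops outside every strand range);
#'   counts sum to \code{length(resno)}
#' @export
blade_count_profile <- function(resno, annotation) {
  if (is.data.frame(resno)) resno <- resno$resno
  nb <- max(annotation$blade)
  blade <- assign_blades(resno, annotation)
  counts <- tabulate(blade, nb)
  names(counts) <- paste0("blade", seq_len(nb))
  c(counts, unassigned = sum(is.na(blade)))
}

#' Permutation test for spatial clustering of mapped sites
#'
#' Null model: the same number of sites placed uniformly at random, without
#' replacement, among eligible residues. For
#' \code{statistic = "max_blade_count"} the eligible set is all residues
#' inside annotated strand ranges and the upper tail is used (clustering =
#' a blade holding many sites); for \code{"mean_pairwise_ca_distance"} it
#' is all resolved residues and the lower tail is used (clustering = small
#' distances). Disordered sites are counted in blade statistics but must be
#' excluded by the caller from the spatial statistic (they have no
#' coordinates; they are dropped with a message).
#'
#' When \code{mode = "auto"}, the null is enumerated exhaustively whenever
#' \code{choose(|eligible|, |sites|) <= 1e5} (p = proportion of subsets at
#' least as extreme); otherwise Monte-Carlo sampling with the add-one
#' correction p = (1 + #extreme) / (1 + n_permutations).
#'
#' @param sites mapped site residue numbers (integer vector, or a table
#'   with a \code{resno} column)
#' @param structure a \code{structure_model}
#' @param annotation a \code{\link{blade_annotation}}
#' @param statistic \code{"max_blade_count"} or
#'   \code{"mean_pairwise_ca_distance"}
#' @param n_permutations Monte-Carlo sample size
#' @param seed integer seed (the caller's RNG state is untouched)
#' @param eligible optional explicit eligible residue-number set
#' @param mode \code{"auto"}, \code{"exhaustive"} or \code{"montecarlo"}
#' @return a \code{clustering_test} list: \code{statistic}, \code{observed},
#'   \code{p_value}, \code{tail}, \code{mode}, \code{n_permutations},
#'   \code{n_sites}, \code{n_eligible}, \code{seed}
#' @export
clustering_test <- function(sites, structure, annotation,
                            statistic = c("max_blade_count",
                                          "mean_pairwise_ca_distance"),
                            n_permutations = 1000L, seed = 1L,
                            eligible = NULL,
                            mode = c("auto", "exhaustive", "montecarlo")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (is.data.frame(sites)) sites <- sites$resno
  sites <- sites[!is.na(sites)]

  if (statistic == "max_blade_count") {
    if (is.null(eligible))
      eligible <- intersect(structure_span(structure),
                            unlist(Map(seq.int, annotation$start,
                                       annotation$end)))
    stat <- function(r) max(tabulate(assign_blades(r, annotation),
                                     max(annotation$blade)))
    upper <- TRUE
  } else {
    xyz <- structure_coords(structure)
    resolved <- as.integer(rownames(xyz))
    drop <- setdiff(sites, resolved)
    if (length(drop)) {
      message(length(drop), " disordered/unresolved site(s) excluded from ",
              "the spatial statistic")
      sites <- intersect(sites, resolved)
    }
    if (is.null(eligible)) eligible <- resolved
    stat <- function(r) {
      p <- xyz[match(r, resolved), , drop = FALSE]
      mean(dist(p))
    }
    upper <- FALSE
  }
  k <- length(sites)
  if (k < 2) stop("need at least 2 mapped sites")
  if (any(!sites %in% eligible))
    stop("site residue(s) outside the eligible set")

  observed <- stat(sites)
  extreme <- if (upper) function(x) x >= observed - 1e-12 else
    function(x) x <= observed + 1e-12

  if (mode == "auto")
    mode <- if (choose(length(eligible), k) <= 1e5) "exhaustive" else
      "montecarlo"
  if (mode == "exhaustive") {
    subsets <- combn(eligible, k)
    null <- apply(subsets, 2, stat)
    p <- mean(extreme(null))
    n_perm <- NA_integer_
  } else {
    null <- with_seed(seed, replicate(n_permutations,
                                      stat(sample(eligible, k))))
    p <- (1 + sum(extreme(null))) / (1 + n_permutations)
    n_perm <- as.integer(n_permutations)
  }
  structure(list(statistic = statistic, observed = observed, p_value = p,
                 tail = if (upper) "upper" else "lower", mode = mode,
                 n_permutations = n_perm, n_sites = k,
                 n_eligible = length(eligible), seed = seed),
            class = "clustering_test")
}

#' @export
print.clustering_test <- function(x, ...) {
  cat(sprintf(
    "Permutation clustering test (%s, %s tail)\n  observed = %.4g, p = %.4g (%s%s; %d sites among %d eligible residues)\n",
    x$statistic, x$tail, x$observed, x$p_value, x$mode,
    if (!is.na(x$n_permutations))
      paste0(", ", x$n_permutations, " permutations") else "",
    x$n_sites, x$n_eligible))
  invisible(x)
}

#' Write the joined site/structure report set
#'
#' Writes the site table (TSV; disordered sites retained and flagged), the
#' molecular-viewer attribute file (disordered and unmapped sites omitted),
#' and a per-blade summary TSV.
#'
#' @param sites a \code{divergent_sites} table already passed through
#'   \code{\link{map_sites_to_structure}}
#' @param annotation a \code{\link{blade_annotation}}
#' @param dir output directory (created if missing)
#' @param header optional comment lines for every file
#' @return named character vector of the files written, invisibly
#' @export
report_divergence_map <- function(sites, annotation, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(sites = file.path(dir, "divergent_sites.tsv"),
             attributes = file.path(dir, "divergence_attributes.tsv"),
             blades = file.path(dir, "blade_summary.tsv"))
  write_site_table(sites, files["sites"], header)
  ok <- !is.na(sites$resno) & !sites$disordered
  write_attribute_map(data.frame(resno = sites$resno[ok],
                                 category = sites$category[ok]),
                      files["attributes"], header = header)
  prof <- blade_count_profile(sites$resno, annotation)
  write_tsv(data.frame(blade = names(prof), n_sites = as.integer(prof)),
            files["blades"], header)
  message(sprintf("wrote %d sites (%d on resolved residues), blade summary over %d blades",
                  nrow(sites), sum(ok), max(annotation$blade)))
  invisible(files)
}
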