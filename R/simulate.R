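# Synthetic paralog families with planted group-diagnostic sites, and a
# toy beta-propeller structure. These provide ground truth for end-to-end
# validation without any external download.
#
# Generator model: one ancestral sequence is duplicated into clade A and
# clade B; each of the k diagnostic sites carries a planted (a, b) residue
# pair satisfying the requested divergence mode; every lineage (species x
# clade, star topology) then accumulates independent neutral substitutions
# at non-diagnostic sites with per-site probability theta. With probability
# epsilon a diagnostic site has one criterion-species row corrupted,
# breaking within-group identity. Indel-free by design: the detection rule
# operates on columns, and gap handling is exercised by hand-built
# alignment fixtures.

#' Simulation parameters for synthetic paralog families
#'
#' Defaults emulate the study design: two paralog clades in three fission
#' yeast-like species, two of which form the conservation criterion, a
#' WD40-domain-sized sequence, ten planted diagnostic sites, a visible but
#' modest level of neutral variation, no within-group noise, and an
#' outgroup lineage.
#'
#' @param n_species number of species (>= 2)
#' @param species species labels
#' @param criterion_species subset of \code{species} used by the
#'   conservation criterion
#' @param length sequence length L
#' @param n_diagnostic number of planted diagnostic sites k (<= L)
#' @param mode divergence mode per site (recycled):
#'   \code{"blosum_negative"}, \code{"opposite_charge"} or \code{"both"}
#'   (pair must satisfy both clauses)
#' @param theta per-site, per-lineage neutral substitution probability
#' @param epsilon per-diagnostic-site probability of corrupting one
#'   criterion-species row
#' @param include_outgroup emit an outgroup lineage?
#' @param group_labels labels of the two paralog clades
#' @param seed integer seed; the generator is deterministic given the seed
#' @return a \code{simulation_params} list
#' @export
simulation_params <- function(n_species = 3,
                              species = paste0("sp", seq_len(n_species)),
                              criterion_species = species[seq_len(min(2, n_species))],
                              length = 400L, n_diagnostic = 10L,
                              mode = "both", theta = 0.05, epsilon = 0,
                              include_outgroup = TRUE,
                              group_labels = c("A", "B"), seed = 1L) {
  stopifnot(n_species >= 2, base::length(species) == n_species,
            all(criterion_species %in% species),
            n_diagnostic <= length, theta >= 0, theta < 1,
            epsilon >= 0, epsilon < 1,
            all(mode %in% c("both", "blosum_negative", "opposite_charge")))
  structure(list(n_species = n_species, species = species,
                 criterion_species = criterion_species, length = length,
                 n_diagnostic = as.integer(n_diagnostic),
                 mode = rep_len(mode, max(0, n_diagnostic)),
                 theta = theta, epsilon = epsilon,
                 include_outgroup = include_outgroup,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "simulation_params")
}

# ordered residue pairs (a != b) satisfying a divergence mode
diagnostic_pair_pool <- function(mode, matrix, h_positive = FALSE) {
  aa <- amino_acids()
  pairs <- expand.grid(a = aa, b = aa, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  neg <- sub_score(matrix, pairs$a, pairs$b) < 0
  opp <- residue_charge(pairs$a, h_positive) *
    residue_charge(pairs$b, h_positive) == -1L
  keep <- switch(mode,
                 blosum_negative = neg,
                 opposite_charge = opp,
                 both = neg & opp)
  pairs[keep, , drop = FALSE]
}

#' Simulate a pair of paralog clades with planted diagnostic sites
#'
#' @param params a \code{\link{simulation_params}}
#' @param matrix the \code{substitution_matrix} used to validate planted
#'   pairs (default packaged BLOSUM62)
#' @return a \code{synthetic_family} list: \code{sequences} (a
#'   \code{\link{protein_set}}: one row per clade x species, plus the
#'   outgroup), \code{truth} (data.frame \code{position},
#'   \code{residue_a}, \code{residue_b}, \code{mode}), \code{params}
#' @export
simulate_paralog_families <- function(params = simulation_params(),
                                      matrix = blosum62()) {
  with_seed(params$seed, {
    L <- params$length
    aa <- amino_acids()
    ancestor <- sample(aa, L, replace = TRUE)
    positions <- sort(sample.int(L, params$n_diagnostic))

    truth <- data.frame(position = integer(0), residue_a = character(0),
                        residue_b = character(0), mode = character(0))
    seq_b <- ancestor
    for (i in seq_along(positions)) {
      pool <- diagnostic_pair_pool(params$mode[i], matrix)
      if (!nrow(pool))
        stop("impossible mode/residue combination: ", params$mode[i])
      pick <- pool[sample.int(nrow(pool), 1), ]
      # clade A keeps the ancestral state at diagnostic sites; the site's
      # ancestral residue is drawn jointly with its clade-B replacement so
      # that the requested mode is always satisfiable
      ancestor[positions[i]] <- pick$a
      seq_b[positions[i]] <- pick$b
      truth <- rbind(truth, data.frame(position = positions[i],
                                       residue_a = pick$a,
                                       residue_b = pick$b,
                                       mode = params$mode[i]))
    }

    mutate_neutral <- function(s, free) {
      hit <- free[runif(length(free)) < params$theta]
      for (p in hit) s[p] <- sample(setdiff(aa, s[p]), 1)
      s
    }
    free <- setdiff(seq_len(L), positions)
    ids <- character(0); spc <- character(0); grp <- character(0)
    seqs <- list()
    for (g in 1:2) {
      base <- if (g == 1) ancestor else seq_b
      for (s in params$species) {
        seqs[[length(seqs) + 1]] <- mutate_neutral(base, free)
        ids <- c(ids, paste0(params$group_labels[g], "_", s))
        spc <- c(spc, s); grp <- c(grp, params$group_labels[g])
      }
    }
    if (params$include_outgroup) {
      seqs[[length(seqs) + 1]] <- mutate_neutral(ancestor, free)
      ids <- c(ids, "outgroup"); spc <- c(spc, NA); grp <- c(grp, "outgroup")
    }

    # within-group corruption at diagnostic sites
    crit_rows <- which(spc %in% params$criterion_species &
                         grp %in% params$group_labels)
    for (i in seq_along(positions)) {
      if (runif(1) < params$epsilon && length(crit_rows)) {
        r <- crit_rows[sample.int(length(crit_rows), 1)]
        p <- positions[i]
        seqs[[r]][p] <- sample(setdiff(aa, seqs[[r]][p]), 1)
      }
    }

    fam <- protein_set(ids, vapply(seqs, paste, "", collapse = ""),
                       species = spc, group = grp)
    structure(list(sequences = fam, truth = truth, params = params),
              class = "synthetic_family")
  })
}

#' Group specification matching a synthetic family
#'
#' @param family a \code{synthetic_family}
#' @return a \code{\link{group_spec}} with the family's clades, criterion
#'   species, and outgroup (if present)
#' @export
family_group_spec <- function(family) {
  p <- family$params
  seqs <- family$sequences
  members <- function(g) {
    rows <- seqs$group == g
    structure(seqs$id[rows], names = seqs$species[rows])
  }
  group_spec(group_a = list(label = p$group_labels[1],
                            members = members(p$group_labels[1])),
             group_b = list(label = p$group_labels[2],
                            members = members(p$group_labels[2])),
             outgroup_id = if (p$include_outgroup) "outgroup" else NULL,
             criterion_species = p$criterion_species)
}

#' Gap-free alignment of a synthetic family
#'
#' The generator is indel-free, so the family's sequences already form an
#' alignment column-for-column.
#'
#' @param family a \code{synthetic_family}
#' @return a \code{\link{protein_msa}}
#' @export
family_msa <- function(family) {
  protein_msa(structure(family$sequences$residues,
                        names = family$sequences$id))
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf(
    "synthetic_family: %d sequences of length %d, %d planted sites (theta=%g, epsilon=%g, seed=%d)\n",
    nrow(x$sequences), x$params$length, nrow(x$truth), x$params$theta,
    x$params$epsilon, x$params$seed))
  invisible(x)
}

#' Build a toy beta-propeller structure
#'
#' CA-only PDB-format text with blades laid out as well-separated spatial
#' clusters (inter-blade centroid distances at least ten times the
#' intra-blade spread), so spatial clustering of sites within one blade is
#' geometrically detectable. The layout is deterministic. Residues inside
#' \code{missing_spans} are omitted from the coordinate records, emulating
#' disordered regions.
#'
#' @param n_blades number of blades (default 7, the WD40 propeller)
#' @param residues_per_blade residues per blade
#' @param start_number author number of the first residue
#' @param missing_spans list of \code{c(first, last)} residue-number ranges
#'   to omit
#' @param chain chain identifier written to the records
#' @return list with \code{pdb} (character vector of PDB lines),
#'   \code{annotation} (a \code{\link{blade_annotation}}, one strand
#'   \code{"A"} per blade), and \code{span} (full residue-number range)
#' @export
make_toy_structure <- function(n_blades = 7L, residues_per_blade = 10L,
                               start_number = 301L, missing_spans = NULL,
                               chain = "A") {
  stopifnot(n_blades >= 1, residues_per_blade >= 1)
  n <- n_blades * residues_per_blade
  numbers <- seq.int(start_number, length.out = n)
  last <- start_number + n - 1L
  omit <- integer(0)
  for (sp in missing_spans) {
    if (sp[1] < start_number || sp[2] > last)
      stop("missing span outside residue range")
    omit <- c(omit, seq.int(sp[1], sp[2]))
  }
  blade_of <- rep(seq_len(n_blades), each = residues_per_blade)
  within <- sequence(rep(residues_per_blade, n_blades)) - 1L
  # blade centroids on a circle of radius 50 A; residues on a tight local
  # helix of ~0.5 A pitch (spread << centroid separation)
  ang <- 2 * pi * (blade_of - 1) / n_blades
  x <- 50 * cos(ang) + 0.5 * cos(within * 1.7)
  y <- 50 * sin(ang) + 0.5 * sin(within * 1.7)
  z <- 0.3 * within
  aa3 <- names(AA3TO1)[(numbers - start_number) %% 20 + 1]
  keep <- !numbers %in% omit
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(sum(keep)), aa3[keep], chain, numbers[keep],
    x[keep], y[keep], z[keep])
  ann <- blade_annotation(
    blade = seq_len(n_blades), strand = "A",
    start = start_number + (seq_len(n_blades) - 1L) * residues_per_blade,
    end = start_number + seq_len(n_blades) * residues_per_blade - 1L)
  list(pdb = c(lines, "END"), annotation = ann,
       span = c(start_number, last), chain = chain)
}
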