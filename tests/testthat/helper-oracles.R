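# Independent oracles used across the suite. These deliberately share no
# code with the package internals.

# Best global alignment score by explicit enumeration of every monotone
# alignment path (no dynamic programming, no memoization). Gap cost is
# charged incrementally: opening a run costs `go`, extending it `ge`.
oracle_align_score <- function(s1, s2, score_fn, go, ge) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  best <- -Inf
  rec <- function(i, j, acc, last) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, acc)
      return(invisible(NULL))
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, acc + score_fn(a[i], b[j]), "M")
    if (i <= length(a))
      rec(i + 1, j, acc - if (last == "X") ge else go, "X")
    if (j <= length(b))
      rec(i, j + 1, acc - if (last == "Y") ge else go, "Y")
  }
  rec(1, 1, 0, "M")
  best
}

# Charge lookup written out independently of residue_charge()
oracle_charge <- function(aa) {
  tab <- c(D = -1, E = -1, K = 1, R = 1)
  ifelse(aa %in% names(tab), tab[aa], 0)
}

# Brute-force divergent-column scan: msa_mat is a character matrix,
# rows_a / rows_b the criterion-row names of the two groups, score_fn a
# pair score lookup. Returns the data.frame of qualifying columns.
oracle_divergent_columns <- function(msa_mat, rows_a, rows_b, score_fn) {
  found <- data.frame(column = integer(0), residue_a = character(0),
                      residue_b = character(0))
  for (j in seq_len(ncol(msa_mat))) {
    va <- msa_mat[rows_a, j]
    vb <- msa_mat[rows_b, j]
    if (any(c(va, vb) %in% c("-", "X"))) next
    if (!all(va == va[1])) next
    if (!all(vb == vb[1])) next
    ra <- va[1]; rb <- vb[1]
    if (ra == rb) next
    significant <- score_fn(ra, rb) < 0 ||
      (oracle_charge(ra) > 0 && oracle_charge(rb) < 0) ||
      (oracle_charge(ra) < 0 && oracle_charge(rb) > 0)
    if (!significant) next
    found <- rbind(found, data.frame(column = j, residue_a = ra,
                                     residue_b = rb))
  }
  found
}

# Biostrings' copy of BLOSUM62, the independent score oracle (falls back
# to the packaged file only if Biostrings is unavailable)
oracle_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- if (requireNamespace("Biostrings", quietly = TRUE)) {
        e <- new.env()
        data("BLOSUM62", package = "Biostrings", envir = e)
        e$BLOSUM62
      } else unclass(blosum62())
    }
    cache
  }
})

# random toy MSA generator for the divergence property tests: columns are
# conserved-within-group with probability p_cons, otherwise iid letters;
# a sprinkling of gap columns exercises the skip rule
random_toy_msa <- function(n_per_group = 3, ncol = 50, p_cons = 0.3,
                           p_gap = 0.05) {
  aa <- amino_acids()
  ids <- c(paste0("a", seq_len(n_per_group)), paste0("b", seq_len(n_per_group)))
  m <- matrix("", 2 * n_per_group, ncol, dimnames = list(ids, NULL))
  for (j in seq_len(ncol)) {
    if (runif(1) < p_cons) {
      m[seq_len(n_per_group), j] <- sample(aa, 1)
      m[n_per_group + seq_len(n_per_group), j] <- sample(aa, 1)
    } else {
      m[, j] <- sample(aa, 2 * n_per_group, replace = TRUE)
    }
    gap <- runif(2 * n_per_group) < p_gap
    m[gap, j] <- "-"
  }
  protein_msa(apply(m, 1, paste, collapse = ""))
}

toy_group_spec <- function(n_per_group = 3, outgroup_id = NULL) {
  sp <- paste0("sp", seq_len(n_per_group))
  group_spec(
    group_a = list(label = "A",
                   members = structure(paste0("a", seq_len(n_per_group)),
                                       names = sp)),
    group_b = list(label = "B",
                   members = structure(paste0("b", seq_len(n_per_group)),
                                       names = sp)),
    outgroup_id = outgroup_id,
    criterion_species = sp)
}

# toy structure written to a temp file and read back as a model
toy_structure_model <- function(...) {
  toy <- make_toy_structure(...)
  f <- tempfile(fileext = ".pdb")
  writeLines(toy$pdb, f)
  model <- read_structure(f, toy$chain, toy$span)
  unlink(f)
  list(model = model, annotation = toy$annotation, span = toy$span)
}
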