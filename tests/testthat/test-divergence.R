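B <- blosum62()

test_that("charge table: D/E negative, K/R positive, others neutral", {
  expect_equal(residue_charge(c("D", "E")), c(-1L, -1L))
  expect_equal(residue_charge(c("K", "R")), c(1L, 1L))
  expect_equal(residue_charge(c("A", "H", "X", "S")), rep(0L, 4))
  expect_equal(residue_charge("H", h_positive = TRUE), 1L)
  expect_error(residue_charge("Z"), "invalid residue")
})

test_that("significance rule fires on negative score or opposite charge", {
  r <- is_significant_pair("D", "K", B)
  expect_true(r$significant)
  expect_setequal(r$reasons, c("blosum_negative", "opposite_charge"))

  r <- is_significant_pair("E", "K", B)  # BLOSUM62(E,K) = +1
  expect_true(r$significant)
  expect_equal(r$reasons, "opposite_charge")

  r <- is_significant_pair("S", "T", B)  # +1, both neutral
  expect_false(r$significant)
  expect_equal(r$reasons, character(0))

  expect_error(is_significant_pair("A", "A", B), "identical")
})

test_that("significance is symmetric in its arguments", {
  aa <- amino_acids()
  set.seed(5)
  for (k in 1:100) {
    p <- sample(aa, 2)
    a <- is_significant_pair(p[1], p[2], B)
    b <- is_significant_pair(p[2], p[1], B)
    expect_equal(a$significant, b$significant)
    expect_setequal(a$reasons, b$reasons)
  }
})

test_that("divergent-site scan applies all four conditions", {
  msa <- protein_msa(c(a1 = "ADKAC", a2 = "ADKAC",
                       b1 = "AKKAC", b2 = "AKKAC"))
  spec <- toy_group_spec(2)
  sites <- find_divergent_sites(msa, spec, B)
  expect_equal(sites$column, 2)
  expect_equal(sites$residue_a, "D")
  expect_equal(sites$residue_b, "K")
  expect_equal(sites$blosum_score, -1L)
  expect_true(sites$blosum_negative & sites$opposite_charge)

  # within-group identity failure: A = (D, E)
  msa2 <- protein_msa(c(a1 = "ADKAC", a2 = "AEKAC",
                        b1 = "AKKAC", b2 = "AKKAC"))
  expect_equal(nrow(find_divergent_sites(msa2, spec, B)), 0)

  # gap or X in a criterion row disqualifies the column
  msa3 <- protein_msa(c(a1 = "AD-AC", a2 = "ADKAC",
                        b1 = "AKXAC", b2 = "AKKAC"))
  got <- find_divergent_sites(msa3, spec, B)
  expect_equal(got$column, 2)

  # identical groups yield nothing
  msa4 <- protein_msa(c(a1 = "ADKAC", a2 = "ADKAC",
                        b1 = "ADKAC", b2 = "ADKAC"))
  expect_equal(nrow(find_divergent_sites(msa4, spec, B)), 0)

  expect_error(find_divergent_sites(msa, toy_group_spec(3), B), "absent")
})

test_that("non-criterion rows never change the reported sites", {
  set.seed(8)
  for (k in 1:20) {
    msa <- random_toy_msa(n_per_group = 2, ncol = 30)
    spec <- toy_group_spec(2)
    base <- find_divergent_sites(msa, spec, B)
    extra <- protein_msa(c(msa_strings(msa),
                           zz = paste(sample(c(amino_acids(), "-"), 30,
                                             replace = TRUE),
                                      collapse = "")))
    expect_equal(find_divergent_sites(extra, spec, B), base)
  }
})

test_that("scan agrees with the brute-force oracle on random alignments", {
  ref <- oracle_blosum62()
  sc <- function(x, y) unname(ref[x, y])
  set.seed(21)
  n_hits <- 0
  for (k in 1:200) {
    msa <- random_toy_msa()
    spec <- toy_group_spec(3)
    mine <- find_divergent_sites(msa, spec, B)
    oracle <- oracle_divergent_columns(unclass(msa), paste0("a", 1:3),
                                       paste0("b", 1:3), sc)
    expect_equal(mine$column, oracle$column, info = paste("trial", k))
    expect_equal(mine$residue_a, oracle$residue_a, info = paste("trial", k))
    expect_equal(mine$residue_b, oracle$residue_b, info = paste("trial", k))
    n_hits <- n_hits + nrow(oracle)
  }
  expect_gt(n_hits, 100)  # the comparison actually exercised hits
})

test_that("outgroup classification follows the color legend", {
  msa <- protein_msa(c(a1 = "ADKRC", a2 = "ADKRC",
                       b1 = "AKDEC", b2 = "AKDEC",
                       out = "AD-SC"))
  spec <- toy_group_spec(2, outgroup_id = "out")
  sites <- find_divergent_sites(msa, spec, B)
  expect_equal(sites$column, c(2, 3, 4))
  sites <- classify_vs_outgroup(sites, msa, "out")
  expect_equal(sites$category,
               c("A_matches_outgroup", "unclassified", "both_differ"))
  # B matches outgroup
  msa2 <- protein_msa(c(a1 = "ADKAC", a2 = "ADKAC",
                        b1 = "AKKAC", b2 = "AKKAC", out = "AKKAC"))
  s2 <- classify_vs_outgroup(find_divergent_sites(msa2, spec, B), msa2, "out")
  expect_equal(s2$category, "B_matches_outgroup")
  # exactly one category per reported site
  expect_true(all(!is.na(s2$category)))
  expect_error(classify_vs_outgroup(s2, msa2, "nope"), "absent")
})
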