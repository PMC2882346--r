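B <- blosum62()

test_that("no mutation channels means identical sequences", {
  fam <- simulate_paralog_families(
    simulation_params(length = 50L, n_diagnostic = 0L, theta = 0,
                      epsilon = 0, seed = 3))
  expect_equal(length(unique(fam$sequences$residues)), 1)
  expect_equal(nrow(fam$truth), 0)
})

test_that("the generator is deterministic given the seed", {
  p <- simulation_params(length = 80L, theta = 0.1, epsilon = 0.2, seed = 42)
  f1 <- simulate_paralog_families(p)
  f2 <- simulate_paralog_families(p)
  expect_identical(f1, f2)
  f3 <- simulate_paralog_families(
    simulation_params(length = 80L, theta = 0.1, epsilon = 0.2, seed = 43))
  expect_false(identical(f1$sequences$residues, f3$sequences$residues))
})

test_that("noise-free planted sites are recovered exactly", {
  fam <- simulate_paralog_families(
    simulation_params(length = 120L, n_diagnostic = 10L, theta = 0,
                      epsilon = 0, seed = 5))
  sites <- find_divergent_sites(family_msa(fam), family_group_spec(fam), B)
  expect_equal(sites$column, fam$truth$position)
  expect_equal(sites$residue_a, fam$truth$residue_a)
  expect_equal(sites$residue_b, fam$truth$residue_b)
})

test_that("every emitted diagnostic pair satisfies the significance rule", {
  for (mode in c("both", "blosum_negative", "opposite_charge")) {
    fam <- simulate_paralog_families(
      simulation_params(length = 60L, n_diagnostic = 8L, mode = mode,
                        theta = 0.05, seed = 9))
    for (i in seq_len(nrow(fam$truth))) {
      r <- is_significant_pair(fam$truth$residue_a[i],
                               fam$truth$residue_b[i], B)
      expect_true(r$significant)
      if (mode != "both")
        expect_true(mode %in% r$reasons)
      else
        expect_setequal(r$reasons, c("blosum_negative", "opposite_charge"))
    }
  }
})

test_that("false positives under neutral noise still satisfy the rule", {
  ref <- oracle_blosum62()
  sc <- function(x, y) unname(ref[x, y])
  fam <- simulate_paralog_families(
    simulation_params(length = 300L, theta = 0.1, epsilon = 0, seed = 13))
  msa <- family_msa(fam)
  spec <- family_group_spec(fam)
  sites <- find_divergent_sites(msa, spec, B)
  # recall 1.0 at epsilon = 0
  expect_true(all(fam$truth$position %in% sites$column))
  # any extra site must itself pass the brute-force checker
  oracle <- oracle_divergent_columns(
    unclass(msa), spec$group_a$members[spec$criterion_species],
    spec$group_b$members[spec$criterion_species], sc)
  expect_equal(sites$column, oracle$column)
})

test_that("recall is non-increasing in the corruption rate", {
  recall_at <- function(eps, seeds = 1:15) {
    mean(vapply(seeds, function(s) {
      fam <- simulate_paralog_families(
        simulation_params(length = 120L, theta = 0, epsilon = eps, seed = s))
      sites <- find_divergent_sites(family_msa(fam), family_group_spec(fam), B)
      mean(fam$truth$position %in% sites$column)
    }, 0))
  }
  r <- vapply(c(0, 0.15, 0.4), recall_at, 0)
  expect_equal(r[1], 1)
  expect_true(all(diff(r) <= 0))
})

test_that("toy structure geometry separates blades and round-trips", {
  toy <- make_toy_structure(7, 10, 301)
  expect_equal(length(toy$pdb), 71)  # 70 CA records + END
  res <- toy_structure_model(7, 10, 301)
  expect_equal(sum(res$model$residues$disordered), 0)

  xyz <- structure_coords(res$model)
  blade_of <- rep(1:7, each = 10)
  centroids <- apply(xyz, 2, function(v) tapply(v, blade_of, mean))
  intra <- max(vapply(1:7, function(b)
    max(dist(xyz[blade_of == b, ])), 0))
  inter <- min(dist(centroids))
  expect_gt(inter, 10 * intra / 2)  # centroid separation >> blade spread

  # sites planted in one blade are tighter than random sets
  b3 <- which(blade_of == 3)
  obs <- mean(dist(xyz[b3, ]))
  set.seed(31)
  rand <- replicate(50, mean(dist(xyz[sample(70, 10), ])))
  expect_true(all(obs < rand))

  expect_error(make_toy_structure(missing_spans = list(c(1, 5))),
               "outside residue range")
})
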