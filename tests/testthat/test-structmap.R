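test_that("alignment columns map to reference numbering, skipping gaps", {
  res <- toy_structure_model(n_blades = 1, residues_per_blade = 4,
                             start_number = 282)
  msa <- protein_msa(c(ref = "ACD", other = "ACD"))
  map <- map_alignment_to_structure(msa, "ref", 282, res$model)
  expect_equal(map$column, 1:3)
  expect_equal(map$resno, 282:284)

  msa2 <- protein_msa(c(ref = "A-CD", other = "AACD"))
  map2 <- map_alignment_to_structure(msa2, "ref", 282, res$model)
  expect_equal(map2$column, c(1, 3, 4))
  expect_equal(map2$resno, 282:284)
  # injective and order-preserving
  expect_false(anyDuplicated(map2$resno) > 0)
  expect_true(all(diff(map2$resno) > 0) && all(diff(map2$column) > 0))

  expect_error(map_alignment_to_structure(msa2, "zz", 282, res$model),
               "absent")
  long <- protein_msa(c(ref = "ACDEFG", o = "ACDEFG"))
  expect_error(map_alignment_to_structure(long, "ref", 282, res$model),
               "outside structure span")
})

test_that("disordered flags propagate through the column map", {
  res <- toy_structure_model(n_blades = 1, residues_per_blade = 4,
                             start_number = 282,
                             missing_spans = list(c(283, 283)))
  msa <- protein_msa(c(ref = "ACD", o = "ACD"))
  map <- map_alignment_to_structure(msa, "ref", 282, res$model)
  expect_equal(map$disordered, c(FALSE, TRUE, FALSE))
})

test_that("blade counts partition the sites", {
  res <- toy_structure_model()
  ann <- res$annotation
  b3 <- seq(ann$start[3], ann$end[3])
  prof <- blade_count_profile(b3[1:4], ann)
  expect_equal(unname(prof), c(0, 0, 4, 0, 0, 0, 0, 0))

  prof2 <- blade_count_profile(c(b3[1], 9999L), ann)
  expect_equal(unname(prof2["unassigned"]), 1L)
  expect_equal(sum(prof2), 2)

  expect_equal(sum(blade_count_profile(integer(0), ann)), 0)
  set.seed(2)
  sites <- sample(seq(res$span[1], res$span[2]), 12)
  expect_equal(sum(blade_count_profile(sites, ann)), 12)
})

test_that("exhaustive clustering p-value equals the enumerated value", {
  res <- toy_structure_model(n_blades = 2, residues_per_blade = 3,
                             start_number = 1)
  ct <- clustering_test(c(1, 2), res$model, res$annotation,
                        "max_blade_count", mode = "exhaustive")
  expect_equal(ct$p_value, 6 / 15)  # C(3,2)*2 same-blade pairs of C(6,2)
  expect_equal(ct$observed, 2)

  # degenerate null: every draw is as extreme as the observation
  one <- toy_structure_model(n_blades = 1, residues_per_blade = 5,
                             start_number = 1)
  ct1 <- clustering_test(c(1, 2), one$model, one$annotation,
                         "max_blade_count", mode = "exhaustive")
  expect_equal(ct1$p_value, 1)
})

test_that("Monte-Carlo p-values converge to the exhaustive value", {
  res <- toy_structure_model(n_blades = 2, residues_per_blade = 4,
                             start_number = 1)
  sites <- c(1, 2, 3)
  ex <- clustering_test(sites, res$model, res$annotation, "max_blade_count",
                        mode = "exhaustive")
  B <- 4000
  mc <- clustering_test(sites, res$model, res$annotation, "max_blade_count",
                        n_permutations = B, seed = 9, mode = "montecarlo")
  se <- sqrt(ex$p_value * (1 - ex$p_value) / B)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 1 / (B + 1))

  exd <- clustering_test(sites, res$model, res$annotation,
                         "mean_pairwise_ca_distance", mode = "exhaustive")
  mcd <- clustering_test(sites, res$model, res$annotation,
                         "mean_pairwise_ca_distance",
                         n_permutations = B, seed = 9, mode = "montecarlo")
  sed <- sqrt(exd$p_value * (1 - exd$p_value) / B)
  expect_lt(abs(mcd$p_value - exd$p_value), 3 * sed + 1 / (B + 1))
})

test_that("identical seeds give identical results; RNG state is untouched", {
  res <- toy_structure_model()
  sites <- seq(res$annotation$start[3], res$annotation$end[3])
  set.seed(123); before <- runif(1)
  a <- clustering_test(sites, res$model, res$annotation, "max_blade_count",
                       n_permutations = 500, seed = 77, mode = "montecarlo")
  b <- clustering_test(sites, res$model, res$annotation, "max_blade_count",
                       n_permutations = 500, seed = 77, mode = "montecarlo")
  expect_identical(a, b)
  set.seed(123)
  expect_identical(before, runif(1))

  expect_error(clustering_test(sites[1], res$model, res$annotation),
               "at least 2")
  expect_error(clustering_test(sites, res$model, res$annotation,
                               n_permutations = 0), ">= 1")
})

test_that("disordered sites are excluded from the spatial statistic only", {
  res <- toy_structure_model(missing_spans = list(c(321, 322)))
  ann <- res$annotation
  sites <- seq(ann$start[3], ann$end[3])  # includes the 2 disordered ones
  prof <- blade_count_profile(sites, ann)
  expect_equal(unname(prof["blade3"]), 10L)
  expect_message(
    ct <- clustering_test(sites, res$model, ann,
                          "mean_pairwise_ca_distance",
                          n_permutations = 200, seed = 4,
                          mode = "montecarlo"),
    "excluded")
  expect_equal(ct$n_sites, 8)
})

test_that("report files serialize mapped sites consistently", {
  res <- toy_structure_model(missing_spans = list(c(311, 311)))
  msa <- protein_msa(c(a1 = "ADKAC", a2 = "ADKAC",
                       b1 = "AKKAC", b2 = "AKKAC", out = "ADKAC"))
  spec <- toy_group_spec(2, outgroup_id = "out")
  sites <- classify_vs_outgroup(find_divergent_sites(msa, spec), msa, "out")
  map <- map_alignment_to_structure(msa, "out", 310, res$model)
  sites <- map_sites_to_structure(sites, map, res$annotation)
  expect_equal(sites$resno, 311L)
  expect_true(sites$disordered)

  dir <- withr::local_tempdir()
  files <- suppressMessages(report_divergence_map(sites, res$annotation, dir))
  tab <- read.table(files["sites"], sep = "\t", header = TRUE)
  expect_equal(tab$resno, 311L)
  expect_true(tab$disordered)
  # disordered site kept in the table but omitted from the attribute file
  expect_equal(length(readLines(files["attributes"])), 1)
  blades <- read.table(files["blades"], sep = "\t", header = TRUE)
  expect_equal(sum(blades$n_sites), 1)  # counted, flagged, in blade 2
  expect_equal(blades$n_sites[blades$blade == "blade2"], 1L)

  # empty site set still writes header-only outputs
  none <- sites[0, ]
  files0 <- suppressMessages(report_divergence_map(none, res$annotation, dir))
  expect_equal(sum(read.table(files0["blades"], sep = "\t",
                              header = TRUE)$n_sites), 0)
})
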