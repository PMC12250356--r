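test_that("kimura2p matches the closed form, limits, and error cases", {
  expect_equal(kimura2p(0, 0), 0)
  expect_equal(kimura2p(0.1, 0.05),
               -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_equal(round(kimura2p(0.1, 0.05), 4), 0.1702)
  expect_error(kimura2p(0.5, 0), "saturation")
  expect_error(kimura2p(0, 0.5), "saturation")
  expect_error(kimura2p(-0.1, 0), "non-negative")
  # monotone increasing in p and q on the domain
  expect_true(all(diff(kimura2p(seq(0, 0.2, by = 0.01), 0.05)) > 0))
  expect_true(all(diff(kimura2p(0.05, seq(0, 0.2, by = 0.01))) > 0))
})

test_that("kimura2p agrees with K ~ p + q at small divergence", {
  set.seed(201)
  p <- runif(50, 0, 0.008)
  q <- pmin(runif(50, 0, 0.008), 0.01 - p)
  k <- kimura2p(p, q)
  rel_err <- abs(k - (p + q)) / (p + q)
  expect_true(all(rel_err < 0.02))
})

test_that("map_reads recovers pure-signal, null, and planted copy-ratio libraries", {
  set.seed(202)
  cons <- rand_dna(28)
  # pure concatemer library
  pure <- Biostrings::DNAStringSet(vapply(1:40, function(i) {
    off <- sample(28, 1)
    substr(strrep(cons, 7), off, off + 149)
  }, character(1)))
  res <- map_reads(pure, c(satA = cons, satB = rand_dna(28)))
  expect_equal(res$abundance[res$sat_name == "satA"], 1.0)
  expect_equal(res$abundance[res$sat_name == "satB"], 0)
  expect_equal(res$mapped_reads[res$sat_name == "satA"], 40L)
  expect_equal(res$mean_divergence[res$sat_name == "satA"], 0)
  # uniform random reads: no satellite signal
  nullreads <- Biostrings::DNAStringSet(replicate(150, rand_dna(150)))
  resn <- map_reads(nullreads, c(satA = cons))
  expect_equal(resn$abundance, 0)
  # planted 2:1 copy ratio, equal rul
  specs <- list(
    sat_family_spec("A", rul = 28, array_copies_per_genome = 200,
                    sex_bias = c(lib = 1)),
    sat_family_spec("B", rul = 28, array_copies_per_genome = 100,
                    sex_bias = c(lib = 1)))
  sim <- simulate_sat_reads(specs, n_reads_per_library = 1200, seed = 11,
                            background_bp = 20000)
  r <- map_reads(sim$reads$lib,
                 setNames(unlist(sim$truth$families),
                          names(sim$truth$families)))
  ratio <- r$abundance[r$sat_name == "A"] / r$abundance[r$sat_name == "B"]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("map_reads assigns each read at most once and is shuffle-invariant", {
  set.seed(203)
  specs <- list(
    sat_family_spec("A", rul = 25, array_copies_per_genome = 120,
                    sex_bias = c(lib = 1)),
    sat_family_spec("B", rul = 40, array_copies_per_genome = 60,
                    sex_bias = c(lib = 1)))
  sim <- simulate_sat_reads(specs, n_reads_per_library = 400, seed = 12,
                            background_bp = 10000)
  catalog <- setNames(unlist(sim$truth$families), names(sim$truth$families))
  r1 <- map_reads(sim$reads$lib, catalog)
  expect_lte(sum(r1$aligned_bp), r1$analyzed_bp[1])
  expect_lte(sum(r1$mapped_reads), length(sim$reads$lib))
  shuffled <- sim$reads$lib[sample(length(sim$reads$lib))]
  r2 <- map_reads(shuffled, catalog)
  expect_equal(r1[order(r1$sat_name), -1], r2[order(r2$sat_name), -1],
               ignore_attr = TRUE)
  # reproducible subsampling
  r3 <- map_reads(sim$reads$lib, catalog, subsample = 200, seed = 99)
  r4 <- map_reads(sim$reads$lib, catalog, subsample = 200, seed = 99)
  expect_identical(r3, r4)
  expect_warning(map_reads(sim$reads$lib, catalog, subsample = 10000),
                 "subsample")
  expect_error(map_reads(Biostrings::DNAStringSet(), catalog), "empty")
})

test_that("sex_ratio computes ratios, sentinels, and candidate flags", {
  rm <- data.frame(sat_name = c("s1", "s2", "s3"),
                   abundance = c(0.002, 0.001, 0.003))
  rf <- data.frame(sat_name = c("s1", "s2", "s3"),
                   abundance = c(0.002, 0.0005, 0))
  sr <- sex_ratio(rm, rf, candidate_threshold = 1.5)
  expect_equal(sr$ratio[sr$sat_name == "s1"], 1.0)
  expect_false(sr$candidate[sr$sat_name == "s1"])
  expect_equal(sr$ratio[sr$sat_name == "s2"], 2.0)
  expect_true(sr$candidate[sr$sat_name == "s2"])
  expect_equal(sr$ratio[sr$sat_name == "s3"], Inf)
  # missing satDNA on one side treated as zero with a warning
  expect_warning(sr2 <- sex_ratio(rm, rf[1:2, ]), "missing")
  expect_equal(sr2$abundance_female[sr2$sat_name == "s3"], 0)
})

test_that("sex_ratio ranks a planted Y-accumulated family on top", {
  specs <- list(
    sat_family_spec("auto1", rul = 30, array_copies_per_genome = 100,
                    sex_bias = c(male = 1, female = 1)),
    sat_family_spec("ybias", rul = 30, array_copies_per_genome = 100,
                    sex_bias = c(male = 3, female = 1)),
    sat_family_spec("auto2", rul = 45, array_copies_per_genome = 80,
                    sex_bias = c(male = 1, female = 1)))
  sim <- simulate_sat_reads(specs, n_reads_per_library = 1200, seed = 13,
                            background_bp = 25000)
  catalog <- setNames(unlist(sim$truth$families), names(sim$truth$families))
  rm <- map_reads(sim$reads$male, catalog)
  rf <- map_reads(sim$reads$female, catalog)
  sr <- sex_ratio(rm, rf)
  expect_equal(sr$sat_name[1], "ybias")
  expect_true(sr$candidate[1])
})

test_that("paired_catalog_test matches the t formula and handles degeneracy", {
  same <- c(0.1, 0.2, 0.3)
  r <- paired_catalog_test(same, same)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  r2 <- paired_catalog_test(c(2, 4, 6), c(1, 2, 3))  # d = (1, 2, 3)
  expect_equal(r2$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r2$df, 2L)
  # agreement with the closed form 2-sided p
  expect_equal(r2$p_value, 2 * pt(2 * sqrt(3), 2, lower.tail = FALSE))
  r3 <- paired_catalog_test(c(1, 2, 3), c(0, 1, 2))  # constant nonzero d
  expect_equal(r3$t, Inf)
  expect_equal(r3$p_value, 0)
  expect_error(paired_catalog_test(1, 2), "n >= 2")
})
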