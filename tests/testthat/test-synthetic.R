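test_that("sat_family_spec and genotype_sim_spec validate their invariants", {
  expect_error(sat_family_spec("f", rul = 5), "rul")
  expect_error(sat_family_spec("f", rul = 20, mutation_rate = 0.5))
  expect_error(sat_family_spec("f", rul = 20, sex_bias = c(m = -1)),
               "positive")
  expect_error(sat_family_spec("f", rul = 20, sex_bias = c(m = 1),
                               exclusive_haplotypes = c(other = 2)),
               "library")
  expect_error(genotype_sim_spec(10, 2, 2, n_planted_xy = 6,
                                 n_planted_zw = 6))
  expect_error(genotype_sim_spec(10, 2, 2, het_prob = 2))
})

test_that("simulate_sat_reads is deterministic and respects its contract", {
  spec <- sat_family_spec("fam", rul = 28, n_variants = 2,
                          mutation_rate = 0.05,
                          array_copies_per_genome = 100,
                          sex_bias = c(male = 2, female = 1))
  s1 <- simulate_sat_reads(spec, n_reads_per_library = 300, seed = 7,
                           background_bp = 10000)
  s2 <- simulate_sat_reads(spec, n_reads_per_library = 300, seed = 7,
                           background_bp = 10000)
  expect_identical(lapply(s1$reads, as.character),
                   lapply(s2$reads, as.character))
  expect_identical(s1$truth$haplotypes, s2$truth$haplotypes)
  expect_true(all(Biostrings::width(s1$reads$male) == 150))
  expect_equal(length(s1$reads$male), 300L)
  # sex bias realized in copy counts
  cc <- s1$truth$copy_counts
  expect_equal(unname(cc[, "male"] / cc[, "female"]), rep(2, nrow(cc)))
  expect_error(simulate_sat_reads(spec, n_reads_per_library = 0),
               "positive")
  expect_warning(simulate_sat_reads(spec, read_length = 40,
                                    n_reads_per_library = 50,
                                    background_bp = 5000),
                 "twice the repeat unit")
})

test_that("zero-mutation single-variant reads yield only the consensus monomer", {
  spec <- sat_family_spec("pure", rul = 30, n_variants = 1,
                          mutation_rate = 0,
                          array_copies_per_genome = 200,
                          sex_bias = c(lib = 1))
  sim <- simulate_sat_reads(spec, n_reads_per_library = 300, seed = 9,
                            background_bp = 0)
  mon <- extract_monomers(sim$reads$lib, sim$truth$families$pure)
  expect_gt(nrow(mon), 250)
  expect_true(all(mon$sequence == sim$truth$families$pure))
})

test_that("exclusive haplotypes appear only in their library, by construction", {
  spec <- sat_family_spec("fam", rul = 28, n_variants = 3,
                          mutation_rate = 0.04,
                          array_copies_per_genome = 90,
                          sex_bias = c(karF_male = 1, karF_female = 1),
                          exclusive_haplotypes = c(karF_male = 5))
  sim <- simulate_sat_reads(spec, n_reads_per_library = 100, seed = 10,
                            background_bp = 5000)
  truth <- sim$truth$haplotypes
  cc <- sim$truth$copy_counts
  excl <- truth$haplotype_id[!is.na(truth$exclusive_to) &
                               truth$exclusive_to == "karF_male"]
  expect_length(excl, 5)
  expect_true(all(cc[excl, "karF_male"] > 0))
  expect_true(all(cc[excl, "karF_female"] == 0))
  # realized haplotype sequences are distinct
  expect_equal(anyDuplicated(truth$sequence), 0L)
})

test_that("a 28 bp repeat in 150 bp reads gives >= 4 complete copies per satellite read", {
  spec <- sat_family_spec("fam", rul = 28, n_variants = 1,
                          mutation_rate = 0,
                          array_copies_per_genome = 300,
                          sex_bias = c(lib = 1))
  sim <- simulate_sat_reads(spec, read_length = 150,
                            n_reads_per_library = 200, seed = 11,
                            background_bp = 0)
  cons <- sim$truth$families$fam
  # direct count of complete copies per read over both strands
  n_copies <- vapply(as.character(sim$reads$lib), function(r) {
    max(count_full_copies(r, cons), count_full_copies(rc(r), cons))
  }, numeric(1))
  expect_gte(mean(n_copies), 4)
  # 150 = 5*28 + 10, so each read holds 4 or 5 complete copies
  expect_true(all(n_copies >= 4))
})

test_that("simulate_genotypes plants patterns and obeys het_prob edge cases", {
  spec <- genotype_sim_spec(300, 4, 4, het_prob = 0.5, n_planted_xy = 3,
                            n_planted_zw = 2, missing_rate = 0, seed = 12)
  g <- simulate_genotypes(spec)
  expect_equal(dim(g$matrix), c(300L, 8L))
  males <- names(g$sexmap)[g$sexmap == "M"]
  females <- names(g$sexmap)[g$sexmap == "F"]
  for (l in g$truth$xy_loci) {
    expect_true(all(g$matrix[l, males] == 2))
    expect_true(all(g$matrix[l, females] %in% c(0, 1)))
  }
  for (l in g$truth$zw_loci) {
    expect_true(all(g$matrix[l, females] == 2))
    expect_true(all(g$matrix[l, males] %in% c(0, 1)))
  }
  # scan recovers the planted set (possibly plus chance hits)
  expect_true(all(g$truth$xy_loci %in% scan_xy(g$matrix, g$sexmap)))
  expect_true(all(g$truth$zw_loci %in% scan_zw(g$matrix, g$sexmap)))
  # het_prob 0 and no planted loci -> no heterozygous calls at all
  g0 <- simulate_genotypes(genotype_sim_spec(100, 3, 3, het_prob = 0,
                                             seed = 13))
  expect_equal(sum(g0$matrix == 2), 0L)
  # missingness hits null loci only
  gm <- simulate_genotypes(genotype_sim_spec(200, 3, 3, het_prob = 0.4,
                                             n_planted_xy = 4,
                                             missing_rate = 0.3, seed = 14))
  expect_gt(sum(is.na(gm$matrix)), 0)
  expect_true(all(!is.na(gm$matrix[gm$truth$xy_loci, ])))
})

test_that("null chance hits at L=64, 3M/3F, h=0.5 average about one per matrix", {
  set.seed(403)
  reps <- 2000
  counts <- vapply(seq_len(reps), function(r) {
    g <- simulate_genotypes(genotype_sim_spec(64, 3, 3, het_prob = 0.5,
                                              seed = 20000 + r))
    length(scan_xy(g$matrix, g$sexmap))
  }, integer(1))
  se <- sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - 1.0), 3 * se)
})
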