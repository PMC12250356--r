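test_that("extract_monomers recovers exact monomers from concatemer reads", {
  set.seed(301)
  cons <- rand_dna(28)
  reads <- Biostrings::DNAStringSet(vapply(1:30, function(i) {
    off <- sample(28, 1)
    substr(strrep(cons, 7), off, off + 149)
  }, character(1)))
  mon <- extract_monomers(reads, cons, library = "lib")
  expect_equal(nrow(mon), 30)
  expect_true(all(mon$sequence == cons))
  expect_true(all(nchar(mon$sequence) == 28))
  # reads with no alignment above the floor contribute nothing
  nullreads <- Biostrings::DNAStringSet(replicate(30, rand_dna(150)))
  expect_equal(nrow(extract_monomers(nullreads, cons)), 0)
  expect_error(extract_monomers(reads, rand_dna(200)), "longer")
})

test_that("extract_monomers is strand-invariant and one-per-read", {
  set.seed(302)
  cons <- rand_dna(28)
  fwd <- Biostrings::DNAStringSet(vapply(1:20, function(i) {
    off <- sample(28, 1)
    substr(strrep(cons, 7), off, off + 149)
  }, character(1)))
  rev <- Biostrings::reverseComplement(fwd)
  m_f <- extract_monomers(fwd, cons)
  m_r <- extract_monomers(rev, cons)
  expect_equal(m_r$sequence, m_f$sequence)
  expect_true(all(m_f$sequence == cons))
  # all-copies mode yields more monomers than one-per-read
  m_all <- extract_monomers(fwd, cons, all_copies = TRUE)
  expect_gt(nrow(m_all), nrow(m_f))
  expect_true(all(m_all$sequence == cons))
})

test_that("extracted haplotype counts follow a planted 10:1 copy ratio", {
  set.seed(304)
  cons <- rand_dna(28)
  v2 <- mutate_chars(cons, 3)
  arr <- paste0(strrep(cons, 400), strrep(v2, 40))
  reads <- Biostrings::DNAStringSet(vapply(1:1200, function(i) {
    start <- sample(nchar(arr) - 149, 1)
    substr(arr, start, start + 149)
  }, character(1)))
  mon <- extract_monomers(reads, cons)
  n1 <- sum(mon$sequence == cons)
  n2 <- sum(mon$sequence == v2)
  ratio <- n1 / n2
  # binomial error around 10 with these depths stays well within [6, 16]
  expect_gt(ratio, 6)
  expect_lt(ratio, 16)
})

test_that("filter_singletons groups exact sequences and drops count-1 classes", {
  mon <- data.frame(
    sequence = c(rep("AAAA", 5), "AAAT"),
    library = c("m", "m", "m", "f", "f", "m"))
  nodes <- filter_singletons(mon)
  expect_equal(nrow(nodes), 1)
  expect_equal(nodes$sequence, "AAAA")
  expect_equal(nodes$total, 5L)
  expect_equal(nodes$m, 3L)
  expect_equal(nodes$f, 2L)
  # all distinct -> empty
  distinct <- data.frame(sequence = c("AAAA", "AAAT", "AATT"),
                         library = "m")
  expect_equal(nrow(filter_singletons(distinct)), 0)
  expect_equal(nrow(filter_singletons(mon[0, ])), 0)
})

test_that("filter_singletons conserves counts and never invents monomers", {
  set.seed(305)
  seqs <- replicate(8, rand_dna(12))
  mon <- data.frame(
    sequence = sample(seqs, 300, replace = TRUE,
                      prob = c(8, 6, 4, 2, 1, 1, 1, 1)),
    library = sample(c("a", "b"), 300, replace = TRUE))
  nodes <- filter_singletons(mon)
  expect_lte(sum(nodes$total), nrow(mon))
  expect_true(all(nodes$total >= 2))
  expect_equal(nodes$total, nodes$a + nodes$b)
  raw <- table(mon$sequence)
  for (i in seq_len(nrow(nodes)))
    expect_equal(nodes$total[i], unname(raw[nodes$sequence[i]]))
})

test_that("build_mst handles forced-topology and degenerate cases", {
  one <- data.frame(sequence = "ACGTACGTACGT", total = 3)
  m1 <- build_mst(one)
  expect_equal(nrow(m1$edges), 0)
  expect_equal(m1$total_weight, 0)
  expect_true(m1$is_spanning_tree)
  # distances (1, 1, 2): MST must use the two distance-1 edges
  tri <- data.frame(sequence = c("AAAA", "AAAT", "AATT"),
                    total = c(5, 3, 2))
  m3 <- build_mst(tri)
  expect_equal(nrow(m3$edges), 2)
  expect_equal(m3$total_weight, 2)
  expect_true(all(m3$edges$weight == 1))
  expect_error(build_mst(data.frame(sequence = c("AAA", "AAAA"),
                                    total = c(2, 2))), "unequal")
  # edit-distance mode accepts unequal lengths
  m_ed <- build_mst(data.frame(sequence = c("AAA", "AAAA"),
                               total = c(2, 2)), distance = "edit")
  expect_equal(m_ed$total_weight, 1)
})

test_that("build_mst weight equals exhaustive enumeration on random instances", {
  set.seed(306)
  for (rep in 1:40) {
    n <- sample(2:7, 1)
    seqs <- unique(replicate(n, rand_dna(8)))
    nodes <- data.frame(sequence = seqs,
                        total = sample(2:30, length(seqs), replace = TRUE))
    mst <- build_mst(nodes)
    D <- hamming_matrix(nodes$sequence)
    expect_equal(mst$total_weight, mst_weight_bruteforce(D))
    expect_equal(nrow(mst$edges), nrow(nodes) - 1)
  }
})

test_that("build_mst is deterministic under ties", {
  set.seed(307)
  seqs <- c("AAAAAAAA", "AAAAAAAT", "AAAAAATA", "AAAAATAA", "AAAATAAA")
  nodes <- data.frame(sequence = seqs, total = c(5, 5, 5, 5, 5))
  m1 <- build_mst(nodes)
  m2 <- build_mst(nodes)
  expect_identical(m1$edges, m2$edges)
  expect_equal(m1$total_weight, 4)
})

test_that("group_stats computes exclusivity and the partition identity", {
  nodes <- data.frame(
    sequence = c("AAAA", "AAAT", "AATT", "ATTT", "TTTT"),
    m1 = c(4L, 3L, 0L, 2L, 1L),
    f1 = c(5L, 0L, 2L, 0L, 1L),
    total = c(9L, 3L, 2L, 2L, 2L))
  attr(nodes, "libraries") <- c("m1", "f1")
  gs <- group_stats(nodes, c(m1 = "M", f1 = "F"))
  expect_equal(gs$total, 5)
  expect_equal(unname(gs$exclusive[c("M", "F")]), c(2L, 1L))
  expect_equal(gs$multi_group, 2)
  expect_equal(sum(gs$exclusive) + gs$multi_group, gs$total)
  expect_equal(gs$shared_all, 2)
  # everything shared -> all exclusive counts zero
  shared <- nodes
  shared$m1 <- shared$f1 <- 2L
  gs2 <- group_stats(shared, c(m1 = "M", f1 = "F"))
  expect_true(all(gs2$exclusive == 0))
  expect_error(group_stats(nodes, c(m1 = "M")), "unmapped")
})

test_that("group_stats partition identity holds on random count tables", {
  set.seed(308)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    libs <- c("karF_m", "karF_f", "karG_m", "karG_f")
    counts <- matrix(rpois(n * 4, 1.2), n, 4, dimnames = list(NULL, libs))
    counts[rowSums(counts) == 0, 1] <- 2L  # every haplotype observed
    nodes <- data.frame(sequence = replicate(n, rand_dna(10)),
                        counts, total = rowSums(counts))
    attr(nodes, "libraries") <- libs
    gs <- group_stats(nodes, c(karF_m = "FM", karF_f = "FF",
                               karG_m = "GM", karG_f = "GF"))
    expect_equal(sum(gs$exclusive) + gs$multi_group, gs$total)
  }
})
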