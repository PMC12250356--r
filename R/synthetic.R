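#' Specification of a synthetic satDNA family
#'
#' Describes one satellite DNA family to plant in simulated libraries:
#' its repeat-unit length, the number of monomer variants (haplotypes)
#' segregating in the arrays, their divergence, the diploid array copy
#' number, per-library copy-number multipliers (sex bias), and the
#' number of haplotypes exclusive to particular libraries. The exclusive
#' haplotypes emulate a repeat accumulated in the non-recombining region
#' of a sex chromosome, whose variants are observed only in the
#' heterogametic sex.
#'
#' @param family_id label for the family.
#' @param rul repeat-unit length in bp, >= 10.
#' @param n_variants number of shared monomer variants.
#' @param mutation_rate substitutions per site between variants, in
#'   \[0, 0.3\].
#' @param array_copies_per_genome total monomer copies in the unbiased
#'   array.
#' @param sex_bias named numeric vector: library label -> copy-number
#'   multiplier (> 0). The names define the simulated libraries.
#' @param exclusive_haplotypes named integer vector: library label ->
#'   number of haplotypes present only in that library (default none).
#' @param consensus optional consensus sequence (length `rul`); random
#'   if omitted.
#' @return an object of class `sat_family_spec`.
#' @export
sat_family_spec <- function(family_id, rul, n_variants = 1,
                            mutation_rate = 0.02,
                            array_copies_per_genome = 100,
                            sex_bias = c(male = 1, female = 1),
                            exclusive_haplotypes = integer(0),
                            consensus = NULL) {
  stopifnot(rul >= 10, mutation_rate >= 0, mutation_rate <= 0.3,
            n_variants >= 1, array_copies_per_genome >= 1)
  if (is.null(names(sex_bias)) || any(sex_bias <= 0))
    stop("sat_family_spec: sex_bias must be a named vector of positive ",
         "multipliers")
  if (length(exclusive_haplotypes) > 0) {
    if (is.null(names(exclusive_haplotypes)) ||
        !all(names(exclusive_haplotypes) %in% names(sex_bias)))
      stop("sat_family_spec: exclusive_haplotypes names must be library ",
           "labels from sex_bias")
  }
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    stopifnot(nchar(consensus) == rul)
  }
  structure(list(family_id = family_id, rul = as.integer(rul),
                 n_variants = as.integer(n_variants),
                 mutation_rate = mutation_rate,
                 array_copies_per_genome = as.integer(array_copies_per_genome),
                 sex_bias = sex_bias,
                 exclusive_haplotypes = exclusive_haplotypes,
                 consensus = consensus),
            class = "sat_family_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute each site with probability `rate` (to a different base);
# `min_subs` forces at least that many substitutions.
mutate_seq <- function(seq, rate, min_subs = 0) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) < min_subs)
    hit <- unique(c(hit, sample(length(chars), min_subs)))
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# Realize the haplotype set of one family: shared variants plus
# per-library exclusive haplotypes, all distinct sequences.
realize_haplotypes <- function(spec) {
  cons <- if (is.null(spec$consensus)) random_dna(spec$rul) else spec$consensus
  seqs <- cons
  if (spec$n_variants > 1) {
    for (i in seq_len(spec$n_variants - 1)) {
      s <- mutate_seq(cons, spec$mutation_rate, min_subs = 1)
      tries <- 0
      while (s %in% seqs && tries < 100) {
        s <- mutate_seq(cons, spec$mutation_rate, min_subs = 1)
        tries <- tries + 1
      }
      seqs <- c(seqs, s)
    }
  }
  shared <- data.frame(sequence = seqs,
                       haplotype_id = paste0(spec$family_id, "_v",
                                             seq_along(seqs)),
                       exclusive_to = NA_character_,
                       stringsAsFactors = FALSE)
  excl <- NULL
  for (lib in names(spec$exclusive_haplotypes)) {
    k <- spec$exclusive_haplotypes[[lib]]
    for (i in seq_len(k)) {
      s <- mutate_seq(cons, max(spec$mutation_rate, 0.02), min_subs = 2)
      tries <- 0
      while (s %in% c(shared$sequence, excl$sequence) && tries < 100) {
        s <- mutate_seq(cons, max(spec$mutation_rate, 0.02), min_subs = 2)
        tries <- tries + 1
      }
      excl <- rbind(excl, data.frame(
        sequence = s,
        haplotype_id = paste0(spec$family_id, "_x", lib, i),
        exclusive_to = lib, stringsAsFactors = FALSE))
    }
  }
  list(consensus = cons, haplotypes = rbind(shared, excl))
}

# Per-library monomer copy counts for the realized haplotypes of a family.
haplotype_copy_counts <- function(spec, haps) {
  libs <- names(spec$sex_bias)
  per_variant <- spec$array_copies_per_genome / spec$n_variants
  counts <- matrix(0L, nrow(haps), length(libs),
                   dimnames = list(haps$haplotype_id, libs))
  for (lib in libs) {
    mult <- spec$sex_bias[[lib]]
    shared <- is.na(haps$exclusive_to)
    counts[shared, lib] <- as.integer(round(per_variant * mult))
    mine <- !shared & haps$exclusive_to == lib
    counts[mine, lib] <- as.integer(round(per_variant * mult))
  }
  counts
}

#' Simulate satDNA-bearing read libraries with ground truth
#'
#' Generates, for each library, a chromosomally phased tandem array per
#' family (head-to-tail monomer copies in random order, copy numbers
#' following the sex-bias multipliers) plus an i.i.d.-uniform background
#' sequence, then fragments this pool into fixed-length single-end reads
#' at uniform random start positions and on random strands. Reads are
#' drawn from array vs background in proportion to their lengths, as in
#' uniform-coverage sequencing. The returned truth ledger records every
#' realized haplotype and its per-library monomer copy counts.
#'
#' @param specs one [sat_family_spec()] or a list of them; all must
#'   share the same `sex_bias` library labels.
#' @param read_length read length in bp (a warning is given below twice
#'   the longest repeat unit, where full-monomer capture is no longer
#'   guaranteed).
#' @param n_reads_per_library reads per library (> 0).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param background_bp length of the background (non-repetitive)
#'   sequence pool per library.
#' @return list with `reads` (named list of [Biostrings::DNAStringSet],
#'   one per library) and `truth` (list: `families` with consensus and
#'   haplotype table, `copy_counts` haplotype x library matrix,
#'   `read_counts` per library: satellite vs background reads).
#' @export
simulate_sat_reads <- function(specs, read_length = 150,
                               n_reads_per_library = 1000, seed = 1,
                               background_bp = 30000) {
  if (inherits(specs, "sat_family_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  if (n_reads_per_library <= 0)
    stop("simulate_sat_reads: n_reads_per_library must be positive")
  libs <- names(specs[[1]]$sex_bias)
  for (sp in specs)
    if (!identical(names(sp$sex_bias), libs))
      stop("simulate_sat_reads: all families must use the same libraries")
  max_rul <- max(vapply(specs, `[[`, integer(1), "rul"))
  if (read_length < max_rul)
    stop("simulate_sat_reads: read_length shorter than the longest ",
         "repeat unit")
  if (read_length < 2 * max_rul)
    warning("simulate_sat_reads: read_length below twice the repeat unit; ",
            "full-monomer capture is not guaranteed")
  set.seed(seed)

  realized <- lapply(specs, realize_haplotypes)
  names(realized) <- vapply(specs, `[[`, "", "family_id")
  counts_list <- mapply(haplotype_copy_counts, specs,
                        lapply(realized, `[[`, "haplotypes"),
                        SIMPLIFY = FALSE)
  copy_counts <- do.call(rbind, counts_list)
  hap_tab <- do.call(rbind, c(lapply(seq_along(specs), function(i)
    cbind(family_id = specs[[i]]$family_id, realized[[i]]$haplotypes)),
    make.row.names = FALSE))

  reads <- list()
  read_counts <- list()
  for (lib in libs) {
    # head-to-tail array; copies of one haplotype form contiguous blocks
    # (variant clusters, as concerted evolution homogenizes arrays), with
    # block order shuffled
    arrays <- lapply(seq_along(specs), function(i) {
      haps <- realized[[i]]$haplotypes
      cnt <- counts_list[[i]][, lib]
      blocks <- strrep(haps$sequence, cnt)
      blocks <- blocks[cnt > 0]
      if (length(blocks) == 0) return("")
      paste(sample(blocks), collapse = "")
    })
    segments <- c(arrays, random_dna(background_bp))
    seg_len <- nchar(segments)
    usable <- pmax(seg_len - read_length + 1L, 0L)
    if (all(usable == 0))
      stop("simulate_sat_reads: no segment long enough for a read")
    seg_of_read <- sample(length(segments), n_reads_per_library,
                          replace = TRUE, prob = seg_len / sum(seg_len))
    # resample reads landing on segments too short to hold one
    while (any(usable[seg_of_read] == 0)) {
      bad <- usable[seg_of_read] == 0
      seg_of_read[bad] <- sample(length(segments), sum(bad), replace = TRUE,
                                 prob = seg_len / sum(seg_len))
    }
    starts <- vapply(seg_of_read, function(s)
      sample.int(usable[s], 1), integer(1))
    seqs <- substr(rep(segments[seg_of_read], 1), starts,
                   starts + read_length - 1L)
    flip <- stats::runif(n_reads_per_library) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    rs <- Biostrings::DNAStringSet(seqs)
    names(rs) <- sprintf("%s_read%05d", lib, seq_along(rs))
    reads[[lib]] <- rs
    read_counts[[lib]] <- c(satellite = sum(seg_of_read <= length(specs)),
                            background = sum(seg_of_read > length(specs)))
  }
  truth <- list(
    families = lapply(realized, `[[`, "consensus"),
    haplotypes = hap_tab,
    copy_counts = copy_counts,
    read_counts = read_counts)
  list(reads = reads, truth = truth)
}

#' Specification of a synthetic SNP genotype matrix
#'
#' @param n_loci number of loci `L`.
#' @param n_males,n_females individuals per sex.
#' @param het_prob probability `h` that a null individual call is
#'   heterozygous.
#' @param n_planted_xy,n_planted_zw perfectly sex-linked loci to plant.
#' @param missing_rate probability a null-locus call is missing.
#' @param seed integer seed.
#' @return an object of class `genotype_sim_spec`.
#' @export
genotype_sim_spec <- function(n_loci, n_males, n_females, het_prob = 0.5,
                              n_planted_xy = 0, n_planted_zw = 0,
                              missing_rate = 0, seed = 1) {
  stopifnot(het_prob >= 0, het_prob <= 1,
            n_planted_xy + n_planted_zw <= n_loci,
            missing_rate >= 0, missing_rate <= 1,
            n_males >= 1, n_females >= 1)
  structure(list(n_loci = as.integer(n_loci), n_males = as.integer(n_males),
                 n_females = as.integer(n_females), het_prob = het_prob,
                 n_planted_xy = as.integer(n_planted_xy),
                 n_planted_zw = as.integer(n_planted_zw),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "genotype_sim_spec")
}

#' Simulate a DArT-style genotype matrix with planted sex-linked loci
#'
#' Null loci are i.i.d.: each individual is heterozygous (code 2) with
#' probability `het_prob`, otherwise homozygous for the reference (0) or
#' the alternate (1) with equal probability. Planted XY loci are code 2
#' in all males and 0/1 in all females; ZW loci are the mirror image.
#' Missingness is applied to null loci only, so planted loci are always
#' recoverable by a complete-locus scan.
#'
#' @param spec a [genotype_sim_spec()].
#' @return list with `matrix` (integer, loci x individuals, `NA` for
#'   missing), `sexmap` (named vector, individual -> `"M"`/`"F"`), and
#'   `truth` (list `xy_loci`, `zw_loci` of planted locus IDs).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "genotype_sim_spec"))
  set.seed(spec$seed)
  n_ind <- spec$n_males + spec$n_females
  inds <- c(sprintf("M%02d", seq_len(spec$n_males)),
            sprintf("F%02d", seq_len(spec$n_females)))
  sexmap <- stats::setNames(rep(c("M", "F"),
                                c(spec$n_males, spec$n_females)), inds)
  loci <- sprintf("L%05d", seq_len(spec$n_loci))
  # null background
  het <- stats::runif(spec$n_loci * n_ind) < spec$het_prob
  hom <- sample(c(0L, 1L), spec$n_loci * n_ind, replace = TRUE)
  m <- matrix(ifelse(het, 2L, hom), spec$n_loci, n_ind,
              dimnames = list(loci, inds))
  planted <- sample.int(spec$n_loci, spec$n_planted_xy + spec$n_planted_zw)
  xy <- planted[seq_len(spec$n_planted_xy)]
  zw <- setdiff(planted, xy)
  males <- sexmap[inds] == "M"
  if (length(xy) > 0) {
    m[xy, males] <- 2L
    m[xy, !males] <- sample(c(0L, 1L), length(xy) * sum(!males),
                            replace = TRUE)
  }
  if (length(zw) > 0) {
    m[zw, !males] <- 2L
    m[zw, males] <- sample(c(0L, 1L), length(zw) * sum(males),
                           replace = TRUE)
  }
  if (spec$missing_rate > 0) {
    null_rows <- setdiff(seq_len(spec$n_loci), planted)
    drop <- matrix(stats::runif(length(null_rows) * n_ind) <
                     spec$missing_rate, length(null_rows), n_ind)
    mm <- m[null_rows, , drop = FALSE]
    mm[drop] <- NA_integer_
    m[null_rows, ] <- mm
  }
  list(matrix = m, sexmap = sexmap,
       truth = list(xy_loci = loci[sort(xy)], zw_loci = loci[sort(zw)]))
}
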