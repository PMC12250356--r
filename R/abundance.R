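#' Kimura 2-parameter divergence
#'
#' Substitution distance distinguishing the transition proportion `p`
#' (A<->G, C<->T) from the transversion proportion `q`:
#' `K = -1/2 * log((1 - 2p - q) * sqrt(1 - 2q))`. Defined only while
#' `1 - 2p - q > 0` and `1 - 2q > 0`; outside that region the distance is
#' saturated and an error is raised.
#'
#' @param p transition proportion per aligned site (vectorized).
#' @param q transversion proportion per aligned site.
#' @return Kimura distance `K >= 0`; `K -> p + q` as `p, q -> 0`.
#' @examples
#' kimura2p(0.1, 0.05)  # ~0.1702
#' @export
kimura2p <- function(p, q) {
  if (any(p < 0) || any(q < 0) || any(p + q > 1))
    stop("kimura2p: p and q must be non-negative proportions with p + q <= 1")
  k <- k2p_safe(p, q)
  if (any(is.na(k)))
    stop("kimura2p: saturation (1 - 2p - q <= 0 or 1 - 2q <= 0); ",
         "divergence undefined")
  k
}

# NA instead of error on saturation; used when aggregating per-read values.
k2p_safe <- function(p, q) {
  a <- 1 - 2 * p - q
  b <- 1 - 2 * q
  ifelse(a > 0 & b > 0, -0.5 * log(a * sqrt(b)), NA_real_)
}

#' Map reads to a satDNA catalog and estimate genomic abundance
#'
#' Each read is locally aligned against a concatemer of every catalog
#' consensus on both strands: at least two copies, so the alignment is
#' independent of monomer phase, and enough copies to span a whole read,
#' so a read consisting purely of tandem copies aligns end to end. A
#' read is assigned to the satDNA giving
#' its best-scoring alignment with identity >= `min_identity` percent and
#' at least `min_aligned` aligned bases, and is counted at most once.
#' Genomic abundance per satDNA is by default the masked-base fraction
#' `aligned_bp / analyzed_bp`, comparable across satDNAs of different
#' repeat-unit lengths; `mode = "reads_per_nt"` gives the literal
#' mapped-reads-per-analyzed-nucleotide variant. Mean divergence per
#' satDNA is the aligned-bp-weighted mean of per-read Kimura 2-parameter
#' distances (reads with saturated distance are excluded from the mean).
#'
#' @param reads a [Biostrings::DNAStringSet] (one read library).
#' @param catalog named character vector (satDNA name -> consensus).
#' @param min_identity minimum percent identity for assignment.
#' @param min_aligned minimum aligned length in bp.
#' @param subsample number of reads to sample (without replacement) before
#'   mapping; `NULL` uses all reads. If larger than the library, all reads
#'   are used with a warning.
#' @param seed integer seed for the subsample.
#' @param mode abundance definition, `"bp_fraction"` (default) or
#'   `"reads_per_nt"`.
#' @param scoring alignment scoring from [sat_scoring()].
#' @return data.frame with one row per catalog entry: `sat_name`,
#'   `mapped_reads`, `aligned_bp`, `analyzed_bp`, `abundance`,
#'   `mean_divergence`.
#' @export
map_reads <- function(reads, catalog, min_identity = 80, min_aligned = 28,
                      subsample = NULL, seed = NULL,
                      mode = c("bp_fraction", "reads_per_nt"),
                      scoring = sat_scoring()) {
  mode <- match.arg(mode)
  if (length(reads) == 0) stop("map_reads: empty read set")
  if (length(catalog) == 0) stop("map_reads: empty catalog")
  if (is.null(names(catalog)))
    names(catalog) <- paste0("sat", seq_along(catalog))
  if (!is.null(subsample)) {
    if (subsample > length(reads)) {
      warning("map_reads: subsample exceeds library size; using all reads")
    } else {
      if (!is.null(seed)) set.seed(seed)
      reads <- reads[sample.int(length(reads), subsample)]
    }
  }
  analyzed_bp <- sum(Biostrings::width(reads))
  nsat <- length(catalog)
  nrd <- length(reads)

  # score every read against every (satellite, strand) consensus
  # concatemer; at least two copies makes the alignment phase-tolerant,
  # and enough copies to span a full read lets tandem reads align
  # end to end
  max_len <- max(Biostrings::width(reads))
  alns <- vector("list", 2 * nsat)
  scores <- matrix(-Inf, nrd, 2 * nsat)
  for (j in seq_len(nsat)) {
    n_copies <- max(2L, ceiling(max_len / nchar(catalog[[j]])) + 1L)
    dimer <- paste(rep(catalog[[j]], n_copies), collapse = "")
    for (s in 1:2) {
      subj <- if (s == 1) dimer else revcomp(dimer)
      k <- 2 * (j - 1) + s
      alns[[k]] <- align_local(reads, subj, scoring)
      scores[, k] <- Biostrings::score(alns[[k]])
    }
  }
  best <- max.col(scores, ties.method = "first")
  best_sat <- (best - 1) %/% 2 + 1

  res <- data.frame(sat_name = names(catalog),
                    mapped_reads = 0L, aligned_bp = 0L,
                    analyzed_bp = analyzed_bp, abundance = 0,
                    mean_divergence = NA_real_,
                    stringsAsFactors = FALSE)
  div_w <- div_wk <- numeric(nsat)
  strs <- lapply(seq_along(alns), function(k) {
    if (k %in% best) aln_strings(alns[[k]]) else NULL
  })
  for (i in seq_len(nrd)) {
    sk <- strs[[best[i]]]
    pc <- strsplit(sk$pat[i], "")[[1]]
    sc <- strsplit(sk$sub[i], "")[[1]]
    st <- aln_column_stats(pc, sc)
    if (st$columns == 0) next
    identity <- 100 * st$matches / st$columns
    read_aln_bp <- sum(pc != "-")
    if (identity < min_identity || read_aln_bp < min_aligned) next
    j <- best_sat[i]
    res$mapped_reads[j] <- res$mapped_reads[j] + 1L
    res$aligned_bp[j] <- res$aligned_bp[j] + read_aln_bp
    if (st$ungapped > 0) {
      k <- k2p_safe(st$transitions / st$ungapped,
                    st$transversions / st$ungapped)
      if (!is.na(k)) {
        div_w[j] <- div_w[j] + read_aln_bp
        div_wk[j] <- div_wk[j] + read_aln_bp * k
      }
    }
  }
  res$abundance <- if (mode == "bp_fraction")
    res$aligned_bp / analyzed_bp else res$mapped_reads / analyzed_bp
  res$mean_divergence <- ifelse(div_w > 0, div_wk / div_w, NA_real_)
  res
}

#' Male:female abundance ratio per satDNA
#'
#' Flags satDNAs whose abundance differs between the sexes as candidates
#' for sex-chromosome accumulation. The ratio is male/female abundance;
#' `Inf` marks satDNAs absent from the female library but present in the
#' male one, `NA` satDNAs absent from both.
#'
#' @param results_male,results_female data.frames from [map_reads()] on
#'   the male and female libraries of one karyomorph.
#' @param candidate_threshold fold change at or beyond which (in either
#'   direction) a satDNA is flagged.
#' @return data.frame `sat_name`, `abundance_male`, `abundance_female`,
#'   `ratio`, `candidate`, sorted by decreasing ratio.
#' @export
sex_ratio <- function(results_male, results_female,
                      candidate_threshold = 1.5) {
  all_sats <- union(results_male$sat_name, results_female$sat_name)
  miss <- c(setdiff(all_sats, results_male$sat_name),
            setdiff(all_sats, results_female$sat_name))
  if (length(miss) > 0)
    warning("sex_ratio: satDNA(s) missing from one library, treated as ",
            "abundance 0: ", paste(unique(miss), collapse = ", "))
  ab_m <- results_male$abundance[match(all_sats, results_male$sat_name)]
  ab_f <- results_female$abundance[match(all_sats, results_female$sat_name)]
  ab_m[is.na(ab_m)] <- 0
  ab_f[is.na(ab_f)] <- 0
  ratio <- ifelse(ab_f > 0, ab_m / ab_f, ifelse(ab_m > 0, Inf, NA_real_))
  candidate <- !is.na(ratio) &
    (ratio >= candidate_threshold | ratio <= 1 / candidate_threshold)
  out <- data.frame(sat_name = all_sats, abundance_male = ab_m,
                    abundance_female = ab_f, ratio = ratio,
                    candidate = candidate, stringsAsFactors = FALSE)
  out[order(-out$ratio), , drop = FALSE]
}

#' Paired t-test between two repeat catalogs
#'
#' Classical paired t-test (via [stats::t.test()]) on per-class repeat
#' proportions of the same genomes, at a 95% confidence threshold.
#' Degenerate inputs are resolved explicitly: all-zero differences give
#' `t = 0, p = 1`; zero-variance differences with nonzero mean give
#' `t = +/-Inf, p = 0`.
#'
#' @param proportions_a,proportions_b equal-length paired numeric vectors,
#'   `n >= 2`.
#' @return list with `t`, `df`, `p_value`, `significant` (at alpha 0.05).
#' @export
paired_catalog_test <- function(proportions_a, proportions_b) {
  stopifnot(length(proportions_a) == length(proportions_b))
  n <- length(proportions_a)
  if (n < 2) stop("paired_catalog_test: need n >= 2 pairs")
  d <- proportions_a - proportions_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(proportions_a, proportions_b, paired = TRUE)
    t <- unname(tt$statistic); p <- tt$p.value
  }
  list(t = t, df = n - 1L, p_value = p, significant = p < 0.05)
}
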