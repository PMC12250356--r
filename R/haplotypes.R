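#' Extract satDNA monomer haplotypes from reads
#'
#' Each read is locally aligned, on both strands, against a concatemer of
#' the satDNA consensus long enough to cover the read, so that every
#' monomer phase is available and complete monomer frames fall at
#' multiples of the repeat-unit length in subject coordinates. From the
#' best-scoring alignment whose identity reaches the floor, every
#' complete, gap-free monomer frame covered by the read is located, and
#' the best-matching copy (ties to the leftmost) is excised from the read
#' in consensus phase. One monomer per read by default, so tandem copies
#' within a read are never double-counted; `all_copies = TRUE` excises
#' every complete copy instead. Reverse-complement reads yield the
#' forward-phase monomer.
#'
#' @param reads a [Biostrings::DNAStringSet].
#' @param sat_consensus consensus monomer (character scalar); its length
#'   is the repeat-unit length `rul`.
#' @param library label recorded with each monomer.
#' @param subsample optional number of reads to sample before extraction.
#' @param seed integer seed for the subsample.
#' @param min_identity identity floor (percent) on the read-vs-consensus
#'   alignment.
#' @param all_copies excise every complete copy instead of the single
#'   best-aligned one.
#' @param scoring alignment scoring from [sat_scoring()].
#' @return data.frame with columns `sequence` (always exactly `rul`
#'   characters) and `library`, one row per excised monomer.
#' @export
extract_monomers <- function(reads, sat_consensus, library = "lib",
                             subsample = NULL, seed = NULL,
                             min_identity = 80, all_copies = FALSE,
                             scoring = sat_scoring()) {
  sat_consensus <- toupper(as.character(sat_consensus))
  rul <- nchar(sat_consensus)
  if (length(reads) == 0)
    return(data.frame(sequence = character(0), library = character(0)))
  max_len <- max(Biostrings::width(reads))
  if (rul > max_len)
    stop("extract_monomers: repeat unit longer than the reads")
  if (!is.null(subsample) && subsample < length(reads)) {
    if (!is.null(seed)) set.seed(seed)
    reads <- reads[sample.int(length(reads), subsample)]
  }
  n_copies <- ceiling(max_len / rul) + 2L
  subject <- paste(rep(sat_consensus, n_copies), collapse = "")
  fwd <- align_local(reads, subject, scoring)
  rev <- align_local(Biostrings::reverseComplement(reads), subject, scoring)
  use_rev <- Biostrings::score(rev) > Biostrings::score(fwd)

  strs_f <- aln_strings(fwd)
  strs_r <- aln_strings(rev)
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    sk <- if (use_rev[i]) strs_r else strs_f
    # cheap pre-filter: the aligned subject span must hold a full frame
    if (sk$sub_end[i] - sk$sub_start[i] + 1 < rul) next
    pc <- strsplit(sk$pat[i], "")[[1]]
    sc <- strsplit(sk$sub[i], "")[[1]]
    st <- aln_column_stats(pc, sc)
    if (st$columns == 0 || 100 * st$matches / st$columns < min_identity)
      next
    mono <- excise_frames(pc, sc, sk$sub_start[i], rul, all_copies)
    if (length(mono) > 0)
      out[[i]] <- mono
  }
  seqs <- unlist(out, use.names = FALSE)
  if (is.null(seqs)) seqs <- character(0)
  data.frame(sequence = seqs,
             library = rep(library, length(seqs)),
             stringsAsFactors = FALSE)
}

# Walk the gapped alignment rows and excise complete, gap-free monomer
# frames (subject positions (j-1)*rul+1 .. j*rul). Returns the best copy
# (highest within-frame identity, ties to the leftmost), or all copies.
excise_frames <- function(pat, sub, sub_start, rul, all_copies) {
  sub_pos <- sub_start - 1L + cumsum(sub != "-")   # undefined where sub=="-"
  frames_hit <- list()
  first <- sub_pos[sub != "-"][1]
  last <- max(sub_pos[sub != "-"])
  j_lo <- ceiling((first - 1) / rul) + 1L          # first frame fully >= first
  j_hi <- last %/% rul
  if (j_hi < j_lo) return(character(0))
  best_seq <- character(0)
  best_id <- -1
  all_out <- character(0)
  for (j in j_lo:j_hi) {
    f1 <- (j - 1L) * rul + 1L
    f2 <- j * rul
    c1 <- match(TRUE, sub != "-" & sub_pos == f1)
    c2 <- match(TRUE, sub != "-" & sub_pos == f2)
    if (is.na(c1) || is.na(c2)) next
    # gap-free: exactly rul columns, no read gaps
    if (c2 - c1 != rul - 1L) next
    span_pat <- pat[c1:c2]
    if (any(span_pat == "-")) next
    idy <- mean(span_pat == sub[c1:c2])
    copy <- paste(span_pat, collapse = "")
    if (all_copies) {
      all_out <- c(all_out, copy)
    } else if (idy > best_id) {
      best_id <- idy
      best_seq <- copy
    }
  }
  if (all_copies) all_out else best_seq
}

#' Collapse monomers to haplotypes and discard singletons
#'
#' A haplotype is an exact-sequence equivalence class of monomers.
#' Classes observed exactly once across all libraries are discarded as
#' likely sequencing errors; per-library counts are retained for the
#' survivors.
#'
#' @param monomers data.frame from [extract_monomers()] (columns
#'   `sequence`, `library`), possibly concatenated over libraries.
#' @param min_total minimum total count to keep a haplotype (2 removes
#'   singletons).
#' @return data.frame with `sequence`, one count column per library,
#'   and `total`, sorted by decreasing total then sequence; the library
#'   column names are in `attr(, "libraries")`.
#' @export
filter_singletons <- function(monomers, min_total = 2) {
  if (nrow(monomers) == 0) {
    out <- data.frame(sequence = character(0), total = integer(0))
    attr(out, "libraries") <- character(0)
    return(out)
  }
  tab <- table(monomers$sequence, monomers$library)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  total <- rowSums(counts)
  keep <- total >= min_total
  counts <- counts[keep, , drop = FALSE]
  total <- total[keep]
  if (nrow(counts) == 0) {
    out <- data.frame(sequence = character(0), total = integer(0))
    attr(out, "libraries") <- colnames(counts)
    return(out)
  }
  ord <- order(-total, rownames(counts))
  out <- data.frame(sequence = rownames(counts)[ord],
                    counts[ord, , drop = FALSE],
                    total = unname(total[ord]),
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  attr(out, "libraries") <- colnames(counts)
  out
}

#' Minimum spanning tree over haplotypes in mutational steps
#'
#' Builds the MST of the complete graph whose nodes are haplotypes and
#' whose edge weights are nucleotide mutational steps (Hamming distance;
#' all sequences must be the same length). Ties between equal-weight
#' edges are broken deterministically: prefer the edge joining the
#' higher combined-count pair of nodes, then the lexicographically
#' smallest (tree-endpoint sequence, new-endpoint sequence) pair.
#' Tie-breaking can change the topology but never the total weight.
#'
#' @param nodes data.frame from [filter_singletons()] (needs columns
#'   `sequence` and `total`).
#' @param distance `"hamming"` (default; requires equal lengths) or
#'   `"edit"` (Levenshtein, for unequal lengths).
#' @return list with `nodes`, `edges` (data.frame `from`, `to`, `weight`;
#'   indices into `nodes`), `total_weight`, `is_spanning_tree`.
#' @export
build_mst <- function(nodes, distance = c("hamming", "edit")) {
  distance <- match.arg(distance)
  n <- nrow(nodes)
  if (n < 1) stop("build_mst: need at least one node")
  seqs <- nodes$sequence
  if (distance == "hamming" && length(unique(nchar(seqs))) > 1)
    stop("build_mst: unequal sequence lengths; use distance = \"edit\"")
  empty <- data.frame(from = integer(0), to = integer(0),
                      weight = numeric(0))
  if (n == 1)
    return(list(nodes = nodes, edges = empty, total_weight = 0,
                is_spanning_tree = TRUE))
  method <- if (distance == "hamming") "hamming" else "levenshtein"
  D <- as.matrix(Biostrings::stringDist(Biostrings::DNAStringSet(seqs),
                                        method = method))
  totals <- nodes$total
  intree <- rep(FALSE, n)
  start <- order(-totals, seqs)[1]
  intree[start] <- TRUE
  edges <- empty
  for (step in seq_len(n - 1)) {
    tr <- which(intree)
    out <- which(!intree)
    W <- D[tr, out, drop = FALSE]
    w_min <- min(W)
    hits <- which(W == w_min, arr.ind = TRUE)
    u <- tr[hits[, 1]]
    v <- out[hits[, 2]]
    pick <- order(-(totals[u] + totals[v]), seqs[u], seqs[v])[1]
    edges <- rbind(edges, data.frame(from = u[pick], to = v[pick],
                                     weight = w_min))
    intree[v[pick]] <- TRUE
  }
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges,
       total_weight = sum(edges$weight), is_spanning_tree = TRUE)
}

#' Per-group sharing and exclusivity of haplotypes
#'
#' Assigns each library to a group (e.g. karyomorph x sex) and reports,
#' over the haplotypes of a graph or node table: the total haplotype
#' count, the number exclusive to each group (nonzero counts only in
#' that group's libraries), the number present in every group, and the
#' top-`k` "major" haplotypes among those shared by all groups.
#'
#' @param graph result of [build_mst()], or a node data.frame from
#'   [filter_singletons()].
#' @param groups named character vector: library label -> group label.
#' @param top_k how many major shared haplotypes to report.
#' @return list with `total`, `exclusive` (named integer vector per
#'   group), `multi_group`, `shared_all`, `major_shared` (data.frame).
#'   `sum(exclusive) + multi_group == total` always holds.
#' @export
group_stats <- function(graph, groups, top_k = 10) {
  nodes <- if (is.data.frame(graph)) graph else graph$nodes
  libs <- attr(nodes, "libraries")
  if (is.null(libs))
    libs <- setdiff(colnames(nodes), c("sequence", "total"))
  unmapped <- setdiff(libs, names(groups))
  if (length(unmapped) > 0)
    stop("group_stats: unmapped library label(s): ",
         paste(unmapped, collapse = ", "))
  glabs <- sort(unique(unname(groups[libs])))
  counts <- as.matrix(nodes[, libs, drop = FALSE])
  presence <- vapply(glabs, function(g)
    rowSums(counts[, libs[groups[libs] == g], drop = FALSE]) > 0,
    logical(nrow(nodes)))
  presence <- matrix(presence, nrow = nrow(nodes),
                     dimnames = list(NULL, glabs))
  n_groups <- rowSums(presence)
  exclusive <- vapply(glabs, function(g)
    sum(n_groups == 1 & presence[, g]), integer(1))
  shared_all <- n_groups == length(glabs)
  major <- nodes[shared_all, c("sequence", libs, "total"), drop = FALSE]
  major <- utils::head(major[order(-major$total), , drop = FALSE], top_k)
  rownames(major) <- NULL
  list(total = nrow(nodes), exclusive = exclusive,
       multi_group = sum(n_groups > 1), shared_all = sum(shared_all),
       major_shared = major)
}
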