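#' Alignment scoring parameters
#'
#' Scoring used for all local alignments in the package (catalog identity,
#' read mapping, monomer excision). Defaults follow conventional
#' short-tandem-repeat scoring: match +1, mismatch -1, gap open -5,
#' gap extend -1. `N` bases are scored 0 against everything and never
#' count as matches when identity is computed.
#'
#' @param match match score (positive).
#' @param mismatch mismatch score (negative).
#' @param gap_open gap opening penalty (positive cost).
#' @param gap_ext gap extension penalty (positive cost).
#' @return a list of scoring parameters, with the substitution matrix
#'   attached as `$submat`.
#' @export
sat_scoring <- function(match = 1, mismatch = -1, gap_open = 5, gap_ext = 1) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_ext = gap_ext, submat = m)
}

# Local alignment of one or more patterns against a single subject.
# Returns a PairwiseAlignments object.
align_local <- function(patterns, subject, scoring = sat_scoring()) {
  Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject, type = "local",
    substitutionMatrix = scoring$submat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
}

# Global-local alignment: the whole pattern against a free window of the
# subject. Used for monomer-vs-dimer identity, where every base of the
# shorter monomer must be accounted for (a purely local alignment would
# return short perfect substrings at identity 100 for unrelated pairs).
align_glocal <- function(patterns, subject, scoring = sat_scoring()) {
  Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject, type = "global-local",
    substitutionMatrix = scoring$submat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
}

# Column-level statistics of one alignment, from its gapped aligned strings.
# Identity counts exact A/C/G/T matches over all aligned columns (gaps and
# N-containing columns are columns but never matches). Transitions are
# A<->G and C<->T; transversions are the remaining base mismatches.
aln_column_stats <- function(pat_chars, sub_chars) {
  cols <- length(pat_chars)
  gap <- pat_chars == "-" | sub_chars == "-"
  p <- pat_chars[!gap]
  s <- sub_chars[!gap]
  ok <- p %in% c("A", "C", "G", "T") & s %in% c("A", "C", "G", "T")
  p <- p[ok]
  s <- s[ok]
  match <- p == s
  mism_p <- p[!match]
  mism_s <- s[!match]
  purine <- c("A", "G")
  transition <- (mism_p %in% purine) == (mism_s %in% purine)
  list(columns = cols,
       ungapped = sum(ok),
       matches = sum(match),
       transitions = sum(transition),
       transversions = sum(!transition))
}

# Gapped aligned pattern/subject strings for every alignment, plus the
# aligned subject start/end, extracted in bulk (per-alignment S4
# subsetting is far slower).
aln_strings <- function(aln) {
  list(pat = as.character(Biostrings::pattern(aln)),
       sub = as.character(Biostrings::subject(aln)),
       sub_start = Biostrings::start(Biostrings::subject(aln)),
       sub_end = Biostrings::end(Biostrings::subject(aln)))
}

# Percent identity of alignment i: 100 * matches / aligned columns.
aln_identity <- function(aln, i = seq_along(aln)) {
  strs <- aln_strings(aln)
  vapply(i, function(k) {
    st <- aln_column_stats(strsplit(strs$pat[k], "")[[1]],
                           strsplit(strs$sub[k], "")[[1]])
    if (st$columns == 0) 0 else 100 * st$matches / st$columns
  }, numeric(1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
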