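#' Phase- and strand-tolerant identity between two satDNA monomers
#'
#' Satellite DNA consensus monomers of the same family may be deposited in
#' any rotational phase and on either strand, so plain global identity is
#' meaningless. Identity is therefore computed by aligning the shorter
#' monomer, end to end, into the best window of the dimerized longer one
#' and of its reverse complement: dimerization makes every monomer phase
#' available as a contiguous substring, so a pure rotation scores 100,
#' while anchoring the whole shorter sequence keeps unrelated monomers
#' from scoring high on short chance substrings.
#'
#' @param a,b DNA sequences (character scalars, alphabet A/C/G/T/N).
#' @param scoring alignment scoring from [sat_scoring()].
#' @return percent identity in \[0, 100\]: `100 * matches / aligned columns`
#'   of the best-scoring local alignment over both strands. `N` never
#'   counts as a match.
#' @examples
#' pairwise_identity("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")  # 100
#' @export
pairwise_identity <- function(a, b, scoring = sat_scoring()) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("pairwise_identity: empty sequence")
  if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b))
    stop("pairwise_identity: alphabet must be A/C/G/T/N")
  if (nchar(a) > nchar(b)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  dimer <- paste0(b, b)
  fwd <- align_glocal(a, dimer, scoring)
  rev <- align_glocal(a, revcomp(dimer), scoring)
  best <- if (Biostrings::score(fwd) >= Biostrings::score(rev)) fwd else rev
  aln_identity(best, 1)
}

#' Classify the relationship between two satDNAs from their identity
#'
#' Two monomers are the same variant, different variants of the same
#' family, or members of a superfamily when their similarity exceeds 95,
#' 80, and 50 percent respectively; inequalities are strict, so boundary
#' values fall to the lower class.
#'
#' @param identity percent identity in \[0, 100\] (vectorized).
#' @return factor with levels `unrelated < superfamily < same_family <
#'   same_variant`.
#' @export
classify_relationship <- function(identity) {
  if (any(is.na(identity)) || any(identity < 0) || any(identity > 100))
    stop("classify_relationship: identity must be in [0, 100]")
  lv <- c("unrelated", "superfamily", "same_family", "same_variant")
  cls <- ifelse(identity > 95, "same_variant",
         ifelse(identity > 80, "same_family",
         ifelse(identity > 50, "superfamily", "unrelated")))
  factor(cls, levels = lv, ordered = TRUE)
}

#' Parse a satDNA name of the form `<prefix>Sat<rank>-<rul>`
#'
#' @param name character vector of names such as `"HmfSat10-28"`.
#' @return data.frame with columns `prefix`, `rank`, `rul`.
#' @export
parse_sat_name <- function(name) {
  m <- regmatches(name, regexec("^(.*)Sat0*([0-9]+)-([0-9]+)$", name))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad))
    stop("parse_sat_name: unparseable name(s): ",
         paste(name[bad], collapse = ", "))
  data.frame(prefix = vapply(m, `[`, "", 2),
             rank = as.integer(vapply(m, `[`, "", 3)),
             rul = as.integer(vapply(m, `[`, "", 4)))
}

#' Rank and name a satDNA catalog by decreasing abundance
#'
#' Records are sorted by decreasing abundance (ties broken by longer
#' repeat unit, then lexicographic consensus) and named
#' `<prefix>Sat<zero-padded rank>-<rul>`, the convention under which the
#' most abundant family of karyomorph F becomes e.g. `HmfSat01-<rul>`.
#'
#' @param consensus character vector of consensus sequences.
#' @param abundance non-negative numeric vector, same length.
#' @param prefix species+karyomorph code, e.g. `"Hmf"`.
#' @return data.frame with columns `name`, `prefix`, `rank`, `rul`,
#'   `consensus`, `abundance`, ordered by rank.
#' @export
name_catalog <- function(consensus, abundance, prefix) {
  stopifnot(length(consensus) == length(abundance))
  if (any(is.na(abundance)) || any(abundance < 0))
    stop("name_catalog: abundances must be present and non-negative")
  if (anyDuplicated(consensus))
    warning("name_catalog: duplicate consensus sequences; both kept")
  rul <- nchar(consensus)
  ord <- order(-abundance, -rul, consensus)
  rank <- seq_along(ord)
  pad <- max(2L, nchar(length(ord)))
  out <- data.frame(
    name = sprintf("%sSat%0*d-%d", prefix, pad, rank, rul[ord]),
    prefix = prefix, rank = rank, rul = rul[ord],
    consensus = consensus[ord], abundance = abundance[ord],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cross-karyomorph catalog comparison
#'
#' Computes phase/strand-tolerant identity for every cross-catalog pair
#' and summarizes the overlap: the number of pairs at 100% identity and
#' the number of families of the smaller catalog with at least one
#' partner above `family_threshold` percent identity in the other
#' catalog. The threshold defaults to 50 (superfamily level or above),
#' since cross-karyomorph homologs can sit below the 80% family
#' threshold while still being counted as shared; pass 80 for the
#' stricter family-level criterion.
#'
#' @param cat_a,cat_b named character vectors (name -> consensus).
#' @param family_threshold percent identity above which a cross-catalog
#'   partner makes a family "shared" (strict inequality).
#' @param scoring alignment scoring from [sat_scoring()].
#' @return list with `relations` (data.frame: `id_a`, `id_b`, `identity`,
#'   `relation`), `identical_pair_count`, `shared_family_count`.
#' @export
compare_catalogs <- function(cat_a, cat_b, family_threshold = 50,
                             scoring = sat_scoring()) {
  if (length(cat_a) == 0 || length(cat_b) == 0)
    stop("compare_catalogs: both catalogs must be non-empty")
  if (is.null(names(cat_a))) names(cat_a) <- paste0("A", seq_along(cat_a))
  if (is.null(names(cat_b))) names(cat_b) <- paste0("B", seq_along(cat_b))
  grid <- expand.grid(a = names(cat_a), b = names(cat_b),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idy <- mapply(function(ia, ib)
    pairwise_identity(cat_a[[ia]], cat_b[[ib]], scoring),
    grid$a, grid$b, USE.NAMES = FALSE)
  relations <- data.frame(id_a = grid$a, id_b = grid$b,
                          identity = idy,
                          relation = classify_relationship(idy),
                          stringsAsFactors = FALSE)
  identical_pair_count <- sum(idy >= 100 - 1e-9)
  # shared families: counted over the smaller catalog
  if (length(cat_a) <= length(cat_b)) {
    by_rec <- tapply(idy > family_threshold, relations$id_a, any)
  } else {
    by_rec <- tapply(idy > family_threshold, relations$id_b, any)
  }
  list(relations = relations,
       identical_pair_count = identical_pair_count,
       shared_family_count = sum(by_rec))
}
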