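#' Screen a genotype matrix for perfectly sex-linked SNPs
#'
#' Under male heterogamety (XY), a perfectly sex-linked SNP is
#' heterozygous (code 2) in every male and homozygous (code 0 or 1) in
#' every female; [scan_zw()] is the mirror image for female heterogamety
#' (ZW). By default only complete loci are considered, since "all males"
#' is undefined under missingness; `max_missing` relaxes this to loci
#' with at most that many missing calls (missing individuals are then
#' ignored in the all-male/all-female condition, but at least one
#' non-missing individual of each sex must remain).
#'
#' @param matrix integer matrix, loci x individuals, codes 0 (hom
#'   reference), 1 (hom alternate), 2 (heterozygous), `NA` (missing);
#'   rownames are locus IDs, colnames individual IDs.
#' @param sexmap named character vector: individual ID -> `"M"` or `"F"`,
#'   covering every column.
#' @param max_missing maximum number of missing calls tolerated per locus.
#' @return character vector of locus IDs matching the pattern.
#' @export
scan_xy <- function(matrix, sexmap, max_missing = 0) {
  scan_pattern(matrix, sexmap, het_sex = "M", max_missing = max_missing)
}

#' @rdname scan_xy
#' @export
scan_zw <- function(matrix, sexmap, max_missing = 0) {
  scan_pattern(matrix, sexmap, het_sex = "F", max_missing = max_missing)
}

scan_pattern <- function(matrix, sexmap, het_sex, max_missing = 0) {
  check_genotype_matrix(matrix, sexmap)
  sex <- sexmap[colnames(matrix)]
  if (!all(c("M", "F") %in% sex))
    stop("scan: need at least one individual of each sex")
  het_cols <- sex == het_sex
  hom_cols <- !het_cols
  het_part <- matrix[, het_cols, drop = FALSE]
  hom_part <- matrix[, hom_cols, drop = FALSE]
  n_missing <- rowSums(is.na(matrix))
  all_het <- rowSums(het_part == 2, na.rm = TRUE) +
    rowSums(is.na(het_part)) == ncol(het_part)
  all_hom <- rowSums(hom_part <= 1, na.rm = TRUE) +
    rowSums(is.na(hom_part)) == ncol(hom_part)
  some_het <- rowSums(!is.na(het_part)) > 0
  some_hom <- rowSums(!is.na(hom_part)) > 0
  hit <- all_het & all_hom & some_het & some_hom & n_missing <= max_missing
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(matrix)))
  ids[hit]
}

check_genotype_matrix <- function(matrix, sexmap) {
  if (is.null(colnames(matrix)))
    stop("genotype matrix must have individual IDs as colnames")
  missing_ids <- setdiff(colnames(matrix), names(sexmap))
  if (length(missing_ids) > 0)
    stop("sex map does not cover individual(s): ",
         paste(missing_ids, collapse = ", "))
  bad <- !is.na(matrix) & !(matrix %in% c(0L, 1L, 2L))
  if (any(bad))
    stop("genotype matrix contains invalid code(s): ",
         paste(unique(matrix[bad]), collapse = ", "))
  invisible(TRUE)
}

#' Number of perfectly sex-linked patterns expected by chance
#'
#' With `L` independent null loci where each individual is heterozygous
#' with probability `h`, the number of loci showing the perfect
#' heterogametic pattern (all het-sex individuals heterozygous, all
#' hom-sex individuals homozygous) by chance alone has expectation
#' `E = L * h^n_het * (1 - h)^n_hom`; at `h = 1/2` this is
#' `L * 2^-(n_m + n_f)`. For the XY pattern the het sex is male
#' (`n_het = n_m`), for ZW it is female.
#'
#' @param L number of loci scanned.
#' @param n_m,n_f number of males and females.
#' @param h per-individual heterozygosity probability of a null locus.
#' @param pattern `"xy"` or `"zw"`.
#' @return expected count, a non-negative real.
#' @examples
#' expected_by_chance(64, 3, 3, 0.5)  # 1.0
#' @export
expected_by_chance <- function(L, n_m, n_f, h = 0.5,
                               pattern = c("xy", "zw")) {
  pattern <- match.arg(pattern)
  if (L < 0 || n_m < 0 || n_f < 0) stop("expected_by_chance: negative input")
  if (h < 0 || h > 1) stop("expected_by_chance: h must be in [0, 1]")
  n_het <- if (pattern == "xy") n_m else n_f
  n_hom <- if (pattern == "xy") n_f else n_m
  L * h^n_het * (1 - h)^n_hom
}

#' Observed per-individual heterozygosity of a genotype matrix
#'
#' Fraction of non-missing calls equal to code 2; the default `h` for
#' [expected_by_chance()] when screening a real matrix.
#'
#' @inheritParams scan_xy
#' @return proportion in \[0, 1\].
#' @export
observed_het_rate <- function(matrix) {
  mean(matrix == 2, na.rm = TRUE)
}

#' Full sex-linked marker screen with chance expectation and verdict
#'
#' Runs both heterogamety scans, computes the chance expectations, and
#' issues a verdict. A system is called suggestive only when the
#' observed count exceeds its chance expectation and the one-sided
#' Poisson tail probability `P(X >= observed)` at that expectation is
#' below `alpha_margin`; otherwise the result is inconclusive, meaning
#' the observed markers cannot be distinguished from chance findings.
#'
#' @inheritParams scan_xy
#' @param het_prob heterozygosity for the null expectation: `"auto"`
#'   (observed rate of the matrix) or a number in \[0, 1\].
#' @param alpha_margin one-sided Poisson tail threshold for a
#'   suggestive verdict.
#' @return list with `xy_loci`, `zw_loci`, `expected_by_chance_xy`,
#'   `expected_by_chance_zw`, `p_xy`, `p_zw`, `het_prob`, `L`, `n_m`,
#'   `n_f`, `verdict` in `{"XY-suggestive", "ZW-suggestive",
#'   "inconclusive"}`.
#' @export
slm_screen <- function(matrix, sexmap, max_missing = 0, het_prob = "auto",
                       alpha_margin = 0.05) {
  check_genotype_matrix(matrix, sexmap)
  sex <- sexmap[colnames(matrix)]
  n_m <- sum(sex == "M")
  n_f <- sum(sex == "F")
  h <- if (identical(het_prob, "auto")) observed_het_rate(matrix)
       else as.numeric(het_prob)
  # only loci that could enter the scan count toward L
  L <- sum(rowSums(is.na(matrix)) <= max_missing)
  xy <- scan_xy(matrix, sexmap, max_missing)
  zw <- scan_zw(matrix, sexmap, max_missing)
  e_xy <- expected_by_chance(L, n_m, n_f, h, "xy")
  e_zw <- expected_by_chance(L, n_m, n_f, h, "zw")
  res <- list(xy_loci = xy, zw_loci = zw,
              expected_by_chance_xy = e_xy, expected_by_chance_zw = e_zw,
              het_prob = h, L = L, n_m = n_m, n_f = n_f)
  classify_system(res, alpha_margin)
}

#' Verdict on a sex-linked marker screen
#'
#' @param result list with `xy_loci`, `zw_loci`, `expected_by_chance_xy`,
#'   `expected_by_chance_zw` (as produced within [slm_screen()]).
#' @param alpha_margin one-sided Poisson tail threshold.
#' @return the input list with `p_xy`, `p_zw`, and `verdict` added.
#' @export
classify_system <- function(result, alpha_margin = 0.05) {
  obs_xy <- length(result$xy_loci)
  obs_zw <- length(result$zw_loci)
  p_xy <- stats::ppois(obs_xy - 1, result$expected_by_chance_xy,
                       lower.tail = FALSE)
  p_zw <- stats::ppois(obs_zw - 1, result$expected_by_chance_zw,
                       lower.tail = FALSE)
  xy_sig <- obs_xy > result$expected_by_chance_xy && p_xy < alpha_margin
  zw_sig <- obs_zw > result$expected_by_chance_zw && p_zw < alpha_margin
  verdict <- if (xy_sig && (!zw_sig || p_xy <= p_zw)) "XY-suggestive"
             else if (zw_sig) "ZW-suggestive"
             else "inconclusive"
  result$p_xy <- p_xy
  result$p_zw <- p_zw
  result$verdict <- verdict
  result
}
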