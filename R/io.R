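#' Read and write FASTA/FASTQ files
#'
#' Thin wrappers over Biostrings with the conventions used throughout
#' the package: FASTA is wrapped at 60 columns; FASTQ is written with a
#' fixed quality string (the simulator has no quality model).
#'
#' @param path file path.
#' @param x a [Biostrings::DNAStringSet] (named).
#' @return `read_fasta`/`read_fastq` return a [Biostrings::DNAStringSet];
#'   the writers return `path` invisibly.
#' @name sat_io
NULL

#' @rdname sat_io
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fasta")
}

#' @rdname sat_io
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 60)
  invisible(path)
}

#' @rdname sat_io
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' @rdname sat_io
#' @export
write_fastq <- function(x, path) {
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
    strrep("I", w), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read/write a genotype matrix CSV and its sex-map sidecar
#'
#' The genotype CSV has a first column of locus IDs, one column per
#' individual with the individual IDs in the header, and cell codes
#' `0` (homozygous reference), `1` (homozygous alternate),
#' `2` (heterozygous), or `-` (missing). The sex map CSV has columns
#' `individual` and `sex` (`M`/`F`).
#'
#' @param path file path.
#' @param matrix integer genotype matrix (loci x individuals, `NA` for
#'   missing) with dimnames.
#' @param sexmap named character vector, individual -> `"M"`/`"F"`.
#' @return `read_genotype_csv` returns the integer matrix;
#'   `read_sexmap_csv` the named vector; writers return `path`
#'   invisibly.
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("genotype CSV needs a locus column and at least ",
                         "one individual column")
  loci <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells[cells %in% c("-", "")] <- NA_character_
  ok <- is.na(cells) | cells %in% c("0", "1", "2")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code '%s' at locus %s, individual %s",
                 cells[bad[1], bad[2]], loci[bad[1]],
                 colnames(cells)[bad[2]]))
  }
  m <- matrix(as.integer(cells), nrow(cells), ncol(cells),
              dimnames = list(loci, colnames(cells)))
  m
}

#' @rdname genotype_io
#' @export
write_genotype_csv <- function(matrix, path) {
  cells <- matrix
  mode(cells) <- "character"
  cells[is.na(cells)] <- "-"
  df <- data.frame(locus = rownames(matrix), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_sexmap_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("individual", "sex") %in% colnames(df)))
    stop("sex map CSV needs columns 'individual' and 'sex'")
  if (!all(df$sex %in% c("M", "F")))
    stop("sex map: sex must be 'M' or 'F'")
  stats::setNames(df$sex, df$individual)
}

#' @rdname genotype_io
#' @export
write_sexmap_csv <- function(sexmap, path) {
  utils::write.csv(data.frame(individual = names(sexmap),
                              sex = unname(sexmap)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a report table as TSV
#'
#' @param df data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a haplotype MST as GraphML
#'
#' Nodes carry the haplotype sequence, per-library counts, and total;
#' edges carry the mutational-step weight. The file can be opened in
#' standard network-visualization tools.
#'
#' @param graph result of [build_mst()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  nodes <- graph$nodes
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = graph$edges$from, to = graph$edges$to,
                   weight = graph$edges$weight),
    vertices = data.frame(name = seq_len(nrow(nodes)), nodes,
                          check.names = TRUE),
    directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
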