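# Independent oracles used across tests.

# Random DNA string of length n.
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Rotate a string left by k positions.
rotate <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

# Substitute exactly k random sites of s with different bases.
mutate_chars <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  for (p in sample(length(ch), k))
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Complete monomer copies of `cons` (any phase) in `read`, by direct
# string matching of every rotation.
count_full_copies <- function(read, cons) {
  n <- nchar(cons)
  max(vapply(seq_len(n) - 1, function(k) {
    hits <- gregexpr(rotate(cons, k), read, fixed = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }, integer(1)))
}

# --- exhaustive spanning-tree oracle (Pruefer enumeration) ---------------

# Decode one Pruefer sequence into an edge matrix (2 x (n-1)).
decode_pruefer <- function(code) {
  n <- length(code) + 2L
  deg <- tabulate(code, n) + 1L
  edges <- matrix(0L, 2, n - 1L)
  for (k in seq_along(code)) {
    leaf <- which(deg == 1L)[1]
    edges[, k] <- c(leaf, code[k])
    deg[leaf] <- 0L
    deg[code[k]] <- deg[code[k]] - 1L
  }
  edges[, n - 1L] <- which(deg == 1L)
  edges
}

# Linear indices into an n x n distance matrix for every spanning tree
# of K_n: an (n-1) x n^(n-2) matrix, one column per tree. Cached per n.
.span_tree_idx <- new.env()
all_spanning_tree_idx <- function(n) {
  key <- as.character(n)
  if (!is.null(.span_tree_idx[[key]])) return(.span_tree_idx[[key]])
  if (n == 2) {
    idx <- matrix((2L - 1L) * n + 1L, 1, 1)  # D[1,2] in column-major
  } else {
    codes <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
    idx <- apply(codes, 1, function(code) {
      e <- decode_pruefer(as.integer(code))
      (e[2, ] - 1L) * n + e[1, ]
    })
  }
  .span_tree_idx[[key]] <- idx
  idx
}

# Minimum spanning-tree weight of distance matrix D by brute force over
# all n^(n-2) labelled spanning trees.
mst_weight_bruteforce <- function(D) {
  n <- nrow(D)
  if (n == 1) return(0)
  idx <- all_spanning_tree_idx(n)
  w <- colSums(matrix(D[idx], nrow = n - 1))
  min(w)
}

# Hamming distance matrix computed independently of the package.
hamming_matrix <- function(seqs) {
  ch <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(ch[i, ] != ch[j, ])
  D
}

# Brute-force identity between two equal-length monomers over all
# rotations and both strands (no indels).
identity_bruteforce_rotations <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  n <- nchar(a)
  best <- 0
  for (s in c(b, rc(b))) {
    for (k in seq_len(n) - 1) {
      r <- rotate(s, k)
      m <- sum(strsplit(a, "")[[1]] == strsplit(r, "")[[1]])
      best <- max(best, 100 * m / n)
    }
  }
  best
}
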