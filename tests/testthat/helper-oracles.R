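# Independent oracles used across the suite. Each deliberately takes a
# different route than the implementation it checks.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

all_substrings <- function(s) {
  n <- nchar(s)
  unique(unlist(lapply(seq_len(n), function(i)
    substring(s, i, i:n))))
}

# exhaustive-enumeration longest common substring: intersect the substring
# sets of every input and take the maximal length
oracle_lcs_length <- function(seqs) {
  common <- all_substrings(seqs[1])
  for (s in seqs[-1]) common <- intersect(common, all_substrings(s))
  if (length(common) == 0L) 0L else max(nchar(common))
}

# repeated-pass transitive closure over an explicit adjacency matrix
oracle_components <- function(adj) {
  n <- nrow(adj)
  label <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && label[j] != label[i]) {
        new <- min(label[i], label[j])
        label[label == label[i] | label == label[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(label, unique(label))
}

# pure-R affine-gap Smith-Waterman (gap of length L costs open + L * ext),
# independent of Biostrings::pairwiseAlignment
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in seq.int(2L, n + 1L)) {
    for (j in seq.int(2L, m + 1L)) {
      E[i, j] <- max(M[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F[i, j] <- max(M[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
      M[i, j] <- max(0, M[i - 1L, j - 1L] + mat[A[i - 1L], B[j - 1L]],
                     E[i, j], F[i, j])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# independent SHA-256 digest (openssl), against the digest-based antibody_id
oracle_sha256 <- function(x) {
  as.character(openssl::sha256(x))
}

# small helper: a valid random variable-region-like chain
fixture_chain <- function(class = c("LIGHT", "HEAVY"), total = 100L,
                          ps = pattern_set()) {
  class <- match.arg(class)
  starts <- if (class == "LIGHT") ps$light_starts else ps$heavy_starts
  ends <- if (class == "LIGHT") ps$light_ends else ps$heavy_ends
  s <- sample(starts, 1L); e <- sample(ends, 1L)
  core_ab <- setdiff(AA20, c("V", "Q", "L"))
  paste0(s, random_seq(total - nchar(s) - nchar(e), core_ab), e)
}
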