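# Independent oracles used across the suite.  All are deliberately naive
# (quadratic DP, exhaustive scans, direct summation) and share no code with
# the package implementations they check.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(len) paste(sample(aa20, len, replace = TRUE),
                                  collapse = "")

random_records <- function(n, len) {
  data.frame(id = sprintf("s%03d", seq_len(n)), description = "",
             sequence = vapply(seq_len(n), function(i) random_seq(len), ""),
             stringsAsFactors = FALSE)
}

# Smith-Waterman local alignment score, affine gaps (length-L gap costs
# gap_open + L * gap_extend), full quadratic DP with three state matrices.
sw_oracle <- function(a, b, m, gap_open, gap_extend) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); mm <- length(b)
  NEG <- -Inf
  M <- matrix(0, n + 1, mm + 1)
  X <- matrix(NEG, n + 1, mm + 1)
  Y <- matrix(NEG, n + 1, mm + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(mm + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend,
                     Y[i - 1, j] - gap_open - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend,
                     X[i, j - 1] - gap_open - gap_extend)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + m[a[i - 1], b[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# Global Needleman-Wunsch optimal score, same gap convention.
nw_oracle <- function(a, b, m, gap_open, gap_extend) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); mm <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, mm + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in 2:(mm + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(mm + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        m[a[i - 1], b[j - 1]]
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend,
                     Y[i - 1, j] - gap_open - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend,
                     X[i, j - 1] - gap_open - gap_extend)
    }
  }
  max(M[n + 1, mm + 1], X[n + 1, mm + 1], Y[n + 1, mm + 1])
}

# Score of a monotone residue pairing interpreted as a global alignment
# (unpaired stretches are gaps, charged per run).
pairs_alignment_score <- function(pairs, a, b, m, gap_open, gap_extend) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  score <- 0
  prev_i <- 0L; prev_j <- 0L
  gap_cost <- function(len) if (len > 0) gap_open + len * gap_extend else 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    score <- score + m[a[i], b[j]] -
      gap_cost(i - prev_i - 1L) - gap_cost(j - prev_j - 1L)
    prev_i <- i; prev_j <- j
  }
  score - gap_cost(length(a) - prev_i) - gap_cost(length(b) - prev_j)
}

# Connected components by union-find.
uf_components <- function(nodes, edges) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges$id_a[[k]]); rb <- find(edges$id_b[[k]])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  comps <- split(nodes, roots)
  comps <- lapply(comps, function(x) sort(unname(x)))
  ord <- order(-vapply(comps, length, 1L), vapply(comps, `[[`, "", 1L))
  unname(comps[ord])
}

# Jensen-Shannon divergence by direct summation over the 20 letters.
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  term <- function(x) {
    i <- x > 0
    sum(x[i] * log2(x[i] / m[i]))
  }
  0.5 * term(p) + 0.5 * term(q)
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# minimal PDB text for a CA trace
write_test_pdb <- function(path, xyz, aa3 = "ALA", chain = "A",
                           resno = seq_len(nrow(xyz))) {
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(xyz)), rep_len(aa3, nrow(xyz)), chain, resno,
    xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  path
}
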