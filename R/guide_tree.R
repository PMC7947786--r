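#' K-mer distance matrix between sequences
#'
#' Distance between two sequences is `1 - shared / min`, where `shared` is
#' the number of distinct k-mers present in both sequences and `min` the
#' smaller of the two distinct k-mer counts.  Fast alignment-free input for
#' the neighbor-joining guide tree.
#'
#' @param records A `divcons_seqs` table.
#' @param k K-mer length (default 3).
#' @return A symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
kmer_distance_matrix <- function(records, k = 3L) {
  records <- as_seqs(records)
  if (k < 1L) stop("k must be >= 1")
  short <- nchar(records$sequence) < k
  if (any(short))
    stop("sequence shorter than k = ", k, ": ", records$id[which(short)[1L]])
  kmers <- lapply(records$sequence, function(s) {
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  sizes <- lengths(kmers)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- sum(kmers[[i]] %in% kmers[[j]])
      d[i, j] <- d[j, i] <- 1 - shared / min(sizes[[i]], sizes[[j]])
    }
  }
  d
}

#' Neighbor-joining guide tree
#'
#' Standard neighbor joining (via [ape::nj()]) with negative branch lengths
#' clamped to zero and the basal trifurcation resolved deterministically so
#' the result is a rooted binary tree usable as a progressive-alignment guide
#' tree.  Two taxa are handled as a simple two-leaf tree.
#'
#' @param dist Square symmetric distance matrix with dimnames.
#' @return An [ape::phylo] tree, rooted and binary, leaves labelled by ids.
#' @export
neighbor_joining <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) stop("distance matrix must be square")
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix is asymmetric")
  ids <- rownames(dist)
  if (is.null(ids)) stop("distance matrix must carry ids as dimnames")
  n <- nrow(dist)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                 edge.length = rep(dist[1, 2] / 2, 2),
                 tip.label = ids, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  tree <- ape::nj(dist)
  tree$edge.length <- pmax(tree$edge.length, 0)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  tree
}
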