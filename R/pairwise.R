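#' Substitution matrix with neutral unknowns
#'
#' Returns a standard BLOSUM substitution matrix restricted to the 20
#' amino-acid letters plus `X`, with every score involving `X` set to 0
#' (unknown residues are treated as neutral).
#'
#' @param name Matrix name: `"BLOSUM62"` (default), `"BLOSUM50"`,
#'   `"BLOSUM45"`, `"BLOSUM80"`.
#' @return A numeric matrix with dimnames over the 21-letter alphabet.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  name <- toupper(name)
  if (!name %in% c("BLOSUM62", "BLOSUM50", "BLOSUM45", "BLOSUM80"))
    stop("unknown substitution matrix: ", name)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- env[[name]]
  keep <- c(.divcons_amino_acids, "X")
  m <- m[keep, keep]
  m["X", ] <- 0
  m[, "X"] <- 0
  storage.mode(m) <- "double"
  m
}

# Gapped Karlin-Altschul constants (lambda, K) per matrix, the standard
# protein-BLAST values; used only to express raw scores in bits, so the SSN
# threshold is configurable rather than hard-coded.
.ka_constants <- list(
  BLOSUM62 = c(lambda = 0.267, K = 0.041),
  BLOSUM50 = c(lambda = 0.232, K = 0.110),
  BLOSUM45 = c(lambda = 0.207, K = 0.049),
  BLOSUM80 = c(lambda = 0.299, K = 0.071))

score_to_bits <- function(raw, matrix_name) {
  k <- .ka_constants[[toupper(matrix_name)]]
  (k[["lambda"]] * raw - log(k[["K"]])) / log(2)
}

check_gap_params <- function(gap_open, gap_extend) {
  if (gap_open < gap_extend)
    stop("gap_open (", gap_open, ") must be >= gap_extend (", gap_extend, ")")
  invisible(TRUE)
}

#' Pairwise local alignment score between two protein sequences
#'
#' Smith-Waterman local alignment with affine gap penalties (a gap of length
#' L costs `gap_open + L * gap_extend`).  The raw score is converted to bits
#' with the matrix's standard gapped Karlin-Altschul constants.  Percent
#' identity is the fraction of identical aligned pairs over all aligned
#' columns (gaps included); percent similarity additionally counts pairs with
#' a positive substitution score.
#'
#' @param a,b Sequences: single-row `divcons_seqs` tables, named character
#'   vectors of length 1, or plain strings (ids `"a"`/`"b"` are then used).
#' @param matrix Substitution matrix name, see [substitution_matrix()].
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return A one-row `data.frame` with `id_a`, `id_b`, `score_raw`,
#'   `score_bits`, `percent_identity`, `percent_similarity`,
#'   `aligned_length`.
#' @examples
#' pairwise_local_score("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
#'                      gap_open = 10, gap_extend = 1)
#' @export
pairwise_local_score <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                                 gap_extend = 1) {
  check_gap_params(gap_open, gap_extend)
  a <- as_single_seq(a, "a"); b <- as_single_seq(b, "b")
  if (!nzchar(a$sequence) || !nzchar(b$sequence))
    stop("sequences must be non-empty")
  m <- substitution_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$sequence), Biostrings::AAString(b$sequence),
    type = "local", substitutionMatrix = m,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  len <- length(pa)
  ident <- sum(pa == pb & pa != "-")
  nongap <- pa != "-" & pb != "-"
  pos <- ident
  if (any(nongap)) {
    sc <- m[cbind(pa[nongap], pb[nongap])]
    pos <- sum(sc > 0 | pa[nongap] == pb[nongap])
  }
  raw <- Biostrings::score(aln)
  data.frame(id_a = a$id, id_b = b$id, score_raw = raw,
             score_bits = score_to_bits(raw, matrix),
             percent_identity = if (len) 100 * ident / len else 0,
             percent_similarity = if (len) 100 * pos / len else 0,
             aligned_length = len, stringsAsFactors = FALSE)
}

as_single_seq <- function(x, default_id) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)))
    return(list(id = default_id, sequence = toupper(x)))
  x <- as_seqs(x)
  if (nrow(x) != 1L) stop("expected a single sequence")
  list(id = x$id[[1L]], sequence = toupper(x$sequence[[1L]]))
}

#' Build a sequence-similarity network
#'
#' Scores all sequence pairs by Smith-Waterman local alignment (bit scores)
#' and keeps the edges at or above `threshold`.  Connected components of the
#' resulting graph define family clusters (see [cluster_families()]).
#'
#' All n(n-1)/2 pairs are scored; for desk-scale inputs only.  The number of
#' pairs is capped by `max_pairs`.
#'
#' @param records A `divcons_seqs` table with at least 2 sequences.
#' @param threshold Bit-score threshold; only edges with
#'   `score_bits >= threshold` are retained.
#' @param matrix,gap_open,gap_extend Alignment parameters, see
#'   [pairwise_local_score()].
#' @param max_pairs Guard against accidentally quadratic-blowup inputs.
#' @return An object of class `divcons_ssn`: list with `nodes` (ids),
#'   `edges` (data.frame `id_a`, `id_b`, `score_bits`), `all_scores` (the
#'   full score table, for re-thresholding), `threshold` and the alignment
#'   parameters.
#' @export
build_ssn <- function(records, threshold, matrix = "BLOSUM62", gap_open = 11,
                      gap_extend = 1, max_pairs = 2e5) {
  check_gap_params(gap_open, gap_extend)
  records <- as_seqs(records)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 sequences to build a network")
  n_pairs <- n * (n - 1) / 2
  if (n_pairs > max_pairs)
    stop("all-vs-all scoring would need ", n_pairs, " pairs (max_pairs = ",
         max_pairs, "); raise max_pairs only for desk-scale inputs")
  m <- substitution_matrix(matrix)
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  ia <- integer(n_pairs); ib <- integer(n_pairs); raw <- numeric(n_pairs)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    idx <- (i + 1L):n
    sc <- Biostrings::pairwiseAlignment(
      aa[idx], aa[[i]], type = "local", substitutionMatrix = m,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
    r <- k + seq_along(idx)
    ia[r] <- i; ib[r] <- idx; raw[r] <- sc
    k <- k + length(idx)
  }
  scores <- data.frame(id_a = records$id[ia], id_b = records$id[ib],
                       score_bits = score_to_bits(raw, matrix),
                       stringsAsFactors = FALSE)
  structure(list(nodes = records$id,
                 edges = scores[scores$score_bits >= threshold, , drop = FALSE],
                 all_scores = scores,
                 threshold = threshold,
                 params = list(matrix = matrix, gap_open = gap_open,
                               gap_extend = gap_extend)),
            class = "divcons_ssn")
}

#' Re-threshold an existing similarity network
#'
#' @param ssn A `divcons_ssn` object.
#' @param threshold New bit-score threshold.
#' @return A `divcons_ssn` with edges filtered at the new threshold.
#' @export
ssn_threshold <- function(ssn, threshold) {
  stopifnot(inherits(ssn, "divcons_ssn"))
  ssn$edges <- ssn$all_scores[ssn$all_scores$score_bits >= threshold, ,
                              drop = FALSE]
  ssn$threshold <- threshold
  ssn
}

#' @export
print.divcons_ssn <- function(x, ...) {
  cat("divcons similarity network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges at threshold", x$threshold, "bits\n")
  invisible(x)
}

#' Partition a similarity network into family clusters
#'
#' Clusters are the connected components of the thresholded network, ordered
#' by decreasing size with ties broken by the lexicographically smallest
#' member id.  Singleton nodes form singleton clusters.
#'
#' @param network A `divcons_ssn` object.
#' @return A list of character vectors (sorted member ids), largest cluster
#'   first.
#' @export
cluster_families <- function(network) {
  stopifnot(inherits(network, "divcons_ssn"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = network$nodes))
  comp <- igraph::components(g)
  clusters <- split(names(comp$membership), comp$membership)
  clusters <- lapply(clusters, function(x) sort(unname(x)))
  ord <- order(-vapply(clusters, length, 1L),
               vapply(clusters, `[[`, "", 1L))
  unname(clusters[ord])
}

#' Tie a cluster to its structure-bearing reference sequence
#'
#' @param cluster Character vector of member ids.
#' @param reference_id Id of the member whose solved structure represents the
#'   family.
#' @return A list of class `divcons_family` with `ids` and `reference_id`.
#' @export
assign_reference <- function(cluster, reference_id) {
  if (!reference_id %in% cluster)
    stop("reference id '", reference_id, "' is not a member of the cluster {",
         paste(utils::head(cluster, 5), collapse = ", "),
         if (length(cluster) > 5) ", ..." else "", "}")
  structure(list(ids = cluster, reference_id = reference_id),
            class = "divcons_family")
}

#' Write the network edge list and cluster membership tables
#'
#' @param network A `divcons_ssn`.
#' @param clusters Output of [cluster_families()].
#' @param dir Output directory (created if missing).
#' @param reference_ids Optional character vector of reference ids flagged in
#'   the membership table.
#' @return Paths of the two TSV files, invisibly.
#' @export
write_ssn <- function(network, clusters, dir, reference_ids = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edge_path <- file.path(dir, "ssn_edges.tsv")
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  members <- data.frame(
    id = unlist(clusters),
    cluster_index = rep(seq_along(clusters), lengths(clusters)),
    stringsAsFactors = FALSE)
  members$is_reference <- members$id %in% reference_ids
  member_path <- file.path(dir, "ssn_clusters.tsv")
  write.table(members, member_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(edge_path, member_path))
}
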