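new_alignment <- function(rows, reference_id = NULL, weights = NULL) {
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- names(rows)[lens != lens[[1L]]][1L]
    stop("ragged alignment: row '", bad, "' has length ",
         nchar(rows[[bad]]), " but row '", names(rows)[[1L]], "' has length ",
         lens[[1L]])
  }
  if (is.null(weights)) weights <- rep(1 / length(rows), length(rows))
  weights <- weights / sum(weights)
  structure(list(ids = names(rows), rows = rows,
                 n_columns = unname(lens[[1L]]),
                 reference_id = reference_id,
                 weights = setNames(weights, names(rows))),
            class = "divcons_alignment")
}

#' @export
print.divcons_alignment <- function(x, ...) {
  cat("divcons alignment:", length(x$rows), "sequences x", x$n_columns,
      "columns", if (!is.null(x$reference_id))
        paste0(" (reference: ", x$reference_id, ")"), "\n")
  invisible(x)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), ""))
}

# residue frequency profile (20 x L); gaps and X contribute nothing, columns
# normalised by the number of rows so gappy columns carry less weight.
residue_profile <- function(mat) {
  f <- matrix(0, length(.divcons_amino_acids), ncol(mat),
              dimnames = list(.divcons_amino_acids, NULL))
  for (a in .divcons_amino_acids) f[a, ] <- colMeans(mat == a)
  f
}

#' Progressive multiple alignment along a guide tree
#'
#' Basic progressive aligner: sequences are merged bottom-up along the guide
#' tree by profile-profile Needleman-Wunsch with affine gaps, scoring column
#' pairs by the expected substitution score between their residue frequency
#' profiles.  Gap columns, once inserted, are never removed ("once a gap,
#' always a gap").  The default gap opening (15) is stiffer than the pairwise
#' local-scoring default: expected profile-profile column scores are weaker
#' than single-sequence scores, and a softer penalty lets spurious gaps
#' proliferate when diverged profiles are merged.  Intended for desk-scale
#' families; larger families should be aligned externally and read with
#' [read_alignment()].
#'
#' @param records A `divcons_seqs` table.
#' @param tree Guide tree from [neighbor_joining()]; leaf labels must equal
#'   the record ids exactly.
#' @param matrix,gap_open,gap_extend Scoring parameters.
#' @param reference_id Optional id recorded as the family reference.
#' @return A `divcons_alignment` with Henikoff sequence weights.
#' @export
progressive_align <- function(records, tree, matrix = "BLOSUM62",
                              gap_open = 15, gap_extend = 1,
                              reference_id = NULL) {
  check_gap_params(gap_open, gap_extend)
  records <- as_seqs(records)
  extra_tree <- setdiff(tree$tip.label, records$id)
  extra_rec <- setdiff(records$id, tree$tip.label)
  if (length(extra_tree) || length(extra_rec))
    stop("guide tree and records disagree; only in tree: {",
         paste(extra_tree, collapse = ","), "}, only in records: {",
         paste(extra_rec, collapse = ","), "}")
  m <- substitution_matrix(matrix)[.divcons_amino_acids, .divcons_amino_acids]
  seqs <- setNames(records$sequence, records$id)

  n_tips <- length(tree$tip.label)
  profiles <- vector("list", n_tips + tree$Nnode)
  for (i in seq_len(n_tips)) {
    mat <- matrix(strsplit(seqs[[tree$tip.label[[i]]]], "")[[1L]], nrow = 1)
    rownames(mat) <- tree$tip.label[[i]]
    profiles[[i]] <- mat
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(tree$edge[, 1L])
  for (p in parents) {
    children <- tree$edge[tree$edge[, 1L] == p, 2L]
    merged <- profiles[[children[[1L]]]]
    for (ch in children[-1L])
      merged <- merge_profiles(merged, profiles[[ch]], m, gap_open, gap_extend)
    profiles[[p]] <- merged
    profiles[children] <- list(NULL)
  }
  root <- n_tips + 1L
  mat <- profiles[[root]]
  rows <- setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
  rows <- rows[records$id]  # restore input order
  aln <- new_alignment(rows, reference_id = reference_id)
  aln$weights <- henikoff_weights(aln)
  stopifnot(identical(unname(gsub("-", "", aln$rows)),
                      unname(records$sequence)))
  aln
}

merge_profiles <- function(a, b, m, gap_open, gap_extend) {
  fa <- residue_profile(a)
  fb <- residue_profile(b)
  s <- crossprod(fa, m %*% fb)
  ops <- .nw_affine_path(s, gap_open, gap_extend)
  la <- ncol(a); lb <- ncol(b); lo <- length(ops)
  out <- matrix("-", nrow(a) + nrow(b), lo,
                dimnames = list(c(rownames(a), rownames(b)), NULL))
  out[seq_len(nrow(a)), ops %in% c(0L, 1L)] <- a
  out[nrow(a) + seq_len(nrow(b)), ops %in% c(0L, 2L)] <- b
  out
}

#' Read a pre-computed multiple alignment from aligned FASTA
#'
#' Rows must have identical gapped lengths.  Sequence weights are provisional
#' (uniform); [conservation_profile()] replaces them with Henikoff weights by
#' default.
#'
#' @param path Aligned FASTA file; `.` gap characters are normalised to `-`.
#' @param reference_id Optional family reference id.
#' @return A `divcons_alignment`.
#' @export
read_alignment <- function(path, reference_id = NULL) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1L]])
  rows <- gsub("\\.", "-", toupper(as.character(raw)))
  rows <- sub("\\*+$", "", rows)
  validate_residues(gsub("-", "", rows), ids)
  new_alignment(setNames(rows, ids), reference_id = reference_id)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln A `divcons_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(new_divcons_seqs(aln$ids, "", unname(aln$rows[aln$ids])), path)
}

#' Recover the ungapped input sequences from an alignment
#'
#' @param aln A `divcons_alignment`.
#' @return A `divcons_seqs` table.
#' @export
ungap_alignment <- function(aln) {
  new_divcons_seqs(aln$ids, "", unname(gsub("-", "", aln$rows[aln$ids])))
}
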