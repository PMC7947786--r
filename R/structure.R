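new_structure <- function(aa, xyz, label = NULL, chain = "A") {
  n <- length(aa)
  stopifnot(nrow(xyz) == n)
  if (is.null(label)) label <- as.character(seq_len(n))
  out <- data.frame(residue_number = seq_len(n), aa = aa,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("divcons_structure", "data.frame")
  attr(out, "chain") <- chain
  out
}

structure_coords <- function(s) as.matrix(s[, c("x", "y", "z")])

structure_sequence <- function(s) paste(s$aa, collapse = "")

#' @export
print.divcons_structure <- function(x, ...) {
  cat("divcons structure: chain", attr(x, "chain"), "-", nrow(x),
      "CA residues\n")
  invisible(x)
}

#' Read a CA-trace structure model from a PDB file
#'
#' Keeps one entry per residue carrying a CA `ATOM` record in the requested
#' chain (HETATM ignored; alternate locations other than blank/`A` dropped;
#' only the first MODEL of multi-model files is read).  Residues are kept in
#' file order and renumbered sequentially from 1 -- all divcons arithmetic
#' (residue pairs, active-site lists) uses this sequential numbering, which
#' matches the 1-based ungapped position in the structure's sequence.  The
#' original author residue number plus insertion code is retained in the
#' `label` column.
#'
#' Residues of the chain that lack a CA atom are omitted with a warning.
#'
#' @param path PDB-format file.
#' @param chain Chain identifier; default the first chain in the file.
#' @return A `divcons_structure`: data.frame with `residue_number`, `aa`
#'   (one-letter), `x`, `y`, `z` (angstrom) and `label`.
#' @export
read_structure <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)
  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[[1L]]
  if (!chain %in% chains)
    stop("chain '", chain, "' not present in ", path,
         "; available chains: ", paste(chains, collapse = ", "))
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  atoms <- atoms[is.na(atoms$alt) | atoms$alt %in% c("", "A"), , drop = FALSE]
  res_key <- paste(atoms$resno, ifelse(is.na(atoms$insert), "", atoms$insert))
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms in chain ", chain, " of ", path)
  ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
  n_missing <- length(unique(res_key)) - nrow(ca)
  if (n_missing > 0L)
    warning(n_missing, " residue(s) without a CA atom omitted from ", path)
  if (any(!is.finite(as.matrix(ca[, c("x", "y", "z")]))))
    stop("non-finite CA coordinates in ", path)
  aa <- bio3d::aa321(ca$resid)
  aa[is.na(aa) | !aa %in% c(.divcons_amino_acids, "X")] <- "X"
  label <- paste0(ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  new_structure(aa, as.matrix(ca[, c("x", "y", "z")]), label = label,
                chain = chain)
}

#' Write a CA-trace structure model in PDB format
#'
#' @param s A `divcons_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  aa3 <- bio3d::aa123(s$aa)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    s$residue_number, aa3, attr(s, "chain"), s$residue_number,
    s$x, s$y, s$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Kabsch least-squares superposition of two matched point sets
#'
#' Finds the proper rotation (determinant +1; reflections are corrected by a
#' singular-vector sign flip) and translation minimising the RMSD between
#' `coords_a`, transformed, and `coords_b`, assuming row i of A corresponds
#' to row i of B.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices, n >= 3.
#' @return A list of class `divcons_superposition`: `rotation` (3x3, applied
#'   on the right of row vectors), `translation` (length-3), `rmsd`.  The
#'   transform maps A onto B: `sweep(coords_a %*% rotation, 2, translation,
#'   "+")`.
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b))
    stop("coordinate sets must have equal numbers of points")
  n <- nrow(coords_a)
  if (n < 3L) stop("need at least 3 points for a superposition")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  a0 <- sweep(coords_a, 2, ca); b0 <- sweep(coords_b, 2, cb)
  h <- crossprod(a0, b0)
  s <- svd(h)
  if (s$d[[2L]] < 1e-9 * max(s$d[[1L]], 1))
    stop("rank-deficient point set (collinear points); superposition undefined")
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  translation <- as.numeric(cb - ca %*% rot)
  moved <- sweep(a0 %*% rot, 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((moved - coords_b)^2)))
  structure(list(rotation = rot, translation = translation, rmsd = rmsd),
            class = "divcons_superposition")
}

#' @export
print.divcons_superposition <- function(x, ...) {
  cat("divcons superposition: rmsd", format(x$rmsd, digits = 4), "A",
      if (!is.null(x$pairs)) paste("over", nrow(x$pairs), "pairs"), "\n")
  invisible(x)
}

apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, "+")
}

#' Initial residue correspondence from a global sequence alignment
#'
#' Aligns the amino-acid strings of the two structures by global
#' Needleman-Wunsch and returns the aligned non-gap residue pairs -- the seed
#' for [iterative_structural_align()].
#'
#' @param model_a,model_b `divcons_structure` objects.
#' @param matrix,gap_open,gap_extend Scoring parameters.
#' @return Integer matrix with columns `res_a`, `res_b` (sequential residue
#'   numbers), strictly increasing in both.
#' @export
seed_pairs <- function(model_a, model_b, matrix = "BLOSUM62", gap_open = 11,
                       gap_extend = 1) {
  m <- substitution_matrix(matrix)
  a <- c(strsplit(structure_sequence(model_a), "")[[1L]])
  b <- c(strsplit(structure_sequence(model_b), "")[[1L]])
  s <- m[a, b, drop = FALSE]
  ops <- .nw_affine_path(s, gap_open, gap_extend)
  ia <- cumsum(ops %in% c(0L, 1L))
  ib <- cumsum(ops %in% c(0L, 2L))
  keep <- ops == 0L
  cbind(res_a = ia[keep], res_b = ib[keep])
}

#' Iterative structure-based residue pairing
#'
#' Starting from sequence-seeded pairs, alternates (1) Kabsch superposition
#' on the current pairs with (2) colinear re-pairing by dynamic programming
#' on the inter-CA distance matrix, keeping only pairs closer than `cutoff`
#' after superposition, until the pair set is stable or `max_iter` is
#' reached.  The DP maximises the number of pairs, breaking ties by minimal
#' total distance, so the result is always a valid sequence-alignment-shaped
#' (monotone) correspondence.  Deterministic given identical inputs.
#'
#' @param model_a,model_b `divcons_structure` objects.
#' @param cutoff Distance cutoff in angstrom for re-pairing (default 5).
#' @param max_iter Maximum refinement iterations (default 20).
#' @param matrix,gap_open,gap_extend Seed-alignment scoring parameters.
#' @return A `divcons_superposition` with an additional `pairs` element
#'   (matrix of sequential residue-number pairs) and `iterations` count.
#' @export
iterative_structural_align <- function(model_a, model_b, cutoff = 5,
                                       max_iter = 20, matrix = "BLOSUM62",
                                       gap_open = 11, gap_extend = 1) {
  if (cutoff <= 0) stop("cutoff must be positive")
  xa <- structure_coords(model_a)
  xb <- structure_coords(model_b)
  na <- nrow(xa); nb <- nrow(xb)

  refine <- function(pairs) {
    if (nrow(pairs) < 3L) return(NULL)
    sp <- NULL
    for (iter in seq_len(max_iter)) {
      sp <- kabsch(xa[pairs[, 1L], , drop = FALSE],
                   xb[pairs[, 2L], , drop = FALSE])
      moved <- apply_superposition(xa, sp)
      d2 <- outer(rowSums(moved^2), rowSums(xb^2), "+") -
        2 * tcrossprod(moved, xb)
      d <- sqrt(pmax(d2, 0))
      new_pairs <- .monotone_pairs(d, cutoff)
      colnames(new_pairs) <- c("res_a", "res_b")
      if (nrow(new_pairs) < 3L) return(NULL)
      converged <- nrow(new_pairs) == nrow(pairs) && all(new_pairs == pairs)
      pairs <- new_pairs
      if (converged) break
    }
    sp <- kabsch(xa[pairs[, 1L], , drop = FALSE],
                 xb[pairs[, 2L], , drop = FALSE])
    sp$pairs <- pairs
    sp$iterations <- iter
    sp
  }

  # Deterministic multi-start: the greedy refinement can lock into a shifted
  # residue register when the sequence seed is poor (distant paralogs), so in
  # addition to the sequence-alignment seed a fan of diagonal-register seeds
  # is refined and the superposition pairing the most residues (ties: lowest
  # rmsd) is kept.
  seeds <- list(seed_pairs(model_a, model_b, matrix, gap_open, gap_extend))
  for (k in seq(-12L, 12L, by = 3L)) {
    i <- seq_len(min(na, nb - k, na + k, nb))
    i <- i[i >= 1L - k]
    if (length(i) >= 3L)
      seeds[[length(seeds) + 1L]] <- cbind(res_a = i, res_b = i + k)
  }
  best <- NULL
  for (seed in seeds) {
    cand <- tryCatch(refine(seed), error = function(e) NULL)
    if (is.null(cand)) next
    if (is.null(best) || nrow(cand$pairs) > nrow(best$pairs) ||
        (nrow(cand$pairs) == nrow(best$pairs) && cand$rmsd < best$rmsd))
      best <- cand
  }
  if (is.null(best))
    stop("structures too divergent at cutoff ", cutoff,
         " A: fewer than 3 residue pairs survive from any seed")
  best$cutoff <- cutoff
  best
}

#' Lift a residue correspondence to alignment columns
#'
#' Converts structure-derived residue pairs of the two family references into
#' a column-to-column map between the family alignments.  Columns without a
#' partner (including columns where a reference is gapped) are reported as
#' unmatched -- for paralog pairs like Dop/PafA these capture
#' insertion-specific regions such as the Dop-loop.
#'
#' @param pairs Matrix of residue pairs (`res_a`, `res_b`) in sequential
#'   numbering of the reference structures, e.g. from
#'   [iterative_structural_align()].
#' @param alignment_a,alignment_b `divcons_alignment` objects whose
#'   `reference_id` rows are the sequences of the two structures.
#' @param provenance Recorded origin of the map.
#' @return A list of class `divcons_map`: `matched` (data.frame `column_a`,
#'   `column_b`, `res_a`, `res_b`), `unmatched_a`, `unmatched_b` (column
#'   indices), `provenance`.
#' @export
lift_to_columns <- function(pairs, alignment_a, alignment_b,
                            provenance = "structural") {
  col_a <- match(seq_len(max(pairs[, 1L])), reference_positions(alignment_a))
  col_b <- match(seq_len(max(pairs[, 2L])), reference_positions(alignment_b))
  if (anyNA(col_a[pairs[, 1L]]))
    stop("reference residue ", pairs[which(is.na(col_a[pairs[, 1L]]))[1L], 1L],
         " of family A is missing from its alignment reference row")
  if (anyNA(col_b[pairs[, 2L]]))
    stop("reference residue ", pairs[which(is.na(col_b[pairs[, 2L]]))[1L], 2L],
         " of family B is missing from its alignment reference row")
  matched <- data.frame(column_a = col_a[pairs[, 1L]],
                        column_b = col_b[pairs[, 2L]],
                        res_a = pairs[, 1L], res_b = pairs[, 2L])
  stopifnot(!is.unsorted(matched$column_a, strictly = TRUE),
            !is.unsorted(matched$column_b, strictly = TRUE))
  structure(list(matched = matched,
                 unmatched_a = setdiff(seq_len(alignment_a$n_columns),
                                       matched$column_a),
                 unmatched_b = setdiff(seq_len(alignment_b$n_columns),
                                       matched$column_b),
                 provenance = provenance),
            class = "divcons_map")
}

#' @export
print.divcons_map <- function(x, ...) {
  cat("divcons cross-family map (", x$provenance, "): ",
      nrow(x$matched), " matched column pairs, ",
      length(x$unmatched_a), "/", length(x$unmatched_b),
      " unmatched in A/B\n", sep = "")
  invisible(x)
}

#' Write a cross-family column map as TSV
#'
#' @param map A `divcons_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  matched <- cbind(map$matched, status = "matched")
  un_a <- if (length(map$unmatched_a))
    data.frame(column_a = map$unmatched_a, column_b = NA, res_a = NA,
               res_b = NA, status = "unmatched_a") else NULL
  un_b <- if (length(map$unmatched_b))
    data.frame(column_a = NA, column_b = map$unmatched_b, res_a = NA,
               res_b = NA, status = "unmatched_b") else NULL
  write.table(rbind(matched, un_a, un_b), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
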