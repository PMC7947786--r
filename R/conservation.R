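#' Henikoff-Henikoff position-based sequence weights
#'
#' Each column distributes one unit of weight among its rows: a row showing
#' symbol `s` in a column with `r` distinct symbols, `c` of them equal to
#' `s`, receives `1/(r*c)`.  Gap characters count as a 21st symbol.  Row
#' weights are the per-column contributions summed and normalised to 1, so
#' divergent sequences receive more weight than redundant ones -- a cheap,
#' deterministic proxy for down-weighting phylogenetically related rows.
#'
#' @param aln A `divcons_alignment`.
#' @return Named numeric weights summing to 1.
#' @export
henikoff_weights <- function(aln) {
  mat <- alignment_matrix(aln)
  n <- nrow(mat)
  w <- numeric(n)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    counts <- table(col)
    r <- length(counts)
    w <- w + 1 / (r * as.numeric(counts[col]))
  }
  setNames(w / sum(w), aln$ids)
}

# Jensen-Shannon divergence (base-2 logs) between probability vectors.
jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * (log2(x[i]) - log2(y[i])))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

resolve_background <- function(background) {
  if (is.character(background)) {
    background <- match.arg(tolower(background), c("blosum62", "uniform"))
    background <- if (background == "uniform")
      setNames(rep(1 / 20, 20), .divcons_amino_acids)
    else .divcons_blosum62_bg
  }
  if (length(background) != 20L)
    stop("background must name 'blosum62'/'uniform' or be a 20-vector")
  if (is.null(names(background))) names(background) <- .divcons_amino_acids
  background <- background[.divcons_amino_acids]
  if (any(is.na(background)) || any(background <= 0))
    stop("background frequencies must be positive for all 20 amino acids")
  background / sum(background)
}

#' Per-column conservation scores for a family alignment
#'
#' For every column the weighted residue frequency vector `p` (gaps and `X`
#' excluded, renormalised) is compared with the background distribution `q`
#' by normalised Jensen-Shannon divergence, and penalised by the gap
#' fraction:
#'
#' `score = (1 - gap_fraction) * JSD(p, q) / max_a JSD(delta_a, q)`
#'
#' The normaliser is the largest divergence any single-residue column can
#' attain against `q` (JSD is convex in `p`, so point masses are extremal),
#' which puts scores in `[0, 1]`: an invariant gap-free column scores 1
#' against a uniform background, and a column whose frequencies equal the
#' background scores 0.  All-gap columns score 0 with consensus `-`.
#'
#' @param aln A `divcons_alignment`.
#' @param weights Sequence weights; default the alignment's stored weights.
#' @param background `"blosum62"` (default), `"uniform"`, or a positive
#'   20-vector of amino-acid frequencies.
#' @return A `data.frame` of class `divcons_profile` with columns `column`,
#'   `reference_position` (1-based ungapped position in the reference row, NA
#'   where the reference is gapped, NA throughout if no reference id is set),
#'   `score`, `grade` (NA until [grade_conservation()]), `gap_fraction`,
#'   `consensus`.
#' @export
column_conservation <- function(aln, weights = aln$weights,
                                background = "blosum62") {
  q <- resolve_background(background)
  mat <- alignment_matrix(aln)
  weights <- weights / sum(weights)
  max_jsd <- max(vapply(seq_along(q), function(i) {
    d <- setNames(numeric(20), names(q)); d[i] <- 1
    jsd(d, q)
  }, 0))
  ncols <- ncol(mat)
  score <- numeric(ncols); gapf <- numeric(ncols)
  consensus <- character(ncols)
  for (j in seq_len(ncols)) {
    col <- mat[, j]
    gapf[j] <- sum(weights[col == "-"])
    keep <- col %in% .divcons_amino_acids
    if (!any(keep)) {
      score[j] <- 0; consensus[j] <- "-"
      next
    }
    p <- vapply(split(weights[keep], factor(col[keep],
                                            levels = .divcons_amino_acids)),
                sum, 0)
    p <- p / sum(p)
    score[j] <- (1 - gapf[j]) * jsd(p, q) / max_jsd
    top <- names(p)[p == max(p)]
    consensus[j] <- sort(top)[[1L]]  # ties broken alphabetically
  }
  out <- data.frame(column = seq_len(ncols),
                    reference_position = reference_positions(aln),
                    score = score, grade = NA_integer_,
                    gap_fraction = gapf, consensus = consensus,
                    stringsAsFactors = FALSE)
  class(out) <- c("divcons_profile", "data.frame")
  attr(out, "reference_id") <- aln$reference_id
  out
}

reference_positions <- function(aln) {
  if (is.null(aln$reference_id)) return(rep(NA_integer_, aln$n_columns))
  if (!aln$reference_id %in% aln$ids)
    stop("reference id '", aln$reference_id, "' is not an alignment row")
  row <- strsplit(aln$rows[[aln$reference_id]], "")[[1L]]
  pos <- cumsum(row != "-")
  pos[row == "-"] <- NA_integer_
  as.integer(pos)
}

#' Bin conservation scores into grades 1-9
#'
#' Columns with `gap_fraction <= gap_threshold` are ranked by score and
#' binned equal-frequency into 9 grades, grade 9 holding the most conserved
#' ninth of the columns (a non-empty top bin regardless of the score
#' distribution).  Tied scores share the higher grade.  Columns gappier than
#' the threshold are deemed unreliable and receive grade 1.
#'
#' @param profile A `divcons_profile` with scores computed.
#' @param gap_threshold Maximum gap fraction for a column to be graded
#'   (default 0.5).
#' @return The profile with the `grade` column filled.
#' @export
grade_conservation <- function(profile, gap_threshold = 0.5) {
  stopifnot(inherits(profile, "divcons_profile"))
  eligible <- profile$gap_fraction <= gap_threshold
  grades <- rep(1L, nrow(profile))
  n <- sum(eligible)
  if (n > 0L) {
    s <- profile$score[eligible]
    rank_desc <- rank(-s, ties.method = "min")
    grades[eligible] <- as.integer(9L - floor((rank_desc - 1) * 9 / n))
  }
  profile$grade <- grades
  profile
}

#' Full conservation profile of a family alignment
#'
#' Convenience wrapper: Henikoff weights, column scores, grades.
#'
#' @inheritParams column_conservation
#' @inheritParams grade_conservation
#' @return A graded `divcons_profile`.
#' @export
conservation_profile <- function(aln, background = "blosum62",
                                 gap_threshold = 0.5) {
  w <- henikoff_weights(aln)
  grade_conservation(column_conservation(aln, weights = w,
                                         background = background),
                     gap_threshold = gap_threshold)
}

#' Write a conservation profile as TSV
#'
#' @param profile A `divcons_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
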