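.candidate_classes <- c("unique_A", "unique_B", "differently_conserved",
                        "indel")

#' Classify mapped alignment positions by differential conservation
#'
#' Every matched column pair is assigned exactly one class from its two
#' conservation grades (9 = maximal) and consensus residues:
#'
#' * `shared_identical` -- grade 9 in both families, same consensus residue;
#' * `differently_conserved` -- grade 9 in both, different consensus;
#' * `unique_A` / `unique_B` -- grade 9 on one side, grade at most
#'   `low_cutoff` (or no partner column) on the other;
#' * `indel` -- an unmatched column that is maximally conserved on its own
#'   side (insertion-specific conservation, e.g. a family-specific loop);
#' * `unconserved` -- everything else.
#'
#' `low_cutoff` is the highest grade still counted as "not conserved" on the
#' partner side.  The default 8 means any partner below the maximal grade,
#' matching how selected positions behave in the Dop/PafA analysis, where
#' uniquely conserved positions have partner grades of 7-8.
#'
#' @param profile_a,profile_b Graded `divcons_profile` objects of the two
#'   families.
#' @param map A `divcons_map` between the two alignments.
#' @param low_cutoff Highest grade counted as unconserved (default 8).
#' @param alignment_a,alignment_b Optional `divcons_alignment` objects; when
#'   given, `aa_a`/`aa_b` carry the actual reference-row residue at each
#'   column instead of the family consensus.
#' @return A `data.frame` of class `divcons_positions`, one row per matched
#'   pair or unmatched column, with columns `column_a`, `column_b`, `res_a`,
#'   `aa_a`, `res_b`, `aa_b`, `grade_a`, `grade_b`, `consensus_a`,
#'   `consensus_b`, `class`, `distance` (NA until
#'   [active_site_distances()]), `selected`.
#' @export
classify_positions <- function(profile_a, profile_b, map, low_cutoff = 8,
                               alignment_a = NULL, alignment_b = NULL) {
  stopifnot(inherits(map, "divcons_map"))
  if (anyNA(profile_a$grade) || anyNA(profile_b$grade))
    stop("profiles must be graded (see grade_conservation) before classification")
  if (low_cutoff < 1 || low_cutoff > 8) stop("low_cutoff must be in 1..8")
  m <- map$matched
  ga <- profile_a$grade[m$column_a]; gb <- profile_b$grade[m$column_b]
  ca <- profile_a$consensus[m$column_a]; cb <- profile_b$consensus[m$column_b]
  ref_letter <- function(aln, cols) {
    if (is.null(aln)) return(NULL)
    strsplit(aln$rows[[aln$reference_id]], "")[[1L]][cols]
  }
  aa_a_ref <- ref_letter(alignment_a, m$column_a)
  aa_b_ref <- ref_letter(alignment_b, m$column_b)
  cls <- rep("unconserved", nrow(m))
  cls[ga == 9L & gb == 9L & ca == cb] <- "shared_identical"
  cls[ga == 9L & gb == 9L & ca != cb] <- "differently_conserved"
  cls[ga == 9L & gb <= low_cutoff] <- "unique_A"
  cls[gb == 9L & ga <= low_cutoff] <- "unique_B"
  matched <- data.frame(
    column_a = m$column_a, column_b = m$column_b,
    res_a = m$res_a, aa_a = if (is.null(aa_a_ref)) ca else aa_a_ref,
    res_b = m$res_b, aa_b = if (is.null(aa_b_ref)) cb else aa_b_ref,
    grade_a = ga, grade_b = gb, consensus_a = ca, consensus_b = cb,
    class = cls, distance = NA_real_, selected = FALSE,
    stringsAsFactors = FALSE)
  un_row <- function(cols, profile, side) {
    if (!length(cols)) return(NULL)
    g <- profile$grade[cols]
    data.frame(
      column_a = if (side == "A") cols else NA_integer_,
      column_b = if (side == "B") cols else NA_integer_,
      res_a = if (side == "A") profile$reference_position[cols]
              else NA_integer_,
      aa_a = if (side == "A") profile$consensus[cols] else NA_character_,
      res_b = if (side == "B") profile$reference_position[cols]
              else NA_integer_,
      aa_b = if (side == "B") profile$consensus[cols] else NA_character_,
      grade_a = if (side == "A") g else NA_integer_,
      grade_b = if (side == "B") g else NA_integer_,
      consensus_a = if (side == "A") profile$consensus[cols]
                    else NA_character_,
      consensus_b = if (side == "B") profile$consensus[cols]
                    else NA_character_,
      class = ifelse(g == 9L, "indel", "unconserved"),
      distance = NA_real_, selected = FALSE, stringsAsFactors = FALSE)
  }
  out <- rbind(matched,
               un_row(map$unmatched_a, profile_a, "A"),
               un_row(map$unmatched_b, profile_b, "B"))
  out <- out[order(is.na(out$column_a), out$column_a, out$column_b), ]
  rownames(out) <- NULL
  class(out) <- c("divcons_positions", "data.frame")
  attr(out, "low_cutoff") <- low_cutoff
  out
}

#' Minimum CA distance from one residue to an active-site residue set
#'
#' @param structure A `divcons_structure`.
#' @param active_site Integer vector of sequential residue numbers defining
#'   the active site.
#' @param residue Sequential residue number to measure from.
#' @return Minimum CA-CA Euclidean distance in angstrom.
#' @export
distance_to_active_site <- function(structure, active_site, residue) {
  missing <- setdiff(active_site, structure$residue_number)
  if (length(missing))
    stop("active-site residue ", missing[[1L]], " absent from structure")
  if (!residue %in% structure$residue_number)
    stop("residue ", residue, " absent from structure")
  xyz <- structure_coords(structure)
  d <- sqrt(colSums((t(xyz[active_site, , drop = FALSE]) -
                       xyz[residue, ])^2))
  min(d)
}

#' Fill active-site distances for classified positions
#'
#' Computes, for every record with a reference residue on the active-site
#' structure's side, the minimum CA-CA distance to the active-site residues.
#' Records on the opposite side only (e.g. insertion columns of the other
#' family) inherit the smallest distance of their flanking matched columns --
#' an inserted segment sits near its flanks -- and records with no computable
#' distance keep `NA`.
#'
#' @param records A `divcons_positions` table.
#' @param structure The `divcons_structure` carrying the active site.
#' @param active_site Integer vector of sequential residue numbers.
#' @param side `"A"` or `"B"`: which family the structure belongs to.
#' @return The records with the `distance` column filled.
#' @export
active_site_distances <- function(records, structure, active_site,
                                  side = c("A", "B")) {
  side <- match.arg(side)
  missing <- setdiff(active_site, structure$residue_number)
  if (length(missing))
    stop("active-site residue ", missing[[1L]], " absent from structure")
  xyz <- structure_coords(structure)
  site <- xyz[active_site, , drop = FALSE]
  res_col <- if (side == "A") "res_a" else "res_b"
  all_d <- vapply(seq_len(nrow(xyz)), function(i)
    min(sqrt(rowSums(sweep(site, 2, xyz[i, ])^2))), 0)
  res <- records[[res_col]]
  ok <- !is.na(res) & res >= 1 & res <= nrow(xyz)
  records$distance[ok] <- all_d[res[ok]]
  # flanking fallback for rows without a residue on the active-site side
  need <- which(!ok)
  if (length(need)) {
    have <- which(ok)
    for (i in need) {
      before <- have[have < i]; after <- have[have > i]
      cand <- c(if (length(before)) records$distance[max(before)],
                if (length(after)) records$distance[min(after)])
      if (length(cand)) records$distance[i] <- min(cand)
    }
  }
  records
}

#' Flag candidate positions within reach of the active site
#'
#' A record is selected when its class is a candidate class (`unique_A`,
#' `unique_B`, `differently_conserved`, `indel`) and its minimum active-site
#' distance is at most `distance_threshold` (default 20 angstrom, the
#' distance beyond which uniquely conserved positions are unlikely to touch
#' catalysis).  Positions listed in `forced` (family-A reference residue
#' numbers) are selected regardless of class -- a manual override for e.g.
#' secondary-structure-preserving mutations.
#'
#' @param records A `divcons_positions` table with distances filled.
#' @param distance_threshold Maximum distance in angstrom (default 20).
#' @param forced Optional integer vector of `res_a` positions always
#'   selected.
#' @return The records with `selected` flags; a summary of counts per class
#'   before/after filtering is attached as attribute `"summary"`.
#' @export
select_candidates <- function(records, distance_threshold = 20,
                              forced = integer()) {
  is_cand <- records$class %in% .candidate_classes
  records$selected <- is_cand & !is.na(records$distance) &
    records$distance <= distance_threshold
  if (length(forced))
    records$selected <- records$selected |
      (!is.na(records$res_a) & records$res_a %in% forced)
  counts <- function(x) table(factor(x, levels = c("shared_identical",
                                                   .candidate_classes,
                                                   "unconserved")))
  attr(records, "summary") <- list(
    before = as.list(counts(records$class)),
    selected = as.list(counts(records$class[records$selected])),
    distance_threshold = distance_threshold,
    n_candidates = sum(is_cand),
    n_selected = sum(records$selected))
  records
}

#' Candidate position report
#'
#' Deterministic table of all classified positions, sorted by family-A
#' reference residue number (records without one sort last by family-B
#' column), optionally written as TSV.
#'
#' @param records A `divcons_positions` table.
#' @param path Optional output TSV path.
#' @param name_a,name_b Family display names used in the header comment.
#' @return The sorted `data.frame` (invisibly if `path` is given).
#' @export
candidate_report <- function(records, path = NULL, name_a = "A",
                             name_b = "B") {
  ord <- order(is.na(records$res_a), records$res_a, records$column_b)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(paste0("# divcons candidate report; family A = ", name_a,
                      ", family B = ", name_b), con)
    close(con)
    suppressWarnings(
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  append = TRUE))
    return(invisible(out))
  }
  out
}

#' @export
print.divcons_positions <- function(x, ...) {
  cat("divcons position classification:", nrow(x), "records\n")
  print(table(x$class))
  if (any(x$selected)) cat("selected:", sum(x$selected), "\n")
  invisible(x)
}
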