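#' Create a table of mutation units
#'
#' A mutation unit is a named edit of the wild-type (base) sequence:
#' a `substitution` (one residue), a `deletion` (inclusive range
#' `start`-`end`), an `insertion` (replacement string inserted *after*
#' position `start`), or a `segment_swap` (range replaced by a string).
#' `base_res`, when non-empty, records the expected wild-type residue(s) at
#' the anchor and is checked at application time (a coordinate-drift guard).
#'
#' @param name Unit names, conventionally `"S27A"`, `"ins94V"`,
#'   `"del43-79"`.
#' @param kind One of `"substitution"`, `"insertion"`, `"deletion"`,
#'   `"segment_swap"`.
#' @param start,end 1-based anchor positions on the base sequence
#'   (`end = start` for substitutions and insertions).
#' @param replacement Replacement amino acids (empty for deletions).
#' @param base_res Expected base residue(s): single letter for
#'   substitutions, first+last letters for deletions/segment swaps, empty to
#'   skip the check.
#' @param segment Optional segment label for combinatorial grouping.
#' @return A `data.frame` of class `divcons_units`.
#' @export
mutation_units <- function(name, kind, start, end = start, replacement = "",
                           base_res = "", segment = NA_character_) {
  if (length(name) == 0L) {
    u <- data.frame(name = character(0), kind = character(0),
                    start = integer(0), end = integer(0),
                    replacement = character(0), base_res = character(0),
                    segment = character(0), stringsAsFactors = FALSE)
    class(u) <- c("divcons_units", "data.frame")
    return(u)
  }
  u <- data.frame(name = name, kind = kind, start = as.integer(start),
                  end = as.integer(end), replacement = toupper(replacement),
                  base_res = toupper(base_res), segment = segment,
                  stringsAsFactors = FALSE)
  validate_units(u)
  class(u) <- c("divcons_units", "data.frame")
  u
}

validate_units <- function(units, base = NULL) {
  kinds <- c("substitution", "insertion", "deletion", "segment_swap")
  bad <- setdiff(units$kind, kinds)
  if (length(bad)) stop("unknown mutation kind: ", bad[[1L]])
  if (any(units$start < 1L) || any(units$end < units$start))
    stop("invalid anchor range in unit ",
         units$name[units$start < 1L | units$end < units$start][1L])
  sub <- units$kind == "substitution"
  if (any(sub & (nchar(units$replacement) != 1L | units$end != units$start)))
    stop("substitutions must have a single anchor and single replacement: ",
         units$name[sub & (nchar(units$replacement) != 1L |
                             units$end != units$start)][1L])
  if (any(units$kind == "deletion" & nzchar(units$replacement)))
    stop("deletions must have an empty replacement")
  if (any(units$kind == "insertion" & !nzchar(units$replacement)))
    stop("insertions must have a non-empty replacement")
  # disjointness in base coordinates (insertions occupy the gap after start)
  if (nrow(units) > 1L) {
    ord <- order(units$start, units$end)
    s <- units$start[ord]; e <- units$end[ord]
    ins <- units$kind[ord] == "insertion"
    e2 <- ifelse(ins, s, e)  # insertions do not consume their anchor
    overlap <- which(s[-1L] <= e2[-length(e2)] &
                       !(ins[-1L] & s[-1L] == e2[-length(e2)]))
    if (length(overlap))
      stop("overlapping mutation units: ", units$name[ord][overlap[1L]],
           " and ", units$name[ord][overlap[1L] + 1L])
  }
  if (!is.null(base)) {
    n <- nchar(base)
    if (any(units$end > n))
      stop("unit ", units$name[units$end > n][1L],
           " is out of bounds for a base of length ", n)
    for (i in seq_len(nrow(units))) {
      br <- units$base_res[[i]]
      if (!nzchar(br)) next
      if (units$kind[[i]] == "substitution") {
        at <- substr(base, units$start[[i]], units$start[[i]])
        if (at != br)
          stop("unit ", units$name[[i]], ": base has '", at, "' at position ",
               units$start[[i]], ", expected '", br, "'")
      } else if (units$kind[[i]] %in% c("deletion", "segment_swap") &&
                 nchar(br) == 2L) {
        at <- paste0(substr(base, units$start[[i]], units$start[[i]]),
                     substr(base, units$end[[i]], units$end[[i]]))
        if (at != br)
          stop("unit ", units$name[[i]], ": base endpoints are '", at,
               "', expected '", br, "'")
      }
    }
  }
  invisible(TRUE)
}

#' Reciprocal mutation units from selected candidate positions
#'
#' Turns selected records of a [classify_positions()] table into mutation
#' units on one family's reference (base) sequence: substitutions replace the
#' base residue by the counterpart family's consensus (`"X<pos>Y"` naming);
#' contiguous runs of selected indel records on the base side become one
#' deletion unit; selected indel records on the counterpart side become an
#' insertion after the preceding matched base position.
#'
#' @param records A `divcons_positions` table with `selected` flags.
#' @param base The base (reference) sequence of the mutated family: a string
#'   or single-row `divcons_seqs`.
#' @param side `"A"` (default) or `"B"`: which family is mutated.
#' @return A `divcons_units` table.
#' @export
reciprocal_units <- function(records, base, side = c("A", "B")) {
  side <- match.arg(side)
  base <- as_single_seq(base, "base")$sequence
  if (side == "B") {
    records <- swap_sides(records)
  }
  sel <- records[records$selected, , drop = FALSE]
  if (!nrow(sel)) stop("no selected records to design from")
  subs <- sel[!is.na(sel$res_a) & !is.na(sel$res_b) &
                sel$class != "indel", , drop = FALSE]
  out <- NULL
  if (nrow(subs)) {
    if (any(subs$aa_a == subs$consensus_b)) {
      i <- which(subs$aa_a == subs$consensus_b)[1L]
      stop("position ", subs$res_a[[i]], " is not a candidate: base and ",
           "counterpart residue are both '", subs$aa_a[[i]], "'")
    }
    out <- mutation_units(
      name = paste0(subs$aa_a, subs$res_a, subs$consensus_b),
      kind = "substitution", start = subs$res_a,
      replacement = subs$consensus_b, base_res = subs$aa_a)
  }
  # deletions: indel records carried by the base side
  del <- sel[sel$class == "indel" & !is.na(sel$res_a), , drop = FALSE]
  if (nrow(del)) {
    runs <- split(del$res_a, cumsum(c(1L, diff(del$res_a) != 1L)))
    for (r in runs) {
      s <- min(r); e <- max(r)
      out <- rbind(out, mutation_units(
        name = paste0("del", s, "-", e), kind = "deletion",
        start = s, end = e,
        base_res = paste0(substr(base, s, s), substr(base, e, e))))
    }
  }
  # insertions: indel records carried by the counterpart side
  ins <- sel[sel$class == "indel" & is.na(sel$res_a), , drop = FALSE]
  if (nrow(ins)) {
    anchors <- vapply(ins$column_b, function(cb) {
      prev <- records$res_a[!is.na(records$res_a) & !is.na(records$column_b) &
                              records$column_b < cb]
      if (length(prev)) max(prev) else 0L
    }, 0L)
    runs <- split(seq_len(nrow(ins)), anchors)
    for (r in runs) {
      anchor <- anchors[r[[1L]]]
      if (anchor < 1L) stop("insertion has no preceding matched base position")
      repl <- paste(ins$consensus_b[r], collapse = "")
      out <- rbind(out, mutation_units(
        name = paste0("ins", anchor, repl), kind = "insertion",
        start = anchor, replacement = repl))
    }
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  validate_units(out, base)
  class(out) <- c("divcons_units", "data.frame")
  out
}

swap_sides <- function(records) {
  swap <- function(df, a, b) { tmp <- df[[a]]; df[[a]] <- df[[b]]; df[[b]] <- tmp; df }
  records <- swap(records, "column_a", "column_b")
  records <- swap(records, "res_a", "res_b")
  records <- swap(records, "aa_a", "aa_b")
  records <- swap(records, "grade_a", "grade_b")
  records <- swap(records, "consensus_a", "consensus_b")
  records$class[records$class == "unique_A"] <- ".tmp"
  records$class[records$class == "unique_B"] <- "unique_A"
  records$class[records$class == ".tmp"] <- "unique_B"
  records
}

#' Apply mutation units to a base sequence
#'
#' Units are applied in canonical descending-coordinate order so earlier
#' anchors stay valid; any stored `base_res` expectations are checked first.
#' Insertions insert after their anchor; deletions remove the inclusive
#' range.
#'
#' @param base Base sequence (string or single-row `divcons_seqs`).
#' @param units A `divcons_units` table (the mutant definition).
#' @param name Name recorded for the mutant.
#' @return A one-row `divcons_seqs` with the mutant sequence; the unit list
#'   is stored in the description.
#' @export
apply_mutations <- function(base, units, name = "mutant") {
  b <- as_single_seq(base, "base")$sequence
  validate_units(units, b)
  ord <- order(-units$start, -units$end)
  s <- b
  for (i in ord) {
    u <- units[i, ]
    s <- switch(u$kind,
      substitution = paste0(substr(s, 1L, u$start - 1L), u$replacement,
                            substr(s, u$start + 1L, nchar(s))),
      insertion = paste0(substr(s, 1L, u$start), u$replacement,
                         substr(s, u$start + 1L, nchar(s))),
      deletion = paste0(substr(s, 1L, u$start - 1L),
                        substr(s, u$end + 1L, nchar(s))),
      segment_swap = paste0(substr(s, 1L, u$start - 1L), u$replacement,
                            substr(s, u$end + 1L, nchar(s))))
  }
  new_divcons_seqs(name, paste(units$name, collapse = ","), s)
}

#' Invert mutation units onto mutant coordinates
#'
#' Builds the unit set that, applied to the mutant sequence, restores the
#' base sequence byte-for-byte: substitutions are swapped, deletions become
#' insertions of the removed residues and vice versa, and anchors are
#' recomputed for the mutant coordinate system.
#'
#' @param units A `divcons_units` table.
#' @param base The base sequence the units apply to.
#' @return A `divcons_units` table in mutant coordinates.
#' @export
invert_units <- function(units, base) {
  b <- as_single_seq(base, "base")$sequence
  validate_units(units, b)
  ord <- order(units$start, units$end)
  units <- units[ord, , drop = FALSE]
  offset <- 0L
  inv <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    removed <- switch(u$kind,
      substitution = substr(b, u$start, u$start),
      insertion = "",
      deletion = substr(b, u$start, u$end),
      segment_swap = substr(b, u$start, u$end))
    new_start <- u$start + offset
    inv[[i]] <- switch(u$kind,
      substitution = mutation_units(
        name = paste0(u$replacement, new_start, removed),
        kind = "substitution", start = new_start, replacement = removed,
        base_res = u$replacement),
      insertion = mutation_units(
        name = paste0("del", new_start + 1L,
                      "-", new_start + nchar(u$replacement)),
        kind = "deletion", start = new_start + 1L,
        end = new_start + nchar(u$replacement)),
      deletion = mutation_units(
        name = paste0("ins", new_start - 1L, removed),
        kind = "insertion", start = new_start - 1L, replacement = removed),
      segment_swap = mutation_units(
        name = paste0("swap", new_start), kind = "segment_swap",
        start = new_start, end = new_start + nchar(u$replacement) - 1L,
        replacement = removed))
    offset <- offset + nchar(u$replacement) -
      (if (u$kind == "insertion") 0L else u$end - u$start + 1L)
  }
  out <- do.call(rbind, inv)
  class(out) <- c("divcons_units", "data.frame")
  out
}

#' Enumerate a combinatorial segment library
#'
#' Every unit carries a segment label; the library contains one mutant per
#' on/off combination of the k segments (2^k members), in deterministic
#' binary-counting order with segments ordered by first appearance.  The
#' all-off member (the unmutated backbone) comes first and the all-on member
#' last.
#'
#' @param segments A `divcons_units` table with a non-NA `segment` column,
#'   or a named list of `divcons_units`.
#' @param backbone Optional `divcons_units` applied to every member (e.g. a
#'   constitutive loop deletion).
#' @return A list of class `divcons_library`; each element is a list with
#'   `name`, `on` (named logical over segments) and `units`.
#' @export
enumerate_library <- function(segments, backbone = NULL) {
  if (is.data.frame(segments)) {
    if (anyNA(segments$segment))
      stop("all units must carry a segment label")
    labels <- unique(segments$segment)
    segments <- lapply(labels, function(l)
      segments[segments$segment == l, , drop = FALSE])
    names(segments) <- labels
  }
  k <- length(segments)
  if (k > 20L) stop("library too large: ", k, " segments would give 2^", k,
                    " mutants")
  labels <- names(segments)
  members <- vector("list", 2^k)
  for (i in seq_len(2^k)) {
    bits <- as.logical(bitwAnd(i - 1L, bitwShiftL(1L, seq_len(k) - 1L)))
    units <- do.call(rbind, c(list(backbone), segments[bits]))
    if (is.null(units))
      units <- mutation_units(character(0), character(0), integer(0))
    class(units) <- c("divcons_units", "data.frame")
    nm <- sprintf("mut_%0*d", max(2L, nchar(2^k)), i)
    members[[i]] <- list(name = nm, on = setNames(bits, labels),
                         units = units)
  }
  structure(members, class = "divcons_library")
}

#' @export
print.divcons_library <- function(x, ...) {
  k <- length(x[[1L]]$on)
  cat("divcons combinatorial library:", length(x), "mutants over", k,
      "segments\n")
  invisible(x)
}

#' Single-reversion series of a multi-unit mutant
#'
#' One definition per removable unit group, each omitting exactly that group.
#' Units sharing a `group` value revert together (e.g. a substitution block
#' spanning an insertion); by default every unit is its own group.
#'
#' @param units A `divcons_units` table (the full mutant).
#' @param group Optional grouping vector (length = rows of `units`).
#' @return Named list of `divcons_units`, one per reversion; names are the
#'   reverted group's unit names.
#' @export
reversion_series <- function(units, group = NULL) {
  if (nrow(units) == 0L) stop("mutant has no units to revert")
  if (is.null(group)) group <- units$name
  stopifnot(length(group) == nrow(units))
  groups <- unique(group)
  out <- lapply(groups, function(g) {
    kept <- units[group != g, , drop = FALSE]
    class(kept) <- c("divcons_units", "data.frame")
    kept
  })
  names(out) <- vapply(groups, function(g)
    paste(units$name[group == g], collapse = "+"), "")
  out
}

#' Write mutant sequences as FASTA
#'
#' @param definitions A `divcons_library`, a named list of `divcons_units`,
#'   or a single `divcons_units` table.
#' @param base Base sequence.
#' @param path Output FASTA path.
#' @return The mutant `divcons_seqs` table, invisibly.
#' @export
write_mutants <- function(definitions, base, path) {
  if (inherits(definitions, "divcons_units"))
    definitions <- list(mutant = definitions)
  recs <- lapply(seq_along(definitions), function(i) {
    d <- definitions[[i]]
    if (is.list(d) && !is.data.frame(d))
      apply_mutations(base, d$units, name = d$name)
    else {
      nm <- names(definitions)[[i]]
      if (is.null(nm) || !nzchar(nm)) nm <- paste0("mutant_", i)
      apply_mutations(base, d, name = nm)
    }
  })
  recs <- do.call(rbind, recs)
  class(recs) <- c("divcons_seqs", "data.frame")
  write_fasta(recs, path)
  invisible(recs)
}
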