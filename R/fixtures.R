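#' Bundled Dop/PafA mutagenesis data
#'
#' The package ships the position set underlying the Dop-to-PafA change of
#' function: the residues selected for reciprocal mutagenesis between the
#' depupylase Dop and the Pup-ligase PafA (with conservation grades in both
#' families, M. smegmatis and structure-ortholog numbering, and notes marking
#' the Dop-loop deletion, the residues neighbouring the catalytic aspartate
#' and the alpha-loop region), the five-segment grouping of the supporting
#' mutations used for the 2^5 combinatorial library, and a synthetic
#' Dop-like base sequence with the documented wild-type residues planted at
#' their M. smegmatis positions (the filler residues are random; the real
#' ortholog sequence is not distributed with the package).
#'
#' @param which One of `"positions"`, `"segments"`, `"base"`.
#' @return The file path of the requested fixture.
#' @export
dop_pafa_file <- function(which = c("positions", "segments", "base")) {
  which <- match.arg(which)
  f <- switch(which, positions = "dop_pafa_positions.tsv",
              segments = "dop_library_segments.tsv",
              base = "dop_msm_synthetic.fasta")
  system.file("extdata", f, package = "divcons", mustWork = TRUE)
}

#' Read a reciprocal-mutagenesis position table
#'
#' Parses a position table in the layout of [dop_pafa_file]`("positions")`:
#' one row per selected position with the residue in each family (e.g.
#' `S27`), the two conservation grades, and a note column (`a` = covered by
#' the Dop-loop deletion, `b` = neighbours the catalytic aspartate, `c` =
#' alpha-loop region).  Special rows: `dop_msm == "ins"` marks a
#' family-B-only insertion, `no == "del"` a family-A-only deletion range
#' (`A43-V79` style).
#'
#' @param path Table path (default: the bundled Dop/PafA table).
#' @return A `data.frame` with parsed `dop_aa`, `dop_pos`, `pafa_aa`,
#'   `pafa_pos` columns added.
#' @export
read_position_table <- function(path = dop_pafa_file("positions")) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  parse_res <- function(x) {
    ok <- grepl("^[A-Z][0-9]+$", x)
    pos <- rep(NA_integer_, length(x))
    pos[ok] <- as.integer(sub("^[A-Z]", "", x[ok]))
    list(aa = ifelse(ok, substr(x, 1, 1), NA), pos = pos)
  }
  d <- parse_res(tab$dop_msm); p <- parse_res(tab$pafa_msm)
  tab$dop_aa <- d$aa; tab$dop_pos <- as.integer(d$pos)
  tab$pafa_aa <- p$aa; tab$pafa_pos <- as.integer(p$pos)
  tab
}

#' Mutation units from a reciprocal-mutagenesis position table
#'
#' Converts a [read_position_table()] table into `divcons_units` on the
#' family-A (Dop) base: one substitution per ordinary row (family-A residue
#' replaced by the family-B residue, `"S27A"` naming), one deletion for the
#' `del` row (the Dop-loop), and one insertion for each `ins` row (anchored
#' after the preceding row's family-A position).  Rows noted `a` are covered
#' by the deletion and never emitted as standalone substitutions.
#'
#' @param tab A [read_position_table()] data.frame.
#' @return A `divcons_units` table; rows noted `c` (alpha-loop) keep the
#'   note in the `segment` column so callers can split alpha-loop from
#'   supporting mutations.
#' @export
position_units <- function(tab = read_position_table()) {
  out <- NULL
  subs <- !is.na(tab$dop_pos) & !is.na(tab$pafa_pos) & tab$note != "a"
  if (any(subs)) {
    t2 <- tab[subs, , drop = FALSE]
    out <- mutation_units(
      name = paste0(t2$dop_aa, t2$dop_pos, t2$pafa_aa),
      kind = "substitution", start = t2$dop_pos, replacement = t2$pafa_aa,
      base_res = t2$dop_aa,
      segment = ifelse(t2$note == "c", "alpha_loop", "supporting"))
  }
  del <- grepl("^[A-Z][0-9]+-[A-Z][0-9]+$", tab$dop_msm)
  for (i in which(del)) {
    ends <- strsplit(tab$dop_msm[[i]], "-")[[1L]]
    s <- as.integer(sub("^[A-Z]", "", ends[[1L]]))
    e <- as.integer(sub("^[A-Z]", "", ends[[2L]]))
    out <- rbind(out, mutation_units(
      name = paste0("del", s, "-", e), kind = "deletion", start = s, end = e,
      base_res = paste0(substr(ends[[1L]], 1, 1), substr(ends[[2L]], 1, 1)),
      segment = "dop_loop"))
  }
  ins <- tab$dop_msm == "ins"
  for (i in which(ins)) {
    anchor_rows <- which(!is.na(tab$dop_pos) & seq_len(nrow(tab)) < i)
    anchor <- tab$dop_pos[[max(anchor_rows)]]
    out <- rbind(out, mutation_units(
      name = paste0("ins", anchor, tab$pafa_aa[[i]]), kind = "insertion",
      start = anchor, replacement = tab$pafa_aa[[i]],
      segment = ifelse(tab$note[[i]] == "c", "alpha_loop", "supporting")))
  }
  out <- out[order(out$start, out$kind != "deletion"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("divcons_units", "data.frame")
  out
}

#' Read a segment table for combinatorial library design
#'
#' Segment files are TSV with columns `segment`, `name`, `kind`, `start`,
#' `end`, `replacement`, `base_res` (see
#' [dop_pafa_file]`("segments")` for the Dop/PafA five-segment grouping).
#'
#' @param path Segment file path.
#' @return A `divcons_units` table with the `segment` column set.
#' @export
read_segments <- function(path = dop_pafa_file("segments")) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  tab$replacement[is.na(tab$replacement)] <- ""
  tab$base_res[is.na(tab$base_res)] <- ""
  mutation_units(name = tab$name, kind = tab$kind,
                 start = as.integer(tab$start), end = as.integer(tab$end),
                 replacement = tab$replacement, base_res = tab$base_res,
                 segment = tab$segment)
}

#' Write a combinatorial library manifest
#'
#' One row per mutant, one column per segment holding the segment's unit
#' names when switched on.
#'
#' @param library A `divcons_library`.
#' @param path Output TSV path.
#' @return The manifest data.frame, invisibly.
#' @export
write_library_manifest <- function(library, path) {
  labels <- names(library[[1L]]$on)
  rows <- lapply(library, function(m) {
    cells <- vapply(labels, function(l) {
      if (!m$on[[l]]) return("")
      paste(m$units$name[!is.na(m$units$segment) & m$units$segment == l],
            collapse = ", ")
    }, "")
    c(mutant = m$name, cells)
  })
  manifest <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
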