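#' Read protein sequences from a FASTA file
#'
#' Parses a (plain or gzip-compressed) FASTA file into a sequence table.
#' Sequences are upper-cased and trailing `*` stop characters are stripped.
#' The sequence id is the first whitespace-delimited token of the header; the
#' remainder is kept as the description.
#'
#' Only the 20 standard amino-acid letters plus `X` (unknown) are accepted;
#' any other character is an error reporting the offending sequence and
#' residue position.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` of class `divcons_seqs` with columns `id`,
#'   `description` and `sequence`, one row per FASTA entry, input order
#'   preserved.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "MKV", ">b", "MKL"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no sequences in ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("empty sequence id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1L]])
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*+$", "", seqs)
  validate_residues(seqs, ids)
  new_divcons_seqs(ids, desc, seqs)
}

new_divcons_seqs <- function(id, description, sequence) {
  out <- data.frame(id = id, description = description, sequence = sequence,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("divcons_seqs", "data.frame")
  out
}

validate_residues <- function(seqs, ids, allow_gap = FALSE) {
  alphabet <- c(.divcons_amino_acids, "X", if (allow_gap) "-")
  pattern <- paste0("[^", paste(alphabet, collapse = ""), "]")
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) stop("empty sequence for id ", ids[[i]])
    bad <- regexpr(pattern, seqs[[i]])
    if (bad > 0L)
      stop("invalid residue '", substr(seqs[[i]], bad, bad), "' at position ",
           bad, " in sequence ", ids[[i]])
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param records A `divcons_seqs` table (or any data.frame with `id`,
#'   `description`, `sequence` columns).
#' @param path Output file path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[[i]]))
      paste(records$id[[i]], records$description[[i]]) else records$id[[i]]
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

as_seqs <- function(x) {
  if (inherits(x, "divcons_seqs")) return(x)
  if (is.character(x) && !is.null(names(x)))
    return(new_divcons_seqs(names(x), "", unname(x)))
  if (is.data.frame(x) && all(c("id", "sequence") %in% names(x))) {
    if (is.null(x$description)) x$description <- ""
    return(new_divcons_seqs(x$id, x$description, x$sequence))
  }
  stop("cannot interpret input as sequence records")
}

#' @export
print.divcons_seqs <- function(x, ...) {
  cat("divcons sequence set:", nrow(x), "sequences, lengths",
      min(nchar(x$sequence)), "-", max(nchar(x$sequence)), "\n")
  invisible(x)
}
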