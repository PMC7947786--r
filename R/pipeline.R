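#' Differential-conservation analysis of two paralogous families
#'
#' The package's central function.  Runs the full analysis on a set of
#' homolog sequences: (1) all-vs-all local alignment scores form a
#' sequence-similarity network whose connected components at `ssn_threshold`
#' bits define the families; the two clusters containing `reference_a` and
#' `reference_b` are analysed.  (2) Each family is aligned progressively
#' along a neighbor-joining guide tree (unless pre-computed alignments are
#' supplied) and per-column conservation grades 1-9 are computed.  (3) The
#' reference structures are superposed (iterative Kabsch refinement) and the
#' residue correspondence is lifted to a column-to-column map.  (4) Mapped
#' positions are classified as shared / uniquely conserved / differently
#' conserved / indel and filtered by CA distance to the active site.
#'
#' @param records Homolog sequences: a `divcons_seqs` table or FASTA path.
#' @param structure_a,structure_b Reference structures (`divcons_structure`
#'   or PDB paths) for the families of `reference_a` and `reference_b`.
#' @param reference_a,reference_b Sequence ids of the structure-bearing
#'   references.
#' @param active_site Integer vector of active-site residue numbers
#'   (sequential numbering of the active-site structure).
#' @param ssn_threshold Bit-score threshold of the similarity network.
#' @param active_site_side `"A"` or `"B"`: which structure carries the
#'   active site (default `"A"`).
#' @param alignment_a,alignment_b Optional pre-computed `divcons_alignment`s
#'   (or aligned-FASTA paths); the clustering and alignment stages then only
#'   validate membership.
#' @param low_cutoff Highest grade counted as "not conserved" (default 8;
#'   see [classify_positions()]).
#' @param distance_threshold Active-site distance filter in angstrom
#'   (default 20).
#' @param structural_cutoff Re-pairing cutoff of the structural alignment in
#'   angstrom (default 5).
#' @param matrix,gap_open,gap_extend Pairwise local-alignment scoring
#'   parameters (similarity network and structural seed alignment).
#' @param msa_gap_open Gap opening penalty of the progressive aligner
#'   (default 15, see [progressive_align()]).
#' @param background Conservation background (`"blosum62"` or `"uniform"`).
#' @param forced Family-A reference positions always selected (manual
#'   override).
#' @return An object of class `divcons`: list with `ssn`, `clusters`,
#'   `family_a`, `family_b` (member ids), `alignment_a`, `alignment_b`,
#'   `profile_a`, `profile_b`, `superposition`, `map`, `positions`,
#'   `summary`, `params`.
#' @seealso [summary.divcons()], [plot.divcons()], [simulate_families()]
#' @export
divcons <- function(records, structure_a, structure_b, reference_a,
                    reference_b, active_site, ssn_threshold,
                    active_site_side = "A",
                    alignment_a = NULL, alignment_b = NULL,
                    low_cutoff = 8, distance_threshold = 20,
                    structural_cutoff = 5, matrix = "BLOSUM62",
                    gap_open = 11, gap_extend = 1, msa_gap_open = 15,
                    background = "blosum62", forced = integer()) {
  if (is.character(records) && length(records) == 1L)
    records <- read_fasta(records)
  records <- as_seqs(records)
  if (is.character(structure_a)) structure_a <- read_structure(structure_a)
  if (is.character(structure_b)) structure_b <- read_structure(structure_b)
  if (is.character(alignment_a)) alignment_a <- read_alignment(alignment_a)
  if (is.character(alignment_b)) alignment_b <- read_alignment(alignment_b)

  ssn <- build_ssn(records, ssn_threshold, matrix, gap_open, gap_extend)
  clusters <- cluster_families(ssn)
  find_cluster <- function(ref) {
    hit <- which(vapply(clusters, function(cl) ref %in% cl, TRUE))
    if (!length(hit)) stop("reference '", ref, "' not found in any cluster")
    clusters[[hit]]
  }
  fam_a <- assign_reference(find_cluster(reference_a), reference_a)
  fam_b <- assign_reference(find_cluster(reference_b), reference_b)
  if (identical(sort(fam_a$ids), sort(fam_b$ids)) &&
      reference_a != reference_b && length(clusters) > 1L)
    warning("both references fall in the same cluster")

  align_family <- function(fam, supplied) {
    if (!is.null(supplied)) {
      missing <- setdiff(fam$ids, supplied$ids)
      if (length(missing))
        stop("supplied alignment lacks family members: ",
             paste(utils::head(missing, 3), collapse = ", "))
      supplied$reference_id <- fam$reference_id
      supplied$weights <- henikoff_weights(supplied)
      return(supplied)
    }
    members <- records[records$id %in% fam$ids, , drop = FALSE]
    class(members) <- c("divcons_seqs", "data.frame")
    tree <- neighbor_joining(kmer_distance_matrix(members))
    progressive_align(members, tree, matrix, msa_gap_open, gap_extend,
                      reference_id = fam$reference_id)
  }
  aligned_supplied <- !is.null(alignment_a) && !is.null(alignment_b)
  aln_a <- align_family(fam_a, alignment_a)
  aln_b <- align_family(fam_b, alignment_b)
  prof_a <- conservation_profile(aln_a, background = background)
  prof_b <- conservation_profile(aln_b, background = background)

  sp <- iterative_structural_align(structure_a, structure_b,
                                   cutoff = structural_cutoff,
                                   matrix = matrix, gap_open = gap_open,
                                   gap_extend = gap_extend)
  map <- lift_to_columns(sp$pairs, aln_a, aln_b)

  positions <- classify_positions(prof_a, prof_b, map, low_cutoff,
                                  alignment_a = aln_a, alignment_b = aln_b)
  as_struct <- if (active_site_side == "A") structure_a else structure_b
  positions <- active_site_distances(positions, as_struct, active_site,
                                     side = active_site_side)
  positions <- select_candidates(positions, distance_threshold, forced)

  smry <- list(
    n_sequences = nrow(records), n_clusters = length(clusters),
    family_sizes = c(A = length(fam_a$ids), B = length(fam_b$ids)),
    n_columns = c(A = aln_a$n_columns, B = aln_b$n_columns),
    n_matched = nrow(map$matched),
    n_unmatched = c(A = length(map$unmatched_a), B = length(map$unmatched_b)),
    superposition_rmsd = sp$rmsd,
    alignment_supplied = aligned_supplied,
    class_counts = attr(positions, "summary")$before,
    n_candidates = attr(positions, "summary")$n_candidates,
    n_selected = attr(positions, "summary")$n_selected)
  stopifnot(smry$n_selected <= smry$n_candidates,
            smry$n_candidates <= smry$n_matched +
              length(map$unmatched_a) + length(map$unmatched_b))

  structure(list(ssn = ssn, clusters = clusters,
                 family_a = fam_a, family_b = fam_b,
                 alignment_a = aln_a, alignment_b = aln_b,
                 profile_a = prof_a, profile_b = prof_b,
                 superposition = sp, map = map, positions = positions,
                 summary = smry,
                 params = list(ssn_threshold = ssn_threshold,
                               low_cutoff = low_cutoff,
                               distance_threshold = distance_threshold,
                               structural_cutoff = structural_cutoff,
                               matrix = matrix, gap_open = gap_open,
                               gap_extend = gap_extend,
                               background = background,
                               active_site = active_site,
                               active_site_side = active_site_side,
                               forced = forced)),
            class = "divcons")
}

#' Run the full analysis on a synthetic bundle
#'
#' Convenience wrapper feeding a [simulate_families()] bundle through
#' [divcons()].
#'
#' @param bundle A `divcons_bundle`.
#' @param ssn_threshold Bit-score threshold (default 40, the generator's
#'   documented separation point between within- and between-family scores
#'   at default parameters).
#' @param ... Further arguments to [divcons()].
#' @return A `divcons` object.
#' @export
divcons_bundle_run <- function(bundle, ssn_threshold = 40, ...) {
  both <- rbind(bundle$seq_a, bundle$seq_b)
  class(both) <- c("divcons_seqs", "data.frame")
  divcons(both, bundle$structure_a, bundle$structure_b,
          reference_a = bundle$reference_a, reference_b = bundle$reference_b,
          active_site = bundle$active_site, ssn_threshold = ssn_threshold,
          ...)
}

#' @export
print.divcons <- function(x, ...) {
  s <- x$summary
  cat("divcons analysis\n")
  cat("  sequences:", s$n_sequences, "in", s$n_clusters, "clusters;",
      "families A/B:", s$family_sizes[["A"]], "/", s$family_sizes[["B"]],
      "\n")
  cat("  columns A/B:", s$n_columns[["A"]], "/", s$n_columns[["B"]],
      "; matched:", s$n_matched, "; superposition rmsd:",
      format(s$superposition_rmsd, digits = 3), "A\n")
  cat("  candidates:", s$n_candidates, "; selected (<=",
      x$params$distance_threshold, "A):", s$n_selected, "\n")
  invisible(x)
}

#' Summarise a divcons analysis
#'
#' @param object A `divcons` object.
#' @param ... Unused.
#' @return A list with per-class counts before and after the distance
#'   filter plus the stage counts, printed compactly.
#' @method summary divcons
#' @export
summary.divcons <- function(object, ...) {
  out <- c(object$summary,
           list(selected_by_class = attr(object$positions,
                                         "summary")$selected,
                params = object$params))
  class(out) <- "summary.divcons"
  out
}

#' @export
print.summary.divcons <- function(x, ...) {
  cat("divcons summary\n")
  cat("  class counts:\n")
  for (nm in names(x$class_counts))
    cat(sprintf("    %-22s %4d  (selected: %d)\n", nm,
                x$class_counts[[nm]], x$selected_by_class[[nm]]))
  cat("  matched columns:", x$n_matched, "; candidates:", x$n_candidates,
      "; selected:", x$n_selected, "\n")
  invisible(x)
}

#' Plot conservation grades of mapped positions
#'
#' Scatter of family-A vs family-B conservation scores for matched columns,
#' coloured by class, with selected candidates highlighted.
#'
#' @param x A `divcons` object.
#' @param ... Passed to [plot.default()].
#' @method plot divcons
#' @export
plot.divcons <- function(x, ...) {
  p <- x$positions
  m <- p[!is.na(p$column_a) & !is.na(p$column_b), , drop = FALSE]
  sa <- x$profile_a$score[m$column_a]
  sb <- x$profile_b$score[m$column_b]
  pal <- c(shared_identical = "forestgreen", differently_conserved = "purple",
           unique_A = "orange", unique_B = "steelblue",
           unconserved = "grey70", indel = "brown")
  plot.default(sa, sb, col = pal[m$class], pch = ifelse(m$selected, 19, 1),
               xlab = "family A conservation score",
               ylab = "family B conservation score", ...)
  legend("bottomright", legend = names(pal), col = pal, pch = 19, cex = 0.7)
  invisible(x)
}

#' Validate a flat key-value pipeline configuration
#'
#' The config format is one `key = value` per line; `#` starts a comment.
#' Required keys: `fasta`, `structure_a`, `structure_b`, `reference_a`,
#' `reference_b`, `active_site` (comma-separated residue numbers),
#' `ssn_threshold`, `out_dir`.  Optional keys with defaults:
#' `distance_threshold` (20), `structural_cutoff` (5), `low_cutoff` (8),
#' `matrix` (BLOSUM62), `gap_open` (11), `gap_extend` (1), `background`
#' (blosum62), `alignment_a`, `alignment_b`, `forced`, `seed` (1).  Unknown
#' keys raise a warning, not an error.
#'
#' @param path Config file path.
#' @return A validated list of class `divcons_config` with defaults filled.
#' @export
validate_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("cannot parse config line: '", lines[bad][1L], "'")
  cfg <- setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  required <- c("fasta", "structure_a", "structure_b", "reference_a",
                "reference_b", "active_site", "ssn_threshold", "out_dir")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) stop("missing required config key: ", missing[[1L]])
  defaults <- list(distance_threshold = "20", structural_cutoff = "5",
                   low_cutoff = "8", matrix = "BLOSUM62", gap_open = "11",
                   gap_extend = "1", background = "blosum62",
                   alignment_a = "", alignment_b = "", forced = "",
                   active_site_side = "A", seed = "1")
  unknown <- setdiff(names(cfg), c(required, names(defaults)))
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("ssn_threshold", "distance_threshold", "structural_cutoff",
              "low_cutoff", "gap_open", "gap_extend", "seed"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  cfg$active_site <- as.integer(strsplit(cfg$active_site, ",")[[1L]])
  cfg$forced <- if (nzchar(cfg$forced))
    as.integer(strsplit(cfg$forced, ",")[[1L]]) else integer()
  if (is.na(cfg$distance_threshold) || cfg$distance_threshold < 0)
    stop("distance_threshold must be >= 0 (got ", cfg$distance_threshold, ")")
  if (is.na(cfg$structural_cutoff) || cfg$structural_cutoff <= 0)
    stop("structural_cutoff must be > 0")
  if (cfg$low_cutoff < 1 || cfg$low_cutoff > 8)
    stop("low_cutoff must be in 1..8")
  for (k in c("fasta", "structure_a", "structure_b"))
    if (!file.exists(cfg[[k]])) stop("config path does not exist: ", cfg[[k]])
  class(cfg) <- "divcons_config"
  cfg
}

#' Run the pipeline from a configuration file
#'
#' Executes cluster, align/conserve, map, classify and select in order,
#' writes all intermediate artifacts (network/cluster TSVs, alignments,
#' profiles, map, candidate report, JSON summary, run log) under
#' `out_dir`, and returns the analysis object.  Reruns with identical config
#' and inputs reproduce identical outputs.
#'
#' @param config Path to a config file or a `divcons_config`.
#' @param quiet Suppress stage log lines on stderr.
#' @return The `divcons` object, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "divcons_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  stage_t0 <- Sys.time()
  timings <- list()
  log_line <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    if (!quiet) message(line)
    writeLines(line, log_con)
  }
  set.seed(as.integer(config$seed))
  log_line("input", paste("reading", config$fasta))
  run <- tryCatch(
    divcons(records = config$fasta,
            structure_a = config$structure_a,
            structure_b = config$structure_b,
            reference_a = config$reference_a,
            reference_b = config$reference_b,
            active_site = config$active_site,
            ssn_threshold = config$ssn_threshold,
            active_site_side = config$active_site_side,
            alignment_a = if (nzchar(config$alignment_a))
              config$alignment_a else NULL,
            alignment_b = if (nzchar(config$alignment_b))
              config$alignment_b else NULL,
            low_cutoff = config$low_cutoff,
            distance_threshold = config$distance_threshold,
            structural_cutoff = config$structural_cutoff,
            matrix = config$matrix, gap_open = config$gap_open,
            gap_extend = config$gap_extend,
            background = config$background, forced = config$forced),
    error = function(e) stop("pipeline aborted: ", conditionMessage(e),
                             call. = FALSE))
  timings$analysis <- as.numeric(Sys.time() - stage_t0, units = "secs")
  log_line("analysis", sprintf("%d sequences, %d clusters, %d selected",
                               run$summary$n_sequences,
                               run$summary$n_clusters,
                               run$summary$n_selected))
  out <- config$out_dir
  write_ssn(run$ssn, run$clusters, out,
            reference_ids = c(config$reference_a, config$reference_b))
  write_alignment(run$alignment_a, file.path(out, "alignment_a.fasta"))
  write_alignment(run$alignment_b, file.path(out, "alignment_b.fasta"))
  write_profile(run$profile_a, file.path(out, "profile_a.tsv"))
  write_profile(run$profile_b, file.path(out, "profile_b.tsv"))
  write_map(run$map, file.path(out, "map.tsv"))
  candidate_report(run$positions, file.path(out, "candidates.tsv"),
                   name_a = config$reference_a, name_b = config$reference_b)
  summary_json <- c(run$summary,
                    list(parameters = run$params,
                         software_version = as.character(
                           utils::packageVersion("divcons")),
                         alignment_stage = if (run$summary$alignment_supplied)
                           "skipped (pre-aligned MSAs supplied)" else "run",
                         wall_time_seconds = timings))
  jsonlite::write_json(summary_json, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("output", paste("artifacts written to", out))
  invisible(run)
}
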