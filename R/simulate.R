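#' Configuration for the two-family synthetic generator
#'
#' Defaults emulate a desk-scale post-duplication scenario: two families of
#' 50 sequences over a 200-residue protein, with 10 family-A-unique, 10
#' family-B-unique, 5 differently-conserved and 5 shared constrained sites
#' planted inside the active-site region (positions `site_window`), a 2%
#' constraint-violation rate, a long post-duplication stem (2 substitutions
#' per site) so between-family identity at free sites is near background, and
#' random within-family trees with exponential branch lengths (mean 0.1
#' substitutions per site, giving within-family identity around 45% -- above
#' the between-family level, as for real ortholog families, while deep enough
#' that unconstrained columns are visibly variable across 50 leaves).
#' Constrained sites sit near the active site by
#' construction, mirroring the biological expectation that specificity
#' determinants cluster around the catalytic cradle.
#'
#' @param n_per_family Sequences per family.
#' @param length Protein length (ancestral coordinates).
#' @param n_unique_a,n_unique_b,n_diff,n_shared Planted site counts per
#'   constraint class.
#' @param epsilon Per-leaf constraint violation probability, in `[0, 0.5)`.
#' @param site_window Integer range within which constrained sites are
#'   planted.
#' @param active_site Sequential residue numbers (family A structure)
#'   defining the active site.
#' @param stem Post-duplication stem length per family (expected
#'   substitutions per site before within-family divergence).
#' @param branch_rate Rate of the exponential branch-length distribution of
#'   the within-family random trees (mean branch length = 1/branch_rate).
#' @param subst_rate Expected substitutions per site per unit branch length.
#' @param insertion `NULL`, or `list(family = "A", start =, length =)`: a
#'   contiguous region present only in that family (sequences and toy
#'   structure).
#' @param noise_sd Gaussian noise (angstrom) added to the second toy
#'   structure.
#' @param seed Mandatory random seed.
#' @return A list of class `divcons_sim_config`.
#' @export
sim_config <- function(n_per_family = 50L, length = 200L,
                       n_unique_a = 10L, n_unique_b = 10L, n_diff = 5L,
                       n_shared = 5L, epsilon = 0.02,
                       site_window = 76:124, active_site = c(88L, 100L, 112L),
                       stem = 2.0, branch_rate = 10, subst_rate = 1.0,
                       insertion = NULL, noise_sd = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  n_sites <- n_unique_a + n_unique_b + n_diff + n_shared
  if (n_sites > length) stop("class counts (", n_sites,
                             ") exceed protein length (", length, ")")
  if (n_sites > base::length(site_window))
    stop("site_window too small for ", n_sites, " constrained sites")
  if (any(site_window < 1L) || any(site_window > length))
    stop("site_window out of bounds")
  if (!is.null(insertion)) {
    if (insertion$start < 1L ||
        insertion$start + insertion$length - 1L > length)
      stop("insertion region out of bounds")
  }
  structure(as.list(environment()), class = "divcons_sim_config")
}

sample_background <- function(n, bg = .divcons_blosum62_bg) {
  sample(names(bg), n, replace = TRUE, prob = bg)
}

evolve_sequence <- function(seq_chars, branch_length, subst_rate) {
  hits <- rpois(length(seq_chars), subst_rate * branch_length) > 0L
  if (any(hits)) seq_chars[hits] <- sample_background(sum(hits))
  seq_chars
}

simulate_family <- function(root_chars, ids, config, targets) {
  n <- length(ids)
  tree <- ape::rtree(n, tip.label = ids,
                     br = function(k) rexp(k, rate = config$branch_rate))
  tree <- ape::reorder.phylo(tree, "cladewise")  # preorder: parents first
  n_nodes <- n + tree$Nnode
  seqs <- vector("list", n_nodes)
  seqs[[n + 1L]] <- root_chars  # root
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    seqs[[child]] <- evolve_sequence(seqs[[parent]], tree$edge.length[[e]],
                                     config$subst_rate)
  }
  leaves <- seqs[seq_len(n)]
  # enforce site constraints at the leaves
  sites <- which(!is.na(targets))
  bg <- .divcons_blosum62_bg
  for (i in seq_len(n)) {
    for (s in sites) {
      if (stats::runif(1) < 1 - config$epsilon) {
        leaves[[i]][s] <- targets[[s]]
      } else {
        others <- bg[names(bg) != targets[[s]]]
        leaves[[i]][s] <- sample(names(others), 1L, prob = others)
      }
    }
  }
  setNames(vapply(leaves, paste, "", collapse = ""), tree$tip.label)
}

#' Simulate a labelled two-family bundle
#'
#' Draws an ancestral sequence from the BLOSUM62 background, duplicates it,
#' evolves each copy along a stem and then along an independent random tree
#' (per-site Poisson substitutions, replacements drawn from the background),
#' and enforces the planted constraint classes at the leaves: each
#' constrained site shows its family target with probability `1 - epsilon`,
#' otherwise a non-target background residue (so the per-site violation rate
#' is exactly `epsilon`).  Toy CA-helix structures with a known rigid
#' transform (and optional planted insertion) accompany the sequences.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `divcons_bundle`: `seq_a`, `seq_b`
#'   (`divcons_seqs`), `reference_a`, `reference_b` (ids), `truth`
#'   (data.frame `site`, `class`, `target_a`, `target_b`; family-A reference
#'   coordinates), `structure_a`, `structure_b`, `correspondence` (true
#'   residue pairs), `transform` (true rotation/translation), `config`.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "divcons_sim_config"))
  set.seed(config$seed)
  L <- config$length
  classes <- rep(c("unique_A", "unique_B", "differently_conserved",
                   "shared_identical"),
                 c(config$n_unique_a, config$n_unique_b, config$n_diff,
                   config$n_shared))
  ins_sites <- integer()
  if (!is.null(config$insertion))
    ins_sites <- seq(config$insertion$start,
                     length.out = config$insertion$length)
  avail <- setdiff(config$site_window, ins_sites)
  if (length(avail) < length(classes))
    stop("site_window (minus insertion) too small for constrained sites")
  sites <- sort(sample(avail, length(classes)))
  classes <- sample(classes)  # shuffle class-site assignment
  target_a <- rep(NA_character_, L); target_b <- rep(NA_character_, L)
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    switch(classes[[i]],
      unique_A = { target_a[s] <- sample_background(1L) },
      unique_B = { target_b[s] <- sample_background(1L) },
      differently_conserved = {
        pair <- sample(names(.divcons_blosum62_bg), 2L,
                       prob = .divcons_blosum62_bg)
        target_a[s] <- pair[[1L]]; target_b[s] <- pair[[2L]]
      },
      shared_identical = {
        r <- sample_background(1L)
        target_a[s] <- r; target_b[s] <- r
      })
  }
  ancestor <- sample_background(L)
  ids_a <- sprintf("A%03d", seq_len(config$n_per_family))
  ids_b <- sprintf("B%03d", seq_len(config$n_per_family))
  root_a <- evolve_sequence(ancestor, config$stem, config$subst_rate)
  root_b <- evolve_sequence(ancestor, config$stem, config$subst_rate)
  fam_a <- simulate_family(root_a, ids_a, config, target_a)
  fam_b <- simulate_family(root_b, ids_b, config, target_b)
  # the insertion region exists only in its own family
  drop_sites <- function(seqs, drop) {
    if (!length(drop)) return(seqs)
    vapply(seqs, function(s)
      paste(strsplit(s, "")[[1L]][-drop], collapse = ""), "")
  }
  ins_fam <- if (length(ins_sites)) config$insertion$family else ""
  if (ins_fam == "A") fam_b <- drop_sites(fam_b, ins_sites)
  if (ins_fam == "B") fam_a <- drop_sites(fam_a, ins_sites)
  seq_a <- new_divcons_seqs(ids_a, "family A", unname(fam_a[ids_a]))
  seq_b <- new_divcons_seqs(ids_b, "family B", unname(fam_b[ids_b]))
  toy <- make_toy_structures(
    length = L, insertion = config$insertion, noise_sd = config$noise_sd,
    aa_a = seq_a$sequence[[1L]], aa_b = seq_b$sequence[[1L]])
  truth <- data.frame(site = sites, class = classes,
                      target_a = target_a[sites], target_b = target_b[sites],
                      stringsAsFactors = FALSE)
  bundle <- structure(list(
    seq_a = seq_a, seq_b = seq_b,
    reference_a = ids_a[[1L]], reference_b = ids_b[[1L]],
    truth = truth,
    structure_a = toy$structure_a, structure_b = toy$structure_b,
    correspondence = toy$correspondence, transform = toy$transform,
    active_site = config$active_site, config = config),
    class = "divcons_bundle")
  chk <- identity_separation(bundle)
  stopifnot(chk$between < chk$within)
  bundle$identity_check <- chk
  bundle
}

# mean within- vs between-family identity over shared (non-insertion) sites,
# on a deterministic subsample; a sanity check of the duplication structure.
identity_separation <- function(bundle, n_sub = 10L) {
  cfg <- bundle$config
  ins_sites <- if (!is.null(cfg$insertion))
    seq(cfg$insertion$start, length.out = cfg$insertion$length) else integer()
  strip <- function(seqs, fam) {
    m <- do.call(rbind, strsplit(seqs, ""))
    if (length(ins_sites) && !is.null(cfg$insertion) &&
        cfg$insertion$family == fam) m <- m[, -ins_sites, drop = FALSE]
    m
  }
  a <- strip(utils::head(bundle$seq_a$sequence, n_sub), "A")
  b <- strip(utils::head(bundle$seq_b$sequence, n_sub), "B")
  pair_mean <- function(x, y) {
    tot <- 0; k <- 0L
    for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y))) {
      if (identical(x, y) && j <= i) next
      tot <- tot + mean(x[i, ] == y[j, ]); k <- k + 1L
    }
    tot / k
  }
  list(within = (pair_mean(a, a) + pair_mean(b, b)) / 2,
       between = pair_mean(a, b))
}

#' @export
print.divcons_bundle <- function(x, ...) {
  cat("divcons synthetic bundle:", nrow(x$seq_a), "+", nrow(x$seq_b),
      "sequences, length", x$config$length, "\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Paired toy CA-helix structures with known truth
#'
#' Structure A is an ideal alpha-helix CA trace (rise 1.5 angstrom, 100
#' degree turn, radius 2.3 angstrom).  Structure B consists of the same
#' residues minus/plus the insertion region, perturbed by isotropic Gaussian
#' noise and a rigid transform.  The true transform and the true residue
#' correspondence are returned alongside.
#'
#' @param length Number of residues of the family-A structure (>= 10).
#' @param insertion `NULL` or `list(family =, start =, length =)`; the region
#'   exists only in the named family's structure.
#' @param noise_sd Coordinate noise (angstrom) applied to structure B.
#' @param transform `NULL` for a random proper rigid transform, `"identity"`,
#'   or a `list(rotation =, translation =)`.
#' @param seed Optional seed (set it when calling standalone; inside
#'   [simulate_families()] the stream is already seeded).
#' @param aa_a,aa_b Optional amino-acid strings for the two structures
#'   (defaults: poly-alanine).
#' @return List with `structure_a`, `structure_b`, `correspondence` (matrix
#'   of true residue pairs `res_a`, `res_b`), `transform`.
#' @export
make_toy_structures <- function(length, insertion = NULL, noise_sd = 0,
                                transform = NULL, seed = NULL,
                                aa_a = NULL, aa_b = NULL) {
  if (length < 10L) stop("toy structures need length >= 10")
  if (!is.null(seed)) set.seed(seed)
  ins_sites <- integer(); ins_fam <- ""
  if (!is.null(insertion)) {
    ins_sites <- seq(insertion$start, length.out = insertion$length)
    ins_fam <- insertion$family
    if (insertion$start < 1L || max(ins_sites) > length)
      stop("insertion region out of bounds")
  }
  # Alpha-helix CA trace (rise 1.5 A, 100 degree turn, radius 2.3 A) wound
  # on a gently curved axis (radius 90 A).  A straight ideal helix has an
  # exact screw symmetry -- shifting the residue register is equivalent to a
  # rigid transform -- which would make the true register unidentifiable
  # from geometry; the axis curvature breaks that degeneracy.
  helix <- function(n) {
    i <- seq_len(n) - 1L
    ang <- i * 100 * pi / 180
    rc <- 90
    theta <- 1.5 * i / rc
    axis <- cbind(rc * (1 - cos(theta)), 0, rc * sin(theta))
    normal <- cbind(cos(theta), 0, -sin(theta))
    binormal <- cbind(0, rep(1, n), 0)
    xyz <- axis + 2.3 * (cos(ang) * normal + sin(ang) * binormal)
    colnames(xyz) <- c("x", "y", "z")
    xyz
  }
  xa <- helix(length)
  keep_b <- if (ins_fam == "A") setdiff(seq_len(length), ins_sites)
            else seq_len(length)
  keep_a <- if (ins_fam == "B") setdiff(seq_len(length), ins_sites)
            else seq_len(length)
  xb <- xa[keep_b, , drop = FALSE]
  xa <- xa[keep_a, , drop = FALSE]
  if (is.null(transform)) {
    transform <- list(rotation = random_rotation(),
                      translation = stats::rnorm(3, sd = 10))
  } else if (identical(transform, "identity")) {
    transform <- list(rotation = diag(3), translation = c(0, 0, 0))
  }
  xb_t <- sweep(xb %*% transform$rotation, 2, transform$translation, "+")
  if (noise_sd > 0)
    xb_t <- xb_t + matrix(stats::rnorm(base::length(xb_t), sd = noise_sd),
                          ncol = 3)
  if (is.null(aa_a)) aa_a <- strrep("A", nrow(xa))
  if (is.null(aa_b)) aa_b <- strrep("A", nrow(xb_t))
  sa <- new_structure(strsplit(aa_a, "")[[1L]], xa, chain = "A")
  sb <- new_structure(strsplit(aa_b, "")[[1L]], xb_t, chain = "B")
  # correspondence in sequential numbering of each structure
  shared <- intersect(keep_a, keep_b)
  correspondence <- cbind(res_a = match(shared, keep_a),
                          res_b = match(shared, keep_b))
  list(structure_a = sa, structure_b = sb,
       correspondence = correspondence, transform = transform)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Precision and recall of recovered candidate positions
#'
#' Compares predicted (selected) positions, in family-A reference
#' coordinates, against the generator's truth table: true candidates are the
#' planted `unique_A`, `unique_B` and `differently_conserved` sites.
#'
#' @param predicted Integer vector of selected family-A positions (e.g.
#'   `res_a` of selected records), or a `divcons_positions` table.
#' @param truth The bundle's `truth` data.frame.
#' @param length Protein length (for the confusion table's free class).
#' @return List with `precision` (NULL with a warning if nothing was
#'   predicted), `recall`, and `confusion` (planted class x selected).
#' @export
evaluate_recovery <- function(predicted, truth, length = NULL) {
  if (inherits(predicted, "divcons_positions"))
    predicted <- predicted$res_a[predicted$selected]
  predicted <- predicted[!is.na(predicted)]
  if (!is.null(length) && base::length(predicted) &&
      max(predicted) > length)
    stop("predicted positions exceed the truth coordinate system")
  true_cand <- truth$site[truth$class %in%
                            c("unique_A", "unique_B",
                              "differently_conserved")]
  hits <- intersect(predicted, true_cand)
  precision <- if (base::length(predicted) == 0L) {
    warning("no positions predicted; precision undefined")
    NULL
  } else base::length(hits) / base::length(predicted)
  recall <- base::length(hits) / base::length(true_cand)
  cls <- c(sort(unique(truth$class)), "free")
  site_class <- setNames(truth$class, truth$site)
  pred_class <- ifelse(as.character(predicted) %in% names(site_class),
                       site_class[as.character(predicted)], "free")
  confusion <- table(factor(pred_class, levels = cls))
  list(precision = precision, recall = recall, confusion = confusion)
}

#' Write a synthetic bundle to disk
#'
#' Writes the combined FASTA (both families), the truth table, the
#' active-site list and the two toy structures in PDB format.
#'
#' @param bundle A `divcons_bundle`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  both <- rbind(bundle$seq_a, bundle$seq_b)
  class(both) <- c("divcons_seqs", "data.frame")
  write_fasta(both, file.path(dir, "sequences.fasta"))
  write.table(bundle$truth, file.path(dir, "truth_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(paste(bundle$active_site, collapse = ","),
             file.path(dir, "active_site.txt"))
  write_structure(bundle$structure_a, file.path(dir, "structure_a.pdb"))
  write_structure(bundle$structure_b, file.path(dir, "structure_b.pdb"))
  invisible(dir)
}
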