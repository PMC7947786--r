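base475 <- function() read_fasta(dop_pafa_file("base"))

test_that("mutation units validate their invariants", {
  expect_error(mutation_units("S27A", "substitution", 27, replacement = "AT"),
               "single")
  expect_error(mutation_units("d", "deletion", 5, 10, replacement = "A"),
               "empty replacement")
  expect_error(mutation_units("i", "insertion", 5, replacement = ""),
               "non-empty")
  d1 <- mutation_units("d1", "deletion", 3, 8)
  s6 <- mutation_units("S6A", "substitution", 6, replacement = "A")
  overlapping <- rbind(d1, s6)
  class(overlapping) <- c("divcons_units", "data.frame")
  expect_error(apply_mutations(strrep("S", 20), overlapping), "overlapping")
  oob <- mutation_units("S99A", "substitution", 99, replacement = "A",
                        base_res = "S")
  expect_error(apply_mutations("MKVLA", oob), "out of bounds")
})

test_that("applying mutations edits coordinates correctly", {
  u <- mutation_units("V3F", "substitution", 3, replacement = "F",
                      base_res = "V")
  expect_equal(apply_mutations("MKVLA", u)$sequence, "MKFLA")
  # coordinate drift guard
  wrong <- mutation_units("K3F", "substitution", 3, replacement = "F",
                          base_res = "K")
  expect_error(apply_mutations("MKVLA", wrong), "expected 'K'")
  # the documented loop deletion removes exactly 37 residues
  base <- base475()
  del <- position_units()[position_units()$kind == "deletion", ]
  class(del) <- c("divcons_units", "data.frame")
  mut <- apply_mutations(base, del)
  expect_equal(nchar(base$sequence) - nchar(mut$sequence), 37L)
  # insertion inserts after the anchor
  ins <- mutation_units("ins2GG", "insertion", 2, replacement = "GG")
  expect_equal(apply_mutations("MKVLA", ins)$sequence, "MKGGVLA")
})

test_that("apply-then-invert restores the base sequence byte-for-byte", {
  set.seed(55)
  for (trial in 1:100) {
    base <- random_seq(sample(30:60, 1))
    pool <- seq(2, nchar(base) - 6, by = 6)
    n_units <- sample(seq_len(min(5, length(pool))), 1)
    # draw disjoint anchor blocks
    starts <- sort(sample(pool, n_units))
    units <- NULL
    for (s in starts) {
      kind <- sample(c("substitution", "insertion", "deletion"), 1)
      u <- switch(kind,
        substitution = {
          old <- substr(base, s, s)
          repl <- sample(setdiff(aa20, old), 1)
          mutation_units(paste0(old, s, repl), "substitution", s,
                         replacement = repl, base_res = old)
        },
        insertion = mutation_units(paste0("ins", s), "insertion", s,
                                   replacement = random_seq(sample(1:3, 1))),
        deletion = mutation_units(paste0("del", s), "deletion", s,
                                  end = s + sample(0:3, 1)))
      units <- rbind(units, u)
    }
    class(units) <- c("divcons_units", "data.frame")
    mut <- apply_mutations(base, units)
    inv <- invert_units(units, base)
    expect_identical(apply_mutations(mut, inv)$sequence, base)
  }
})

test_that("application order is canonical: any valid order agrees", {
  set.seed(66)
  base <- random_seq(50)
  units <- rbind(
    mutation_units("ins10", "insertion", 10, replacement = "WW"),
    mutation_units("del20", "deletion", 20, end = 24),
    mutation_units(paste0(substr(base, 40, 40), "40A"), "substitution", 40,
                   replacement = "A"))
  class(units) <- c("divcons_units", "data.frame")
  canonical <- apply_mutations(base, units)$sequence
  # naive left-to-right application with explicit re-anchoring
  s <- base; offset <- 0L
  for (i in order(units$start)) {
    u <- units[i, ]
    st <- u$start + offset; en <- u$end + offset
    s <- switch(u$kind,
      substitution = paste0(substr(s, 1, st - 1), u$replacement,
                            substr(s, st + 1, nchar(s))),
      insertion = paste0(substr(s, 1, st), u$replacement,
                         substr(s, st + 1, nchar(s))),
      deletion = paste0(substr(s, 1, st - 1), substr(s, en + 1, nchar(s))))
    offset <- offset + nchar(u$replacement) -
      (if (u$kind == "insertion") 0L else u$end - u$start + 1L)
  }
  expect_identical(canonical, s)
})

test_that("reciprocal units come from selected records with guard rails", {
  rec <- data.frame(
    column_a = 1:2, column_b = 1:2, res_a = c(27L, 31L), aa_a = c("S", "V"),
    res_b = 1:2, aa_b = c("A", "F"), grade_a = c(9L, 8L), grade_b = c(9L, 9L),
    consensus_a = c("S", "V"), consensus_b = c("A", "F"),
    class = c("differently_conserved", "unique_B"),
    distance = c(3, 4), selected = TRUE, stringsAsFactors = FALSE)
  class(rec) <- c("divcons_positions", "data.frame")
  base <- paste0(strrep("G", 26), "S", strrep("G", 3), "V", strrep("G", 10))
  u <- reciprocal_units(rec, base)
  expect_equal(u$name, c("S27A", "V31F"))
  expect_equal(u$kind, rep("substitution", 2))
  # a no-op "mutation" is rejected
  rec$consensus_b[1] <- "S"
  expect_error(reciprocal_units(rec, base), "not a candidate")
})

test_that("library enumeration is exactly 2^k with distinct members", {
  seg <- read_segments()
  for (k in 0:6) {
    labs <- unique(seg$segment)[seq_len(min(k, 5))]
    sub <- seg[seg$segment %in% labs, , drop = FALSE]
    if (k > 5) {  # pad with singleton segments to reach k
      extra <- mutation_units(sprintf("G%dA", 300 + seq_len(k - 5)),
                              "substitution", 300 + seq_len(k - 5),
                              replacement = "A",
                              segment = sprintf("x%d", seq_len(k - 5)))
      sub <- rbind(sub, extra)
    }
    class(sub) <- c("divcons_units", "data.frame")
    lib <- if (k == 0) enumerate_library(list()) else enumerate_library(sub)
    expect_length(lib, 2^k)
  }
  too_many <- mutation_units(sprintf("A%dG", 1:21 * 2), "substitution",
                             1:21 * 2, replacement = "G",
                             segment = as.character(1:21))
  expect_error(enumerate_library(too_many), "library too large")
})

test_that("the five-segment library matches the documented design", {
  seg <- read_segments()
  base <- base475()
  lib <- enumerate_library(seg)
  expect_length(lib, 32L)
  expect_true(all(!lib[[1L]]$on))   # backbone first
  expect_true(all(lib[[32L]]$on))   # full mutant last
  f <- tempfile(fileext = ".fasta")
  recs <- write_mutants(lib, base, f)
  expect_equal(nrow(recs), 32L)
  expect_equal(length(unique(recs$sequence)), 32L)  # all members distinct
  back <- read_fasta(f)
  expect_equal(back$sequence, recs$sequence)
  # backbone member sequence equals the unmutated base
  expect_identical(recs$sequence[[1L]], base$sequence)
  # the supporting positions span 2^11 combinations one-by-one
  u <- position_units()
  sup <- u[u$segment == "supporting", ]
  sup$segment <- sup$name
  class(sup) <- c("divcons_units", "data.frame")
  expect_length(enumerate_library(sup), 2048L)
})

test_that("reciprocal units from the position table match the segment naming", {
  u <- position_units()
  emitted <- u$name[u$kind != "deletion"]
  expect_length(emitted, 20L)  # selected positions
  seg <- read_segments()
  expect_true(all(seg$name %in% u$name))  # segments 1-5 use the same units
  expect_setequal(u$name[u$segment == "supporting"], seg$name)
  expect_equal(sum(u$segment == "alpha_loop"), 9L)
  expect_equal(sum(u$segment == "supporting"), 11L)
})

test_that("reversion series drop exactly one unit group each", {
  seg <- read_segments()
  by_unit <- reversion_series(seg)
  expect_length(by_unit, nrow(seg))
  for (i in seq_along(by_unit))
    expect_equal(nrow(by_unit[[i]]), nrow(seg) - 1L)
  by_segment <- reversion_series(seg, group = seg$segment)
  expect_length(by_segment, 5L)
  expect_equal(names(by_segment)[[3L]], "V94L+ins94V+H96G+A97S")
  base <- base475()
  full <- apply_mutations(base, seg)$sequence
  for (rv in by_segment)
    expect_false(identical(apply_mutations(base, rv)$sequence, full))
  expect_error(reversion_series(seg[0, ]), "no units")
})
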