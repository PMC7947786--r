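make_profile <- function(grades, consensus,
                         refpos = seq_along(grades),
                         score = grades / 9, gapf = 0) {
  out <- data.frame(column = seq_along(grades), reference_position = refpos,
                    score = score, grade = as.integer(grades),
                    gap_fraction = gapf, consensus = consensus,
                    stringsAsFactors = FALSE)
  class(out) <- c("divcons_profile", "data.frame")
  out
}

make_map <- function(n_a, n_b, matched_a, matched_b) {
  structure(list(matched = data.frame(column_a = matched_a,
                                      column_b = matched_b,
                                      res_a = matched_a, res_b = matched_b),
                 unmatched_a = setdiff(seq_len(n_a), matched_a),
                 unmatched_b = setdiff(seq_len(n_b), matched_b),
                 provenance = "structural"),
            class = "divcons_map")
}

helix_structure <- function(n) {
  toy <- make_toy_structures(max(n, 10), noise_sd = 0,
                             transform = "identity", seed = 1)
  toy$structure_a[seq_len(n), ]
}

test_that("position classes follow the grade/consensus rules", {
  pa <- make_profile(c(9, 9, 9, 3, 9, 5, 9), c("T", "K", "A", "G", "V", "L", "S"))
  pb <- make_profile(c(9, 9, 3, 9, 7, 5, 9), c("T", "N", "A", "G", "V", "L", "S"))
  map <- make_map(7, 7, 1:7, 1:7)
  rec <- classify_positions(pa, pb, map, low_cutoff = 6)
  expect_equal(rec$class,
               c("shared_identical",        # 9/9 same consensus
                 "differently_conserved",   # 9/9 different consensus
                 "unique_A",                # 9 vs 3
                 "unique_B",                # 3 vs 9
                 "unconserved",             # 9 vs 7 above low_cutoff
                 "unconserved",             # 5 vs 5
                 "shared_identical"))
  # exactly one class per record
  expect_true(all(table(seq_len(nrow(rec))) == 1))
  expect_error(classify_positions(pa, pb, map, low_cutoff = 0), "low_cutoff")
})

test_that("unmatched maximally conserved columns become indel records", {
  pa <- make_profile(c(9, 9, 2, 9), c("T", "W", "A", "G"))
  pb <- make_profile(c(9, 9), c("T", "G"))
  map <- make_map(4, 2, c(1, 4), c(1, 2))  # columns 2,3 of A unmatched
  rec <- classify_positions(pa, pb, map, low_cutoff = 6)
  un <- rec[is.na(rec$column_b), ]
  expect_equal(un$class[un$column_a == 2], "indel")
  expect_equal(un$class[un$column_a == 3], "unconserved")
  expect_equal(nrow(rec), 4L)  # every column accounted for exactly once
})

test_that("active-site distances match constructed geometry", {
  s <- divcons:::new_structure(rep("A", 3),
                               rbind(c(0, 0, 0), c(21, 0, 0), c(5, 0, 0)))
  expect_equal(distance_to_active_site(s, active_site = 1L, residue = 1L), 0)
  expect_equal(distance_to_active_site(s, active_site = 1L, residue = 2L), 21)
  expect_error(distance_to_active_site(s, active_site = 9L, residue = 1L),
               "active-site residue 9")
})

test_that("minimum distances equal an exhaustive pair scan", {
  set.seed(33)
  for (trial in 1:10) {
    n <- sample(10:40, 1)
    xyz <- matrix(rnorm(3 * n, sd = 8), ncol = 3)
    s <- divcons:::new_structure(rep("A", n), xyz)
    site <- sample(n, sample(1:4, 1))
    res <- sample(n, 1)
    brute <- min(vapply(site, function(j)
      sqrt(sum((xyz[res, ] - xyz[j, ])^2)), 0))
    expect_equal(distance_to_active_site(s, site, res), brute)
  }
})

test_that("candidate selection respects and is monotone in the threshold", {
  pa <- make_profile(rep(9, 6), c("T", "K", "A", "G", "V", "L"))
  pb <- make_profile(c(3, 3, 3, 3, 3, 9),
                     c("S", "N", "W", "H", "C", "L"))
  map <- make_map(6, 6, 1:6, 1:6)
  rec <- classify_positions(pa, pb, map, low_cutoff = 6)
  s <- helix_structure(6)
  rec <- active_site_distances(rec, s, active_site = 1L, side = "A")
  at0 <- select_candidates(rec, distance_threshold = 0)
  expect_equal(sum(at0$selected), 1L)  # only the active-site residue itself
  atInf <- select_candidates(rec, distance_threshold = Inf)
  expect_equal(sum(atInf$selected), 5L)  # all candidates (class 6 is shared)
  prev <- integer(0)
  for (t in c(0, 4, 8, 16, Inf)) {
    cur <- which(select_candidates(rec, t)$selected)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # manual override forces non-candidate positions in
  forced <- select_candidates(rec, 0, forced = c(1L, 6L))
  expect_true(all(forced$selected[c(1, 6)]))
  smry <- attr(forced, "summary")
  expect_lte(smry$n_selected, nrow(rec))
})

test_that("candidate reports are deterministic and conserve records", {
  pa <- make_profile(c(9, 9), c("T", "K"))
  pb <- make_profile(c(9, 2), c("T", "N"))
  map <- make_map(2, 2, 1:2, 1:2)
  rec <- classify_positions(pa, pb, map, low_cutoff = 6)
  out <- candidate_report(rec)
  expect_equal(nrow(out), nrow(map$matched))
  expect_false(is.unsorted(out$res_a))
  empty <- rec[0, ]
  f <- tempfile()
  candidate_report(empty, f)
  tab <- read.delim(f, comment.char = "#")
  expect_equal(nrow(tab), 0L)
  expect_true("class" %in% names(tab))
})

test_that("the bundled position table re-emits losslessly", {
  path <- dop_pafa_file("positions")
  tab <- read.delim(path, colClasses = "character")
  out <- tempfile(fileext = ".tsv")
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(readLines(out), readLines(path))
  parsed <- read_position_table(path)
  expect_equal(nrow(parsed), 23L)
  expect_equal(sum(parsed$note == "c"), 9L)       # alpha-loop rows
  expect_equal(sum(parsed$note == "a"), 2L)       # deletion-covered rows
  expect_equal(parsed$dop_pos[parsed$no == "3"], 27L)
})
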