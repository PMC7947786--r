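test_that("read_fasta parses entries, preserves order and normalises", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a first one", "mkv", ">b", "MKL*"), f)
  recs <- read_fasta(f)
  expect_s3_class(recs, "divcons_seqs")
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$sequence, c("MKV", "MKL"))
  expect_equal(recs$description[[1L]], "first one")
})

test_that("read_fasta rejects malformed input with informative errors", {
  empty <- tempfile(); writeLines(character(0), empty)
  expect_error(read_fasta(empty), "no sequences")
  dup <- tempfile(); writeLines(c(">a", "MK", ">a", "ML"), dup)
  expect_error(read_fasta(dup), "duplicate sequence id: a")
  bad <- tempfile(); writeLines(c(">a", "MK1"), bad)
  expect_error(read_fasta(bad), "position 3")
  expect_error(read_fasta(bad), "'1'")
})

test_that("a generated 40-record family round-trips through FASTA", {
  set.seed(11)
  recs <- as.data.frame(random_records(40, 60))
  class(recs) <- c("divcons_seqs", "data.frame")
  f <- tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(nrow(back), 40L)
  expect_false(any(duplicated(back$id)))
  expect_equal(back$sequence, recs$sequence)
})

test_that("local alignment scores match trivial expectations", {
  set.seed(3)
  s <- random_seq(50)
  self <- pairwise_local_score(s, s)
  expect_equal(self$percent_identity, 100)
  expect_equal(self$percent_similarity, 100)
  shuffled <- paste(sample(strsplit(s, "")[[1L]]), collapse = "")
  expect_lt(pairwise_local_score(s, shuffled)$percent_identity, 100)
  expect_error(pairwise_local_score(s, s, matrix = "PAM250"),
               "unknown substitution matrix")
  expect_error(pairwise_local_score(s, s, gap_open = 0.5, gap_extend = 1),
               "gap_open")
})

test_that("local alignment equals the quadratic DP oracle and is symmetric", {
  set.seed(21)
  m62 <- substitution_matrix("BLOSUM62")
  for (i in 1:40) {
    a <- random_seq(sample(5:30, 1)); b <- random_seq(sample(5:30, 1))
    ab <- pairwise_local_score(a, b)
    expect_equal(ab$score_raw, sw_oracle(a, b, m62, 11, 1))
    expect_equal(ab$score_bits, pairwise_local_score(b, a)$score_bits)
    expect_gte(ab$percent_similarity, ab$percent_identity)
  }
  # the classic two-peptide example under BLOSUM50
  m50 <- substitution_matrix("BLOSUM50")
  p <- pairwise_local_score("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
                            gap_open = 10, gap_extend = 1)
  expect_equal(p$score_raw,
               sw_oracle("HEAGAWGHEE", "PAWHEAE", m50, 10, 1))
})

test_that("X is a neutral unknown in scoring", {
  m <- substitution_matrix("BLOSUM62")
  expect_true(all(m["X", ] == 0))
  expect_true(all(m[, "X"] == 0))
})

test_that("similarity network edges respect the threshold", {
  recs <- data.frame(id = c("a", "b", "c"), description = "",
                     sequence = rep(strrep("MKVLAWGHEE", 5), 3))
  class(recs) <- c("divcons_seqs", "data.frame")
  ssn <- build_ssn(recs, threshold = 20)
  expect_equal(nrow(ssn$edges), 3L)  # complete triangle of identical seqs
  expect_equal(nrow(ssn_threshold(ssn, Inf)$edges), 0L)
  expect_error(build_ssn(recs[1, ], threshold = 1), "at least 2")
  expect_error(build_ssn(recs, 1, max_pairs = 2), "max_pairs")
})

test_that("clusters are connected components, deterministically ordered", {
  set.seed(5)
  for (trial in 1:30) {
    n <- sample(5:30, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    n_edges <- sample(0:(2 * n), 1)
    edges <- data.frame(
      id_a = sample(nodes, n_edges, replace = TRUE),
      id_b = sample(nodes, n_edges, replace = TRUE),
      score_bits = rep(10, n_edges), stringsAsFactors = FALSE)
    edges <- edges[edges$id_a != edges$id_b, , drop = FALSE]
    ssn <- structure(list(nodes = nodes, edges = edges, all_scores = edges,
                          threshold = 1), class = "divcons_ssn")
    expect_identical(cluster_families(ssn), uf_components(nodes, edges))
  }
  lonely <- structure(list(nodes = letters[1:5],
                           edges = data.frame(id_a = character(0),
                                              id_b = character(0),
                                              score_bits = numeric(0)),
                           threshold = 1), class = "divcons_ssn")
  expect_equal(lengths(cluster_families(lonely)), rep(1L, 5))
})

test_that("raising the threshold never decreases the component count", {
  set.seed(8)
  recs <- as.data.frame(random_records(12, 40))
  # make some related pairs so scores spread
  recs$sequence[7:12] <- vapply(recs$sequence[1:6], function(s) {
    ch <- strsplit(s, "")[[1L]]
    ch[sample(40, 8)] <- sample(aa20, 8, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  class(recs) <- c("divcons_seqs", "data.frame")
  ssn <- build_ssn(recs, threshold = 0)
  n_comp <- vapply(seq(0, 120, by = 5), function(t)
    length(cluster_families(ssn_threshold(ssn, t))), 1L)
  expect_true(all(diff(n_comp) >= 0))
})

test_that("two planted families separate at the documented threshold", {
  b <- simulate_families(sim_config(seed = 303, n_per_family = 10))
  both <- rbind(b$seq_a, b$seq_b)
  class(both) <- c("divcons_seqs", "data.frame")
  ssn <- build_ssn(both, threshold = 40)
  fam <- substr(ssn$edges$id_a, 1, 1)
  expect_true(all(fam == substr(ssn$edges$id_b, 1, 1)))  # no between edges
  cl <- cluster_families(ssn)
  expect_equal(length(cl), 2L)
  expect_setequal(cl[[which(vapply(cl, function(x) "A001" %in% x, TRUE))]],
                  b$seq_a$id)
})

test_that("assign_reference validates membership", {
  expect_equal(assign_reference(c("a", "b", "c"), "b")$reference_id, "b")
  expect_error(assign_reference(c("a", "b"), "z"), "'z'")
})
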