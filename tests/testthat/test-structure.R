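test_that("PDB CA traces parse with exact coordinates", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  MET A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  LYS A   2       4.500  -1.250   0.000  1.00  0.00           C",
    "ATOM      3  CA  VAL A   3      -2.000   0.000   9.125  1.00  0.00           C",
    "END"), f)
  s <- read_structure(f, chain = "A")
  expect_equal(nrow(s), 3L)
  expect_equal(s$aa, c("M", "K", "V"))
  expect_equal(s$x, c(1, 4.5, -2))
  expect_equal(s$y, c(2, -1.25, 0))
  expect_equal(s$residue_number, 1:3)
  expect_error(read_structure(f, chain = "B"), "available chains: A")
})

test_that("residues lacking a CA atom are omitted with a warning", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  MET A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  N   LYS A   2       4.500  -1.250   0.000  1.00  0.00           N",
    "ATOM      3  CA  VAL A   3      -2.000   0.000   9.125  1.00  0.00           C",
    "END"), f)
  expect_warning(s <- read_structure(f, "A"), "without a CA")
  expect_equal(nrow(s), 2L)
  expect_equal(s$aa, c("M", "V"))
})

test_that("toy structures survive a write/read round trip", {
  toy <- make_toy_structures(20, noise_sd = 0, transform = "identity",
                             seed = 5)
  f <- tempfile(fileext = ".pdb")
  write_structure(toy$structure_a, f)
  back <- read_structure(f, chain = "A")
  expect_equal(back$residue_number, toy$structure_a$residue_number)
  expect_equal(back$x, toy$structure_a$x, tolerance = 1e-3)
  expect_equal(back$z, toy$structure_a$z, tolerance = 1e-3)
})

test_that("kabsch recovers planted rigid transforms", {
  set.seed(17)
  a <- matrix(rnorm(60), ncol = 3)
  ident <- kabsch(a, a)
  expect_equal(ident$rmsd, 0, tolerance = 1e-10)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-10)
  for (trial in 1:10) {
    r <- random_rotation_matrix()
    t <- rnorm(3, sd = 20)
    b <- sweep(a %*% r, 2, t, "+")
    sp <- kabsch(a, b)
    expect_lt(sp$rmsd, 1e-6)
    expect_equal(sp$rotation, r, tolerance = 1e-6)
    expect_equal(sp$translation, t, tolerance = 1e-6)
  }
  expect_error(kabsch(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch(line, line), "rank-deficient")
})

test_that("kabsch never returns a reflection for mirror-image inputs", {
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.3, 1))
  mirror <- chiral %*% diag(c(1, 1, -1))
  sp <- kabsch(chiral, mirror)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_gt(sp$rmsd, 0.1)
})

test_that("kabsch rmsd is invariant under rigid motion and optimal", {
  set.seed(23)
  a <- matrix(rnorm(45), ncol = 3)
  b <- a + matrix(rnorm(45, sd = 0.5), ncol = 3)
  base <- kabsch(a, b)$rmsd
  for (trial in 1:5) {
    r <- random_rotation_matrix()
    b2 <- sweep(b %*% r, 2, rnorm(3, sd = 10), "+")
    expect_equal(kabsch(a, b2)$rmsd, base, tolerance = 1e-6)
  }
  expect_lte(base, sqrt(mean(rowSums((a - b)^2))))  # beats identity transform
})

test_that("sequence seeding pairs identical structures completely", {
  toy <- make_toy_structures(30, noise_sd = 0, transform = "identity",
                             seed = 2, aa_a = random_seq(30),
                             aa_b = NULL)
  toy$structure_b$aa <- toy$structure_a$aa
  pr <- seed_pairs(toy$structure_a, toy$structure_b)
  expect_equal(pr[, 1], 1:30, ignore_attr = TRUE)
  expect_equal(pr[, 2], 1:30, ignore_attr = TRUE)
  # colinear by construction
  expect_true(all(diff(pr[, 1]) > 0) && all(diff(pr[, 2]) > 0))
})

test_that("seed pairs achieve the two-sequence global DP optimum", {
  set.seed(41)
  m62 <- substitution_matrix("BLOSUM62")
  for (trial in 1:10) {
    la <- sample(10:30, 1); lb <- sample(10:30, 1)
    sa <- random_seq(la); sb <- random_seq(lb)
    ma <- divcons:::new_structure(strsplit(sa, "")[[1L]],
                                  matrix(rnorm(3 * la), ncol = 3))
    mb <- divcons:::new_structure(strsplit(sb, "")[[1L]],
                                  matrix(rnorm(3 * lb), ncol = 3))
    pr <- seed_pairs(ma, mb)
    expect_equal(pairs_alignment_score(pr, sa, sb, m62, 11, 1),
                 nw_oracle(sa, sb, m62, 11, 1), ignore_attr = TRUE)
  }
})

test_that("iterative alignment pairs identical structures at rmsd 0", {
  toy <- make_toy_structures(40, noise_sd = 0, transform = "identity",
                             seed = 3)
  sp <- iterative_structural_align(toy$structure_a, toy$structure_b)
  expect_equal(nrow(sp$pairs), 40L)
  expect_equal(sp$pairs[, 1], sp$pairs[, 2], ignore_attr = TRUE)
  expect_lt(sp$rmsd, 1e-9)
})

test_that("a planted insertion is excluded from the structural pairing", {
  for (s in c(6, 7)) {
    toy <- make_toy_structures(60, insertion = list(family = "A",
                                                    start = 25, length = 5),
                               noise_sd = 0.2, seed = s)
    sp <- iterative_structural_align(toy$structure_a, toy$structure_b)
    expect_equal(sum(sp$pairs[, 1] %in% 25:29), 0L)
    expect_equal(nrow(sp$pairs), 55L)
    expect_equal(sp$pairs[, 1][sp$pairs[, 1] < 25],
                 sp$pairs[, 2][sp$pairs[, 1] < 25], ignore_attr = TRUE)
  }
})

test_that("the structural pairing is invariant to initial rigid transforms", {
  toy <- make_toy_structures(50, noise_sd = 0.2, seed = 11)
  ref <- iterative_structural_align(toy$structure_a, toy$structure_b)
  set.seed(19)
  for (trial in 1:5) {
    r <- random_rotation_matrix(); t <- rnorm(3, sd = 30)
    sb <- toy$structure_b
    xyz <- sweep(as.matrix(sb[, c("x", "y", "z")]) %*% r, 2, t, "+")
    sb$x <- xyz[, 1]; sb$y <- xyz[, 2]; sb$z <- xyz[, 3]
    sp <- iterative_structural_align(toy$structure_a, sb)
    expect_equal(sp$pairs, ref$pairs)
    expect_equal(sp$rmsd, ref$rmsd, tolerance = 1e-6)
  }
})

test_that("residue pairs lift to colinear alignment columns", {
  # single-sequence 'families', gap-free and identical
  s <- random_seq(12)
  aln <- divcons:::new_alignment(c(ref = s), reference_id = "ref")
  pairs <- cbind(res_a = 1:12, res_b = 1:12)
  map <- lift_to_columns(pairs, aln, aln)
  expect_equal(nrow(map$matched), 12L)
  expect_equal(length(map$unmatched_a), 0L)
  expect_true(all(diff(map$matched$column_a) > 0))
  expect_true(all(diff(map$matched$column_b) > 0))
  # a residue number beyond the reference errors informatively
  expect_error(lift_to_columns(cbind(1:13, 1:13), aln, aln),
               "residue 13")
})

test_that("unmatched reference columns cover the planted insertion", {
  b <- simulate_families(sim_config(seed = 13, n_per_family = 12,
                                    insertion = list(family = "A",
                                                     start = 40,
                                                     length = 5)))
  sp <- iterative_structural_align(b$structure_a, b$structure_b)
  aln_a <- divcons:::new_alignment(
    setNames(b$seq_a$sequence[1], b$reference_a),
    reference_id = b$reference_a)
  aln_b <- divcons:::new_alignment(
    setNames(b$seq_b$sequence[1], b$reference_b),
    reference_id = b$reference_b)
  map <- lift_to_columns(sp$pairs, aln_a, aln_b)
  expect_equal(map$unmatched_a, 40:44)
  expect_equal(length(map$unmatched_b), 0L)
})
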