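test_that("pair_distance is the weighted L1 distance on normalized scales", {
  ps <- example_property_set()
  # hand evaluation on the printed example values: hydrophobicity range
  # 2.46 (-1.76..0.7), size range 146 (0..146)
  expected <- 0.6 * abs((0.25 + 1.76) / 2.46 - (0.2 + 1.76) / 2.46) +
    0.4 * abs(28 / 146 - 0)
  expect_equal(pair_distance("A", "G", ps), expected, tolerance = 1e-9)
  expect_equal(pair_distance("A", "G", ps), 0.088907, tolerance = 1e-5)
  # identical residues at distance zero; symmetry
  for (a in c("A", "W", "C")) expect_identical(pair_distance(a, a, ps), 0)
  for (pair in list(c("A", "W"), c("R", "C"), c("G", "V")))
    expect_identical(pair_distance(pair[1], pair[2], ps),
                     pair_distance(pair[2], pair[1], ps))
  # raw (unnormalized) distances are also available
  expect_equal(pair_distance("A", "G", ps, normalize = FALSE),
               0.6 * abs(0.25 - 0.2) + 0.4 * 28, tolerance = 1e-12)
})

test_that("a single unit-weight scale reduces the distance to |p(x) - p(y)|", {
  sizes <- example_property_set()$scales$Size
  ps1 <- property_set(list(Size = sizes), 1)
  for (pair in list(c("A", "G"), c("W", "G"), c("K", "M")))
    expect_equal(pair_distance(pair[1], pair[2], ps1),
                 abs(sizes[[pair[1]]] - sizes[[pair[2]]]) / 146,
                 tolerance = 1e-12)
})

test_that("unknown residues follow the strict/mean policy", {
  ps <- example_property_set()
  expect_error(pair_distance("B", "A", ps), "non-standard residue 'B'")
  expect_error(align_property("ACB", "ACD", ps), "position 3")
  d <- pair_distance("X", "X", ps, on_unknown = "mean")
  expect_identical(d, 0)
  aln <- align_property("ACX", "ACX", ps, on_unknown = "mean")
  expect_identical(aln$score, 0)
})

test_that("gap_penalty implements the affine form alpha + (r - 1) * beta", {
  expect_identical(gap_penalty(1, gap_params(0.7, 0.1)), 0.7)
  expect_equal(gap_penalty(3, gap_params(0.7, 0.1)), 0.9, tolerance = 1e-12)
  expect_identical(gap_penalty(1, gap_params(0, 5)), 0)
  expect_error(gap_penalty(0, gap_params(0.7, 0.1)), ">= 1")
  expect_error(gap_params(-0.1, 0.1), ">= 0")
})

test_that("boundary alignments behave per the DP boundary conditions", {
  ps <- example_property_set()
  # empty vs length-m: m gap columns costing one affine run
  aln <- align_property("", "ACDEF", ps, gap_params(0.5, 0.1))
  expect_identical(aln$aligned_x, "-----")
  expect_identical(aln$aligned_y, "ACDEF")
  expect_equal(aln$score, 0.5 + 4 * 0.1, tolerance = 1e-12)
  # both empty
  aln0 <- align_property("", "", ps)
  expect_identical(aln0$score, 0)
  expect_identical(aln0$n_columns, 0L)
  # identical sequences align gaplessly at score 0
  aln1 <- align_property("MKVLAW", "MKVLAW", ps, gap_params(0.7, 0.1))
  expect_identical(aln1$aligned_x, "MKVLAW")
  expect_identical(aln1$score, 0)
  expect_identical(aln1$percent_identity, 100)
})

test_that("property aligner matches exhaustive enumeration on small instances", {
  ps <- example_property_set()
  D <- oracle_distance_matrix(ps)
  sub_ab <- c("A", "G", "W", "C")
  set.seed(42)
  for (rep in 1:120) {
    x <- random_protein(sample(0:6, 1), sub_ab)
    y <- random_protein(sample(0:6, 1), sub_ab)
    a <- runif(1, 0.1, 1); b <- runif(1, 0, a)
    oracle <- brute_force_optimum(x, y, D, a, b, minimize = TRUE)
    aln <- align_property(x, y, ps, gap_params(a, b))
    expect_equal(aln$score, oracle, tolerance = 1e-9)
    # returned alignment re-scores to the reported optimum
    expect_equal(score_alignment(aln$aligned_x, aln$aligned_y, ps,
                                 gap_params(a, b)),
                 aln$score, tolerance = 1e-9)
  }
})

test_that("matrix aligner matches exhaustive enumeration and hand cases", {
  m <- toy_identity_matrix(match = 2, mismatch = -1)
  # two matches plus one length-1 gap
  expect_identical(align_matrix("AAA", "AA", m, open = -1, extend = -1)$score, 3)
  # self-alignment is gapless with summed diagonal score
  aln <- align_matrix("AWCK", "AWCK", m, open = -5, extend = -1)
  expect_identical(aln$aligned_x, "AWCK")
  expect_identical(aln$score, 8)
  set.seed(7)
  sub_ab <- c("A", "G", "W", "C")
  for (rep in 1:60) {
    x <- random_protein(sample(1:6, 1), sub_ab)
    y <- random_protein(sample(1:6, 1), sub_ab)
    open <- -sample(1:5, 1); ext <- -sample(1:3, 1)
    oracle <- brute_force_optimum(x, y, m, open, ext, minimize = FALSE)
    expect_equal(align_matrix(x, y, m, open, ext)$score, oracle,
                 tolerance = 1e-9)
  }
})

test_that("matrix aligner agrees with Biostrings on global alignment scores", {
  m <- toy_identity_matrix(match = 3L, mismatch = -2L)
  storage.mode(m) <- "integer"
  set.seed(11)
  for (rep in 1:20) {
    x <- random_protein(sample(3:12, 1))
    y <- random_protein(sample(3:12, 1))
    open <- -sample(2:8, 1); ext <- -sample(1:2, 1)
    mine <- align_matrix(x, y, m, open, ext)$score
    # Biostrings charges gapOpening + r * gapExtension for a length-r gap,
    # so opening there is alpha - beta in this package's affine form
    ref <- Biostrings::pairwiseAlignment(x, y, type = "global",
                                         substitutionMatrix = m,
                                         gapOpening = -(open - ext),
                                         gapExtension = -ext,
                                         scoreOnly = TRUE)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("alignment score is symmetric and monotone in the gap penalties", {
  ps <- example_property_set()
  set.seed(3)
  for (rep in 1:25) {
    x <- random_protein(sample(1:10, 1))
    y <- random_protein(sample(1:10, 1))
    g <- gap_params(runif(1, 0.1, 0.9), runif(1, 0.05, 0.3))
    sxy <- align_property(x, y, ps, g)$score
    syx <- align_property(y, x, ps, g)$score
    expect_equal(sxy, syx, tolerance = 1e-9)
    # raising alpha or beta can only raise the optimal distance
    expect_gte(align_property(x, y, ps, gap_params(g$alpha + 0.2, g$beta))$score,
               sxy - 1e-12)
    expect_gte(align_property(x, y, ps, gap_params(g$alpha, g$beta + 0.1))$score,
               sxy - 1e-12)
    # with free gaps the optimum is still nonnegative
    expect_gte(align_property(x, y, ps, gap_params(0, 0))$score, 0)
  }
})

test_that("alignment results reconstruct their inputs and internal tallies", {
  ps <- example_property_set()
  set.seed(5)
  for (rep in 1:25) {
    x <- random_protein(sample(0:12, 1))
    y <- random_protein(sample(0:12, 1))
    aln <- align_property(x, y, ps, gap_params(0.4, 0.1))
    expect_identical(gsub("-", "", aln$aligned_x), x)
    expect_identical(gsub("-", "", aln$aligned_y), y)
    cx <- strsplit(aln$aligned_x, "")[[1]]; cy <- strsplit(aln$aligned_y, "")[[1]]
    expect_false(any(cx == "-" & cy == "-"))
    expect_identical(aln$n_columns, nchar(aln$aligned_x))
    expect_identical(aln$n_aligned_pairs, sum(cx != "-" & cy != "-"))
  }
})

test_that("score_alignment validates its inputs", {
  ps <- example_property_set()
  expect_identical(score_alignment("ACD", "ACD", ps, gap_params(0.7, 0.1)), 0)
  expect_error(score_alignment("AC-", "A-C-", ps, gap_params(0.7, 0.1)), "equal length")
  expect_error(score_alignment("A-D", "A-D", ps, gap_params(0.7, 0.1)), "gap-gap")
})

test_that("substitution matrix files parse and validate", {
  m <- toy_identity_matrix(1, 0)
  path <- withr::local_tempfile(fileext = ".mat")
  writeLines(c("# toy matrix",
               paste(" ", paste(colnames(m), collapse = "  ")),
               vapply(rownames(m), function(r)
                 paste(r, paste(m[r, ], collapse = " ")), "")),
             path)
  m2 <- read_substitution_matrix(path)
  expect_identical(unname(m2), unname(m) * 1.0)
  expect_identical(rownames(m2), aa_alphabet())
  # asymmetric matrices are rejected
  bad <- m; bad["A", "C"] <- 5
  writeLines(c(paste(colnames(bad), collapse = " "),
               vapply(rownames(bad), function(r)
                 paste(r, paste(bad[r, ], collapse = " ")), "")),
             path)
  expect_error(read_substitution_matrix(path), "symmetric")
})

test_that("identity estimation counts identities over aligned pairs", {
  expect_identical(estimate_identity("MKVAW", "MKVAW"), 100)
  m <- toy_identity_matrix(2, 1)  # positive everywhere: no-gap alignment
  expect_identical(estimate_identity("AAAA", "GGGG", m), 0)
  # 4 identical of 8 aligned pairs under a gapless optimal alignment
  expect_identical(estimate_identity("AGAGAGAG", "AAAAGGGG", m), 50)
  expect_error(estimate_identity("", "ACD"), "empty")
})
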