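test_that("weight_grid enumerates the simplex grid exactly once", {
  expect_identical(weight_grid(1, 0.05), matrix(1, 1, 1))
  g2 <- weight_grid(2, 0.5)
  expect_identical(nrow(g2), 3L)
  expect_identical(g2[, 1], c(0, 0.5, 1))
  # stars-and-bars count for the default 4-property, 0.05-step grid
  g4 <- weight_grid(4, 0.05)
  expect_identical(nrow(g4), as.integer(choose(23, 3)))  # 1771
  expect_false(anyDuplicated(g4) > 0)
  expect_true(all(abs(rowSums(g4) - 1) <= 1e-9))
  expect_true(all(g4 >= 0))
  # closed-form count holds for other (k, step) too
  for (cfg in list(c(2, 0.25), c(3, 0.2), c(5, 0.5))) {
    g <- weight_grid(cfg[1], cfg[2])
    expect_identical(nrow(g),
                     as.integer(choose(round(1 / cfg[2]) + cfg[1] - 1,
                                       cfg[1] - 1)))
    expect_true(all(abs(rowSums(g) - 1) <= 1e-9))
  }
  expect_error(weight_grid(2, 0.3), "integer")
})

test_that("family subsampling caps over-represented families deterministically", {
  mk <- function(fam, i) reference_pair(sprintf("%s_%d", fam, i),
                                        c("ACDE", "ACDE"), family_id = fam)
  pairs <- c(lapply(1:4, mk, fam = "a"),
             lapply(1:12, mk, fam = "b"),
             lapply(1:30, mk, fam = "c"))
  # all families under the cap: unchanged, order preserved
  small <- lapply(1:3, mk, fam = "z")
  expect_identical(subsample_families(small, 10, seed = 1), small)
  out <- subsample_families(pairs, 10, seed = 7)
  expect_length(out, 4 + 10 + 10)
  fams <- vapply(out, function(p) p$family_id, "")
  expect_identical(sum(fams == "a"), 4L)
  expect_identical(sum(fams == "b"), 10L)
  expect_identical(sum(fams == "c"), 10L)
  # reproducible for a fixed seed, and ignores the caller's RNG state
  set.seed(999)
  out2 <- subsample_families(pairs, 10, seed = 7)
  expect_identical(vapply(out2, function(p) p$pair_id, ""),
                   vapply(out, function(p) p$pair_id, ""))
  out3 <- subsample_families(pairs, 10, seed = 8)
  expect_false(identical(vapply(out3, function(p) p$pair_id, ""),
                         vapply(out, function(p) p$pair_id, "")))
})

test_that("complexity_estimate reproduces the grid-search alignment counts", {
  expect_equal(complexity_estimate(6000, 20, 4), 3.84e11, tolerance = 1e-12)
  expect_identical(complexity_estimate(1, 1, 3), 1)
  expect_identical(complexity_estimate(10, 3, 2), 810)
})

test_that("property grid search maximizes Q_AVER over the full grid", {
  ps <- example_property_set()
  # perfect-identity benchmark: every grid point achieves 100, so the
  # first point in enumeration order is returned
  pairs_eq <- lapply(1:3, function(i) {
    s <- random_protein(10)
    reference_pair(paste0("e", i), c(s, s), family_id = "f")
  })
  grid <- grid_spec(weight_step = 0.5, gap_grid = c(0.3, 0.6),
                    max_pairs_per_family = Inf, keep_trace = TRUE)
  res <- grid_search_property(pairs_eq, ps, grid)
  expect_identical(res$best_q_aver, 100)
  expect_identical(unname(res$best_weights), c(0, 1))
  expect_identical(res$best_alpha, 0.3)
  expect_identical(res$best_beta, 0.3)
  expect_identical(res$evaluated, 3L * 4L)
  expect_identical(max(res$trace$q_aver), res$best_q_aver)

  # independent exhaustive loop over the same grid reproduces the optimum
  set.seed(17)
  cfg <- simulation_config(n_families = 4, pairs_per_family = 3,
                           ancestor_length = 30, seed = 17)
  bench <- generate_benchmark(cfg)
  grid2 <- grid_spec(weight_step = 0.5, gap_grid = c(0.2, 0.5, 0.8),
                     max_pairs_per_family = Inf)
  res2 <- grid_search_property(bench$pairs, ps, grid2)
  best <- -Inf; arg <- NULL
  for (r in seq_len(nrow(weight_grid(2, 0.5)))) {
    w <- weight_grid(2, 0.5)[r, ]
    psw <- property_set(ps$scales, w)
    for (a in c(0.2, 0.5, 0.8)) for (b in c(0.2, 0.5, 0.8)) {
      alns <- lapply(bench$pairs, function(p)
        align_property(p$x, p$y, psw, gap_params(a, b)))
      q <- q_aver(alns, lapply(bench$pairs, function(p) p$reference))
      if (q > best) { best <- q; arg <- c(w, a, b) }
    }
  }
  expect_identical(res2$best_q_aver, best)
  expect_identical(unname(res2$best_weights), arg[1:2])
  expect_identical(res2$best_alpha, arg[3])
  expect_identical(res2$best_beta, arg[4])
  # invariant to the order of the input pairs
  res2r <- grid_search_property(rev(bench$pairs), ps, grid2)
  expect_identical(res2r$best_q_aver, res2$best_q_aver)
  expect_identical(res2r$best_weights, res2$best_weights)
})

test_that("refining the grid can only improve or tie the optimum", {
  ps <- example_property_set()
  set.seed(29)
  cfg <- simulation_config(n_families = 3, pairs_per_family = 3,
                           ancestor_length = 25, seed = 29)
  bench <- generate_benchmark(cfg)
  coarse <- grid_search_property(bench$pairs, ps,
                                 grid_spec(weight_step = 1,
                                           gap_grid = c(0.2, 0.8),
                                           max_pairs_per_family = Inf))
  fine <- grid_search_property(bench$pairs, ps,
                               grid_spec(weight_step = 0.5,
                                         gap_grid = c(0.2, 0.5, 0.8),
                                         max_pairs_per_family = Inf))
  expect_gte(fine$best_q_aver, coarse$best_q_aver)
})

test_that("matrix grid search matches an independent exhaustive loop", {
  m <- toy_identity_matrix(2, -1)
  set.seed(37)
  cfg <- simulation_config(n_families = 3, pairs_per_family = 3,
                           ancestor_length = 25, seed = 37)
  bench <- generate_benchmark(cfg)
  # single-point grid returns that point
  res1 <- grid_search_matrix(bench$pairs, m, open_grid = -3, extend_grid = -1)
  expect_identical(res1$evaluated, 1L)
  expect_identical(res1$best_open, -3)
  og <- -(1:4); eg <- -(1:2)
  res <- grid_search_matrix(bench$pairs, m, og, eg, keep_trace = TRUE)
  expect_identical(res$evaluated, 8L)
  best <- -Inf; arg <- NULL
  for (o in og) for (e in eg) {
    alns <- lapply(bench$pairs, function(p) align_matrix(p$x, p$y, m, o, e))
    q <- q_aver(alns, lapply(bench$pairs, function(p) p$reference))
    if (q > best) { best <- q; arg <- c(o, e) }
  }
  expect_identical(res$best_q_aver, best)
  expect_identical(c(res$best_open, res$best_extend), arg)
})
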