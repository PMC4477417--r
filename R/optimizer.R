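# Exhaustive grid search for the property weights and affine gap penalties
# maximizing mean alignment accuracy (Q_AVER) on a benchmark of reference
# alignments. The search is deliberately exhaustive -- no hill climbing --
# and its enumeration order (weight vectors lexicographic, then alpha, then
# beta ascending) fixes the argmax on ties, so results are deterministic and
# independent of the order of the input pairs.

#' All weight vectors on a simplex grid
#'
#' Enumerates every vector of `k` nonnegative multiples of `step` summing to
#' 1 -- the compositions of `1/step` into `k` parts -- in lexicographic
#' order of the first, then second, ... coordinate (ascending).
#'
#' @param k Number of properties, `>= 1`.
#' @param step Grid increment; `1/step` must be an integer (within `1e-9`).
#' @return A matrix with `k` columns, one row per weight vector. The row
#'   count is `choose(1/step + k - 1, k - 1)`.
#' @export
#' @examples
#' weight_grid(2, 0.5)
weight_grid <- function(k, step) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
    stop("'k' must be an integer >= 1")
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a positive number")
  m <- 1 / step
  if (abs(m - round(m)) > 1e-9)
    stop(sprintf("1/step must be an integer (step = %g does not divide 1)", step))
  m <- as.integer(round(m))
  compositions <- function(total, parts) {
    if (parts == 1L) return(matrix(total, 1L, 1L))
    out <- vector("list", total + 1L)
    for (first in 0:total) {
      rest <- compositions(total - first, parts - 1L)
      out[[first + 1L]] <- cbind(first, rest)
    }
    do.call(rbind, out)
  }
  g <- compositions(m, as.integer(k)) * step
  dimnames(g) <- NULL
  g
}

#' Cap the number of benchmark pairs per family
#'
#' Families (e.g. protein super-families) with more than `max_per_family`
#' pairs are down-sampled uniformly without replacement so over-represented
#' families do not dominate the optimization objective. Selection is
#' reproducible for a fixed seed; the caller's RNG state is untouched, and
#' the original order of the retained pairs is preserved.
#'
#' @param pairs List of [reference_pair()] objects with `family_id` set.
#' @param max_per_family Maximum pairs retained per family, `>= 1`.
#' @param seed Integer seed for the subsampling.
#' @return The retained pairs, in original order.
#' @export
subsample_families <- function(pairs, max_per_family = 10L, seed = 1L) {
  if (max_per_family < 1L) stop("'max_per_family' must be >= 1")
  fams <- vapply(pairs, function(p) {
    if (!inherits(p, "reference_pair") || is.na(p$family_id) || !nzchar(p$family_id))
      stop("every pair must be a reference_pair with a family_id")
    p$family_id
  }, "")
  keep <- rep(TRUE, length(pairs))
  with_seed(seed, {
    for (f in unique(fams)) {
      idx <- which(fams == f)
      if (length(idx) > max_per_family)
        keep[setdiff(idx, sort(sample(idx, max_per_family)))] <- FALSE
    }
  })
  pairs[keep]
}

#' Grid-search specification
#'
#' @param weight_step Increment of the weight simplex grid (default 0.05,
#'   a 20-point grid).
#' @param gap_grid Numeric vector of candidate values shared by the gap
#'   initiation and extension penalties (default `0.1, 0.2, ..., 1.0`, a
#'   10-point grid with 0.1 increments).
#' @param max_pairs_per_family Subsampling cap applied before the search
#'   (`Inf` to disable).
#' @param seed Seed for the subsampling.
#' @param keep_trace Keep the full per-grid-point Q_AVER landscape.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(weight_step = 0.05, gap_grid = seq(0.1, 1.0, by = 0.1),
                      max_pairs_per_family = 10L, seed = 1L,
                      keep_trace = FALSE) {
  if (weight_step <= 0 || any(gap_grid < 0)) stop("grid values must be nonnegative")
  structure(list(weight_step = weight_step, gap_grid = gap_grid,
                 max_pairs_per_family = max_pairs_per_family, seed = seed,
                 keep_trace = isTRUE(keep_trace)),
            class = "grid_spec")
}

# shared exhaustive-search loop: `eval_point(point) -> Q_AVER`
run_grid <- function(points, eval_point) {
  best_q <- -Inf; best_i <- NA_integer_
  qs <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    q <- eval_point(points[i, ])
    qs[i] <- q
    if (q > best_q) { best_q <- q; best_i <- i }   # first-encountered tie-break
  }
  list(best_i = best_i, best_q = best_q, qs = qs)
}

# fast inner loop shared by both searches: pre-encoded sequences + reference
# pair keys, alignment by the C-level DP, Q from index-pair set overlap
prepare_pairs <- function(pairs) {
  lapply(pairs, function(p) {
    stopifnot(inherits(p, "reference_pair"))
    cx <- seq_chars(p$x$seq); cy <- seq_chars(p$y$seq)
    m <- length(cy)
    list(xi = match(cx, aa_alphabet()) - 1L,
         yi = match(cy, aa_alphabet()) - 1L,
         m = m,
         ref_keys = aligned_pair_keys(p$reference, m),
         ref_n = n_aligned_pairs(p$reference))
  })
}

q_from_dp <- function(fit, prep) {
  both <- fit$ax >= 0L & fit$ay >= 0L
  xpos <- cumsum(fit$ax >= 0L)[both]
  ypos <- cumsum(fit$ay >= 0L)[both]
  keys <- xpos * (prep$m + 1) + ypos
  n_i <- length(intersect(keys, prep$ref_keys))
  l_t <- sum(both)
  f_d <- n_i / prep$ref_n * 100
  f_m <- if (l_t == 0L) 0 else n_i / l_t * 100
  (f_d + f_m) / 2
}

#' Grid search over property weights and gap penalties
#'
#' Evaluates mean accuracy (Q_AVER, see [q_aver()]) of the property aligner
#' for every combination of a weight vector on the simplex grid and gap
#' penalties `alpha`, `beta` on the gap grid, and returns the maximizer.
#' Any unknown residues in the benchmark sequences are rejected.
#'
#' @param pairs List of [reference_pair()] objects.
#' @param props A [property_set()] supplying the scales; its weights are
#'   replaced by each grid point in turn.
#' @param grid A [grid_spec()].
#' @param normalize Min-max normalize the scales (default `TRUE`).
#' @return A list of class `grid_search_result`: `best_weights` (named),
#'   `best_alpha`, `best_beta`, `best_q_aver`, `evaluated` (number of grid
#'   points), `n_pairs` (after subsampling), and `trace` (data frame, when
#'   kept).
#' @export
grid_search_property <- function(pairs, props, grid = grid_spec(),
                                 normalize = TRUE) {
  stopifnot(inherits(props, "property_set"), inherits(grid, "grid_spec"))
  if (length(pairs) == 0L) stop("'pairs' must contain at least one reference pair")
  if (is.finite(grid$max_pairs_per_family))
    pairs <- subsample_families(pairs, grid$max_pairs_per_family, grid$seed)
  prep <- prepare_pairs(pairs)
  k <- length(props$scales)
  W <- weight_grid(k, grid$weight_step)
  P <- profile_matrix(props, normalize = normalize)
  gg <- grid$gap_grid
  points <- cbind(W[rep(seq_len(nrow(W)), each = length(gg)^2), , drop = FALSE],
                  alpha = rep(rep(gg, each = length(gg)), nrow(W)),
                  beta = rep(gg, nrow(W) * length(gg)))
  abs_diffs <- lapply(seq_len(k), function(b) abs(outer(P[, b], P[, b], "-")))
  last_w <- NULL; D <- NULL
  res <- run_grid(points, function(pt) {
    w <- pt[seq_len(k)]
    if (is.null(last_w) || any(w != last_w)) {
      D <<- Reduce(`+`, Map(`*`, as.list(w), abs_diffs))
      last_w <<- w
    }
    qs <- vapply(prep, function(pp) {
      fit <- .gotoh_align(pp$xi, pp$yi, D, pt[[k + 1L]], pt[[k + 2L]])
      q_from_dp(fit, pp)
    }, 0)
    mean(qs)
  })
  out <- list(best_weights = stats::setNames(points[res$best_i, seq_len(k)],
                                             names(props$scales)),
              best_alpha = unname(points[res$best_i, k + 1L]),
              best_beta = unname(points[res$best_i, k + 2L]),
              best_q_aver = res$best_q, evaluated = nrow(points),
              n_pairs = length(pairs), trace = NULL)
  if (grid$keep_trace)
    out$trace <- data.frame(points, q_aver = res$qs)
  structure(out, class = "grid_search_result")
}

#' Grid search over integer gap penalties for the matrix baseline
#'
#' Exhaustively evaluates Q_AVER of [align_matrix()] over an integer grid of
#' (opening, extension) penalties and returns the maximizer (ties broken by
#' enumeration order: opening, then extension, ascending over the supplied
#' grids).
#'
#' @param pairs List of [reference_pair()] objects.
#' @param matrix Substitution matrix.
#' @param open_grid,extend_grid Candidate penalties (conventional negative
#'   values, e.g. `-(1:50)` for a 50-point grid).
#' @param max_pairs_per_family,seed Family subsampling as in
#'   [grid_search_property()] (`Inf` disables).
#' @param keep_trace Keep the full landscape.
#' @return A `grid_search_result` with `best_open`, `best_extend`,
#'   `best_q_aver`, `evaluated`, `n_pairs`, `trace`.
#' @export
grid_search_matrix <- function(pairs, matrix, open_grid = -(1:50),
                               extend_grid = -(1:50),
                               max_pairs_per_family = Inf, seed = 1L,
                               keep_trace = FALSE) {
  if (length(pairs) == 0L) stop("'pairs' must contain at least one reference pair")
  if (any(open_grid > 0) || any(extend_grid > 0))
    stop("matrix gap penalties are conventional negative values")
  if (is.finite(max_pairs_per_family))
    pairs <- subsample_families(pairs, max_pairs_per_family, seed)
  for (p in pairs) {
    check_matrix_coverage(matrix, seq_chars(p$x$seq), p$pair_id)
    check_matrix_coverage(matrix, seq_chars(p$y$seq), p$pair_id)
  }
  prep <- lapply(pairs, function(p) {
    cx <- seq_chars(p$x$seq); cy <- seq_chars(p$y$seq)
    m <- length(cy)
    list(xi = match(cx, rownames(matrix)) - 1L,
         yi = match(cy, rownames(matrix)) - 1L,
         m = m,
         ref_keys = aligned_pair_keys(p$reference, m),
         ref_n = n_aligned_pairs(p$reference))
  })
  negD <- -matrix
  points <- cbind(open = rep(open_grid, each = length(extend_grid)),
                  extend = rep(extend_grid, length(open_grid)))
  res <- run_grid(points, function(pt) {
    qs <- vapply(prep, function(pp) {
      fit <- .gotoh_align(pp$xi, pp$yi, negD, -pt[["open"]], -pt[["extend"]])
      q_from_dp(fit, pp)
    }, 0)
    mean(qs)
  })
  out <- list(best_open = unname(points[res$best_i, "open"]),
              best_extend = unname(points[res$best_i, "extend"]),
              best_q_aver = res$best_q, evaluated = nrow(points),
              n_pairs = length(pairs), trace = NULL)
  if (keep_trace) out$trace <- data.frame(points, q_aver = res$qs)
  structure(out, class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("Grid search: %d point(s) evaluated on %d pair(s)\n",
              x$evaluated, x$n_pairs))
  if (!is.null(x$best_weights))
    cat("  best weights:", paste(sprintf("%s=%.6g", names(x$best_weights),
                                         x$best_weights), collapse = ", "), "\n")
  if (!is.null(x$best_alpha))
    cat(sprintf("  best gap penalties: alpha=%.6g beta=%.6g\n",
                x$best_alpha, x$best_beta))
  if (!is.null(x$best_open))
    cat(sprintf("  best gap penalties: open=%g extend=%g\n",
                x$best_open, x$best_extend))
  cat(sprintf("  best Q_AVER: %.6g\n", x$best_q_aver))
  invisible(x)
}

#' Number of alignments a full grid search performs
#'
#' A search over `grid_points` values for each of `k` property weights and
#' the two gap penalties, on `n_pairs` benchmark pairs, performs
#' `n_pairs * grid_points^(k + 2)` pairwise alignments -- the reason the
#' number of default properties is kept small.
#'
#' @param n_pairs Number of benchmark sequence pairs.
#' @param grid_points Grid points per dimension.
#' @param k Number of properties.
#' @return The alignment count (as a double, since it overflows integers).
#' @export
#' @examples
#' complexity_estimate(6000, 20, 4)   # ~3.8e11
complexity_estimate <- function(n_pairs, grid_points, k) {
  stopifnot(n_pairs >= 1, grid_points >= 1, k >= 1)
  as.numeric(n_pairs) * as.numeric(grid_points)^(k + 2)
}
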