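#' Affine gap penalties
#'
#' The cost of a gap of length `r` is `alpha + (r - 1) * beta`: a fixed gap
#' initiation cost plus a linear extension cost per additional gapped
#' position. Both parameters are distances (nonnegative); terminal gaps are
#' penalized like internal ones (true global alignment).
#'
#' @param alpha Gap initiation penalty, `>= 0`.
#' @param beta Gap extension penalty, `>= 0`.
#' @return An object of class `gap_params`.
#' @export
gap_params <- function(alpha = 0.7, beta = 0.1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("'alpha' (gap initiation penalty) must be a single number >= 0")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0)
    stop("'beta' (gap extension penalty) must be a single number >= 0")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "gap_params")
}

#' Affine penalty of a single gap
#'
#' @param length Gap length in positions, `>= 1`.
#' @param gaps A [gap_params()].
#' @return `alpha + (length - 1) * beta`.
#' @export
#' @examples
#' gap_penalty(3, gap_params(0.7, 0.1))
gap_penalty <- function(length, gaps) {
  stopifnot(inherits(gaps, "gap_params"))
  if (any(length < 1) || any(length != floor(length)))
    stop("gap 'length' must be an integer >= 1")
  gaps$alpha + (length - 1) * gaps$beta
}

# ---- residue coding ------------------------------------------------------

as_seq_record <- function(x, id = "seq") {
  if (is.list(x) && !is.null(x$seq))
    return(list(id = as.character(x$id %||% id),
                desc = as.character(x$desc %||% ""),
                seq = toupper(as.character(x$seq))))
  if (is.character(x) && length(x) == 1L)
    return(list(id = id, desc = "", seq = toupper(x)))
  stop("expected a sequence string or a record with a $seq field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seq_chars <- function(seq) {
  if (nchar(seq) == 0L) character(0) else strsplit(seq, "", fixed = TRUE)[[1L]]
}

# Map residues to 0-based rows of the profile matrix. Unknown residues are a
# hard error by default; the "mean" policy sends them to an appended row
# holding each scale's mean over the 20 standard letters.
encode_residues <- function(chars, extra_letters = character(0),
                            on_unknown = c("error", "mean"), what = "sequence") {
  on_unknown <- match.arg(on_unknown)
  idx <- match(chars, c(aa_alphabet(), extra_letters))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    if (on_unknown == "error")
      stop(sprintf("%s contains non-standard residue '%s' at position %d (use on_unknown = \"mean\" to impute)",
                   what, chars[bad], bad))
    return(NULL) # caller augments the profile and re-encodes
  }
  idx - 1L
}

# Weighted L1 distance matrix over (possibly augmented) profile rows
property_distance_matrix <- function(props, normalize = TRUE,
                                     extra_letters = character(0)) {
  P <- profile_matrix(props, normalize = normalize)
  if (length(extra_letters) > 0L) {
    mean_row <- colMeans(P)
    P <- rbind(P, matrix(rep(mean_row, each = length(extra_letters)),
                         nrow = length(extra_letters)))
  }
  w <- unname(props$weights)
  D <- matrix(0, nrow(P), nrow(P))
  for (b in seq_along(w))
    D <- D + w[b] * abs(outer(P[, b], P[, b], "-"))
  D
}

#' Weighted property distance between two residues
#'
#' The distance between residues `x` and `y` is the weighted L1 distance
#' between their property vectors: `sum_b w(b) * |p_b(x) - p_b(y)|`. It is
#' symmetric and zero exactly when all property values agree.
#'
#' @param x,y Single residue characters.
#' @param props A [property_set()].
#' @param normalize Apply min-max normalization to each scale first
#'   (default `TRUE`).
#' @param on_unknown Policy for residues outside the 20-letter alphabet:
#'   `"error"` (default) or `"mean"` (impute each scale's mean).
#' @return A nonnegative number.
#' @export
pair_distance <- function(x, y, props, normalize = TRUE,
                          on_unknown = c("error", "mean")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(inherits(props, "property_set"))
  chars <- toupper(c(x, y))
  if (any(nchar(chars) != 1L)) stop("'x' and 'y' must be single residues")
  idx <- encode_residues(chars, on_unknown = on_unknown, what = "residue pair")
  extra <- character(0)
  if (is.null(idx)) {
    extra <- unique(setdiff(chars, aa_alphabet()))
    idx <- encode_residues(chars, extra_letters = extra, what = "residue pair")
  }
  D <- property_distance_matrix(props, normalize = normalize, extra_letters = extra)
  D[idx[1L] + 1L, idx[2L] + 1L]
}

# ---- alignment result ----------------------------------------------------

build_alignment <- function(cx, cy, ax, ay, score, mode, x_id, y_id,
                            alpha, beta, D = NULL) {
  gap_x <- ax < 0L
  gap_y <- ay < 0L
  n_col <- length(ax)
  x_pos <- ifelse(gap_x, NA_integer_, cumsum(!gap_x))
  y_pos <- ifelse(gap_y, NA_integer_, cumsum(!gap_y))
  x_res <- ifelse(gap_x, "-", cx[x_pos])
  y_res <- ifelse(gap_y, "-", cy[y_pos])
  if (n_col == 0L) x_res <- y_res <- character(0)
  pair_score <- rep(NA_real_, n_col)
  both <- !gap_x & !gap_y
  if (!is.null(D) && any(both))
    pair_score[both] <- D[cbind(ax[both] + 1L, ay[both] + 1L)]
  n_pairs <- sum(both)
  n_ident <- sum(both & x_res == y_res)
  structure(list(
    aligned_x = paste(x_res, collapse = ""),
    aligned_y = paste(y_res, collapse = ""),
    x_id = x_id, y_id = y_id,
    score = score, mode = mode, alpha = alpha, beta = beta,
    columns = data.frame(x_pos = x_pos, y_pos = y_pos,
                         x_res = x_res, y_res = y_res,
                         pair_score = pair_score,
                         stringsAsFactors = FALSE),
    n_columns = n_col,
    n_aligned_pairs = n_pairs,
    n_identical = n_ident,
    percent_identity = if (n_pairs > 0L) 100 * n_ident / n_pairs else NA_real_
  ), class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, width = 60L, ...) {
  cx <- seq_chars(x$aligned_x)
  cy <- seq_chars(x$aligned_y)
  mid <- ifelse(cx == cy & cx != "-", "|", " ")
  n <- length(cx)
  if (n > 0L) {
    for (s in seq(1L, n, by = width)) {
      e <- min(s + width - 1L, n)
      cat(x$x_id, "\n", sep = "")
      cat(paste(cx[s:e], collapse = ""), "\n",
          paste(mid[s:e], collapse = ""), "\n",
          paste(cy[s:e], collapse = ""), "\n", sep = "")
      cat(x$y_id, "\n\n", sep = "")
    }
  }
  cat(sprintf("Objective: %s | score: %.9g\n",
              if (x$mode == "distance") "minimal property distance"
              else "maximal matrix similarity", x$score))
  cat(sprintf("Alignment length: %d columns, %d aligned pairs\n",
              x$n_columns, x$n_aligned_pairs))
  cat(sprintf("Percent identity: %s (over aligned pairs)\n",
              if (is.na(x$percent_identity)) "NA"
              else sprintf("%.1f%%", x$percent_identity)))
  invisible(x)
}

#' Percent identity of an alignment
#'
#' @param aln A `pair_alignment`.
#' @param denominator `"pairs"` (identical residues over residue-residue
#'   columns, the default) or `"columns"` (over all alignment columns,
#'   gaps included).
#' @return Percent identity in `[0, 100]` (`NA` if the denominator is 0).
#' @export
percent_identity <- function(aln, denominator = c("pairs", "columns")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(aln, "pair_alignment"))
  den <- if (denominator == "pairs") aln$n_aligned_pairs else aln$n_columns
  if (den == 0L) return(NA_real_)
  100 * aln$n_identical / den
}

# ---- property aligner ----------------------------------------------------

#' Minimal-distance global alignment under a weighted property profile
#'
#' Finds the global alignment of two protein sequences minimizing the total
#' weighted property distance over aligned residue pairs plus affine gap
#' penalties over all gaps (terminal gaps included). The dynamic program is
#' the exact three-state affine-gap recurrence (Gotoh), equivalent to the
#' naive all-gap-lengths recursion because the gap cost is affine. Traceback
#' ties prefer the diagonal move, then a gap in `y`, then a gap in `x`, so
#' the returned alignment is deterministic.
#'
#' @param x,y Sequences: plain strings or records with `$id`/`$seq` (as
#'   returned by [read_fasta()]).
#' @param props A [property_set()].
#' @param gaps A [gap_params()] (defaults to the 30--40% identity preset's
#'   penalties, `alpha = 0.7`, `beta = 0.1`).
#' @param normalize Min-max normalize every scale before aligning
#'   (default `TRUE`; disabling is possible but not recommended).
#' @param on_unknown Policy for non-standard residues: `"error"` or `"mean"`.
#' @return A `pair_alignment`: gapped sequences, total distance score,
#'   per-column detail and summary statistics.
#' @export
#' @examples
#' ps <- default_property_set()
#' aln <- align_property("GAVLIC", "GAVLC", ps)
#' aln$score
align_property <- function(x, y, props, gaps = gap_params(0.7, 0.1),
                           normalize = TRUE,
                           on_unknown = c("error", "mean")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(inherits(props, "property_set"), inherits(gaps, "gap_params"))
  rx <- as_seq_record(x, "x"); ry <- as_seq_record(y, "y")
  cx <- seq_chars(rx$seq); cy <- seq_chars(ry$seq)
  extra <- character(0)
  xi <- encode_residues(cx, on_unknown = on_unknown, what = paste0("sequence '", rx$id, "'"))
  yi <- encode_residues(cy, on_unknown = on_unknown, what = paste0("sequence '", ry$id, "'"))
  if (is.null(xi) || is.null(yi)) {
    extra <- unique(setdiff(c(cx, cy), aa_alphabet()))
    xi <- encode_residues(cx, extra_letters = extra, what = rx$id)
    yi <- encode_residues(cy, extra_letters = extra, what = ry$id)
  }
  D <- property_distance_matrix(props, normalize = normalize, extra_letters = extra)
  res <- .gotoh_align(xi, yi, D, gaps$alpha, gaps$beta)
  build_alignment(cx, cy, res$ax, res$ay, res$score, "distance",
                  rx$id, ry$id, gaps$alpha, gaps$beta, D = D)
}

#' Re-score a given gapped alignment under the property distance
#'
#' Computes the total alignment score directly from its columns: the sum of
#' weighted property distances over residue-residue columns plus the affine
#' penalty of every maximal gap run (terminal runs included).
#'
#' @param aligned_x,aligned_y Equal-length gapped strings (gap character
#'   `-`); no column may be gap-gap.
#' @inheritParams align_property
#' @return The total distance score.
#' @export
score_alignment <- function(aligned_x, aligned_y, props,
                            gaps = gap_params(0.7, 0.1), normalize = TRUE,
                            on_unknown = c("error", "mean")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(inherits(props, "property_set"), inherits(gaps, "gap_params"))
  cx <- seq_chars(toupper(aligned_x)); cy <- seq_chars(toupper(aligned_y))
  if (length(cx) != length(cy))
    stop("aligned sequences must have equal length")
  gx <- cx == "-"; gy <- cy == "-"
  if (any(gx & gy)) stop("alignment contains a gap-gap column")
  extra <- character(0)
  resx <- cx[!gx]; resy <- cy[!gy]
  xi <- encode_residues(resx, on_unknown = on_unknown, what = "aligned_x")
  yi <- encode_residues(resy, on_unknown = on_unknown, what = "aligned_y")
  if (is.null(xi) || is.null(yi)) {
    extra <- unique(setdiff(c(resx, resy), aa_alphabet()))
    xi <- encode_residues(resx, extra_letters = extra, what = "aligned_x")
    yi <- encode_residues(resy, extra_letters = extra, what = "aligned_y")
  }
  D <- property_distance_matrix(props, normalize = normalize, extra_letters = extra)
  ix <- cumsum(!gx); iy <- cumsum(!gy)
  both <- !gx & !gy
  s <- sum(D[cbind(xi[ix[both]] + 1L, yi[iy[both]] + 1L)])
  for (mask in list(gx, gy)) {
    r <- rle(mask)
    runs <- r$lengths[r$values]
    if (length(runs) > 0L) s <- s + sum(gap_penalty(runs, gaps))
  }
  s
}

# ---- matrix baseline -----------------------------------------------------

#' Read a substitution matrix in NCBI/BLAST layout
#'
#' Whitespace-delimited square matrix with a header row and leading column
#' of residue letters; lines starting with `#` are comments. The matrix must
#' be symmetric.
#'
#' @param path File path.
#' @return A numeric matrix with residue-letter dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("substitution matrix file has no data")
  letters_ <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- length(letters_)
  m <- matrix(NA_real_, n, n, dimnames = list(letters_, letters_))
  for (ln in lines[-1L]) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) != n + 1L)
      stop(sprintf("matrix row '%s' has %d values, expected %d", f[1L], length(f) - 1L, n))
    vals <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(vals)) stop(sprintf("non-numeric value in matrix row '%s'", f[1L]))
    m[f[1L], ] <- vals
  }
  if (anyNA(m)) stop("matrix is missing rows for some header letters")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
    stop("substitution matrix is not symmetric")
  m
}

check_matrix_coverage <- function(m, chars, what) {
  missing <- setdiff(unique(chars), rownames(m))
  if (length(missing) > 0L)
    stop(sprintf("%s contains residues absent from the substitution matrix: %s",
                 what, paste(missing, collapse = ", ")))
}

#' Maximal-similarity global alignment with a substitution matrix
#'
#' Conventional global alignment baseline: maximizes the summed substitution
#' matrix similarity plus affine gap penalties supplied as the conventional
#' negative opening/extension values (which are added to the objective).
#' Internally the problem is negated and solved by the same minimal-distance
#' dynamic program as [align_property()], so traceback tie-breaking is
#' identical.
#'
#' @param x,y Sequences as in [align_property()].
#' @param matrix Numeric symmetric similarity matrix with residue dimnames
#'   (see [read_substitution_matrix()]).
#' @param open,extend Gap opening/extension values, `<= 0`; a gap of length
#'   `r` contributes `open + (r - 1) * extend`.
#' @return A `pair_alignment` with `mode = "similarity"`.
#' @export
#' @examples
#' m <- diag(2, 20); dimnames(m) <- list(aa_alphabet(), aa_alphabet())
#' align_matrix("AAA", "AA", m, open = -1, extend = -1)$score
align_matrix <- function(x, y, matrix, open = -16, extend = -1) {
  if (!is.matrix(matrix) || is.null(rownames(matrix)))
    stop("'matrix' must be a numeric matrix with residue-letter dimnames")
  if (open > 0 || extend > 0)
    stop("'open' and 'extend' are penalties added to a similarity: supply values <= 0")
  rx <- as_seq_record(x, "x"); ry <- as_seq_record(y, "y")
  cx <- seq_chars(rx$seq); cy <- seq_chars(ry$seq)
  check_matrix_coverage(matrix, cx, rx$id)
  check_matrix_coverage(matrix, cy, ry$id)
  xi <- match(cx, rownames(matrix)) - 1L
  yi <- match(cy, rownames(matrix)) - 1L
  res <- .gotoh_align(xi, yi, -matrix, -open, -extend)
  out <- build_alignment(cx, cy, res$ax, res$ay, -res$score, "similarity",
                         rx$id, ry$id, open, extend, D = matrix)
  out
}

#' Estimate percent identity from a quick matrix alignment
#'
#' Aligns the two sequences with [align_matrix()] and returns the percent
#' identity over aligned residue pairs. Intended to pick a preset via
#' [select_preset()]; the estimate is rough and may differ from the identity
#' of the final property-based alignment. The original implementation of
#' this method used the VTML200 matrix with penalties -15/-1; VTML200 values
#' are not bundled, so the default here is BLOSUM62 (from Biostrings) with
#' the same penalties.
#'
#' @param x,y Non-empty sequences.
#' @param matrix Substitution matrix; `NULL` for BLOSUM62.
#' @param open,extend Gap penalties (default -15/-1).
#' @return Percent identity in `[0, 100]`.
#' @export
estimate_identity <- function(x, y, matrix = NULL, open = -15, extend = -1) {
  rx <- as_seq_record(x, "x"); ry <- as_seq_record(y, "y")
  if (nchar(rx$seq) == 0L || nchar(ry$seq) == 0L)
    stop("cannot estimate identity of an empty sequence")
  if (is.null(matrix)) matrix <- blosum62_matrix()
  aln <- align_matrix(rx, ry, matrix, open = open, extend = extend)
  if (aln$n_aligned_pairs == 0L) return(0)
  100 * aln$n_identical / aln$n_aligned_pairs
}

# BLOSUM62 restricted to the 20 standard letters (shipped by Biostrings)
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[aa_alphabet(), aa_alphabet()]
  storage.mode(m) <- "double"
  m
}
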