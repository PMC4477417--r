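# Accuracy of a test alignment against a gold (reference) alignment:
# developer score f_D = n_I / l_R * 100, modeler score f_M = n_I / l_T * 100,
# Q = (f_D + f_M) / 2, where n_I counts residue pairs aligned identically in
# both. "Length" l_R / l_T is by default the number of residue-residue
# (aligned-pair) columns, which makes Q(reference, reference) = 100 even for
# gapped references; counting all columns is available via length_mode.

as_gapped_pair <- function(x) {
  if (inherits(x, "pair_alignment"))
    return(list(aligned_x = x$aligned_x, aligned_y = x$aligned_y))
  if (is.list(x) && !is.null(x$aligned_x) && !is.null(x$aligned_y))
    return(list(aligned_x = toupper(x$aligned_x), aligned_y = toupper(x$aligned_y)))
  if (is.character(x) && length(x) == 2L)
    return(list(aligned_x = toupper(x[1L]), aligned_y = toupper(x[2L])))
  stop("expected a pair_alignment, a list with $aligned_x/$aligned_y, or two gapped strings")
}

degap <- function(s) gsub("-", "", s, fixed = TRUE)

# residue-index pairs (1-based in the ungapped sequences) appearing as
# residue-residue columns, encoded as x_pos * (m + 1) + y_pos for set ops
aligned_pair_keys <- function(aln, m) {
  cx <- seq_chars(aln$aligned_x); cy <- seq_chars(aln$aligned_y)
  if (length(cx) != length(cy)) stop("gapped sequences have unequal lengths")
  gx <- cx == "-"; gy <- cy == "-"
  if (any(gx & gy)) stop("alignment contains a gap-gap column")
  both <- !gx & !gy
  (cumsum(!gx)[both]) * (m + 1) + cumsum(!gy)[both]
}

n_aligned_pairs <- function(aln) {
  cx <- seq_chars(aln$aligned_x); cy <- seq_chars(aln$aligned_y)
  sum(cx != "-" & cy != "-")
}

check_same_sequences <- function(test, ref) {
  if (!identical(degap(test$aligned_x), degap(ref$aligned_x)) ||
      !identical(degap(test$aligned_y), degap(ref$aligned_y)))
    stop("test and reference alignments are not over the same underlying sequences")
}

#' Count residue pairs aligned identically in two alignments
#'
#' A residue pair (a, b) -- position `a` of the first ungapped sequence
#' aligned to position `b` of the second -- is counted when it appears as a
#' residue-residue column in both alignments.
#'
#' @param test,reference Alignments over the same underlying sequences: a
#'   `pair_alignment`, a list with `$aligned_x`/`$aligned_y`, or a character
#'   vector of two gapped strings.
#' @return Nonnegative integer count.
#' @export
identically_aligned_pairs <- function(test, reference) {
  test <- as_gapped_pair(test); reference <- as_gapped_pair(reference)
  check_same_sequences(test, reference)
  m <- nchar(degap(test$aligned_y))
  length(intersect(aligned_pair_keys(test, m), aligned_pair_keys(reference, m)))
}

#' Alignment accuracy Q against a reference alignment
#'
#' `Q = (f_D + f_M) / 2` with `f_D = n_I / l_R * 100` (developer-style:
#' fraction of the reference's pairs recovered) and `f_M = n_I / l_T * 100`
#' (modeler-style: fraction of the test's pairs that are correct).
#'
#' @inheritParams identically_aligned_pairs
#' @param length_mode How `l_R` and `l_T` are counted: `"pairs"`
#'   (residue-residue columns; default) or `"columns"` (all alignment
#'   columns, gaps included).
#' @return `Q` in `[0, 100]`, with attributes `n_I`, `f_D`, `f_M`.
#' @export
#' @examples
#' q_score(c("AC-D", "ACGD"), c("AC-D", "ACGD"))   # 100
q_score <- function(test, reference, length_mode = c("pairs", "columns")) {
  length_mode <- match.arg(length_mode)
  test <- as_gapped_pair(test); reference <- as_gapped_pair(reference)
  check_same_sequences(test, reference)
  n_i <- identically_aligned_pairs(test, reference)
  if (length_mode == "pairs") {
    l_r <- n_aligned_pairs(reference)
    l_t <- n_aligned_pairs(test)
  } else {
    l_r <- nchar(reference$aligned_x)
    l_t <- nchar(test$aligned_x)
  }
  if (l_r == 0L)
    stop("reference alignment has no aligned residue pairs; f_D is undefined")
  f_d <- n_i / l_r * 100
  f_m <- if (l_t == 0L) 0 else n_i / l_t * 100
  structure((f_d + f_m) / 2, n_I = n_i, f_D = f_d, f_M = f_m)
}

#' Mean alignment accuracy over a benchmark
#'
#' Arithmetic mean of [q_score()] over a collection of (test, reference)
#' alignment pairs -- the objective maximized by the grid-search optimizer.
#'
#' @param tests,references Parallel lists of alignments (see
#'   [identically_aligned_pairs()] for accepted forms).
#' @inheritParams q_score
#' @return Mean Q in `[0, 100]`.
#' @export
q_aver <- function(tests, references, length_mode = c("pairs", "columns")) {
  length_mode <- match.arg(length_mode)
  if (length(tests) == 0L) stop("cannot average over an empty collection")
  if (length(tests) != length(references))
    stop("'tests' and 'references' must have the same length")
  qs <- mapply(function(t, r) as.numeric(q_score(t, r, length_mode)),
               tests, references)
  mean(qs)
}

# ---- reference pairs and method comparison -------------------------------

#' Bundle two sequences with their gold reference alignment
#'
#' @param pair_id Identifier for the pair.
#' @param x,y Sequences (strings or records); must equal the reference's
#'   ungapped sequences. When `NULL` they are derived from the reference.
#' @param reference The gold alignment: two gapped strings or anything
#'   [identically_aligned_pairs()] accepts.
#' @param family_id Grouping label used by family subsampling.
#' @param identity_bin Optional identity-range label.
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(pair_id, reference, x = NULL, y = NULL,
                           family_id = pair_id, identity_bin = NA_character_) {
  ref <- as_gapped_pair(reference)
  if (nchar(ref$aligned_x) != nchar(ref$aligned_y))
    stop("reference gapped sequences have unequal lengths")
  sx <- degap(ref$aligned_x); sy <- degap(ref$aligned_y)
  rx <- if (is.null(x)) list(id = paste0(pair_id, "_x"), desc = "", seq = sx)
        else as_seq_record(x, paste0(pair_id, "_x"))
  ry <- if (is.null(y)) list(id = paste0(pair_id, "_y"), desc = "", seq = sy)
        else as_seq_record(y, paste0(pair_id, "_y"))
  if (!identical(rx$seq, sx) || !identical(ry$seq, sy))
    stop(sprintf("pair '%s': reference alignment does not match the sequences", pair_id))
  structure(list(pair_id = as.character(pair_id), x = rx, y = ry,
                 reference = ref, family_id = as.character(family_id),
                 identity_bin = identity_bin),
            class = "reference_pair")
}

#' Compare the property aligner against the matrix baseline on a benchmark
#'
#' Aligns every pair with both methods, scores each against the reference
#' (`Q1` for the property aligner, `Q2` for the matrix aligner), and
#' categorizes the difference `D = Q1 - Q2`: `better` (`D > 0`), `equal`
#' (`D == 0`, exact tie after identical arithmetic), `worse` (`D < 0`).
#'
#' @param pairs List of [reference_pair()] objects.
#' @param props,gaps,normalize Parameters of the property aligner.
#' @param matrix,open,extend Parameters of the matrix baseline.
#' @inheritParams q_score
#' @return A list of class `method_comparison`: `records` (one row per pair:
#'   `pair_id`, `family_id`, `identity_bin`, `q1`, `q2`, `d`, `category`)
#'   and `summary` (counts and percentages per category, overall and per
#'   identity bin when bins are present).
#' @export
compare_methods <- function(pairs, props, gaps = gap_params(0.7, 0.1),
                            matrix = NULL, open = -16, extend = -1,
                            normalize = TRUE,
                            length_mode = c("pairs", "columns")) {
  length_mode <- match.arg(length_mode)
  if (length(pairs) == 0L) stop("'pairs' must contain at least one reference pair")
  if (is.null(matrix)) matrix <- blosum62_matrix()
  rec <- lapply(pairs, function(p) {
    stopifnot(inherits(p, "reference_pair"))
    q1 <- tryCatch(as.numeric(q_score(align_property(p$x, p$y, props, gaps,
                                                     normalize = normalize),
                                      p$reference, length_mode)),
                   error = function(e) stop(sprintf("pair '%s': %s", p$pair_id,
                                                    conditionMessage(e)), call. = FALSE))
    q2 <- tryCatch(as.numeric(q_score(align_matrix(p$x, p$y, matrix, open, extend),
                                      p$reference, length_mode)),
                   error = function(e) stop(sprintf("pair '%s': %s", p$pair_id,
                                                    conditionMessage(e)), call. = FALSE))
    d <- q1 - q2
    data.frame(pair_id = p$pair_id, family_id = p$family_id,
               identity_bin = p$identity_bin, q1 = q1, q2 = q2, d = d,
               category = if (d > 0) "better" else if (d < 0) "worse" else "equal",
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rec)
  summarize <- function(df, label) {
    n <- nrow(df)
    counts <- vapply(c("better", "equal", "worse"),
                     function(k) sum(df$category == k), 0L)
    data.frame(bin = label, n = n,
               n_better = counts[["better"]], n_equal = counts[["equal"]],
               n_worse = counts[["worse"]],
               pct_better = 100 * counts[["better"]] / n,
               pct_equal = 100 * counts[["equal"]] / n,
               pct_worse = 100 * counts[["worse"]] / n,
               stringsAsFactors = FALSE)
  }
  summary <- summarize(records, "overall")
  if (any(!is.na(records$identity_bin))) {
    for (b in unique(records$identity_bin[!is.na(records$identity_bin)]))
      summary <- rbind(summary,
                       summarize(records[records$identity_bin %in% b, ], b))
  }
  structure(list(records = records, summary = summary),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Property-profile aligner vs matrix baseline\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
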