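# Independent oracles and fixture builders shared across the test files.

# The documented example property file: two scales (hydrophobicity, size)
# with weights 0.6 / 0.4.
example_property_text <- function() {
  c("Header line goes here...",
    "A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V",
    "#PROPERTY Hydrophobicity",
    "0.25,-1.76,-0.6,-0.7,0.1,-0.7,-0.6,0.2,-0.4,0.7,0.5,-1.1,0.3,0.6,-0.1,-0.3,-0.2,0.4,0.1,0.5",
    "W:0.6",
    "#PROPERTY Size",
    "28,105,59,40,45,81,62,0,79,94,94,100,94,112,42,23,51,146,117,72",
    "W:0.4")
}

example_property_set <- function() {
  parse_property_file(paste(example_property_text(), collapse = "\n"))
}

toy_identity_matrix <- function(match = 2, mismatch = -1) {
  m <- matrix(mismatch, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  diag(m) <- match
  m
}

# Exhaustive enumeration of every global alignment of two short sequences,
# scoring each with the summed pair score plus affine gap costs over maximal
# gap runs, fully independently of the dynamic program. `pair_mat` is looked
# up by residue letters. For minimize = TRUE, gap costs alpha/beta are added
# and the minimum returned; for maximize, `open`/`extend` (<= 0) are added
# and the maximum returned.
brute_force_optimum <- function(x, y, pair_mat, g_open, g_ext,
                                minimize = TRUE) {
  cx <- if (nchar(x)) strsplit(x, "")[[1]] else character(0)
  cy <- if (nchar(y)) strsplit(y, "")[[1]] else character(0)
  n <- length(cx); m <- length(cy)
  best <- if (minimize) Inf else -Inf
  rec <- function(i, j, last, acc) {
    if (i == n && j == m) {
      best <<- if (minimize) min(best, acc) else max(best, acc)
      return(invisible(NULL))
    }
    if (i < n && j < m)
      rec(i + 1, j + 1, "M", acc + pair_mat[cx[i + 1], cy[j + 1]])
    if (i < n)   # x residue over a gap in y
      rec(i + 1, j, "X", acc + if (last == "X") g_ext else g_open)
    if (j < m)   # gap in x under a y residue
      rec(i, j + 1, "Y", acc + if (last == "Y") g_ext else g_open)
    invisible(NULL)
  }
  rec(0L, 0L, "start", 0)
  best
}

# weighted L1 distance matrix computed by plain spreadsheet-style arithmetic
oracle_distance_matrix <- function(props, normalize = TRUE) {
  scales <- props$scales
  if (normalize)
    scales <- lapply(scales, function(v) (v - min(v)) / (max(v) - min(v)))
  D <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  for (a in aa_alphabet()) for (b in aa_alphabet())
    D[a, b] <- sum(unname(props$weights) *
                     vapply(scales, function(s) abs(s[[a]] - s[[b]]), 0))
  D
}

random_protein <- function(n, letters = aa_alphabet()) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

n_aligned_pairs_oracle <- function(aln) {
  if (is.character(aln)) { ax <- aln[1]; ay <- aln[2] }
  else { ax <- aln$aligned_x; ay <- aln$aligned_y }
  cx <- strsplit(ax, "")[[1]]
  cy <- strsplit(ay, "")[[1]]
  sum(cx != "-" & cy != "-")
}

# random monotone global alignment of x and y (no gap-gap columns)
random_alignment <- function(x, y) {
  cx <- if (nchar(x)) strsplit(x, "")[[1]] else character(0)
  cy <- if (nchar(y)) strsplit(y, "")[[1]] else character(0)
  n <- length(cx); m <- length(cy)
  i <- 0L; j <- 0L; ax <- character(0); ay <- character(0)
  while (i < n || j < m) {
    moves <- c(if (i < n && j < m) "M", if (i < n) "X", if (j < m) "Y")
    mv <- if (length(moves) == 1L) moves else sample(moves, 1L)
    if (mv == "M") { i <- i + 1L; j <- j + 1L; ax <- c(ax, cx[i]); ay <- c(ay, cy[j]) }
    else if (mv == "X") { i <- i + 1L; ax <- c(ax, cx[i]); ay <- c(ay, "-") }
    else { j <- j + 1L; ay <- c(ay, cy[j]); ax <- c(ax, "-") }
  }
  list(aligned_x = paste(ax, collapse = ""), aligned_y = paste(ay, collapse = ""))
}
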