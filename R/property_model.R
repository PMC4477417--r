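#' Construct a weighted set of amino acid property scales
#'
#' A property set holds `k >= 1` numerical scales over the 20 standard amino
#' acids together with one nonnegative weight per scale. The distance between
#' two residues is the weighted L1 distance over the scales, so the weights
#' form a convex combination: they must be nonnegative and sum to 1.
#'
#' @param scales Named list of numeric vectors. Each vector must have one
#'   value per standard amino acid. Named vectors are reordered to the
#'   canonical alphabet order (see [aa_alphabet()]); unnamed vectors of
#'   length 20 are taken to already be in canonical order.
#' @param weights Numeric vector of per-scale weights, `>= 0`, summing to 1
#'   within `tol`. Recycled names are taken from `scales`.
#' @param normalized Logical flag recording whether min-max normalization has
#'   already been applied to every scale.
#' @param tol Tolerance on the weight sum (default `1e-9`).
#' @return An object of class `property_set` with elements `scales`,
#'   `weights` (named by scale) and `normalized`.
#' @export
#' @examples
#' ps <- property_set(
#'   scales = list(thiol = as.numeric(aa_alphabet() == "C")),
#'   weights = 1
#' )
#' pair_distance("C", "A", ps)
property_set <- function(scales, weights, normalized = FALSE, tol = 1e-9) {
  if (!is.list(scales) || length(scales) < 1L)
    stop("'scales' must be a list with at least one property scale")
  if (is.null(names(scales)) || any(!nzchar(names(scales))))
    stop("every scale must be named")
  if (anyDuplicated(names(scales)))
    stop("scale names must be unique")
  ab <- aa_alphabet()
  scales <- lapply(stats::setNames(names(scales), names(scales)), function(nm) {
    v <- scales[[nm]]
    if (!is.numeric(v) || length(v) != 20L)
      stop(sprintf("scale '%s' must be a numeric vector of length 20", nm))
    if (is.null(names(v))) {
      names(v) <- ab
    } else {
      if (!setequal(names(v), ab))
        stop(sprintf("scale '%s' must be named by the 20 standard amino acid letters", nm))
      v <- v[ab]
    }
    if (anyNA(v)) stop(sprintf("scale '%s' contains missing values", nm))
    v
  })
  if (!is.numeric(weights) || length(weights) != length(scales))
    stop("'weights' must be numeric with one value per scale")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > tol)
    stop(sprintf("weights must sum to 1.0 (got %.12g)", sum(weights)))
  structure(list(scales = scales,
                 weights = stats::setNames(as.numeric(weights), names(scales)),
                 normalized = isTRUE(normalized)),
            class = "property_set")
}

#' @export
print.property_set <- function(x, ...) {
  cat(sprintf("Weighted property set: %d scale(s)%s\n", length(x$scales),
              if (x$normalized) " (normalized to [0, 1])" else ""))
  for (nm in names(x$scales))
    cat(sprintf("  %-24s weight %.6g\n", nm, x$weights[[nm]]))
  invisible(x)
}

#' Min-max normalize a property scale to the unit interval
#'
#' Rescales a property scale linearly so that its minimum maps to 0 and its
#' maximum to 1: `np(x) = (p(x) - min) / (max - min)`. A constant scale has
#' no information to rescale and is rejected.
#'
#' @param scale Numeric vector of 20 property values (any names are kept).
#' @return The rescaled vector, all values in `[0, 1]`.
#' @export
#' @examples
#' sizes <- c(28, 105, 59, 40, 45, 81, 62, 0, 79, 94,
#'            94, 100, 94, 112, 42, 23, 51, 146, 117, 72)
#' normalize_scale(sizes)[8]   # glycine, the minimum, maps to 0
normalize_scale <- function(scale) {
  if (!is.numeric(scale)) stop("'scale' must be numeric")
  rng <- range(scale)
  if (rng[1] == rng[2])
    stop("constant scale (max == min) cannot be min-max normalized")
  (scale - rng[1]) / (rng[2] - rng[1])
}

#' Apply min-max normalization to every scale of a property set
#'
#' @param props A [property_set()].
#' @return A `property_set` with every scale rescaled to `[0, 1]` and the
#'   `normalized` flag set. Idempotent: a normalized scale has min 0 and
#'   max 1, which are fixed points of the rescaling.
#' @export
normalize_property_set <- function(props) {
  stopifnot(inherits(props, "property_set"))
  props$scales <- lapply(props$scales, normalize_scale)
  props$normalized <- TRUE
  props
}

# profile matrix: 20 x k, rows in canonical alphabet order
profile_matrix <- function(props, normalize = TRUE) {
  if (normalize && !props$normalized) props <- normalize_property_set(props)
  do.call(cbind, props$scales)
}

#' Parse a property/weights file
#'
#' Reads the comma-delimited property file format: a free-text header line; a
#' line with the 20 standard amino acid letters in canonical order; then, for
#' each property, a `#PROPERTY <name>` line, a line of 20 comma-delimited
#' values (in alphabet order), and a `W:<weight>` line giving its weight.
#'
#' @param path Path to a property file, or a character vector of lines
#'   (anything of length > 1, or containing a newline, is treated as content).
#' @param on_weight_sum What to do when the `W:` weights do not sum to 1
#'   within `1e-9`: `"reject"` (default) raises an error, `"renormalize"`
#'   divides by the sum with a warning.
#' @return A [property_set()] with scales in file order.
#' @export
parse_property_file <- function(path, on_weight_sum = c("reject", "renormalize")) {
  on_weight_sum <- match.arg(on_weight_sum)
  if (length(path) == 1L && !grepl("\n", path)) {
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  lnum <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) < 2L) stop("property file is missing its header or alphabet line")
  # line 1: header, content ignored; line 2: the canonical alphabet
  ab <- trimws(strsplit(lines[2L], ",", fixed = TRUE)[[1L]])
  if (!identical(ab, aa_alphabet()))
    stop(sprintf("line %d: alphabet line must be the 20 standard letters '%s'",
                 lnum[2L], paste(aa_alphabet(), collapse = ",")))
  i <- 3L
  scales <- list()
  weights <- numeric()
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "#PROPERTY"))
      stop(sprintf("line %d: expected '#PROPERTY <name>', got '%s'", lnum[i], lines[i]))
    name <- trimws(sub("^#PROPERTY", "", lines[i]))
    if (!nzchar(name)) stop(sprintf("line %d: property has no name", lnum[i]))
    if (i + 1L > length(lines))
      stop(sprintf("property '%s': missing value line", name))
    fields <- trimws(strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]])
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 20L || anyNA(vals))
      stop(sprintf("line %d: property '%s' needs 20 comma-delimited numbers, got %d field(s)",
                   lnum[i + 1L], name, length(fields)))
    if (i + 2L > length(lines) || !startsWith(lines[i + 2L], "W:"))
      stop(sprintf("property '%s': missing 'W:' weight line", name))
    w <- suppressWarnings(as.numeric(sub("^W:", "", lines[i + 2L])))
    if (is.na(w)) stop(sprintf("line %d: unreadable weight for property '%s'", lnum[i + 2L], name))
    scales[[name]] <- stats::setNames(vals, aa_alphabet())
    weights <- c(weights, w)
    i <- i + 3L
  }
  if (length(scales) == 0L) stop("property file contains no #PROPERTY blocks")
  if (abs(sum(weights) - 1) > 1e-9) {
    if (on_weight_sum == "reject")
      stop(sprintf("property weights sum to %.12g, not 1.0", sum(weights)))
    warning(sprintf("renormalizing property weights (sum was %.12g)", sum(weights)))
    weights <- weights / sum(weights)
  }
  property_set(scales, weights)
}

#' Write a property set in the property-file format
#'
#' Inverse of [parse_property_file()]: the written text re-parses to a set
#' with identical names, values and weights (numbers are written with full
#' double precision).
#'
#' @param props A [property_set()].
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the character vector
#'   of file lines.
#' @export
write_property_file <- function(props, path = NULL) {
  stopifnot(inherits(props, "property_set"))
  # shortest decimal that round-trips through as.numeric
  num1 <- function(v) {
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }
  num <- function(v) vapply(v, num1, "")
  lines <- c("Amino acid property scales and weights",
             paste(aa_alphabet(), collapse = ","))
  for (nm in names(props$scales)) {
    lines <- c(lines,
               paste("#PROPERTY", nm),
               paste(num(props$scales[[nm]]), collapse = ","),
               paste0("W:", num(props$weights[[nm]])))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
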