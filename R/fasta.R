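#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to Biostrings; multi-line sequences are joined,
#' sequences are upper-cased, and each record's header is split into an
#' `id` (first word) and `desc` (remainder).
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Permit `-` characters (aligned FASTA). Plain sequence
#'   input (the default) rejects them.
#' @return A list of records, each a list with `id`, `desc` and `seq`.
#' @export
#' @examples
#' fa <- system.file("extdata", "example.fasta", package = "propalign")
#' nchar(read_fasta(fa)[[1]]$seq)
read_fasta <- function(path, allow_gaps = FALSE) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop(sprintf("cannot read FASTA '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("FASTA file '%s' contains no records", path))
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    h <- headers[i]
    id <- sub("\\s.*$", "", h)
    desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    seq <- toupper(as.character(set[[i]]))
    if (!allow_gaps && grepl("-", seq, fixed = TRUE))
      stop(sprintf("record '%s' contains gap characters; use allow_gaps = TRUE for aligned FASTA", id))
    list(id = if (nzchar(id)) id else sprintf("seq%d", i), desc = desc, seq = seq)
  })
}

#' Write records to a FASTA file
#'
#' @param records List of records (`id`, optional `desc`, `seq`), as
#'   returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for wrapping sequences (default 60).
#' @return Invisibly, the written lines.
#' @export
write_fasta <- function(records, path, width = 60L) {
  lines <- unlist(lapply(records, function(r) {
    r <- as_seq_record(r)
    header <- paste0(">", r$id, if (nzchar(r$desc)) paste0(" ", r$desc) else "")
    s <- r$seq
    if (nchar(s) == 0L) return(header)
    starts <- seq(1L, nchar(s), by = width)
    c(header, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a pairwise alignment from an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file whose first two records are the
#'   gapped sequences of one pairwise alignment (equal lengths required).
#' @return A list with `aligned_x`, `aligned_y`, `x_id`, `y_id`.
#' @export
read_alignment_fasta <- function(path) {
  recs <- read_fasta(path, allow_gaps = TRUE)
  if (length(recs) < 2L)
    stop(sprintf("aligned FASTA '%s' must contain two records", path))
  if (nchar(recs[[1L]]$seq) != nchar(recs[[2L]]$seq))
    stop(sprintf("aligned FASTA '%s': records have unequal lengths", path))
  list(aligned_x = recs[[1L]]$seq, aligned_y = recs[[2L]]$seq,
       x_id = recs[[1L]]$id, y_id = recs[[2L]]$id)
}
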