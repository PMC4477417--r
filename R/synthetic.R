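# Desk-scale benchmark generator: families of homologous protein pairs
# descended from a common ancestor by per-site substitutions and geometric
# length indels, with the true alignment kept exact through the edit
# history (ancestor coordinates), never inferred.

#' Simulation settings for the synthetic benchmark
#'
#' Each family draws one ancestor sequence; each pair of the family evolves
#' two descendants independently (per-site substitution to a uniformly
#' chosen other residue; per-site insertion/deletion events of geometric
#' length). The implied true alignment is recorded as the pair's reference.
#'
#' @param n_families Number of families.
#' @param pairs_per_family Pairs generated per family (sharing an ancestor).
#' @param ancestor_length Ancestor length in residues, `>= 1`.
#' @param substitution_rate Per-site substitution probability on each
#'   branch, in `[0, 1]`.
#' @param indel_rate Per-site probability of an indel event on each branch,
#'   in `[0, 1]` (split evenly between insertion and deletion).
#' @param mean_indel_length Mean indel length, `>= 1` (geometric).
#' @param alphabet_frequencies Residue frequencies for ancestors and
#'   inserted residues; 20 values summing to 1 (default uniform).
#' @param seed Integer seed making the benchmark reproducible.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_families = 5L, pairs_per_family = 4L,
                              ancestor_length = 120L,
                              substitution_rate = 0.35, indel_rate = 0.03,
                              mean_indel_length = 2,
                              alphabet_frequencies = rep(1 / 20, 20),
                              seed = 1L) {
  if (ancestor_length < 1L) stop("'ancestor_length' must be >= 1")
  if (n_families < 1L || pairs_per_family < 1L)
    stop("'n_families' and 'pairs_per_family' must be >= 1")
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1)
    stop("rates must lie in [0, 1]")
  if (mean_indel_length < 1) stop("'mean_indel_length' must be >= 1")
  if (length(alphabet_frequencies) != 20L ||
      any(alphabet_frequencies < 0) ||
      abs(sum(alphabet_frequencies) - 1) > 1e-9)
    stop("'alphabet_frequencies' must be 20 nonnegative values summing to 1")
  structure(list(n_families = as.integer(n_families),
                 pairs_per_family = as.integer(pairs_per_family),
                 ancestor_length = as.integer(ancestor_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 mean_indel_length = mean_indel_length,
                 alphabet_frequencies = alphabet_frequencies,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# evolve one descendant; returns site residues (NA = deleted) and the
# insertions after each ancestor position (index 1 = before site 1)
evolve_branch <- function(anc, config) {
  ab <- aa_alphabet()
  L <- length(anc)
  res <- anc
  sub <- runif(L) < config$substitution_rate
  if (any(sub)) {
    res[sub] <- vapply(anc[sub], function(a) {
      others <- ab[ab != a]
      others[sample.int(19L, 1L)]
    }, "")
  }
  p_len <- 1 / config$mean_indel_length
  indel_len <- function() rgeom(1L, p_len) + 1L
  deleted <- rep(FALSE, L)
  for (i in seq_len(L)) {
    if (runif(1L) < config$indel_rate / 2) {
      len <- indel_len()
      deleted[i:min(L, i + len - 1L)] <- TRUE
    }
  }
  res[deleted] <- NA_character_
  ins <- vector("list", L + 1L)
  for (i in seq_len(L + 1L)) {
    if (runif(1L) < config$indel_rate / 2) {
      len <- indel_len()
      ins[[i]] <- ab[sample.int(20L, len, replace = TRUE,
                                prob = config$alphabet_frequencies)]
    } else ins[[i]] <- character(0)
  }
  list(res = res, ins = ins)
}

# merge two branch edit histories into reference alignment columns
branches_to_alignment <- function(bx, by, L) {
  ax <- character(0); ay <- character(0)
  for (i in seq_len(L + 1L)) {
    # insertions relative to the ancestor are unalignable: pair with gaps
    if (length(bx$ins[[i]]) > 0L) {
      ax <- c(ax, bx$ins[[i]]); ay <- c(ay, rep("-", length(bx$ins[[i]])))
    }
    if (length(by$ins[[i]]) > 0L) {
      ax <- c(ax, rep("-", length(by$ins[[i]]))); ay <- c(ay, by$ins[[i]])
    }
    if (i <= L) {
      xr <- bx$res[i]; yr <- by$res[i]
      if (!is.na(xr) || !is.na(yr)) {
        ax <- c(ax, if (is.na(xr)) "-" else xr)
        ay <- c(ay, if (is.na(yr)) "-" else yr)
      }
    }
  }
  list(aligned_x = paste(ax, collapse = ""), aligned_y = paste(ay, collapse = ""))
}

identity_bin_label <- function(pct) {
  if (is.na(pct)) return(NA_character_)
  if (pct < 10) "0-10" else if (pct < 20) "10-20" else if (pct < 30) "20-30"
  else if (pct < 40) "30-40" else "40-100"
}

#' Generate one homologous pair with its true alignment
#'
#' Uses the current RNG state; seed via [generate_benchmark()] or
#' `set.seed()` for reproducibility.
#'
#' @param config A [simulation_config()].
#' @param pair_id,family_id Identifiers for the produced [reference_pair()].
#' @param ancestor Optional pre-drawn ancestor (character vector of
#'   residues); drawn from `alphabet_frequencies` when `NULL`.
#' @return A [reference_pair()]; `identity_bin` is the realized percent
#'   identity bin of the true alignment.
#' @export
generate_pair <- function(config, pair_id = "pair1", family_id = "fam1",
                          ancestor = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ab <- aa_alphabet()
  anc <- if (is.null(ancestor))
    ab[sample.int(20L, config$ancestor_length, replace = TRUE,
                  prob = config$alphabet_frequencies)]
  else ancestor
  repeat {
    bx <- evolve_branch(anc, config)
    by <- evolve_branch(anc, config)
    # a descendant erased entirely by deletions cannot form a pair; redraw
    if (sum(!is.na(bx$res)) + sum(lengths(bx$ins)) > 0L &&
        sum(!is.na(by$res)) + sum(lengths(by$ins)) > 0L) break
  }
  ref <- branches_to_alignment(bx, by, length(anc))
  cx <- seq_chars(ref$aligned_x); cy <- seq_chars(ref$aligned_y)
  both <- cx != "-" & cy != "-"
  pct <- if (sum(both) > 0L) 100 * sum(both & cx == cy) / sum(both) else NA_real_
  reference_pair(pair_id, ref, family_id = family_id,
                 identity_bin = identity_bin_label(pct))
}

#' Generate a benchmark of families of homologous pairs
#'
#' Draws `n_families` ancestors and `pairs_per_family` independent
#' descendant pairs from each. Optionally writes the benchmark to disk as
#' one aligned-FASTA reference per pair plus a tab-separated manifest
#' (`pair_id`, `reference`, `family_id`, `identity_bin`) that
#' [read_benchmark()] re-ingests unchanged.
#'
#' @param config A [simulation_config()]; `config$seed` fixes the whole
#'   benchmark.
#' @param dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @return Invisibly for written benchmarks, otherwise visibly: a list with
#'   `pairs` (list of [reference_pair()]) and `manifest` (data frame).
#' @export
generate_benchmark <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pairs <- with_seed(config$seed, {
    out <- vector("list", config$n_families * config$pairs_per_family)
    k <- 0L
    for (f in seq_len(config$n_families)) {
      fam <- sprintf("fam%02d", f)
      anc <- aa_alphabet()[sample.int(20L, config$ancestor_length,
                                      replace = TRUE,
                                      prob = config$alphabet_frequencies)]
      for (p in seq_len(config$pairs_per_family)) {
        k <- k + 1L
        out[[k]] <- generate_pair(config,
                                  pair_id = sprintf("%s_p%02d", fam, p),
                                  family_id = fam, ancestor = anc)
      }
    }
    out
  })
  manifest <- data.frame(
    pair_id = vapply(pairs, `[[`, "", "pair_id"),
    reference = paste0("ref_", vapply(pairs, `[[`, "", "pair_id"), ".afa"),
    family_id = vapply(pairs, `[[`, "", "family_id"),
    identity_bin = vapply(pairs, `[[`, "", "identity_bin"),
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      write_fasta(list(list(id = p$x$id, desc = "", seq = p$reference$aligned_x),
                       list(id = p$y$id, desc = "", seq = p$reference$aligned_y)),
                  file.path(dir, manifest$reference[i]))
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(list(pairs = pairs, manifest = manifest)))
  }
  list(pairs = pairs, manifest = manifest)
}

#' Read a benchmark written by [generate_benchmark()]
#'
#' @param manifest_path Path to the tab-separated manifest; reference paths
#'   are resolved relative to its directory.
#' @return A list with `pairs` and `manifest`, equal (up to in-memory
#'   details) to what [generate_benchmark()] produced.
#' @export
read_benchmark <- function(manifest_path) {
  manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                colClasses = "character")
  need <- c("pair_id", "reference", "family_id")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns pair_id, reference, family_id")
  base <- dirname(manifest_path)
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    recs <- read_fasta(file.path(base, manifest$reference[i]), allow_gaps = TRUE)
    if (length(recs) < 2L)
      stop(sprintf("reference '%s' must contain two gapped records",
                   manifest$reference[i]))
    reference_pair(manifest$pair_id[i],
                   list(aligned_x = recs[[1L]]$seq, aligned_y = recs[[2L]]$seq),
                   family_id = manifest$family_id[i],
                   identity_bin = if ("identity_bin" %in% names(manifest))
                     manifest$identity_bin[i] else NA_character_)
  })
  list(pairs = pairs, manifest = manifest)
}
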