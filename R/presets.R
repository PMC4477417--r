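# Optimized weight/gap-penalty presets for the four default properties,
# one row per pair-wise identity range (benchmarked on structure-based
# reference alignments of homologous protein pairs). The 30-40% row is the
# package default.

.preset_table <- function() {
  data.frame(
    identity_low  = c(0, 10, 20, 30, 40),
    identity_high = c(10, 20, 30, 40, 100),
    label = c("0-10%", "10-20%", "20-30%", "30-40%", "Above 40%"),
    w_hydrophobicity = c(0.70, 0.30, 0.30, 0.25, 0.20),
    w_size           = c(0.15, 0.20, 0.20, 0.20, 0.20),
    w_coil           = c(0.10, 0.15, 0.15, 0.15, 0.25),
    w_thiol          = c(0.05, 0.35, 0.35, 0.40, 0.35),
    alpha = c(0.8, 0.6, 0.7, 0.7, 0.6),
    beta  = c(0.2, 0.1, 0.1, 0.1, 0.1),
    n_pairs = c(1282L, 2023L, 1674L, 1100L, 705L),
    stringsAsFactors = FALSE
  )
}

#' Shipped weight/gap-penalty presets by percent-identity range
#'
#' Five presets, one per range of pair-wise sequence identity, each giving
#' the four default-property weights (hydrophobicity, size, coil propensity,
#' thiol group) and affine gap penalties optimized against structure-based
#' reference alignments. The 30--40% row is the package default.
#'
#' @return A data frame with one row per preset: identity range, label, four
#'   weights, `alpha` (gap initiation), `beta` (gap extension), and the size
#'   of the benchmark each row was optimized on.
#' @export
#' @examples
#' default_presets()
default_presets <- function() .preset_table()

#' Select the preset for an expected percent identity
#'
#' Identity ranges are half-open `[low, high)`, so an identity of exactly
#' 10, 20, 30 or 40 falls in the higher range; the last range is closed at
#' 100.
#'
#' @param percent_identity Expected pair-wise sequence identity, in
#'   `[0, 100]`.
#' @return A list with `label`, `identity_range`, `weights` (named numeric,
#'   summing to 1), `alpha` and `beta`.
#' @export
#' @examples
#' select_preset(35)$weights
select_preset <- function(percent_identity) {
  if (!is.numeric(percent_identity) || length(percent_identity) != 1L ||
      is.na(percent_identity) || percent_identity < 0 || percent_identity > 100)
    stop("'percent_identity' must be a single number in [0, 100]")
  tab <- .preset_table()
  row <- which(percent_identity >= tab$identity_low &
                 (percent_identity < tab$identity_high |
                    (tab$identity_high == 100 & percent_identity <= 100)))[1L]
  list(label = tab$label[row],
       identity_range = c(tab$identity_low[row], tab$identity_high[row]),
       weights = c(hydrophobicity = tab$w_hydrophobicity[row],
                   size = tab$w_size[row],
                   coil = tab$w_coil[row],
                   thiol = tab$w_thiol[row]),
       alpha = tab$alpha[row],
       beta = tab$beta[row])
}

#' The bundled default property set
#'
#' Loads the four default amino acid property scales bundled with the
#' package -- hydrophobicity (Kyte--Doolittle hydropathy index), size
#' (Zamyatnin residue volume), coil propensity (Deleage--Roux coil
#' conformational parameter) and presence of a thiol group (1 for cysteine,
#' 0 otherwise) -- and attaches the weights of a preset. The numerical scale
#' values are sourced from the published scales named in the bundled file's
#' header; they are ordinary literature scales and fully user-replaceable
#' via [parse_property_file()].
#'
#' @param preset Either a percent identity in `[0, 100]` (routed through
#'   [select_preset()]) or `NULL` for the default 30--40% preset.
#' @return A [property_set()] with four scales and the preset's weights.
#' @export
#' @examples
#' default_property_set()
default_property_set <- function(preset = NULL) {
  path <- system.file("extdata", "default_properties.txt",
                      package = "propalign", mustWork = TRUE)
  ps <- parse_property_file(path)
  p <- select_preset(if (is.null(preset)) 35 else preset)
  property_set(ps$scales, unname(p$weights))
}
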