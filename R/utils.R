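#' Canonical amino-acid codes
#'
#' The amino acids recognised by the package, in the three-letter codes used
#' throughout isotope ecology. `Glx` is the combined glutamic-acid + glutamine
#' pool and `Asx` the combined aspartic-acid + asparagine pool; acid hydrolysis
#' during sample preparation converts Gln to Glu and Asn to Asp, so only the
#' combined pools are measurable.
#'
#' @return Character vector of canonical codes.
#' @export
#' @examples
#' aa_codes()
aa_codes <- function() {
  c("Glx", "Asx", "Ala", "Ile", "Leu", "Pro", "Val", "Gly", "Phe", "Thr", "Met")
}

# aliases normalised on ingest: the single-AA labels map to the hydrolysis pools
aa_alias_map <- c(
  Glu = "Glx", Gln = "Glx",
  Asp = "Asx", Asn = "Asx"
)

normalize_aa <- function(aa) {
  aa <- as.character(aa)
  hit <- aa %in% names(aa_alias_map)
  aa[hit] <- aa_alias_map[aa[hit]]
  aa
}

# plausibility window for delta-15N of individual amino acids (permil vs. air N2)
D15N_RANGE <- c(-30, 60)

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 2.25 -> 2.3 at one
#' decimal), matching how the source tables print trophic positions. Base R's
#' `round()` rounds ties to even, which disagrees on exactly-half values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.25, 1) # 2.3, where round() gives 2.2
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  trunc(x * p + 0.5 * sign(x)) / p
}

# collapse a list of per-row flag character vectors into "a;b" strings
collapse_flags <- function(flags) {
  vapply(flags, function(f) paste(unique(f), collapse = ";"), character(1))
}

has_flag <- function(flag_str, flag) {
  vapply(strsplit(flag_str, ";", fixed = TRUE), function(f) flag %in% f, logical(1))
}
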