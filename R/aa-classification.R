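#' Trophic / source amino-acid classification
#'
#' Defines which amino acids count as "trophic" (their nitrogen passes through
#' transamination and deamination, enriching 15N with every trophic transfer)
#' and which as "source" (amine nitrogen is largely conserved up the food
#' chain, so their delta-15N proxies the primary-producer baseline). The
#' defaults are the seven a-priori trophic AAs (Glx, Asx, Ala, Ile, Leu, Pro,
#' Val) and Phe as the sole source AA; Gly is excluded because it is no longer
#' considered a reliable source AA.
#'
#' @param trophic Character vector of trophic AA codes.
#' @param source Character vector of source AA codes.
#' @param excluded Character vector of AAs barred from any mean.
#' @return An object of class `aa_classification`.
#' @export
#' @examples
#' aa_classification()
#' aa_classification(source = c("Phe", "Met"))
aa_classification <- function(trophic = c("Glx", "Asx", "Ala", "Ile", "Leu", "Pro", "Val"),
                              source = "Phe",
                              excluded = "Gly") {
  trophic <- normalize_aa(trophic)
  source <- normalize_aa(source)
  excluded <- normalize_aa(excluded)
  bad <- setdiff(c(trophic, source, excluded), aa_codes())
  if (length(bad) > 0) {
    abort(paste0("Unknown amino-acid code(s): ", paste(bad, collapse = ", ")))
  }
  if (length(trophic) == 0 || length(source) == 0) {
    abort("Trophic and source sets must both be non-empty.")
  }
  if (length(intersect(trophic, source)) > 0) {
    abort("Trophic and source sets must be disjoint.")
  }
  overlap <- intersect(excluded, c(trophic, source))
  if (length(overlap) > 0) {
    abort(paste0(
      "Excluded AAs cannot also be trophic or source: ",
      paste(overlap, collapse = ", ")
    ))
  }
  structure(
    list(trophic = trophic, source = source, excluded = excluded),
    class = "aa_classification"
  )
}

#' @export
print.aa_classification <- function(x, ...) {
  cat("<aa_classification>\n")
  cat("  trophic: ", paste(x$trophic, collapse = ", "), "\n", sep = "")
  cat("  source:  ", paste(x$source, collapse = ", "), "\n", sep = "")
  cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
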