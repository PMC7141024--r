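#' Compiled cetacean study dataset
#'
#' The package's built-in multi-species cetacean dataset, compiled from a
#' published comparison of amino-acid-derived and stomach-content trophic
#' positions across five species (bowhead whale, beluga, short-beaked common
#' dolphin, sperm whale, and fish-eating and marine-mammal-eating killer
#' whale ecotypes) and three tissues (baleen, skin, dentine collagen).
#'
#' Three tables are returned:
#'
#' * `deltas` - 60 per-individual Glx-Phe delta-15N differences (permil) with
#'   species/tissue labels, the stomach-content TP (`tp_sc`), and the
#'   originally printed 1-dp TP values and SDs per equation (`tp1` ... `tp4_sd`),
#'   for cross-checking recomputation.
#' * `aa_means` - species x tissue group means and SDs of nine amino acids.
#' * `diets` - diet compositions behind the killer-whale `tp_sc` values
#'   (fish-eating: 100% salmon at TP 3.3; marine-mammal-eating: 100% higher
#'   vertebrates at TP 4.0).
#'
#' Per-individual amino-acid values were not published, so the multi-AA
#' equation cannot be recomputed from this fixture. Note also that the source
#' prints a bowhead-skin mean Glx-Phe difference of 13.50 permil while its own
#' ten per-individual values average 13.59; summaries here always recompute
#' from the per-individual values.
#'
#' @return A list with tibbles `deltas`, `aa_means` and `diets`.
#' @export
#' @examples
#' nrow(study_fixture()$deltas) # 60
study_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "csiatp", mustWork = TRUE)
  read <- function(f) {
    readr::read_csv(path(f), show_col_types = FALSE, progress = FALSE)
  }
  list(
    deltas = read("cetacean_study_deltas.csv"),
    aa_means = read("cetacean_study_aa_means.csv"),
    diets = read("killer_whale_diets.csv")
  )
}
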