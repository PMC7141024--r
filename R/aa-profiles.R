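#' Validate a table of amino-acid delta-15N measurements
#'
#' Checks and normalises a long-format table of per-specimen amino-acid
#' delta-15N values (permil vs. atmospheric N2). One row is one (specimen,
#' amino acid) measurement. `Glu`/`Gln` are folded into `Glx` and `Asp`/`Asn`
#' into `Asx` (acid hydrolysis makes only the combined pools measurable).
#'
#' @param data A data frame with columns `specimen_id`, `species`, `tissue`,
#'   `aa`, `d15n`, and optionally `sd` (replicate standard deviation, permil)
#'   and `n_reps`.
#' @param strict If `TRUE` (default) rows with unknown amino-acid codes are an
#'   error; if `FALSE` they are dropped with a warning.
#' @return A tibble with class `aa_profiles` prepended, columns as above
#'   (always including `sd` and `n_reps`, `NA` where absent).
#' @export
#' @examples
#' as_aa_profiles(data.frame(
#'   specimen_id = "w1", species = "bowhead", tissue = "baleen",
#'   aa = c("Glu", "Phe"), d15n = c(18.75, 6.17)
#' ))
as_aa_profiles <- function(data, strict = TRUE) {
  required <- c("specimen_id", "species", "tissue", "aa", "d15n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Missing mandatory column(s): ", paste(missing_cols, collapse = ", ")
    ), class = "csiatp_format_error")
  }
  out <- tibble::as_tibble(data)
  if (!"sd" %in% names(out)) out$sd <- NA_real_
  if (!"n_reps" %in% names(out)) out$n_reps <- NA_integer_
  out <- dplyr::select(
    out, "specimen_id", "species", "tissue", "aa", "d15n", "sd", "n_reps"
  )
  out$specimen_id <- as.character(out$specimen_id)
  out$aa <- normalize_aa(out$aa)

  unknown <- !(out$aa %in% aa_codes())
  if (any(unknown)) {
    msg <- paste0(
      "Unknown amino-acid code(s): ",
      paste(unique(out$aa[unknown]), collapse = ", ")
    )
    if (strict) {
      abort(msg, class = "csiatp_ingest_error")
    }
    warn(paste0(msg, " - ", sum(unknown), " row(s) dropped."))
    out <- out[!unknown, , drop = FALSE]
  }

  dup <- duplicated(out[, c("specimen_id", "aa")])
  if (any(dup)) {
    abort(paste0(
      "Duplicate (specimen, amino acid) rows for specimen(s): ",
      paste(unique(out$specimen_id[dup]), collapse = ", ")
    ), class = "csiatp_ingest_error")
  }

  bad <- !is.finite(out$d15n) | out$d15n < D15N_RANGE[1] | out$d15n > D15N_RANGE[2]
  if (any(bad)) {
    abort(paste0(
      "Implausible delta-15N value(s) (outside [", D15N_RANGE[1], ", ",
      D15N_RANGE[2], "] permil) for specimen(s): ",
      paste(unique(out$specimen_id[bad]), collapse = ", ")
    ), class = "csiatp_ingest_error")
  }
  if (any(!is.na(out$sd) & out$sd < 0)) {
    abort("Replicate SDs must be >= 0.", class = "csiatp_ingest_error")
  }
  if (nrow(out) == 0) warn("No amino-acid measurements: empty profile collection.")
  class(out) <- c("aa_profiles", class(out))
  out
}

#' Read amino-acid delta-15N profiles from delimited text
#'
#' Reads a long-format table (columns `specimen_id`, `species`, `tissue`,
#' `aa`, `d15n`, optional `sd`, `n_reps`) or a wide-format convenience layout
#' (one row per specimen, one column per amino acid) and returns a validated
#' [as_aa_profiles()] tibble. Comma and tab delimiters are auto-detected from
#' the extension; header row is mandatory.
#'
#' @param path Path to a delimited text file (UTF-8).
#' @param format `"long"` (canonical) or `"wide"`.
#' @param delim Field delimiter; defaults to tab for `.tsv`, comma otherwise.
#' @param strict Passed to [as_aa_profiles()].
#' @return An `aa_profiles` tibble.
#' @export
read_aa_profiles <- function(path, format = c("long", "wide"), delim = NULL,
                             strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "csiatp_format_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    comment = "#"
  )
  if (format == "wide") {
    id_cols <- intersect(c("specimen_id", "species", "tissue"), names(raw))
    if (!"specimen_id" %in% id_cols) {
      abort("Wide format requires a specimen_id column.",
        class = "csiatp_format_error"
      )
    }
    raw <- tidyr::pivot_longer(
      raw,
      cols = -dplyr::all_of(id_cols),
      names_to = "aa", values_to = "d15n", values_drop_na = TRUE
    )
    if (!"species" %in% names(raw)) raw$species <- NA_character_
    if (!"tissue" %in% names(raw)) raw$tissue <- NA_character_
  }
  as_aa_profiles(raw, strict = strict)
}

#' Write amino-acid profiles back to delimited text
#'
#' Values are written at full precision; rounding is a display concern only.
#'
#' @param profiles An `aa_profiles` tibble.
#' @param path Output path; tab-delimited for `.tsv`, comma otherwise.
#' @return `path`, invisibly.
#' @export
write_aa_profiles <- function(profiles, path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(as.data.frame(profiles), path, delim = delim, na = "")
  invisible(path)
}

#' Glx-Phe delta-15N difference per specimen
#'
#' The internal-calibration statistic of CSIA-AA trophic-position work:
#' delta-15N of the combined glutamic-acid pool minus delta-15N of
#' phenylalanine, per specimen. Adding a constant to every amino acid of a
#' profile (a baseline shift) leaves it unchanged.
#'
#' @param profiles An `aa_profiles` tibble (or data frame accepted by
#'   [as_aa_profiles()]).
#' @param default_sd Fallback per-AA measurement SD (permil) used when a
#'   specimen carries no replicate SD; set `NULL` to skip SD computation.
#' @return A tibble with one row per specimen: `specimen_id`, `species`,
#'   `tissue`, `delta_glx_phe`, `delta_sd`, `flags` (`missing_sd_defaulted`
#'   when the fallback SD was used).
#' @export
#' @examples
#' prof <- as_aa_profiles(data.frame(
#'   specimen_id = "b1", species = "beluga", tissue = "skin",
#'   aa = c("Glx", "Phe"), d15n = c(28.99, 9.14)
#' ))
#' glx_phe_difference(prof) # delta_glx_phe = 19.85
glx_phe_difference <- function(profiles, default_sd = 0.5) {
  if (!inherits(profiles, "aa_profiles")) profiles <- as_aa_profiles(profiles)
  wide <- tidyr::pivot_wider(
    dplyr::select(profiles, "specimen_id", "species", "tissue", "aa", "d15n"),
    names_from = "aa", values_from = "d15n"
  )
  for (need in c("Glx", "Phe")) {
    if (!need %in% names(wide)) wide[[need]] <- NA_real_
  }
  missing <- is.na(wide$Glx) | is.na(wide$Phe)
  if (any(missing)) {
    abort(paste0(
      "Missing Glx or Phe for specimen(s): ",
      paste(wide$specimen_id[missing], collapse = ", ")
    ), class = "csiatp_missing_analyte")
  }
  sds <- tidyr::pivot_wider(
    dplyr::select(profiles, "specimen_id", "aa", "sd"),
    names_from = "aa", values_from = "sd"
  )
  sds <- sds[match(wide$specimen_id, sds$specimen_id), , drop = FALSE]
  glx_sd <- if ("Glx" %in% names(sds)) sds$Glx else rep(NA_real_, nrow(wide))
  phe_sd <- if ("Phe" %in% names(sds)) sds$Phe else rep(NA_real_, nrow(wide))
  defaulted <- is.na(glx_sd) | is.na(phe_sd)
  delta_sd <- rep(NA_real_, nrow(wide))
  if (!is.null(default_sd)) {
    if (any(defaulted)) {
      inform(paste0(
        "Replicate SD missing for ", sum(defaulted),
        " specimen(s); using default measurement SD of ", default_sd,
        " permil per amino acid."
      ))
    }
    glx_sd[is.na(glx_sd)] <- default_sd
    phe_sd[is.na(phe_sd)] <- default_sd
    delta_sd <- sqrt(glx_sd^2 + phe_sd^2)
  }
  tibble::tibble(
    specimen_id = wide$specimen_id,
    species = wide$species,
    tissue = wide$tissue,
    delta_glx_phe = wide$Glx - wide$Phe,
    delta_sd = delta_sd,
    flags = ifelse(defaulted & !is.null(default_sd), "missing_sd_defaulted", "")
  )
}

#' Per-specimen trophic and source amino-acid means
#'
#' Unweighted arithmetic means of the trophic-AA and source-AA delta-15N
#' values of each specimen, the averaged inputs of the multi-AA
#' trophic-position equation. Excluded AAs (Gly by default) never enter a
#' mean.
#'
#' @inheritParams glx_phe_difference
#' @param classification An [aa_classification()].
#' @param strict If `TRUE` (default) every AA of each set must be present for
#'   every specimen; if `FALSE` the mean is taken over the AAs present and the
#'   row flagged `permissive_aa_set`.
#' @return A tibble: `specimen_id`, `species`, `tissue`, `mean_trophic`,
#'   `mean_source`, `mean_sd_trophic`, `mean_sd_source`, `flags`.
#' @export
aa_means <- function(profiles, classification = aa_classification(),
                     strict = TRUE, default_sd = 0.5) {
  if (!inherits(profiles, "aa_profiles")) profiles <- as_aa_profiles(profiles)
  stopifnot(inherits(classification, "aa_classification"))
  keep <- profiles[!profiles$aa %in% classification$excluded, , drop = FALSE]
  set_mean <- function(set, label) {
    sub <- keep[keep$aa %in% set, , drop = FALSE]
    sub$sd[is.na(sub$sd)] <- default_sd %||% NA_real_
    res <- dplyr::summarise(
      dplyr::group_by(sub, .data$specimen_id, .data$species, .data$tissue),
      mean_val = mean(.data$d15n),
      # SD of an unweighted mean of independent measurements
      mean_sd = sqrt(sum(.data$sd^2)) / dplyr::n(),
      n_aa = dplyr::n(),
      .groups = "drop"
    )
    res$complete <- res$n_aa == length(set)
    res
  }
  tro <- set_mean(classification$trophic, "trophic")
  src <- set_mean(classification$source, "source")
  all_ids <- unique(profiles$specimen_id)
  missing_any <- setdiff(all_ids, intersect(tro$specimen_id, src$specimen_id))
  if (length(missing_any) > 0) {
    abort(paste0(
      "No trophic or source amino acids for specimen(s): ",
      paste(missing_any, collapse = ", ")
    ), class = "csiatp_missing_analyte")
  }
  incomplete <- unique(c(
    tro$specimen_id[!tro$complete], src$specimen_id[!src$complete]
  ))
  if (strict && length(incomplete) > 0) {
    abort(paste0(
      "Incomplete amino-acid set (strict mode) for specimen(s): ",
      paste(incomplete, collapse = ", ")
    ), class = "csiatp_missing_analyte")
  }
  out <- dplyr::left_join(
    dplyr::rename(tro,
      mean_trophic = "mean_val", mean_sd_trophic = "mean_sd"
    )[, c("specimen_id", "species", "tissue", "mean_trophic", "mean_sd_trophic")],
    dplyr::rename(src,
      mean_source = "mean_val", mean_sd_source = "mean_sd"
    )[, c("specimen_id", "mean_source", "mean_sd_source")],
    by = "specimen_id"
  )
  out$flags <- ifelse(out$specimen_id %in% incomplete, "permissive_aa_set", "")
  out
}

#' Group summaries of delta-15N quantities
#'
#' Per-group (species x tissue by default) mean, sample standard deviation
#' (n - 1 denominator) and n. Accepts either an `aa_profiles` table (each AA
#' is summarised, plus the per-specimen Glx-Phe difference) or any table that
#' already carries a `delta_glx_phe` column. Means are returned at full
#' precision; single-member groups report `NA` SD.
#'
#' @param data An `aa_profiles` tibble or a per-specimen table with a
#'   `delta_glx_phe` column.
#' @param group Character vector of grouping columns.
#' @return A tibble: grouping columns, `quantity` (an AA code or
#'   `"delta_glx_phe"`), `mean`, `sd`, `n`.
#' @export
summarize_profiles <- function(data, group = c("species", "tissue")) {
  if ("delta_glx_phe" %in% names(data)) {
    long <- dplyr::transmute(
      tibble::as_tibble(data),
      dplyr::across(dplyr::all_of(group)),
      quantity = "delta_glx_phe", value = .data$delta_glx_phe
    )
  } else {
    profiles <- if (inherits(data, "aa_profiles")) data else as_aa_profiles(data)
    deltas <- glx_phe_difference(profiles, default_sd = NULL)
    long <- dplyr::bind_rows(
      dplyr::transmute(profiles,
        dplyr::across(dplyr::all_of(group)),
        quantity = .data$aa, value = .data$d15n
      ),
      dplyr::transmute(deltas,
        dplyr::across(dplyr::all_of(group)),
        quantity = "delta_glx_phe", value = .data$delta_glx_phe
      )
    )
  }
  dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(group, "quantity")))),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
    n = dplyr::n(),
    .groups = "drop"
  )
}
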