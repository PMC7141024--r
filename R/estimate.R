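#' Estimate trophic positions under one or more frameworks
#'
#' The workhorse of the package: takes either a validated amino-acid profile
#' table ([as_aa_profiles()]) or a per-specimen table that already carries a
#' `delta_glx_phe` column, applies every requested framework, and returns one
#' row per (specimen, framework) with the trophic position and its propagated
#' standard deviation ([propagate_taylor()]).
#'
#' Equation 2 (the multi-AA framework) needs full per-AA data, so in a
#' delta-only table its rows are returned with `NA` TP and a
#' `missing_analyte` flag rather than being dropped. Likewise, in strict mode
#' a specimen with an incomplete trophic/source AA set yields a flagged `NA`
#' row; in permissive mode the mean is taken over the AAs present and flagged
#' `permissive_aa_set`. TP values below 1 are reported as-is and flagged
#' `below_one`, never clamped.
#'
#' @param data An `aa_profiles` tibble, or a data frame with columns
#'   `specimen_id` and `delta_glx_phe` (optionally `species`, `tissue`,
#'   `delta_sd`, `tp_sc`).
#' @param frameworks A named list of [tdf_framework()] objects (default: all
#'   four published sets).
#' @param classification An [aa_classification()] (used by equation 2).
#' @param default_sd Per-AA measurement SD (permil) used where no replicate SD
#'   is available; such rows are flagged `missing_sd_defaulted`. The default
#'   0.5 permil sits mid-range of the reported sub-permil analytical
#'   precision.
#' @param strict Strict amino-acid-set handling for equation 2 (see above).
#' @return A `tp_estimates` tibble: `specimen_id`, `species`, `tissue`,
#'   `framework`, `equation_id`, `delta_input`, `tp`, `tp_sd`, `flags`, plus
#'   `tp_sc` when present in the input; ordered by (specimen_id, equation_id).
#' @export
#' @examples
#' deltas <- data.frame(specimen_id = "w1", delta_glx_phe = 12.40)
#' est <- estimate_tp(deltas, default_frameworks("chikaraishi_single"))
#' round_half_up(est$tp, 1) # 2.2
estimate_tp <- function(data,
                        frameworks = default_frameworks(),
                        classification = aa_classification(),
                        default_sd = 0.5,
                        strict = TRUE) {
  if (inherits(frameworks, "tdf_framework")) frameworks <- list(frameworks)
  stopifnot(length(frameworks) > 0)
  profile_mode <- all(c("aa", "d15n") %in% names(data))
  if (profile_mode) {
    profiles <- if (inherits(data, "aa_profiles")) data else as_aa_profiles(data)
    base <- delta_table_permissive(profiles, default_sd)
    means <- means_table_permissive(profiles, classification, default_sd)
  } else {
    if (!"delta_glx_phe" %in% names(data)) {
      abort(paste0(
        "Input must be an amino-acid profile table (columns aa, d15n) or a ",
        "per-specimen table with a delta_glx_phe column."
      ), class = "csiatp_format_error")
    }
    base <- tibble::as_tibble(data)
    base$specimen_id <- as.character(base$specimen_id)
    if (!"species" %in% names(base)) base$species <- NA_character_
    if (!"tissue" %in% names(base)) base$tissue <- NA_character_
    if (!"delta_sd" %in% names(base)) base$delta_sd <- NA_real_
    defaulted <- is.na(base$delta_sd)
    base$delta_sd[defaulted] <- sqrt(2) * default_sd
    base$flags <- ifelse(defaulted, "missing_sd_defaulted", "")
    means <- NULL
  }
  if (nrow(base) == 0) {
    return(new_tp_estimates(empty_estimates(), frameworks, classification, default_sd))
  }

  one_framework <- function(fw, name) {
    if (fw$equation_id == 2) {
      rows <- eq2_rows(base, means, fw, strict)
    } else {
      tp <- tp_from_delta(base$delta_glx_phe, fw)
      tp_sd <- propagate_taylor(fw, base$delta_glx_phe, delta_sd = base$delta_sd)
      rows <- tibble::tibble(
        specimen_id = base$specimen_id, species = base$species,
        tissue = base$tissue,
        delta_input = base$delta_glx_phe, tp = tp, tp_sd = tp_sd,
        flags = base$flags
      )
    }
    rows$framework <- name
    rows$equation_id <- fw$equation_id
    rows$flags <- add_flag(rows$flags, "below_one", !is.na(rows$tp) & rows$tp < 1)
    rows
  }
  nm <- names(frameworks) %||% vapply(frameworks, `[[`, character(1), "name")
  out <- dplyr::bind_rows(purrr::map2(frameworks, nm, one_framework))
  keep <- c(
    "specimen_id", "species", "tissue", "framework", "equation_id",
    "delta_input", "tp", "tp_sd", "flags"
  )
  if ("tp_sc" %in% names(base)) {
    out <- dplyr::left_join(out, base[, c("specimen_id", "tp_sc")],
      by = "specimen_id"
    )
    keep <- append(keep, "tp_sc", after = 5)
  }
  out <- dplyr::arrange(
    out[, keep], .data$specimen_id, .data$equation_id
  )
  new_tp_estimates(out, frameworks, classification, default_sd)
}

# per-specimen Glx-Phe differences; missing analytes become flagged NA rows
delta_table_permissive <- function(profiles, default_sd) {
  wide <- tidyr::pivot_wider(
    dplyr::select(profiles, "specimen_id", "species", "tissue", "aa", "d15n"),
    names_from = "aa", values_from = "d15n"
  )
  for (need in c("Glx", "Phe")) {
    if (!need %in% names(wide)) wide[[need]] <- NA_real_
  }
  sd_wide <- tidyr::pivot_wider(
    dplyr::select(profiles, "specimen_id", "aa", "sd"),
    names_from = "aa", values_from = "sd"
  )
  sd_wide <- sd_wide[match(wide$specimen_id, sd_wide$specimen_id), , drop = FALSE]
  glx_sd <- if ("Glx" %in% names(sd_wide)) sd_wide$Glx else rep(NA_real_, nrow(wide))
  phe_sd <- if ("Phe" %in% names(sd_wide)) sd_wide$Phe else rep(NA_real_, nrow(wide))
  defaulted <- is.na(glx_sd) | is.na(phe_sd)
  glx_sd[is.na(glx_sd)] <- default_sd
  phe_sd[is.na(phe_sd)] <- default_sd
  missing <- is.na(wide$Glx) | is.na(wide$Phe)
  flags <- character(nrow(wide))
  flags <- add_flag(flags, "missing_sd_defaulted", defaulted & !missing)
  flags <- add_flag(flags, "missing_analyte", missing)
  out <- tibble::tibble(
    specimen_id = wide$specimen_id, species = wide$species, tissue = wide$tissue,
    delta_glx_phe = wide$Glx - wide$Phe,
    delta_sd = sqrt(glx_sd^2 + phe_sd^2),
    flags = flags
  )
  if ("tp_sc" %in% names(profiles)) {
    out <- dplyr::left_join(
      out,
      dplyr::distinct(profiles[, c("specimen_id", "tp_sc")]),
      by = "specimen_id"
    )
  }
  out
}

means_table_permissive <- function(profiles, classification, default_sd) {
  keep <- profiles[!profiles$aa %in% classification$excluded, , drop = FALSE]
  keep$sd[is.na(keep$sd)] <- NA_real_
  one_set <- function(set) {
    sub <- keep[keep$aa %in% set, , drop = FALSE]
    defaulted <- is.na(sub$sd)
    sub$sd[defaulted] <- default_sd
    dplyr::summarise(
      dplyr::group_by(sub, .data$specimen_id),
      mean_val = mean(.data$d15n),
      mean_sd = sqrt(sum(.data$sd^2)) / dplyr::n(),
      n_aa = dplyr::n(),
      any_defaulted = any(defaulted),
      .groups = "drop"
    )
  }
  tro <- one_set(classification$trophic)
  src <- one_set(classification$source)
  ids <- dplyr::distinct(profiles[, c("specimen_id", "species", "tissue")])
  out <- dplyr::left_join(ids, tro, by = "specimen_id")
  out <- dplyr::left_join(out, src,
    by = "specimen_id", suffix = c("_trophic", "_source")
  )
  out$complete <- !is.na(out$n_aa_trophic) & !is.na(out$n_aa_source) &
    out$n_aa_trophic == length(classification$trophic) &
    out$n_aa_source == length(classification$source)
  out
}

eq2_rows <- function(base, means, fw, strict) {
  if (is.null(means)) {
    # delta-only input: the multi-AA equation has no per-AA data to work from
    return(tibble::tibble(
      specimen_id = base$specimen_id, species = base$species,
      tissue = base$tissue,
      delta_input = NA_real_, tp = NA_real_, tp_sd = NA_real_,
      flags = "missing_analyte"
    ))
  }
  delta <- means$mean_val_trophic - means$mean_val_source
  delta_sd <- sqrt(means$mean_sd_trophic^2 + means$mean_sd_source^2)
  usable <- !is.na(delta) & (means$complete | !strict)
  tp <- ifelse(usable, tp_from_delta(delta, fw), NA_real_)
  tp_sd <- ifelse(usable, propagate_taylor(fw, delta, delta_sd = delta_sd), NA_real_)
  flags <- character(nrow(means))
  flags <- add_flag(flags, "missing_analyte", !usable)
  flags <- add_flag(flags, "permissive_aa_set", usable & !means$complete)
  flags <- add_flag(
    flags, "missing_sd_defaulted",
    usable & (means$any_defaulted_trophic | means$any_defaulted_source)
  )
  tibble::tibble(
    specimen_id = means$specimen_id, species = means$species,
    tissue = means$tissue,
    delta_input = ifelse(usable, delta, NA_real_), tp = tp, tp_sd = tp_sd,
    flags = flags
  )
}

add_flag <- function(flags, flag, where) {
  flags[where] <- ifelse(
    flags[where] == "", flag, paste(flags[where], flag, sep = ";")
  )
  flags
}

empty_estimates <- function() {
  tibble::tibble(
    specimen_id = character(), species = character(), tissue = character(),
    framework = character(), equation_id = integer(),
    delta_input = double(), tp = double(), tp_sd = double(), flags = character()
  )
}

new_tp_estimates <- function(tbl, frameworks, classification, default_sd) {
  structure(
    tbl,
    frameworks = frameworks, classification = classification,
    default_sd = default_sd,
    class = c("tp_estimates", class(tbl))
  )
}

#' Wide, display-rounded TP table
#'
#' Reshapes a [estimate_tp()] result into the one-row-per-specimen layout the
#' field's tables use: the Glx-Phe difference, the stomach-content TP when
#' available, and `tp`/`sd` column pairs per framework, rounded half-up (TP
#' to `digits` decimals).
#'
#' @param estimates A `tp_estimates` tibble.
#' @param digits Decimal places for display rounding (default 1).
#' @return A tibble, one row per specimen.
#' @export
tp_table <- function(estimates, digits = 1) {
  est <- tibble::as_tibble(estimates)
  est$tp <- round_half_up(est$tp, digits)
  est$tp_sd <- round_half_up(est$tp_sd, digits)
  id_cols <- intersect(
    c("specimen_id", "species", "tissue", "delta_input", "tp_sc"),
    names(est)
  )
  # delta_input differs per equation (eq 2 averages); key the row on eq-1/3/4 delta
  delta <- dplyr::summarise(
    dplyr::group_by(est, .data$specimen_id),
    delta_glx_phe = {
      d <- .data$delta_input[.data$equation_id != 2]
      if (length(d) > 0) d[1] else NA_real_
    },
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(est, -"delta_input", -"flags"),
    names_from = "equation_id", values_from = c("tp", "tp_sd"),
    names_glue = "{.value}_eq{equation_id}", id_cols = dplyr::all_of(setdiff(id_cols, "delta_input")),
    unused_fn = list()
  )
  dplyr::left_join(delta, wide, by = "specimen_id")
}

#' @export
print.tp_estimates <- function(x, ...) {
  cat("# Trophic-position estimates:", nrow(x), "rows (",
    length(unique(x$specimen_id)), "specimens x",
    length(unique(x$framework)), "frameworks )\n")
  NextMethod()
}

#' Tidy a trophic-position estimate table
#'
#' One row per (specimen, framework) with display-ready columns; flags are
#' kept verbatim.
#'
#' @param x A `tp_estimates` object.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy tp_estimates
#' @export
tidy.tp_estimates <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "tp_estimates")
  out
}

#' One-line summary of a trophic-position estimate table
#'
#' @param x A `tp_estimates` object.
#' @param ... Unused.
#' @return A one-row tibble: specimen and framework counts, TP range, number
#'   of flagged rows.
#' @method glance tp_estimates
#' @export
glance.tp_estimates <- function(x, ...) {
  tibble::tibble(
    n_specimens = length(unique(x$specimen_id)),
    n_frameworks = length(unique(x$framework)),
    n_estimates = sum(!is.na(x$tp)),
    n_flagged = sum(x$flags != ""),
    tp_min = suppressWarnings(min(x$tp, na.rm = TRUE)),
    tp_max = suppressWarnings(max(x$tp, na.rm = TRUE)),
    mean_tp_sd = mean(x$tp_sd, na.rm = TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
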