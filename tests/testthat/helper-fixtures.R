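# in-code fixture builders shared across test files

# one specimen's long-format profile from a named vector of d15n values
make_profile <- function(specimen_id, values, species = "test", tissue = "skin",
                         sd = NULL) {
  tibble::tibble(
    specimen_id = specimen_id,
    species = species,
    tissue = tissue,
    aa = names(values),
    d15n = unname(values),
    sd = if (is.null(sd)) NA_real_ else unname(sd[names(values)])
  )
}

# the nine group-mean values for bowhead skin, used as a single pseudo-profile
bowhead_skin_means <- c(
  Glx = 19.02, Asx = 13.91, Ala = 17.03, Ile = 17.42, Leu = 15.24,
  Pro = 19.41, Val = 19.29, Gly = 8.18, Phe = 5.53
)

beluga_skin_means <- c(
  Glx = 28.99, Asx = 22.45, Ala = 26.77, Ile = 27.95, Leu = 27.65,
  Pro = 32.37, Val = 29.55, Gly = 3.73, Phe = 9.14
)

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}
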