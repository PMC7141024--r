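test_that("long-format reading builds one profile per specimen and normalizes aliases", {
  path <- write_temp_csv(tibble::tibble(
    specimen_id = c("w1", "w1", "w2", "w2"),
    species = "bowhead", tissue = "baleen",
    aa = c("Glx", "Phe", "Glu", "Phe"),
    d15n = c(18.75, 6.17, 18.10, 6.00)
  ))
  prof <- read_aa_profiles(path)
  expect_s3_class(prof, "aa_profiles")
  expect_equal(nrow(prof), 4)
  w1 <- prof[prof$specimen_id == "w1", ]
  expect_equal(setNames(w1$d15n, w1$aa), c(Glx = 18.75, Phe = 6.17))
  # "Glu" ingested under the combined hydrolysis pool Glx
  expect_true(all(prof$aa[prof$specimen_id == "w2"] %in% c("Glx", "Phe")))
})

test_that("empty input yields an empty collection with a warning", {
  path <- write_temp_csv(tibble::tibble(
    specimen_id = character(), species = character(), tissue = character(),
    aa = character(), d15n = double()
  ))
  expect_warning(prof <- read_aa_profiles(path), "empty")
  expect_equal(nrow(prof), 0)
})

test_that("ingest validation rejects malformed tables", {
  base <- make_profile("w1", c(Glx = 18, Phe = 6))
  expect_error(
    as_aa_profiles(base[, setdiff(names(base), "d15n")]),
    "d15n",
    class = "csiatp_format_error"
  )
  dup <- dplyr::bind_rows(base, base[1, ])
  expect_error(as_aa_profiles(dup), "w1", class = "csiatp_ingest_error")
  out_of_range <- make_profile("w9", c(Glx = 75, Phe = 6))
  expect_error(as_aa_profiles(out_of_range), "w9", class = "csiatp_ingest_error")
  neg_sd <- make_profile("w1", c(Glx = 18, Phe = 6), sd = c(Glx = -1, Phe = 0.2))
  expect_error(as_aa_profiles(neg_sd), "SD", class = "csiatp_ingest_error")
  unk <- make_profile("w1", c(Glx = 18, Phe = 6, Foo = 1))
  expect_error(as_aa_profiles(unk), "Foo", class = "csiatp_ingest_error")
  expect_warning(ok <- as_aa_profiles(unk, strict = FALSE), "Foo")
  expect_equal(nrow(ok), 2)
})

test_that("Glx-Phe difference matches published group means and flags defaults", {
  prof <- as_aa_profiles(make_profile("b1", beluga_skin_means,
    species = "beluga"
  ))
  res <- suppressMessages(glx_phe_difference(prof))
  expect_equal(res$delta_glx_phe, 19.85)
  expect_true(has_flag <- grepl("missing_sd_defaulted", res$flags))
  expect_equal(res$delta_sd, sqrt(2) * 0.5)

  equal <- as_aa_profiles(make_profile("e1", c(Glx = 10, Phe = 10)))
  expect_equal(suppressMessages(glx_phe_difference(equal))$delta_glx_phe, 0)
  one_step <- as_aa_profiles(make_profile("s1", c(Glx = 11.0, Phe = 3.4)))
  expect_equal(suppressMessages(glx_phe_difference(one_step))$delta_glx_phe, 7.6)
})

test_that("Glx-Phe difference errors name the specimen missing an analyte", {
  prof <- as_aa_profiles(dplyr::bind_rows(
    make_profile("ok1", c(Glx = 18, Phe = 6)),
    make_profile("bad7", c(Glx = 18, Ala = 12))
  ))
  expect_error(
    suppressMessages(glx_phe_difference(prof)), "bad7",
    class = "csiatp_missing_analyte"
  )
})

test_that("Glx-Phe difference is invariant under baseline translation", {
  set.seed(11)
  for (i in 1:10) {
    vals <- setNames(runif(9, 0, 30), names(bowhead_skin_means))
    shift <- runif(1, -10, 10)
    p1 <- as_aa_profiles(make_profile("a", vals))
    p2 <- as_aa_profiles(make_profile("a", vals + shift))
    expect_equal(
      suppressMessages(glx_phe_difference(p1))$delta_glx_phe,
      suppressMessages(glx_phe_difference(p2))$delta_glx_phe
    )
  }
})

test_that("trophic and source means reproduce hand-computed values", {
  prof <- as_aa_profiles(make_profile("bw", bowhead_skin_means))
  m <- suppressMessages(aa_means(prof))
  # hand sum of the seven trophic AAs / 7
  hand <- (19.02 + 13.91 + 17.03 + 17.42 + 15.24 + 19.41 + 19.29) / 7
  expect_equal(m$mean_trophic, hand)
  expect_equal(round(m$mean_trophic, 2), 17.33)
  expect_equal(m$mean_source, 5.53) # singleton source set
})

test_that("trophic mean is order-independent and constant profiles give the constant", {
  cls <- aa_classification()
  vals <- bowhead_skin_means
  perm <- vals[sample(names(vals))]
  m1 <- suppressMessages(aa_means(as_aa_profiles(make_profile("a", vals)), cls))
  m2 <- suppressMessages(aa_means(as_aa_profiles(make_profile("a", perm)), cls))
  expect_equal(m1$mean_trophic, m2$mean_trophic)

  flat <- setNames(rep(7.7, 8), c(cls$trophic, cls$source))
  mf <- suppressMessages(aa_means(as_aa_profiles(make_profile("f", flat)), cls))
  expect_equal(mf$mean_trophic, 7.7)
})

test_that("strict mode rejects incomplete AA sets; permissive mode flags them", {
  partial <- as_aa_profiles(make_profile("p1", c(Glx = 18, Ala = 15, Phe = 6)))
  expect_error(
    suppressMessages(aa_means(partial, strict = TRUE)), "p1",
    class = "csiatp_missing_analyte"
  )
  m <- suppressMessages(aa_means(partial, strict = FALSE))
  expect_equal(m$mean_trophic, (18 + 15) / 2)
  expect_match(m$flags, "permissive_aa_set")
  no_source <- as_aa_profiles(make_profile("p2", c(Glx = 18, Ala = 15)))
  expect_error(
    suppressMessages(aa_means(no_source, strict = FALSE)), "p2",
    class = "csiatp_missing_analyte"
  )
})

test_that("excluded amino acids never enter a mean", {
  with_gly <- bowhead_skin_means
  without_gly <- bowhead_skin_means[names(bowhead_skin_means) != "Gly"]
  m1 <- suppressMessages(aa_means(as_aa_profiles(make_profile("a", with_gly))))
  m2 <- suppressMessages(aa_means(as_aa_profiles(make_profile("a", without_gly))))
  expect_equal(m1$mean_trophic, m2$mean_trophic)
  expect_equal(m1$mean_source, m2$mean_source)
})

test_that("classification invariants are enforced", {
  expect_error(aa_classification(trophic = character()), "non-empty")
  expect_error(aa_classification(trophic = "Phe"), "disjoint")
  expect_error(aa_classification(excluded = "Phe"), "Excluded")
  expect_error(aa_classification(trophic = c("Glx", "Xyz")), "Xyz")
})

test_that("group summaries use the n-1 SD and recover printed species means", {
  fx <- study_fixture()
  summ <- summarize_profiles(fx$deltas)
  dolphin <- summ[summ$species == "common_dolphin", ]
  expect_equal(round(dolphin$mean, 2), 13.65)
  expect_equal(dolphin$n, 9)
  d <- fx$deltas$delta_glx_phe[fx$deltas$species == "common_dolphin"]
  expect_equal(dolphin$sd, sd(d)) # sample SD, n-1 denominator

  single <- summarize_profiles(
    tibble::tibble(species = "x", tissue = "skin", delta_glx_phe = 12)
  )
  expect_true(is.na(single$sd))
  expect_equal(single$n, 1)
})

test_that("profiles round-trip through write/read at full precision", {
  vals <- setNames(
    c(18.123456789012345, 6.98765432109876543, 12.3, 15.000000000000071),
    c("Glx", "Phe", "Ala", "Pro")
  )
  prof <- as_aa_profiles(make_profile("rt1", vals))
  path <- withr::local_tempfile(fileext = ".csv")
  write_aa_profiles(prof, path)
  back <- read_aa_profiles(path)
  expect_equal(back$d15n, prof$d15n, tolerance = 1e-15)
  expect_equal(back$specimen_id, prof$specimen_id)
})

test_that("the wide-format convenience reader matches the long reader", {
  wide <- tibble::tibble(
    specimen_id = c("w1", "w2"), species = "beluga", tissue = "skin",
    Glx = c(28.99, 28.10), Phe = c(9.14, 9.00)
  )
  path <- write_temp_csv(wide)
  prof <- read_aa_profiles(path, format = "wide")
  expect_equal(nrow(prof), 4)
  expect_equal(
    suppressMessages(glx_phe_difference(prof))$delta_glx_phe,
    c(19.85, 19.10)
  )
})
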