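fw <- default_frameworks()

test_that("equation 1 reproduces printed trophic positions and anchors", {
  eq1 <- fw$chikaraishi_single
  expect_equal(tp_from_delta(12.40, eq1), (12.40 - 3.4) / 7.6 + 1)
  expect_equal(round_half_up(tp_from_delta(12.40, eq1), 1), 2.2)
  expect_equal(tp_from_delta(3.4, eq1), 1) # primary producer
  expect_equal(tp_from_delta(3.4 + 2 * 7.6, eq1), 3) # two full steps
})

test_that("equation 2 matches arithmetic on published group means", {
  eq2 <- fw$multi_aa
  # brute-force oracle: recompute the trophic mean by summation, then the
  # closed form, entirely outside the package's code path
  tro <- sum(c(19.02, 13.91, 17.03, 17.42, 15.24, 19.41, 19.29)) / 7
  src <- 5.53
  oracle <- (tro - src - 3.4) / 7.6 + 1
  expect_equal(tp_from_delta(tro - src, eq2), oracle)
  expect_equal(round(oracle, 3), 2.105)
  expect_equal(tp_from_delta(3.4, eq2), 1)
  expect_equal(tp_from_delta(3.4 + 7.6, eq2), 2)
})

test_that("equation 3 applies the seal TDF to the final transfer only", {
  eq3 <- fw$germain_dual
  expect_equal(round_half_up(tp_from_delta(20.16, eq3), 1), 3.6)
  expect_equal(round_half_up(tp_from_delta(12.40, eq3), 1), 2.6)
  expect_equal(tp_from_delta(3.4 + 4.3, eq3), 2) # one consumer transfer
})

test_that("equation 4 applies the penguin TDF to upper transfers", {
  eq4 <- fw$mcmahon_dual
  expect_equal(round_half_up(tp_from_delta(13.36, eq4), 1), 2.7)
  expect_equal(round_half_up(tp_from_delta(9.23, eq4), 1), 1.5)
  expect_equal(tp_from_delta(3.4 + 7.6, eq4), 2) # zeroed numerator
})

test_that("framework construction enforces the parameter contracts", {
  expect_error(tdf_framework("x", 3), class = "csiatp_configuration_error")
  expect_error(
    tdf_framework("x", 1, tdf_consumer = uncertain(4.3, 1.2)),
    class = "csiatp_configuration_error"
  )
  expect_error(
    tdf_framework("x", 1, tdf_base = uncertain(0, 1)),
    class = "csiatp_parameter_error"
  )
  expect_error(
    tdf_framework("x", 4, tdf_consumer = uncertain(-1, 0.4)),
    class = "csiatp_parameter_error"
  )
  expect_error(uncertain(1, -0.1), "SD")
})

test_that("adding the denominator TDF to delta raises TP by exactly one", {
  grid <- seq(8, 22, by = 0.5)
  for (f in fw) {
    denom <- if (f$equation_id == 4) f$tdf_consumer$value else f$tdf_base$value
    expect_equal(
      tp_from_delta(grid + denom, f),
      tp_from_delta(grid, f) + 1
    )
  }
})

test_that("equations 3 and 1 differ by a constant offset over the delta grid", {
  grid <- seq(8, 22, by = 0.1)
  diff <- tp_from_delta(grid, fw$germain_dual) -
    tp_from_delta(grid, fw$chikaraishi_single)
  expect_equal(diff, rep(1 - 4.3 / 7.6, length(grid)))
})

test_that("equations 1 and 4 agree at the one-full-step anchor", {
  expect_equal(tp_from_delta(3.4 + 7.6, fw$chikaraishi_single), 2)
  expect_equal(tp_from_delta(3.4 + 7.6, fw$mcmahon_dual), 2)
})

test_that("stomach-content TP is the diet-weighted prey TP plus one", {
  expect_equal(tp_stomach_content(data.frame(prey_tp = 3.3, proportion = 1)), 4.3)
  expect_equal(tp_stomach_content(data.frame(prey_tp = 4.0, proportion = 1)), 5.0)
  expect_equal(
    tp_stomach_content(data.frame(prey_tp = c(2, 4), proportion = c(0.5, 0.5))),
    4.0
  )
  expect_error(
    tp_stomach_content(data.frame(prey_tp = double(), proportion = double())),
    class = "csiatp_parameter_error"
  )
  expect_error(
    tp_stomach_content(data.frame(prey_tp = 3, proportion = 0.7)),
    class = "csiatp_parameter_error"
  )
  expect_error(
    tp_stomach_content(data.frame(prey_tp = 0.5, proportion = 1)),
    class = "csiatp_parameter_error"
  )
  by_sp <- tp_stomach_content(study_fixture()$diets, by = "species")
  expect_equal(by_sp$tp_sc[by_sp$species == "killer_whale_fe"], 4.3)
  expect_equal(by_sp$tp_sc[by_sp$species == "killer_whale_mme"], 5.0)
})

test_that("estimate_tp produces one ordered row per specimen and framework", {
  fx <- study_fixture()
  est <- estimate_tp(fx$deltas)
  expect_equal(nrow(est), 60 * 4)
  expect_equal(
    order(est$specimen_id, est$equation_id), seq_len(nrow(est))
  )
  bb <- tidy(est)[tidy(est)$specimen_id == "bw_bal_01", ]
  expect_equal(
    round_half_up(bb$tp[match(c(1, 3, 4), bb$equation_id)], 1),
    c(2.2, 2.6, 2.4)
  )
})

test_that("estimate_tp on an empty collection returns an empty result", {
  empty <- tibble::tibble(specimen_id = character(), delta_glx_phe = double())
  est <- estimate_tp(empty)
  expect_s3_class(est, "tp_estimates")
  expect_equal(nrow(est), 0)
})

test_that("the multi-AA equation is flagged, not dropped, without per-AA data", {
  fx <- study_fixture()
  est <- tidy(estimate_tp(fx$deltas))
  eq2 <- est[est$equation_id == 2, ]
  expect_equal(nrow(eq2), 60)
  expect_true(all(is.na(eq2$tp)))
  expect_true(all(grepl("missing_analyte", eq2$flags)))
})

test_that("estimate_tp runs all four equations on full profiles", {
  profs <- as_aa_profiles(dplyr::bind_rows(
    make_profile("bw", bowhead_skin_means, species = "bowhead"),
    make_profile("bel", beluga_skin_means, species = "beluga")
  ))
  est <- tidy(suppressMessages(estimate_tp(profs)))
  expect_equal(nrow(est), 8)
  expect_false(any(is.na(est$tp)))
  eq2_bw <- est$tp[est$specimen_id == "bw" & est$equation_id == 2]
  expect_equal(round(eq2_bw, 3), 2.105)
})

test_that("sub-1 trophic positions are flagged below_one, never clamped", {
  est <- tidy(estimate_tp(
    tibble::tibble(specimen_id = "low", delta_glx_phe = 2.0),
    default_frameworks("chikaraishi_single")
  ))
  expect_lt(est$tp, 1)
  expect_equal(est$tp, (2.0 - 3.4) / 7.6 + 1)
  expect_match(est$flags, "below_one")
})

test_that("tidy and glance summarise an estimate table", {
  est <- estimate_tp(study_fixture()$deltas)
  td <- tidy(est)
  expect_false(inherits(td, "tp_estimates"))
  g <- glance(est)
  expect_equal(g$n_specimens, 60)
  expect_equal(g$n_frameworks, 4)
  expect_equal(g$n_estimates, 180) # equation 2 has no per-AA data here
})
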