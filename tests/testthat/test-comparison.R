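test_that("RRR is the proton/photon relative-risk quotient", {
  expect_equal(round(compute_rrr(7.27, 8.37), 2), 0.87)
  expect_equal(round(compute_rrr(1.28, 8.39), 2), 0.15)
  expect_equal(compute_rrr(3.3, 3.3), 1)
  expect_error(compute_rrr(2, 0), "positive")
})

test_that("RNTCP handles the numerically-zero regimes explicitly", {
  # published myocardium values (percent scale): 2.17 / 2.67 -> 0.8
  r <- compute_rntcp(0.0217, 0.0267)
  expect_equal(round(r$rntcp, 1), 0.8)
  expect_identical(r$flag, "ok")
  r2 <- compute_rntcp(0.0211, 0.0192)
  expect_equal(round(r2$rntcp, 1), 1.1)
  r3 <- compute_rntcp(0, 0)
  expect_identical(r3$flag, "both_zero")
  expect_equal(r3$rntcp, 0)
  r4 <- compute_rntcp(0.1, 0)
  expect_identical(r4$flag, "photon_zero")
  expect_false(is.finite(r4$rntcp))
  expect_error(compute_rntcp(1.2, 0.5), "\\[0, 1\\]")
})

test_that("run_case regenerates the published RR values from mean doses alone", {
  for (pat in c("HD", "MB")) {
    tab <- cardiac_dose_table()
    case <- cardrisk_case(pat, tab[tab$patient == pat, ],
                          fractionation = reference_fractionation(pat))
    res <- run_case(case)
    wh <- res$rr[res$rr$structure == "whole_heart", ]
    if (pat == "HD") {
      expect_equal(round(wh$rr_proton, 2), 7.27)
      expect_equal(round(wh$rr_photon, 2), 8.37)
      expect_equal(round(wh$rrr, 2), 0.87)
    } else {
      expect_equal(round(wh$rr_proton, 2), 1.28)
      expect_equal(round(wh$rr_photon, 2), 8.39)
      expect_equal(round(wh$rrr, 2), 0.15)
    }
    expect_equal(nrow(res$ntcp), 0)  # no DVHs supplied, RR still computable
  }
})

test_that("identical proton and photon inputs give unit ratios throughout", {
  d <- random_dvh(30, bin_width = 0.6, unit = "Sv")
  tab <- data.frame(structure = "whole_heart", primary_gy = 10,
                    stray_gy = 0, stray_sv = 0, photon_gy = 11)
  # equalize the mean paths: photon dose = weighted proton total
  tab$photon_gy <- 1.1 * tab$primary_gy
  dphoton <- dvh_differential(d$dose, d$volume, d$structure, "Gy",
                              bin_width = d$bin_width)
  # photon DVH numerically equal to the proton equivalent-dose DVH
  case <- cardrisk_case("X", tab,
                        dvhs = list(whole_heart = list(proton = d,
                                                       photon = dphoton)),
                        fractionation = fractionation_scheme(18))
  res <- run_case(case)
  expect_equal(res$rr$rrr, 1)
  expect_true(all(abs(res$ntcp$rntcp - 1) < 1e-12))
})

test_that("NTCP requests without DVHs fail loudly while RR does not", {
  tab <- cardiac_dose_table()
  case <- cardrisk_case("HD", tab[tab$patient == "HD", ],
                        fractionation = reference_fractionation("HD"))
  expect_error(prepare_equivalent_dvh(case, "whole_heart", "proton"),
               "no proton DVH")
  expect_s3_class(run_case(case)$rr, "data.frame")
})

test_that("published proton totals may replace the component computation", {
  tab <- cardiac_dose_table()
  case <- cardrisk_case("HD", tab[tab$patient == "HD", ],
                        fractionation = reference_fractionation("HD"))
  res <- run_case(case, total_from = "table")
  wh <- res$rr[res$rr$structure == "whole_heart", ]
  expect_equal(wh$d_proton_sv, 10.45)
  expect_error(run_case(case, total_from = "table", neutron_scale = 2),
               "neutron_scale")
})

test_that("absolute NTCP values are flagged for reporting only on matched cohorts", {
  set <- cardiac_param_sets()
  hd <- build_case("HD", generator_settings(seed = 3))
  res <- run_case(hd)
  expect_true(all(res$ntcp$report_absolute == (res$ntcp$source == "hodgkin")))
  mb <- build_case("MB", generator_settings(seed = 3))
  expect_false(any(run_case(mb)$ntcp$report_absolute))
  # full-precision internal values: RRR equals the RR quotient exactly
  expect_equal(res$rr$rrr, res$rr$rr_proton / res$rr$rr_photon,
               tolerance = 1e-12)
})

test_that("a comparison result flattens to a long data frame", {
  hd <- build_case("HD", generator_settings(seed = 5))
  res <- run_case(hd)
  df <- as.data.frame(res)
  expect_true(all(c("structure", "set_id", "rntcp", "rrr") %in% names(df)))
  expect_equal(nrow(df), nrow(res$ntcp))
})
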