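test_that("a degenerate one-point grid reproduces the baseline ratio exactly", {
  mb <- build_case("MB", generator_settings(seed = 11))
  base <- run_case(mb)
  row <- base$ntcp[base$ntcp$set_id == "whole_heart_rs_70.3", ]
  sw <- sweep_parameters(mb, "whole_heart", "rs",
                         axes = list(d50 = 70.3),
                         fixed = list(gamma = 0.96, s = 1))
  expect_equal(nrow(sw$grid), 1)
  expect_equal(sw$grid$rntcp, row$rntcp)
  expect_equal(unname(sw$summary["min"]), unname(sw$summary["max"]))
})

test_that("invalid grid points are skipped with a warning", {
  mb <- build_case("MB", generator_settings(seed = 11))
  expect_warning(
    sw <- sweep_parameters(mb, "whole_heart", "rs",
                           axes = list(gamma = c(-1, 0.96)),
                           fixed = list(d50 = 70.3, s = 1)),
    "skipping")
  expect_true(is.na(sw$grid$rntcp[1]))
  expect_false(is.na(sw$grid$rntcp[2]))
})

test_that("RRR is strictly increasing in the neutron scaling factor", {
  hd <- build_case("HD", generator_settings(seed = 11))
  sw <- sweep_neutron_wr(hd, seq(0.5, 10, length.out = 12))
  wh <- sw$rrr[sw$rrr$structure == "whole_heart", ]
  expect_true(all(diff(wh$rrr) > 0))
  # photon arm is unaffected by neutron scaling
  expect_equal(length(unique(wh$rr_photon)), 1L)
})

test_that("the RRR unity crossing matches its closed form", {
  tab <- cardiac_dose_table()
  hd <- cardrisk_case("HD", tab[tab$patient == "HD", ],
                      fractionation = reference_fractionation("HD"))
  f_star <- rrr_unity_crossing(hd, "whole_heart")
  expect_equal(f_star, (12.28 - 9.79) / 0.66, tolerance = 1e-9)
  # at the crossing the two total mean doses coincide
  expect_equal(total_mean_equivalent_dose(8.90, 1.1, 0.66, f_star), 12.28,
               tolerance = 1e-9)
})

test_that("contour-variant comparison is the identity for identical cases and RNTCP inverts under modality swap", {
  mb <- build_case("MB", generator_settings(seed = 11))
  cmp <- compare_contour_variants(mb, mb)
  expect_equal(cmp$rntcp_a, cmp$rntcp_b)
  # swapping proton and photon inputs inverts each finite nonzero ratio
  swapped <- mb
  for (st in names(swapped$dvhs)) {
    pr <- prepare_equivalent_dvh(mb, st, "proton")
    ph <- prepare_equivalent_dvh(mb, st, "photon")
    # rebuild a case whose raw DVHs are the processed ones, swapped, with
    # no further shifting/correction (zero stray, 2 Gy/fraction identity)
    swapped$dvhs[[st]] <- list(
      proton = ph,
      photon = dvh_differential(pr$dose, pr$volume, st, "Gy"))
  }
  tab <- swapped$dose_table
  tab$stray_sv <- 0
  tab$stray_gy <- 0
  flat <- cardrisk_case("MBswap", tab, swapped$dvhs,
                        fractionation_scheme(1e6), mb$weighting)
  tab0 <- mb$dose_table
  tab0$stray_sv <- 0
  tab0$stray_gy <- 0
  orig_dvhs <- lapply(names(mb$dvhs), function(st) list(
    proton = prepare_equivalent_dvh(mb, st, "proton"),
    photon = {
      ph <- prepare_equivalent_dvh(mb, st, "photon")
      dvh_differential(ph$dose, ph$volume, st, "Gy")
    }))
  names(orig_dvhs) <- names(mb$dvhs)
  flat0 <- cardrisk_case("MB0", tab0, orig_dvhs,
                         fractionation_scheme(1e6), mb$weighting)
  a <- run_case(flat0)$ntcp
  b <- run_case(flat)$ntcp
  ok <- a$flag == "ok" & b$flag == "ok"
  expect_true(any(ok))
  expect_equal(b$rntcp[ok], 1 / a$rntcp[ok], tolerance = 1e-9)
})

test_that("thicker-shell contour variants stay qualitatively below unity for the craniospinal case", {
  mb <- build_case("MB", generator_settings(seed = 11))
  expect_identical(perturb_contour_variant(mb, 1), mb)
  rev5 <- perturb_contour_variant(mb, 5)
  cmp <- compare_contour_variants(mb, rev5)
  expect_true(all(cmp$rntcp_b < 1))
  # mixture conserves fractional volume
  for (st in names(rev5$dvhs))
    for (mod in c("proton", "photon"))
      expect_equal(sum(rev5$dvhs[[st]][[mod]]$volume), 1, tolerance = 1e-9)
})

test_that("grid evaluation order does not affect sweep results", {
  mb <- build_case("MB", generator_settings(seed = 11))
  ax <- list(d50 = c(50, 70), gamma = c(0.9, 1.2))
  sw1 <- sweep_parameters(mb, "myocardium", "rs", ax, fixed = list(s = 1))
  ax_rev <- list(d50 = rev(ax$d50), gamma = rev(ax$gamma))
  sw2 <- sweep_parameters(mb, "myocardium", "rs", ax_rev, fixed = list(s = 1))
  m1 <- sw1$grid[order(sw1$grid$d50, sw1$grid$gamma), "rntcp"]
  m2 <- sw2$grid[order(sw2$grid$d50, sw2$grid$gamma), "rntcp"]
  expect_equal(m1, m2)
})
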