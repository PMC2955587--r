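test_that("the Michaelis-Menten rate obeys its defining identities", {
  # half-maximal at S = Km
  expect_equal(michaelis_menten_rate(77, 77, 0.38), 0.38 / 2)
  # linear regime: v ~ (kcat/Km) * S for S << Km
  expect_equal(michaelis_menten_rate(1e-4, 77, 0.38),
               0.38 / 77 * 1e-4, tolerance = 1e-5)
  # saturation: v -> kcat * E0
  expect_equal(michaelis_menten_rate(1e9, 77, 0.38, E0_uM = 2),
               0.76, tolerance = 1e-6)
  expect_equal(michaelis_menten_rate(0, 77, 0.38), 0)
  expect_error(michaelis_menten_rate(10, -1, 0.38),
               class = "chitokin_invalid_parameter")
})

test_that("noiseless initial-rate data return the generating Km and kcat", {
  d <- generate_initial_rates(77, 0.38, noise = NULL)
  fit <- fit_michaelis_menten(d)
  expect_equal(fit$Km_uM, 77, tolerance = 1e-6)
  expect_equal(fit$kcat_s, 0.38, tolerance = 1e-6)
  expect_equal(fit$kcat_over_Km, 0.38 / 77e-6, tolerance = 1e-6)
  # criterion-level check: round trip holds Km to within 0.5 uM
  expect_lt(abs(fit$Km_uM - 77), 0.5)
})

test_that("the two-point design is solved algebraically and exactly", {
  S <- c(50, 200)
  d <- tibble::tibble(substrate_uM = S,
                      rate = michaelis_menten_rate(S, 77, 0.38))
  fit <- fit_michaelis_menten(d)
  expect_equal(fit$Km_uM, 77, tolerance = 1e-10)
  expect_equal(fit$kcat_s, 0.38, tolerance = 1e-10)
  expect_null(fit$fit)  # no iterative fit was run
})

test_that("enzyme normalisation divides Vmax into kcat", {
  d <- generate_initial_rates(77, 0.38, E0_uM = 38, noise = NULL)
  fit <- fit_michaelis_menten(d, enzyme_total_uM = 38)
  expect_equal(fit$kcat_s, 0.38, tolerance = 1e-6)
  expect_equal(fit$Vmax, 0.38 * 38, tolerance = 1e-6)
})

test_that("across noisy replicates the Km estimates centre on the truth", {
  est <- vapply(1:50, function(s) {
    d <- generate_initial_rates(77, 0.38, noise = noise_model(cv = 0.05, seed = s))
    fit_michaelis_menten(d)$Km_uM
  }, numeric(1))
  expect_lt(abs(stats::median(est) - 77), 5)
  expect_lt(stats::sd(est), 15)
})

test_that("refitting a curve simulated from fitted parameters is idempotent", {
  d <- generate_initial_rates(77, 0.38, noise = noise_model(cv = 0.05, seed = 3))
  f1 <- fit_michaelis_menten(d)
  d2 <- generate_initial_rates(f1$Km_uM, f1$kcat_s, noise = NULL)
  f2 <- fit_michaelis_menten(d2)
  expect_equal(f2$Km_uM, f1$Km_uM, tolerance = 1e-6)
  expect_equal(f2$kcat_s, f1$kcat_s, tolerance = 1e-6)
})

test_that("kcat/Km arithmetic reproduces every reported integer efficiency", {
  tab <- vhnag2_kinetic_table()
  eff <- catalytic_efficiency(tab$Km_uM, tab$kcat_s, rounded = TRUE)
  exact <- tab$substrate != "GlcNAc3"
  expect_equal(eff[exact], tab$kcat_over_Km_printed[exact])
  # the trimer row disagrees with plain rounding by one integer unit
  expect_lte(abs(eff[!exact] - tab$kcat_over_Km_printed[!exact]), 1)
  # spot values
  expect_equal(catalytic_efficiency(77, 0.38, rounded = TRUE), 4935)
  expect_equal(catalytic_efficiency(172, 0.08, rounded = TRUE), 465)
  expect_equal(catalytic_efficiency(179, 0.01, rounded = TRUE), 56)
})

test_that("fold ratios between efficiencies match the reported comparisons", {
  e_nag2 <- catalytic_efficiency(77, 0.38)    # pNP-GlcNAc, VhNag2
  e_nag1 <- catalytic_efficiency(172, 0.08)   # pNP-GlcNAc, VhNag1
  e_dimer <- catalytic_efficiency(179, 0.01)  # GlcNAc2
  e_tetramer <- catalytic_efficiency(329, 0.10)
  expect_equal(efficiency_ratio(e_nag2, e_nag1), 11)
  expect_equal(efficiency_ratio(e_nag2, e_dimer), 88)
  expect_equal(efficiency_ratio(e_nag2, e_tetramer), 16)
  expect_equal(efficiency_ratio(3, 2, rounded = FALSE), 1.5)
  expect_error(efficiency_ratio(1, 0), class = "chitokin_invalid_parameter")
})

test_that("half-integers round away from zero, matching the report convention", {
  expect_equal(catalytic_efficiency(2, 1e-6 * 2 * 10.5, rounded = TRUE), 11)
  expect_equal(efficiency_ratio(21, 2), 11)       # 10.5 -> 11
  expect_equal(efficiency_ratio(-21, 2), -11)     # -10.5 -> -11
})

test_that("degenerate initial-rate designs raise typed errors", {
  expect_error(fit_michaelis_menten(tibble::tibble(x = 1)),
               class = "chitokin_invalid_input")
  expect_error(
    fit_michaelis_menten(tibble::tibble(substrate_uM = c(50, 100), rate = c(0, 0))),
    class = "chitokin_unidentifiable_fit")
  expect_error(
    fit_michaelis_menten(tibble::tibble(substrate_uM = c(100, 100),
                                        rate = c(0.1, 0.1))),
    class = "chitokin_unidentifiable_fit")
  expect_error(
    fit_michaelis_menten(tibble::tibble(substrate_uM = c(-5, 100),
                                        rate = c(0.1, 0.2))),
    class = "chitokin_invalid_input")
})

test_that("tidy and glance summarise a Michaelis-Menten fit", {
  d <- generate_initial_rates(77, 0.38, noise = noise_model(cv = 0.02, seed = 9))
  fit <- fit_michaelis_menten(d)
  td <- tidy(fit)
  expect_equal(td$term, c("Km_uM", "kcat_s"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$n, 6)
  expect_equal(gl$Km_uM, fit$Km_uM)
})
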