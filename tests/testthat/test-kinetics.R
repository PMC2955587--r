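test_that("binding equilibrium is exact in the trivial and single-mode cases", {
  sys <- kinetic_system()

  eq0 <- solve_binding_equilibrium(sys, numeric(6))
  expect_equal(eq0$free_enzyme_M, 38e-6)
  expect_equal(sum(eq0$complexes$conc_M), 0)

  # single-mode system: one-subsite cleft, monomer ligand; compare against the
  # closed-form root of the binding quadratic K C^2 - (K E0 + K S0 + 1) C + K E0 S0 = 0
  dG <- -4
  one <- kinetic_system(cleft = subsite_cleft(1L, dG),
                        rates = rate_constants(k_plus1 = c(`2` = 0)),
                        enzyme_total_uM = 38, max_chain = 2)
  m <- enumerate_binding_modes(1, one$cleft)
  expect_equal(nrow(m), 1)
  K <- association_constant(dG)
  E0 <- 38e-6; S0 <- 0.5e-3
  b <- E0 + S0 + 1 / K
  C_closed <- (b - sqrt(b^2 - 4 * E0 * S0)) / 2
  eq <- solve_binding_equilibrium(one, c(`1` = S0 * 1e3))
  C_num <- sum(eq$complexes$conc_M[eq$complexes$chain_length == 1])
  expect_equal(C_num, C_closed, tolerance = 1e-10)
  expect_equal(eq$free_enzyme_M + sum(eq$complexes$conc_M), E0, tolerance = 1e-12)
})

test_that("vanishing-enzyme limit reproduces the series expression for occupancy", {
  sys <- kinetic_system(enzyme_total_uM = 1e-6)  # 1 pM: E0 -> 0 limit
  S0 <- 1.25e-3
  eq <- solve_binding_equilibrium(sys, c(`6` = 1.25))
  K6 <- association_constant(
    mode_free_energy(enumerate_binding_modes(6, sys$cleft), sys$cleft))
  expected_frac <- sum(K6) * S0 / (1 + sum(K6) * S0)
  got_frac <- sum(eq$complexes$conc_M[eq$complexes$chain_length == 6]) /
    eq$enzyme_total_M
  expect_equal(got_frac, expected_frac, tolerance = 1e-4)
})

test_that("cleavage fluxes follow k_plus1 times productive occupancy", {
  sys <- kinetic_system()
  eq1 <- solve_binding_equilibrium(sys, c(`1` = 2))
  fl1 <- cleavage_fluxes(eq1, sys$rates)
  expect_equal(sum(fl1$fluxes$flux_M_per_s), 0)   # monomer is terminal
  expect_equal(fl1$monomer_rate_M_per_s, 0)

  zero <- kinetic_system(rates = rate_constants(
    k_plus1 = c(`2` = 0, `3` = 0, `4` = 0, `5` = 0, `6` = 0)))
  fl0 <- cleavage_fluxes(solve_binding_equilibrium(zero, c(`6` = 1.25)), zero$rates)
  expect_equal(sum(fl0$fluxes$flux_M_per_s), 0)

  # dimer: one productive mode; cleavage yields two monomers
  eq2 <- solve_binding_equilibrium(sys, c(`2` = 1.25))
  c_prod <- sum(eq2$complexes$conc_M[eq2$complexes$chain_length == 2 &
                                       eq2$complexes$productive])
  fl2 <- cleavage_fluxes(eq2, sys$rates)
  expect_equal(fl2$fluxes$flux_M_per_s[2], 0.01 * c_prod, tolerance = 1e-12)
  expect_equal(fl2$monomer_rate_M_per_s, 0.02 * c_prod, tolerance = 1e-12)
})

test_that("with zero cleavage rates the trajectory is constant", {
  sys <- kinetic_system(rates = rate_constants(
    k_plus1 = c(`2` = 0, `3` = 0, `4` = 0, `5` = 0, `6` = 0)))
  tc <- simulate_time_course(sys, c(`6` = 1.25), c(5, 60, 500))
  expect_equal(tc$glcnac6_mM, rep(1.25, 3), tolerance = 1e-9)
  expect_equal(sum(tc$glcnac1_mM, tc$glcnac2_mM), 0, tolerance = 1e-12)
})

test_that("glycosidic units are conserved along the hexamer trajectory", {
  tc <- hexamer_course_short()
  units <- total_glcnac_units(tc)
  expect_lt(diff(range(units)) / units[1], 1e-6)
  expect_equal(units[1], 6 * 1.25, tolerance = 1e-4)
  expect_true(all(as.matrix(tc[paste0("glcnac", 1:6, "_mM")]) >= 0))
})

test_that("initial-rate ordering across substrates matches the exo-cleft model", {
  sys <- kinetic_system()
  v <- vapply(2:6, function(n) initial_hydrolysis_rate(sys, n, 1.25), numeric(1))
  names(v) <- 2:6
  # tetramer ~ trimer fastest, then pentamer, hexamer, dimer slowest
  expect_equal(unname(v["4"] / v["3"]), 1, tolerance = 0.1)
  expect_gt(v["3"], v["5"])
  expect_gt(v["5"], v["6"])
  expect_gt(v["6"], v["2"])
  expect_equal(initial_hydrolysis_rate(sys, 1, 1.25), 0)
  expect_equal(initial_hydrolysis_rate(sys, 4, 0), 0)
})

test_that("initial rate is homogeneous in enzyme concentration when binding is weak", {
  # in the dilute-enzyme regime doubling E0 doubles the rate
  s1 <- kinetic_system(enzyme_total_uM = 0.01)
  s2 <- kinetic_system(enzyme_total_uM = 0.02)
  v1 <- initial_hydrolysis_rate(s1, 4, 1.25)
  v2 <- initial_hydrolysis_rate(s2, 4, 1.25)
  expect_equal(v2 / v1, 2, tolerance = 1e-6)
})

test_that("numeric dimer initial rate matches the analytic rapid-equilibrium rate", {
  sys <- kinetic_system(enzyme_total_uM = 0.001)  # 1 nM << S0 and << K_d
  S0 <- 0.05e-3  # 0.05 mM
  m2 <- enumerate_binding_modes(2, sys$cleft)
  K2 <- association_constant(mode_free_energy(m2, sys$cleft))
  K_prod <- sum(K2[m2$productive])
  v_analytic <- 0.01 * 1e-9 * K_prod * S0 / (1 + sum(K2) * S0)

  v_eq <- initial_hydrolysis_rate(sys, 2, S0 * 1e3)
  expect_equal(v_eq, v_analytic, tolerance = 0.01)

  # and the integrator sees the same slope over a short window
  tc <- simulate_time_course(sys, c(`2` = S0 * 1e3), c(0.05, 0.1))
  slope <- (S0 * 1e3 - tc$glcnac2_mM[1]) / (0.05 * 60) * 1e-3
  expect_equal(slope, v_analytic, tolerance = 0.01)
})

test_that("all material converges to monomer, the unique absorbing species", {
  sys <- kinetic_system()
  tc <- simulate_time_course(sys, c(`3` = 0.2), c(1000, 4000),
                             scheme = "collapsed")
  units <- 0.2 * 3
  expect_gt(tail(tc$glcnac1_mM, 1), 0.995 * units)
  expect_lt(tail(tc$glcnac3_mM, 1), 1e-4)
})

test_that("explicit-intermediate and collapsed schemes agree closely", {
  tc_e <- hexamer_course_short()
  tc_c <- simulate_time_course(kinetic_system(), c(`6` = 1.25),
                               tc_e$time_min, scheme = "collapsed")
  sp <- paste0("glcnac", 1:6, "_mM")
  a <- as.matrix(tc_e[sp]); b <- as.matrix(tc_c[sp])
  mask <- a > 1e-3
  expect_lt(max(abs(a - b)[mask] / a[mask]), 0.005)
  expect_lt(max(abs(a - b)), 0.005 * 1.25)
})

test_that("tightening the integrator tolerance tenfold leaves concentrations unchanged", {
  sys <- kinetic_system()
  t1 <- simulate_time_course(sys, c(`6` = 1.25), c(15, 60, 180))
  t2 <- simulate_time_course(sys, c(`6` = 1.25), c(15, 60, 180),
                             rtol = 1e-9, atol_mM = 1e-11)
  sp <- paste0("glcnac", 1:6, "_mM")
  expect_lt(max(abs(as.matrix(t1[sp]) - as.matrix(t2[sp]))), 1e-4)
})

test_that("invalid simulation inputs are rejected", {
  sys <- kinetic_system()
  expect_error(simulate_time_course(sys, c(`6` = -1), c(5, 10)),
               class = "chitokin_invalid_input")
  expect_error(simulate_time_course(sys, c(`6` = 1), c(10, 5)),
               class = "chitokin_invalid_input")
  expect_error(simulate_time_course(sys, c(`9` = 1), c(5, 10)),
               class = "chitokin_invalid_input")
})
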