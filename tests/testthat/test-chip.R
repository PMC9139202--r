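# Parallel-plate chip algebra and site-to-operating-point mapping.

test_that("shear rate and stress follow gamma = 6Q/h^2 w and tau = gamma mu", {
  chip <- chip_spec()
  expect_equal(shear_rate_from_flow(0, chip), 0)
  expect_equal(shear_rate_from_flow(4.33e-9, chip),
               6 * 4.33e-9 / (1e-4^2 * 1.2e-3))
  expect_equal(signif(shear_rate_from_flow(4.33e-9, chip), 4), 2165)
  # halving h quadruples gamma
  chip2 <- chip_spec(height = 0.5e-4)
  expect_equal(shear_rate_from_flow(1e-9, chip2),
               4 * shear_rate_from_flow(1e-9, chip))
  expect_equal(shear_stress_from_flow(0, chip), 0)
  expect_equal(signif(shear_stress_from_flow(4.33e-9, chip), 2), 1.5)
  expect_error(shear_rate_from_flow(-1e-9, chip), class = "aneuflow_domain_error")
})

test_that("the published low-flow pair is flagged as internally inconsistent", {
  chip <- chip_spec()
  # the formula gives 0.30 Pa at 8.67e-10 m^3/s, 10x the stated 0.03 Pa
  expect_equal(signif(shear_stress_from_flow(8.67e-10, chip), 2), 0.30)
  expect_warning(check_operating_pair(0.03, 8.67e-10, chip), "factor 10")
  # the self-consistent pair passes silently
  expect_silent(check_operating_pair(1.5, flow_for_target_shear(1.5, chip),
                                     chip))
})

test_that("tau <-> Q round trips are exact and monotone", {
  chip <- chip_spec()
  for (tau in c(0.01, 0.1, 1, 10)) {
    expect_equal(shear_stress_from_flow(flow_for_target_shear(tau, chip),
                                        chip), tau, tolerance = 1e-15)
  }
  expect_equal(flow_for_target_shear(1.5, chip), 4.2857e-9,
               tolerance = 1e-4)
  expect_equal(flow_for_target_shear(0, chip), 0)
  taus <- c(0.01, 0.1, 1, 10)
  expect_true(all(diff(sapply(taus, flow_for_target_shear, chip = chip)) > 0))
  # dimensional homogeneity: scaling (h, w) by c scales Q by c^3 at fixed tau
  chip_c <- chip_spec(height = 2e-4, width = 2.4e-3)
  expect_equal(flow_for_target_shear(1.5, chip_c),
               8 * flow_for_target_shear(1.5, chip))
})

test_that("operating points carry exact algebraic consistency and warnings", {
  chip <- chip_spec()
  for (tau in c(0.03, 1.5, 10)) {
    pt <- operating_point(tau, chip)
    # exact up to one floating-point division
    expect_equal(pt$tau / pt$gamma, chip$viscosity, tolerance = 1e-14)
    expect_identical(pt$gamma * chip$height^2 * chip$width / 6, pt$Q)
    expect_equal(pt$Q_uL_min, pt$Q * 6e10)
    expect_lt(pt$reynolds_chip, 2000)
    expect_length(pt$warnings, 0L)
  }
  # square channel violates the wide-shallow assumption
  sq <- chip_spec(height = 1.2e-3, width = 1.2e-3)
  expect_match(operating_point(1, sq)$warnings, "aspect ratio", all = FALSE)
  expect_error(chip_spec(height = 2e-3, width = 1e-3),
               class = "aneuflow_domain_error")
})

test_that("map_sites converts dimensional sites and rejects nondimensional ones", {
  mk_site <- function(tau_pa) list(centroid = c(x = 0, y = 0), n_faces = 5L,
                                   tau_median = tau_pa / 0.17,
                                   tau_mean = tau_pa / 0.17,
                                   tau_median_Pa = tau_pa, tau_mean_Pa = tau_pa)
  sites <- structure(list(low_sites = list(mk_site(0.03)),
                          high_sites = list(mk_site(1.5))),
                     class = "shear_sites")
  mapped <- map_sites(sites)
  tab <- operating_table(mapped)
  expect_identical(nrow(tab), 2L)
  expect_equal(shear_stress_from_flow(tab$Q_m3_per_s, chip_spec()),
               tab$tau_Pa)
  bare <- structure(list(low_sites = list(list(centroid = c(0, 0),
                                               n_faces = 3L,
                                               tau_median = 1)),
                         high_sites = list()), class = "shear_sites")
  expect_error(map_sites(bare), class = "aneuflow_usage_error")
})

test_that("a solver run through the chip cross-section reproduces the target stress", {
  tau_solver <- chip_crosscheck_tau(1.5)
  expect_lt(abs(tau_solver / 1.5 - 1), 0.10)
})
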