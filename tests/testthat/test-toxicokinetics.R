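toy_tk <- function(mw = 100, fub = 0.5, clint = 10)
  list(analyte_id = "toy", molecular_weight = mw, fraction_unbound = fub,
       intrinsic_clearance = clint)

test_that("measured equivalent dose follows the ingestion-rate conversion", {
  expect_identical(compute_med(1), 2e-4)
  expect_identical(compute_med(0), 0)
  expect_identical(compute_med(50), 0.01)
  expect_error(compute_med(-1), ">= 0")
})

test_that("steady-state Css matches its closed-form limits", {
  phys <- default_physiology()

  # CLint = 0: clearance is renal only, Css = dose_rate / (GFR * fup)
  tk0 <- toy_tk(clint = 0)
  css <- css_steady_state(tk0, phys)
  dose_rate <- 1 * phys$body_weight / 24
  expected <- dose_rate / (phys$glomerular_filtration_rate * 0.5) / 100 * 1000
  expect_equal(css, expected, tolerance = 1e-9)

  # CLint -> Inf with fup = 1: flow-limited, Css = dose_rate / (GFR + Q)
  tk_inf <- toy_tk(fub = 1, clint = 1e12)
  css_inf <- css_steady_state(tk_inf, phys)
  expected_inf <- dose_rate /
    (phys$glomerular_filtration_rate + phys$liver_blood_flow) / 100 * 1000
  expect_equal(css_inf, expected_inf, tolerance = 1e-6)
  expect_equal(css_steady_state(toy_tk(fub = 1, clint = Inf), phys),
               expected_inf, tolerance = 1e-9)

  # fixed toy parameters against the pre-computed closed-form value:
  # MW 100, fup 0.5, whole-liver CLint 1 L/h, Q 90, GFR 6.7, BW 70, dose 1
  clint_per_cell <- 1 / (phys$hepatocellularity * phys$liver_mass * 60e-6)
  css_toy <- css_steady_state(toy_tk(clint = clint_per_cell), phys)
  expect_equal(css_toy, 7.581197194897202, tolerance = 1e-12)

  # all-zero clearance is an explicit failure, not a silent Inf
  phys0 <- phys; phys0$glomerular_filtration_rate <- 0
  expect_error(css_steady_state(toy_tk(clint = 0), phys0),
               "clearance is zero")
})

test_that("Css is monotone in GFR and linear in dose", {
  tk <- toy_tk()
  phys <- default_physiology()
  gfrs <- c(2, 5, 10, 20)
  css <- vapply(gfrs, function(g) {
    p <- phys; p$glomerular_filtration_rate <- g
    css_steady_state(tk, p)
  }, numeric(1))
  expect_true(all(diff(css) < 0))
  expect_equal(css_steady_state(tk, phys, dose = 3),
               3 * css_steady_state(tk, phys, dose = 1), tolerance = 1e-12)
})

test_that("Monte Carlo Css95 degenerates, is seed-deterministic, converges", {
  tk <- toy_tk()
  # zero CVs: identical to the deterministic value
  v0 <- variability_spec(cv = 0, n_draws = 50, seed = 4)
  expect_equal(css95_monte_carlo(tk, var = v0), css_steady_state(tk),
               tolerance = 1e-12)

  v <- variability_spec(cv = 0.3, n_draws = 2000, seed = 10)
  a <- css95_monte_carlo(tk, var = v)
  b <- css95_monte_carlo(tk, var = v)
  expect_identical(a, b)
  expect_false(identical(a, css95_monte_carlo(
    tk, var = variability_spec(cv = 0.3, n_draws = 2000, seed = 11))))

  # right-skewed variation puts the 95th percentile above the center
  expect_gt(a, css_steady_state(tk))

  # large-n convergence of the quantile
  big1 <- css95_monte_carlo(tk, var = variability_spec(0.3, 10000, seed = 1))
  big2 <- css95_monte_carlo(tk, var = variability_spec(0.3, 50000, seed = 2))
  expect_lt(abs(big1 - big2) / big2, 0.05)
})

test_that("AED95 arithmetic and the 5th-percentile chemical floor", {
  expect_equal(aed95_per_endpoint(2, 2), 1)
  expect_equal(aed95_per_endpoint(2, 4), 0.5)
  expect_error(aed95_per_endpoint(-1, 2), "> 0")

  set.seed(3)
  acc <- rlnorm(6); css <- rlnorm(6)
  got <- aed95_per_endpoint(acc, css)
  for (i in 1:6) expect_equal(got[i], acc[i] / css[i])

  # AED95 decreases as Css95 increases
  expect_true(all(diff(aed95_per_endpoint(2, c(1, 2, 4, 8))) < 0))

  expect_equal(chemical_aed_floor(3.2), 3.2)
  expect_equal(chemical_aed_floor(rep(7, 5)), 7)
  expect_equal(chemical_aed_floor(1:100), 5.95)  # linear interpolation
  expect_error(chemical_aed_floor(numeric(0)), "coverage")
})

test_that("per-sample EAR_MED equals the brute-force oracle", {
  set.seed(91)
  cat_ <- tiny_catalog()
  n_chem <- 3
  det <- rbind(
    tiny_detection("w1", "atrz", rlnorm(1)),
    tiny_detection("w1", "335-67-1", rlnorm(1)),
    tiny_detection("w1", "1763-23-1", rlnorm(1)),
    tiny_detection("w2", "atrz", rlnorm(1)))
  ds <- dw_dataset(det, cat_)
  floors <- data.frame(analyte_id = c("atrz", "335-67-1", "1763-23-1"),
                       css95_uM = 1, aed_floor = c(0.1, 0.02, 5),
                       n_endpoints = 2L, stringsAsFactors = FALSE)
  got <- summarize_sample_ear_med(ds, floors)
  for (sid in c("w1", "w2")) {
    rows <- det[det$sample_id == sid, ]
    brute <- 0
    for (i in seq_len(nrow(rows))) {
      med <- rows$concentration[i] * 0.2 * 0.001
      em <- med / floors$aed_floor[match(rows$analyte_id[i],
                                         floors$analyte_id)]
      if (em >= 1e-5) brute <- brute + em
    }
    expect_equal(got$per_sample$sum_ear_med[got$per_sample$sample_id == sid],
                 brute, tolerance = 1e-12)
  }
  expect_equal(got$per_chemical$ear_med,
               got$per_chemical$med / got$per_chemical$aed_floor)
  # med 2e-4 with floor 0.1 -> 2e-3, over the 0.001 screening level
  one <- summarize_sample_ear_med(
    dw_dataset(tiny_detection("w9", "atrz", 1), cat_), floors)
  expect_equal(one$per_sample$sum_ear_med, 0.002)
  expect_true(one$per_sample$exceeds_0p001)
})

test_that("EAR_MED is invariant to the unit path", {
  # direct dimensional route: C (ug/L) -> dose; ACC (uM) -> dose via Css95;
  # ratio must match the packaged MED / AED composition to 1e-12 relative.
  tk <- toy_tk(mw = 215.7, fub = 0.3, clint = 25)
  css95 <- css95_monte_carlo(tk, var = variability_spec(0.2, 500, seed = 6))
  acc_uM <- 1.8
  conc <- 0.37
  aed <- aed95_per_endpoint(acc_uM, css95)
  packaged <- compute_med(conc) / chemical_aed_floor(aed)
  direct <- (conc * 0.2e-3) * css95 / acc_uM
  expect_equal(packaged, direct, tolerance = 1e-12)
})

test_that("AED floors skip chemicals without usable TK information", {
  cat_ <- tiny_catalog()
  acc <- rbind(
    data.frame(analyte_id = "atrz", endpoint_id = c("e1", "e2"),
               acc_uM = c(1, 4), acc_ugL = NA_real_,
               flag_nonspecific = FALSE, flag_baseline = FALSE,
               flag_unreliable = FALSE, stringsAsFactors = FALSE),
    data.frame(analyte_id = "335-67-1", endpoint_id = "e1", acc_uM = 2,
               acc_ugL = NA_real_, flag_nonspecific = FALSE,
               flag_baseline = FALSE, flag_unreliable = FALSE,
               stringsAsFactors = FALSE))
  tk <- data.frame(analyte_id = "atrz", molecular_weight = 215.7,
                   fraction_unbound = 0.3, intrinsic_clearance = 25,
                   stringsAsFactors = FALSE)
  out <- compute_aed_floors(acc, tk, cat_,
                            var = variability_spec(0.3, 200, seed = 2))
  expect_equal(out$floors$analyte_id, "atrz")
  expect_equal(attr(out, "uncovered"), "335-67-1")
  expect_equal(nrow(out$aed), 2)
  expect_equal(out$floors$aed_floor,
               chemical_aed_floor(out$aed$aed95))
})
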