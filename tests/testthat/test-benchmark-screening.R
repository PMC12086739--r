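test_that("resolve_benchmark picks the minimum and breaks ties by priority", {
  cand <- data.frame(analyte_id = "x",
                     benchmark_type = c("WHO", "STATE", "DWHA"),
                     value = c(0.5, 0.1, 0.3), stringsAsFactors = FALSE)
  rb <- resolve_benchmark("x", cand)
  expect_equal(rb$effective_value, 0.1)
  expect_equal(rb$source_type, "STATE")
  expect_false(rb$substitution_applied)

  # minimality: effective value <= every positive candidate
  set.seed(42)
  for (i in 1:20) {
    vals <- round(rlnorm(5, 0, 2), 4)
    cand <- data.frame(analyte_id = "x",
                       benchmark_type = sample(c("MCL", "DWHA", "WHO",
                                                 "STATE", "HBSL"), 5,
                                               replace = TRUE),
                       value = vals, stringsAsFactors = FALSE)
    expect_equal(resolve_benchmark("x", cand)$effective_value, min(vals))
  }

  # equal minima resolve by fixed type order (DWHA before WHO)
  tie <- data.frame(analyte_id = "x",
                    benchmark_type = c("WHO", "DWHA"), value = c(1, 1),
                    stringsAsFactors = FALSE)
  expect_equal(resolve_benchmark("x", tie)$source_type, "DWHA")

  expect_error(resolve_benchmark("x", tie[0, ]), "no benchmark")
})

test_that("zero-MCLG substitution applies class and per-analyte rules", {
  rules <- default_substitution_rules()
  as_cand <- data.frame(analyte_id = "7440-38-2",
                        benchmark_type = c("MCLG", "MCL"), value = c(0, 10),
                        stringsAsFactors = FALSE)
  rb <- resolve_benchmark("7440-38-2", as_cand, rules, "inorganic")
  expect_equal(rb$effective_value, 0.1)
  expect_true(rb$substitution_applied)

  pfos <- data.frame(analyte_id = "1763-23-1", benchmark_type = "MCLG",
                     value = 0, stringsAsFactors = FALSE)
  rb <- resolve_benchmark("1763-23-1", pfos, rules, "PFAS")
  expect_equal(rb$effective_value, 0.0001)

  # zero MCLG with no covering rule is a configuration error
  orphan <- data.frame(analyte_id = "mystery", benchmark_type = "MCLG",
                       value = 0, stringsAsFactors = FALSE)
  expect_error(resolve_benchmark("mystery", orphan, rules, "pharmaceutical"),
               "configuration error")
})

test_that("TQ arithmetic follows substituted denominators", {
  cat_ <- tiny_catalog()
  det <- rbind(tiny_detection("w1", "7440-38-2", 1.0),
               tiny_detection("w1", "335-67-1", 0.004))
  ds <- dw_dataset(det, cat_)
  resolved <- resolve_benchmarks(tiny_benchmarks(), cat_)
  tq <- compute_tq(ds, resolved)
  tq_by <- setNames(tq$tq, tq$analyte_id)
  expect_equal(unname(tq_by["7440-38-2"]), 10)   # 1 / 0.1 substituted
  expect_equal(unname(tq_by["335-67-1"]), 40)    # 0.004 / 0.0001 substituted
  expect_true(all(tq$included))
})

test_that("sample TQ summary equals brute-force sums with correct flags", {
  ds <- random_dataset(n_samples = 12, seed = 21)
  resolved <- resolve_benchmarks(tiny_benchmarks(), ds$catalog)
  tq <- compute_tq(ds, resolved)
  summ <- summarize_sample_tq(tq, ds$samples)

  for (sid in summ$sample_id) {
    rows <- tq[tq$sample_id == sid & tq$included, ]
    brute <- 0
    for (i in seq_len(nrow(rows))) brute <- brute + rows$tq[i]
    expect_equal(summ$sum_tq[summ$sample_id == sid], brute,
                 tolerance = 1e-12)
    expect_equal(summ$n_tq_over_1[summ$sample_id == sid],
                 sum(rows$tq > 1))
  }
  expect_equal(summ$exceeds_0p1, summ$sum_tq > 0.1)
  expect_equal(summ$exceeds_1, summ$sum_tq > 1)
  expect_true(all(summ$exceeds_0p1[summ$exceeds_1]))

  # contribution fractions sum to one wherever sum_tq > 0
  for (i in which(summ$sum_tq > 0)) {
    r <- summ$driver_ranking[[i]]
    expect_equal(sum(r$contribution_fraction), 1, tolerance = 1e-12)
    expect_true(all(diff(r$contribution_fraction) <= 0))
  }

  # no detections -> zero sum, flags off
  empty <- summarize_sample_tq(tq[0, ], ds$samples)
  expect_true(all(empty$sum_tq == 0))
  expect_false(any(empty$exceeds_0p1))
})

test_that("cumulative TQ is additive, monotone, and scales linearly", {
  ds <- random_dataset(n_samples = 8, seed = 5)
  resolved <- resolve_benchmarks(tiny_benchmarks(), ds$catalog)
  tq <- compute_tq(ds, resolved)
  base <- summarize_sample_tq(tq, ds$samples)

  # scaling all concentrations by k scales sum_tq by k
  k <- 3.7
  ds_k <- ds
  ds_k$detections$concentration <- ds_k$detections$concentration * k
  tq_k <- compute_tq(ds_k, resolved)
  # use the same inclusion set so the comparison is purely about linearity
  tq_k$included <- tq$included
  summ_k <- summarize_sample_tq(tq_k, ds$samples)
  expect_equal(summ_k$sum_tq, base$sum_tq * k, tolerance = 1e-12)

  # adding a detection never decreases sum_tq
  extra <- compute_tq(dw_dataset(tiny_detection("rw01", "7440-38-2", 0.5),
                                 ds$catalog, ds$samples), resolved)
  augmented <- summarize_sample_tq(rbind(tq, extra), ds$samples)
  expect_true(all(augmented$sum_tq >= base$sum_tq))

  # lower effective benchmark => weakly greater sum_tq
  resolved_low <- resolved
  resolved_low$effective_value <- resolved_low$effective_value / 2
  summ_low <- summarize_sample_tq(compute_tq(ds, resolved_low), ds$samples)
  expect_true(all(summ_low$sum_tq >= base$sum_tq))
})

test_that("individual exceedance uses strict inequality and zero-MCLG rule", {
  cat_ <- tiny_catalog()
  det <- rbind(
    tiny_detection("w1", "7440-38-2", 10),    # equal to MCL: not exceeding
    tiny_detection("w2", "7440-38-2", 10.1),  # above MCL
    tiny_detection("w3", "7440-38-2", 0.05),  # any detection > MCLG zero
    tiny_detection("w4", "atrz", 2.5),        # above HHBP 2, below MCL 3
    tiny_detection("w5", "atrz", 1.0))        # below both
  ds <- dw_dataset(det, cat_)
  reg <- tiny_benchmarks()
  tab <- individual_exceedance_table(ds, reg)

  mcl <- tab[tab$benchmark_type == "MCL" & tab$analyte_id == "7440-38-2", ]
  expect_equal(mcl$exceeds[mcl$sample_id == "w1"], FALSE)
  expect_equal(mcl$exceeds[mcl$sample_id == "w2"], TRUE)
  mclg <- tab[tab$benchmark_type == "MCLG" & tab$analyte_id == "7440-38-2", ]
  expect_true(all(mclg$exceeds))

  # hand enumeration: per benchmark row, count exceedances
  atrz <- tab[tab$analyte_id == "atrz", ]
  expect_equal(sum(atrz$exceeds), 1)  # only w4 vs HHBP 2
})

test_that("coverage counts detected analytes with and without benchmarks", {
  ds <- tiny_dataset()  # detected: As, atrazine, PFOA, bdcm
  resolved <- resolve_benchmarks(tiny_benchmarks(), ds$catalog)
  cov <- benchmark_coverage(ds, resolved)
  expect_equal(sum(cov$n_detected_analytes), 4)
  expect_equal(sum(cov$n_with_benchmark), 4)
  # drop the PFOA benchmark: coverage gap appears
  bm <- tiny_benchmarks()
  resolved2 <- resolve_benchmarks(bm[bm$analyte_id != "335-67-1", ],
                                  ds$catalog)
  cov2 <- benchmark_coverage(ds, resolved2)
  expect_equal(sum(cov2$n_with_benchmark), 3)
})
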