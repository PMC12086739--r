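# Small in-code fixtures shared across test files.

tiny_catalog <- function() {
  data.frame(
    analyte_id = c("7440-38-2", "1763-23-1", "335-67-1", "atrz", "bdcm",
                   "HPC"),
    analyte_name = c("arsenic", "PFOS", "PFOA", "atrazine",
                     "bromodichloromethane", "plate count"),
    analyte_class = c("inorganic", "PFAS", "PFAS", "pesticide", "DBP",
                      "microbial"),
    core_flag = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    molecular_weight = c(74.92, 500.1, 414.1, 215.7, 163.8, NA),
    stringsAsFactors = FALSE)
}

tiny_detection <- function(sample_id, analyte_id, conc, catalog = tiny_catalog(),
                           supply = "private_tw", detected = TRUE,
                           rl = 0.01, study = "s1") {
  i <- match(analyte_id, catalog$analyte_id)
  data.frame(study_id = study, sample_id = sample_id, supply_class = supply,
             analyte_id = analyte_id, analyte_name = catalog$analyte_name[i],
             analyte_class = catalog$analyte_class[i],
             concentration = conc, reporting_limit = rl, detected = detected,
             stringsAsFactors = FALSE)
}

tiny_dataset <- function() {
  cat_ <- tiny_catalog()
  det <- rbind(
    tiny_detection("w1", "7440-38-2", 1.0),
    tiny_detection("w1", "atrz", 0.5),
    tiny_detection("w1", "1763-23-1", NA, detected = FALSE),
    tiny_detection("w2", "335-67-1", 0.004, supply = "public_tw"),
    tiny_detection("w2", "bdcm", 12, supply = "public_tw"),
    tiny_detection("w3", "7440-38-2", 0.2, supply = "bottled"))
  dw_dataset(det, cat_)
}

tiny_benchmarks <- function() {
  data.frame(
    analyte_id = c("7440-38-2", "7440-38-2", "1763-23-1", "335-67-1",
                   "atrz", "atrz", "bdcm"),
    benchmark_type = c("MCLG", "MCL", "MCLG", "MCLG", "MCL", "HHBP", "MCLG"),
    value = c(0, 10, 0, 0, 3, 2, 0),
    enforceable = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# Random dataset over the tiny catalog, for round-trip and oracle tests.
random_dataset <- function(n_samples = 8, seed = 1) {
  set.seed(seed)
  cat_ <- tiny_catalog()
  chem <- cat_[cat_$analyte_class != "microbial", ]
  rows <- list()
  for (s in seq_len(n_samples)) {
    sid <- sprintf("rw%02d", s)
    sup <- sample(c("private_tw", "public_tw", "bottled"), 1)
    for (a in seq_len(nrow(chem))) {
      detected <- runif(1) < 0.7
      conc <- if (detected) rlnorm(1, 0, 1) else NA_real_
      rows[[length(rows) + 1]] <- tiny_detection(
        sid, chem$analyte_id[a], conc, cat_, supply = sup,
        detected = detected)
    }
  }
  dw_dataset(do.call(rbind, rows), cat_)
}

# Independent brute-force pseudo-F from first principles (double loops),
# used as the PERMANOVA oracle.
brute_force_f <- function(d, groups) {
  n <- length(groups)
  a <- length(unique(groups))
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + d[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      s <- 0
      for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]^2
      ss_within <- ss_within + s / length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  if (ss_within == 0) return(if (ss_among == 0) NaN else Inf)
  (ss_among / (a - 1)) / (ss_within / (n - a))
}
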