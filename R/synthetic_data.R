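# Synthetic exposure-data generator.  Emulates the statistical structure of
# harmonized multi-study point-of-use drinking-water data: supply-specific
# detection frequencies, right-skewed (lognormal) concentrations left-censored
# at analyte-specific reporting limits, mixed inorganic/organic/microbial
# analyte classes, and companion benchmark / ACC / TK tables with realistic
# coverage gaps.  Every numeric rate is synthetic and documented as such;
# ground truth (generating parameters and analytic exceedance probabilities)
# is returned alongside so pipeline recovery can be checked.

#' Construct a simulation scenario
#'
#' @param seed integer seed; the same seed reproduces the dataset byte for
#'   byte.
#' @param catalog analyte catalog data.frame (see [dw_dataset()]).
#' @param samples data.frame `supply_class`, `study_id`, `n_samples` — one
#'   row per supply chain.
#' @param profiles data.frame `supply_class`, `analyte_id`,
#'   `detection_probability` (Bernoulli presence), `log_mean`, `log_sd`
#'   (lognormal concentration parameters, ln ug/L).  Analytes absent from a
#'   supply's profile are assessed there as all-non-detect rows only when
#'   `detection_probability` is 0; omit the row to skip assessment entirely.
#' @param reporting_limits data.frame `analyte_id`, `reporting_limit`
#'   (ug/L); draws below the reporting limit are censored to non-detects.
#'   An optional `study_id` column makes limits study-specific.
#' @param benchmarks benchmark table (as [read_benchmarks()] returns).
#' @param acc ACC endpoint table (as [read_acc()] returns).
#' @param tk TK parameter table (as [read_tk_params()] returns).
#' @return list of class `dw_scenario`.
#' @export
dw_scenario <- function(seed, catalog, samples, profiles, reporting_limits,
                        benchmarks, acc, tk) {
  stopifnot(all(samples$supply_class %in% .SUPPLY_CLASSES),
            all(samples$n_samples >= 0),
            all(profiles$detection_probability >= 0),
            all(profiles$detection_probability <= 1),
            all(profiles$log_sd > 0),
            all(reporting_limits$reporting_limit > 0))
  missing_rl <- setdiff(unique(profiles$analyte_id),
                        reporting_limits$analyte_id)
  if (length(missing_rl))
    stop("profiles reference analyte(s) without a reporting limit: ",
         paste(missing_rl, collapse = ", "))
  missing_cat <- setdiff(unique(profiles$analyte_id), catalog$analyte_id)
  if (length(missing_cat))
    stop("profiles reference analyte(s) absent from catalog: ",
         paste(missing_cat, collapse = ", "))
  structure(list(seed = as.integer(seed), catalog = catalog,
                 samples = samples, profiles = profiles,
                 reporting_limits = reporting_limits,
                 benchmarks = benchmarks, acc = acc, tk = tk),
            class = "dw_scenario")
}

#' @export
print.dw_scenario <- function(x, ...) {
  cat("<dw_scenario> seed", x$seed, "\n")
  cat("  supplies:", paste(paste0(x$samples$supply_class, " (n = ",
                                  x$samples$n_samples, ")"),
                           collapse = ", "), "\n")
  cat("  analytes:", nrow(x$catalog), "| profiled:",
      length(unique(x$profiles$analyte_id)), "\n")
  cat("  benchmarks:", nrow(x$benchmarks), "rows | ACC:", nrow(x$acc),
      "rows | TK:", nrow(x$tk), "rows\n")
  invisible(x)
}

.rl_lookup <- function(reporting_limits, analyte_id, study_id) {
  if ("study_id" %in% names(reporting_limits)) {
    hit <- reporting_limits$analyte_id == analyte_id &
      reporting_limits$study_id == study_id
    if (any(hit)) return(reporting_limits$reporting_limit[which(hit)[1]])
    hit <- reporting_limits$analyte_id == analyte_id &
      is.na(reporting_limits$study_id)
    if (any(hit)) return(reporting_limits$reporting_limit[which(hit)[1]])
    stop("no reporting limit for analyte ", analyte_id)
  }
  reporting_limits$reporting_limit[
    match(analyte_id, reporting_limits$analyte_id)]
}

#' Generate a synthetic exposure dataset from a scenario
#'
#' For every sample x profiled analyte, presence is drawn
#' Bernoulli(detection_probability); present concentrations are drawn
#' lognormal(log_mean, log_sd) and left-censored at the analyte's reporting
#' limit (draws below it become non-detects).  Non-detect rows are retained
#' with `detected = FALSE` and `NA` concentration so coverage counts are
#' exact.  Ground truth records the generating parameters, the effective
#' (post-substitution) benchmark where one exists, and the analytic
#' probabilities P(detect) = p (1 - F(RL)) and
#' P(TQ > 1) = p (1 - F(max(benchmark, RL))) under the lognormal CDF F.
#'
#' @param cfg a [dw_scenario()].
#' @param seed overrides `cfg$seed` when given.
#' @return list: `dataset` (a `dw_dataset`), `benchmarks`, `acc`, `tk`,
#'   `ground_truth` (data.frame per supply x analyte).
#' @export
generate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "dw_scenario"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  abbrev <- c(private_tw = "priv", public_tw = "publ", bottled = "bott")
  roster <- do.call(rbind, lapply(seq_len(nrow(cfg$samples)), function(i) {
    sc <- cfg$samples$supply_class[i]
    n <- cfg$samples$n_samples[i]
    if (n == 0) return(NULL)
    data.frame(sample_id = sprintf("%s_%03d", abbrev[[sc]], seq_len(n)),
               supply_class = sc, study_id = cfg$samples$study_id[i],
               stringsAsFactors = FALSE)
  }))
  rownames(roster) <- NULL

  cat_name <- setNames(cfg$catalog$analyte_name, cfg$catalog$analyte_id)
  cat_class <- setNames(cfg$catalog$analyte_class, cfg$catalog$analyte_id)

  det_rows <- list()
  for (i in seq_len(nrow(cfg$samples))) {
    sc <- cfg$samples$supply_class[i]
    study <- cfg$samples$study_id[i]
    ids <- roster$sample_id[roster$supply_class == sc]
    n <- length(ids)
    if (n == 0) next
    prof <- cfg$profiles[cfg$profiles$supply_class == sc, , drop = FALSE]
    for (j in seq_len(nrow(prof))) {
      aid <- prof$analyte_id[j]
      rl <- .rl_lookup(cfg$reporting_limits, aid, study)
      present <- rbinom(n, 1, prof$detection_probability[j]) == 1
      conc <- rep(NA_real_, n)
      conc[present] <- rlnorm(sum(present), prof$log_mean[j], prof$log_sd[j])
      detected <- present & !is.na(conc) & conc >= rl
      conc[!detected] <- NA_real_
      det_rows[[length(det_rows) + 1L]] <- data.frame(
        study_id = study, sample_id = ids, supply_class = sc,
        analyte_id = aid, analyte_name = unname(cat_name[aid]),
        analyte_class = unname(cat_class[aid]),
        concentration = conc, reporting_limit = rl, detected = detected,
        stringsAsFactors = FALSE)
    }
  }
  detections <- do.call(rbind, det_rows)
  rownames(detections) <- NULL
  ds <- dw_dataset(detections, cfg$catalog, roster)

  resolved <- if (nrow(cfg$benchmarks))
    resolve_benchmarks(cfg$benchmarks, cfg$catalog) else
      data.frame(analyte_id = character(0), effective_value = numeric(0))
  eff <- setNames(resolved$effective_value, resolved$analyte_id)
  gt <- cfg$profiles
  gt$reporting_limit <- vapply(seq_len(nrow(gt)), function(k)
    .rl_lookup(cfg$reporting_limits, gt$analyte_id[k],
               cfg$samples$study_id[match(gt$supply_class[k],
                                          cfg$samples$supply_class)]),
    numeric(1))
  gt$effective_benchmark <- unname(eff[gt$analyte_id])
  gt$p_detect <- gt$detection_probability *
    (1 - plnorm(gt$reporting_limit, gt$log_mean, gt$log_sd))
  gt$p_tq_over_1 <- ifelse(
    is.na(gt$effective_benchmark), NA_real_,
    gt$detection_probability *
      (1 - plnorm(pmax(gt$effective_benchmark, gt$reporting_limit),
                  gt$log_mean, gt$log_sd)))

  list(dataset = ds, benchmarks = cfg$benchmarks, acc = cfg$acc, tk = cfg$tk,
       ground_truth = gt)
}

#' Packaged three-supply scenario at the harmonized study sizes
#'
#' A default scenario with 98 private-tapwater, 126 public-tapwater, and 30
#' bottled-water samples and a 21-analyte core catalog spanning geogenic
#' inorganics (enriched in private tapwater and groundwater-sourced bottled
#' water), disinfection byproducts (concentrated in public tapwater and
#' purified-tapwater-style bottled samples), volatile organics, a
#' tapwater-only PFAS class, pesticides, pharmaceuticals, and a pass-through
#' microbial indicator.  The qualitative supply structure follows the
#' observed contrasts between supply chains; every numeric rate
#' (detection probabilities, lognormal parameters, benchmark and assay
#' values) is synthetic.  Deliberate coverage gaps are built in: analytes
#' without benchmarks, organics without ACC endpoints, chemicals without TK
#' parameters, flagged assay endpoints, and one non-core analyte.
#'
#' @param seed integer seed stored in the scenario (default 421).
#' @return a `dw_scenario`.
#' @export
three_supply_scenario <- function(seed = 421) {
  catalog <- data.frame(
    analyte_id = c("7440-38-2", "7439-92-1", "7440-61-1", "7439-96-5",
                   "14797-55-8",
                   "75-27-4", "75-25-2", "67-66-3",
                   "127-18-4", "79-01-6", "71-43-2",
                   "1763-23-1", "335-67-1", "307-24-4",
                   "1912-24-9", "94-75-7", "25057-89-0",
                   "298-46-4", "71-36-3", "95-47-6",
                   "58-08-2", "HPC"),
    analyte_name = c("arsenic", "lead", "uranium", "manganese", "nitrate-N",
                     "bromodichloromethane", "tribromomethane",
                     "trichloromethane",
                     "tetrachloroethene", "trichloroethene", "benzene",
                     "PFOS", "PFOA", "PFHxA",
                     "atrazine", "2,4-D", "bentazone",
                     "carbamazepine", "1-butanol", "o-xylene",
                     "caffeine", "heterotrophic plate count"),
    analyte_class = c(rep("inorganic", 5), rep("DBP", 3), rep("VOC", 3),
                      rep("PFAS", 3), rep("pesticide", 3),
                      "pharmaceutical", "other_organic", "other_organic",
                      "pharmaceutical", "microbial"),
    core_flag = c(rep(TRUE, 20), FALSE, TRUE),
    molecular_weight = c(74.92, 207.2, 238.0, 54.94, 62.0,
                         163.8, 252.7, 119.4,
                         165.8, 131.4, 78.1,
                         500.1, 414.1, 314.1,
                         215.7, 221.0, 240.3,
                         236.3, 74.1, 106.2,
                         194.2, NA),
    stringsAsFactors = FALSE)

  samples <- data.frame(
    supply_class = c("private_tw", "public_tw", "bottled"),
    study_id = c("synth_private", "synth_public", "synth_bottled"),
    n_samples = c(98L, 126L, 30L),
    stringsAsFactors = FALSE)

  # supply_class, analyte_id, detection_probability, log_mean (ln ug/L),
  # log_sd -- all rates synthetic; structure: geogenic metals in private TW
  # and groundwater-sourced bottled water, DBP in public TW and
  # purified-TW-style bottled samples, PFAS in tapwater only, pesticides
  # mostly rural/private.
  prof <- function(sc, id, p, mu, sd)
    data.frame(supply_class = sc, analyte_id = id, detection_probability = p,
               log_mean = mu, log_sd = sd, stringsAsFactors = FALSE)
  profiles <- rbind(
    # private tapwater
    prof("private_tw", "7440-38-2", 0.22, log(1.2), 1.2),
    prof("private_tw", "7439-92-1", 0.18, log(0.6), 1.1),
    prof("private_tw", "7440-61-1", 0.32, log(1.5), 1.3),
    prof("private_tw", "7439-96-5", 0.60, log(25), 1.5),
    prof("private_tw", "14797-55-8", 0.55, log(1500), 1.2),
    prof("private_tw", "75-27-4", 0.01, log(0.5), 0.8),
    prof("private_tw", "67-66-3", 0.02, log(0.5), 0.8),
    prof("private_tw", "127-18-4", 0.02, log(0.3), 0.8),
    prof("private_tw", "79-01-6", 0.02, log(0.3), 0.8),
    prof("private_tw", "1763-23-1", 0.05, log(0.004), 0.8),
    prof("private_tw", "335-67-1", 0.04, log(0.004), 0.8),
    prof("private_tw", "307-24-4", 0.05, log(0.005), 0.8),
    prof("private_tw", "1912-24-9", 0.30, log(0.06), 1.0),
    prof("private_tw", "94-75-7", 0.20, log(0.04), 1.0),
    prof("private_tw", "25057-89-0", 0.10, log(0.05), 1.0),
    prof("private_tw", "71-36-3", 0.01, log(40), 0.7),
    prof("private_tw", "95-47-6", 0.02, log(0.2), 0.8),
    prof("private_tw", "HPC", 0.50, log(200), 1.8),
    # public tapwater
    prof("public_tw", "7440-38-2", 0.51, log(0.4), 1.0),
    prof("public_tw", "7439-92-1", 0.67, log(0.7), 1.2),
    prof("public_tw", "7440-61-1", 0.50, log(0.3), 1.1),
    prof("public_tw", "7439-96-5", 0.50, log(8), 1.3),
    prof("public_tw", "14797-55-8", 0.40, log(700), 1.0),
    prof("public_tw", "75-27-4", 0.84, log(8), 1.0),
    prof("public_tw", "75-25-2", 0.60, log(3), 1.0),
    prof("public_tw", "67-66-3", 0.80, log(15), 1.0),
    prof("public_tw", "127-18-4", 0.05, log(0.3), 0.8),
    prof("public_tw", "79-01-6", 0.06, log(0.3), 0.8),
    prof("public_tw", "71-43-2", 0.02, log(0.2), 0.8),
    prof("public_tw", "1763-23-1", 0.20, log(0.005), 0.8),
    prof("public_tw", "335-67-1", 0.15, log(0.004), 0.8),
    prof("public_tw", "307-24-4", 0.10, log(0.006), 0.8),
    prof("public_tw", "1912-24-9", 0.10, log(0.04), 1.0),
    prof("public_tw", "94-75-7", 0.15, log(0.03), 1.0),
    prof("public_tw", "25057-89-0", 0.05, log(0.04), 1.0),
    prof("public_tw", "298-46-4", 0.10, log(0.02), 0.9),
    prof("public_tw", "95-47-6", 0.05, log(0.2), 0.8),
    prof("public_tw", "58-08-2", 0.08, log(0.05), 1.0),
    prof("public_tw", "HPC", 0.40, log(80), 1.6),
    # bottled water (77% groundwater-sourced: geogenic metals; 23%
    # purified-TW-style: DBP)
    prof("bottled", "7440-38-2", 0.67, log(1.0), 1.1),
    prof("bottled", "7440-61-1", 0.57, log(1.2), 1.2),
    prof("bottled", "7439-92-1", 0.17, log(0.4), 1.0),
    prof("bottled", "7439-96-5", 0.30, log(5), 1.2),
    prof("bottled", "14797-55-8", 0.20, log(400), 1.0),
    prof("bottled", "75-27-4", 0.27, log(4), 1.0),
    prof("bottled", "75-25-2", 0.20, log(2), 1.0),
    prof("bottled", "67-66-3", 0.40, log(6), 1.0),
    prof("bottled", "127-18-4", 0.10, log(0.3), 0.8),
    prof("bottled", "79-01-6", 0.08, log(0.3), 0.8),
    prof("bottled", "71-43-2", 0.05, log(0.2), 0.8),
    prof("bottled", "71-36-3", 0.10, log(50), 0.7),
    prof("bottled", "95-47-6", 0.03, log(0.2), 0.8),
    prof("bottled", "HPC", 0.60, log(400), 1.8))

  reporting_limits <- data.frame(
    analyte_id = c("7440-38-2", "7439-92-1", "7440-61-1", "7439-96-5",
                   "14797-55-8", "75-27-4", "75-25-2", "67-66-3",
                   "127-18-4", "79-01-6", "71-43-2", "1763-23-1",
                   "335-67-1", "307-24-4", "1912-24-9", "94-75-7",
                   "25057-89-0", "298-46-4", "71-36-3", "95-47-6",
                   "58-08-2", "HPC"),
    reporting_limit = c(0.1, 0.1, 0.05, 1, 40, 0.1, 0.1, 0.2,
                        0.1, 0.1, 0.1, 0.002, 0.002, 0.002, 0.01, 0.01,
                        0.01, 0.005, 2, 0.05, 0.01, 1),
    stringsAsFactors = FALSE)

  bm <- function(id, type, value, enforceable)
    data.frame(analyte_id = id, benchmark_type = type, value = value,
               enforceable = enforceable, stringsAsFactors = FALSE)
  benchmarks <- rbind(
    bm("7440-38-2", "MCLG", 0, FALSE), bm("7440-38-2", "MCL", 10, TRUE),
    bm("7440-38-2", "SOQ", 10, TRUE),
    bm("7439-92-1", "MCLG", 0, FALSE), bm("7439-92-1", "MCL", 15, TRUE),
    bm("7439-92-1", "SOQ", 5, TRUE),
    bm("7440-61-1", "MCLG", 0, FALSE), bm("7440-61-1", "MCL", 30, TRUE),
    bm("7439-96-5", "STATE", 100, FALSE), bm("7439-96-5", "DWHA", 300, FALSE),
    bm("14797-55-8", "MCLG", 10000, FALSE), bm("14797-55-8", "MCL", 10000, TRUE),
    bm("75-27-4", "MCLG", 0, FALSE), bm("75-27-4", "MCL", 80, TRUE),
    bm("75-25-2", "MCLG", 0, FALSE), bm("75-25-2", "MCL", 80, TRUE),
    bm("67-66-3", "DWHA", 70, FALSE), bm("67-66-3", "MCL", 80, TRUE),
    bm("127-18-4", "MCLG", 0, FALSE), bm("127-18-4", "MCL", 5, TRUE),
    bm("79-01-6", "MCLG", 0, FALSE), bm("79-01-6", "MCL", 5, TRUE),
    bm("71-43-2", "MCLG", 0, FALSE), bm("71-43-2", "MCL", 5, TRUE),
    bm("1763-23-1", "MCLG", 0, FALSE), bm("1763-23-1", "MCL", 0.004, TRUE),
    bm("335-67-1", "MCLG", 0, FALSE), bm("335-67-1", "MCL", 0.004, TRUE),
    bm("1912-24-9", "HHBP", 2, FALSE), bm("1912-24-9", "MCL", 3, TRUE),
    bm("94-75-7", "MCL", 70, TRUE), bm("94-75-7", "HHBP", 20, FALSE),
    bm("95-47-6", "DWHA", 10000, FALSE))
  # no benchmark: PFHxA, bentazone, carbamazepine, butanol, caffeine, HPC

  ep <- function(id, endpoint, acc_uM, ns = FALSE, bl = FALSE, ur = FALSE)
    data.frame(analyte_id = id, endpoint_id = endpoint, acc_uM = acc_uM,
               acc_ugL = NA_real_, flag_nonspecific = ns, flag_baseline = bl,
               flag_unreliable = ur, stringsAsFactors = FALSE)
  acc <- rbind(
    ep("75-27-4", "NVS_NR_1", 30), ep("75-27-4", "ATG_TRANS_2", 80),
    ep("75-27-4", "TOX21_lum_3", 15, bl = TRUE),
    ep("75-25-2", "NVS_NR_1", 50), ep("75-25-2", "ATG_TRANS_2", 120),
    ep("67-66-3", "NVS_NR_1", 90), ep("67-66-3", "ACEA_ER_4", 200,
                                      ur = TRUE),
    ep("127-18-4", "NVS_NR_1", 20), ep("127-18-4", "ATG_TRANS_2", 60),
    ep("79-01-6", "NVS_NR_1", 25), ep("79-01-6", "TOX21_lum_3", 10,
                                      ns = TRUE),
    ep("71-43-2", "NVS_NR_1", 40),
    ep("1763-23-1", "ATG_TRANS_2", 5), ep("1763-23-1", "NVS_NR_1", 12),
    ep("335-67-1", "ATG_TRANS_2", 8), ep("335-67-1", "ACEA_ER_4", 20),
    ep("307-24-4", "ATG_TRANS_2", 0.9), ep("307-24-4", "NVS_NR_1", 3),
    ep("1912-24-9", "NVS_NR_1", 0.8), ep("1912-24-9", "ATG_TRANS_2", 2.5),
    ep("1912-24-9", "ACEA_ER_4", 6, bl = TRUE),
    ep("94-75-7", "NVS_NR_1", 1.5), ep("94-75-7", "ATG_TRANS_2", 5),
    ep("25057-89-0", "NVS_NR_1", 1.2), ep("25057-89-0", "ATG_TRANS_2", 4),
    ep("298-46-4", "NVS_NR_1", 3), ep("298-46-4", "ATG_TRANS_2", 9),
    ep("71-36-3", "TOX21_lum_3", 0.04), ep("71-36-3", "NVS_NR_1", 0.15),
    ep("58-08-2", "NVS_NR_1", 10))
  # no ACC endpoints: o-xylene (organic coverage gap); inorganics never enter

  tkrow <- function(id, mw, fub, clint)
    data.frame(analyte_id = id, molecular_weight = mw, fraction_unbound = fub,
               intrinsic_clearance = clint, stringsAsFactors = FALSE)
  tk <- rbind(
    tkrow("75-27-4", 163.8, 0.35, 12),
    tkrow("75-25-2", 252.7, 0.30, 10),
    tkrow("67-66-3", 119.4, 0.40, 15),
    tkrow("127-18-4", 165.8, 0.10, 8),
    tkrow("79-01-6", 131.4, 0.15, 9),
    tkrow("71-43-2", 78.1, 0.25, 20),
    tkrow("1763-23-1", 500.1, 0.02, 0),
    tkrow("335-67-1", 414.1, 0.03, 0.5),
    tkrow("307-24-4", 314.1, 0.05, 1),
    tkrow("1912-24-9", 215.7, 0.30, 25),
    tkrow("94-75-7", 221.0, 0.10, 5),
    tkrow("25057-89-0", 240.3, 0.20, 6),
    tkrow("71-36-3", 74.1, 0.80, 40),
    tkrow("58-08-2", 194.2, 0.70, 30))
  # no TK information: carbamazepine, o-xylene (TK coverage gap)

  dw_scenario(seed = seed, catalog = catalog, samples = samples,
              profiles = profiles, reporting_limits = reporting_limits,
              benchmarks = benchmarks, acc = acc, tk = tk)
}

#' Single-driver scenario for analytic parameter recovery
#'
#' One analyte, one supply: presence Bernoulli(`detection_probability`),
#' concentration lognormal(`log_mean`, `log_sd`) censored at
#' `reporting_limit`, benchmark `benchmark` (DWHA type).  The fraction of
#' samples with cumulative TQ above 1 then has the closed form
#' p (1 - F(max(benchmark, reporting_limit))) recorded in the ground truth,
#' which the pipeline's observed fraction must recover to within binomial
#' error.
#'
#' @param n_samples number of samples (default 2000).
#' @param detection_probability Bernoulli presence probability.
#' @param log_mean,log_sd lognormal parameters (ln ug/L).
#' @param benchmark benchmark value, ug/L.
#' @param reporting_limit censoring threshold, ug/L.
#' @param seed integer seed.
#' @return a `dw_scenario`.
#' @export
single_driver_scenario <- function(n_samples = 2000,
                                   detection_probability = 0.8,
                                   log_mean = 0, log_sd = 1, benchmark = 1,
                                   reporting_limit = 0.01, seed = 7) {
  catalog <- data.frame(analyte_id = "driver-1", analyte_name = "driver",
                        analyte_class = "other_organic", core_flag = TRUE,
                        molecular_weight = 100, stringsAsFactors = FALSE)
  samples <- data.frame(supply_class = "private_tw", study_id = "synth_sd",
                        n_samples = as.integer(n_samples),
                        stringsAsFactors = FALSE)
  profiles <- data.frame(supply_class = "private_tw", analyte_id = "driver-1",
                         detection_probability = detection_probability,
                         log_mean = log_mean, log_sd = log_sd,
                         stringsAsFactors = FALSE)
  rl <- data.frame(analyte_id = "driver-1",
                   reporting_limit = reporting_limit, stringsAsFactors = FALSE)
  benchmarks <- data.frame(analyte_id = "driver-1", benchmark_type = "DWHA",
                           value = benchmark, enforceable = FALSE,
                           stringsAsFactors = FALSE)
  acc <- data.frame(analyte_id = character(0), endpoint_id = character(0),
                    acc_uM = numeric(0), acc_ugL = numeric(0),
                    flag_nonspecific = logical(0), flag_baseline = logical(0),
                    flag_unreliable = logical(0))
  tk <- data.frame(analyte_id = character(0), molecular_weight = numeric(0),
                   fraction_unbound = numeric(0),
                   intrinsic_clearance = numeric(0))
  dw_scenario(seed = seed, catalog = catalog, samples = samples,
              profiles = profiles, reporting_limits = rl,
              benchmarks = benchmarks, acc = acc, tk = tk)
}
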