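# Reporting layer: group distribution summaries, driver attribution, and the
# end-to-end pipeline orchestrator.

#' Per-group distribution summary of a sample metric
#'
#' Quantiles (linear interpolation, the convention used throughout the
#' package) and threshold-exceedance fractions of one per-sample metric,
#' split by supply class.  Exceedance uses strict `>` at each threshold.
#' Groups with no samples are omitted with a warning.
#'
#' @param summaries per-sample summary data.frame carrying `supply_class`
#'   and the metric column.
#' @param metric column name (e.g. `"sum_tq"`).
#' @param thresholds numeric thresholds for exceedance fractions
#'   (defaults: 0.1 and 1, the hazard-index screening levels; use
#'   `c(0.001, 1)` for the EAR metrics).
#' @return data.frame: `supply_class`, `metric`, `n`, `p5`, `q25`, `median`,
#'   `q75`, `p95`, and one `frac_gt_<threshold>` column per threshold.
#' @export
summarize_groups <- function(summaries, metric, thresholds = c(0.1, 1)) {
  x <- summaries[[metric]]
  if (is.null(x)) stop("metric column not found: ", metric)
  present <- intersect(.SUPPLY_CLASSES, unique(summaries$supply_class))
  rows <- lapply(present, function(sc) {
    v <- x[summaries$supply_class == sc]
    if (length(v) == 0) {
      warning("no samples in group ", sc, "; omitted")
      return(NULL)
    }
    qq <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7)
    row <- data.frame(supply_class = sc, metric = metric, n = length(v),
                      p5 = qq[[1]], q25 = qq[[2]], median = qq[[3]],
                      q75 = qq[[4]], p95 = qq[[5]], stringsAsFactors = FALSE)
    for (t in thresholds)
      row[[paste0("frac_gt_", gsub("\\.", "p", format(t)))]] <- mean(v > t)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Driver attribution report
#'
#' Ranks, per supply class, the analytes by how often they are the largest
#' contributor to a sample's cumulative quotient and by their mean
#' contribution fraction across samples where they contribute.
#'
#' @param quotients per-(sample, chemical) quotient table with columns
#'   `sample_id`, `supply_class`, `analyte_id`, `included`, and the value
#'   column.
#' @param value_col name of the quotient column (`"tq"`, `"ear"`,
#'   `"ear_med"`).
#' @param top_k keep the top k analytes per supply (default 10).
#' @return data.frame: `supply_class`, `analyte_id`,
#'   `n_samples_as_top_driver`, `mean_contribution`, ordered within supply
#'   by `n_samples_as_top_driver` then `mean_contribution`, descending.
#' @export
driver_report <- function(quotients, value_col = "tq", top_k = 10) {
  q <- quotients[quotients$included, , drop = FALSE]
  if (nrow(q) == 0)
    return(data.frame(supply_class = character(0), analyte_id = character(0),
                      n_samples_as_top_driver = integer(0),
                      mean_contribution = numeric(0)))
  totals <- tapply(q[[value_col]], q$sample_id, sum)
  q$contribution <- q[[value_col]] / as.numeric(totals[q$sample_id])
  ord <- order(q$sample_id, -q[[value_col]])
  top <- q[ord, ][!duplicated(q$sample_id[ord]), ]
  rows <- list()
  for (sc in intersect(.SUPPLY_CLASSES, unique(q$supply_class))) {
    qs <- q[q$supply_class == sc, ]
    tops <- top[top$supply_class == sc, ]
    n_top <- table(tops$analyte_id)
    mean_contr <- tapply(qs$contribution, qs$analyte_id, mean)
    ids <- names(mean_contr)
    df <- data.frame(supply_class = sc, analyte_id = ids,
                     n_samples_as_top_driver =
                       as.integer(ifelse(is.na(n_top[ids]), 0, n_top[ids])),
                     mean_contribution = as.numeric(mean_contr),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$n_samples_as_top_driver, -df$mean_contribution), ]
    rows[[sc]] <- head(df, top_k)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full screening pipeline
#'
#' Orchestrates simulate/ingest -> core-analyte constraint -> benchmark
#' resolution and cumulative TQ -> endpoint filtering and cumulative EAR ->
#' toxicokinetic AED floors and cumulative EAR_MED -> PERMANOVA supply-group
#' comparisons -> group summaries and driver reports.  Stages degrade
#' rather than abort when an input table is absent: without an ACC table the
#' EAR and EAR_MED stages report no coverage; without TK parameters the
#' EAR_MED stage does.  With `outdir` set, all result tables are written as
#' CSV together with a JSON run manifest recording the seed, package
#' version, conventions in effect, and row counts; identical seeds yield
#' byte-identical outputs.
#'
#' @param scenario a `dw_scenario` to simulate from, or `NULL` when
#'   `inputs` is given.
#' @param inputs optional list of pre-built inputs: `dataset` (a
#'   `dw_dataset`), `benchmarks`, `acc`, `tk`.
#' @param seed integer seed driving simulation, Monte Carlo TK draws, and
#'   permutation streams (default: the scenario's seed, else 1).
#' @param outdir output directory for CSV tables and the manifest; `NULL`
#'   (default) writes nothing.
#' @param n_permutations permutations per PERMANOVA comparison
#'   (default 9999).
#' @param substitution_rules see [default_substitution_rules()].
#' @param phys physiology list for the TK stage.
#' @param variability a [variability_spec()]; its seed is overridden by
#'   `seed`.
#' @param ear_aggregation chemical-level EAR aggregation
#'   (see [compute_ear()]).
#' @return list of class `dw_report`: inputs and every stage's tables
#'   (`tq`, `tq_per_sample`, `ear`, `ear_per_sample`, `aed`,
#'   `ear_med_per_sample`, coverage tables, `permanova`, `group_summaries`,
#'   `drivers`, `manifest`).
#' @export
run_pipeline <- function(scenario = NULL, inputs = NULL, seed = NULL,
                         outdir = NULL, n_permutations = 9999,
                         substitution_rules = default_substitution_rules(),
                         phys = default_physiology(),
                         variability = variability_spec(),
                         ear_aggregation = "max_endpoint") {
  if (is.null(scenario) && is.null(inputs))
    stop("either a scenario or an inputs list is required")
  if (is.null(seed))
    seed <- if (!is.null(scenario)) scenario$seed else 1L
  seed <- as.integer(seed)

  if (!is.null(scenario)) {
    gen <- generate_dataset(scenario, seed = seed)
    ds <- gen$dataset
    benchmarks <- gen$benchmarks
    acc <- gen$acc
    tk <- gen$tk
    ground_truth <- gen$ground_truth
  } else {
    ds <- inputs$dataset
    benchmarks <- inputs$benchmarks
    acc <- inputs$acc
    tk <- inputs$tk
    ground_truth <- NULL
  }
  stopifnot(inherits(ds, "dw_dataset"))

  ds <- constrain_to_core(ds)
  samples <- ds$samples

  # --- hazard-index stage -------------------------------------------------
  have_benchmarks <- !is.null(benchmarks) && nrow(benchmarks) > 0
  if (have_benchmarks) {
    resolved <- resolve_benchmarks(benchmarks, ds$catalog, substitution_rules)
    tq <- compute_tq(ds, resolved)
    regulatory <- benchmarks[benchmarks$benchmark_type %in%
                               c("MCL", "SOQ", "MCLG"), , drop = FALSE]
    exceed <- individual_exceedance_table(ds, regulatory)
    coverage <- benchmark_coverage(ds, resolved)
  } else {
    resolved <- NULL
    tq <- compute_tq(ds, data.frame(analyte_id = character(0),
                                    effective_value = numeric(0)))
    exceed <- NULL
    coverage <- NULL
  }
  tq_per_sample <- summarize_sample_tq(tq, samples)

  # --- bioactivity stage --------------------------------------------------
  have_acc <- !is.null(acc) && nrow(acc) > 0
  if (have_acc) {
    acc_clean <- filter_endpoints(acc)
    ear <- compute_ear(ds, acc_clean, aggregation = ear_aggregation)
    ear_cov <- ear_coverage(ds, acc_clean)
  } else {
    acc_clean <- NULL
    ear <- data.frame(sample_id = character(0), supply_class = character(0),
                      analyte_id = character(0), analyte_class = character(0),
                      concentration = numeric(0), endpoint_id = character(0),
                      ear = numeric(0), included = logical(0))
    ear_cov <- NULL
  }
  ear_per_sample <- summarize_sample_ear(ear, samples)

  # --- toxicokinetic stage ------------------------------------------------
  have_tk <- have_acc && !is.null(tk) && nrow(tk) > 0
  var <- variability
  var$seed <- seed
  if (have_tk) {
    aed <- compute_aed_floors(acc_clean, tk, ds$catalog, phys, var)
    earmed <- summarize_sample_ear_med(ds, aed$floors, samples)
  } else {
    aed <- list(aed = NULL,
                floors = data.frame(analyte_id = character(0),
                                    css95_uM = numeric(0),
                                    aed_floor = numeric(0),
                                    n_endpoints = integer(0)))
    earmed <- summarize_sample_ear_med(ds, aed$floors, samples)
  }

  # --- group comparison stage ---------------------------------------------
  multi_group <- length(unique(samples$supply_class)) >= 2 &&
    nrow(samples) >= 3
  permanova <- NULL
  if (multi_group) {
    permanova <- list(
      sum_tq = compare_supply_groups(tq_per_sample, "sum_tq",
                                     n_permutations, seed = seed + 1L),
      sum_ear = compare_supply_groups(ear_per_sample, "sum_ear",
                                      n_permutations, seed = seed + 2L),
      sum_ear_med = compare_supply_groups(earmed$per_sample, "sum_ear_med",
                                          n_permutations, seed = seed + 3L))
  }

  # The lower screening threshold differs by metric (0.1 for sum_tq, 0.001
  # for the EAR metrics); the stacked table calls that column frac_gt_low.
  group_summaries <- rbind(
    .pad_cols(summarize_groups(tq_per_sample, "sum_tq", c(0.1, 1))),
    .pad_cols(summarize_groups(ear_per_sample, "sum_ear", c(0.001, 1))),
    .pad_cols(summarize_groups(earmed$per_sample, "sum_ear_med",
                               c(0.001, 1))))

  drivers <- rbind(
    .tagged(driver_report(tq, "tq"), "sum_tq"),
    .tagged(driver_report(ear, "ear"), "sum_ear"),
    .tagged(driver_report(earmed$per_chemical, "ear_med"), "sum_ear_med"))

  manifest <- list(
    package = "dwscreen",
    version = as.character(utils::packageVersion("dwscreen")),
    seed = seed,
    n_samples = nrow(samples),
    n_samples_by_supply = as.list(table(samples$supply_class)),
    n_core_analytes = sum(ds$catalog$core_flag),
    n_permutations = n_permutations,
    ear_aggregation = ear_aggregation,
    quantile_convention = "linear interpolation (type 7)",
    thresholds = list(sum_tq = c(0.1, 1), sum_ear = c(0.001, 1),
                      sum_ear_med = c(0.001, 1)),
    inclusion_floor = .TQ_INCLUSION_FLOOR,
    substitution_rules = substitution_rules,
    physiology = phys,
    variability = list(cv = as.list(var$cv), n_draws = var$n_draws),
    stages = list(benchmarks = have_benchmarks, acc = have_acc,
                  tk = have_tk))

  out <- list(dataset = ds, resolved_benchmarks = resolved,
              tq = tq, tq_per_sample = tq_per_sample,
              individual_exceedances = exceed,
              benchmark_coverage = coverage,
              ear = ear, ear_per_sample = ear_per_sample,
              ear_coverage = ear_cov,
              aed = aed$aed, aed_floors = aed$floors,
              ear_med = earmed$per_chemical,
              ear_med_per_sample = earmed$per_sample,
              permanova = permanova,
              group_summaries = group_summaries,
              drivers = drivers,
              ground_truth = ground_truth,
              manifest = manifest)
  class(out) <- "dw_report"

  if (!is.null(outdir)) write_report(out, outdir)
  out
}

.pad_cols <- function(df) {
  names(df) <- sub("^frac_gt_0p(001|1)$", "frac_gt_low", names(df))
  df
}

.tagged <- function(df, metric) {
  if (nrow(df) == 0)
    return(cbind(data.frame(metric = character(0)), df))
  cbind(data.frame(metric = metric, stringsAsFactors = FALSE), df)
}

#' Write a pipeline report bundle to disk
#'
#' Writes every stage table as CSV plus `manifest.json`.  Output is
#' deterministic: rerunning the pipeline with the same seed reproduces
#' every file byte for byte.
#'
#' @param report a `dw_report` from [run_pipeline()].
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) if (!is.null(df))
    write_table(df, file.path(outdir, name))
  w(report$tq, "tq_per_detection.csv")
  w(report$tq_per_sample, "tq_per_sample.csv")
  w(report$individual_exceedances, "individual_exceedances.csv")
  w(report$benchmark_coverage, "coverage.csv")
  w(report$ear, "ear_per_chemical.csv")
  w(attr(report$ear, "per_endpoint"), "ear_per_endpoint.csv")
  w(report$ear_per_sample, "ear_per_sample.csv")
  w(report$ear_coverage, "ear_coverage.csv")
  w(report$aed, "aed95_per_endpoint.csv")
  w(report$aed_floors, "aed_floors.csv")
  w(report$ear_med, "ear_med_per_chemical.csv")
  w(report$ear_med_per_sample, "ear_med_per_sample.csv")
  w(report$group_summaries, "group_summaries.csv")
  w(report$drivers, "drivers.csv")
  if (!is.null(report$permanova)) {
    pm <- do.call(rbind, lapply(names(report$permanova), function(m) {
      r <- report$permanova[[m]]
      data.frame(metric = m, f_stat = r$f_stat, p_value = r$p_value,
                 n_permutations = r$n_permutations,
                 ss_total = r$ss_total, ss_among = r$ss_among,
                 ss_within = r$ss_within, seed = r$seed,
                 stringsAsFactors = FALSE)
    }))
    w(pm, "permanova.csv")
  }
  jsonlite::write_json(report$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.dw_report <- function(x, ...) {
  cat("<dw_report> seed", x$manifest$seed, "-", x$manifest$n_samples,
      "samples\n")
  gs <- x$group_summaries
  tq <- gs[gs$metric == "sum_tq", ]
  if (nrow(tq))
    cat("  sum_tq > 1: ",
        paste(sprintf("%s %.0f%%", tq$supply_class, 100 * tq$frac_gt_1),
              collapse = ", "), "\n", sep = "")
  if (!is.null(x$permanova))
    for (m in names(x$permanova))
      cat(sprintf("  PERMANOVA %s: F = %.3g, p = %.4g\n", m,
                  x$permanova[[m]]$f_stat, x$permanova[[m]]$p_value))
  invisible(x)
}
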