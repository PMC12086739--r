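# Apical human-health benchmark screening: per-detection toxicity quotients
# (TQ = detected concentration / most protective benchmark) and per-sample
# concentration-addition sums (hazard index, sum_tq).

#' Default zero-MCLG substitution rules
#'
#' Health-based maximum-contaminant-level goals (MCLG) are set to "zero" for
#' contaminants with no safe dose (e.g. As, Pb, U, several DBP/VOC, PFOS,
#' PFOA).  A zero denominator makes a toxicity quotient undefined, so
#' harmonized screening substitutes a small positive value: 0.1 ug/L for
#' metals, disinfection byproducts, and volatile organics (a routinely
#' achievable analytical reporting limit) and 0.0001 ug/L for PFOS and PFOA.
#'
#' @return list with `class` (named vector of ug/L substitutions keyed by
#'   analyte class) and `analyte` (named vector of per-analyte overrides,
#'   keyed by analyte_id; defaults carry the PFOS/PFOA CAS numbers).
#' @export
default_substitution_rules <- function() {
  list(
    class = c(inorganic = 0.1, DBP = 0.1, VOC = 0.1),
    analyte = c("1763-23-1" = 0.0001,   # PFOS
                "335-67-1" = 0.0001)    # PFOA
  )
}

#' Read substitution rules from a YAML file
#'
#' @param path YAML file with top-level keys `class` and `analyte`, each a
#'   mapping to positive ug/L substitution values.
#' @return rules list as in [default_substitution_rules()].
#' @export
read_substitution_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  list(class = unlist(raw$class), analyte = unlist(raw$analyte))
}

.substitution_value <- function(analyte_id, analyte_class, rules) {
  if (!is.null(rules$analyte) && analyte_id %in% names(rules$analyte))
    return(unname(rules$analyte[[analyte_id]]))
  if (!is.null(rules$class) && analyte_class %in% names(rules$class))
    return(unname(rules$class[[analyte_class]]))
  NA_real_
}

#' Resolve the effective benchmark for one analyte
#'
#' Selects the most protective (lowest-valued) benchmark among the
#' candidates.  Ties on value break by a fixed type priority
#' (MCLG > DWHA > WHO > STATE > HBSL > HHBP > MCL > SOQ).  When the selected
#' benchmark is an MCLG of zero, the effective value is taken from the
#' substitution rules and `substitution_applied` is set.
#'
#' @param analyte_id analyte key; all candidates must carry it.
#' @param candidates data.frame of benchmark records for this analyte
#'   (columns `analyte_id`, `benchmark_type`, `value`).
#' @param substitution_rules rules list (see
#'   [default_substitution_rules()]).
#' @param analyte_class class used for class-level substitution lookup.
#' @return one-row data.frame: `analyte_id`, `effective_value` (> 0, ug/L),
#'   `source_type`, `substitution_applied`.
#' @export
#' @examples
#' cand <- data.frame(analyte_id = "7440-38-2",
#'                    benchmark_type = c("MCLG", "MCL"), value = c(0, 10))
#' resolve_benchmark("7440-38-2", cand, default_substitution_rules(),
#'                   "inorganic")
resolve_benchmark <- function(analyte_id, candidates,
                              substitution_rules = default_substitution_rules(),
                              analyte_class = NA_character_) {
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("no benchmark candidates for analyte ", analyte_id)
  if (!all(candidates$analyte_id == analyte_id))
    stop("candidates must all be for analyte ", analyte_id)
  prio <- match(candidates$benchmark_type, .BENCHMARK_PRIORITY)
  ord <- order(candidates$value, prio)
  sel <- candidates[ord[1], ]
  substituted <- FALSE
  eff <- sel$value
  if (eff == 0) {
    if (sel$benchmark_type != "MCLG")
      stop("zero benchmark value only permitted for MCLG (analyte ",
           analyte_id, ")")
    eff <- .substitution_value(analyte_id, analyte_class, substitution_rules)
    if (is.na(eff))
      stop("configuration error: MCLG of zero for analyte ", analyte_id,
           " but no substitution rule covers it")
    substituted <- TRUE
  }
  data.frame(analyte_id = analyte_id, effective_value = eff,
             source_type = sel$benchmark_type,
             substitution_applied = substituted,
             stringsAsFactors = FALSE)
}

#' Resolve effective benchmarks for every analyte in a table
#'
#' @param benchmarks data.frame of benchmark records (see
#'   [read_benchmarks()]).
#' @param catalog analyte catalog (supplies `analyte_class` for class-level
#'   substitution rules).
#' @param substitution_rules see [default_substitution_rules()].
#' @return data.frame with one row per analyte present in `benchmarks`.
#' @export
resolve_benchmarks <- function(benchmarks, catalog,
                               substitution_rules =
                                 default_substitution_rules()) {
  ids <- unique(benchmarks$analyte_id)
  cls <- setNames(catalog$analyte_class, catalog$analyte_id)
  rows <- lapply(ids, function(id) {
    resolve_benchmark(id, benchmarks[benchmarks$analyte_id == id, ,
                                     drop = FALSE],
                      substitution_rules, unname(cls[id]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-detection toxicity quotients
#'
#' TQ = detected concentration / effective benchmark, for every detected,
#' non-microbial record whose analyte has a resolved benchmark.  Detections
#' of analytes without any benchmark are excluded here and counted by
#' [benchmark_coverage()].  A quotient enters the cumulative assessment only
#' when it reaches the inclusion floor (TQ >= 1e-5).
#'
#' @param ds a `dw_dataset`.
#' @param resolved resolved benchmark table from [resolve_benchmarks()].
#' @return data.frame: `sample_id`, `supply_class`, `analyte_id`,
#'   `analyte_class`, `concentration`, `effective_value`, `tq`, `included`.
#' @export
compute_tq <- function(ds, resolved) {
  det <- detected_concentrations(ds)
  det <- det[det$analyte_id %in% resolved$analyte_id, , drop = FALSE]
  if (nrow(det) == 0) {
    return(data.frame(sample_id = character(0), supply_class = character(0),
                      analyte_id = character(0), analyte_class = character(0),
                      concentration = numeric(0), effective_value = numeric(0),
                      tq = numeric(0), included = logical(0)))
  }
  eff <- setNames(resolved$effective_value, resolved$analyte_id)
  tq <- det$concentration / unname(eff[det$analyte_id])
  data.frame(sample_id = det$sample_id, supply_class = det$supply_class,
             analyte_id = det$analyte_id, analyte_class = det$analyte_class,
             concentration = det$concentration,
             effective_value = unname(eff[det$analyte_id]),
             tq = tq, included = tq >= .TQ_INCLUSION_FLOOR,
             stringsAsFactors = FALSE)
}

# Shared roll-up from a per-(sample, chemical) quotient table to per-sample
# cumulative sums under the non-interactive concentration-addition model.
# `value_col` holds the quotient; thresholds are strict (> t).
.summarize_sample_quotients <- function(quot, samples, value_col, thresholds) {
  quot <- quot[quot$included, , drop = FALSE]
  sums <- setNames(numeric(nrow(samples)), samples$sample_id)
  n_over_1 <- setNames(integer(nrow(samples)), samples$sample_id)
  rankings <- setNames(vector("list", nrow(samples)), samples$sample_id)
  if (nrow(quot)) {
    agg <- tapply(quot[[value_col]], quot$sample_id, sum)
    sums[names(agg)] <- as.numeric(agg)
    agg1 <- tapply(quot[[value_col]] > 1, quot$sample_id, sum)
    n_over_1[names(agg1)] <- as.integer(agg1)
    split_idx <- split(seq_len(nrow(quot)), quot$sample_id)
    for (sid in names(split_idx)) {
      rows <- quot[split_idx[[sid]], , drop = FALSE]
      tot <- sum(rows[[value_col]])
      if (tot > 0) {
        frac <- rows[[value_col]] / tot
        ord <- order(frac, decreasing = TRUE)
        rankings[[sid]] <- data.frame(
          analyte_id = rows$analyte_id[ord],
          contribution_fraction = frac[ord],
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_rank <- data.frame(analyte_id = character(0),
                           contribution_fraction = numeric(0))
  rankings <- lapply(rankings, function(r) if (is.null(r)) empty_rank else r)
  out <- data.frame(sample_id = samples$sample_id,
                    supply_class = samples$supply_class,
                    stringsAsFactors = FALSE)
  out$sum <- unname(sums[out$sample_id])
  out$n_over_1 <- unname(n_over_1[out$sample_id])
  out[[paste0("exceeds_", gsub("\\.", "p", thresholds[1]))]] <-
    out$sum > thresholds[1]
  out[[paste0("exceeds_", gsub("\\.", "p", thresholds[2]))]] <-
    out$sum > thresholds[2]
  out$driver_ranking <- unname(rankings[out$sample_id])
  out
}

#' Per-sample cumulative toxicity quotients (hazard index)
#'
#' Sums included per-detection TQs within each sample under the
#' non-interactive concentration-addition model, giving the sample's
#' cumulative TQ (`sum_tq`).  Reports the count of individual quotients above
#' 1, exceedance flags at the screening thresholds 0.1 and 1 (strict `>`),
#' and a per-sample driver ranking (analytes ordered by contribution
#' fraction tq_i / sum_tq).  Samples with no included quotient appear with
#' `sum_tq = 0`.
#'
#' @param tq_table per-detection TQ table from [compute_tq()].
#' @param samples sample roster data.frame (`sample_id`, `supply_class`).
#' @return data.frame with columns `sample_id`, `supply_class`, `sum_tq`,
#'   `n_tq_over_1`, `exceeds_0p1`, `exceeds_1`, and list column
#'   `driver_ranking`.
#' @export
summarize_sample_tq <- function(tq_table, samples) {
  out <- .summarize_sample_quotients(tq_table, samples, "tq", c(0.1, 1))
  names(out)[names(out) == "sum"] <- "sum_tq"
  names(out)[names(out) == "n_over_1"] <- "n_tq_over_1"
  out
}

#' Individual-contaminant regulatory exceedance table
#'
#' Compares each detected concentration with the regulatory-context
#' benchmarks (enforceable MCL for public tapwater, SOQ for bottled water)
#' and the health-based MCLG.  Exceedance is a strict inequality
#' (concentration > value); an MCLG of zero is exceeded by any detection.
#'
#' @param ds a `dw_dataset`.
#' @param regulatory data.frame of benchmark records restricted by the
#'   caller to the types of interest (typically MCL, SOQ, MCLG).
#' @return data.frame: `sample_id`, `supply_class`, `analyte_id`,
#'   `concentration`, `benchmark_type`, `value`, `exceeds`.
#' @export
individual_exceedance_table <- function(ds, regulatory) {
  det <- detected_concentrations(ds)
  m <- merge(det[, c("sample_id", "supply_class", "analyte_id",
                     "concentration")],
             regulatory[, c("analyte_id", "benchmark_type", "value")],
             by = "analyte_id")
  m$exceeds <- ifelse(m$value == 0, TRUE, m$concentration > m$value)
  out <- m[, c("sample_id", "supply_class", "analyte_id", "concentration",
               "benchmark_type", "value", "exceeds")]
  out <- out[order(out$sample_id, out$analyte_id, out$benchmark_type), ]
  rownames(out) <- NULL
  out
}

#' Benchmark coverage report
#'
#' Counts, per analyte class, how many detected analytes have a resolved
#' benchmark (and thus enter the cumulative assessment) versus how many were
#' detected at all — the assessed-but-uncovered gap that bounds what the
#' hazard index can see.
#'
#' @param ds a `dw_dataset`.
#' @param resolved resolved benchmark table from [resolve_benchmarks()].
#' @return data.frame: `analyte_class`, `n_detected_analytes`,
#'   `n_with_benchmark`.
#' @export
benchmark_coverage <- function(ds, resolved) {
  det <- detected_concentrations(ds)
  per <- unique(det[, c("analyte_id", "analyte_class")])
  per$has_benchmark <- per$analyte_id %in% resolved$analyte_id
  agg_n <- tapply(per$analyte_id, per$analyte_class, length)
  agg_b <- tapply(per$has_benchmark, per$analyte_class, sum)
  out <- data.frame(analyte_class = names(agg_n),
                    n_detected_analytes = as.integer(agg_n),
                    n_with_benchmark = as.integer(agg_b),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
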