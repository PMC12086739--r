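# Molecular-effects screening: exposure-activity ratios (EAR) against
# high-throughput assay activity concentrations at cutoff (ACC), aggregated
# to chemical level and summed per sample (sum_ear).  Applied to organic
# contaminants only; inorganics and microbial rows never enter.

#' Exclude flagged assay endpoints
#'
#' Drops ACC records flagged as non-specific-endpoint, baseline, or
#' unreliable response-curve assays; only clean endpoints enter any EAR.
#' The number of records removed per flag is attached as the `removals`
#' attribute (a record with several flags counts once under each).
#'
#' @param acc data.frame of ACC records (see [read_acc()]).
#' @return the retained records, with attribute `removals`.
#' @export
filter_endpoints <- function(acc) {
  flags <- c("flag_nonspecific", "flag_baseline", "flag_unreliable")
  for (fl in flags) if (!fl %in% names(acc)) acc[[fl]] <- FALSE
  any_flag <- Reduce(`|`, lapply(flags, function(fl) acc[[fl]] %in% TRUE))
  removals <- vapply(flags, function(fl) sum(acc[[fl]] %in% TRUE & any_flag),
                     integer(1))
  out <- acc[!any_flag, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removals") <- removals
  out
}

# Fill acc_ugL from acc_uM where absent: uM x MW (g/mol) = ug/L, since
# umol/L x g/mol = ug/L.  And the reverse for acc_uM.
.complete_acc_units <- function(acc, catalog) {
  mw <- setNames(catalog$molecular_weight, catalog$analyte_id)
  need_ugl <- is.na(acc$acc_ugL) & !is.na(acc$acc_uM)
  acc$acc_ugL[need_ugl] <- acc$acc_uM[need_ugl] *
    unname(mw[acc$analyte_id[need_ugl]])
  need_um <- is.na(acc$acc_uM) & !is.na(acc$acc_ugL)
  acc$acc_uM[need_um] <- acc$acc_ugL[need_um] /
    unname(mw[acc$analyte_id[need_um]])
  acc
}

#' Per-endpoint and chemical-level exposure-activity ratios
#'
#' EAR = detected concentration / ACC (both ug/L), per retained endpoint.
#' Chemical-level aggregation (the value summed across chemicals) defaults
#' to the maximum EAR over a chemical's endpoints (`max_endpoint`);
#' `per_endpoint` instead keeps the full endpoint-wise table for
#' endpoint-level mixture summaries.  Inorganic and microbial detections are
#' excluded; organic detections whose analyte has no retained endpoint are
#' excluded here and counted by [ear_coverage()].
#'
#' @param ds a `dw_dataset`.
#' @param acc ACC records, already passed through [filter_endpoints()];
#'   records still carrying a flag are refused.
#' @param aggregation `"max_endpoint"` (default) or `"per_endpoint"`.
#' @return for `max_endpoint`, a data.frame with one row per
#'   (sample, chemical): `sample_id`, `supply_class`, `analyte_id`,
#'   `analyte_class`, `concentration`, `ear`, `endpoint_id` (the arg-max
#'   endpoint), `included` (ear >= 1e-5); the full per-endpoint table is
#'   attached as attribute `per_endpoint`.  For `per_endpoint`, the
#'   endpoint-wise table itself.
#' @export
compute_ear <- function(ds, acc, aggregation = c("max_endpoint",
                                                 "per_endpoint")) {
  aggregation <- match.arg(aggregation)
  flags <- c("flag_nonspecific", "flag_baseline", "flag_unreliable")
  if (any(vapply(flags, function(fl)
    fl %in% names(acc) && any(acc[[fl]] %in% TRUE), logical(1))))
    stop("ACC table still contains flagged endpoints; ",
         "apply filter_endpoints() first")
  acc <- .complete_acc_units(acc, ds$catalog)
  if (any(is.na(acc$acc_ugL)))
    stop("ACC records lack acc_ugL and no molecular weight to derive it: ",
         paste(unique(acc$analyte_id[is.na(acc$acc_ugL)]), collapse = ", "))

  organic_classes <- setdiff(.ANALYTE_CLASSES, c("inorganic", "microbial"))
  det <- detected_concentrations(ds, classes = organic_classes)
  per <- merge(det[, c("sample_id", "supply_class", "analyte_id",
                       "analyte_class", "concentration")],
               acc[, c("analyte_id", "endpoint_id", "acc_ugL")],
               by = "analyte_id")
  per$ear <- per$concentration / per$acc_ugL
  per <- per[order(per$sample_id, per$analyte_id, per$endpoint_id), ]
  rownames(per) <- NULL
  per <- per[, c("sample_id", "supply_class", "analyte_id", "analyte_class",
                 "concentration", "endpoint_id", "acc_ugL", "ear")]
  if (aggregation == "per_endpoint") return(per)

  key <- paste(per$sample_id, per$analyte_id, sep = "\r")
  ord <- order(key, -per$ear)
  per_sorted <- per[ord, ]
  keep <- !duplicated(key[ord])
  chem <- per_sorted[keep, c("sample_id", "supply_class", "analyte_id",
                             "analyte_class", "concentration", "endpoint_id",
                             "ear")]
  chem <- chem[order(chem$sample_id, chem$analyte_id), ]
  rownames(chem) <- NULL
  chem$included <- chem$ear >= .TQ_INCLUSION_FLOOR
  attr(chem, "per_endpoint") <- per
  chem
}

#' Per-sample cumulative exposure-activity ratios
#'
#' Sums included chemical-level EARs within each sample (concentration
#' addition), flagging exceedance of the 0.001 screening level of potential
#' molecular-effects concern and of 1 (both strict `>`), with a per-sample
#' driver ranking by contribution fraction.
#'
#' @param ear_table chemical-level EAR table from [compute_ear()]
#'   (`max_endpoint` aggregation).
#' @param samples sample roster data.frame.
#' @return data.frame: `sample_id`, `supply_class`, `sum_ear`,
#'   `n_ear_over_1`, `exceeds_0p001`, `exceeds_1`, list column
#'   `driver_ranking`.
#' @export
summarize_sample_ear <- function(ear_table, samples) {
  out <- .summarize_sample_quotients(ear_table, samples, "ear", c(0.001, 1))
  names(out)[names(out) == "sum"] <- "sum_ear"
  names(out)[names(out) == "n_over_1"] <- "n_ear_over_1"
  out
}

#' Bioactivity coverage report
#'
#' Counts, per analyte class, how many detected organic analytes have at
#' least one retained ACC endpoint versus how many were detected.
#'
#' @param ds a `dw_dataset`.
#' @param acc filtered ACC records.
#' @return data.frame: `analyte_class`, `n_detected_analytes`, `n_with_acc`.
#' @export
ear_coverage <- function(ds, acc) {
  organic_classes <- setdiff(.ANALYTE_CLASSES, c("inorganic", "microbial"))
  det <- detected_concentrations(ds, classes = organic_classes)
  per <- unique(det[, c("analyte_id", "analyte_class")])
  per$has_acc <- per$analyte_id %in% acc$analyte_id
  agg_n <- tapply(per$analyte_id, per$analyte_class, length)
  agg_b <- tapply(per$has_acc, per$analyte_class, sum)
  out <- data.frame(analyte_class = names(agg_n),
                    n_detected_analytes = as.integer(agg_n),
                    n_with_acc = as.integer(agg_b),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
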