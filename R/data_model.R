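#' Assemble a drinking-water exposure dataset
#'
#' Bundles long-format detection records, the analyte catalog they key into,
#' and the sample roster into a validated `dw_dataset` object, the container
#' every screening stage consumes.  Non-detect rows (`detected = FALSE`) are
#' retained so that coverage can be reported for assessed-but-undetected
#' analytes; they contribute zero to every cumulative sum.
#'
#' @param detections data.frame with columns `study_id`, `sample_id`,
#'   `supply_class`, `analyte_id`, `analyte_name`, `analyte_class`,
#'   `concentration` (ug/L; CFU/100 mL for microbial rows), `reporting_limit`
#'   (same units), `detected` (logical).  `concentration` may be `NA` on
#'   non-detect rows.
#' @param catalog data.frame with columns `analyte_id`, `analyte_name`,
#'   `analyte_class`, `core_flag` (logical), `molecular_weight` (g/mol,
#'   `NA` allowed).
#' @param samples optional data.frame with columns `sample_id`,
#'   `supply_class`, `study_id`; derived from `detections` when omitted.
#'   Supplying it explicitly preserves samples that carry no detection rows.
#'
#' @return An object of class `dw_dataset`: a list with elements
#'   `detections`, `catalog`, `samples`.
#' @export
#' @examples
#' cat <- data.frame(analyte_id = "7440-38-2", analyte_name = "arsenic",
#'                   analyte_class = "inorganic", core_flag = TRUE,
#'                   molecular_weight = NA_real_)
#' det <- data.frame(study_id = "s1", sample_id = "w1",
#'                   supply_class = "private_tw", analyte_id = "7440-38-2",
#'                   analyte_name = "arsenic", analyte_class = "inorganic",
#'                   concentration = 2.5, reporting_limit = 0.1,
#'                   detected = TRUE)
#' ds <- dw_dataset(det, cat)
#' n_samples(ds)
dw_dataset <- function(detections, catalog, samples = NULL) {
  detections <- as.data.frame(detections)
  catalog <- as.data.frame(catalog)
  if (is.null(samples)) {
    samples <- unique(detections[, c("sample_id", "supply_class", "study_id")])
    rownames(samples) <- NULL
  } else {
    samples <- as.data.frame(samples)
  }
  ds <- structure(list(detections = detections, catalog = catalog,
                       samples = samples),
                  class = "dw_dataset")
  validate_dw_dataset(ds)
  ds
}

#' Validate a dw_dataset
#'
#' Checks the structural invariants: required columns, non-negative
#' concentrations, positive reporting limits, known supply and analyte
#' classes, unique sample and analyte keys, and that every detection row
#' resolves to a catalog analyte and a roster sample.
#'
#' @param ds object to validate.
#' @return `ds`, invisibly, if valid; otherwise an error describing every
#'   violated constraint.
#' @export
validate_dw_dataset <- function(ds) {
  stopifnot(inherits(ds, "dw_dataset"))
  det <- ds$detections
  cat_ <- ds$catalog
  smp <- ds$samples

  need_det <- c("study_id", "sample_id", "supply_class", "analyte_id",
                "analyte_name", "analyte_class", "concentration",
                "reporting_limit", "detected")
  need_cat <- c("analyte_id", "analyte_name", "analyte_class", "core_flag",
                "molecular_weight")
  need_smp <- c("sample_id", "supply_class", "study_id")

  problems <- character(0)
  miss <- setdiff(need_det, names(det))
  if (length(miss))
    problems <- c(problems, paste0("detections missing column(s): ",
                                   paste(miss, collapse = ", ")))
  miss <- setdiff(need_cat, names(cat_))
  if (length(miss))
    problems <- c(problems, paste0("catalog missing column(s): ",
                                   paste(miss, collapse = ", ")))
  miss <- setdiff(need_smp, names(smp))
  if (length(miss))
    problems <- c(problems, paste0("samples missing column(s): ",
                                   paste(miss, collapse = ", ")))
  if (length(problems)) stop(paste(problems, collapse = "\n"))

  bad <- which(det$detected & (is.na(det$concentration) | det$concentration < 0))
  if (length(bad))
    problems <- c(problems,
                  paste0("negative or missing concentration on detected row(s): ",
                         paste(head(bad, 10), collapse = ", ")))
  bad <- which(!is.na(det$concentration) & det$concentration < 0)
  if (length(bad))
    problems <- c(problems, paste0("negative concentration on row(s): ",
                                   paste(head(bad, 10), collapse = ", ")))
  bad <- which(is.na(det$reporting_limit) | det$reporting_limit <= 0)
  if (length(bad))
    problems <- c(problems, paste0("non-positive reporting_limit on row(s): ",
                                   paste(head(bad, 10), collapse = ", ")))
  if (!all(det$supply_class %in% .SUPPLY_CLASSES))
    problems <- c(problems,
                  paste0("unknown supply_class value(s): ",
                         paste(setdiff(unique(det$supply_class),
                                       .SUPPLY_CLASSES), collapse = ", ")))
  if (!all(cat_$analyte_class %in% .ANALYTE_CLASSES))
    problems <- c(problems,
                  paste0("unknown analyte_class value(s): ",
                         paste(setdiff(unique(cat_$analyte_class),
                                       .ANALYTE_CLASSES), collapse = ", ")))
  if (anyDuplicated(cat_$analyte_id))
    problems <- c(problems, "duplicate analyte_id in catalog")
  if (anyDuplicated(smp$sample_id))
    problems <- c(problems, "duplicate sample_id in samples")
  unknown <- setdiff(unique(det$analyte_id), cat_$analyte_id)
  if (length(unknown))
    problems <- c(problems, paste0("detections reference analyte_id absent ",
                                   "from catalog: ",
                                   paste(unknown, collapse = ", ")))
  orphan <- setdiff(unique(det$sample_id), smp$sample_id)
  if (length(orphan))
    problems <- c(problems, paste0("detections reference sample_id absent ",
                                   "from samples: ",
                                   paste(orphan, collapse = ", ")))
  mw <- cat_$molecular_weight
  if (any(!is.na(mw) & mw <= 0))
    problems <- c(problems, "molecular_weight must be > 0 when present")
  if (length(problems)) stop(paste(problems, collapse = "\n"))
  invisible(ds)
}

#' @export
print.dw_dataset <- function(x, ...) {
  tab <- table(factor(x$samples$supply_class, levels = .SUPPLY_CLASSES))
  cat("<dw_dataset>\n")
  cat("  samples:   ", nrow(x$samples), " (",
      paste(paste0(names(tab), " = ", as.integer(tab)), collapse = ", "),
      ")\n", sep = "")
  cat("  analytes:  ", nrow(x$catalog), " in catalog, ",
      length(unique(x$detections$analyte_id)), " with records\n", sep = "")
  cat("  detections:", sum(x$detections$detected), "detected /",
      nrow(x$detections), "rows\n")
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds a `dw_dataset`.
#' @return integer count of roster samples.
#' @export
n_samples <- function(ds) nrow(ds$samples)

#' Restrict a dataset to core analytes
#'
#' Harmonization across studies requires constraining records to the core
#' analyte list maintained in every study; the catalog's `core_flag` marks
#' that list.  The sample roster is kept unchanged, so samples may become
#' detection-free but still appear (with zero sums) in every summary.
#'
#' @param ds a `dw_dataset`.
#' @return a `dw_dataset` containing only detections of core analytes.
#'   Idempotent: applying it twice equals applying it once.
#' @export
constrain_to_core <- function(ds) {
  stopifnot(inherits(ds, "dw_dataset"))
  core_ids <- ds$catalog$analyte_id[ds$catalog$core_flag]
  det <- ds$detections[ds$detections$analyte_id %in% core_ids, , drop = FALSE]
  rownames(det) <- NULL
  dw_dataset(det, ds$catalog, ds$samples)
}

#' Detected concentrations as a screening input table
#'
#' Extracts the detected rows of a dataset, optionally restricted to a set of
#' analyte classes, joined to the sample roster.  This is the numerator table
#' for every quotient stage.
#'
#' @param ds a `dw_dataset`.
#' @param classes analyte classes to keep (default: all non-microbial).
#' @return data.frame of detected rows.
#' @export
detected_concentrations <- function(ds,
                                    classes = setdiff(.ANALYTE_CLASSES,
                                                      "microbial")) {
  det <- ds$detections
  out <- det[det$detected & det$analyte_class %in% classes, , drop = FALSE]
  rownames(out) <- NULL
  out
}
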