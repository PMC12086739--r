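# Readers and writers for the package's CSV interchange tables.  All numeric
# columns are written with full double precision (17 significant digits) so
# that write -> read round-trips reproduce values exactly.

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("format error in ", what, " file '", path,
         "': missing required column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read an analyte catalog
#'
#' @param path CSV with columns `analyte_id`, `analyte_name`,
#'   `analyte_class`, `core_flag`, `molecular_weight`.
#' @return data.frame catalog.
#' @export
read_catalog <- function(path) {
  df <- .read_csv_checked(path, c("analyte_id", "analyte_name",
                                  "analyte_class", "core_flag",
                                  "molecular_weight"), "catalog")
  df$core_flag <- as.logical(df$core_flag)
  df$molecular_weight <- as.numeric(df$molecular_weight)
  if (anyDuplicated(df$analyte_id))
    stop("duplicate analyte_id in catalog: ",
         paste(unique(df$analyte_id[duplicated(df$analyte_id)]),
               collapse = ", "))
  df
}

#' Read detection records
#'
#' Reads a long-format detections CSV and assembles a validated
#' [dw_dataset()].  Concentrations and reporting limits are expected in ug/L;
#' rows whose `units` column reads `ng/L` are converted to ug/L on ingest.
#' Rows whose `analyte_id` is not in the catalog are rejected collectively
#' with an error listing every unknown id.
#'
#' @param path CSV with columns `study_id`, `sample_id`, `supply_class`,
#'   `analyte_id`, `analyte_name`, `analyte_class`, `concentration`, `units`,
#'   `reporting_limit`, `detected`.
#' @param catalog analyte catalog data.frame (see [read_catalog()]).
#' @param samples optional explicit sample roster (see [dw_dataset()]).
#' @return a `dw_dataset`.
#' @export
read_detections <- function(path, catalog, samples = NULL) {
  need <- c("study_id", "sample_id", "supply_class", "analyte_id",
            "analyte_name", "analyte_class", "concentration", "units",
            "reporting_limit", "detected")
  df <- .read_csv_checked(path, need, "detections")
  df$detected <- as.logical(df$detected)
  df$concentration <- as.numeric(df$concentration)
  df$reporting_limit <- as.numeric(df$reporting_limit)

  bad <- which(!is.na(df$concentration) & df$concentration < 0)
  if (length(bad))
    stop("validation error in '", path, "': negative concentration on row(s) ",
         paste(head(bad, 10), collapse = ", "))

  unknown <- setdiff(unique(df$analyte_id), catalog$analyte_id)
  if (length(unknown))
    stop("validation error in '", path, "': unknown analyte_id(s) not in ",
         "catalog: ", paste(unknown, collapse = ", "))

  ng <- !is.na(df$units) & df$units %in% c("ng/L", "ng/l")
  df$concentration[ng] <- df$concentration[ng] / 1000
  df$reporting_limit[ng] <- df$reporting_limit[ng] / 1000
  df$units <- NULL

  dw_dataset(df, catalog, samples)
}

#' Write detection records
#'
#' Inverse of [read_detections()]: writes the detections of a dataset,
#' with an explicit `units` column (always `ug/L` after ingest), such that
#' reading the file back with the same catalog reproduces the dataset.
#'
#' @param ds a `dw_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(ds, path) {
  det <- ds$detections
  out <- data.frame(study_id = det$study_id, sample_id = det$sample_id,
                    supply_class = det$supply_class,
                    analyte_id = det$analyte_id,
                    analyte_name = det$analyte_name,
                    analyte_class = det$analyte_class,
                    concentration = det$concentration,
                    units = "ug/L",
                    reporting_limit = det$reporting_limit,
                    detected = det$detected,
                    stringsAsFactors = FALSE)
  write_table(out, path)
}

#' Read a benchmark table
#'
#' @param path CSV with columns `analyte_id`, `benchmark_type`, `value`,
#'   `units`, `enforceable`.  Values are ug/L; a value of zero is permitted
#'   only for the MCLG type (health-based goals set to "zero" for
#'   carcinogens).
#' @return data.frame of benchmark records.
#' @export
read_benchmarks <- function(path) {
  df <- .read_csv_checked(path, c("analyte_id", "benchmark_type", "value",
                                  "units", "enforceable"), "benchmarks")
  df$value <- as.numeric(df$value)
  df$enforceable <- as.logical(df$enforceable)
  bad_type <- setdiff(unique(df$benchmark_type), .BENCHMARK_TYPES)
  if (length(bad_type))
    stop("unknown benchmark_type(s): ", paste(bad_type, collapse = ", "))
  if (any(df$value < 0, na.rm = TRUE))
    stop("benchmark values must be >= 0")
  zero_bad <- df$value == 0 & df$benchmark_type != "MCLG"
  if (any(zero_bad, na.rm = TRUE))
    stop("zero benchmark value only permitted for MCLG")
  df$units <- NULL
  df
}

#' Read an ACC endpoint table
#'
#' @param path CSV with columns `analyte_id`, `endpoint_id`, `acc_uM`,
#'   `acc_ugL`, `flag_nonspecific`, `flag_baseline`, `flag_unreliable`.
#'   Either activity-concentration column may be blank; missing `acc_ugL`
#'   values are derived later from `acc_uM` and the catalog molecular weight.
#' @return data.frame of ACC records.
#' @export
read_acc <- function(path) {
  df <- .read_csv_checked(path, c("analyte_id", "endpoint_id", "acc_uM",
                                  "acc_ugL", "flag_nonspecific",
                                  "flag_baseline", "flag_unreliable"), "ACC")
  for (fl in c("flag_nonspecific", "flag_baseline", "flag_unreliable"))
    df[[fl]] <- as.logical(df[[fl]])
  df$acc_uM <- as.numeric(df$acc_uM)
  df$acc_ugL <- as.numeric(df$acc_ugL)
  if (any(!is.na(df$acc_ugL) & df$acc_ugL <= 0) ||
      any(!is.na(df$acc_uM) & df$acc_uM <= 0))
    stop("ACC values must be > 0")
  df
}

#' Read a toxicokinetic parameter table
#'
#' @param path CSV with columns `analyte_id`, `molecular_weight` (g/mol),
#'   `fraction_unbound` (plasma, in (0,1]), `intrinsic_clearance`
#'   (uL/min per million hepatocytes, >= 0).
#' @return data.frame of TK parameter records.
#' @export
read_tk_params <- function(path) {
  df <- .read_csv_checked(path, c("analyte_id", "molecular_weight",
                                  "fraction_unbound", "intrinsic_clearance"),
                          "TK parameters")
  for (cc in c("molecular_weight", "fraction_unbound", "intrinsic_clearance"))
    df[[cc]] <- as.numeric(df[[cc]])
  ok <- is.na(df$fraction_unbound) |
    (df$fraction_unbound > 0 & df$fraction_unbound <= 1)
  if (!all(ok)) stop("fraction_unbound must lie in (0, 1]")
  if (any(!is.na(df$molecular_weight) & df$molecular_weight <= 0))
    stop("molecular_weight must be > 0")
  if (any(!is.na(df$intrinsic_clearance) & df$intrinsic_clearance < 0))
    stop("intrinsic_clearance must be >= 0")
  df
}

#' Write a result table with stable column order and full precision
#'
#' All pipeline outputs funnel through this writer: columns keep their input
#' order, doubles are rendered with 17 significant digits (lossless for IEEE
#' doubles), and list columns (e.g. per-sample driver rankings) are
#' serialized as JSON strings.
#'
#' @param df data.frame to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.list(col)) {
      df[[nm]] <- vapply(col, function(x)
        as.character(jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)),
        character(1))
    } else if (is.double(col)) {
      df[[nm]] <- vapply(col, function(x) {
        if (is.na(x)) NA_character_ else format(x, digits = 17)
      }, character(1))
    }
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored to doubles.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}
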