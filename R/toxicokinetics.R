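# Toxicokinetically adjusted molecular-effects screening (sum_ear_med).
# Chain: water concentration -> measured equivalent dose (MED, mg/kg/d) ->
# steady-state plasma concentration per unit dose (Css, three-compartment
# steady-state, restrictive clearance, 100% oral bioavailability) -> 95th
# population percentile Css under Monte Carlo parameter variability ->
# administered equivalent dose per endpoint (AED95 = ACC / Css95) -> 5th
# percentile AED across endpoints per chemical -> EAR_MED = MED / AED floor.

#' Reference adult physiology for steady-state clearance
#'
#' Conventional adult reference values: 70 kg body weight, 90 L/h liver
#' blood flow, 6.7 L/h glomerular filtration rate, 110 million hepatocytes
#' per gram of liver, 1820 g liver.  All configurable; clearance scales
#' linearly in the hepatocellularity x liver-mass product.
#'
#' @return named list: `body_weight` (kg), `liver_blood_flow` (L/h),
#'   `glomerular_filtration_rate` (L/h), `hepatocellularity`
#'   (1e6 cells/g liver), `liver_mass` (g).
#' @export
default_physiology <- function() {
  list(body_weight = 70, liver_blood_flow = 90,
       glomerular_filtration_rate = 6.7,
       hepatocellularity = 110, liver_mass = 1820)
}

#' Monte Carlo variability specification
#'
#' Population variability is approximated by varying intrinsic clearance,
#' fraction unbound, liver blood flow, and glomerular filtration rate
#' independently as truncated normals about their central values with a
#' common default coefficient of variation of 0.3.  Draws are truncated to
#' the positive half-line (fraction unbound additionally to (0, 1]);
#' `truncation` narrows the support further as multipliers of the central
#' value.
#'
#' @param cv named numeric vector of coefficients of variation; any of
#'   `intrinsic_clearance`, `fraction_unbound`, `liver_blood_flow`,
#'   `glomerular_filtration_rate`.  A single unnamed value applies to all.
#' @param n_draws number of Monte Carlo draws (default 1000).
#' @param seed integer seed; fixed seed gives identical Css95.
#' @param truncation length-2 numeric `c(lower, upper)` multipliers of the
#'   central value bounding each draw (default `c(0, Inf)`).
#' @return list of class `variability_spec`.
#' @export
variability_spec <- function(cv = 0.3, n_draws = 1000, seed = 1,
                             truncation = c(0, Inf)) {
  pars <- c("intrinsic_clearance", "fraction_unbound", "liver_blood_flow",
            "glomerular_filtration_rate")
  if (is.null(names(cv))) cv <- setNames(rep(cv[1], length(pars)), pars)
  cv_full <- setNames(rep(0, length(pars)), pars)
  cv_full[names(cv)] <- cv
  stopifnot(all(cv_full >= 0), n_draws >= 1, truncation[1] < truncation[2])
  structure(list(cv = cv_full, n_draws = as.integer(n_draws),
                 seed = as.integer(seed), truncation = truncation),
            class = "variability_spec")
}

#' Measured equivalent dose from a water concentration
#'
#' Converts a drinking-water concentration (ug/L) to a daily oral dose
#' (mg/kg/d) at the conservative birth-to-one-month ingestion rate of 0.2 L
#' of water per kg body weight per day: MED = C x 0.2 L/kg/d x 0.001 mg/ug.
#'
#' @param concentration non-negative concentration(s), ug/L.
#' @param ingestion_rate L water per kg body weight per day (default 0.2).
#' @return dose(s), mg/kg/d.
#' @export
#' @examples
#' compute_med(1)    # 2e-4 mg/kg/d
#' compute_med(50)   # 0.01 mg/kg/d
compute_med <- function(concentration, ingestion_rate = 0.2) {
  if (any(concentration < 0, na.rm = TRUE))
    stop("concentration must be >= 0")
  concentration * ingestion_rate * 0.001
}

#' Steady-state plasma concentration for a unit oral dose
#'
#' Three-compartment steady-state model with restrictive (fraction-unbound
#' scaled) clearance and 100% oral bioavailability.  Whole-liver intrinsic
#' clearance scales the per-cell rate by hepatocellularity and liver mass
#' (uL/min/1e6 cells x 1e6 cells/g x g x 60 min/h x 1e-6 L/uL = L/h);
#' hepatic clearance follows the well-stirred liver model
#' CL_h = Q f_up CL_int / (Q + f_up CL_int); renal clearance is passive
#' glomerular filtration of unbound drug, CL_r = GFR x f_up.  Then
#' Css (mg/L) = dose-rate (mg/h) / (CL_r + CL_h) and is converted to uM by
#' dividing by the molecular weight (mg/L / (g/mol) = mmol/m3 = uM).
#'
#' @param tk one-row data.frame or list with `molecular_weight` (g/mol),
#'   `fraction_unbound` ((0,1]), `intrinsic_clearance` (uL/min/1e6 cells).
#' @param phys physiology list (see [default_physiology()]).
#' @param dose oral dose, mg/kg/d (default 1, giving Css per unit dose).
#' @return steady-state plasma concentration, uM.
#' @export
css_steady_state <- function(tk, phys = default_physiology(), dose = 1) {
  mw <- tk$molecular_weight
  fup <- tk$fraction_unbound
  clint <- tk$intrinsic_clearance
  stopifnot(mw > 0, fup > 0, fup <= 1, clint >= 0, dose > 0)
  clint_whole <- clint * phys$hepatocellularity * phys$liver_mass * 60 * 1e-6
  q <- phys$liver_blood_flow
  cl_h <- (q * fup * clint_whole) / (q + fup * clint_whole)
  if (!is.finite(cl_h)) cl_h <- q   # CLint -> Inf limit: flow-limited
  cl_r <- phys$glomerular_filtration_rate * fup
  cl_total <- cl_r + cl_h
  if (cl_total <= 0)
    stop("total clearance is zero: steady state undefined for analyte ",
         if (!is.null(tk$analyte_id)) tk$analyte_id else "<unnamed>")
  dose_rate <- dose * phys$body_weight / 24       # mg/h
  css_mgL <- dose_rate / cl_total
  css_mgL / mw * 1000
}

# One truncated-normal draw vector: rejection sampling about `center` with
# sd = cv * center, support clipped to (lower, upper].  cv = 0 degenerates
# to the center point.
.rtrunc_about <- function(n, center, cv, lower, upper) {
  if (cv == 0 || center == 0) return(rep(center, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean = center, sd = cv * center)
    ok <- draw > lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' 95th population percentile of Css under Monte Carlo variability
#'
#' Draws intrinsic clearance, fraction unbound, liver blood flow, and
#' glomerular filtration rate independently from truncated normals about
#' their central values (fraction unbound truncated to (0, 1]) and returns
#' the 95th percentile (linear-interpolation quantile) of the resulting
#' per-unit-dose Css values.  Deterministic for a fixed seed; with all CVs
#' zero it equals [css_steady_state()] exactly.
#'
#' @param tk chemical TK parameters as in [css_steady_state()].
#' @param phys physiology list.
#' @param var a [variability_spec()].
#' @return Css95, uM per (mg/kg/d).
#' @export
css95_monte_carlo <- function(tk, phys = default_physiology(),
                              var = variability_spec()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(var$seed)

  n <- var$n_draws
  lo <- var$truncation[1]
  hi <- var$truncation[2]
  clint <- .rtrunc_about(n, tk$intrinsic_clearance,
                         var$cv[["intrinsic_clearance"]],
                         max(0, lo * tk$intrinsic_clearance),
                         hi * max(tk$intrinsic_clearance, 1))
  fup <- .rtrunc_about(n, tk$fraction_unbound,
                       var$cv[["fraction_unbound"]],
                       max(0, lo * tk$fraction_unbound),
                       min(1, hi * tk$fraction_unbound))
  q <- .rtrunc_about(n, phys$liver_blood_flow,
                     var$cv[["liver_blood_flow"]],
                     max(0, lo * phys$liver_blood_flow),
                     hi * phys$liver_blood_flow)
  gfr <- .rtrunc_about(n, phys$glomerular_filtration_rate,
                       var$cv[["glomerular_filtration_rate"]],
                       max(0, lo * phys$glomerular_filtration_rate),
                       hi * phys$glomerular_filtration_rate)

  css <- vapply(seq_len(n), function(i) {
    css_steady_state(list(molecular_weight = tk$molecular_weight,
                          fraction_unbound = fup[i],
                          intrinsic_clearance = clint[i]),
                     phys = list(body_weight = phys$body_weight,
                                 liver_blood_flow = q[i],
                                 glomerular_filtration_rate = gfr[i],
                                 hepatocellularity = phys$hepatocellularity,
                                 liver_mass = phys$liver_mass),
                     dose = 1)
  }, numeric(1))
  unname(quantile(css, 0.95, type = 7))
}

#' Administered equivalent dose for one assay endpoint
#'
#' AED95 = bioactive concentration (uM) x 1 mg/kg/d / Css95 (uM): the daily
#' oral dose at which the population-conservative (95th percentile) plasma
#' concentration reaches the endpoint's activity concentration at cutoff.
#'
#' @param acc_uM activity concentration(s) at cutoff, uM.
#' @param css95_uM Css95 per unit dose, uM per (mg/kg/d).
#' @return dose(s), mg/kg/d.
#' @export
aed95_per_endpoint <- function(acc_uM, css95_uM) {
  if (any(acc_uM <= 0, na.rm = TRUE) || any(css95_uM <= 0, na.rm = TRUE))
    stop("acc_uM and css95_uM must be > 0")
  acc_uM / css95_uM
}

#' Chemical-level AED floor (5th percentile across endpoints)
#'
#' The dose floor used in EAR_MED is the 5th percentile
#' (linear-interpolation quantile) of a chemical's AED95 values across all
#' retained endpoints — a conservative lower-bound effect dose.
#'
#' @param aed95 numeric vector of per-endpoint AED95 values, mg/kg/d.
#' @return 5th percentile, mg/kg/d.
#' @export
chemical_aed_floor <- function(aed95) {
  if (length(aed95) == 0)
    stop("no AED95 values: chemical lacks toxicokinetic coverage")
  unname(quantile(aed95, 0.05, type = 7))
}

#' AED95 table and per-chemical dose floors
#'
#' For every chemical with both retained ACC endpoints and complete TK
#' parameters, computes Css95 per unit dose, per-endpoint AED95, and the
#' 5th-percentile AED floor.  Chemicals missing molecular weight, fraction
#' unbound, or intrinsic clearance are skipped and listed in the
#' `uncovered` attribute.  Each chemical draws its Monte Carlo sample from
#' a sub-seed derived deterministically from `var$seed`, so results do not
#' depend on table order.
#'
#' @param acc filtered ACC records (uM values present or derivable).
#' @param tk TK parameter table (see [read_tk_params()]).
#' @param catalog analyte catalog (molecular weights for unit completion).
#' @param phys physiology list.
#' @param var a [variability_spec()].
#' @return list with `aed`: data.frame (`analyte_id`, `endpoint_id`,
#'   `acc_uM`, `css95_uM`, `aed95`); and `floors`: data.frame
#'   (`analyte_id`, `css95_uM`, `aed_floor`, `n_endpoints`).  Attribute
#'   `uncovered` lists skipped analyte ids.
#' @export
compute_aed_floors <- function(acc, tk, catalog, phys = default_physiology(),
                               var = variability_spec()) {
  acc <- .complete_acc_units(acc, catalog)
  tk_ok <- tk[!is.na(tk$molecular_weight) & !is.na(tk$fraction_unbound) &
                !is.na(tk$intrinsic_clearance), , drop = FALSE]
  ids <- sort(intersect(unique(acc$analyte_id[!is.na(acc$acc_uM)]),
                        tk_ok$analyte_id))
  uncovered <- sort(setdiff(unique(acc$analyte_id), ids))
  aed_rows <- list()
  floor_rows <- list()
  for (id in ids) {
    tkr <- tk_ok[tk_ok$analyte_id == id, ][1, ]
    sub_seed <- (var$seed + sum(utf8ToInt(id)) * 131) %% .Machine$integer.max
    var_i <- var
    var_i$seed <- as.integer(sub_seed)
    css95 <- css95_monte_carlo(tkr, phys, var_i)
    a <- acc[acc$analyte_id == id & !is.na(acc$acc_uM), , drop = FALSE]
    aed <- aed95_per_endpoint(a$acc_uM, css95)
    aed_rows[[id]] <- data.frame(analyte_id = id, endpoint_id = a$endpoint_id,
                                 acc_uM = a$acc_uM, css95_uM = css95,
                                 aed95 = aed, stringsAsFactors = FALSE)
    floor_rows[[id]] <- data.frame(analyte_id = id, css95_uM = css95,
                                   aed_floor = chemical_aed_floor(aed),
                                   n_endpoints = nrow(a),
                                   stringsAsFactors = FALSE)
  }
  aed <- if (length(aed_rows)) do.call(rbind, aed_rows) else
    data.frame(analyte_id = character(0), endpoint_id = character(0),
               acc_uM = numeric(0), css95_uM = numeric(0), aed95 = numeric(0))
  floors <- if (length(floor_rows)) do.call(rbind, floor_rows) else
    data.frame(analyte_id = character(0), css95_uM = numeric(0),
               aed_floor = numeric(0), n_endpoints = integer(0))
  rownames(aed) <- rownames(floors) <- NULL
  out <- list(aed = aed, floors = floors)
  attr(out, "uncovered") <- uncovered
  out
}

#' Per-sample toxicokinetically adjusted cumulative EAR
#'
#' For every detected organic chemical with an AED floor, EAR_MED =
#' MED / AED floor; included chemicals (EAR_MED >= 1e-5) are summed per
#' sample, with threshold flags at 0.001 and 1 and a driver ranking, as in
#' the other cumulative screens.
#'
#' @param ds a `dw_dataset`.
#' @param floors `floors` data.frame from [compute_aed_floors()].
#' @param samples sample roster; defaults to `ds$samples`.
#' @return list with `per_chemical`: data.frame (`sample_id`,
#'   `supply_class`, `analyte_id`, `concentration`, `med`, `aed_floor`,
#'   `ear_med`, `included`); and `per_sample`: data.frame (`sample_id`,
#'   `supply_class`, `sum_ear_med`, `n_ear_med_over_1`, `exceeds_0p001`,
#'   `exceeds_1`, list column `driver_ranking`).
#' @export
summarize_sample_ear_med <- function(ds, floors, samples = ds$samples) {
  organic_classes <- setdiff(.ANALYTE_CLASSES, c("inorganic", "microbial"))
  det <- detected_concentrations(ds, classes = organic_classes)
  det <- det[det$analyte_id %in% floors$analyte_id, , drop = FALSE]
  fl <- setNames(floors$aed_floor, floors$analyte_id)
  per <- data.frame(sample_id = det$sample_id,
                    supply_class = det$supply_class,
                    analyte_id = det$analyte_id,
                    concentration = det$concentration,
                    med = compute_med(det$concentration),
                    aed_floor = unname(fl[det$analyte_id]),
                    stringsAsFactors = FALSE)
  per$ear_med <- per$med / per$aed_floor
  per$included <- per$ear_med >= .TQ_INCLUSION_FLOOR
  per_sample <- .summarize_sample_quotients(per, samples, "ear_med",
                                            c(0.001, 1))
  names(per_sample)[names(per_sample) == "sum"] <- "sum_ear_med"
  names(per_sample)[names(per_sample) == "n_over_1"] <- "n_ear_med_over_1"
  list(per_chemical = per, per_sample = per_sample)
}
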