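# Published regional reference standards for fertigated banana and the
# norm-set container used throughout calibration and diagnosis.

#' Canonical tissue part labels
#'
#' The 13 quantified leaf-tissue elements in canonical order, optionally
#' followed by the filling value `Fv`.
#'
#' @param with_fv Include the filling value label (default `TRUE`).
#' @return Character vector of part labels.
#' @export
tissue_parts <- function(with_fv = TRUE) {
  p <- c("N", "S", "P", "K", "Mg", "Ca",
         "Cu", "Zn", "Mn", "Fe", "Al", "B", "Na")
  if (with_fv) c(p, "Fv") else p
}

#' Native reporting units of the tissue elements
#'
#' Laboratory convention: macronutrients in g kg^-1, micronutrients and
#' non-essential elements in mg kg^-1. Internally everything is converted to
#' mg kg^-1 before closure to 10^6 mg kg^-1.
#'
#' @return Named character vector mapping element to `"g/kg"` or `"mg/kg"`.
#' @export
tissue_units <- function() {
  stats::setNames(
    c(rep("g/kg", 6), rep("mg/kg", 7)),
    tissue_parts(with_fv = FALSE)
  )
}

#' Default yield cut-offs separating high from low yielders
#'
#' kg ha^-1 semester^-1 per cultivar subgroup.
#'
#' @return Named numeric vector.
#' @export
yield_cutoffs <- function() {
  c(Prata = 17500, Cavendish = 25000)
}

#' Regional clr norm set
#'
#' Container for regional CND standards: per-component clr means and
#' standard deviations for one cultivar, with the specimen count and the
#' confusion-quadrant policy (`"TN"` or `"TN+FN"`) that selected the
#' reference subpopulation.
#'
#' @param cultivar Cultivar name.
#' @param labels Component labels (tissue elements plus `Fv`).
#' @param clr_mean,clr_sd Numeric vectors, one value per label. Means must
#'   sum to zero within 0.005 (printed standards round to 4 decimals); SDs
#'   must be positive. Zero SDs (degenerate, e.g. identical specimens) are
#'   accepted with a warning.
#' @param n Number of specimens behind the norms.
#' @param policy Which quadrants defined the reference subpopulation.
#' @return Object of class `norm_set`.
#' @export
norm_set <- function(cultivar, labels, clr_mean, clr_sd, n,
                     policy = c("TN+FN", "TN")) {
  policy <- match.arg(policy)
  stopifnot(length(labels) == length(clr_mean),
            length(labels) == length(clr_sd))
  if (abs(sum(clr_mean)) > 0.005) {
    stop("clr means sum to ", sum(clr_mean), "; not centered")
  }
  if (any(clr_sd < 0)) stop("negative clr SD")
  if (any(clr_sd == 0)) warning("degenerate norm set: zero SD component(s)")
  structure(
    list(cultivar = cultivar, labels = labels,
         clr_mean = stats::setNames(as.numeric(clr_mean), labels),
         clr_sd = stats::setNames(as.numeric(clr_sd), labels),
         n = n, policy = policy),
    class = "norm_set"
  )
}

#' @export
print.norm_set <- function(x, ...) {
  cat("regional clr norms for \"", x$cultivar, "\" (n = ", x$n,
      ", policy ", x$policy, ")\n", sep = "")
  print(data.frame(component = x$labels, clr_mean = x$clr_mean,
                   clr_sd = x$clr_sd, row.names = NULL), ...)
  invisible(x)
}

#' Published regional clr standards for banana
#'
#' Regional centered log-ratio means and standard deviations of the
#' nutritionally balanced (TN and FN) specimens, by cultivar subgroup
#' ("Prata": n = 462; "Cavendish": n = 70), over the 13 tissue elements plus
#' the filling value closed to 10^6 mg kg^-1.
#'
#' @param cultivar `"Prata"` or `"Cavendish"`.
#' @return A [norm_set()].
#' @export
banana_clr_norms <- function(cultivar = c("Prata", "Cavendish")) {
  cultivar <- match.arg(cultivar)
  labels <- tissue_parts()
  if (cultivar == "Prata") {
    m <- c(3.6912, 1.0265, 1.1192, 4.0906, 1.4888, 2.4570,
           -4.5820, -3.5007, -1.3624, -2.1283, -3.1097, -4.0284,
           -2.6115, 7.4495)
    s <- c(0.1306, 0.1240, 0.1389, 0.1838, 0.1489, 0.1908,
           0.2233, 0.1744, 0.5945, 0.1355, 0.4142, 0.3887,
           0.4981, 0.1214)
    n <- 462
  } else {
    m <- c(3.6639, 1.0080, 1.0940, 4.1750, 1.5314, 2.6655,
           -4.6557, -3.5622, -1.6231, -2.0954, -3.0136, -4.0743,
           -2.5281, 7.4146)
    s <- c(0.1194, 0.1162, 0.1360, 0.1952, 0.1582, 0.3049,
           0.2122, 0.1874, 0.6839, 0.1345, 0.4710, 0.3555,
           0.4104, 0.1198)
    n <- 70
  }
  norm_set(cultivar, labels, m, s, n, policy = "TN+FN")
}

#' Published median tissue concentrations
#'
#' Cultivar-wise medians of the observed leaf concentrations, in native
#' units (macronutrients g kg^-1, micronutrients mg kg^-1).
#'
#' @param cultivar `"Prata"` or `"Cavendish"`.
#' @return Named numeric vector over the 13 elements.
#' @export
banana_tissue_medians <- function(cultivar = c("Prata", "Cavendish")) {
  cultivar <- match.arg(cultivar)
  if (cultivar == "Prata") {
    v <- c(N = 21.9, S = 1.5, P = 1.6, K = 34.2, Mg = 2.4, Ca = 6.2,
           Cu = 5.2, Zn = 16.1, Mn = 119.9, Fe = 64.0, Al = 23.3,
           B = 10.0, Na = 49.6)
  } else {
    v <- c(N = 21.9, S = 1.6, P = 1.6, K = 37.4, Mg = 2.6, Ca = 8.2,
           Cu = 5.2, Zn = 15.6, Mn = 82.1, Fe = 66.6, Al = 26.7,
           B = 10.2, Na = 50.0)
  }
  v
}

#' Convert native-unit tissue concentrations to a closed composition
#'
#' Converts g kg^-1 columns to mg kg^-1, appends the filling value and
#' closes to 10^6 mg kg^-1.
#'
#' @param conc Named numeric vector over the 13 elements in native units
#'   (see [tissue_units()]).
#' @return A 14-part [composition()] (elements + `Fv`, kappa 10^6).
#' @export
tissue_composition <- function(conc) {
  units <- tissue_units()
  miss <- setdiff(names(units), names(conc))
  if (length(miss)) stop("missing element(s): ", paste(miss, collapse = ", "))
  conc <- conc[names(units)]
  mg <- ifelse(units == "g/kg", conc * 1000, conc)
  add_fill_value(stats::setNames(as.numeric(mg), names(units)), kappa = 1e6)
}

#' Median tissue composition of a cultivar
#'
#' [banana_tissue_medians()] mapped through [tissue_composition()].
#'
#' @inheritParams banana_tissue_medians
#' @return A 14-part [composition()].
#' @export
banana_median_composition <- function(cultivar = c("Prata", "Cavendish")) {
  tissue_composition(banana_tissue_medians(cultivar))
}

#' Published soil property statistics
#'
#' Means and standard deviations of the soil properties of the fertigated
#' plots, by cultivar subgroup.
#'
#' @return Data frame with columns `cultivar`, `property`, `unit`, `mean`,
#'   `sd`.
#' @export
banana_soil_stats <- function() {
  props <- c("pH", "OM", "P", "K", "Mg", "Ca", "CEC")
  units <- c("pH_water", "g/dm3", rep("mg/dm3", 4), "cmolc/dm3")
  prata_m <- c(7.19, 22.0, 119.2, 176.5, 171.6, 1141.2, 8.71)
  prata_s <- c(0.31, 6.9, 54.1, 111.4, 114.3, 607.1, 4.14)
  cav_m <- c(7.26, 17.8, 114.6, 154.2, 128.0, 944.2, 7.20)
  cav_s <- c(0.30, 6.5, 44.6, 97.9, 84.7, 621.3, 4.01)
  rbind(
    data.frame(cultivar = "Prata", property = props, unit = units,
               mean = prata_m, sd = prata_s),
    data.frame(cultivar = "Cavendish", property = props, unit = units,
               mean = cav_m, sd = cav_s)
  )
}

#' Published compatibility intervals (quartile concentration ranges)
#'
#' Q25-Q75 concentration ranges of the nutritionally balanced (TN and FN)
#' specimens, in native units.
#'
#' @param cultivar `"Prata"` or `"Cavendish"`.
#' @return Data frame with columns `component`, `unit`, `q25`, `q75`.
#' @export
banana_compatibility_intervals <- function(cultivar = c("Prata", "Cavendish")) {
  cultivar <- match.arg(cultivar)
  units <- tissue_units()
  if (cultivar == "Prata") {
    q25 <- c(20.6, 1.4, 1.5, 29.3, 2.2, 5.7, 5, 15, 95, 59, 18, 8, 30)
    q75 <- c(22.8, 1.6, 1.8, 37.0, 2.7, 7.1, 6, 19, 231, 70, 31, 13, 60)
  } else {
    q25 <- c(20.7, 1.4, 1.6, 32.0, 2.4, 7.1, 4, 14, 69, 62, 22, 8, 30)
    q75 <- c(22.8, 1.6, 1.8, 41.6, 2.9, 9.4, 6, 18, 184, 75, 40, 12, 66)
  }
  out <- data.frame(component = names(units), unit = unname(units),
                    q25 = q25, q75 = q75)
  stopifnot(all(out$q25 <= out$q75))
  out
}

#' Packaged tissue balance scheme
#'
#' Sequential binary partition over the 14 tissue parts, following the
#' published dendrogram design: the filling value is contrasted first, then
#' elements originating from well water and soil mineralogy (Na, B, Al, Fe)
#' against the fertilizer-managed nutrients, macronutrients against cationic
#' micronutrients, cationic macroelements against anionic N, S, P, the K-Mg
#' antagonism and the N-P (Redfield) ratio. The exact ordering is an
#' interpretation of the published dendrogram figure.
#'
#' @return A [balance_scheme()].
#' @export
tissue_sbp <- function() {
  read_sbp(system.file("extdata", "sbp_tissue.csv", package = "cndiag",
                       mustWork = TRUE))
}

#' Packaged soil balance scheme
#'
#' Sequential binary partition over a 7-part soil composition (organic
#' matter, P, K, Ca, Mg, exchangeable acidity, filling value): organic
#' matter is contrasted with the mineral pool, the lime requirement appears
#' as exchangeable cations against exchangeable acidity, and the Ca:Mg
#' liming balance closes the design. Interpretive reading of the published
#' dendrogram figure.
#'
#' @return A [balance_scheme()].
#' @export
soil_sbp <- function() {
  read_sbp(system.file("extdata", "sbp_soil.csv", package = "cndiag",
                       mustWork = TRUE))
}

#' Phloem-mobility balance groups
#'
#' Mobile nutrients (N, P, K, Mg) against relatively immobile ones (Ca, B);
#' use with [balance_value()]. The coefficient is `sqrt(4 * 2 / 6)`.
#'
#' @return List with elements `plus` (mobile) and `minus` (immobile).
#' @export
mobility_balance <- function() {
  list(plus = c("N", "P", "K", "Mg"), minus = c("Ca", "B"))
}
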