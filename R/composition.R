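# Core compositional types: closed compositions, clr vectors, perturbation.

#' Create a closed composition
#'
#' A composition is a vector of strictly positive parts carrying a common
#' measurement unit and closed (scaled) to a constant `kappa`, e.g. leaf
#' tissue concentrations in mg kg^-1 closed to 10^6 mg kg^-1 of dry matter.
#'
#' @param values Named numeric vector of strictly positive parts. Names are
#'   the part labels and must be unique; at least two parts are required.
#' @param kappa Closure constant (positive scalar), e.g. `1e6` for mg kg^-1.
#' @param close If `TRUE` (default) values are rescaled so they sum to
#'   `kappa`. If `FALSE` the values must already sum to `kappa` to within a
#'   relative tolerance of 1e-9.
#' @return An object of class `composition`: a named numeric vector summing
#'   to `kappa`, with attribute `kappa`.
#' @examples
#' composition(c(a = 1, b = 1, c = 2), kappa = 1)
#' @export
composition <- function(values, kappa = 1e6, close = TRUE) {
  if (length(values) < 2L) {
    stop("a composition needs at least 2 parts, got ", length(values))
  }
  labels <- names(values)
  if (is.null(labels) || anyNA(labels) || any(labels == "")) {
    stop("all parts must be named")
  }
  if (anyDuplicated(labels)) {
    stop("duplicated part labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0) {
    stop("kappa must be a positive scalar")
  }
  bad <- !is.finite(values) | values <= 0
  if (any(bad)) {
    stop("nonpositive or non-finite part(s): ",
         paste(labels[bad], collapse = ", "))
  }
  values <- as.numeric(values)
  names(values) <- labels
  if (close) {
    values <- values * (kappa / sum(values))
  } else if (abs(sum(values) - kappa) > 1e-9 * kappa) {
    stop("values sum to ", sum(values), ", not to kappa = ", kappa,
         "; use close = TRUE to rescale")
  }
  structure(values, kappa = kappa, class = "composition")
}

#' Close a vector of parts to a constant
#'
#' Proportional rescaling of strictly positive parts so they sum to `kappa`.
#'
#' @inheritParams composition
#' @return A [composition()].
#' @export
close_composition <- function(values, kappa = 1e6) {
  composition(values, kappa = kappa, close = TRUE)
}

#' @export
print.composition <- function(x, ...) {
  cat("composition of", length(x), "parts, closed to kappa =",
      format(attr(x, "kappa")), "\n")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Closure constant of a composition
#' @param x A `composition`.
#' @return The closure constant `kappa`.
#' @export
comp_kappa <- function(x) {
  stopifnot(inherits(x, "composition"))
  attr(x, "kappa")
}

#' Filling value closing a measured tissue composition
#'
#' Tissue tests quantify a handful of elements; the remainder of the dry
#' matter (C, H, O, ...) is represented by a filling value
#' `Fv = kappa - sum(measured)` so the measured parts plus `Fv` close
#' exactly to the measurement scale.
#'
#' @param measured Named numeric vector of measured concentrations, all in
#'   the unit of `kappa` (mg kg^-1 when `kappa = 1e6`).
#' @param kappa Measurement scale; defaults to `1e6` mg kg^-1.
#' @return The filling value, a positive scalar.
#' @examples
#' fill_value(c(N = 21900, K = 34200), kappa = 1e6)
#' @export
fill_value <- function(measured, kappa = 1e6) {
  if (length(measured) == 0L) stop("no measured parts supplied")
  bad <- !is.finite(measured) | measured <= 0
  if (any(bad)) {
    stop("nonpositive or non-finite part(s): ",
         paste(names(measured)[bad], collapse = ", "))
  }
  tot <- sum(measured)
  if (tot >= kappa) {
    stop("measured parts sum to ", tot, " >= kappa = ", kappa,
         "; impossible composition (check measurement units)")
  }
  kappa - tot
}

#' Append the filling value and close
#'
#' @inheritParams fill_value
#' @param label Label for the filling part (default `"Fv"`).
#' @return A [composition()] of the measured parts plus the filling value,
#'   closed to `kappa`.
#' @export
add_fill_value <- function(measured, kappa = 1e6, label = "Fv") {
  if (label %in% names(measured)) {
    stop("part '", label, "' already present")
  }
  fv <- fill_value(measured, kappa)
  composition(c(measured, stats::setNames(fv, label)), kappa = kappa,
              close = FALSE)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Centered log-ratio (clr) transform
#'
#' `clr_i = ln(x_i / G)` where `G` is the geometric mean over all parts.
#' The clr vector sums to zero and is invariant to the closure constant.
#'
#' @param x A [composition()].
#' @return A named numeric vector of class `clr`, summing to zero.
#' @export
clr_transform <- function(x) {
  stopifnot(inherits(x, "composition"))
  v <- log(as.numeric(x)) - mean(log(as.numeric(x)))
  structure(stats::setNames(v, names(x)), class = "clr")
}

#' @export
print.clr <- function(x, ...) {
  cat("clr vector (", length(x), " parts, sum ",
      format(sum(as.numeric(x)), digits = 3), ")\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Inverse clr transform
#'
#' Maps a zero-sum clr vector back to the simplex:
#' `close(exp(v), kappa)`. Vectors whose sum deviates from zero by at most
#' `1e-6` are re-centered (with a message); larger deviations are rejected
#' as likely unit errors.
#'
#' @param v Named numeric vector (clr scale).
#' @param kappa Closure constant for the output composition.
#' @return A [composition()].
#' @export
clr_inverse <- function(v, kappa = 1e6) {
  s <- sum(v)
  if (abs(s) > 1e-6) {
    stop("clr vector sums to ", s, " (|sum| > 1e-6); not a clr vector")
  }
  labels <- names(v)
  v <- as.numeric(v)
  if (abs(s) > 1e-12) {
    message("re-centering clr vector (sum = ", format(s), ")")
    v <- v - mean(v)
  }
  composition(stats::setNames(exp(v), labels), kappa = kappa, close = TRUE)
}

#' Difference between two compositions on the clr scale
#'
#' `clr(diagnosed) - clr(reference)`. More negative components indicate
#' relative shortage of that nutrient in the diagnosed composition; more
#' positive components indicate relative excess.
#'
#' @param diagnosed,reference [composition()] objects with identical labels.
#' @return A named numeric vector of class `clr` (sums to zero).
#' @export
clr_difference <- function(diagnosed, reference) {
  check_same_labels(diagnosed, reference)
  d <- as.numeric(clr_transform(diagnosed)) - as.numeric(clr_transform(reference))
  structure(stats::setNames(d, names(diagnosed)), class = "clr")
}

#' Perturbation vector between two compositions
#'
#' The componentwise ratio `X_i / x_i` between the diagnosed composition `X`
#' and a reference composition `x`, both closed to the same constant. Ratios
#' above 1 flag relative excess, below 1 relative shortage. This is the
#' Aitchison-geometry difference operator between compositions.
#'
#' @param diagnosed,reference [composition()] objects with identical labels
#'   and equal closure constants.
#' @return Named numeric vector of class `perturbation` (strictly positive).
#' @export
perturbation <- function(diagnosed, reference) {
  check_same_labels(diagnosed, reference)
  if (!isTRUE(all.equal(comp_kappa(diagnosed), comp_kappa(reference)))) {
    stop("compositions are closed to different constants (",
         comp_kappa(diagnosed), " vs ", comp_kappa(reference),
         "); ratios would mix units")
  }
  structure(stats::setNames(as.numeric(diagnosed) / as.numeric(reference),
                            names(diagnosed)),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat("perturbation vector (ratios; <1 shortage, >1 excess)\n")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Deviation from Optimum Percentage (DOP)
#'
#' `100 * c / c_ref - 100`: the single-nutrient percentage deviation of a
#' diagnosed concentration from a reference concentration.
#'
#' @param c_diag Diagnosed concentration (positive).
#' @param c_ref Reference concentration (positive, same unit).
#' @return Percentage deviation (0 when equal, 50 when 1.5x the reference).
#' @export
dop <- function(c_diag, c_ref) {
  if (any(!is.finite(c_diag) | c_diag <= 0) ||
      any(!is.finite(c_ref) | c_ref <= 0)) {
    stop("concentrations must be strictly positive")
  }
  100 * c_diag / c_ref - 100
}

check_same_labels <- function(a, b) {
  if (!identical(names(a), names(b))) {
    stop("part labels differ between the two compositions")
  }
  invisible(TRUE)
}
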