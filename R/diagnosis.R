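# Regional (CND index) and local (closest-successful-neighbor) diagnosis.

#' CND indices of a specimen against regional norms
#'
#' `I_i = (clr_i - clr*_i) / SD*_i`. More negative indices flag relative
#' nutrient shortage, more positive indices relative excess.
#'
#' @param specimen A 14-part [composition()] (or any composition whose
#'   labels match the norms).
#' @param norms A [norm_set()].
#' @return Named numeric vector of indices.
#' @export
cnd_indices <- function(specimen, norms) {
  stopifnot(inherits(specimen, "composition"), inherits(norms, "norm_set"))
  if (!identical(names(specimen), norms$labels)) {
    stop("specimen labels do not match the norm set")
  }
  zero <- norms$clr_sd == 0
  if (any(zero)) {
    stop("zero norm SD for component(s): ",
         paste(norms$labels[zero], collapse = ", "))
  }
  (as.numeric(clr_transform(specimen)) - norms$clr_mean) / norms$clr_sd
}

#' CND nutrient imbalance index
#'
#' The sum of squared CND indices; zero for a specimen at the norm centroid.
#'
#' @param indices Numeric vector from [cnd_indices()].
#' @return Nonnegative scalar.
#' @export
cnd_nii <- function(indices) {
  if (any(!is.finite(indices))) stop("indices must be finite")
  sum(indices^2)
}

#' Squared Mahalanobis imbalance distance in ilr coordinates
#'
#' `M^2 = (ilr - ilr*)' COV^-1 (ilr - ilr*)`. Under a Gaussian reference
#' population M^2 is distributed as chi-square with D-1 degrees of freedom.
#' A near-singular covariance is ridge-regularized (with a message) before
#' inversion.
#'
#' @param specimen A [composition()].
#' @param ilr_mean Reference ilr mean vector.
#' @param ilr_cov Reference ilr covariance matrix (symmetric positive
#'   definite).
#' @param scheme A [balance_scheme()] matching the specimen labels.
#' @param ridge Relative ridge added to the diagonal when the covariance is
#'   numerically singular.
#' @return Nonnegative scalar.
#' @export
mahalanobis_imbalance <- function(specimen, ilr_mean, ilr_cov, scheme,
                                  ridge = 1e-8) {
  v <- as.numeric(ilr_transform(specimen, scheme))
  stopifnot(length(v) == length(ilr_mean),
            all(dim(ilr_cov) == length(v)))
  if (max(abs(ilr_cov - t(ilr_cov))) > 1e-8 * max(abs(ilr_cov))) {
    stop("covariance matrix is not symmetric")
  }
  d <- v - as.numeric(ilr_mean)
  inv <- tryCatch(solve(ilr_cov), error = function(e) NULL)
  if (is.null(inv)) {
    message("near-singular covariance; applying ridge regularization")
    reg <- ilr_cov + diag(ridge * mean(diag(ilr_cov)), nrow(ilr_cov))
    inv <- tryCatch(solve(reg), error = function(e)
      stop("covariance remains singular after ridge regularization"))
  }
  drop(t(d) %*% inv %*% d)
}

#' Regional CND diagnosis of a specimen
#'
#' @param specimen A [composition()].
#' @param norms A [norm_set()].
#' @param ilr_reference Optional list with `mean`, `cov` and `scheme` for
#'   the Mahalanobis distance (e.g. from a calibrated population).
#' @param probability_high Optional classifier probability of the high-yield
#'   class for this specimen.
#' @return Object of class `regional_diagnosis`: indices, `nii`,
#'   `m_squared` (or `NA`), shortage-first component ranking and the norm
#'   provenance.
#' @export
regional_diagnose <- function(specimen, norms, ilr_reference = NULL,
                              probability_high = NULL) {
  idx <- cnd_indices(specimen, norms)
  m2 <- NA_real_
  if (!is.null(ilr_reference)) {
    m2 <- mahalanobis_imbalance(specimen, ilr_reference$mean,
                                ilr_reference$cov, ilr_reference$scheme)
  }
  structure(
    list(indices = idx,
         nii = cnd_nii(idx),
         m_squared = m2,
         probability_high = probability_high,
         ranking = names(idx)[order(idx, seq_along(idx))],
         cultivar = norms$cultivar,
         policy = norms$policy),
    class = "regional_diagnosis"
  )
}

#' @export
print.regional_diagnosis <- function(x, ...) {
  cat("regional CND diagnosis (\"", x$cultivar, "\", policy ", x$policy,
      ")\n", sep = "")
  cat("NII =", round(x$nii, 3),
      if (!is.na(x$m_squared)) paste(" M^2 =", round(x$m_squared, 3)), "\n")
  cat("shortage -> excess:", paste(x$ranking, collapse = " < "), "\n")
  invisible(x)
}

#' Neighbor query settings for local diagnosis
#'
#' @param mandatory_keys Record columns that must match the diagnosed record
#'   exactly (default `"cultivar"`).
#' @param optional_keys Columns matched when possible: candidates matching
#'   them are preferred, but the filter is dropped (with a message) if it
#'   empties the candidate set.
#' @param success `"TN"`: successful means the TN confusion quadrant
#'   (requires quadrants from a calibration; falls back to actual-high when
#'   none are supplied) or `"actual-high"`: observed yield at or above the
#'   cultivar cut-off.
#' @param k Number of neighbors (default 1, the closest successful one).
#' @param space `"clr"` or `"ilr"`; the distance is identical, `"ilr"`
#'   requires `scheme`.
#' @param scheme Optional [balance_scheme()] for `space = "ilr"`.
#' @param soil_weight Weight `w` in `[0, 1]` of the z-scored soil Euclidean
#'   distance: `d = (1 - w) d_tissue + w d_soil` (default 0, tissue only).
#' @return Object of class `neighbor_query`.
#' @export
neighbor_query <- function(mandatory_keys = "cultivar",
                           optional_keys = character(),
                           success = c("TN", "actual-high"),
                           k = 1L, space = c("clr", "ilr"),
                           scheme = NULL, soil_weight = 0) {
  success <- match.arg(success)
  space <- match.arg(space)
  if (k < 1) stop("k must be >= 1")
  if (soil_weight < 0 || soil_weight > 1) {
    stop("soil_weight must lie in [0, 1]")
  }
  if (space == "ilr" && is.null(scheme)) {
    stop("space = 'ilr' requires a balance scheme")
  }
  structure(list(mandatory_keys = mandatory_keys,
                 optional_keys = optional_keys, success = success,
                 k = as.integer(k), space = space, scheme = scheme,
                 soil_weight = soil_weight),
            class = "neighbor_query")
}

#' Closest successful neighbors of a diagnosed record
#'
#' Filters the reference table to candidates matching the diagnosed record
#' on the mandatory keys and qualifying as successful (TN quadrant, or
#' observed high yield), excludes the diagnosed record itself, and returns
#' the k candidates at smallest distance
#' `(1 - w) * Aitchison(tissue) + w * Euclidean(z-scored soil)`,
#' ties broken by record id.
#'
#' @param diagnosed One-row observation record (data frame).
#' @param reference Observation table of candidate records.
#' @param query A [neighbor_query()].
#' @param quadrants Optional confusion quadrants aligned with `reference`
#'   (from [calibrate()]), used when `query$success == "TN"`.
#' @param cutoffs Yield cut-offs for the actual-high success rule.
#' @return Object of class `neighbor_set`: data frame `neighbors`
#'   (`record_id`, `distance`, `yield`), the selected `records`, and the
#'   query.
#' @export
find_successful_neighbors <- function(diagnosed, reference, query = neighbor_query(),
                                      quadrants = NULL,
                                      cutoffs = yield_cutoffs()) {
  stopifnot(nrow(diagnosed) == 1L)
  cand <- reference
  qd <- quadrants
  for (key in query$mandatory_keys) {
    keep <- cand[[key]] == diagnosed[[key]]
    cand <- cand[keep, , drop = FALSE]
    if (!is.null(qd)) qd <- qd[keep]
    if (nrow(cand) == 0) {
      stop("no candidates left after matching on '", key, "'")
    }
  }
  if (query$success == "TN" && !is.null(qd)) {
    keep <- qd == "TN"
  } else {
    if (query$success == "TN" && is.null(qd)) {
      message("no quadrants supplied; falling back to actual-high success")
    }
    keep <- classify_yield(cand$yield, cand$cultivar, cutoffs) == "high"
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) stop("no candidates left after the success filter")
  if (!is.null(diagnosed$record_id) && !is.null(cand$record_id)) {
    cand <- cand[cand$record_id != diagnosed$record_id, , drop = FALSE]
    if (nrow(cand) == 0) {
      stop("the diagnosed record was the only successful candidate")
    }
  }
  for (key in query$optional_keys) {
    keep <- cand[[key]] == diagnosed[[key]]
    if (any(keep)) {
      cand <- cand[keep, , drop = FALSE]
    } else {
      message("optional key '", key, "' matched no candidate; dropped")
    }
  }
  ids <- if (is.null(cand$record_id)) {
    as.character(seq_len(nrow(cand)))
  } else {
    cand$record_id
  }
  d <- neighbor_distances(diagnosed, cand, query)
  ord <- order(d, ids)
  k <- min(query$k, nrow(cand))
  sel <- ord[seq_len(k)]
  structure(
    list(neighbors = data.frame(record_id = ids[sel],
                                distance = d[sel],
                                yield = cand$yield[sel]),
         records = cand[sel, , drop = FALSE],
         query = query),
    class = "neighbor_set"
  )
}

neighbor_distances <- function(diagnosed, candidates, query) {
  clr_d <- drop(records_clr_matrix(diagnosed))
  clr_c <- records_clr_matrix(candidates)
  if (query$space == "ilr") {
    psi <- contrast_matrix(query$scheme)
    clr_d <- drop(psi %*% clr_d)
    clr_c <- clr_c %*% t(psi)
  }
  d_tissue <- sqrt(rowSums(sweep(clr_c, 2, clr_d)^2))
  w <- query$soil_weight
  if (w == 0) return(d_tissue)
  soil_cols <- grep("^soil_", names(candidates), value = TRUE)
  if (!length(soil_cols)) stop("soil_weight > 0 but no soil_* columns")
  mu <- colMeans(candidates[, soil_cols, drop = FALSE])
  sdv <- pmax(apply(candidates[, soil_cols, drop = FALSE], 2, stats::sd),
              1e-8)
  zc <- sweep(sweep(as.matrix(candidates[, soil_cols]), 2, mu), 2, sdv, "/")
  zd <- (as.numeric(diagnosed[, soil_cols]) - mu) / sdv
  d_soil <- sqrt(rowSums(sweep(zc, 2, zd)^2))
  (1 - w) * d_tissue + w * d_soil
}

#' Local (plot-scale) diagnosis against successful neighbors
#'
#' Compares the diagnosed tissue composition with its closest successful
#' benchmark: the single nearest neighbor (k = 1) or the closed geometric
#' mean composition of the k neighbors (the Aitchison-coherent average).
#' Nutrients are ranked by the perturbation vector, shortage (smallest
#' ratio) first; the clr differences give the same ordering.
#'
#' @param diagnosed One-row observation record.
#' @param neighbors A `neighbor_set` from [find_successful_neighbors()].
#' @return Object of class `local_diagnosis`: `perturbation`, `clr_diff`,
#'   `expected_yield` (mean neighbor yield), `ranking`, `balanced` flag and
#'   neighbor provenance.
#' @export
local_diagnose <- function(diagnosed, neighbors) {
  stopifnot(inherits(neighbors, "neighbor_set"))
  comp_d <- record_composition(diagnosed)
  m <- records_tissue_matrix(neighbors$records)
  bench <- composition(exp(colMeans(log(m))), kappa = 1e6, close = TRUE)
  p <- perturbation(comp_d, bench)
  dclr <- clr_difference(comp_d, bench)
  structure(
    list(neighbors = neighbors$neighbors,
         benchmark = bench,
         perturbation = p,
         clr_diff = dclr,
         expected_yield = mean(neighbors$neighbors$yield),
         ranking = names(p)[order(as.numeric(p), seq_along(p))],
         balanced = max(abs(log(as.numeric(p)))) < 1e-8),
    class = "local_diagnosis"
  )
}

#' @export
print.local_diagnosis <- function(x, ...) {
  cat("local diagnosis vs", nrow(x$neighbors), "successful neighbor(s);",
      "expected yield", round(x$expected_yield), "kg/ha\n")
  if (x$balanced) {
    cat("diagnosed composition matches the benchmark (balanced)\n")
  } else {
    cat("shortage -> excess:", paste(x$ranking, collapse = " < "), "\n")
  }
  invisible(x)
}

#' Assemble a JSON-serializable diagnosis report
#'
#' Combines the regional and/or local diagnosis of one specimen. Shortage
#' flags for the non-essential elements Na and Al are suppressed (their
#' relative shortage is agronomically irrelevant); their excess flags are
#' retained for antagonism (K-Na) and toxicity (Al) screening.
#'
#' @param regional Optional `regional_diagnosis`.
#' @param local Optional `local_diagnosis`.
#' @param metadata Named list of specimen metadata (ids, cultivar, ...).
#' @return Object of class `diagnosis_report` (a plain nested list).
#' @export
build_report <- function(regional = NULL, local = NULL, metadata = list()) {
  if (is.null(regional) && is.null(local)) {
    stop("at least one diagnosis must be supplied")
  }
  non_essential <- c("Na", "Al")
  flag <- function(values, shortage_when_below) {
    f <- ifelse(values < shortage_when_below, "shortage",
                ifelse(values > shortage_when_below, "excess", "balanced"))
    f[names(values) %in% non_essential & f == "shortage"] <-
      "none (non-essential)"
    as.list(stats::setNames(f, names(values)))
  }
  rep_regional <- NULL
  if (!is.null(regional)) {
    rep_regional <- list(
      indices = as.list(regional$indices),
      nii = regional$nii,
      m_squared = if (is.na(regional$m_squared)) NULL
                  else regional$m_squared,
      probability_high = regional$probability_high,
      ranking = regional$ranking,
      flags = flag(regional$indices, 0),
      cultivar = regional$cultivar,
      norm_policy = regional$policy
    )
  }
  rep_local <- NULL
  if (!is.null(local)) {
    rep_local <- list(
      neighbors = lapply(seq_len(nrow(local$neighbors)), function(i)
        as.list(local$neighbors[i, ])),
      perturbation = as.list(stats::setNames(as.numeric(local$perturbation),
                                             names(local$perturbation))),
      clr_diff = as.list(stats::setNames(as.numeric(local$clr_diff),
                                         names(local$clr_diff))),
      expected_yield = local$expected_yield,
      ranking = local$ranking,
      balanced = local$balanced,
      flags = flag(stats::setNames(as.numeric(local$perturbation),
                                   names(local$perturbation)), 1)
    )
  }
  structure(list(metadata = metadata,
                 regional = rep_regional,
                 local = rep_local,
                 config_hash = report_hash(list(metadata, rep_regional,
                                                rep_local))),
            class = "diagnosis_report")
}

# Cheap polynomial rolling hash; provenance fingerprint for reports.
report_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a diagnosis report as JSON
#'
#' @param report A `diagnosis_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "diagnosis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a diagnosis report from JSON
#'
#' @param path Path to a report written by [write_report()].
#' @return A `diagnosis_report`.
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "diagnosis_report")
}
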