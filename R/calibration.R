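# Calibration of regional standards: yield classes, cross-validated
# classifier, confusion-matrix partition, clr norms and compatibility
# intervals.

#' Classify yields into high and low about the cultivar cut-off
#'
#' @param yield Numeric vector, kg ha^-1 semester^-1.
#' @param cultivar Character vector (recycled) of cultivar names.
#' @param cutoffs Named numeric vector of cut-offs; defaults to
#'   [yield_cutoffs()]. Ties (`yield == cutoff`) classify as high.
#' @return Factor with levels `low`, `high`.
#' @export
classify_yield <- function(yield, cultivar, cutoffs = yield_cutoffs()) {
  if (any(!is.finite(yield) | yield <= 0)) stop("yields must be positive")
  cultivar <- rep_len(as.character(cultivar), length(yield))
  unknown <- setdiff(unique(cultivar), names(cutoffs))
  if (length(unknown)) {
    stop("no yield cut-off for cultivar(s): ",
         paste(unknown, collapse = ", "))
  }
  factor(ifelse(yield >= cutoffs[cultivar], "high", "low"),
         levels = c("low", "high"))
}

# Closed tissue compositions (mg/kg incl. Fv) from an observation table.
records_tissue_matrix <- function(records) {
  units <- tissue_units()
  miss <- setdiff(names(units), names(records))
  if (length(miss)) {
    stop("missing tissue column(s): ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(records[, names(units), drop = FALSE])
  macro <- units == "g/kg"
  m[, macro] <- m[, macro] * 1000
  if (any(!is.finite(m) | m <= 0)) stop("nonpositive tissue concentration")
  tot <- rowSums(m)
  if (any(tot >= 1e6)) {
    stop("tissue rows sum to >= 10^6 mg kg^-1; check units")
  }
  m <- cbind(m, Fv = 1e6 - tot)
  m
}

# clr values of every record's closed tissue composition (rows sum to 0).
records_clr_matrix <- function(records) {
  m <- records_tissue_matrix(records)
  lm_ <- log(m)
  lm_ - rowMeans(lm_)
}

record_composition <- function(records, i = 1L) {
  m <- records_tissue_matrix(records)
  composition(m[i, ], kappa = 1e6, close = FALSE)
}

#' Cross-validated yield-class probabilities
#'
#' Fits a classifier of the high/low yield class in stratified k-fold
#' cross-validation and returns the out-of-fold probability of the high
#' class for every record. The default feature set is tissue-only (the 14
#' clr values), so "predicted high" reads as "nutritionally balanced";
#' categories and soil properties can be added for yield prediction.
#'
#' @param records Observation table (see [generate_dataset()] /
#'   [read_observations()]).
#' @param features Subset of `c("tissue", "soil", "cultivar", "year",
#'   "semester", "plot", "well")`.
#' @param learner `"rf"` (probability random forest) or `"nnet"`
#'   (single-hidden-layer feedforward network).
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param cutoffs Yield cut-offs, see [classify_yield()].
#' @return Numeric vector of out-of-fold probabilities of class high.
#' @export
fit_yield_classifier <- function(records, features = "tissue",
                                 learner = c("rf", "nnet"),
                                 folds = 10, seed = 1,
                                 cutoffs = yield_cutoffs()) {
  learner <- match.arg(learner)
  allowed <- c("tissue", "soil", "cultivar", "year", "semester",
               "plot", "well")
  bad <- setdiff(features, allowed)
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  y <- classify_yield(records$yield, records$cultivar, cutoffs)
  if (nlevels(droplevels(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 records in each yield class")
  }
  X <- build_feature_frame(records, features)
  n <- nrow(X)
  folds <- min(folds, min(table(y)))
  set.seed(seed)
  fold_id <- integer(n)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  prob <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    train <- !test
    if (learner == "rf") {
      fit <- ranger::ranger(
        x = X[train, , drop = FALSE], y = y[train],
        probability = TRUE, num.trees = 300,
        seed = seed + f, num.threads = 1
      )
      p <- stats::predict(fit, X[test, , drop = FALSE],
                          num.threads = 1)$predictions[, "high"]
    } else {
      Xn <- stats::model.matrix(~ . - 1, data = X)
      mu <- colMeans(Xn[train, , drop = FALSE])
      sdv <- pmax(apply(Xn[train, , drop = FALSE], 2, stats::sd), 1e-8)
      Xs <- sweep(sweep(Xn, 2, mu), 2, sdv, "/")
      set.seed(seed + f)
      fit <- nnet::nnet(Xs[train, , drop = FALSE],
                        as.numeric(y[train] == "high"),
                        size = 8, decay = 0.01, maxit = 300,
                        entropy = TRUE, trace = FALSE)
      p <- as.numeric(stats::predict(fit, Xs[test, , drop = FALSE]))
    }
    prob[test] <- p
  }
  prob
}

build_feature_frame <- function(records, features) {
  cols <- list()
  if ("tissue" %in% features) {
    clr <- records_clr_matrix(records)
    colnames(clr) <- paste0("clr_", colnames(clr))
    cols <- c(cols, as.data.frame(clr))
  }
  if ("soil" %in% features) {
    soil_cols <- grep("^soil_", names(records), value = TRUE)
    if (!length(soil_cols)) stop("no soil_* columns in the records")
    cols <- c(cols, as.data.frame(scale(records[, soil_cols])))
  }
  cat_map <- c(cultivar = "cultivar", year = "year", semester = "semester",
               plot = "plot_id", well = "well_id")
  for (f in intersect(features, names(cat_map))) {
    col <- cat_map[[f]]
    if (!col %in% names(records)) stop("missing column: ", col)
    cols[[col]] <- factor(records[[col]])
  }
  as.data.frame(cols)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with midranks for ties:
#' the probability that a randomly chosen high-class record scores above a
#' randomly chosen low-class record, ties counting one half.
#'
#' @param prob Numeric scores (higher = more likely high class).
#' @param actual Factor or character of actual classes (`high` positive).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(prob, actual) {
  pos <- actual == "high"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(prob, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix quadrant of each record
#'
#' Crosses the actual yield class with the predicted (nutritional) class:
#' `TN` = predicted high & actually high (the nutritionally balanced,
#' high-yield reference subpopulation); `FN` = predicted high & actually low
#' (yield limited by non-nutritional factors); `FP` = predicted low &
#' actually high (luxury consumption or contamination); `TP` = predicted low
#' & actually low (imbalance-driven yield loss).
#'
#' @param actual,predicted Factors/characters with values `low` / `high`.
#' @return Factor with levels `TN`, `FN`, `TP`, `FP`.
#' @export
partition_confusion <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  q <- ifelse(predicted == "high",
              ifelse(actual == "high", "TN", "FN"),
              ifelse(actual == "high", "FP", "TP"))
  factor(q, levels = c("TN", "FN", "TP", "FP"))
}

#' Classification accuracy from quadrant counts
#'
#' `(TN + TP) / (TN + FN + TP + FP)`.
#'
#' @param counts Named numeric vector or table with entries `TN`, `FN`,
#'   `TP`, `FP`.
#' @return Accuracy in `[0, 1]`.
#' @export
classification_accuracy <- function(counts) {
  counts <- counts[c("TN", "FN", "TP", "FP")]
  if (anyNA(counts)) stop("counts must be named TN, FN, TP, FP")
  total <- sum(counts)
  if (total == 0) stop("no records")
  unname((counts[["TN"]] + counts[["TP"]]) / total)
}

#' Chi-square test of the quadrant partition against equal distribution
#'
#' Pearson statistic `sum((O - E)^2 / E)` with `E = total / 4` and p-value
#' from the chi-square distribution with 3 degrees of freedom.
#'
#' @param counts Four nonnegative quadrant counts.
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_uniform <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 4, all(counts >= 0))
  if (sum(counts) == 0) stop("no records")
  ht <- suppressWarnings(stats::chisq.test(counts))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Regional clr norms from qualifying specimens
#'
#' Means and standard deviations of the clr values of the specimens in the
#' reference subpopulation of one cultivar: the TN quadrant, or TN and FN
#' merged (default, matching the published standards).
#'
#' @param records Observation table.
#' @param cultivar Cultivar to calibrate.
#' @param quadrants Optional factor from [partition_confusion()], aligned
#'   with `records`. When omitted, all records of the cultivar qualify (the
#'   caller has pre-filtered).
#' @param policy `"TN+FN"` (default) or `"TN"`.
#' @return A [norm_set()].
#' @export
compute_clr_norms <- function(records, cultivar, quadrants = NULL,
                              policy = c("TN+FN", "TN")) {
  policy <- match.arg(policy)
  keep <- qualifying_rows(records, cultivar, quadrants, policy)
  if (sum(keep) < 3L) {
    stop("only ", sum(keep), " qualifying specimen(s) for ", cultivar,
         "; need at least 3")
  }
  clr <- records_clr_matrix(records[keep, , drop = FALSE])
  norm_set(cultivar, colnames(clr), colMeans(clr),
           apply(clr, 2, stats::sd), n = sum(keep), policy = policy)
}

qualifying_rows <- function(records, cultivar, quadrants, policy) {
  keep <- records$cultivar == cultivar
  if (!is.null(quadrants)) {
    stopifnot(length(quadrants) == nrow(records))
    ok <- if (policy == "TN") "TN" else c("TN", "FN")
    keep <- keep & quadrants %in% ok
  }
  keep
}

#' Compatibility intervals (quartile concentration ranges)
#'
#' Q25 and Q75 of the native-unit concentrations of the qualifying
#' specimens, per element (linear-interpolation quantiles, type 7).
#'
#' @inheritParams compute_clr_norms
#' @return Data frame with columns `component`, `unit`, `q25`, `q75`.
#' @export
compute_compatibility_intervals <- function(records, cultivar,
                                            quadrants = NULL,
                                            policy = c("TN+FN", "TN")) {
  policy <- match.arg(policy)
  keep <- qualifying_rows(records, cultivar, quadrants, policy)
  if (sum(keep) < 4L) {
    stop("only ", sum(keep), " qualifying specimen(s) for ", cultivar,
         "; need at least 4")
  }
  units <- tissue_units()
  sub <- records[keep, names(units), drop = FALSE]
  q <- t(apply(sub, 2, stats::quantile, probs = c(0.25, 0.75),
               type = 7, names = FALSE))
  data.frame(component = names(units), unit = unname(units),
             q25 = q[, 1], q75 = q[, 2], row.names = NULL)
}

#' Components ranked by descending clr variability
#'
#' @param norms A [norm_set()].
#' @return Character vector of component labels, most variable first; ties
#'   keep the original label order.
#' @export
clr_variance_ranking <- function(norms) {
  stopifnot(inherits(norms, "norm_set"))
  norms$labels[order(-norms$clr_sd, seq_along(norms$clr_sd))]
}

#' Full calibration of regional standards from an observation table
#'
#' Runs the regional pipeline: actual yield classes about the cultivar
#' cut-offs, cross-validated classifier probabilities, predicted classes at
#' the probability threshold, confusion-quadrant partition (with chi-square
#' test against equal distribution, AUC and classification accuracy), then
#' per-cultivar clr norms and compatibility intervals from the reference
#' subpopulation.
#'
#' @param records Observation table.
#' @param config A [pipeline_config()].
#' @return Object of class `calibration`: list with `probabilities`,
#'   `actual`, `predicted`, `quadrants`, `report` (AUC, CA, counts,
#'   chi-square), `norms` and `intervals` (per cultivar), and the `config`.
#' @export
calibrate <- function(records, config = pipeline_config()) {
  actual <- classify_yield(records$yield, records$cultivar, config$cutoffs)
  prob <- fit_yield_classifier(records,
                               features = config$classifier$features,
                               learner = config$classifier$learner,
                               folds = config$classifier$folds,
                               seed = config$classifier$seed,
                               cutoffs = config$cutoffs)
  predicted <- factor(ifelse(prob >= config$classifier$threshold,
                             "high", "low"),
                      levels = c("low", "high"))
  quadrants <- partition_confusion(actual, predicted)
  counts <- table(quadrants)
  chi <- chi_square_uniform(as.numeric(counts[c("TN", "FN", "TP", "FP")]))
  report <- list(
    auc = compute_auc(prob, actual),
    ca = classification_accuracy(counts),
    counts = as.list(counts),
    chi_square = chi$statistic,
    p_value = chi$p_value,
    n = length(actual),
    policy = config$norm_policy,
    learner = config$classifier$learner,
    features = config$classifier$features,
    threshold = config$classifier$threshold
  )
  cultivars <- unique(records$cultivar)
  norms <- lapply(stats::setNames(cultivars, cultivars), function(cv)
    compute_clr_norms(records, cv, quadrants, config$norm_policy))
  intervals <- lapply(stats::setNames(cultivars, cultivars), function(cv)
    compute_compatibility_intervals(records, cv, quadrants,
                                    config$norm_policy))
  structure(list(probabilities = prob, actual = actual,
                 predicted = predicted, quadrants = quadrants,
                 report = report, norms = norms, intervals = intervals,
                 config = config),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("calibration on", x$report$n, "records:",
      "AUC", round(x$report$auc, 3),
      "CA", round(x$report$ca, 3), "\n")
  cat("quadrants:",
      paste(names(x$report$counts), unlist(x$report$counts),
            collapse = ", "),
      sprintf(" (chi-square %.1f, p %.2g)\n",
              x$report$chi_square, x$report$p_value))
  invisible(x)
}
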