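# Synthetic observation generator. Emulates the statistical structure the
# calibration and diagnosis stages assume: logistic-normal tissue
# compositions around the published regional clr standards, soil properties
# from the published summary statistics, and yields depressed by multivariate
# nutrient imbalance.

#' Configuration for the synthetic observation generator
#'
#' Defaults reproduce the documented study conditions: 811 "Prata" and 129
#' "Cavendish" plot-semester observations, tissue compositions drawn
#' logistic-normally around the published regional clr standards, soil
#' properties from the published means and standard deviations (truncated at
#' zero), and semestral yields anchored to the published yield cut-offs
#' (17,500 / 25,000 kg ha^-1 semester^-1).
#'
#' A fraction `imbalance_fraction` of specimens receives a random clr shift
#' of scale `imbalance_shift_sd` on 1-3 components (nutrient imbalance);
#' yield is reduced in proportion to the squared Mahalanobis distance of the
#' tissue composition from the cultivar norms, so imbalance depresses yield
#' -- the premise behind the confusion-matrix calibration. No functional
#' yield-imbalance form is published; this link is a modeling stand-in.
#'
#' @param n Named integer vector: observations per cultivar.
#' @param clr_means,clr_sds Named lists (per cultivar) of clr means / SDs
#'   over the 14 tissue parts; default the published regional standards.
#' @param clr_correlation Optional 14 x 14 correlation matrix for the clr
#'   draws (default identity). With a non-identity correlation the marginal
#'   clr SDs of the closed compositions are only approximate.
#' @param soil_stats Data frame as [banana_soil_stats()].
#' @param soil_coupling In `[0, 1]`: ties soil K and Mg multiplicatively to
#'   the tissue K and Mg clr deviations (0 = independent, default).
#' @param yield_baseline Named vector, kg ha^-1 semester^-1: mean yield of a
#'   perfectly balanced specimen per cultivar. Defaults sit above the yield
#'   cut-offs by about one noise SD plus the expected imbalance penalty, so
#'   both yield classes are populated.
#' @param yield_noise_sd Gaussian yield noise, kg ha^-1 semester^-1.
#' @param yield_penalty kg ha^-1 lost per unit of squared Mahalanobis
#'   imbalance distance above its balanced expectation.
#' @param m2_cap Cap on the squared Mahalanobis distance entering the
#'   penalty (prevents absurd negative yields).
#' @param imbalance_fraction Fraction of specimens drawn imbalanced.
#' @param imbalance_shift_sd SD (clr units) of the imbalance shift.
#' @param n_plots,n_wells Sizes of the plot and well category pools.
#' @param years,semesters Category pools for harvest time.
#' @param plot_effect_sd SD of the per-plot yield effect (kg ha^-1).
#' @param semester_effect Half-difference between rainy (semester 1) and dry
#'   (semester 2) season yields (kg ha^-1).
#' @param min_yield Positive floor for generated yields (kg ha^-1).
#' @param seed Integer seed consumed by [generate_dataset()].
#' @return Object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n = c(Prata = 811, Cavendish = 129),
                             clr_means = NULL,
                             clr_sds = NULL,
                             clr_correlation = NULL,
                             soil_stats = banana_soil_stats(),
                             soil_coupling = 0,
                             yield_baseline = c(Prata = 21000,
                                                Cavendish = 28500),
                             yield_noise_sd = 2500,
                             yield_penalty = 150,
                             m2_cap = 60,
                             imbalance_fraction = 0.4,
                             imbalance_shift_sd = 0.8,
                             n_plots = 40,
                             n_wells = 8,
                             years = 2010:2017,
                             semesters = 1:2,
                             plot_effect_sd = 500,
                             semester_effect = 400,
                             min_yield = 500,
                             seed = 1L) {
  cultivars <- names(n)
  if (is.null(cultivars)) stop("n must be named by cultivar")
  if (is.null(clr_means)) {
    clr_means <- lapply(stats::setNames(cultivars, cultivars), function(cv)
      banana_clr_norms(cv)$clr_mean)
  }
  if (is.null(clr_sds)) {
    clr_sds <- lapply(stats::setNames(cultivars, cultivars), function(cv)
      banana_clr_norms(cv)$clr_sd)
  }
  for (cv in cultivars) {
    if (any(clr_sds[[cv]] <= 0)) stop("clr SDs must be positive")
  }
  if (imbalance_fraction < 0 || imbalance_fraction > 1) {
    stop("imbalance_fraction must lie in [0, 1]")
  }
  if (soil_coupling < 0 || soil_coupling > 1) {
    stop("soil_coupling must lie in [0, 1]")
  }
  stopifnot(imbalance_shift_sd > 0, yield_noise_sd >= 0, min_yield > 0)
  structure(
    list(n = n, clr_means = clr_means, clr_sds = clr_sds,
         clr_correlation = clr_correlation, soil_stats = soil_stats,
         soil_coupling = soil_coupling, yield_baseline = yield_baseline,
         yield_noise_sd = yield_noise_sd, yield_penalty = yield_penalty,
         m2_cap = m2_cap, imbalance_fraction = imbalance_fraction,
         imbalance_shift_sd = imbalance_shift_sd, n_plots = n_plots,
         n_wells = n_wells, years = years, semesters = semesters,
         plot_effect_sd = plot_effect_sd, semester_effect = semester_effect,
         min_yield = min_yield, seed = seed),
    class = "generator_config"
  )
}

# Draw SDs solved so that, after the intrinsic clr centering of the closed
# composition, the marginal clr SDs equal the target SDs exactly:
# diag(G diag(d) G) = sd^2 with G the centering projector.
draw_variances <- function(sd) {
  D <- length(sd)
  S <- sum(sd^2) * D / (D - 1)
  d <- (sd^2 - S / D^2) / (1 - 2 / D)
  if (any(d <= 0)) stop("target clr SDs incompatible with a diagonal draw")
  d
}

#' Draw one synthetic tissue composition
#'
#' Draws a clr vector from a Gaussian centered on the cultivar's clr means
#' (diagonal covariance calibrated so that the closed composition's marginal
#' clr SDs match the configured SDs; or the supplied correlation structure),
#' re-centers it, and maps it to the simplex with kappa = 10^6 mg kg^-1.
#' Imbalanced draws additionally shift 1-3 randomly chosen components by
#' Gaussian amounts of SD `imbalance_shift_sd` before re-centering.
#'
#' Uses the current RNG state; seed upstream (see [generate_dataset()]).
#'
#' @param config A [generator_config()].
#' @param cultivar Cultivar name present in `config$n`.
#' @param balanced Logical: draw from the balanced population?
#' @return A 14-part [composition()].
#' @export
sample_tissue <- function(config, cultivar, balanced = TRUE) {
  sample_tissue_clr(config, cultivar, !balanced, n = 1L) |>
    drop() |>
    clr_inverse(kappa = 1e6)
}

# Matrix of n clr draws (rows = draws, re-centered to zero sum).
sample_tissue_clr <- function(config, cultivar, imbalanced, n) {
  mu <- config$clr_means[[cultivar]]
  sd <- config$clr_sds[[cultivar]]
  D <- length(mu)
  if (is.null(config$clr_correlation)) {
    z <- matrix(stats::rnorm(n * D, sd = rep(sqrt(draw_variances(sd)),
                                             each = n)),
                nrow = n, ncol = D)
  } else {
    R <- config$clr_correlation
    L <- chol(diag(sd) %*% R %*% diag(sd))
    z <- matrix(stats::rnorm(n * D), nrow = n, ncol = D) %*% L
  }
  z <- sweep(z, 2, -mu)
  imbalanced <- rep_len(imbalanced, n)
  for (i in which(imbalanced)) {
    k <- sample(1:3, 1L)
    idx <- sample.int(D, k)
    z[i, idx] <- z[i, idx] + stats::rnorm(k, 0, config$imbalance_shift_sd)
  }
  z <- z - rowMeans(z)
  colnames(z) <- names(mu)
  z
}

# ilr reference distribution implied by the generator's balanced population.
generator_ilr_reference <- function(config, cultivar,
                                    scheme = tissue_sbp()) {
  mu <- config$clr_means[[cultivar]]
  sd <- config$clr_sds[[cultivar]]
  psi <- contrast_matrix(scheme)
  if (is.null(config$clr_correlation)) {
    cov_draw <- diag(draw_variances(sd))
  } else {
    cov_draw <- diag(sd) %*% config$clr_correlation %*% diag(sd)
  }
  list(mean = drop(psi %*% mu),
       cov = psi %*% cov_draw %*% t(psi),
       scheme = scheme)
}

#' Assign a yield to a sampled tissue composition
#'
#' `yield = baseline - penalty * min(max(M^2 - (D-1), 0), cap) + effects +
#' noise`, floored at a positive minimum, where `M^2` is the squared
#' Mahalanobis distance of the tissue composition from the cultivar's
#' generating norms in ilr coordinates (its expectation for a balanced draw
#' is `D - 1`, so balanced specimens pay no systematic penalty).
#'
#' Uses the current RNG state for the noise term.
#'
#' @param tissue A 14-part [composition()].
#' @param cultivar Cultivar name.
#' @param config A [generator_config()].
#' @param effects Additional fixed effects (plot, semester), kg ha^-1.
#' @return Positive yield, kg ha^-1 semester^-1.
#' @export
assign_yield <- function(tissue, cultivar, config, effects = 0) {
  ref <- generator_ilr_reference(config, cultivar)
  m2 <- mahalanobis_imbalance(tissue, ref$mean, ref$cov, ref$scheme)
  D <- length(tissue)
  penalty <- config$yield_penalty * min(max(m2 - (D - 1), 0), config$m2_cap)
  y <- config$yield_baseline[[cultivar]] - penalty + effects +
    stats::rnorm(1, 0, config$yield_noise_sd)
  max(y, config$min_yield)
}

#' Generate a synthetic observation table
#'
#' Reproducible under `config$seed`. Each row is one plot-semester record:
#' categories (cultivar, year, semester, plot, well), soil properties drawn
#' from zero-truncated Gaussians, tissue concentrations in native units
#' (macronutrients g kg^-1, others mg kg^-1), yield, and the generator-only
#' label `truth_balanced`.
#'
#' @param config A [generator_config()].
#' @return Data frame of observation records.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  units <- tissue_units()
  plot_eff <- stats::rnorm(config$n_plots, 0, config$plot_effect_sd)
  out <- list()
  for (cv in names(config$n)) {
    n <- config$n[[cv]]
    if (n == 0) next
    balanced <- stats::runif(n) >= config$imbalance_fraction
    z <- sample_tissue_clr(config, cv, !balanced, n)
    comp <- exp(z)
    comp <- comp * (1e6 / rowSums(comp))
    ref <- generator_ilr_reference(config, cv)
    psi <- contrast_matrix(ref$scheme)
    ilr <- z %*% t(psi)
    dev <- sweep(ilr, 2, ref$mean)
    m2 <- rowSums((dev %*% solve(ref$cov)) * dev)
    D <- ncol(z)
    pen <- config$yield_penalty *
      pmin(pmax(m2 - (D - 1), 0), config$m2_cap)
    plot_id <- sample.int(config$n_plots, n, replace = TRUE)
    well_id <- sample.int(config$n_wells, n, replace = TRUE)
    year <- sample(config$years, n, replace = TRUE)
    semester <- sample(config$semesters, n, replace = TRUE)
    sem_eff <- ifelse(semester == 1, config$semester_effect,
                      -config$semester_effect)
    yield <- pmax(config$yield_baseline[[cv]] - pen + plot_eff[plot_id] +
                    sem_eff + stats::rnorm(n, 0, config$yield_noise_sd),
                  config$min_yield)
    soil <- sample_soil(config, cv, n)
    if (config$soil_coupling > 0) {
      mu <- config$clr_means[[cv]]
      soil$soil_K <- soil$soil_K * exp(config$soil_coupling *
                                         (z[, "K"] - mu[["K"]]))
      soil$soil_Mg <- soil$soil_Mg * exp(config$soil_coupling *
                                           (z[, "Mg"] - mu[["Mg"]]))
    }
    tissue <- comp[, names(units), drop = FALSE]
    macro <- units == "g/kg"
    tissue[, macro] <- tissue[, macro] / 1000
    out[[cv]] <- data.frame(
      cultivar = cv,
      year = year,
      semester = semester,
      plot_id = sprintf("plot_%02d", plot_id),
      well_id = sprintf("well_%02d", well_id),
      soil,
      tissue,
      yield = yield,
      truth_balanced = balanced
    )
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  records$record_id <- sprintf("obs_%04d", seq_len(nrow(records)))
  records
}

sample_soil <- function(config, cultivar, n) {
  st <- config$soil_stats[config$soil_stats$cultivar == cultivar, ]
  if (nrow(st) == 0) stop("no soil statistics for cultivar ", cultivar)
  cols <- lapply(seq_len(nrow(st)), function(i) {
    rtrunc_pos(n, st$mean[i], st$sd[i])
  })
  names(cols) <- paste0("soil_", st$property)
  as.data.frame(cols)
}

# Zero-truncated Gaussian by rejection.
rtrunc_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}
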