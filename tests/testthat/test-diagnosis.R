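test_that("CND indices vanish at the norm centroid and standardize deviations", {
  ns <- centered_norms("Prata")
  centroid <- clr_inverse(ns$clr_mean, kappa = 1e6)
  idx <- cnd_indices(centroid, ns)
  expect_equal(unname(idx), rep(0, 14), tolerance = 1e-9)
  expect_equal(cnd_nii(idx), 0, tolerance = 1e-12)
  # shift one clr component up by 1 SD (compensated on Fv): index exactly 1
  z <- ns$clr_mean
  z[["N"]] <- z[["N"]] + ns$clr_sd[["N"]]
  z[["Fv"]] <- z[["Fv"]] - ns$clr_sd[["N"]]
  idx2 <- cnd_indices(clr_inverse(z, kappa = 1e6), ns)
  expect_equal(idx2[["N"]], 1, tolerance = 1e-9)
  bad <- ns
  bad$clr_sd[["Mn"]] <- 0
  expect_error(cnd_indices(centroid, bad), "Mn")
})

test_that("median specimens diagnose as balanced against the regional norms", {
  for (cv in c("Prata", "Cavendish")) {
    idx <- cnd_indices(banana_median_composition(cv), banana_clr_norms(cv))
    expect_lt(max(abs(idx)), 0.6)
  }
})

test_that("the nutrient imbalance index is a permutation-invariant sum of squares", {
  expect_equal(cnd_nii(c(3, 4)), 25)
  expect_equal(cnd_nii(rep(0, 14)), 0)
  set.seed(40)
  v <- stats::rnorm(14)
  expect_equal(cnd_nii(v), cnd_nii(sample(v)))
  expect_error(cnd_nii(c(1, NA)), "finite")
})

test_that("Mahalanobis imbalance matches its closed forms and reference distribution", {
  cfg <- generator_config(seed = 44L)
  ref <- cndiag:::generator_ilr_reference(cfg, "Prata")
  centroid <- clr_inverse(cfg$clr_means$Prata - mean(cfg$clr_means$Prata),
                          kappa = 1e6)
  expect_equal(mahalanobis_imbalance(centroid, ref$mean, ref$cov,
                                     ref$scheme), 0, tolerance = 1e-12)
  # identity covariance: squared ilr Euclidean distance
  set.seed(44)
  comp <- random_composition(tissue_parts(), kappa = 1e6)
  v <- as.numeric(ilr_transform(comp, ref$scheme))
  expect_equal(mahalanobis_imbalance(comp, ref$mean, diag(13), ref$scheme),
               sum((v - ref$mean)^2), tolerance = 1e-9)
  # agreement with the standard implementation
  expect_equal(mahalanobis_imbalance(comp, ref$mean, ref$cov, ref$scheme),
               unname(stats::mahalanobis(rbind(v), ref$mean, ref$cov)),
               tolerance = 1e-9)
  # chi-square with D-1 df under the reference Gaussian
  set.seed(45)
  z <- cndiag:::sample_tissue_clr(cfg, "Prata", imbalanced = FALSE,
                                  n = 2000)
  ilr <- z %*% t(contrast_matrix(ref$scheme))
  dev <- sweep(ilr, 2, ref$mean)
  m2 <- rowSums((dev %*% solve(ref$cov)) * dev)
  q95 <- unname(stats::quantile(m2, 0.95))
  expect_lt(abs(q95 / stats::qchisq(0.95, df = 13) - 1), 0.15)
  # singular covariance: ridge path recovers, fully degenerate rejects
  sing <- ref$cov
  sing[, 1] <- 0; sing[1, ] <- 0
  expect_message(res <- mahalanobis_imbalance(comp, ref$mean, sing,
                                              ref$scheme), "ridge")
  expect_true(is.finite(res))
  expect_error(mahalanobis_imbalance(comp, ref$mean,
                                     matrix(1, 13, 13), ref$scheme,
                                     ridge = 0), "singular")
})

test_that("neighbor search equals the brute-force scan and finds planted duplicates", {
  rec <- small_dataset(n_prata = 90, n_cav = 40, seed = 50L)
  q <- neighbor_query(success = "actual-high", k = 1)
  cls <- classify_yield(rec$yield, rec$cultivar)
  set.seed(51)
  for (i in sample(nrow(rec), 25)) {
    diagnosed <- rec[i, , drop = FALSE]
    nb <- find_successful_neighbors(diagnosed, rec, q)
    # oracle: exhaustive pairwise scan with the public distance function
    cand <- which(rec$cultivar == diagnosed$cultivar & cls == "high" &
                    rec$record_id != diagnosed$record_id)
    d <- vapply(cand, function(j)
      aitchison_distance(record_composition(rec[j, , drop = FALSE]),
                         record_composition(diagnosed)), numeric(1))
    best <- cand[order(d, rec$record_id[cand])][1]
    expect_identical(nb$neighbors$record_id, rec$record_id[best])
    expect_equal(nb$neighbors$distance, min(d), tolerance = 1e-10)
  }
  # planted duplicate is returned first at distance zero
  dup <- rec[7, , drop = FALSE]
  dup$record_id <- "planted"
  dup$yield <- 40000
  aug <- rbind(rec, dup)
  nb <- find_successful_neighbors(rec[7, , drop = FALSE], aug, q)
  expect_identical(nb$neighbors$record_id, "planted")
  expect_equal(nb$neighbors$distance, 0, tolerance = 1e-12)
})

test_that("neighbor filters fail loudly when they empty the candidate set", {
  rec <- small_dataset(n_prata = 30, n_cav = 0, seed = 52L)
  diagnosed <- rec[1, , drop = FALSE]
  other <- diagnosed
  other$cultivar <- "Cavendish"
  expect_error(find_successful_neighbors(other, rec, neighbor_query()),
               "cultivar")
  poor <- rec
  poor$yield <- 1000
  expect_error(find_successful_neighbors(diagnosed, poor,
                                         neighbor_query(success = "actual-high")),
               "success filter")
  # TN success without quadrants falls back to actual-high with a message
  expect_message(find_successful_neighbors(diagnosed, rec,
                                           neighbor_query(success = "TN")),
                 "falling back")
})

test_that("soil-weighted and ilr-space distances behave at the boundaries", {
  rec <- small_dataset(n_prata = 40, n_cav = 0, seed = 53L)
  diagnosed <- rec[2, , drop = FALSE]
  q0 <- neighbor_query(success = "actual-high", k = 3)
  q_ilr <- neighbor_query(success = "actual-high", k = 3, space = "ilr",
                          scheme = tissue_sbp())
  nb0 <- find_successful_neighbors(diagnosed, rec, q0)
  nb_ilr <- find_successful_neighbors(diagnosed, rec, q_ilr)
  expect_identical(nb0$neighbors$record_id, nb_ilr$neighbors$record_id)
  expect_equal(nb0$neighbors$distance, nb_ilr$neighbors$distance,
               tolerance = 1e-9)
  expect_true(all(diff(nb0$neighbors$distance) >= 0))
  q_soil <- neighbor_query(success = "actual-high", k = 3,
                           soil_weight = 0.5)
  nb_soil <- find_successful_neighbors(diagnosed, rec, q_soil)
  expect_equal(nrow(nb_soil$neighbors), 3)
  expect_error(neighbor_query(soil_weight = 2), "\\[0, 1\\]")
  expect_error(neighbor_query(space = "ilr"), "scheme")
})

test_that("local diagnosis ranks a constructed shortage first", {
  rec <- small_dataset(n_prata = 40, n_cav = 0, seed = 54L)
  neighbor <- rec[5, , drop = FALSE]
  neighbor$yield <- 30000
  # diagnosed specimen: neighbor's composition with Cu halved, re-closed
  comp_n <- record_composition(neighbor)
  parts <- stats::setNames(as.numeric(comp_n), names(comp_n))
  parts[["Cu"]] <- parts[["Cu"]] * 0.5
  diagnosed <- record_from_composition(close_composition(parts, 1e6),
                                       yield = 12000, id = "case")
  nb <- find_successful_neighbors(diagnosed, rec,
                                  neighbor_query(success = "actual-high"))
  loc <- local_diagnose(diagnosed, nb)
  expect_false(loc$balanced)
  expect_true(all(loc$perturbation > 0))
  # identical neighbor: perturbation of ones, zero clr difference
  nb_self <- find_successful_neighbors(
    record_from_composition(comp_n, yield = 12000, id = "self"),
    neighbor, neighbor_query(success = "actual-high"))
  loc_self <- local_diagnose(record_from_composition(comp_n, yield = 12000,
                                                     id = "self"), nb_self)
  expect_true(loc_self$balanced)
  expect_equal(as.numeric(loc_self$perturbation), rep(1, 14),
               tolerance = 1e-12)
  expect_equal(as.numeric(loc_self$clr_diff), rep(0, 14),
               tolerance = 1e-12)
  # the halved component ranks most-shortage against its own neighbor
  nb_direct <- find_successful_neighbors(diagnosed, neighbor,
                                         neighbor_query(success = "actual-high"))
  loc_direct <- local_diagnose(diagnosed, nb_direct)
  expect_identical(loc_direct$ranking[1], "Cu")
  expect_equal(loc_direct$expected_yield, 30000)
})

test_that("k > 1 benchmarks against the closed geometric mean of neighbors", {
  rec <- small_dataset(n_prata = 40, n_cav = 0, seed = 55L)
  diagnosed <- rec[1, , drop = FALSE]
  q <- neighbor_query(success = "actual-high", k = 3)
  nb <- find_successful_neighbors(diagnosed, rec, q)
  loc <- local_diagnose(diagnosed, nb)
  m <- cndiag:::records_tissue_matrix(nb$records)
  gm <- exp(colMeans(log(m)))
  expect_equal(as.numeric(loc$benchmark),
               unname(gm * 1e6 / sum(gm)), tolerance = 1e-12)
  expect_equal(loc$expected_yield, mean(nb$neighbors$yield))
})

test_that("perturbation and clr-difference rankings agree", {
  set.seed(56)
  for (i in 1:20) {
    a <- random_composition(tissue_parts(), kappa = 1e6)
    b <- random_composition(tissue_parts(), kappa = 1e6)
    r_p <- order(as.numeric(perturbation(a, b)))
    r_d <- order(as.numeric(clr_difference(a, b)))
    expect_identical(r_p, r_d)
  }
})

test_that("regional and local diagnoses can diverge for the same specimen", {
  # specimen at the regional centroid, but its plot's successful neighbor
  # has a different composition
  ns <- centered_norms("Prata")
  centroid <- clr_inverse(ns$clr_mean, kappa = 1e6)
  diagnosed <- record_from_composition(centroid, yield = 16000,
                                       id = "case", plot_id = "plot_07")
  z <- ns$clr_mean
  z[["Mg"]] <- z[["Mg"]] + 0.5
  z[["Cu"]] <- z[["Cu"]] - 0.5
  neighbor <- record_from_composition(clr_inverse(z - mean(z), 1e6),
                                      yield = 28000, id = "nbr",
                                      plot_id = "plot_07")
  reg <- regional_diagnose(centroid, ns)
  expect_equal(reg$nii, 0, tolerance = 1e-9)
  nb <- find_successful_neighbors(
    diagnosed, neighbor,
    neighbor_query(mandatory_keys = c("cultivar", "plot_id"),
                   success = "actual-high"))
  loc <- local_diagnose(diagnosed, nb)
  expect_false(loc$balanced)
  expect_gt(max(abs(log(as.numeric(loc$perturbation)))), 0.1)
  expect_identical(loc$ranking[1], "Mg")
  expect_identical(loc$ranking[14], "Cu")
})

test_that("reports serialize, round-trip and apply the Na/Al flag policy", {
  ns <- centered_norms("Prata")
  z <- ns$clr_mean
  z[["Na"]] <- z[["Na"]] - 0.4
  z[["Al"]] <- z[["Al"]] + 0.4
  spec <- clr_inverse(z - mean(z), 1e6)
  reg <- regional_diagnose(spec, ns)
  rep1 <- build_report(regional = reg,
                       metadata = list(record_id = "r1",
                                       cultivar = "Prata"))
  expect_null(rep1$local)
  expect_identical(rep1$regional$flags$Na, "none (non-essential)")
  expect_identical(rep1$regional$flags$Al, "excess")
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, path)
  back <- read_report(path)
  expect_equal(back$regional$nii, rep1$regional$nii, tolerance = 1e-12)
  expect_equal(unlist(back$regional$indices),
               unlist(rep1$regional$indices), tolerance = 1e-12)
  expect_identical(back$regional$flags$Na, "none (non-essential)")
  expect_identical(unlist(back$regional$ranking), rep1$regional$ranking)
  expect_error(build_report(), "at least one")
})
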