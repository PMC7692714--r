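# Shared test helpers: random compositions and small observation tables.

# Random strictly positive composition with given labels.
random_composition <- function(labels = letters[1:5], kappa = 1) {
  composition(stats::setNames(exp(stats::rnorm(length(labels))), labels),
              kappa = kappa)
}

# Small synthetic observation table for neighbor / calibration tests.
small_dataset <- function(n_prata = 80, n_cav = 40, seed = 11L, ...) {
  generate_dataset(generator_config(n = c(Prata = n_prata,
                                          Cavendish = n_cav),
                                    seed = seed, ...))
}

# One observation row rebuilt from a 14-part composition (native units).
record_from_composition <- function(comp, cultivar = "Prata",
                                    yield = 20000, id = "obs_x",
                                    plot_id = "plot_01") {
  units <- tissue_units()
  vals <- as.numeric(comp)[match(names(units), names(comp))]
  vals[units == "g/kg"] <- vals[units == "g/kg"] / 1000
  df <- as.data.frame(as.list(stats::setNames(vals, names(units))))
  cbind(data.frame(cultivar = cultivar, year = 2015, semester = 1,
                   plot_id = plot_id, well_id = "well_01",
                   record_id = id),
        df,
        data.frame(yield = yield))
}

# Exactly-centered norm set for constructions needing zero indices.
centered_norms <- function(cultivar = "Prata") {
  ns <- banana_clr_norms(cultivar)
  norm_set(cultivar, ns$labels, ns$clr_mean - mean(ns$clr_mean),
           ns$clr_sd, n = ns$n, policy = ns$policy)
}
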