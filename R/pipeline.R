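# Observation I/O, pipeline configuration and the command-line workflow.

#' Pipeline configuration
#'
#' @param cutoffs Named yield cut-offs per cultivar (kg ha^-1 semester^-1).
#' @param norm_policy `"TN+FN"` (default, matching the published standards)
#'   or `"TN"` (the strict reference-subpopulation definition).
#' @param classifier List: `features` (see [fit_yield_classifier()]),
#'   `learner`, `folds`, `seed`, `threshold` (probability cut for the
#'   predicted class).
#' @param neighbor Default [neighbor_query()] settings as a list: `k`,
#'   `space`, `soil_weight`, `success`, `mandatory_keys`.
#' @param units Declared unit per tissue column, each `"g/kg"` or `"mg/kg"`;
#'   defaults to the laboratory convention of [tissue_units()]. Columns
#'   declared in a different unit are converted on read.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cutoffs = yield_cutoffs(),
                            norm_policy = c("TN+FN", "TN"),
                            classifier = list(),
                            neighbor = list(),
                            units = tissue_units()) {
  norm_policy <- match.arg(norm_policy)
  if (any(cutoffs <= 0)) stop("yield cut-offs must be positive")
  if (!all(units %in% c("g/kg", "mg/kg"))) {
    stop("tissue units must be 'g/kg' or 'mg/kg'")
  }
  cls <- utils::modifyList(
    list(features = "tissue", learner = "rf", folds = 10, seed = 1,
         threshold = 0.5),
    classifier
  )
  nb <- utils::modifyList(
    list(mandatory_keys = "cultivar", success = "TN", k = 1L,
         space = "clr", soil_weight = 0),
    neighbor
  )
  structure(list(cutoffs = cutoffs, norm_policy = norm_policy,
                 classifier = cls, neighbor = nb, units = units),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys map to the arguments of [pipeline_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$cutoffs)) args$cutoffs <- unlist(raw$cutoffs)
  if (!is.null(raw$norm_policy)) args$norm_policy <- raw$norm_policy
  if (!is.null(raw$classifier)) args$classifier <- raw$classifier
  if (!is.null(raw$neighbor)) args$neighbor <- raw$neighbor
  if (!is.null(raw$units)) args$units <- unlist(raw$units)
  do.call(pipeline_config, args)
}

#' Read an observation table from CSV
#'
#' Mandatory columns: `cultivar`, `yield` and the 13 tissue elements.
#' Optional: `year`, `semester`, `plot_id`, `well_id`, `record_id` and
#' `soil_*` properties. Tissue columns declared in a unit other than the
#' laboratory convention (see [tissue_units()]) are converted. Rows with a
#' nonpositive yield or tissue concentration, or whose closed tissue sum
#' reaches the measurement scale, are rejected; rejections are reported with
#' their file line numbers in a message and attached as attribute
#' `"rejected"`.
#'
#' @param path CSV path.
#' @param config A [pipeline_config()].
#' @return Observation data frame (canonical native units) with attribute
#'   `rejected`.
#' @export
read_observations <- function(path, config = pipeline_config()) {
  tab <- utils::read.csv(path, check.names = FALSE)
  canonical <- tissue_units()
  mandatory <- c("cultivar", "yield", names(canonical))
  miss <- setdiff(mandatory, names(tab))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  for (el in names(canonical)) {
    declared <- config$units[[el]]
    if (is.null(declared)) declared <- canonical[[el]]
    if (declared == "g/kg" && canonical[[el]] == "mg/kg") {
      tab[[el]] <- tab[[el]] * 1000
    } else if (declared == "mg/kg" && canonical[[el]] == "g/kg") {
      tab[[el]] <- tab[[el]] / 1000
    }
  }
  mg <- as.matrix(tab[, names(canonical), drop = FALSE])
  mg[, canonical == "g/kg"] <- mg[, canonical == "g/kg"] * 1000
  reasons <- character(nrow(tab))
  bad_pos <- apply(!is.finite(mg) | mg <= 0, 1, any) |
    !is.finite(tab$yield) | tab$yield <= 0
  reasons[bad_pos] <- "nonpositive yield or concentration"
  over <- !bad_pos & rowSums(mg) >= 1e6
  reasons[over] <- "tissue sum reaches the measurement scale (unit error?)"
  rejected <- data.frame(line = which(reasons != "") + 1L,
                         reason = reasons[reasons != ""])
  if (nrow(rejected) > 0) {
    message("read_observations: rejected ", nrow(rejected), " of ",
            nrow(tab), " row(s) [lines ",
            paste(rejected$line, collapse = ", "), "]")
  }
  out <- tab[reasons == "", , drop = FALSE]
  if (is.null(out$record_id)) {
    out$record_id <- sprintf("obs_%04d", seq_len(nrow(tab)))[reasons == ""]
  }
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write an observation table to CSV
#'
#' @param records Observation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write norm sets to CSV
#'
#' One row per cultivar and component, mirroring the published standards
#' layout (component, clr mean, clr SD) plus provenance columns.
#'
#' @param norms A [norm_set()] or list of norm sets.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_norms <- function(norms, path) {
  if (inherits(norms, "norm_set")) norms <- list(norms)
  rows <- lapply(norms, function(ns)
    data.frame(cultivar = ns$cultivar, component = ns$labels,
               clr_mean = unname(ns$clr_mean), clr_sd = unname(ns$clr_sd),
               n = ns$n, policy = ns$policy))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read norm sets from CSV
#'
#' Norms are validated on load (zero-sum means, positive SDs).
#'
#' @param path Path written by [write_norms()].
#' @return Named list of [norm_set()] objects, one per cultivar.
#' @export
read_norms <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("cultivar", "component", "clr_mean", "clr_sd", "n", "policy")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("norms file lacks column(s): ",
                         paste(miss, collapse = ", "))
  cvs <- unique(tab$cultivar)
  out <- lapply(stats::setNames(cvs, cvs), function(cv) {
    sub <- tab[tab$cultivar == cv, ]
    norm_set(cv, sub$component, sub$clr_mean, sub$clr_sd,
             n = sub$n[1], policy = sub$policy[1])
  })
  out
}

#' Command-line workflow
#'
#' Subcommands: `generate` (synthetic observation CSV), `calibrate` (norms
#' CSV and classifier report JSON), `diagnose-regional`,
#' `diagnose-local` and `report` (both scales). Flags: `--config`,
#' `--input`, `--norms`, `--id`, `--seed`, `--out`, `--policy`, `--k`,
#' `--space`, `--soil-weight`. Deterministic under a fixed `--seed`.
#'
#' @param args Character vector of command-line arguments (the subcommand
#'   followed by flags), e.g. `c("generate", "--seed", "7", "--out",
#'   "obs.csv")`.
#' @return Exit status, invisibly: 0 on success, 1 on a processing error,
#'   2 on a usage error.
#' @export
cnd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cndiag <generate|calibrate|diagnose-regional|diagnose-local|report>",
    "  generate          --seed <int> --out <csv>",
    "  calibrate         --input <csv> --out <prefix> [--policy TN+FN|TN]",
    "                    [--seed <int>] [--config <yaml|json>]",
    "  diagnose-regional --input <csv> --norms <csv> --out <json>",
    "  diagnose-local    --input <csv> --id <record_id> --out <json>",
    "                    [--k <int>] [--space clr|ilr] [--soil-weight <w>]",
    "  report            --input <csv> --id <record_id> --norms <csv>",
    "                    --out <json> [--k <int>]",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(2L))
  }
  sub <- args[1]
  flags <- tryCatch(parse_flags(args[-1]),
                    error = function(e) {
                      message(conditionMessage(e), "\n", usage)
                      NULL
                    })
  if (is.null(flags)) return(invisible(2L))
  handler <- switch(sub,
                    "generate" = cli_generate,
                    "calibrate" = cli_calibrate,
                    "diagnose-regional" = cli_diagnose_regional,
                    "diagnose-local" = cli_diagnose_local,
                    "report" = cli_report,
                    NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    handler(flags)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      stop("flag ", a, " needs a value")
    }
    flags[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

need_flag <- function(flags, name) {
  v <- flags[[name]]
  if (is.null(v)) stop("missing required flag --", name)
  v
}

cli_config <- function(flags) {
  if (!is.null(flags$config)) read_pipeline_config(flags$config)
  else pipeline_config()
}

cli_generate <- function(flags) {
  out <- need_flag(flags, "out")
  cfg <- generator_config(seed = as.integer(need_flag(flags, "seed")))
  records <- generate_dataset(cfg)
  write_observations(records, out)
  message("generate: wrote ", nrow(records), " records to ", out)
}

cli_calibrate <- function(flags) {
  cfg <- cli_config(flags)
  if (!is.null(flags$policy)) cfg$norm_policy <- flags$policy
  if (!is.null(flags$seed)) cfg$classifier$seed <- as.integer(flags$seed)
  records <- read_observations(need_flag(flags, "input"), cfg)
  cal <- calibrate(records, cfg)
  prefix <- need_flag(flags, "out")
  write_norms(cal$norms, paste0(prefix, "_norms.csv"))
  jsonlite::write_json(cal$report, paste0(prefix, "_classifier.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("calibrate: ", cal$report$n, " records; AUC ",
          round(cal$report$auc, 3), "; norms -> ", prefix, "_norms.csv")
}

cli_diagnose_regional <- function(flags) {
  cfg <- cli_config(flags)
  records <- read_observations(need_flag(flags, "input"), cfg)
  norms <- read_norms(need_flag(flags, "norms"))
  out <- need_flag(flags, "out")
  reports <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    ns <- norms[[rec$cultivar]]
    if (is.null(ns)) stop("no norms for cultivar ", rec$cultivar)
    reg <- regional_diagnose(record_composition(rec), ns)
    unclass(build_report(regional = reg,
                         metadata = list(record_id = rec$record_id,
                                         cultivar = rec$cultivar)))
  })
  jsonlite::write_json(reports, out, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  message("diagnose-regional: ", length(reports), " report(s) -> ", out)
}

cli_diagnose_local <- function(flags) {
  cfg <- cli_config(flags)
  records <- read_observations(need_flag(flags, "input"), cfg)
  id <- need_flag(flags, "id")
  out <- need_flag(flags, "out")
  i <- which(records$record_id == id)
  if (length(i) != 1L) stop("record_id not found: ", id)
  q <- neighbor_query(
    success = "actual-high",
    k = as.integer(flags$k %||% cfg$neighbor$k),
    space = flags$space %||% cfg$neighbor$space,
    scheme = if ((flags$space %||% cfg$neighbor$space) == "ilr")
      tissue_sbp() else NULL,
    soil_weight = as.numeric(flags[["soil-weight"]] %||%
                               cfg$neighbor$soil_weight)
  )
  diagnosed <- records[i, , drop = FALSE]
  nb <- find_successful_neighbors(diagnosed, records, q,
                                  cutoffs = cfg$cutoffs)
  loc <- local_diagnose(diagnosed, nb)
  rep <- build_report(local = loc,
                      metadata = list(record_id = id,
                                      cultivar = diagnosed$cultivar))
  write_report(rep, out)
  message("diagnose-local: ", id, " vs ", nrow(nb$neighbors),
          " neighbor(s) -> ", out)
}

cli_report <- function(flags) {
  cfg <- cli_config(flags)
  records <- read_observations(need_flag(flags, "input"), cfg)
  norms <- read_norms(need_flag(flags, "norms"))
  id <- need_flag(flags, "id")
  out <- need_flag(flags, "out")
  i <- which(records$record_id == id)
  if (length(i) != 1L) stop("record_id not found: ", id)
  diagnosed <- records[i, , drop = FALSE]
  ns <- norms[[diagnosed$cultivar]]
  if (is.null(ns)) stop("no norms for cultivar ", diagnosed$cultivar)
  reg <- regional_diagnose(record_composition(diagnosed), ns)
  q <- neighbor_query(success = "actual-high",
                      k = as.integer(flags$k %||% cfg$neighbor$k))
  nb <- find_successful_neighbors(diagnosed, records, q,
                                  cutoffs = cfg$cutoffs)
  loc <- local_diagnose(diagnosed, nb)
  rep <- build_report(regional = reg, local = loc,
                      metadata = list(record_id = id,
                                      cultivar = diagnosed$cultivar))
  write_report(rep, out)
  message("report: ", id, " -> ", out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
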