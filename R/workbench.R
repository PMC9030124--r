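# Workbench: configuration files, run manifests, and the CLI surface
# (thin Rscript at inst/cli/exposcore.R dispatches to these functions).

.SCENARIO_FIELDS <- list(
  cherrie96 = c("eps_i", "h", "eta_lev", "eps_p", "t_a_nf", "t_a_ff",
                "eta_ppe", "d_gv"),
  cherrie99 = c("eps_i_nf", "eps_i_ff", "h", "eta_lev", "eps_p", "t_a_nf",
                "t_a_ff", "eta_ppe", "d_gv"),
  stoffenmanager = c("E", "H", "eta_lcnf", "eta_gvnf", "eta_lcff",
                     "eta_gvff", "a", "eta_imm", "t_h", "f_h"),
  art = c("E_nf", "H_nf", "LC_nf", "P_nf", "Su_nf", "D_nf", "E_ff",
          "H_ff", "LC_ff", "Seg_ff", "Su_ff", "D_ff", "Sep_ff", "RPE")
)

.SCENARIO_CTOR <- list(
  cherrie96 = scenario_cherrie96, cherrie99 = scenario_cherrie99,
  stoffenmanager = scenario_sm, art = scenario_art
)

#' Read a scenario file
#'
#' Reads a YAML (or JSON) scenario file whose keys are exactly the
#' multiplier names of the chosen model. Every field of the model must be
#' present; unknown keys are rejected. A value may be either a number
#' (user-supplied exact multiplier) or a descriptor string, which is
#' resolved through the taxonomy table (factor = field name) and inherits
#' the taxonomy entry's provenance class.
#'
#' @param path Scenario file path (`.yaml`/`.yml`/`.json`).
#' @param model `"cherrie96"`, `"cherrie99"`, `"stoffenmanager"` or
#'   `"art"`.
#' @param taxonomy Optional `taxonomy_table`, required when any value is a
#'   descriptor string.
#' @return A list: `scenario` (an `exposure_scenario`) and `multipliers`
#'   (data frame with `factor`, `value`, `provenance_class`, `source`).
#' @export
read_scenario <- function(path, model, taxonomy = NULL) {
  model <- match.arg(model, names(.SCENARIO_FIELDS))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  fields <- .SCENARIO_FIELDS[[model]]
  unknown <- setdiff(names(raw), fields)
  if (length(unknown) > 0) {
    stop("unknown scenario key(s) for model '", model, "': ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(fields, names(raw))
  if (length(missing) > 0) {
    stop("scenario is missing field(s): ", paste(missing, collapse = ", "))
  }
  resolved <- lapply(fields, function(nm) {
    v <- raw[[nm]]
    if (is.character(v)) {
      if (is.null(taxonomy)) {
        stop("field '", nm, "' is a descriptor ('", v,
             "') but no taxonomy table was supplied")
      }
      lookup_multiplier(taxonomy, model, nm, v)
    } else {
      structure(list(factor = nm, descriptor = NA_character_,
                     value = as.numeric(v),
                     provenance_class = "quantitative_exact",
                     source = "user-supplied exact"),
                class = "multiplier_assignment")
    }
  })
  values <- vapply(resolved, `[[`, numeric(1), "value")
  names(values) <- fields
  scenario <- do.call(.SCENARIO_CTOR[[model]], as.list(values))
  multipliers <- data.frame(
    factor = fields,
    value = values,
    provenance_class = vapply(resolved, `[[`, character(1),
                              "provenance_class"),
    source = vapply(resolved, `[[`, character(1), "source"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(scenario = scenario, multipliers = multipliers)
}

#' Write a run manifest
#'
#' Every workbench run emits one manifest recording the command, input and
#' output paths, MD5 hashes of the input files, the seed whenever
#' randomness was used, the package version, and timestamps — enough to
#' reproduce the run exactly.
#'
#' @param path Manifest output path (JSON).
#' @param command Command name.
#' @param inputs Character vector of input file paths (hashed if they
#'   exist).
#' @param outputs Character vector of output paths.
#' @param seed Integer seed or `NULL` when the run used no randomness.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, command, inputs = character(),
                           outputs = character(), seed = NULL) {
  hashes <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(
    command = command,
    tool = "exposcore",
    version = as.character(utils::packageVersion("exposcore")),
    seed = seed,
    inputs = as.list(inputs),
    input_md5 = hashes,
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}

#' Score a scenario file (CLI backend)
#'
#' Computes the chosen model's exposure score for a scenario file and
#' translates it to a concentration through an OEL or a calibration fit,
#' reporting every multiplier with its provenance class.
#'
#' @param scenario_file Scenario YAML/JSON path.
#' @param model Score model name.
#' @param taxonomy_file Optional taxonomy CSV (needed for descriptor
#'   values).
#' @param oel Optional OEL (mg m\eqn{^{-3}}) for the OEL translation.
#' @param fit Optional [calibration_fit()] for the calibration
#'   translation.
#' @param manifest Optional path to write a run manifest.
#' @return A list of class `score_report`: `model`, `score`,
#'   `multipliers`, `translation` (`"oel"`, `"calibration"` or `"none"`),
#'   `concentration` (mg m\eqn{^{-3}} or `NA`).
#' @export
cli_score <- function(scenario_file, model, taxonomy_file = NULL,
                      oel = NULL, fit = NULL, manifest = NULL) {
  taxonomy <- if (!is.null(taxonomy_file)) load_taxonomy(taxonomy_file)
  sc <- read_scenario(scenario_file, model, taxonomy)
  score <- score_scenario(sc$scenario)
  if (!is.null(oel)) {
    translation <- "oel"
    conc <- score_to_concentration_oel(score, oel)
  } else if (!is.null(fit)) {
    translation <- "calibration"
    conc <- if (score > 0) predict_gm(fit, score) else 0
  } else {
    translation <- "none"
    conc <- NA_real_
  }
  if (!is.null(manifest)) {
    write_manifest(manifest, "score",
                   inputs = c(scenario_file, taxonomy_file),
                   outputs = character())
  }
  structure(list(model = model, score = score,
                 multipliers = sc$multipliers,
                 translation = translation, concentration = conc),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report> model =", x$model, "\n")
  print.data.frame(x$multipliers, row.names = FALSE)
  cat(sprintf("  score = %g\n", x$score))
  if (x$translation != "none") {
    cat(sprintf("  concentration = %g mg m-3 (via %s)\n",
                x$concentration, x$translation))
  }
  invisible(x)
}

#' Simulate a two-compartment parameter file (CLI backend)
#'
#' Reads a YAML parameter file (keys of [two_compartment_params()] plus
#' `t_end` and `dt`, minutes), simulates the transient, and — for a
#' constant source with Q > 0 — reports the closed-form steady state.
#'
#' @param params_file YAML parameter file path.
#' @param out_csv Optional CSV path for the series (`time,C_nf,C_ff`).
#' @param manifest Optional manifest path.
#' @return List: `params`, `series` (a `concentration_series`),
#'   `steady_state` (or `NULL` when undefined).
#' @export
cli_simulate_box <- function(params_file, out_csv = NULL, manifest = NULL) {
  raw <- yaml::read_yaml(params_file)
  known <- c("V_nf", "V_ff", "Q", "beta", "G", "C0_nf", "C0_ff",
             "lev_efficiency", "t_end", "dt")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  }
  need <- c("V_nf", "V_ff", "Q", "beta", "G", "t_end", "dt")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("parameter file missing key(s): ",
         paste(missing, collapse = ", "))
  }
  p <- two_compartment_params(
    V_nf = raw$V_nf, V_ff = raw$V_ff, Q = raw$Q, beta = raw$beta,
    G = raw$G, C0_nf = raw$C0_nf %||% 0, C0_ff = raw$C0_ff %||% 0,
    lev_efficiency = raw$lev_efficiency %||% 0)
  series <- simulate_transient(p, t_end = raw$t_end, dt = raw$dt)
  ss <- tryCatch(steady_state(p), error = function(e) NULL)
  if (!is.null(out_csv)) {
    utils::write.csv(series, out_csv, row.names = FALSE)
  }
  if (!is.null(manifest)) {
    write_manifest(manifest, "simulate-box", inputs = params_file,
                   outputs = out_csv %||% character())
  }
  list(params = p, series = series, steady_state = ss)
}

#' Read a study configuration file
#'
#' YAML keys mirror the arguments of [study_config()] (`group_counts` as a
#' named mapping); absent keys take the defaults.
#'
#' @param path YAML config path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$group_counts)) {
    args$group_counts <- unlist(raw$group_counts)
  }
  for (nm in c("companies_per_group", "workers_per_company", "n_strata",
               "alpha", "beta", "sigma_bc", "sigma_bw", "measurement_gsd",
               "p_mis", "seed")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(study_config, args)
}

#' Run the full closed-loop synthetic study (CLI backend)
#'
#' One command reproduces the whole experiment: generate a synthetic
#' calibration study, fit per-group calibrations, predict a precautionary
#' percentile for every record, and evaluate the predictions against the
#' synthetic measurements (ratio statistics, correlations, residual trend,
#' exceedance, SEC criteria). All randomness flows from the config seed.
#'
#' @param cfg A [study_config()], or a path to a YAML config file.
#' @param out_dir Optional output directory: writes `study.csv` (observed
#'   channel), `truth.json`, `report.json` and `manifest.json`.
#' @param percentile Percentile used for the precautionary prediction
#'   (default 0.9).
#' @param mode Calibration mode, `"sm"` or `"art"`.
#' @return A list of class `study_report`: `group_sizes`, `fits`,
#'   `evaluation` (per group: ratio stats, correlations, residual trend,
#'   exceedance, SEC criteria), `seed`.
#' @export
cli_study <- function(cfg, out_dir = NULL, percentile = 0.9, mode = "sm") {
  if (is.character(cfg)) cfg <- read_study_config(cfg)
  stopifnot(inherits(cfg, "study_config"))
  study <- make_study(cfg)
  groups <- assemble_groups(as.data.frame(study), mode = mode)
  fits <- lapply(groups$datasets, fit_calibration, mode = mode)
  evaluation <- lapply(names(fits), function(g) {
    d <- groups$datasets[[g]]
    fit <- fits[[g]]
    sigma_tot <- sqrt(sum(fit$varcomp))
    pred <- predict_gm(fit, d$score) *
      exp(stats::qnorm(percentile) * sigma_tot)
    cs <- comparison_set(pred, d$concentration, scenario = d$scenario,
                         flavour = "percentile")
    list(group = g,
         ratio_stats = unclass(ratio_stats(cs)),
         correlation = correlation_summary(cs),
         residual_trend = unclass(residual_trend(cs)),
         sec_criteria = unclass(sec_criteria_check(cs)))
  })
  names(evaluation) <- names(fits)
  report <- structure(
    list(group_sizes = as.list(table(study$group)[
           names(cfg$group_counts)]),
         fits = lapply(fits, function(f) {
           list(group = f$group, alpha = f$alpha, beta = f$beta,
                varcomp = as.list(f$varcomp), n = f$n_records,
                method = f$diagnostics$method)
         }),
         evaluation = evaluation,
         percentile = percentile,
         seed = cfg$seed),
    class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, "study.csv")
    truth <- file.path(out_dir, "truth.json")
    rpt <- file.path(out_dir, "report.json")
    export_study(study, csv, truth)
    jsonlite::write_json(unclass(report), rpt, auto_unbox = TRUE,
                         digits = NA)
    write_manifest(file.path(out_dir, "manifest.json"), "synth-study",
                   outputs = c(csv, truth, rpt), seed = cfg$seed)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed =", x$seed, "\n")
  cat("  group sizes:",
      paste(names(x$group_sizes), unlist(x$group_sizes), sep = "=",
            collapse = ", "), "\n")
  for (g in names(x$fits)) {
    f <- x$fits[[g]]
    ev <- x$evaluation[[g]]
    cat(sprintf(
      "  %-18s alpha=%6.3f beta=%6.3f  r_sp=%5.2f  exceed=%4.1f%%  SEC:%s\n",
      g, f$alpha, f$beta, ev$correlation$spearman,
      100 * ev$sec_criteria$exceedance_fraction,
      ifelse(ev$sec_criteria$overall_pass, "pass", "FAIL")))
  }
  invisible(x)
}
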