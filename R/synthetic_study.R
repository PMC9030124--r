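# Synthetic calibration-study generator.
#
# Emulates the structure of the pooled calibration studies the score models
# are fitted on: four exposure groups, companies nested in industry strata,
# workers nested in companies, lognormal measurement noise, and subjective
# assessor assignment noise (a one-step random walk on the {1,3}x10^k
# multiplier grid applied to qualitative multipliers only).
#
# Generative model per record, within stratum s:
#   ln C = alpha_s + beta_s * ln B_true + b_company + b_worker + eps
# where B_true is the STOFFENMANAGER-form score computed from the true
# multipliers, eps ~ N(0, ln(GSD)^2), and alpha_s is anchored so that the
# stratum's reference scenario maps onto the near-field steady-state
# concentration of a stratum-specific two-compartment parameter set.

# Qualitative multiplier choice sets (values on the half-decade grid); the
# reference scenario takes the middle (or first) choice of every factor.
.SM_FACTORS <- list(
  E        = list(choices = c(1, 3, 10),     qualitative = TRUE),
  H        = list(choices = c(0.3, 1, 3),    qualitative = TRUE),
  eta_lcnf = list(choices = c(0.3, 1),       qualitative = TRUE),
  eta_gvnf = list(choices = c(0.3, 1),       qualitative = TRUE),
  eta_lcff = list(choices = c(0.3, 1),       qualitative = TRUE),
  eta_gvff = list(choices = c(0.3, 1),       qualitative = TRUE),
  a        = list(choices = c(0.03, 0.1, 0.3), qualitative = TRUE),
  eta_imm  = list(choices = 1,               qualitative = FALSE),
  t_h      = list(choices = c(0.3, 1),       qualitative = FALSE),
  f_h      = list(choices = c(0.3, 1),       qualitative = FALSE)
)

.DEFAULT_GROUP_COUNTS <- c(powders_granules = 408, comminuting = 112,
                           low_volatile = 256, volatile = 176)

# Stratum-specific mechanistic parameter sets anchoring the intercepts:
# three industry strata per group differing in source strength and
# ventilation (e.g. pharmacy / bakery / construction style contrasts).
.default_strata <- function(n_strata) {
  Q <- c(2, 5, 15); beta_flow <- c(2, 5, 10); G <- c(30, 100, 300)
  # stratum-specific intrinsic-emission grids; decade shifts keep the
  # choice sets on the {1,3}x10^k grid
  E_shift <- c(1, 0.1, 10)
  lapply(seq_len(n_strata), function(s) {
    i <- ((s - 1) %% 3) + 1
    list(beta = 1,
         E_shift = E_shift[i],
         box = two_compartment_params(V_nf = 8, V_ff = 100, Q = Q[i],
                                      beta = beta_flow[i], G = G[i]))
  })
}

#' Configuration of a synthetic calibration study
#'
#' Defaults mimic the pooled calibration-study structure described for the
#' score models: four exposure groups with 408/112/256/176 measurements,
#' companies nested in heterogeneous industry strata, and between-company /
#' between-worker random effects.
#'
#' @param group_counts Named integer vector of records per exposure group.
#' @param companies_per_group Companies per group (default 12).
#' @param workers_per_company Workers per company (default 3).
#' @param n_strata Industry strata per group (default 3); companies are
#'   assigned to strata cyclically.
#' @param strata Optional list overriding the per-stratum truth: each
#'   element a list with `beta` (slope), `E_shift` (factor applied to the
#'   intrinsic-emission choice set) and `box` (a
#'   [two_compartment_params()] whose near-field steady state anchors the
#'   stratum intercept).
#' @param alpha,beta Optional explicit truth overriding the mechanistic
#'   anchoring: with `alpha` given, every stratum uses
#'   `ln C = alpha + beta ln B + effects`.
#' @param sigma_bc,sigma_bw Between-company and between-worker standard
#'   deviations on the natural-log scale (defaults 0.5 and 0.3).
#' @param measurement_gsd Geometric standard deviation of the within-worker
#'   (measurement) noise (default 1.5; 1 means no noise).
#' @param p_mis Probability that the assessor shifts a qualitative
#'   multiplier one grid step (default 0.3; the real prevalence of
#'   assignment error is unknown, so this default is illustrative).
#' @param seed Integer seed; all randomness in [make_study()] flows from it.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(group_counts = .DEFAULT_GROUP_COUNTS,
                         companies_per_group = 12,
                         workers_per_company = 3,
                         n_strata = 3,
                         strata = NULL,
                         alpha = NULL, beta = NULL,
                         sigma_bc = 0.5, sigma_bw = 0.3,
                         measurement_gsd = 1.5,
                         p_mis = 0.3,
                         seed = 1L) {
  stopifnot(length(group_counts) >= 1, all(group_counts > 0),
            !is.null(names(group_counts)),
            companies_per_group >= 1, workers_per_company >= 1,
            n_strata >= 1, sigma_bc >= 0, sigma_bw >= 0,
            measurement_gsd >= 1, p_mis >= 0, p_mis <= 1)
  if (is.null(strata)) strata <- .default_strata(n_strata)
  if (!is.null(beta)) for (i in seq_along(strata)) strata[[i]]$beta <- beta
  structure(list(group_counts = group_counts,
                 companies_per_group = companies_per_group,
                 workers_per_company = workers_per_company,
                 n_strata = length(strata), strata = strata,
                 alpha = alpha,
                 sigma_bc = sigma_bc, sigma_bw = sigma_bw,
                 measurement_gsd = measurement_gsd,
                 p_mis = p_mis, seed = as.integer(seed)),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  groups:", paste(names(x$group_counts), x$group_counts, sep = "=",
                         collapse = ", "), "\n")
  cat(sprintf("  %d companies/group, %d workers/company, %d strata\n",
              x$companies_per_group, x$workers_per_company, x$n_strata))
  cat(sprintf("  sigma_bc=%g sigma_bw=%g GSD=%g p_mis=%g seed=%d\n",
              x$sigma_bc, x$sigma_bw, x$measurement_gsd, x$p_mis, x$seed))
  invisible(x)
}

# Score of a named multiplier vector under the STOFFENMANAGER form.
.sm_score_from_values <- function(v) {
  stoffenmanager_score(scenario_sm(
    E = v[["E"]], H = v[["H"]], eta_lcnf = v[["eta_lcnf"]],
    eta_gvnf = v[["eta_gvnf"]], eta_lcff = v[["eta_lcff"]],
    eta_gvff = v[["eta_gvff"]], a = v[["a"]], eta_imm = v[["eta_imm"]],
    t_h = v[["t_h"]], f_h = v[["f_h"]]))
}

.stratum_factors <- function(stratum) {
  f <- .SM_FACTORS
  f$E$choices <- f$E$choices * (stratum$E_shift %||% 1)
  f
}

.reference_values <- function(factors) {
  vapply(factors, function(fc) {
    ch <- fc$choices
    ch[ceiling(length(ch) / 2)]
  }, numeric(1))
}

.stratum_alpha <- function(cfg, stratum) {
  if (!is.null(cfg$alpha)) return(cfg$alpha)
  fx <- .stratum_factors(stratum)
  B_ref <- .sm_score_from_values(.reference_values(fx))
  M <- unname(steady_state(stratum$box)["C_nf"])
  log(M) - stratum$beta * log(B_ref)
}

#' Generate true scenarios and concentrations
#'
#' Draws, deterministically under the config seed, one true multiplier set
#' per record (each qualitative multiplier sampled from its stratum's grid
#' choice set), computes the true exposure score, and draws the true
#' concentration lognormally dispersed around the stratum regression line
#' (whose intercept is anchored to the stratum's mechanistic near-field
#' steady state).
#'
#' @param cfg A [study_config()].
#' @return A data frame with one row per record: design columns (`group`,
#'   `scenario`, `company`, `worker`, `stratum`), true multipliers
#'   (`<factor>_true`), `score_true`, `gm_true` (regression-line
#'   concentration for the record's score, before any random effect) and
#'   `concentration` (with company/worker effects and measurement noise).
#' @export
generate_true_scenarios <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(cfg$seed)
  .generate_impl(cfg)
}

.generate_impl <- function(cfg) {
  sig_e <- log(cfg$measurement_gsd)
  out <- list()
  for (g in names(cfg$group_counts)) {
    n <- cfg$group_counts[[g]]
    company_ix <- ((seq_len(n) - 1) %% cfg$companies_per_group) + 1
    worker_ix <- (((seq_len(n) - 1) %/% cfg$companies_per_group) %%
                    cfg$workers_per_company) + 1
    stratum_ix <- ((company_ix - 1) %% cfg$n_strata) + 1
    b_c <- stats::rnorm(cfg$companies_per_group, 0, cfg$sigma_bc)
    b_w <- matrix(stats::rnorm(cfg$companies_per_group *
                                 cfg$workers_per_company, 0, cfg$sigma_bw),
                  cfg$companies_per_group, cfg$workers_per_company)
    alphas <- vapply(cfg$strata, function(s) .stratum_alpha(cfg, s),
                     numeric(1))
    betas <- vapply(cfg$strata, function(s) s$beta, numeric(1))

    nm <- names(.SM_FACTORS)
    vals <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
    for (i in seq_len(n)) {
      fx <- .stratum_factors(cfg$strata[[stratum_ix[i]]])
      vals[i, ] <- vapply(fx, function(fc) {
        ch <- fc$choices
        if (length(ch) == 1) ch else sample(ch, 1)
      }, numeric(1))
    }
    score_true <- apply(vals, 1, .sm_score_from_values)
    gm_true <- exp(alphas[stratum_ix] + betas[stratum_ix] * log(score_true))
    eps <- if (sig_e > 0) stats::rnorm(n, 0, sig_e) else numeric(n)
    conc <- gm_true * exp(b_c[company_ix] +
                            b_w[cbind(company_ix, worker_ix)] + eps)

    df <- data.frame(
      group = g,
      scenario = sprintf("%s_s%04d", g, seq_len(n)),
      company = sprintf("%s_c%02d", g, company_ix),
      worker = sprintf("%s_c%02d_w%02d", g, company_ix, worker_ix),
      stratum = stratum_ix,
      stringsAsFactors = FALSE
    )
    colnames(vals) <- paste0(nm, "_true")
    df <- cbind(df, as.data.frame(vals))
    df$score_true <- score_true
    df$gm_true <- gm_true
    df$concentration <- conc
    out[[g]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply assessor assignment noise to a multiplier set
#'
#' Each qualitative multiplier is independently shifted one step on the
#' \{1,3\}x10^k grid (up or down with equal probability) with probability
#' `p_mis`; quantitative multipliers are never perturbed. Off-grid
#' qualitative inputs are an error.
#'
#' @param values Named numeric vector of multiplier values.
#' @param qualitative Logical vector (same length/names) marking which
#'   entries are qualitative.
#' @param p_mis Mis-assignment probability in \[0, 1\].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Named numeric vector of assigned multipliers.
#' @export
emulate_assessor <- function(values, qualitative, p_mis, seed = NULL) {
  stopifnot(is.numeric(values), length(qualitative) == length(values),
            p_mis >= 0, p_mis <= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- values
  for (i in which(qualitative)) {
    if (!on_grid(values[i])) {
      stop("qualitative multiplier '", names(values)[i], "' = ", values[i],
           " is not on the {1,3}x10^k grid")
    }
    if (p_mis > 0 && stats::runif(1) < p_mis) {
      nb <- grid_neighbours(values[i])
      out[i] <- nb[sample.int(2, 1)]
    }
  }
  out
}

#' Generate a full synthetic calibration study
#'
#' Composes [generate_true_scenarios()] (true multipliers, scores and
#' concentrations), [emulate_assessor()] (noisy multiplier assignment),
#' and the score model (observed scores from assigned multipliers). The
#' returned records carry both the observed channel (what a calibration
#' would see) and the truth channel.
#'
#' @param cfg A [study_config()].
#' @return A data frame of class `synthetic_study`: the columns of
#'   [generate_true_scenarios()] plus assigned multipliers
#'   (`<factor>_obs`) and the observed `score`. `concentration` and
#'   `score` together with `company`/`worker`/`group` form the observed
#'   calibration dataset.
#' @examples
#' cfg <- study_config(group_counts = c(powders_granules = 40),
#'                     companies_per_group = 4, seed = 7)
#' head(make_study(cfg))
#' @export
make_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(cfg$seed)
  truth <- .generate_impl(cfg)
  nm <- names(.SM_FACTORS)
  qual <- vapply(.SM_FACTORS, `[[`, logical(1), "qualitative")
  tv <- as.matrix(truth[, paste0(nm, "_true")])
  obs <- tv
  for (i in seq_len(nrow(tv))) {
    v <- tv[i, ]
    names(v) <- nm
    obs[i, ] <- emulate_assessor(v, qual, cfg$p_mis)
  }
  colnames(obs) <- paste0(nm, "_obs")
  res <- cbind(truth, as.data.frame(obs))
  res$score <- apply(obs, 1, function(r) {
    names(r) <- nm
    .sm_score_from_values(r)
  })
  class(res) <- c("synthetic_study", "data.frame")
  attr(res, "config") <- cfg
  res
}

#' Export a synthetic study to files
#'
#' Writes the observed channel (what a real calibration study would see) as
#' CSV and the truth channel as a JSON sidecar; the seed is recorded in
#' both.
#'
#' @param study A `synthetic_study` from [make_study()].
#' @param csv_path Output CSV path (observed records).
#' @param truth_path Output JSON path (truth channel), or `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
export_study <- function(study, csv_path, truth_path = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  cfg <- attr(study, "config")
  obs_cols <- c("scenario", "group", "company", "worker", "score",
                "concentration")
  obs <- study[, obs_cols]
  names(obs)[names(obs) == "concentration"] <- "concentration_mg_m3"
  obs$seed <- cfg$seed
  utils::write.csv(obs, csv_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    truth_cols <- setdiff(names(study), c("score", "concentration"))
    jsonlite::write_json(
      list(seed = cfg$seed,
           p_mis = cfg$p_mis,
           measurement_gsd = cfg$measurement_gsd,
           records = study[, truth_cols]),
      truth_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, truth_path))
}
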