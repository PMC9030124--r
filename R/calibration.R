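# Score -> concentration calibration: lognormal mixed-effects regression.
#
# ln(concentration) = alpha + beta_s * ln(score) + random effects + residual
#
# "sm" mode uses random between-company intercepts (between-company and
# within-company variance components); "art" mode adds a worker-within-
# company intercept (between-company, between-worker, within-worker).
# Natural logarithms throughout.

.CAL_GROUPS_SM <- c("powders_granules", "comminuting", "low_volatile",
                    "volatile")
.CAL_GROUPS_ART <- c("dusts", "vapours", "mists_low_volatile",
                     "solid_abrasion")

.check_records <- function(records) {
  need <- c("concentration", "score", "company", "group")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("measurement records missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(!is.finite(records$concentration) | records$concentration <= 0)) {
    stop("all concentrations must be strictly positive (log-transformable)")
  }
  if (any(!is.finite(records$score) | records$score <= 0)) {
    stop("all scores must be strictly positive (log-transformable)")
  }
  invisible(records)
}

#' Partition measurement records into exposure groups
#'
#' Splits a table of (score, concentration) measurement records by exposure
#' group and reports per-group record and company counts. Groups with fewer
#' records than `min_n` are flagged and excluded from fitting unless
#' `force = TRUE`.
#'
#' @param records Data frame with columns `concentration` (mg m\eqn{^{-3}},
#'   > 0), `score` (> 0), `company`, `group`, and optionally `worker` and
#'   `scenario`.
#' @param mode `"sm"` (two variance components) or `"art"` (three).
#' @param min_n Minimum records per group for fitting (default 20).
#' @param force Keep under-sized groups anyway.
#' @return A list of class `calibration_groups`: `datasets` (named list of
#'   per-group data frames), `summary` (counts), `excluded` (names of
#'   flagged groups).
#' @export
assemble_groups <- function(records, mode = c("sm", "art"), min_n = 20,
                            force = FALSE) {
  mode <- match.arg(mode)
  if (nrow(records) == 0) {
    return(structure(list(datasets = list(),
                          summary = data.frame(group = character(),
                                               n = integer(),
                                               n_companies = integer(),
                                               excluded = logical()),
                          excluded = character(), mode = mode),
                     class = "calibration_groups"))
  }
  .check_records(records)
  sp <- split(records, records$group)
  summary <- data.frame(
    group = names(sp),
    n = vapply(sp, nrow, integer(1)),
    n_companies = vapply(sp, function(d) length(unique(d$company)),
                         integer(1)),
    stringsAsFactors = FALSE
  )
  summary$excluded <- summary$n < min_n & !force
  keep <- names(sp)[!summary$excluded]
  structure(list(datasets = sp[keep], summary = summary,
                 excluded = setdiff(names(sp), keep), mode = mode),
            class = "calibration_groups")
}

#' @export
print.calibration_groups <- function(x, ...) {
  cat("<calibration_groups> mode =", x$mode, "\n")
  print.data.frame(x$summary, row.names = FALSE)
  invisible(x)
}

# Method-of-moments fallback: OLS fixed effects plus one-way ANOVA variance
# components on the residuals grouped by company.
.mom_fit <- function(d, mode, fix_slope = FALSE) {
  ols <- if (fix_slope) {
    stats::lm(log(concentration) ~ 1 + offset(log(score)), data = d)
  } else {
    stats::lm(log(concentration) ~ log(score), data = d)
  }
  res <- stats::resid(ols)
  comp <- factor(d$company)
  k <- nlevels(comp)
  grand <- mean(res)
  within <- res - stats::ave(res, comp)
  s2_w <- sum(within^2) / max(length(res) - k, 1)
  means <- tapply(res, comp, mean)
  ni <- tapply(res, comp, length)
  n0 <- (sum(ni) - sum(ni^2) / sum(ni)) / max(k - 1, 1)
  s2_b <- max((sum(ni * (means - grand)^2) / max(k - 1, 1) - s2_w) / n0, 0)
  vc <- if (mode == "sm") {
    c(between_company = s2_b, within_company = s2_w)
  } else {
    c(between_company = s2_b, between_worker = 0, within_worker = s2_w)
  }
  list(coef = stats::coef(ols), vcov = stats::vcov(ols), varcomp = vc,
       method = "method-of-moments")
}

#' Fit a lognormal mixed-effects calibration model
#'
#' Fits, by restricted maximum likelihood,
#' \deqn{\ln C = \alpha + \beta_s \ln S + b_{company} (+ b_{worker}) +
#'       \epsilon}
#' to the records of one exposure group. In `"sm"` mode the variance
#' components are between-company and within-company; in `"art"` mode a
#' worker-within-company intercept splits the residual into between-worker
#' and within-worker components. With a single company (or a singular fit)
#' the between-company component is reported as 0 with a warning; on
#' convergence failure a method-of-moments fallback is used and recorded in
#' the diagnostics.
#'
#' @param dataset Data frame of one group's records (columns
#'   `concentration`, `score`, `company`, and `worker` for `"art"` mode).
#' @param mode `"sm"` or `"art"`.
#' @param min_n Minimum number of records (default 20).
#' @param fix_slope If `TRUE`, fixes \eqn{\beta_s = 1} (single
#'   multiplicative calibration-factor reading) and estimates only the
#'   intercept.
#' @return An object of class `calibration_fit` with elements `alpha`,
#'   `beta` (natural-log scale), `varcomp` (named variance components),
#'   `vcov` (fixed-effect covariance), `n_records`, `n_companies`,
#'   `group`, `mode`, `log_base` (`"natural"`), `diagnostics`.
#' @export
fit_calibration <- function(dataset, mode = c("sm", "art"), min_n = 20,
                            fix_slope = FALSE) {
  mode <- match.arg(mode)
  .check_records(dataset)
  if (nrow(dataset) < min_n) {
    stop("group has ", nrow(dataset), " records; minimum is ", min_n)
  }
  d <- dataset
  d$lnC <- log(d$concentration)
  d$lnS <- log(d$score)
  n_comp <- length(unique(d$company))
  if (mode == "art" && is.null(d$worker)) {
    stop("'art' mode requires a 'worker' column")
  }

  single_company <- n_comp < 2
  fit <- NULL
  method <- "REML"
  if (!single_company) {
    form <- if (mode == "sm") {
      if (fix_slope) lnC ~ 1 + offset(lnS) + (1 | company)
      else lnC ~ lnS + (1 | company)
    } else {
      if (fix_slope) lnC ~ 1 + offset(lnS) + (1 | company) + (1 | company:worker)
      else lnC ~ lnS + (1 | company) + (1 | company:worker)
    }
    fit <- tryCatch(
      suppressMessages(lme4::lmer(form, data = d, REML = TRUE)),
      error = function(e) NULL)
  }

  if (is.null(fit)) {
    if (single_company) {
      warning("only one company: between-company variance reported as 0")
    }
    mm <- .mom_fit(d, mode, fix_slope)
    if (single_company) mm$varcomp["between_company"] <- 0
    coefs <- mm$coef
    alpha <- unname(coefs[1])
    beta <- if (fix_slope) 1 else unname(coefs[2])
    vc <- mm$varcomp
    vcv <- mm$vcov
    method <- mm$method
  } else {
    vcl <- lme4::VarCorr(fit)
    s2_comp <- as.numeric(vcl$company[1, 1])
    s2_res <- attr(vcl, "sc")^2
    if (mode == "sm") {
      vc <- c(between_company = s2_comp, within_company = s2_res)
    } else {
      s2_wrk <- as.numeric(vcl[["company:worker"]][1, 1])
      vc <- c(between_company = s2_comp, between_worker = s2_wrk,
              within_worker = s2_res)
    }
    if (lme4::isSingular(fit) && vc["between_company"] == 0) {
      warning("singular fit: between-company variance estimated as 0")
    }
    fe <- lme4::fixef(fit)
    alpha <- unname(fe[1])
    beta <- if (fix_slope) 1 else unname(fe["lnS"])
    vcv <- as.matrix(stats::vcov(fit))
  }
  # fixed-slope fits carry a 1x1 covariance; embed it so downstream
  # bootstrap code can always draw (alpha, beta) jointly
  if (nrow(vcv) == 1) {
    vcv <- matrix(c(vcv[1, 1], 0, 0, 0), 2, 2)
  }

  structure(list(alpha = alpha, beta = beta, varcomp = vc, vcov = vcv,
                 n_records = nrow(d), n_companies = n_comp,
                 group = if (!is.null(d$group)) as.character(d$group[1])
                         else NA_character_,
                 mode = mode, fix_slope = fix_slope,
                 log_base = "natural",
                 diagnostics = list(method = method)),
            class = "calibration_fit")
}

#' Construct a calibration fit from known parameters
#'
#' Builds a `calibration_fit` directly from intercept, slope and variance
#' components — useful for prediction with externally supplied calibration
#' constants or in simulation studies.
#'
#' @param alpha Intercept on the natural-log scale.
#' @param beta Slope on ln(score).
#' @param varcomp Named numeric vector of non-negative variance components.
#' @param mode `"sm"` or `"art"`.
#' @return A `calibration_fit`.
#' @export
calibration_fit <- function(alpha, beta = 1, varcomp = c(
                              between_company = 0, within_company = 0),
                            mode = "sm") {
  stopifnot(all(varcomp >= 0))
  structure(list(alpha = alpha, beta = beta, varcomp = varcomp,
                 vcov = matrix(0, 2, 2), n_records = NA_integer_,
                 n_companies = NA_integer_, group = NA_character_,
                 mode = mode, fix_slope = FALSE, log_base = "natural",
                 diagnostics = list(method = "supplied")),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>", if (!is.na(x$group)) paste0("group = ", x$group),
      "\n")
  cat(sprintf("  ln C = %.4f + %.4f ln S   (natural log, %s)\n",
              x$alpha, x$beta, x$diagnostics$method))
  cat("  variance components:",
      paste(names(x$varcomp), signif(x$varcomp, 4), sep = "=",
            collapse = ", "), "\n")
  cat(sprintf("  n = %s records, %s companies\n", x$n_records,
              x$n_companies))
  invisible(x)
}

#' Predicted geometric-mean concentration for a score
#'
#' \deqn{GM(S) = \exp(\alpha + \beta_s \ln S)}
#'
#' @param fit A `calibration_fit`.
#' @param score Exposure score (> 0); vectorized.
#' @return Geometric-mean concentration, mg m\eqn{^{-3}}.
#' @export
predict_gm <- function(fit, score) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (any(!is.finite(score) | score <= 0)) {
    stop("score must be strictly positive")
  }
  exp(fit$alpha + fit$beta * log(score))
}

#' Predicted exposure-distribution percentile for a score
#'
#' The exposure distribution around the calibration line is lognormal with
#' total variance equal to the sum of the fitted variance components, so
#' \deqn{X_p(S) = GM(S) \exp(z_p \sigma_{total}).}
#' With `conf` given, the upper confidence bound on that percentile is
#' computed by a seeded parametric bootstrap: fixed effects are drawn from
#' a bivariate normal with the fit's covariance, and each variance
#' component from a scaled inverse-chi-square with its effective degrees of
#' freedom (companies - 1 for the between-company component; records -
#' companies for the residual component).
#'
#' @param fit A `calibration_fit`.
#' @param score Exposure score (> 0), scalar.
#' @param p Percentile in (0, 1), e.g. 0.9.
#' @param conf Confidence level for an upper bound on the percentile, or
#'   `NULL` for the point estimate.
#' @param n_boot Bootstrap draws (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return Concentration, mg m\eqn{^{-3}}.
#' @export
predict_percentile <- function(fit, score, p, conf = NULL, n_boot = 2000,
                               seed = 1L) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    stop("percentile p must lie strictly between 0 and 1")
  }
  sigma_tot <- sqrt(sum(fit$varcomp))
  point <- predict_gm(fit, score) * exp(stats::qnorm(p) * sigma_tot)
  if (is.null(conf)) return(point)
  stopifnot(conf > 0, conf < 1)

  n <- fit$n_records
  k <- fit$n_companies
  if (is.na(n) || is.na(k)) {
    stop("confidence bounds require a fit with known sample sizes")
  }
  df_for <- function(nm) {
    switch(nm,
           between_company = max(k - 1, 1),
           between_worker = max(k - 1, 1),
           within_company = max(n - k, 1),
           within_worker = max(n - k, 1),
           max(n - 1, 1))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fe <- .mvrnorm2(n_boot, c(fit$alpha, fit$beta), fit$vcov)
  vdraw <- vapply(names(fit$varcomp), function(nm) {
    df <- df_for(nm)
    fit$varcomp[[nm]] * df / stats::rchisq(n_boot, df)
  }, numeric(n_boot))
  if (is.null(dim(vdraw))) vdraw <- matrix(vdraw, nrow = n_boot)
  sig <- sqrt(rowSums(vdraw))
  draws <- exp(fe[, 1] + fe[, 2] * log(score) + stats::qnorm(p) * sig)
  max(stats::quantile(draws, conf, names = FALSE), point)
}

# Bivariate/multivariate normal draw via Cholesky (with a PSD fallback).
.mvrnorm2 <- function(n, mu, Sigma) {
  d <- length(mu)
  L <- tryCatch(chol(Sigma), error = function(e) {
    ev <- eigen(Sigma, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d) %*% t(ev$vectors)
  })
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% L, 2, mu, "+")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
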