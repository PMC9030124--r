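# The multiplicative exposure-score model family.
#
# All scores are dimensionless by construction: concentration units only
# appear after translation through an OEL (score_to_concentration_oel) or a
# fitted calibration (predict_gm / predict_percentile).

.check_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop("'", what, "' must be a single non-negative number")
  }
  invisible(x)
}

#' Multiplicative workplace exposure estimate
#'
#' The simplest multiplicative model: a measured base estimate BE
#' (mg m\eqn{^{-3}}) scaled by dimensionless exposure-modifying factors,
#' \deqn{WE = BE \cdot K_1 \cdot K_2 \cdots K_n.}
#' An empty factor list returns BE unchanged.
#'
#' @param BE Base estimate concentration, mg m\eqn{^{-3}} (>= 0).
#' @param K Numeric vector of exposure-modifying factors, all > 0.
#' @return Workplace exposure estimate WE, mg m\eqn{^{-3}}.
#' @examples
#' multiplicative_estimate(2, c(0.5, 3))  # 3
#' @export
multiplicative_estimate <- function(BE, K = numeric()) {
  .check_nonneg(BE, "BE")
  if (length(K) > 0 && (!is.numeric(K) || any(is.na(K)) || any(K <= 0))) {
    stop("all exposure-modifying factors K must be > 0")
  }
  BE * prod(K)
}

.scenario <- function(fields, cls) {
  for (nm in names(fields)) .check_nonneg(fields[[nm]], nm)
  structure(fields, class = c(cls, "exposure_scenario"))
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Scenario for the 1996 structured subjective exposure score
#'
#' Bundles the multipliers of the two-zone score in which the total emission
#' \eqn{\epsilon_T = \epsilon_i h \eta_{lev} + \epsilon_p} (active plus
#' passive) is shared by the near-field and far-field terms.
#'
#' @param eps_i Intrinsic emission multiplier (dimensionless).
#' @param h Handling/processing multiplier.
#' @param eta_lev Engineering-control (local exhaust) multiplier.
#' @param eps_p Passive emission multiplier.
#' @param t_a_nf,t_a_ff Source active-time multipliers for the near and far
#'   field.
#' @param eta_ppe Personal protection multiplier.
#' @param d_gv General ventilation multiplier applied to the far-field term.
#' @return An `exposure_scenario` of class `scenario_cherrie96`.
#' @export
scenario_cherrie96 <- function(eps_i, h, eta_lev, eps_p = 0,
                               t_a_nf = 1, t_a_ff = 0,
                               eta_ppe = 1, d_gv = 1) {
  .scenario(list(eps_i = eps_i, h = h, eta_lev = eta_lev, eps_p = eps_p,
                 t_a_nf = t_a_nf, t_a_ff = t_a_ff, eta_ppe = eta_ppe,
                 d_gv = d_gv), "scenario_cherrie96")
}

#' Compute the 1996-form exposure score C
#'
#' \deqn{C = \epsilon_T t_{a,NF} \eta_{ppe} +
#'           \epsilon_T t_{a,FF} \eta_{ppe} d_{gv}}
#' with \eqn{\epsilon_T = \epsilon_i h \eta_{lev} + \epsilon_p}. The general
#' ventilation multiplier is grouped outermost on the far-field term.
#'
#' @param s A `scenario_cherrie96`.
#' @return Dimensionless exposure score C.
#' @examples
#' cherrie96_score(scenario_cherrie96(eps_i = 10, h = 1, eta_lev = 1,
#'                                    t_a_nf = 1, t_a_ff = 1, d_gv = 0.1))
#' @export
cherrie96_score <- function(s) {
  stopifnot(inherits(s, "scenario_cherrie96"))
  eps_T <- s$eps_i * s$h * s$eta_lev + s$eps_p
  eps_T * s$t_a_nf * s$eta_ppe + eps_T * s$t_a_ff * s$eta_ppe * s$d_gv
}

#' Scenario for the 1999 revision of the subjective exposure score
#'
#' The passive emission multiplier is separated from the source active time,
#' and the near- and far-field intrinsic emissions may differ.
#'
#' @param eps_i_nf,eps_i_ff Intrinsic emission multipliers per zone.
#' @param h Handling multiplier (shared across zones).
#' @param eta_lev Engineering-control multiplier.
#' @param eps_p Passive emission multiplier.
#' @param t_a_nf,t_a_ff Source active-time multipliers.
#' @param eta_ppe Personal protection multiplier.
#' @param d_gv General ventilation multiplier on the far-field term.
#' @return An `exposure_scenario` of class `scenario_cherrie99`.
#' @export
scenario_cherrie99 <- function(eps_i_nf, eps_i_ff, h, eta_lev, eps_p = 0,
                               t_a_nf = 1, t_a_ff = 0, eta_ppe = 1,
                               d_gv = 1) {
  .scenario(list(eps_i_nf = eps_i_nf, eps_i_ff = eps_i_ff, h = h,
                 eta_lev = eta_lev, eps_p = eps_p, t_a_nf = t_a_nf,
                 t_a_ff = t_a_ff, eta_ppe = eta_ppe, d_gv = d_gv),
            "scenario_cherrie99")
}

#' Compute the 1999-form exposure score C
#'
#' \deqn{C = (\epsilon_{i,NF} h \eta_{lev} t_{a,NF} + \epsilon_p)\eta_{ppe}
#'         + (\epsilon_{i,FF} h \eta_{lev} t_{a,FF} + \epsilon_p)\eta_{ppe}
#'           d_{gv}}
#'
#' @param s A `scenario_cherrie99`.
#' @return Dimensionless exposure score C.
#' @export
cherrie99_score <- function(s) {
  stopifnot(inherits(s, "scenario_cherrie99"))
  nf <- (s$eps_i_nf * s$h * s$eta_lev * s$t_a_nf + s$eps_p) * s$eta_ppe
  ff <- (s$eps_i_ff * s$h * s$eta_lev * s$t_a_ff + s$eps_p) * s$eta_ppe *
    s$d_gv
  nf + ff
}

#' STOFFENMANAGER-style scenario
#'
#' A single intrinsic-emission multiplier `E` is shared by the near-field,
#' far-field and background terms (the tool assumes the worker is always in
#' the near field and that the same handling `H` is conducted in the far
#' field as in the near field, so `H` is likewise a single field — requests
#' for zone-specific handling are unrepresentable by construction).
#'
#' @param E Intrinsic emission multiplier.
#' @param H Activity (handling) emission potential multiplier.
#' @param eta_lcnf,eta_lcff Localized-control multipliers, NF and FF.
#' @param eta_gvnf,eta_gvff General-ventilation multipliers, NF and FF.
#' @param a Relative multiplier for background/diffusive sources.
#' @param eta_imm Personal protection (immission) multiplier.
#' @param t_h Source active-time multiplier.
#' @param f_h Handling-frequency multiplier.
#' @return An `exposure_scenario` of class `scenario_sm`.
#' @export
scenario_sm <- function(E, H, eta_lcnf = 1, eta_gvnf = 1, eta_lcff = 1,
                        eta_gvff = 1, a = 0, eta_imm = 1, t_h = 1,
                        f_h = 1) {
  .scenario(list(E = E, H = H, eta_lcnf = eta_lcnf, eta_gvnf = eta_gvnf,
                 eta_lcff = eta_lcff, eta_gvff = eta_gvff, a = a,
                 eta_imm = eta_imm, t_h = t_h, f_h = f_h), "scenario_sm")
}

#' Compute the STOFFENMANAGER subjective exposure score B
#'
#' \deqn{B = [(E H \eta_{lcnf} \eta_{gvnf}) + (E H \eta_{lcff} \eta_{gvff})
#'          + (E a)] \cdot \eta_{imm} t_h f_h}
#' The score is linear in `E` because all three additive terms carry it.
#'
#' @param s A `scenario_sm`.
#' @return Dimensionless exposure score B.
#' @examples
#' s <- scenario_sm(E = 10, H = 3, eta_gvnf = 0.3, eta_gvff = 0.3, a = 0.1)
#' stoffenmanager_score(s)  # 19
#' @export
stoffenmanager_score <- function(s) {
  stopifnot(inherits(s, "scenario_sm"))
  ((s$E * s$H * s$eta_lcnf * s$eta_gvnf) +
     (s$E * s$H * s$eta_lcff * s$eta_gvff) +
     (s$E * s$a)) * s$eta_imm * s$t_h * s$f_h
}

#' Advanced-REACH-Tool-style scenario
#'
#' Extends the STOFFENMANAGER structure with personal behavior (`P_nf`),
#' surface contamination (`Su`, replacing the background term and allowed to
#' be zero), dilution per zone (`D`), far-field segregation (`Seg_ff`),
#' worker separation (`Sep_ff`), and respiratory protection (`RPE`).
#'
#' @param E_nf,E_ff Substance emission potential multipliers per zone.
#' @param H_nf,H_ff Activity emission potential multipliers per zone.
#' @param LC_nf,LC_ff Localized-control multipliers per zone.
#' @param P_nf Personal behavior multiplier (near field).
#' @param Su_nf,Su_ff Surface contamination multipliers (may be 0).
#' @param D_nf,D_ff Dilution multipliers per zone.
#' @param Seg_ff Segregation multiplier (far field).
#' @param Sep_ff Separation multiplier (far field).
#' @param RPE Respiratory protective equipment multiplier.
#' @return An `exposure_scenario` of class `scenario_art`.
#' @export
scenario_art <- function(E_nf, H_nf, LC_nf = 1, P_nf = 1, Su_nf = 0,
                         D_nf = 1, E_ff = 0, H_ff = 0, LC_ff = 1,
                         Seg_ff = 1, Su_ff = 0, D_ff = 1, Sep_ff = 1,
                         RPE = 1) {
  .scenario(list(E_nf = E_nf, H_nf = H_nf, LC_nf = LC_nf, P_nf = P_nf,
                 Su_nf = Su_nf, D_nf = D_nf, E_ff = E_ff, H_ff = H_ff,
                 LC_ff = LC_ff, Seg_ff = Seg_ff, Su_ff = Su_ff,
                 D_ff = D_ff, Sep_ff = Sep_ff, RPE = RPE), "scenario_art")
}

#' Compute the ART subjective exposure score Ct
#'
#' \deqn{C_t = [(E_{nf} H_{nf} LC_{nf} P_{nf} + Su_{nf}) D_{nf}
#'           + (E_{ff} H_{ff} LC_{ff} Seg_{ff} + Su_{ff}) D_{ff} Sep_{ff}]
#'           \cdot RPE}
#'
#' @param s A `scenario_art`.
#' @return Dimensionless exposure score Ct.
#' @examples
#' s <- scenario_art(E_nf = 10, H_nf = 3, LC_nf = 0.3, D_nf = 3,
#'                   E_ff = 10, H_ff = 3, D_ff = 0.3, RPE = 0.1)
#' art_score(s)  # 3.6
#' @export
art_score <- function(s) {
  stopifnot(inherits(s, "scenario_art"))
  nf <- (s$E_nf * s$H_nf * s$LC_nf * s$P_nf + s$Su_nf) * s$D_nf
  ff <- (s$E_ff * s$H_ff * s$LC_ff * s$Seg_ff + s$Su_ff) * s$D_ff * s$Sep_ff
  (nf + ff) * s$RPE
}

#' Translate an exposure score to a concentration via an OEL
#'
#' In the OEL translation a dimensionless exposure score of 1 corresponds to
#' the occupational exposure limit, so the concentration is simply
#' `score * OEL`.
#'
#' @param score Dimensionless exposure score (>= 0).
#' @param OEL Occupational exposure limit, mg m\eqn{^{-3}} (> 0).
#' @return Concentration, mg m\eqn{^{-3}}.
#' @export
score_to_concentration_oel <- function(score, OEL) {
  .check_nonneg(score, "score")
  if (!is.numeric(OEL) || length(OEL) != 1 || is.na(OEL) || OEL <= 0) {
    stop("'OEL' must be a single positive concentration (mg m-3)")
  }
  score * OEL
}

# Generic score dispatcher used by the workbench CLI.
score_scenario <- function(s) {
  switch(class(s)[1],
         scenario_cherrie96 = cherrie96_score(s),
         scenario_cherrie99 = cherrie99_score(s),
         scenario_sm = stoffenmanager_score(s),
         scenario_art = art_score(s),
         stop("not an exposure scenario"))
}
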