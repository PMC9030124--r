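# Independent oracles used across the suite. These are literal
# transcriptions / brute-force routes kept deliberately separate from the
# package implementations they check.

# Literal transcriptions of the printed score equations ------------------

oracle_cherrie96 <- function(eps_i, h, eta_lev, eps_p, t_a_nf, t_a_ff,
                             eta_ppe, d_gv) {
  eps_T <- eps_i * h * eta_lev + eps_p
  eps_T * t_a_nf * eta_ppe + eps_T * t_a_ff * eta_ppe * d_gv
}

oracle_cherrie99 <- function(eps_i_nf, eps_i_ff, h, eta_lev, eps_p,
                             t_a_nf, t_a_ff, eta_ppe, d_gv) {
  (eps_i_nf * h * eta_lev * t_a_nf + eps_p) * eta_ppe +
    (eps_i_ff * h * eta_lev * t_a_ff + eps_p) * eta_ppe * d_gv
}

oracle_sm <- function(E, H, eta_lcnf, eta_gvnf, eta_lcff, eta_gvff, a,
                      eta_imm, t_h, f_h) {
  ((E * H * eta_lcnf * eta_gvnf) + (E * H * eta_lcff * eta_gvff) +
     (E * a)) * eta_imm * t_h * f_h
}

oracle_art <- function(E_nf, H_nf, LC_nf, P_nf, Su_nf, D_nf, E_ff, H_ff,
                       LC_ff, Seg_ff, Su_ff, D_ff, Sep_ff, RPE) {
  ((E_nf * H_nf * LC_nf * P_nf + Su_nf) * D_nf +
     (E_ff * H_ff * LC_ff * Seg_ff + Su_ff) * D_ff * Sep_ff) * RPE
}

# Analytic two-box solution for constant emission ------------------------
# dC/dt = A C + b with
#   A = [ -beta/V_nf            beta/V_nf        ]
#       [  beta/V_ff   -(beta + Q)/V_ff          ]
#   b = (G'/V_nf, 0)
# solved by eigen-decomposition: C(t) = S exp(Lt) S^-1 (C0 - Css) + Css
oracle_two_box <- function(p, times) {
  Geff <- p$G * (1 - p$lev_efficiency)
  A <- matrix(c(-p$beta / p$V_nf, p$beta / p$V_nf,
                p$beta / p$V_ff, -(p$beta + p$Q) / p$V_ff),
              2, 2, byrow = TRUE)
  b <- c(Geff / p$V_nf, 0)
  css <- if (p$Q > 0 || Geff == 0) solve(A, -b) else
    stop("oracle needs Q > 0 or a zero source")
  ev <- eigen(A)
  S <- ev$vectors
  Sinv <- solve(S)
  C0 <- c(p$C0_nf, p$C0_ff)
  t(vapply(times, function(t) {
    as.numeric(S %*% diag(exp(ev$values * t)) %*% Sinv %*% (C0 - css) +
                 css)
  }, numeric(2)))
}

# Brute-force rank correlation (midranks, Pearson on ranks) --------------

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Random valid scenarios -------------------------------------------------

rand_pos <- function(n) exp(runif(n, log(0.05), log(20)))

rand_sm_scenario <- function() {
  v <- rand_pos(10)
  scenario_sm(E = v[1], H = v[2], eta_lcnf = v[3], eta_gvnf = v[4],
              eta_lcff = v[5], eta_gvff = v[6], a = v[7], eta_imm = v[8],
              t_h = v[9], f_h = v[10])
}

rand_art_scenario <- function() {
  v <- rand_pos(14)
  scenario_art(E_nf = v[1], H_nf = v[2], LC_nf = v[3], P_nf = v[4],
               Su_nf = v[5], D_nf = v[6], E_ff = v[7], H_ff = v[8],
               LC_ff = v[9], Seg_ff = v[10], Su_ff = v[11], D_ff = v[12],
               Sep_ff = v[13], RPE = v[14])
}

quoted_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "taxonomy_quoted.csv",
                            package = "exposcore"))
}

# Small simulated calibration dataset with known truth -------------------

sim_records <- function(n, alpha, beta, sigma_bc = 0, sigma_res = 0,
                        n_companies = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  score <- exp(runif(n, log(0.5), log(50)))
  company <- rep_len(sprintf("c%02d", seq_len(n_companies)), n)
  bc <- stats::rnorm(n_companies, 0, sigma_bc)[rep_len(
    seq_len(n_companies), n)]
  conc <- exp(alpha + beta * log(score) + bc +
                stats::rnorm(n, 0, sigma_res))
  data.frame(concentration = conc, score = score, company = company,
             worker = paste0(company, "_w1"), group = "powders_granules",
             stringsAsFactors = FALSE)
}

# all permutations of 1..n (tiny n only)
.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
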