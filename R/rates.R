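## Individual rate laws, exposed for direct use and testing.

#' Transcription elongation rates
#'
#' The global transcript elongation rate saturates in the internal metabolite
#' pool, `tau_X(M) = tau_max * M / (K_tau + M)` (nucleotides per hour).  Each
#' mRNA gene completes transcripts at `tau_j = tau_X / (3 * n_j)` (its length
#' in nucleotides is three times its codon count); the rRNA gene elongates at
#' the constant `tau_r = tau_r_max / n_r` unless the model option
#' `rrn_M_dependent` makes it share the metabolite dependence.
#'
#' @param model a [CellModel-class].
#' @param M internal metabolite count (must be >= 0).
#' @return list with `tau_X` (nt/h) and `tau_j` (completed transcripts per
#'   complex per hour, named per gene).
#' @export
transcriptionElongation <- function(model, M) {
  if (!is.finite(M) || M < 0) stop("M must be finite and >= 0")
  p <- model@params
  g <- model@genes
  tau_X <- p[["tau_max"]] * M / (p[["K_tau"]] + M)
  tau_j <- ifelse(g$class == "rrn",
                  if (isTRUE(model@options$rrn_M_dependent))
                    p[["tau_r_max"]] * M / ((p[["K_tau"]] + M) * g$n)
                  else p[["tau_r_max"]] / g$n,
                  tau_X / (3 * g$n))
  list(tau_X = tau_X, tau_j = setNames(tau_j, g$name))
}

#' Translation elongation rates
#'
#' The global peptide elongation rate saturates in charged tRNA,
#' `gamma_X(t_c) = D_gamma * gamma_max * t_c / (K_gamma + t_c)` (amino acids
#' per hour; the perturbation `D_gamma` scales the maximum).  Each protein is
#' completed at `gamma_j = gamma_X / n_j`.
#'
#' @param model a [CellModel-class].
#' @param tc charged tRNA count (must be >= 0).
#' @return list with `gamma_X` (aa/h) and `gamma_j` (proteins per complex per
#'   hour, named per translated gene).
#' @export
translationElongation <- function(model, tc) {
  if (!is.finite(tc) || tc < 0) stop("tc must be finite and >= 0")
  p <- model@params
  g <- model@genes[model@genes$class != "rrn", ]
  gamma_X <- p[["D_gamma"]] * p[["gamma_max"]] * tc / (p[["K_gamma"]] + tc)
  list(gamma_X = gamma_X, gamma_j = setNames(gamma_X / g$n, g$name))
}

#' Alarmone proxy
#'
#' The regulation variable is the charged/uncharged tRNA ratio
#' `theta = t_c / t_u` (effectively the inverse of the alarmone
#' concentration), scaled by the perturbation `D_g`:
#' `theta_eff = D_g * t_c / t_u`.  `t_u` is floored at `theta_floor` inside
#' the ratio only, so that integrator trial states at the boundary stay
#' finite.
#'
#' @param tc,tu charged/uncharged tRNA counts (>= 0).
#' @param D_g regulation scaling (> 0, default 1).
#' @param theta_floor floor applied to `tu` (default 1e-9 molecules).
#' @return theta_eff >= 0.
#' @export
ppgppProxy <- function(tc, tu, D_g = 1, theta_floor = 1e-9) {
  if (any(tc < 0) || any(tu < 0)) stop("tc and tu must be >= 0")
  if (D_g <= 0) stop("D_g must be > 0")
  D_g * tc / pmax(tu, theta_floor)
}

#' Regulation functions
#'
#' Per-gene promoter regulation values in \[0, 1\]: housekeeping genes are
#' negatively autoregulated, `R_Q = 1 / (1 + (p_Q/kappa_q)^h_q)`; resource
#' genes (RNA polymerase, r-protein, rRNA) are activated by translational
#' sufficiency, `R = theta / (theta + kappa_theta)`; the enzyme gene is
#' activated by the alarmone, `R_E = kappa_theta / (theta + kappa_theta)`;
#' circuit genes scale the enzyme-type factor by their induction,
#' `R_i = (kappa_theta / (theta + kappa_theta)) * u_i`.  Note
#' `R_E + R_P = 1` at any theta.
#'
#' @param model a [CellModel-class].
#' @param state state vector; theta and `p_Q` are read from it.
#' @return named numeric vector of R_j in \[0, 1\].
#' @export
regulationValues <- function(model, state)
  derivedQuantities(model, state)$regulation

#' Effective gene copy numbers
#'
#' `g_j = g0 * exp(q_x * lambda)` captures copy-number expansion at high
#' growth rate; the rRNA gene is additionally scaled by the dosage
#' perturbation, `g_r = D_r * g_r0 * exp(q_x * lambda)`.  Circuit genes
#' follow the same expansion unless the model option
#' `circuit_copy_expansion` is `FALSE`.
#'
#' @param model a [CellModel-class].
#' @param lambda growth rate (>= 0, per hour).
#' @return named numeric vector of effective copy numbers.
#' @export
effectiveCopyNumber <- function(model, lambda) {
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be finite and >= 0")
  g <- model@genes
  p <- model@params
  ge <- g$g0 * exp(p[["q_x"]] * lambda)
  if (!isTRUE(model@options$circuit_copy_expansion))
    ge[g$class == "circuit"] <- g$g0[g$class == "circuit"]
  ge[g$class == "rrn"] <- ge[g$class == "rrn"] * p[["D_r"]]
  setNames(ge, g$name)
}

#' Proteome mass fractions
#'
#' Mass fraction of every protein class: `Phi_j = n_j * copies_j / total`,
#' where copies count free protein plus complex-bound and
#' antibiotic-sequestered copies.  The RNA polymerase class counts
#' `p_P + Pab` (transcription-complex RNAP is part of `p_P`); the ribosomal
#' class counts free r-protein plus one r-protein unit per assembled
#' (functional or sequestered) ribosome, `p_R + Rt + Rab`.  Fractions sum to
#' one.
#'
#' @param model a [CellModel-class].
#' @param state state vector.
#' @return named numeric vector of mass fractions (one entry per translated
#'   gene, names as in the gene table).
#' @export
massFractions <- function(model, state) {
  ctx <- .ctx(model)
  if (length(state) != ctx$nstate)
    stop("state length ", length(state), " != expected ", ctx$nstate)
  .mass_frac(ctx, unname(state))
}

.mass_frac <- function(ctx, x) {
  x <- pmax(x, 0)
  copies <- x[ctx$ip]
  copies[ctx$jP] <- copies[ctx$jP] + x[ctx$iPab]
  copies[ctx$jR] <- copies[ctx$jR] + x[ctx$iRt] + x[ctx$iRab]
  mass <- ctx$n[ctx$mg] * copies
  tot <- sum(mass)
  if (tot <= 0) stop("zero total protein mass; mass fractions undefined")
  setNames(mass / tot, ctx$mnames)
}
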