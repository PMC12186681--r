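## Model core: state layout, rate laws, quasi-steady-state complex partition
## and the assembled ODE right-hand side.

## Precompiled evaluation context.  Everything the RHS needs, unpacked from
## the S4 object once, so repeated evaluation (integration, Newton, sweeps)
## avoids slot access and name matching.
.ctx <- function(model) {
  g <- model@genes
  p <- as.list(model@params)
  cls <- g$class
  i_rrn <- which(cls == "rrn")
  mg <- which(cls != "rrn")          # translated (= mRNA-carrying) genes
  nm <- length(mg)
  nms <- g$name[mg]
  has_pathway <- length(model@pathway) > 0
  im <- 5L + seq_len(nm)
  ip <- 5L + nm + seq_len(nm)
  ir <- 5L + 2L * nm + 1L
  snames <- c("S", "N", "M", "tu", "tc",
              paste0("m_", nms), paste0("p_", nms),
              "r", "Rt", "Pab", "Rab",
              if (has_pathway) "X")
  list(
    p = p,
    g0 = g$g0, n = g$n,
    pb_f = g$pb_f, pb_r = g$pb_r,
    rb_f = g$rb_f[mg], rb_r = g$rb_r[mg],
    u = g$u,
    cls = cls, i_rrn = i_rrn, mg = mg, nm = nm, gnames = g$name,
    mnames = nms,
    jE = match("E", cls[mg]), jQ = match("Q", cls[mg]),
    jP = match("P", cls[mg]), jR = match("R", cls[mg]),
    jC = which(cls[mg] == "circuit"),
    iS = 1L, iN = 2L, iM = 3L, iTu = 4L, iTc = 5L,
    im = im, ip = ip, ir = ir, iRt = ir + 1L, iPab = ir + 2L, iRab = ir + 3L,
    iX = if (has_pathway) ir + 4L else 0L,
    nstate = ir + 3L + has_pathway,
    snames = snames,
    mode = match(model@culture$mode, c("single_cell", "batch", "chemostat")),
    S0 = model@culture$S0, k_in = model@culture$k_in,
    delta = model@culture$delta,
    pathway = has_pathway,
    v_ME = if (has_pathway) model@pathway$v_ME else 0,
    kappa_ME = if (has_pathway) model@pathway$kappa_ME else 1,
    jPW = if (has_pathway) match(model@pathway$enzyme, nms) else 0L,
    rrn_M_dep = isTRUE(model@options$rrn_M_dependent),
    circ_exp = isTRUE(model@options$circuit_copy_expansion),
    msk_act = which(cls %in% c("P", "R", "rrn")),
    msk_inh = which(cls == "E"),
    msk_Q = which(cls == "Q"),
    msk_circ = which(cls == "circuit")
  )
}

## Full derivative + derived-quantity evaluation.  `x` is the flat state
## vector; small negative entries (stiff-integrator trial states) are clipped
## to zero for rate computation.  Returns list(dx, lambda, theta, ...) when
## full = TRUE, otherwise just list(dx).
.derive <- function(ctx, x, full = FALSE) {
  if (any(!is.finite(x)))
    stop("non-finite state in RHS evaluation: ",
         paste(ctx$snames, signif(x, 4), sep = "=", collapse = " "))
  x <- pmax(x, 0)
  p <- ctx$p
  S <- x[ctx$iS]; N <- x[ctx$iN]; M <- x[ctx$iM]
  tu <- x[ctx$iTu]; tc <- x[ctx$iTc]
  m <- x[ctx$im]; pr <- x[ctx$ip]
  r <- x[ctx$ir]; Rt <- x[ctx$iRt]
  Ptot <- pr[ctx$jP]; p_r <- pr[ctx$jR]
  pQ <- pr[ctx$jQ]; pE <- pr[ctx$jE]

  ## global elongation rates
  tau_X <- p$tau_max * M / (p$K_tau + M)
  gamma_X <- p$D_gamma * p$gamma_max * tc / (p$K_gamma + tc)

  ## alarmone proxy and regulation functions
  theta <- p$D_g * tc / max(tu, p$theta_floor)
  act <- theta / (theta + p$kappa_theta)      # resource genes (P, R, rrn)
  inh <- p$kappa_theta / (theta + p$kappa_theta)  # enzyme gene, circuits
  reg <- numeric(length(ctx$cls))
  reg[ctx$msk_act] <- act
  reg[ctx$msk_inh] <- inh
  reg[ctx$msk_Q] <- 1 / (1 + (pQ / p$kappa_q)^p$h_q)
  if (length(ctx$msk_circ))
    reg[ctx$msk_circ] <- inh * ctx$u[ctx$msk_circ]

  ## translation side first: complexes and growth rate are independent of the
  ## transcription side and of the copy-number expansion.
  gamma_j <- gamma_X / ctx$n[ctx$mg]
  KL <- m * ctx$rb_f / (ctx$rb_r + gamma_j + p$k_cm)
  denL <- 1 + sum(KL)
  ctilde <- KL * Rt / denL
  freeR <- Rt / denL
  lambda <- gamma_X * sum(ctilde) / p$M0

  ## transcription side
  g_eff <- ctx$g0 * exp(p$q_x * lambda)
  if (!ctx$circ_exp && length(ctx$jC))
    g_eff[ctx$mg[ctx$jC]] <- ctx$g0[ctx$mg[ctx$jC]]
  g_eff[ctx$i_rrn] <- g_eff[ctx$i_rrn] * p$D_r
  tau_gene <- numeric(length(ctx$cls))
  tau_gene[ctx$mg] <- tau_X / (3 * ctx$n[ctx$mg])
  tau_gene[ctx$i_rrn] <- if (ctx$rrn_M_dep)
    p$tau_r_max * M / ((p$K_tau + M) * ctx$n[ctx$i_rrn])
  else p$tau_r_max / ctx$n[ctx$i_rrn]
  kappa_X <- (ctx$pb_r + tau_gene + p$k_rf) / ctx$pb_f
  KX <- g_eff * reg / kappa_X
  denX <- 1 + sum(KX)
  ktilde <- KX * Ptot / denX
  freeP <- Ptot / denX

  ## shared fluxes
  uptake <- p$v_E * S * pE / (p$kappa_E + S)
  charge <- p$v_T * pE / (1 + p$K_u / tu + p$K_M / M)  # 0 when tu or M is 0
  if (!is.finite(charge)) charge <- 0
  transl <- gamma_X * sum(ctilde)
  drain <- if (ctx$pathway)
    ctx$v_ME * M * pr[ctx$jPW] / (ctx$kappa_ME + M) else 0

  dx <- numeric(ctx$nstate)
  if (ctx$mode == 2L) {            # batch
    dx[ctx$iS] <- -uptake * N
    dx[ctx$iN] <- lambda * N
  } else if (ctx$mode == 3L) {     # chemostat
    dx[ctx$iS] <- ctx$k_in - uptake * N - ctx$delta * S
    dx[ctx$iN] <- (lambda - ctx$delta) * N
  }                                # single_cell: dS = dN = 0
  dx[ctx$iM] <- p$phi_M * uptake - charge - lambda * M - drain
  dx[ctx$iTu] <- p$psi_max * p$D_psi * act - charge + transl - lambda * tu
  dx[ctx$iTc] <- charge - transl - lambda * tc
  dx[ctx$im] <- tau_gene[ctx$mg] * ktilde[ctx$mg] - (p$delta_m + lambda) * m
  dp <- gamma_j * ctilde - lambda * pr
  asm <- p$beta_rho * p_r * r
  dis <- p$mu_rho * Rt
  dp[ctx$jP] <- dp[ctx$jP] - p$k_rf * Ptot
  dp[ctx$jR] <- dp[ctx$jR] - asm + dis
  dx[ctx$ip] <- dp
  dx[ctx$ir] <- tau_gene[ctx$i_rrn] * ktilde[ctx$i_rrn] - lambda * r - asm + dis
  dx[ctx$iRt] <- asm - dis - lambda * Rt - p$k_cm * Rt
  dx[ctx$iPab] <- p$k_rf * Ptot - lambda * x[ctx$iPab]
  dx[ctx$iRab] <- p$k_cm * Rt - lambda * x[ctx$iRab]
  if (ctx$pathway) dx[ctx$iX] <- drain - lambda * x[ctx$iX]

  if (!full) return(list(dx = dx))
  list(dx = dx, lambda = lambda, theta = theta,
       tau_X = tau_X, gamma_X = gamma_X,
       tau_j = setNames(tau_gene, ctx$gnames),
       gamma_j = setNames(gamma_j, ctx$mnames),
       regulation = setNames(reg, ctx$gnames),
       g_eff = setNames(g_eff, ctx$gnames),
       ktilde = setNames(ktilde, ctx$gnames),
       ctilde = setNames(ctilde, ctx$mnames),
       free_RNAP = freeP, free_ribosomes = freeR,
       uptake = uptake, charge = charge, drain = drain)
}

#' State vector layout
#'
#' The flat state vector of a model is fixed and documented: `S` (external
#' substrate), `N` (population), `M` (internal metabolite), `tu`/`tc`
#' (uncharged/charged tRNA), one `m_<gene>` per translated gene, one
#' `p_<gene>` per translated gene (`p_P` is total functional RNA polymerase,
#' `p_R` free ribosomal protein), `r` (free rRNA), `Rt` (functional
#' ribosomes), `Pab`/`Rab` (antibiotic-sequestered RNA polymerase/ribosomes)
#' and, when a pathway is attached, `X` (pathway product).  All intracellular
#' species are molecules per cell; `S` and `N` are culture-level.
#'
#' @param model a [CellModel-class].
#' @return character vector of state names, in vector order.
#' @export
stateNames <- function(model) .ctx(model)$snames

#' Evaluate the model right-hand side
#'
#' Returns the time derivative of every state entry.  Evaluation order:
#' global elongation rates, alarmone proxy and regulation, translation
#' complexes and growth rate (which depend only on the translation side),
#' growth-rate-expanded copy numbers, transcription complexes, then the flux
#' balance of every species.  The tRNA charging flux enters `dtc` with `+`
#' and `dtu`, `dM` with `-` (flux conservation).  Small negative entries are
#' clipped to zero for rate evaluation; non-finite input is a hard error
#' carrying a state dump.
#'
#' @param model a [CellModel-class].
#' @param state named or unnamed numeric state vector ([stateNames()] order).
#' @param t time (unused; the system is autonomous).
#' @return named numeric vector of derivatives.
#' @export
cellRHS <- function(model, state, t = 0) {
  ctx <- .ctx(model)
  if (length(state) != ctx$nstate)
    stop("state length ", length(state), " != expected ", ctx$nstate)
  setNames(.derive(ctx, unname(state))$dx, ctx$snames)
}

#' Derived quantities of a state
#'
#' Growth rate, alarmone proxy, global elongation rates, per-gene elongation
#' and regulation values, quasi-steady-state transcription and translation
#' complex counts and the free RNA polymerase/ribosome pools.  The complex
#' partition satisfies `sum(ktilde) + free_RNAP == p_P` and
#' `sum(ctilde) + free_ribosomes == Rt` by construction.
#'
#' @inheritParams cellRHS
#' @return list with elements `lambda`, `theta`, `tau_X`, `gamma_X`,
#'   `tau_j`, `gamma_j`, `regulation`, `g_eff`, `ktilde`, `ctilde`,
#'   `free_RNAP`, `free_ribosomes`, `uptake`, `charge`, `drain`, `dx`.
#' @export
derivedQuantities <- function(model, state) {
  ctx <- .ctx(model)
  if (length(state) != ctx$nstate)
    stop("state length ", length(state), " != expected ", ctx$nstate)
  out <- .derive(ctx, unname(state), full = TRUE)
  out$dx <- setNames(out$dx, ctx$snames)
  out
}

#' Growth rate of a state
#'
#' `lambda = gamma_X(t_c) * sum(ctilde) / M0`: the global peptide elongation
#' rate times the number of translating ribosomes, divided by the
#' mid-exponential cell mass.
#'
#' @inheritParams cellRHS
#' @return growth rate (per hour).
#' @export
growthRate <- function(model, state)
  derivedQuantities(model, state)$lambda

#' Quasi-steady-state complex partitions
#'
#' `transcriptionComplexes()` partitions total RNA polymerase over all
#' promoters (including the rRNA gene) according to sequestration potentials
#' `K = g_j * R_j / kappa_X_j` with
#' `kappa_X_j = (pb_r + tau_j + k_rf) / pb_f`;
#' `translationComplexes()` partitions functional ribosomes over all mRNAs
#' (the rRNA gene never competes for ribosomes) with `K = m_j / kappa_L_j`,
#' `kappa_L_j = (rb_r + gamma_j + k_cm) / rb_f`.
#'
#' @inheritParams cellRHS
#' @return list with the named complex vector (`ktilde` resp. `ctilde`) and
#'   the free pool (`free`).
#' @export
transcriptionComplexes <- function(model, state) {
  d <- derivedQuantities(model, state)
  list(ktilde = d$ktilde, free = d$free_RNAP)
}

#' @rdname transcriptionComplexes
#' @export
translationComplexes <- function(model, state) {
  d <- derivedQuantities(model, state)
  list(ctilde = d$ctilde, free = d$free_ribosomes)
}
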