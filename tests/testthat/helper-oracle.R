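# Brute-force mechanistic oracle for the quasi-steady-state reduction.
#
# The package computes promoter-RNAP and mRNA-ribosome complexes
# algebraically from the totals.  This oracle instead carries every complex
# as an explicit ODE species with mass-action binding/unbinding, integrates
# the full mechanistic system, and reports its steady state.  It shares no
# code with the package RHS: the rate laws are re-derived here directly
# from the reaction scheme, so agreement is evidence for the reduction, not
# for copy-paste consistency.

# toy parameterization: binding and unbinding at least 100x faster than any
# elongation step, two reporter genes on top of the host, no copy-number
# expansion (q_x = 0) so the comparison is clean of the g(lambda) loop.
# Unbinding rates are raised to >= 100x the elongation rates and binding
# rates rescaled so each gene's dissociation constant at a reference
# operating point (M ~ 1.5e5, t_c ~ 9e4 molecules) is preserved -- the toy
# cell stays alive while the complexes equilibrate fast.
qss_toy_model <- function() {
  speed_up <- function(g, p) {
    M_ref <- 1.5e5; tc_ref <- 9e4
    tau_X <- p[["tau_max"]] * M_ref / (p[["K_tau"]] + M_ref)
    gamma_X <- p[["gamma_max"]] * tc_ref / (p[["K_gamma"]] + tc_ref)
    tau_j <- ifelse(g$class == "rrn", p[["tau_r_max"]] / g$n,
                    tau_X / (3 * g$n))
    U_pb <- 100 * max(tau_j)
    kappa_X <- (g$pb_r + tau_j) / g$pb_f
    g$pb_r <- U_pb
    g$pb_f <- (U_pb + tau_j) / kappa_X
    tr <- g$class != "rrn"
    gamma_j <- gamma_X / g$n[tr]
    U_rb <- 100 * max(gamma_j)
    kappa_L <- (g$rb_r[tr] + gamma_j) / g$rb_f[tr]
    g$rb_r[tr] <- U_rb
    g$rb_f[tr] <- (U_rb + gamma_j) / kappa_L
    g
  }
  p <- defaultParams()
  g <- speed_up(rbind(defaultGenes(),
                      twoReporterCircuit(u1 = 0.5, u2 = 1)), p)
  cellModel(genes = g, params = c(q_x = 0))
}

# integrate the explicit-binding system to steady state; returns named
# m_* / p_* values comparable to the package's state entries
mechanistic_oracle_ss <- function(model, t_end = 4000) {
  g <- model@genes
  p <- as.list(model@params)
  cu <- model@culture
  i_rrn <- which(g$class == "rrn")
  mg <- which(g$class != "rrn")
  nm <- length(mg)
  nG <- nrow(g)
  jE <- which(g$class[mg] == "E"); jQ <- which(g$class[mg] == "Q")
  jP <- which(g$class[mg] == "P"); jR <- which(g$class[mg] == "R")
  # layout: M, tu, tc, m[nm], p[nm], r, Rt, k[nG], c[nm]
  iM <- 1; iTu <- 2; iTc <- 3
  im <- 3 + seq_len(nm); ip <- 3 + nm + seq_len(nm)
  ir <- 3 + 2 * nm + 1; iRt <- ir + 1
  ik <- iRt + seq_len(nG); ic <- iRt + nG + seq_len(nm)
  rhs <- function(t, x, parms) {
    x <- pmax(x, 0)
    M <- x[iM]; tu <- x[iTu]; tc <- x[iTc]
    m <- x[im]; pr <- x[ip]; r <- x[ir]; Rt <- x[iRt]
    k <- x[ik]; cc <- x[ic]
    Ptot <- pr[jP]
    tau_X <- p$tau_max * M / (p$K_tau + M)
    gamma_X <- p$D_gamma * p$gamma_max * tc / (p$K_gamma + tc)
    theta <- p$D_g * tc / max(tu, p$theta_floor)
    act <- theta / (theta + p$kappa_theta)
    inh <- p$kappa_theta / (theta + p$kappa_theta)
    reg <- numeric(nG)
    for (q in seq_len(nG)) {
      reg[q] <- switch(g$class[q],
        E = inh, Q = 1 / (1 + (pr[jQ] / p$kappa_q)^p$h_q),
        P = act, R = act, rrn = act, circuit = inh * g$u[q])
    }
    gamma_j <- gamma_X / g$n[mg]
    tau_g <- numeric(nG)
    tau_g[mg] <- tau_X / (3 * g$n[mg])
    tau_g[i_rrn] <- p$tau_r_max / g$n[i_rrn]
    lambda <- gamma_X * sum(cc) / p$M0
    g_eff <- g$g0 * exp(p$q_x * lambda)
    g_eff[i_rrn] <- g_eff[i_rrn] * p$D_r
    P_free <- max(Ptot - sum(k), 0)
    R_free <- max(Rt - sum(cc), 0)
    # explicit complex dynamics (the part the QSS removes)
    dk <- g$pb_f * P_free * g_eff * reg - (g$pb_r + tau_g + p$k_rf) * k
    dc <- g$rb_f[mg] * R_free * m - (g$rb_r[mg] + gamma_j + p$k_cm) * cc
    uptake <- p$v_E * cu$S0 * pr[jE] / (p$kappa_E + cu$S0)
    charge <- p$v_T * pr[jE] / (1 + p$K_u / tu + p$K_M / M)
    if (!is.finite(charge)) charge <- 0
    transl <- gamma_X * sum(cc)
    dx <- numeric(length(x))
    dx[iM] <- p$phi_M * uptake - charge - lambda * M
    dx[iTu] <- p$psi_max * p$D_psi * act - charge + transl - lambda * tu
    dx[iTc] <- charge - transl - lambda * tc
    dx[im] <- tau_g[mg] * k[mg] - (p$delta_m + lambda) * m
    dp <- gamma_j * cc - lambda * pr
    asm <- p$beta_rho * pr[jR] * r
    dis <- p$mu_rho * Rt
    dp[jP] <- dp[jP] - p$k_rf * Ptot
    dp[jR] <- dp[jR] - asm + dis
    dx[ip] <- dp
    dx[ir] <- tau_g[i_rrn] * k[i_rrn] - lambda * r - asm + dis
    dx[iRt] <- asm - dis - lambda * Rt - p$k_cm * Rt
    dx[ik] <- dk
    dx[ic] <- dc
    list(dx)
  }
  x0 <- numeric(iRt + nG + nm)
  x0[c(iM, iTu, iTc)] <- 1e3
  x0[ip] <- 100
  x0[iRt] <- 100
  sol <- deSolve::ode(y = x0, times = c(0, t_end / 2, t_end), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-8, maxsteps = 2e5)
  xe <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
  half <- pmax(as.numeric(sol[2, -1]), 0)
  list(
    m = setNames(xe[im], g$name[mg]),
    p = setNames(xe[ip], g$name[mg]),
    r = xe[ir], Rt = xe[iRt],
    complexes_k = setNames(xe[ik], g$name),
    complexes_c = setNames(xe[ic], g$name[mg]),
    settled = max(abs(xe - half) / pmax(abs(xe), 1)) < 1e-4
  )
}
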