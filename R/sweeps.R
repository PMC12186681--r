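## Sweep protocols: generic steady-state sweeps over a control, and the
## isocost-line protocol for two-reporter circuits.

.sweep_controls <- c("u1", "u2", "delta", "lambda_set", "krf", "kcm",
                     "Dr", "Dgamma", "Dpsi", "Dg")

## apply one control value to a model
.apply_control <- function(model, control, value) {
  switch(control,
    u1 = setInduction(model, model@genes$name[model@genes$class == "circuit"][1], value),
    u2 = setInduction(model, model@genes$name[model@genes$class == "circuit"][2], value),
    delta = , lambda_set = {
      if (model@culture$mode != "chemostat")
        model@culture$mode <- "chemostat"
      model@culture$delta <- value
      model
    },
    krf = { model@params[["k_rf"]] <- value; model },
    kcm = { model@params[["k_cm"]] <- value; model },
    Dr = { model@params[["D_r"]] <- value; model },
    Dgamma = { model@params[["D_gamma"]] <- value; model },
    Dpsi = { model@params[["D_psi"]] <- value; model },
    Dg = { model@params[["D_g"]] <- value; model },
    stop("unknown sweep control '", control, "'")
  )
}

.ss_row <- function(model, ss) {
  g <- model@genes
  circ <- g$name[g$class == "circuit"]
  row <- data.frame(lambda = ss@lambda, theta = ss@theta,
                    phi_p = ss@phi[["P"]], phi_r = ss@phi[["R"]],
                    converged = ss@converged, residual = ss@residual)
  for (cn in circ) {
    row[[paste0("p_", cn)]] <- ss@state[[paste0("p_", cn)]]
    row[[paste0("phi_", cn)]] <- ss@phi[[cn]]
  }
  if (length(model@pathway)) {
    row$X <- ss@state[["X"]]
    row$production <- ss@lambda * ss@state[["X"]]
    row$phi_pathway <- ss@phi[[model@pathway$enzyme]]
  }
  row
}

#' Sweep a control across a grid of steady states
#'
#' Solves one steady state per grid point, warm-starting each point from the
#' previous one (branch continuity and a large speedup).  The first point is
#' seeded from the base model's own steady state.  Controls: circuit
#' inductions (`u1`, `u2`), chemostat dilution (`delta`; `lambda_set` is the
#' same control under the name used when a target growth rate is imposed),
#' antibiotic sequestration rates (`krf`, `kcm`) and the perturbation
#' scalings (`Dr`, `Dgamma`, `Dpsi`, `Dg`).
#'
#' @param model a [CellModel-class].
#' @param control one of `r paste0('"', .sweep_controls, '"', collapse = ", ")`.
#' @param grid numeric grid (strictly monotone).
#' @param tol,t0,tmax steady-state solver settings, see [solveSteadyState()].
#' @return a [SweepResult-class]; non-converged points are flagged in the
#'   table, not dropped.
#' @export
runSweep <- function(model, control, grid, tol = 1e-3, t0 = 100, tmax = 1e6) {
  control <- match.arg(control, .sweep_controls)
  if (length(grid) < 1 || any(!is.finite(grid)))
    stop("grid must be finite and nonempty")
  if (length(grid) > 1 && !(all(diff(grid) > 0) || all(diff(grid) < 0)))
    stop("grid must be strictly monotone")
  warm <- tryCatch(
    solveSteadyState(model, tol = tol, t0 = t0, tmax = min(tmax, 1e4))@state,
    error = function(e) NULL)
  states <- vector("list", length(grid))
  rows <- NULL
  for (i in seq_along(grid)) {
    mi <- .apply_control(model, control, grid[i])
    ss <- solveSteadyState(mi, state0 = warm, tol = tol, t0 = t0, tmax = tmax)
    if (ss@converged) warm <- ss@state
    states[[i]] <- ss
    rows <- rbind(rows, cbind(data.frame(value = grid[i]), .ss_row(mi, ss)))
  }
  names(rows)[1] <- control
  new("SweepResult", control = control, grid = as.numeric(grid),
      table = rows, states = states, fit = list())
}

#' Isocost-line sweep
#'
#' The standard protocol for probing the expression trade-off of a
#' two-reporter circuit: the first reporter's induction `u1` is varied over
#' \[0, 1\] while the second is held at `u2 = 1`; each point is solved to
#' steady state and the line through the steady-state protein pairs
#' `(p1*, p2*)` is fit by ordinary least squares of `p2` on `p1`.  A tight
#' linear fit (R2 near 1) with negative slope is the isocost line: the
#' shared-resource budget that couples the two genes.
#'
#' @param model a [CellModel-class] with exactly two circuit genes.
#' @param u1_grid induction grid for the first circuit gene.
#' @param u2 fixed induction of the second circuit gene (default 1).
#' @param normalize also report protein levels normalized by the maximum of
#'   each reporter over the sweep (columns `p1_norm`, `p2_norm`), the scaling
#'   used for plotting expression relative to maximum production.
#' @param ... passed to [runSweep()].
#' @return a [SweepResult-class] whose `fit` holds `slope`, `intercept`,
#'   `r2` and `n_used` (non-converged points are excluded from the fit and
#'   flagged in the table).
#' @export
isocostSweep <- function(model, u1_grid = seq(0, 1, length.out = 11),
                         u2 = 1, normalize = TRUE, ...) {
  circ <- model@genes$name[model@genes$class == "circuit"]
  if (length(circ) != 2)
    stop("isocost sweep needs a model with exactly two circuit genes")
  model <- setInduction(model, circ[2], u2)
  sw <- runSweep(model, "u1", u1_grid, ...)
  tb <- sw@table
  p1 <- tb[[paste0("p_", circ[1])]]
  p2 <- tb[[paste0("p_", circ[2])]]
  ok <- tb$converged
  fit <- list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
              n_used = sum(ok))
  if (sum(ok) >= 3) {
    lmfit <- lm(y ~ x, data = data.frame(x = p1[ok], y = p2[ok]))
    fit$slope <- unname(coef(lmfit)[2])
    fit$intercept <- unname(coef(lmfit)[1])
    fit$r2 <- summary(lmfit)$r.squared
  }
  if (normalize) {
    tb$p1_norm <- p1 / max(p1[ok])
    tb$p2_norm <- p2 / max(p2[ok])
  }
  sw@table <- tb
  sw@fit <- fit
  sw
}
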