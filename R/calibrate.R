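## Growth-law calibration: simulated growth-law curves over nutrient quality
## and translation inhibition, normalized SSE terms, the weighted cost, and
## particle swarm optimization.

#' Simulate growth-law curves
#'
#' Growth rate is varied the way the calibration protocol prescribes: by
#' simulating the exponential (single-cell) regime over a range of nutrient
#' qualities `phi` (the metabolite yield per substrate) and translation
#' inhibitor levels `k_cm`.  Each grid point is solved to steady state and
#' reported as one row of observables: growth rate `lambda`, ribosomal mass
#' fraction `phi_R`, global peptide elongation rate `gamma` (aa/h) and the
#' charged/uncharged tRNA ratio `theta`.
#'
#' @param model a [CellModel-class]; its culture mode is forced to
#'   single-cell.
#' @param phi_grid nutrient-quality grid (values of the yield parameter
#'   `phi_M`).
#' @param kcm_grid ribosome-sequestration grid (values of `k_cm`, per hour).
#' @param tol steady-state tolerance.
#' @param warm_cache internal; an environment used to warm-start repeated
#'   calls during fitting.
#' @param conditions optional data.frame with columns `phi`, `k_cm` giving
#'   explicit condition pairs; overrides the two grids.
#' @return data.frame with columns `phi`, `k_cm`, `lambda`, `phi_R`,
#'   `gamma`, `theta`, `converged`.  Non-converged points are kept but
#'   flagged (and dropped, with a warning, by [fitCost()]).
#' @export
growthLawCurves <- function(model, phi_grid = defaultParams()[["phi_M"]] *
                              c(0.03, 0.1, 0.3, 1),
                            kcm_grid = c(0, 2), tol = 1e-3,
                            warm_cache = NULL, conditions = NULL) {
  if (is.null(conditions)) {
    if (!length(phi_grid) || !length(kcm_grid))
      stop("phi_grid and kcm_grid must be nonempty")
    conditions <- expand.grid(k_cm = kcm_grid, phi = phi_grid)
  }
  model@culture$mode <- "single_cell"
  rows <- NULL
  warm <- NULL
  for (ci in seq_len(nrow(conditions))) {
    phi <- conditions$phi[ci]
    kcm <- conditions$k_cm[ci]
    {
      m <- model
      m@params[["phi_M"]] <- phi
      m@params[["k_cm"]] <- kcm
      key <- paste0("p", format(phi), "k", format(kcm))
      w0 <- if (!is.null(warm_cache) && !is.null(warm_cache[[key]]))
        warm_cache[[key]] else warm
      ss <- tryCatch(
        solveSteadyState(m, state0 = w0, tol = tol, tmax = 1e5),
        error = function(e) NULL)
      if (is.null(ss) && !is.null(w0))  # retry cold if the warm start failed
        ss <- tryCatch(solveSteadyState(m, tol = tol, tmax = 1e5),
                       error = function(e) NULL)
      if (is.null(ss)) {
        rows <- rbind(rows, data.frame(phi = phi, k_cm = kcm, lambda = NA,
                                       phi_R = NA, gamma = NA, theta = NA,
                                       converged = FALSE))
        next
      }
      if (ss@converged && ss@lambda > 1e-8) {
        warm <- ss@state
        if (!is.null(warm_cache)) warm_cache[[key]] <- ss@state
      }
      rows <- rbind(rows, data.frame(phi = phi, k_cm = kcm,
                                     lambda = ss@lambda,
                                     phi_R = ss@phi[["R"]],
                                     gamma = ss@gamma, theta = ss@theta,
                                     converged = ss@converged))
  }
  }
  rows
}

#' Normalized sum of squared errors
#'
#' `sigma = sum((sim - exp)^2) / sum(exp^2)`: the squared error normalized
#' by the summed squared experimental values, which puts observables of
#' different magnitudes on a common scale.  Zero iff the simulation matches
#' exactly; invariant under a common rescaling of both vectors.
#'
#' @param sim,exp numeric vectors of equal length; pairs with missing values
#'   are dropped.
#' @return sigma >= 0.
#' @export
normalizedSSE <- function(sim, exp) {
  if (length(sim) != length(exp))
    stop("sim and exp must have equal length")
  keep <- is.finite(sim) & is.finite(exp)
  sim <- sim[keep]; exp <- exp[keep]
  if (!length(exp) || sum(exp^2) == 0)
    stop("experimental vector is empty or all zero; sigma undefined")
  sum((sim - exp)^2) / sum(exp^2)
}

## weights of the six error terms in the calibration cost
.cost_weights <- c(lambda_DB = 10, lambda_Scott = 5, R_Scott = 5,
                   R_DB = 1, Gamma_DB = 1, theta_DB = 1)

#' Weighted calibration cost
#'
#' The calibration cost is a weighted sum of six normalized SSE terms:
#' growth rate and ribosomal mass fraction against both reference data sets
#' ("Scott"-type: lambda and phi_R only; "DB"-type: lambda, phi_R, peptide
#' elongation rate Gamma and theta), with weights
#' `10*sigma_lambda_DB + 5*sigma_lambda_Scott + 5*sigma_R_Scott +
#' sigma_R_DB + sigma_Gamma_DB + sigma_theta_DB`.
#' Series missing from `data` contribute 0 with a warning.  Candidate
#' parameter sets whose simulations fail or do not converge receive the
#' finite penalty `1e6` (so a population-based optimizer keeps running).
#'
#' @param model a [CellModel-class] carrying the candidate parameters.
#' @param data growth-law dataset: data.frame with columns `source`
#'   (`"Scott"` or `"DB"`), `condition`, `phi`, `k_cm` (the nutrient-quality
#'   and inhibition inputs of each condition) and observables `lambda`,
#'   `phi_R`, `gamma`, `theta` (NA where a source does not report one).
#' @param tol steady-state tolerance used for the candidate simulations.
#' @param warm_cache internal, see [growthLawCurves()].
#' @return the scalar cost, with attribute `sigma` (the six terms).
#' @export
fitCost <- function(model, data, tol = 1e-3, warm_cache = NULL) {
  req <- c("source", "condition", "phi", "k_cm")
  if (!all(req %in% names(data)))
    stop("data needs columns: ", paste(req, collapse = ", "))
  conds <- unique(data[, c("phi", "k_cm")])
  sim <- growthLawCurves(model, tol = tol, warm_cache = warm_cache,
                         conditions = conds)
  key <- function(p, k) paste0(format(p), "|", format(k))
  sim_idx <- match(key(data$phi, data$k_cm), key(sim$phi, sim$k_cm))
  simrows <- sim[sim_idx, ]
  if (any(!simrows$converged | !is.finite(simrows$lambda) |
            simrows$lambda <= 1e-8)) {
    out <- 1e6
    attr(out, "sigma") <- setNames(rep(NA_real_, 6), names(.cost_weights))
    return(out)
  }
  obs_map <- list(
    lambda_DB    = list(src = "DB", col = "lambda"),
    lambda_Scott = list(src = "Scott", col = "lambda"),
    R_Scott      = list(src = "Scott", col = "phi_R"),
    R_DB         = list(src = "DB", col = "phi_R"),
    Gamma_DB     = list(src = "DB", col = "gamma"),
    theta_DB     = list(src = "DB", col = "theta"))
  sigma <- setNames(numeric(6), names(.cost_weights))
  for (term in names(obs_map)) {
    src <- obs_map[[term]]$src; col <- obs_map[[term]]$col
    sel <- data$source == src & is.finite(data[[col]])
    if (!any(sel)) {
      warning("no data for term ", term, "; contributes 0")
      next
    }
    sigma[term] <- normalizedSSE(
      simrows[[if (col == "gamma") "gamma" else col]][sel],
      data[[col]][sel])
  }
  out <- sum(.cost_weights * sigma)
  attr(out, "sigma") <- sigma
  out
}

#' Synthetic growth-law dataset
#'
#' Generates a growth-law dataset from a known ("true") model by running
#' [growthLawCurves()] and assembling Scott-type rows (lambda, phi_R) and
#' DB-type rows (lambda, phi_R, gamma, theta) over the same conditions,
#' optionally corrupted with multiplicative Gaussian noise
#' `value * (1 + sd * Z)` clipped at zero.  Stands in for the external
#' growth-law compilations so the calibration path is fully testable
#' offline; reproducible given `seed`.
#'
#' @param model the true [CellModel-class].
#' @param phi_grid,kcm_grid condition grids, see [growthLawCurves()].
#' @param noise_sd multiplicative noise level (>= 0; 0 returns the exact
#'   simulated values).
#' @param seed RNG seed.
#' @param sources which source types to emit.
#' @return a growth-law data.frame in the format [fitCost()] consumes.
#' @export
synthGrowthLawData <- function(model,
                               phi_grid = defaultParams()[["phi_M"]] *
                                 c(0.03, 0.1, 0.3, 1),
                               kcm_grid = c(0, 2),
                               noise_sd = 0, seed = 1,
                               sources = c("DB", "Scott")) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  curves <- growthLawCurves(model, phi_grid, kcm_grid)
  curves <- curves[curves$converged, ]
  out <- NULL
  for (src in sources) {
    d <- data.frame(source = src,
                    condition = paste0(src, "_", seq_len(nrow(curves))),
                    phi = curves$phi, k_cm = curves$k_cm,
                    lambda = curves$lambda, phi_R = curves$phi_R,
                    gamma = curves$gamma, theta = curves$theta,
                    stringsAsFactors = FALSE)
    if (src == "Scott") d$gamma <- d$theta <- NA_real_
    out <- rbind(out, d)
  }
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()))
    for (col in c("lambda", "phi_R", "gamma", "theta")) {
      v <- out[[col]]
      ok <- is.finite(v)
      v[ok] <- pmax(v[ok] * (1 + noise_sd * rnorm(sum(ok))), 0)
      out[[col]] <- v
    }
  }
  rownames(out) <- NULL
  out
}

#' Fit model parameters by particle swarm optimization
#'
#' Global optimization of the weighted growth-law cost over a box of free
#' parameters, using a constriction-coefficient particle swarm (inertia
#' 0.729, cognitive and social weights 1.49); the reference protocol uses a
#' population of 500 particles and stops after 500 generations, which are
#' the defaults here (use smaller values for quick work).  Deterministic
#' given `seed`; the best-so-far cost trace is nonincreasing by
#' construction.
#'
#' @param model base [CellModel-class]; fitted parameters are written over
#'   its parameter vector.
#' @param data growth-law dataset, see [fitCost()].
#' @param free named list or data.frame of parameter bounds: each element
#'   `c(lower, upper)` with finite bounds, lower < upper.  Names must be
#'   parameters of [defaultParams()].
#' @param swarm number of particles (default 500).
#' @param generations number of generations (default 500).
#' @param seed RNG seed.
#' @param tol steady-state tolerance inside cost evaluations.
#' @param verbose print progress every 10 generations.
#' @return list: `par` (named fitted values), `cost`, `model` (the model
#'   with fitted parameters installed), `trace` (best cost per generation),
#'   `evaluations`.
#' @export
fitParameters <- function(model, data, free, swarm = 500, generations = 500,
                          seed = 1, tol = 1e-3, verbose = FALSE) {
  if (is.data.frame(free)) free <- as.list(free)
  pn <- names(free)
  if (is.null(pn) || !all(pn %in% names(model@params)))
    stop("free must be a named list of bounds over model parameters")
  lb <- vapply(free, function(b) b[1], 0)
  ub <- vapply(free, function(b) b[2], 0)
  if (any(!is.finite(lb)) || any(!is.finite(ub)) || any(lb >= ub))
    stop("bounds must be finite with lower < upper")
  nd <- length(pn)
  warm_cache <- new.env(parent = emptyenv())
  cost_at <- function(x) {
    m <- model
    m@params[pn] <- x
    as.numeric(tryCatch(fitCost(m, data, tol = tol, warm_cache = warm_cache),
                        error = function(e) 1e6))
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  ## constriction-coefficient swarm (standard defaults)
  w <- 0.729; c1 <- 1.49; c2 <- 1.49
  span <- ub - lb
  X <- matrix(runif(swarm * nd, lb, ub), nrow = swarm, byrow = TRUE)
  V <- matrix(runif(swarm * nd, -span, span), nrow = swarm, byrow = TRUE) * 0.1
  pbest <- X
  pcost <- apply(X, 1, cost_at)
  gi <- which.min(pcost)
  gbest <- X[gi, ]; gcost <- pcost[gi]
  trace <- numeric(generations)
  evals <- swarm
  for (gen in seq_len(generations)) {
    R1 <- matrix(runif(swarm * nd), swarm)
    R2 <- matrix(runif(swarm * nd), swarm)
    G <- matrix(gbest, swarm, nd, byrow = TRUE)
    V <- w * V + c1 * R1 * (pbest - X) + c2 * R2 * (G - X)
    vmax <- matrix(span, swarm, nd, byrow = TRUE)
    V <- pmin(pmax(V, -vmax), vmax)
    X <- X + V
    X <- pmin(pmax(X, matrix(lb, swarm, nd, byrow = TRUE)),
              matrix(ub, swarm, nd, byrow = TRUE))
    cost <- apply(X, 1, cost_at)
    evals <- evals + swarm
    imp <- cost < pcost
    pbest[imp, ] <- X[imp, ]
    pcost[imp] <- cost[imp]
    gi <- which.min(pcost)
    if (pcost[gi] < gcost) { gbest <- pbest[gi, ]; gcost <- pcost[gi] }
    trace[gen] <- gcost
    if (verbose && gen %% 10 == 0)
      message("generation ", gen, ": best cost ", signif(gcost, 6))
  }
  fitted <- model
  fitted@params[pn] <- gbest
  list(par = setNames(gbest, pn), cost = gcost, model = fitted,
       trace = trace, evaluations = evals)
}
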