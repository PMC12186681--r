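#' @include cellecon-package.R
NULL

## ---------------------------------------------------------------------------
## CellModel
## ---------------------------------------------------------------------------

#' CellModel: a whole-cell resource allocation model
#'
#' Central S4 container holding the gene table (one row per transcription
#' unit), the kinetic parameter set, the culture mode, an optional
#' metabolite-draining pathway, and numerical options.  Build instances with
#' [cellModel()]; do not construct slots by hand.
#'
#' @slot genes data.frame with one row per gene: `name`, `class` (one of
#'   `"E"`, `"Q"`, `"P"`, `"R"`, `"rrn"`, `"circuit"`), `g0` (copies per
#'   chromosome), `n` (protein length in amino acids; for the rRNA gene,
#'   transcript length in nucleotides), promoter--RNA polymerase binding and
#'   unbinding rates `pb_f`, `pb_r`, mRNA--ribosome binding and unbinding
#'   rates `rb_f`, `rb_r` (NA for the rRNA gene, which is never translated),
#'   and induction `u` in \[0, 1\] (NA except for circuit genes).
#' @slot params named numeric vector of kinetic constants, see
#'   [defaultParams()].
#' @slot culture list with `mode` (`"single_cell"`, `"batch"`, `"chemostat"`)
#'   and the culture constants `S0`, `N0`, `k_in`, `delta`.
#' @slot pathway empty list, or list with `enzyme` (name of a circuit gene),
#'   `v_ME` and `kappa_ME` describing one lumped reaction draining the
#'   internal metabolite into a product X.
#' @slot options list of numerical/structural switches, see [cellModel()].
#'
#' @seealso [cellModel()], [addCircuit()], [addPathway()],
#'   [applyPerturbations()]
#' @export
setClass("CellModel",
  representation(
    genes   = "data.frame",
    params  = "numeric",
    culture = "list",
    pathway = "list",
    options = "list"
  )
)

.gene_classes <- c("E", "Q", "P", "R", "rrn", "circuit")

.gene_cols <- c("name", "class", "g0", "n", "pb_f", "pb_r", "rb_f", "rb_r", "u")

validCellModel <- function(object) {
  errs <- character(0)
  g <- object@genes
  p <- object@params
  if (!all(.gene_cols %in% names(g)))
    errs <- c(errs, paste0("genes: missing columns ",
                           paste(setdiff(.gene_cols, names(g)), collapse = ", ")))
  else {
    if (anyDuplicated(g$name))
      errs <- c(errs, "genes: duplicate gene names")
    if (!all(g$class %in% .gene_classes))
      errs <- c(errs, "genes: unknown regulation class")
    if (sum(g$class == "rrn") != 1L)
      errs <- c(errs, "genes: exactly one rRNA gene required")
    for (cls in c("E", "Q", "P", "R"))
      if (sum(g$class == cls) != 1L)
        errs <- c(errs, paste0("genes: exactly one gene of class ", cls, " required"))
    if (any(!is.finite(g$g0)) || any(g$g0 <= 0))
      errs <- c(errs, "genes: g0 must be > 0")
    if (any(!is.finite(g$n)) || any(g$n < 1))
      errs <- c(errs, "genes: n must be >= 1")
    for (col in c("pb_f", "pb_r")) {
      if (any(!is.finite(g[[col]])) || any(g[[col]] < 0))
        errs <- c(errs, paste0("genes: ", col, " must be >= 0 and finite"))
    }
    if (any(g$pb_f == 0))
      errs <- c(errs, "genes: pb_f must be > 0 (promoter binding rate)")
    mg <- g$class != "rrn"
    for (col in c("rb_f", "rb_r")) {
      v <- g[[col]][mg]
      if (any(!is.finite(v)) || any(v < 0))
        errs <- c(errs, paste0("genes: ", col, " must be >= 0 and finite for translated genes"))
    }
    if (any(g$rb_f[mg] == 0))
      errs <- c(errs, "genes: rb_f must be > 0 (ribosome binding rate)")
    ic <- g$class == "circuit"
    if (any(ic)) {
      uu <- g$u[ic]
      if (any(!is.finite(uu)) || any(uu < 0 | uu > 1))
        errs <- c(errs, "genes: circuit induction u must lie in [0, 1]")
    }
  }
  need <- .param_names
  if (!all(need %in% names(p)))
    errs <- c(errs, paste0("params: missing ",
                           paste(setdiff(need, names(p)), collapse = ", ")))
  else {
    if (any(!is.finite(p)))
      errs <- c(errs, "params: all parameters must be finite")
    if (any(p[setdiff(need, c("q_x"))] < 0))
      errs <- c(errs, "params: parameters must be >= 0")
    if (p[["M0"]] <= 0) errs <- c(errs, "params: M0 must be > 0")
    for (d in c("D_r", "D_gamma", "D_psi", "D_g"))
      if (p[[d]] <= 0) errs <- c(errs, paste0("params: ", d, " must be > 0"))
  }
  cu <- object@culture
  if (!identical(sort(names(cu)), sort(c("mode", "S0", "N0", "k_in", "delta"))))
    errs <- c(errs, "culture: fields mode, S0, N0, k_in, delta required")
  else {
    if (!cu$mode %in% c("single_cell", "batch", "chemostat"))
      errs <- c(errs, "culture: unknown mode")
    if (identical(cu$mode, "chemostat") && cu$delta <= 0)
      errs <- c(errs, "culture: delta must be > 0 in chemostat mode")
  }
  pw <- object@pathway
  if (length(pw)) {
    if (!all(c("enzyme", "v_ME", "kappa_ME") %in% names(pw)))
      errs <- c(errs, "pathway: fields enzyme, v_ME, kappa_ME required")
    else {
      if (!pw$enzyme %in% g$name[g$class == "circuit"])
        errs <- c(errs, paste0("pathway: enzyme gene '", pw$enzyme,
                               "' is not a circuit gene of the model"))
      if (pw$v_ME < 0 || pw$kappa_ME < 0)
        errs <- c(errs, "pathway: v_ME and kappa_ME must be >= 0")
    }
  }
  if (length(errs)) errs else TRUE
}

setValidity("CellModel", validCellModel)

## ---------------------------------------------------------------------------
## SteadyState
## ---------------------------------------------------------------------------

#' SteadyState: a converged (or flagged) fixed point of a CellModel
#'
#' @slot state named numeric state vector at the fixed point (layout of
#'   [stateNames()]).
#' @slot lambda growth rate at the fixed point (per hour).
#' @slot theta effective charged/uncharged tRNA ratio.
#' @slot gamma global peptide elongation rate (aa/h) at the fixed point.
#' @slot phi named numeric vector of proteome mass fractions (sums to 1).
#' @slot residual max absolute time derivative at the returned state.
#' @slot converged logical, `TRUE` when `residual < tol`.
#' @slot horizon total simulated time used by the horizon-doubling schedule.
#'
#' @seealso [solveSteadyState()]
#' @export
setClass("SteadyState",
  representation(
    state     = "numeric",
    lambda    = "numeric",
    theta     = "numeric",
    gamma     = "numeric",
    phi       = "numeric",
    residual  = "numeric",
    converged = "logical",
    horizon   = "numeric"
  )
)

## ---------------------------------------------------------------------------
## SweepResult
## ---------------------------------------------------------------------------

#' SweepResult: tabulated steady states over a swept control
#'
#' @slot control name of the swept control (`"u1"`, `"delta"`, `"krf"`,
#'   `"kcm"`, `"Dr"`, `"Dgamma"`, `"Dpsi"`, `"Dg"`, `"lambda_set"`).
#' @slot grid numeric grid of control values (strictly monotone).
#' @slot table data.frame with one row per grid point: control value, growth
#'   rate, theta, mass fractions, circuit protein levels, pathway product,
#'   convergence flag and residual.
#' @slot states list of [SteadyState-class] objects, one per grid point.
#' @slot fit list; for isocost sweeps the ordinary least squares line through
#'   the two circuit protein steady states (`slope`, `intercept`, `r2`,
#'   `n_used`), otherwise empty.
#'
#' @seealso [runSweep()], [isocostSweep()]
#' @export
setClass("SweepResult",
  representation(
    control = "character",
    grid    = "numeric",
    table   = "data.frame",
    states  = "list",
    fit     = "list"
  )
)

## ---------------------------------------------------------------------------
## FluxNetwork
## ---------------------------------------------------------------------------

#' FluxNetwork: a stoichiometric metabolic network for FBA/FVA
#'
#' @slot S stoichiometric matrix (metabolites x reactions).
#' @slot reactions data.frame: `id`, `name`, `lb`, `ub`, `subsystem`,
#'   `objective` (objective coefficient).
#' @slot metabolites data.frame: `id`, `name`, `compartment`, `boundary`.
#'
#' @seealso [readSBMLNetwork()], [toyNetworkFixture()], [maxProteinFlux()]
#' @export
setClass("FluxNetwork",
  representation(
    S           = "matrix",
    reactions   = "data.frame",
    metabolites = "data.frame"
  )
)

validFluxNetwork <- function(object) {
  errs <- character(0)
  r <- object@reactions
  m <- object@metabolites
  if (nrow(object@S) != nrow(m))
    errs <- c(errs, "S rows must match metabolites")
  if (ncol(object@S) != nrow(r))
    errs <- c(errs, "S columns must match reactions")
  if (any(r$lb > r$ub))
    errs <- c(errs, "reaction bounds must satisfy lb <= ub")
  if (anyDuplicated(r$id)) errs <- c(errs, "duplicate reaction ids")
  if (anyDuplicated(m$id)) errs <- c(errs, "duplicate metabolite ids")
  if (any(is.na(r$subsystem)))
    errs <- c(errs, "every reaction needs a subsystem label (use 'unassigned')")
  if (length(errs)) errs else TRUE
}

setValidity("FluxNetwork", validFluxNetwork)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "CellModel", function(object) {
  g <- object@genes
  nc <- sum(g$class == "circuit")
  cat("CellModel (", object@culture$mode, " mode)\n", sep = "")
  cat("  genes: ", nrow(g), " (", nc, " circuit)",
      if (length(object@pathway)) " + pathway" else "", "\n", sep = "")
  pert <- object@params[c("D_r", "D_gamma", "D_psi", "D_g", "k_rf", "k_cm")]
  on <- pert[pert != c(1, 1, 1, 1, 0, 0)]
  if (length(on))
    cat("  perturbations:", paste(names(on), signif(on, 3), sep = "=",
                                  collapse = ", "), "\n")
  cat("  state vector:", length(stateNames(object)), "species\n")
  invisible(object)
})

setMethod("show", "SteadyState", function(object) {
  cat("SteadyState: lambda = ", signif(object@lambda, 4),
      " /h, theta = ", signif(object@theta, 4),
      if (object@converged) " (converged" else " (NOT converged",
      ", residual ", signif(object@residual, 2), ")\n", sep = "")
  cat("  Phi:", paste(names(object@phi), signif(object@phi, 3),
                      sep = "=", collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult over ", object@control, ": ", length(object@grid),
      " points, ", sum(object@table$converged), " converged\n", sep = "")
  if (length(object@fit))
    cat("  isocost fit: slope ", signif(object@fit$slope, 4),
        ", intercept ", signif(object@fit$intercept, 4),
        ", R2 ", signif(object@fit$r2, 4), "\n", sep = "")
  invisible(object)
})

setMethod("show", "FluxNetwork", function(object) {
  cat("FluxNetwork: ", nrow(object@metabolites), " metabolites, ",
      nrow(object@reactions), " reactions, ",
      length(unique(object@reactions$subsystem)), " subsystems\n", sep = "")
  invisible(object)
})

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' Accessors for model and result objects
#'
#' `modelGenes()`, `modelParams()` and `cultureMode()` read the corresponding
#' parts of a [CellModel-class]; `ssState()`, `growthRateOf()` and
#' `massFractionsOf()` read a [SteadyState-class]; `sweepTable()` and
#' `isocostFit()` read a [SweepResult-class]; `reactions()`, `metabolites()`
#' and `stoichiometry()` read a [FluxNetwork-class].
#'
#' @param x the object.
#' @return the slot contents (data.frame, numeric vector, list or matrix).
#' @name accessors
NULL

#' @rdname accessors
#' @export
modelGenes <- function(x) { stopifnot(is(x, "CellModel")); x@genes }

#' @rdname accessors
#' @export
modelParams <- function(x) { stopifnot(is(x, "CellModel")); x@params }

#' @rdname accessors
#' @export
cultureMode <- function(x) { stopifnot(is(x, "CellModel")); x@culture }

#' @rdname accessors
#' @export
ssState <- function(x) { stopifnot(is(x, "SteadyState")); x@state }

#' @rdname accessors
#' @export
growthRateOf <- function(x) { stopifnot(is(x, "SteadyState")); x@lambda }

#' @rdname accessors
#' @export
massFractionsOf <- function(x) { stopifnot(is(x, "SteadyState")); x@phi }

#' @rdname accessors
#' @export
sweepTable <- function(x) { stopifnot(is(x, "SweepResult")); x@table }

#' @rdname accessors
#' @export
isocostFit <- function(x) { stopifnot(is(x, "SweepResult")); x@fit }

#' @rdname accessors
#' @export
reactions <- function(x) { stopifnot(is(x, "FluxNetwork")); x@reactions }

#' @rdname accessors
#' @export
metabolites <- function(x) { stopifnot(is(x, "FluxNetwork")); x@metabolites }

#' @rdname accessors
#' @export
stoichiometry <- function(x) { stopifnot(is(x, "FluxNetwork")); x@S }
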