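## Parameter set and model constructor.

.param_names <- c(
  "v_E", "kappa_E", "phi_M", "v_T", "K_u", "K_M", "psi_max", "delta_m",
  "tau_max", "K_tau", "tau_r_max", "gamma_max", "K_gamma", "q_x",
  "kappa_q", "h_q", "kappa_theta", "beta_rho", "mu_rho", "M0",
  "k_rf", "k_cm", "D_r", "D_gamma", "D_psi", "D_g", "theta_floor"
)

#' Default kinetic parameter set
#'
#' Returns the package's default parameters.  Units: all species in molecules
#' per cell, all rates per hour, cell mass `M0` in amino-acid equivalents per
#' cell.  The values are a coarse manual calibration to Escherichia coli-like
#' scales chosen so that the default cell grows at 0.5--1.5/h on saturating
#' substrate and sustains chemostat steady states across dilution rates
#' 0.1--0.5/h; they are intended to be replaced by a user's own fit (see
#' [fitParameters()]) when quantitative work on a specific organism is
#' intended.
#'
#' \describe{
#'   \item{v_E, kappa_E}{substrate import/turnover: uptake per enzyme is
#'     `v_E*S/(kappa_E+S)` (per hour, molecules).}
#'   \item{phi_M}{yield of internal metabolite M per substrate molecule.}
#'   \item{v_T, K_u, K_M}{tRNA charging: flux `v_T*p_E/(1+K_u/t_u+K_M/M)`.}
#'   \item{psi_max}{maximum (unregulated) tRNA production rate.}
#'   \item{delta_m}{mRNA decay rate.}
#'   \item{tau_max, K_tau}{transcript elongation `tau_max*M/(K_tau+M)` (nt/h).}
#'   \item{tau_r_max}{maximal rRNA elongation rate (nt/h); rRNA elongation is
#'     metabolite-independent by default.}
#'   \item{gamma_max, K_gamma}{peptide elongation `gamma_max*t_c/(K_gamma+t_c)`
#'     (aa/h).}
#'   \item{q_x}{growth-rate copy-number expansion coefficient in
#'     `g = g0*exp(q_x*lambda)`.}
#'   \item{kappa_q, h_q}{housekeeping negative feedback
#'     `1/(1+(p_Q/kappa_q)^h_q)`.}
#'   \item{kappa_theta}{half-constant of the alarmone-proxy regulation.}
#'   \item{beta_rho, mu_rho}{ribosome assembly/disassembly rates.}
#'   \item{M0}{mid-exponential cell mass in amino-acid equivalents.}
#'   \item{k_rf, k_cm}{antibiotic sequestration rates for RNA polymerase
#'     (rifampicin-like) and ribosomes (chloramphenicol-like).}
#'   \item{D_r, D_gamma, D_psi, D_g}{perturbation scalings of rRNA gene
#'     dosage, maximal peptide elongation, maximal tRNA production and the
#'     alarmone-proxy variable; all default 1 (unperturbed).}
#'   \item{theta_floor}{numerical floor applied to `t_u` inside the ratio
#'     `theta = t_c/t_u` only, so integrator trial states at the boundary
#'     stay finite.}
#' }
#'
#' @return named numeric vector.
#' @seealso [cellModel()], [defaultGenes()]
#' @export
defaultParams <- function() {
  c(
    v_E         = 3000,
    kappa_E     = 1e3,
    phi_M       = 1.0,
    v_T         = 6000,
    K_u         = 3e5,
    K_M         = 2e4,
    psi_max     = 2.3e5,
    delta_m     = 6,
    tau_max     = 1.8e5,
    K_tau       = 2000,
    tau_r_max   = 3e5,
    gamma_max   = 4.5e5,
    K_gamma     = 1e6,
    q_x         = 0.3,
    kappa_q     = 4000,
    h_q         = 1,
    kappa_theta = 1,
    beta_rho    = 0.02,
    mu_rho      = 0.1,
    M0          = 3e6,
    k_rf        = 0,
    k_cm        = 0,
    D_r         = 1,
    D_gamma     = 1,
    D_psi       = 1,
    D_g         = 1,
    theta_floor = 1e-9
  )
}

#' Default host gene table
#'
#' Five lumped host transcription units: `E` (metabolic enzymes, alarmone
#' activated), `Q` (housekeeping bulk, negative autoregulation), `P` (RNA
#' polymerase), `R` (ribosomal protein) and `rrn` (ribosomal RNA; transcribed
#' but never translated).  Lengths are in amino acids except `rrn`, whose `n`
#' is the transcript length in nucleotides.  Copy numbers `g0` are per
#' chromosome, with `E` and `Q` lumping many genes into one unit.
#'
#' @return data.frame in the layout required by [cellModel()].
#' @export
defaultGenes <- function() {
  data.frame(
    name  = c("E", "Q", "P", "R", "rrn"),
    class = c("E", "Q", "P", "R", "rrn"),
    g0    = c(400, 800, 15, 60, 7),
    n     = c(300, 300, 4000, 7500, 4566),
    pb_f  = c(0.1, 0.1, 0.1, 0.1, 1),
    pb_r  = c(1300, 1300, 66, 98, 20),
    rb_f  = c(100, 100, 100, 100, NA),
    rb_r  = c(10, 10, 10, 10, NA),
    u     = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Construct a whole-cell resource allocation model
#'
#' @param genes gene table as in [defaultGenes()]; circuit genes may be
#'   included directly or added later with [addCircuit()].
#' @param params named numeric vector of kinetic constants; entries override
#'   [defaultParams()].
#' @param mode culture mode: `"single_cell"` (constant external substrate,
#'   frozen population), `"batch"` (substrate depletes, population grows) or
#'   `"chemostat"` (substrate influx `k_in`, dilution `delta`).
#' @param S0 initial (single cell: constant) external substrate.
#' @param N0 initial population size.
#' @param k_in chemostat substrate influx (molecules per hour into the
#'   vessel); the default sustains a positive population at dilution 0.5/h.
#' @param delta chemostat dilution rate (per hour).
#' @param pathway optional pathway spec, see [addPathway()].
#' @param options list of switches: `rrn_M_dependent` (logical, default
#'   `FALSE`; make rRNA elongation share the metabolite dependence of mRNA
#'   elongation instead of being constant), `circuit_copy_expansion`
#'   (logical, default `TRUE`; apply the growth-rate copy-number expansion
#'   `exp(q_x*lambda)` to circuit genes as well as host genes).
#'
#' @return a validated [CellModel-class].
#' @examples
#' m <- cellModel()
#' m2 <- addCircuit(m, twoReporterCircuit())
#' @export
cellModel <- function(genes = defaultGenes(), params = NULL,
                      mode = c("single_cell", "batch", "chemostat"),
                      S0 = 1e4, N0 = 1, k_in = 1e8, delta = 0.5,
                      pathway = list(), options = list()) {
  mode <- match.arg(mode)
  p <- defaultParams()
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(params)] <- params
  }
  opt <- modifyList(list(rrn_M_dependent = FALSE, circuit_copy_expansion = TRUE),
                    options)
  bad <- setdiff(names(opt), c("rrn_M_dependent", "circuit_copy_expansion"))
  if (length(bad))
    stop("unknown option(s): ", paste(bad, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  obj <- new("CellModel",
             genes = genes, params = p,
             culture = list(mode = mode, S0 = S0, N0 = N0,
                            k_in = k_in, delta = delta),
             pathway = pathway, options = opt)
  validObject(obj)
  obj
}

#' Define circuit genes
#'
#' `circuitGene()` builds one circuit gene row; unspecified kinetic columns
#' default to the host enzyme gene's values so that isocost slopes between
#' two reporters are interpretable (equal per-protein cost unless
#' overridden).  `twoReporterCircuit()` returns the standard two-reporter
#' competition circuit (both genes identical apart from their induction
#' inputs), the configuration used for isocost-line simulation.
#'
#' @param name gene name (must be unique in the model).
#' @param u induction level in \[0, 1\]; scales the RNA polymerase--promoter
#'   association.
#' @param g0 plasmid copy number.
#' @param n protein length (amino acids).
#' @param pb_f,pb_r promoter binding/unbinding rates (defaults: host enzyme
#'   gene values).
#' @param rb_f,rb_r ribosome binding/unbinding rates (defaults likewise).
#' @param u1,u2 induction levels of the two reporters.
#' @return data.frame of circuit gene rows for [addCircuit()].
#' @export
circuitGene <- function(name, u = 1, g0 = 40, n = 300,
                        pb_f = 0.1, pb_r = 100, rb_f = 100, rb_r = 10) {
  data.frame(name = name, class = "circuit", g0 = g0, n = n,
             pb_f = pb_f, pb_r = pb_r, rb_f = rb_f, rb_r = rb_r, u = u,
             stringsAsFactors = FALSE)
}

#' @rdname circuitGene
#' @export
twoReporterCircuit <- function(u1 = 1, u2 = 1) {
  rbind(circuitGene("c1", u = u1), circuitGene("c2", u = u2))
}
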