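## Circuit genes, metabolite-draining pathway, perturbation knobs.

#' Add circuit genes to a model
#'
#' Appends synthetic circuit genes (regulation
#' `R_i = (kappa_theta/(theta+kappa_theta)) * u_i`) to the model.  The new
#' genes enter both the RNA polymerase and the ribosome competition sums and
#' the growth-rate sum; the base model is untouched (pure augmentation), so
#' `removeCircuit()` restores a model whose RHS equals the original on the
#' original state space.
#'
#' @param model a [CellModel-class].
#' @param genes data.frame of circuit gene rows, see [circuitGene()] /
#'   [twoReporterCircuit()].
#' @return the augmented model.
#' @export
addCircuit <- function(model, genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!all(.gene_cols %in% names(genes)))
    stop("circuit gene table needs columns: ",
         paste(setdiff(.gene_cols, names(genes)), collapse = ", "))
  if (any(genes$class != "circuit"))
    stop("all added genes must have class 'circuit'")
  if (anyDuplicated(c(model@genes$name, genes$name)))
    stop("duplicate gene name(s): ",
         paste(intersect(model@genes$name, genes$name), collapse = ", "))
  model@genes <- rbind(model@genes, genes)
  validObject(model)
  model
}

#' @rdname addCircuit
#' @param names circuit gene names to remove (default: all circuit genes).
#' @export
removeCircuit <- function(model, names = NULL) {
  g <- model@genes
  if (is.null(names)) names <- g$name[g$class == "circuit"]
  if (!all(names %in% g$name[g$class == "circuit"]))
    stop("not a circuit gene: ",
         paste(setdiff(names, g$name[g$class == "circuit"]), collapse = ", "))
  if (length(model@pathway) && model@pathway$enzyme %in% names)
    stop("cannot remove the pathway enzyme gene; detach the pathway first")
  model@genes <- g[!(g$name %in% names), , drop = FALSE]
  rownames(model@genes) <- NULL
  validObject(model)
  model
}

#' Attach a metabolite-draining pathway
#'
#' One lumped reaction converts the internal metabolite M into a product X
#' at rate `v_ME * M * p_1 / (kappa_ME + M)`, where `p_1` is the pathway
#' enzyme level (a circuit gene of the model).  The flux leaves `dM/dt` and
#' enters `dX/dt` with the same magnitude (term-level mass balance); X is
#' additionally diluted by growth.
#'
#' @param model a [CellModel-class].
#' @param enzyme name of an existing circuit gene whose protein is the
#'   pathway enzyme.
#' @param v_ME turnover rate (per enzyme per hour).
#' @param kappa_ME half-saturation constant (molecules of M).
#' @return the augmented model (state vector gains the `X` entry).
#' @export
addPathway <- function(model, enzyme, v_ME, kappa_ME) {
  if (!enzyme %in% model@genes$name[model@genes$class == "circuit"])
    stop("pathway enzyme '", enzyme, "' is not a circuit gene of the model")
  model@pathway <- list(enzyme = enzyme, v_ME = v_ME, kappa_ME = kappa_ME)
  validObject(model)
  model
}

#' @rdname addPathway
#' @export
removePathway <- function(model) {
  model@pathway <- list()
  model
}

#' Apply perturbation knobs
#'
#' Composable scalings of the unperturbed model: `D_r` scales rRNA gene
#' dosage, `D_gamma` the maximal peptide elongation rate, `D_psi` the
#' maximal tRNA production rate, `D_g` the alarmone-proxy variable
#' (multiplicative; applying twice multiplies), and `k_rf`/`k_cm` add
#' antibiotic sequestration rates for RNA polymerase/ribosomes (additive).
#' The all-defaults call (`D_* = 1`, `k_* = 0`) returns an equivalent model.
#'
#' @param model a [CellModel-class].
#' @param D_r,D_gamma,D_psi,D_g multiplicative scalings (> 0).
#' @param k_rf,k_cm additional sequestration rates (>= 0, per hour).
#' @return the perturbed model.
#' @export
applyPerturbations <- function(model, D_r = 1, D_gamma = 1, D_psi = 1,
                               D_g = 1, k_rf = 0, k_cm = 0) {
  for (d in c(D_r = D_r, D_gamma = D_gamma, D_psi = D_psi, D_g = D_g))
    if (!is.finite(d) || d <= 0)
      stop("perturbation scalings D_* must be finite and > 0")
  if (k_rf < 0 || k_cm < 0) stop("k_rf and k_cm must be >= 0")
  p <- model@params
  p[["D_r"]] <- p[["D_r"]] * D_r
  p[["D_gamma"]] <- p[["D_gamma"]] * D_gamma
  p[["D_psi"]] <- p[["D_psi"]] * D_psi
  p[["D_g"]] <- p[["D_g"]] * D_g
  p[["k_rf"]] <- p[["k_rf"]] + k_rf
  p[["k_cm"]] <- p[["k_cm"]] + k_cm
  model@params <- p
  validObject(model)
  model
}

#' Change induction of a circuit gene
#'
#' @param model a [CellModel-class].
#' @param gene circuit gene name.
#' @param u new induction level in \[0, 1\].
#' @return the updated model.
#' @export
setInduction <- function(model, gene, u) {
  i <- which(model@genes$name == gene & model@genes$class == "circuit")
  if (!length(i)) stop("'", gene, "' is not a circuit gene")
  if (!is.finite(u) || u < 0 || u > 1) stop("u must lie in [0, 1]")
  model@genes$u[i] <- u
  model
}
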