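# Shared fixtures: standard model configurations and random-state
# generation.  Everything is built in code; nothing is read from disk.

two_reporter_model <- function(mode = "single_cell", delta = 0.3,
                               u1 = 0, u2 = 1, ...) {
  addCircuit(cellModel(mode = mode, delta = delta, ...),
             twoReporterCircuit(u1 = u1, u2 = u2))
}

pathway_model <- function(mode = "chemostat", delta = 0.3, u = 1) {
  m <- cellModel(mode = mode, delta = delta)
  m <- addCircuit(m, circuitGene("enz", u = u))
  addPathway(m, "enz", v_ME = 30, kappa_ME = 300)
}

# random positive states spanning several decades, in the model layout;
# the upper bound keeps implied growth rates finite under the exponential
# copy-number expansion
random_states <- function(model, n, seed = 1, lo = 1e-2, hi = 1e6) {
  nm <- stateNames(model)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- exp(runif(length(nm), log(lo), log(hi)))
    setNames(x, nm)
  })
}

# sweep helper: steady states along a grid with warm starts, returning the
# selected columns of the sweep table
sweep_values <- function(model, control, grid, cols) {
  sw <- runSweep(model, control, grid)
  stopifnot(all(sw@table$converged))
  sw@table[, cols, drop = FALSE]
}
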