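## Configuration files, run manifests and table writers.

.config_sections <- c("params", "genes", "circuit", "pathway", "perturb",
                      "culture", "options", "run")

#' Load a model configuration
#'
#' Reads a YAML configuration and builds the model.  Recognized sections
#' (all optional; an empty file yields the default single-cell model):
#' \describe{
#'   \item{params}{named kinetic parameter overrides, see [defaultParams()].}
#'   \item{genes}{list of per-gene overrides keyed by gene name; each entry
#'     may set `g0`, `n`, `pb_f`, `pb_r`, `rb_f`, `rb_r`.}
#'   \item{circuit}{list of circuit gene specs (fields of [circuitGene()];
#'     `name` required).}
#'   \item{pathway}{`enzyme`, `v_ME`, `kappa_ME`, see [addPathway()].}
#'   \item{perturb}{`D_r`, `D_gamma`, `D_psi`, `D_g`, `k_rf`, `k_cm`, see
#'     [applyPerturbations()].}
#'   \item{culture}{`mode`, `S0`, `N0`, `k_in`, `delta`.}
#'   \item{options}{model options, see [cellModel()].}
#'   \item{run}{free-form command options, passed through untouched.}
#' }
#' Unknown sections or keys are errors naming the offending key path (no
#' silent typos); every type-invariant violation is reported with its key.
#'
#' @param path YAML file.
#' @return list: `model` (a [CellModel-class]) and `run` (list of command
#'   options).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), .config_sections)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown key(s) ", paste0(where, ".", extra, collapse = ", "))
  }
  params <- unlist(cfg$params %||% list())
  check_keys(as.list(params), names(defaultParams()), "params")
  genes <- defaultGenes()
  for (gname in names(cfg$genes)) {
    i <- match(gname, genes$name)
    if (is.na(i)) stop("unknown gene in genes.", gname)
    ov <- cfg$genes[[gname]]
    check_keys(ov, c("g0", "n", "pb_f", "pb_r", "rb_f", "rb_r"),
               paste0("genes.", gname))
    for (k in names(ov)) genes[[k]][i] <- ov[[k]]
  }
  culture <- cfg$culture %||% list()
  check_keys(culture, c("mode", "S0", "N0", "k_in", "delta"), "culture")
  cu <- modifyList(list(mode = "single_cell", S0 = 1e4, N0 = 1,
                        k_in = 1e8, delta = 0.5), culture)
  options <- cfg$options %||% list()
  check_keys(options, c("rrn_M_dependent", "circuit_copy_expansion"),
             "options")
  model <- cellModel(genes = genes,
                     params = if (length(params)) params else NULL,
                     mode = cu$mode, S0 = cu$S0, N0 = cu$N0,
                     k_in = cu$k_in, delta = cu$delta, options = options)
  for (cg in cfg$circuit) {
    check_keys(cg, c("name", "u", "g0", "n", "pb_f", "pb_r", "rb_f", "rb_r"),
               "circuit")
    if (is.null(cg$name)) stop("circuit gene without a name")
    model <- addCircuit(model, do.call(circuitGene, cg))
  }
  if (!is.null(cfg$pathway)) {
    check_keys(cfg$pathway, c("enzyme", "v_ME", "kappa_ME"), "pathway")
    model <- addPathway(model, cfg$pathway$enzyme, cfg$pathway$v_ME,
                        cfg$pathway$kappa_ME)
  }
  if (!is.null(cfg$perturb)) {
    check_keys(cfg$perturb, c("D_r", "D_gamma", "D_psi", "D_g",
                              "k_rf", "k_cm"), "perturb")
    pe <- cfg$perturb
    for (d in c("D_r", "D_gamma", "D_psi", "D_g"))
      if (!is.null(pe[[d]]) && (!is.numeric(pe[[d]]) || pe[[d]] <= 0))
        stop("invalid perturb.", d, ": must be > 0")
    model <- do.call(applyPerturbations,
                     c(list(model), pe))
  }
  list(model = model, run = cfg$run %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname loadConfig
#' @param model a [CellModel-class] to serialize.
#' @details `dumpConfig()` writes a configuration that [loadConfig()] reads
#'   back into a semantically identical model (round trip).
#' @export
dumpConfig <- function(model, path) {
  g <- model@genes
  host <- g[g$class != "circuit", ]
  circ <- g[g$class == "circuit", ]
  def <- defaultGenes()
  gene_ov <- list()
  for (i in seq_len(nrow(host))) {
    j <- match(host$name[i], def$name)
    ov <- list()
    for (k in c("g0", "n", "pb_f", "pb_r", "rb_f", "rb_r")) {
      if (is.na(j) || !identical(host[[k]][i], def[[k]][j]))
        if (!is.na(host[[k]][i])) ov[[k]] <- host[[k]][i]
    }
    if (length(ov)) gene_ov[[host$name[i]]] <- ov
  }
  cfg <- list(
    params = as.list(model@params),
    culture = model@culture,
    options = model@options)
  if (length(gene_ov)) cfg$genes <- gene_ov
  if (nrow(circ))
    cfg$circuit <- lapply(seq_len(nrow(circ)), function(i)
      list(name = circ$name[i], u = circ$u[i], g0 = circ$g0[i],
           n = circ$n[i], pb_f = circ$pb_f[i], pb_r = circ$pb_r[i],
           rb_f = circ$rb_f[i], rb_r = circ$rb_r[i]))
  if (length(model@pathway)) cfg$pathway <- model@pathway
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run manifest
#'
#' Collects everything needed to re-run a job: the fully resolved parameter
#' set and gene table, culture, pathway, options, the seed, package and R
#' versions, a timestamp and any extra records (convergence flags, fit
#' results).
#'
#' @param model a [CellModel-class].
#' @param seed integer seed used for the run.
#' @param extra named list of additional records.
#' @return manifest list.
#' @export
runManifest <- function(model, seed = NULL, extra = list()) {
  c(list(
    package = "cellecon",
    version = as.character(packageVersion("cellecon")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = as.list(model@params),
    genes = model@genes,
    culture = model@culture,
    pathway = model@pathway,
    options = model@options), extra)
}

#' @rdname runManifest
#' @param manifest a manifest list.
#' @param path output JSON path.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
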