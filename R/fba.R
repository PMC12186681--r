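## Flux balance / flux variability analysis of protein production capacity.

## LP wrapper around pracma::linprog.  Maximize/minimize obj'v subject to
## S v = 0, lb <= v <= ub, and optional extra rows A v <= b.  Variables are
## shifted by their (finite) lower bounds so the solver sees y >= 0 with
## upper bounds as inequality rows.
.solve_lp <- function(obj, S, lb, ub, A = NULL, b = NULL, maximize = TRUE) {
  n <- length(obj)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("flux bounds must be finite")
  beq <- as.numeric(-S %*% lb)
  Aub <- diag(n)
  bub <- ub - lb
  if (!is.null(A)) {
    Aub <- rbind(Aub, A)
    bub <- c(bub, b - as.numeric(A %*% lb))
  }
  res <- tryCatch(
    suppressWarnings(
      pracma::linprog(cc = obj, A = Aub, b = bub, Aeq = S, beq = beq,
                      maxiter = 100 * (n + nrow(Aub)), maximize = maximize)),
    error = function(e) NULL)
  if (is.null(res) || is.null(res$x) || anyNA(res$x) || res$errno < 0)
    return(list(status = "infeasible", flux = NULL, objval = NA_real_))
  v <- res$x + lb
  list(status = "optimal", flux = v,
       objval = sum(obj * v))
}

.require_rxn <- function(network, id) {
  j <- match(id, network@reactions$id)
  if (is.na(j)) stop("no reaction '", id, "' in the network")
  j
}

#' Add a protein translation demand reaction
#'
#' Augments the network with the translation demand of one protein: a
#' reaction consuming the amino-acid composition of `sequence` (count of
#' residue i from its amino-acid metabolite) and `gtp_per_bond * (L - 1)`
#' GTP (hydrolyzed to GDP + Pi), producing one unit of a pseudo-metabolite
#' `protein_c` that leaves through an added sink.  The demand reaction
#' becomes the network objective.
#'
#' @param network a [FluxNetwork-class].
#' @param sequence protein amino-acid sequence (one-letter codes, length
#'   >= 1); a vector of lines is concatenated, whitespace ignored.
#' @param gtp_per_bond GTP consumed per peptide bond (default 2: one for
#'   delivery, one for translocation; tRNA-charging ATP costs are not
#'   included).
#' @param aa_map residue-to-metabolite mapping, see [aminoAcidMap()];
#'   `NULL` picks `"toy"` or `"bigg"` by inspecting the network.
#' @param gtp_id,gdp_id,pi_id energy metabolite ids.
#' @param demand_id,sink_id ids for the two added reactions.
#' @return the augmented network, with attribute `composition` (the residue
#'   counts used).
#' @export
addProteinDemand <- function(network, sequence, gtp_per_bond = 2,
                             aa_map = NULL, gtp_id = "gtp_c",
                             gdp_id = "gdp_c", pi_id = "pi_c",
                             demand_id = "PROT_DEMAND",
                             sink_id = "SK_protein_c") {
  seqstr <- toupper(gsub("\\s", "", paste(sequence, collapse = "")))
  if (!nchar(seqstr)) stop("empty protein sequence")
  res <- strsplit(seqstr, "")[[1]]
  bad <- setdiff(unique(res), .aa_letters)
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  if (is.null(aa_map)) {
    aa_map <- if (any(aminoAcidMap("toy") %in% network@metabolites$id))
      aminoAcidMap("toy") else aminoAcidMap("bigg")
  }
  counts <- table(factor(res, levels = .aa_letters))
  counts <- counts[counts > 0]
  aa_ids <- aa_map[names(counts)]
  missing <- c(setdiff(aa_ids, network@metabolites$id),
               setdiff(c(gtp_id, gdp_id, pi_id), network@metabolites$id))
  if (length(missing))
    stop("network lacks metabolite(s) required by the demand reaction: ",
         paste(missing, collapse = ", "))
  L <- length(res)
  gtp <- gtp_per_bond * (L - 1)
  m <- network@metabolites
  m <- rbind(m, data.frame(id = "protein_c", name = "protein pseudo-metabolite",
                           compartment = "c", boundary = FALSE,
                           stringsAsFactors = FALSE))
  r <- network@reactions
  r$objective <- 0
  r <- rbind(r,
    data.frame(id = demand_id, name = "protein translation demand",
               lb = 0, ub = 1000, subsystem = "Protein Production",
               objective = 1, stringsAsFactors = FALSE),
    data.frame(id = sink_id, name = "protein sink",
               lb = 0, ub = 1000, subsystem = "Protein Production",
               objective = 0, stringsAsFactors = FALSE))
  S <- matrix(0, nrow(m), nrow(r), dimnames = list(m$id, r$id))
  S[seq_len(nrow(network@S)), seq_len(ncol(network@S))] <- network@S
  sto <- setNames(-as.numeric(counts), aa_ids)
  if (gtp > 0) {
    sto[gtp_id] <- if (gtp_id %in% names(sto)) sto[gtp_id] - gtp else -gtp
    sto[gdp_id] <- gtp
    sto[pi_id] <- gtp
  }
  sto["protein_c"] <- 1
  S[names(sto), demand_id] <- sto
  S["protein_c", sink_id] <- -1
  out <- fluxNetwork(r, m, S)
  attr(out, "composition") <- counts
  out
}

#' Maximal protein production flux
#'
#' Solves the FBA problem: maximize the objective (the protein demand flux)
#' subject to steady-state mass balance, a carbon uptake bound and a fixed
#' biomass flux.  The uptake bound opens the named exchange reaction to
#' `[-uptake, ub]` (uptake is a negative exchange flux); biomass is fixed
#' as an equality (`lb = ub = biomass`).
#'
#' @param network network with an objective (see [addProteinDemand()]).
#' @param uptake named numeric: exchange reaction id(s) and maximal uptake
#'   rate(s) (positive numbers, mmol/gDCW/h).
#' @param biomass biomass flux to fix (same units); `NULL` leaves biomass
#'   bounds untouched.
#' @param biomass_id biomass reaction id.
#' @return list: `objval` (maximal protein flux; `NA` when infeasible —
#'   infeasible is reported as such, never as 0), `flux` (named flux vector
#'   or `NULL`), `status`.
#' @export
maxProteinFlux <- function(network, uptake, biomass = NULL,
                           biomass_id = "BIOMASS") {
  r <- network@reactions
  if (all(r$objective == 0)) stop("network has no objective reaction")
  for (ex in names(uptake)) {
    j <- .require_rxn(network, ex)
    r$lb[j] <- -abs(uptake[[ex]])
  }
  if (!is.null(biomass)) {
    j <- .require_rxn(network, biomass_id)
    r$lb[j] <- r$ub[j] <- biomass
  }
  sol <- .solve_lp(r$objective, network@S, r$lb, r$ub, maximize = TRUE)
  if (sol$status != "optimal")
    return(list(objval = NA_real_, flux = NULL, status = sol$status))
  list(objval = sol$objval, flux = setNames(sol$flux, r$id),
       status = "optimal")
}

#' Protein production capacity grid
#'
#' [maxProteinFlux()] over a grid of uptake rates and biomass fluxes.
#'
#' @inheritParams maxProteinFlux
#' @param exchange_id carbon-source exchange reaction id.
#' @param uptake_grid,biomass_grid numeric grids.
#' @return data.frame: `uptake`, `biomass`, `protein_flux` (`NA` where
#'   infeasible), `status`.
#' @export
capacityGrid <- function(network, exchange_id, uptake_grid, biomass_grid,
                         biomass_id = "BIOMASS") {
  out <- NULL
  for (u in uptake_grid) for (b in biomass_grid) {
    sol <- maxProteinFlux(network, setNames(u, exchange_id), b, biomass_id)
    out <- rbind(out, data.frame(uptake = u, biomass = b,
                                 protein_flux = sol$objval,
                                 status = sol$status))
  }
  out
}

#' Flux variability analysis
#'
#' With the objective constrained to at least `fraction` of its optimum,
#' minimizes and maximizes every reaction flux in turn.  A reaction is
#' classified flexible ("slack") when its flux range exceeds `threshold`
#' (default 0.001 mmol/gDCW/h).
#'
#' @inheritParams maxProteinFlux
#' @param fraction fraction of the optimal objective to retain (default 1).
#' @param threshold flexibility threshold on `|max - min|`.
#' @return data.frame (one row per reaction): `id`, `subsystem`, `min`,
#'   `max`, `flexible`, `status`; attribute `threshold`.
#' @export
runFVA <- function(network, uptake, biomass = NULL, biomass_id = "BIOMASS",
                   fraction = 1, threshold = 0.001) {
  r <- network@reactions
  for (ex in names(uptake)) {
    j <- .require_rxn(network, ex)
    r$lb[j] <- -abs(uptake[[ex]])
  }
  if (!is.null(biomass)) {
    j <- .require_rxn(network, biomass_id)
    r$lb[j] <- r$ub[j] <- biomass
  }
  base <- .solve_lp(r$objective, network@S, r$lb, r$ub, maximize = TRUE)
  if (base$status != "optimal")
    stop("FVA base problem is ", base$status)
  ## keep the objective at (a fraction of) its optimum: -obj'v <= -f*opt
  A <- matrix(-r$objective, 1)
  b <- -fraction * base$objval
  ## tiny slack keeps the constrained problems feasible in exact arithmetic
  b <- b + 1e-9 * max(1, abs(base$objval))
  n <- nrow(r)
  vmin <- vmax <- rep(NA_real_, n)
  status <- rep("optimal", n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    lo <- .solve_lp(e, network@S, r$lb, r$ub, A = A, b = b, maximize = FALSE)
    hi <- .solve_lp(e, network@S, r$lb, r$ub, A = A, b = b, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      status[j] <- "failed"
      next
    }
    vmin[j] <- lo$objval; vmax[j] <- hi$objval
  }
  out <- data.frame(id = r$id, subsystem = r$subsystem,
                    min = vmin, max = vmax,
                    flexible = abs(vmax - vmin) > threshold,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Subsystem net fluxes
#'
#' The signed sum of fluxes over every subsystem, and (when an FVA report is
#' supplied) the same sum restricted to inflexible reactions — the portion
#' of each subsystem whose flux is pinned by the optimum.
#'
#' @param network a [FluxNetwork-class].
#' @param flux named flux vector (e.g. from [maxProteinFlux()]).
#' @param fva optional FVA report from [runFVA()].
#' @return data.frame: `subsystem`, `net_flux`, and with `fva` also
#'   `inflexible_net_flux` and `n_flexible`.
#' @export
subsystemNetFlux <- function(network, flux, fva = NULL) {
  r <- network@reactions
  v <- flux[r$id]
  subs <- sort(unique(r$subsystem))
  out <- data.frame(subsystem = subs,
                    net_flux = vapply(subs, function(s)
                      sum(v[r$subsystem == s]), 0),
                    stringsAsFactors = FALSE)
  if (!is.null(fva)) {
    infl <- !fva$flexible[match(r$id, fva$id)]
    out$inflexible_net_flux <- vapply(subs, function(s)
      sum(v[r$subsystem == s & infl]), 0)
    out$n_flexible <- vapply(subs, function(s)
      sum(fva$flexible[match(r$id[r$subsystem == s], fva$id)]), 0L)
  }
  rownames(out) <- NULL
  out
}

#' Metabolite net flux through inflexible reactions
#'
#' For each requested metabolite, the production and consumption flux summed
#' over the inflexible reactions of an FVA report — the committed turnover
#' of key translation precursors.
#'
#' @inheritParams subsystemNetFlux
#' @param metabolites metabolite ids (default: all).
#' @return data.frame: `metabolite`, `produced`, `consumed` (negative),
#'   `net`.
#' @export
metaboliteNetFlux <- function(network, flux, fva,
                              metabolites = network@metabolites$id) {
  r <- network@reactions
  v <- flux[r$id]
  infl <- !fva$flexible[match(r$id, fva$id)]
  i <- match(metabolites, network@metabolites$id)
  if (anyNA(i))
    stop("unknown metabolite(s): ",
         paste(metabolites[is.na(i)], collapse = ", "))
  rates <- network@S[i, , drop = FALSE] *
    matrix(v * infl, length(i), nrow(r), byrow = TRUE)
  data.frame(metabolite = metabolites,
             produced = apply(rates, 1, function(z) sum(z[z > 0])),
             consumed = apply(rates, 1, function(z) sum(z[z < 0])),
             net = rowSums(rates),
             stringsAsFactors = FALSE)
}
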