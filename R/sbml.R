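## Minimal SBML level-3 FBC-v2 serialization for FluxNetwork objects, plus
## the deterministic desk-scale fixture network.  The writer emits a fixed
## subset (species, reactions with stoichiometry, fbc bounds, one maximizing
## objective, one group per subsystem); the reader accepts that subset and
## the common conventions of published reconstructions (fbc bound
## parameters, groups, or "SUBSYSTEM:" notes).

#' Construct a FluxNetwork
#'
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`,
#'   `subsystem`, `objective`; missing `name`/`subsystem`/`objective` are
#'   filled with defaults (`id`, `"unassigned"`, 0).
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `boundary` (missing filled likewise).
#' @param stoich list mapping reaction id to a named numeric vector of
#'   stoichiometric coefficients (negative = consumed), or a complete
#'   metabolite-by-reaction matrix.
#' @return a validated [FluxNetwork-class].
#' @export
fluxNetwork <- function(reactions, metabolites, stoich) {
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem)) reactions$subsystem <- "unassigned"
  reactions$subsystem[is.na(reactions$subsystem)] <- "unassigned"
  if (is.null(reactions$objective)) reactions$objective <- 0
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$boundary)) metabolites$boundary <- FALSE
  if (is.matrix(stoich)) {
    S <- stoich
  } else {
    S <- matrix(0, nrow(metabolites), nrow(reactions),
                dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoich)) {
      sto <- stoich[[rid]]
      j <- match(rid, reactions$id)
      if (is.na(j)) stop("stoichiometry for unknown reaction '", rid, "'")
      i <- match(names(sto), metabolites$id)
      if (anyNA(i))
        stop("unknown metabolite(s) in reaction '", rid, "': ",
             paste(names(sto)[is.na(i)], collapse = ", "))
      S[i, j] <- sto
    }
  }
  obj <- new("FluxNetwork", S = S, reactions = reactions,
             metabolites = metabolites)
  validObject(obj)
  obj
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a FluxNetwork as SBML (FBC v2)
#'
#' Deterministic serialization: the same network always produces
#' byte-identical output.  Flux bounds are emitted as fbc parameters, the
#' objective as a maximizing fbc objective over reactions with nonzero
#' objective coefficient, and subsystems as SBML groups.
#'
#' @param network a [FluxNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSBMLNetwork <- function(network, path) {
  r <- network@reactions
  m <- network@metabolites
  S <- network@S
  num <- function(x) {
    x[x == 0] <- 0   # normalize negative zero
    formatC(x, format = "g", digits = 15)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1" ',
           'level="3" version="1" fbc:required="false" groups:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>')
  for (cp in sort(unique(m$compartment)))
    lines <- c(lines, sprintf('      <compartment id="%s" constant="true"/>', cp))
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(m)))
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s" ',
             'boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>'),
      m$id[i], .xml_escape(m$name[i]), m$compartment[i],
      tolower(as.character(m$boundary[i]))))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (i in seq_len(nrow(r))) {
    lines <- c(lines,
      sprintf('      <parameter id="%s_lb" value="%s" constant="true"/>',
              r$id[i], num(r$lb[i])),
      sprintf('      <parameter id="%s_ub" value="%s" constant="true"/>',
              r$id[i], num(r$ub[i])))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(r))) {
    sto <- S[, i]
    reac <- which(sto < 0); prod <- which(sto > 0)
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s_lb" fbc:upperFluxBound="%s_ub">'),
      r$id[i], .xml_escape(r$name[i]), tolower(as.character(r$lb[i] < 0)),
      r$id[i], r$id[i]))
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>')
      for (k in reac)
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          m$id[k], num(-sto[k])))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>')
      for (k in prod)
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          m$id[k], num(sto[k])))
      lines <- c(lines, '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  obj <- which(r$objective != 0)
  lines <- c(lines,
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>')
  for (i in obj)
    lines <- c(lines, sprintf(
      '          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
      r$id[i], num(r$objective[i])))
  lines <- c(lines,
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '    <groups:listOfGroups>')
  subs <- unique(r$subsystem)
  for (si in seq_along(subs)) {
    lines <- c(lines, sprintf(
      '      <groups:group groups:id="g%d" groups:name="%s" groups:kind="partonomy">',
      si, .xml_escape(subs[si])),
      '        <groups:listOfMembers>')
    for (i in which(r$subsystem == subs[si]))
      lines <- c(lines, sprintf(
        '          <groups:member groups:idRef="%s"/>', r$id[i]))
    lines <- c(lines, '        </groups:listOfMembers>',
               '      </groups:group>')
  }
  lines <- c(lines, '    </groups:listOfGroups>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Read an SBML (FBC) metabolic network
#'
#' Parses species, reactions with stoichiometry, FBC flux bounds (bound
#' parameters), the active FBC objective and subsystem labels (SBML groups,
#' or `SUBSYSTEM:` annotations in reaction notes; `"unassigned"` otherwise).
#'
#' @param path SBML file.
#' @return a [FluxNetwork-class].
#' @export
readSBMLNetwork <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse error in '", path, "': ", conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
          g = "http://www.sbml.org/sbml/level3/version1/groups/version1")
  att <- function(nodes, a) xml2::xml_attr(nodes, a)
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("no species found in '", path, "'")
  metabolites <- data.frame(
    id = att(sp, "id"), name = att(sp, "name"),
    compartment = att(sp, "compartment"),
    boundary = att(sp, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)
  metabolites$name[is.na(metabolites$name)] <-
    metabolites$id[is.na(metabolites$name)]
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- setNames(as.numeric(att(pars, "value")), att(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("no reactions found in '", path, "'")
  n_r <- length(rx)
  rid <- att(rx, "id")
  bound_of <- function(ref, fallback) {
    v <- unname(parval[ref])
    v[is.na(v)] <- fallback
    v
  }
  lb <- bound_of(att(rx, "fbc:lowerFluxBound"),
                 ifelse(att(rx, "reversible") %in% "true", -1000, 0))
  ub <- bound_of(att(rx, "fbc:upperFluxBound"), 1000)
  S <- matrix(0, nrow(metabolites), n_r,
              dimnames = list(metabolites$id, rid))
  subsys <- rep(NA_character_, n_r)
  for (j in seq_len(n_r)) {
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rx[[j]], paste0("./s:", tag,
                                                 "/s:speciesReference"), ns)
      if (!length(refs)) next
      ids <- att(refs, "species")
      sto <- as.numeric(att(refs, "stoichiometry"))
      sto[is.na(sto)] <- 1
      i <- match(ids, metabolites$id)
      if (anyNA(i))
        stop("reaction '", rid[j], "' references unknown species: ",
             paste(ids[is.na(i)], collapse = ", "))
      S[i, j] <- S[i, j] + side * sto
    }
    notes <- xml2::xml_find_first(rx[[j]], "./s:notes", ns)
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(notes)
      hit <- regmatches(txt, regexpr("SUBSYSTEM:\\s*[^<\n]*", txt))
      if (length(hit))
        subsys[j] <- trimws(sub("SUBSYSTEM:\\s*", "", hit))
    }
  }
  ## subsystems from groups override notes
  grp <- xml2::xml_find_all(doc, ".//g:listOfGroups/g:group", ns)
  for (gnode in grp) {
    gname <- xml2::xml_attr(gnode, "name")
    mem <- xml2::xml_find_all(gnode, "./g:listOfMembers/g:member", ns)
    refs <- xml2::xml_attr(mem, "idRef")
    subsys[match(refs, rid)] <- gname
  }
  subsys[is.na(subsys)] <- "unassigned"
  objective <- numeric(n_r)
  fo <- xml2::xml_find_all(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (length(fo)) {
    j <- match(att(fo, "fbc:reaction"), rid)
    objective[j[!is.na(j)]] <-
      as.numeric(att(fo, "fbc:coefficient"))[!is.na(j)]
  }
  rname <- att(rx, "name"); rname[is.na(rname)] <- rid[is.na(rname)]
  fluxNetwork(
    reactions = data.frame(id = rid, name = rname, lb = lb, ub = ub,
                           subsystem = subsys, objective = objective,
                           stringsAsFactors = FALSE),
    metabolites = metabolites, stoich = S)
}

## residues in fixed order; the fixture synthesizes one metabolite per residue
.aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid metabolite id mapping
#'
#' Mapping from one-letter residue codes to metabolite ids.  `"toy"` is the
#' fixture convention (`aa_<letter>_c`); `"bigg"` follows the BiGG cytosolic
#' L-amino-acid ids used by published reconstructions (glycine has no
#' L-form).  Pass a modified copy to [addProteinDemand()] when a
#' reconstruction uses other conventions.
#'
#' @param style `"toy"` or `"bigg"`.
#' @return named character vector (names = residue letters).
#' @export
aminoAcidMap <- function(style = c("toy", "bigg")) {
  style <- match.arg(style)
  if (style == "toy")
    return(setNames(paste0("aa_", .aa_letters, "_c"), .aa_letters))
  bigg <- c(A = "ala__L_c", C = "cys__L_c", D = "asp__L_c", E = "glu__L_c",
            F = "phe__L_c", G = "gly_c", H = "his__L_c", I = "ile__L_c",
            K = "lys__L_c", L = "leu__L_c", M = "met__L_c", N = "asn__L_c",
            P = "pro__L_c", Q = "gln__L_c", R = "arg__L_c", S = "ser__L_c",
            T = "thr__L_c", V = "val__L_c", W = "trp__L_c", Y = "tyr__L_c")
  bigg
}

#' Desk-scale fixture network
#'
#' A deterministic toy metabolic network standing in for a genome-scale
#' reconstruction: two carbon sources of unequal quality (the rich source
#' yields two precursor units per molecule, the poor one yields one, echoing
#' the glucose/glycerol contrast), a parallel-path motif in central
#' metabolism (two equivalent precursor-to-pyruvate reactions, which flux
#' variability analysis must classify as flexible), synthesis of all twenty
#' amino-acid metabolites and of GTP, a biomass drain and sink reactions.
#' Optima are hand-computable: with rich-carbon uptake `U` and biomass flux
#' `b`, a protein of length `L` with `g` GTP per peptide bond has maximal
#' demand flux `(2U - b) / (L + g*(L-1)/2)`.
#'
#' @param path optional file path; when given the network is also written as
#'   SBML (byte-identical across calls).
#' @return a [FluxNetwork-class] (invisibly when `path` is given).
#' @export
toyNetworkFixture <- function(path = NULL) {
  aa_ids <- unname(aminoAcidMap("toy"))
  mets <- data.frame(
    id = c("glc_e", "gly_e", "prec_c", "pyr_c", aa_ids,
           "gtp_c", "gdp_c", "pi_c"),
    compartment = c("e", "e", rep("c", 2 + length(aa_ids) + 3)),
    boundary = FALSE, stringsAsFactors = FALSE)
  mets$name <- mets$id
  rx <- data.frame(
    id = c("EX_glc_e", "EX_gly_e", "T_GLC", "T_GLY", "PATH_A", "PATH_B",
           paste0("AASYN_", .aa_letters), "GTPSYN", "BIOMASS",
           "SK_gdp_c", "SK_pi_c"),
    lb = 0,   # exchanges closed by default; uptake bounds are set per run
    ub = 1000,
    subsystem = c("Exchange", "Exchange", "Transport", "Transport",
                  "Central Metabolism", "Central Metabolism",
                  rep("Amino Acid Biosynthesis", length(.aa_letters)),
                  "Energy", "Biomass", "Sinks", "Sinks"),
    objective = 0, stringsAsFactors = FALSE)
  rx$name <- rx$id
  sto <- c(
    list(EX_glc_e = c(glc_e = -1), EX_gly_e = c(gly_e = -1),
         T_GLC = c(glc_e = -1, prec_c = 2),
         T_GLY = c(gly_e = -1, prec_c = 1),
         PATH_A = c(prec_c = -1, pyr_c = 1),
         PATH_B = c(prec_c = -1, pyr_c = 1),
         GTPSYN = c(pyr_c = -1, gtp_c = 2),
         BIOMASS = c(pyr_c = -1),
         SK_gdp_c = c(gdp_c = -1), SK_pi_c = c(pi_c = -1)),
    setNames(lapply(aa_ids, function(a) setNames(c(-1, 1), c("pyr_c", a))),
             paste0("AASYN_", .aa_letters)))
  net <- fluxNetwork(rx, mets, sto)
  if (!is.null(path)) {
    writeSBMLNetwork(net, path)
    return(invisible(net))
  }
  net
}
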