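#' Read a constraint-based model from file
#'
#' Two formats are supported.
#'
#' * `"tabular"`: one reaction per line,
#'   `id TAB formula TAB lb TAB ub`, with formulas like `2 A + B -> C`
#'   (`<->` for reversible; an empty side denotes an exchange, e.g.
#'   `GLC ->` exports GLC so that negative flux is uptake).  Metabolites
#'   may carry a compartment suffix `met[compartment]`.  Comment lines
#'   start with `#`; a directive `# @set name: id1,id2` populates
#'   `named_sets`.
#' * `"sbml"`: SBML Level 2 (kineticLaw `LOWER_BOUND`/`UPPER_BOUND`
#'   parameters) or Level 3 with the fbc bounds package.
#'
#' Reversibility is inferred from the bounds when no explicit flag is
#' present (`lb < 0` implies reversible).
#'
#' @param path file path.
#' @param format `"tabular"` or `"sbml"` (default guessed from the
#'   extension).
#' @return A `metabolic_model`.
#' @export
read_model <- function(path, format = c("guess", "tabular", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "guess")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "tabular"
  switch(format,
         tabular = read_tabular_model(path),
         sbml = read_sbml_model(path))
}

parse_formula_side <- function(side) {
  side <- trimws(side)
  if (side == "") return(list(mets = character(), coefs = numeric()))
  terms <- strsplit(side, "\\s*\\+\\s+")[[1]]
  mets <- character(length(terms)); coefs <- numeric(length(terms))
  for (i in seq_along(terms)) {
    m <- regmatches(terms[i],
                    regexec("^\\s*(?:([0-9]*\\.?[0-9]+)\\s+)?(\\S+)\\s*$",
                            terms[i]))[[1]]
    if (length(m) == 0) stop("cannot parse reaction term: '", terms[i], "'")
    coefs[i] <- if (m[2] == "") 1 else as.numeric(m[2])
    mets[i] <- m[3]
  }
  list(mets = mets, coefs = coefs)
}

read_tabular_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  named_sets <- list()
  for (ln in grep("^#\\s*@set\\s", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*@set\\s+(\\S+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m))
      named_sets[[m[2]]] <- trimws(strsplit(m[3], ",")[[1]])
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty model file: ", path)
  ids <- character(); lb <- numeric(); ub <- numeric(); rev <- logical()
  rows <- list()
  comp <- list()
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\t")[[1]]
    if (length(parts) != 4)
      stop("line ", k, ": expected 4 tab-separated fields, got ",
           length(parts))
    id <- trimws(parts[1])
    arrow_rev <- grepl("<->", parts[2], fixed = TRUE)
    sides <- strsplit(parts[2], "<->|->")[[1]]
    if (length(sides) > 2) stop("line ", k, ": malformed formula")
    lhs <- parse_formula_side(sides[1])
    rhs <- parse_formula_side(if (length(sides) == 2) sides[2] else "")
    l <- as.numeric(parts[3]); u <- as.numeric(parts[4])
    if (is.na(l) || is.na(u)) stop("line ", k, ": non-numeric bounds")
    if (l > u) stop("validation error for reaction '", id, "': lb (", l,
                    ") > ub (", u, ")")
    coefs <- c(-lhs$coefs, rhs$coefs)
    mets <- c(lhs$mets, rhs$mets)
    bare <- sub("\\[[^]]*\\]$", "", mets)
    cm <- regmatches(mets, regexec("\\[([^]]*)\\]$", mets))
    for (i in seq_along(mets)) {
      cmp <- if (length(cm[[i]])) cm[[i]][2] else NA_character_
      if (!is.na(cmp)) comp[[bare[i]]] <- cmp
    }
    ids <- c(ids, id); lb <- c(lb, l); ub <- c(ub, u)
    rev <- c(rev, arrow_rev | l < 0)
    rows[[k]] <- stats::setNames(coefs, bare)
  }
  all_mets <- unique(unlist(lapply(rows, names)))
  S <- matrix(0, length(all_mets), length(ids),
              dimnames = list(all_mets, ids))
  for (k in seq_along(rows))
    for (m in names(rows[[k]]))
      S[m, k] <- S[m, k] + rows[[k]][[m]]
  compartment <- vapply(all_mets, function(m)
    if (!is.null(comp[[m]])) comp[[m]] else "matrix", character(1))
  metabolic_model(S, lb, ub, reversible = rev,
                  compartment = unname(compartment),
                  named_sets = named_sets)
}

#' Write a model in the tabular dialect
#'
#' Inverse of [read_model()] for `format = "tabular"`; named sets are
#' written as `# @set` directives.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tabular_model <- function(model, path) {
  fmt_side <- function(coefs, mets) {
    if (!length(mets)) return("")
    paste(ifelse(coefs == 1, mets, paste(format(coefs, trim = TRUE), mets)),
          collapse = " + ")
  }
  cmp <- model$compartment
  met_lab <- ifelse(cmp == "matrix", model$metabolite_ids,
                    paste0(model$metabolite_ids, "[", cmp, "]"))
  lines <- character()
  for (nm in names(model$named_sets))
    lines <- c(lines, paste0("# @set ", nm, ": ",
                             paste(model$named_sets[[nm]], collapse = ",")))
  for (j in seq_along(model$reaction_ids)) {
    col <- model$stoichiometry[, j]
    neg <- which(col < 0); pos <- which(col > 0)
    arrow <- if (model$reversible[j]) "<->" else "->"
    formula <- paste(fmt_side(-col[neg], met_lab[neg]), arrow,
                     fmt_side(col[pos], met_lab[pos]))
    lines <- c(lines, paste(model$reaction_ids[j], trimws(formula),
                            format(model$lower_bounds[j], trim = TRUE),
                            format(model$upper_bounds[j], trim = TRUE),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# --- SBML ------------------------------------------------------------------

local_attr <- function(node, local) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", local, "$"), names(at))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("SBML file has no species: ", path)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_bnd <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% c("true", "1")
  keep <- !sp_bnd
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("SBML file has no reactions: ", path)
  n <- length(rx_nodes)
  ids <- xml2::xml_attr(rx_nodes, "id")
  rev <- !(xml2::xml_attr(rx_nodes, "reversible") %in% c("false", "0"))
  mets <- sp_id[keep]
  S <- matrix(0, length(mets), n, dimnames = list(mets, ids))
  lb <- numeric(n); ub <- numeric(n)
  for (j in seq_len(n)) {
    rx <- rx_nodes[[j]]
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(sr, "species")
      st <- xml2::xml_attr(sr, "stoichiometry")
      if (s %in% mets)
        S[s, j] <- S[s, j] - (if (is.na(st)) 1 else as.numeric(st))
    }
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(sr, "species")
      st <- xml2::xml_attr(sr, "stoichiometry")
      if (s %in% mets)
        S[s, j] <- S[s, j] + (if (is.na(st)) 1 else as.numeric(st))
    }
    lbr <- local_attr(rx, "lowerFluxBound")
    ubr <- local_attr(rx, "upperFluxBound")
    if (!is.na(lbr) && lbr %in% names(pval)) {
      lb[j] <- pval[[lbr]]; ub[j] <- pval[[ubr]]
    } else {
      kl <- xml2::xml_find_first(
        rx, "./kineticLaw//parameter[@id='LOWER_BOUND']")
      ku <- xml2::xml_find_first(
        rx, "./kineticLaw//parameter[@id='UPPER_BOUND']")
      lb[j] <- if (!inherits(kl, "xml_missing"))
        as.numeric(xml2::xml_attr(kl, "value"))
      else if (rev[j]) -1000 else 0
      ub[j] <- if (!inherits(ku, "xml_missing"))
        as.numeric(xml2::xml_attr(ku, "value")) else 1000
    }
    if (lb[j] > ub[j])
      stop("validation error for reaction '", ids[j], "': lb > ub")
  }
  comp <- sp_comp[keep]
  metabolic_model(S, lb, ub, reversible = rev | lb < 0, compartment = comp)
}

#' Write a model as SBML Level 3 with fbc bounds
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path, model_id = "model") {
  core <- "http://www.sbml.org/sbml/level3/version1/core"
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root("sbml", xmlns = core, "xmlns:fbc" = fbc,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model_id,
                             "fbc:strict" = "true")
  comps <- unique(model$compartment)
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cc in comps)
    xml2::xml_add_child(loc, "compartment", id = cc, constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_along(model$metabolite_ids))
    xml2::xml_add_child(los, "species", id = model$metabolite_ids[i],
                        compartment = model$compartment[i],
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  num <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)
  for (j in seq_along(model$reaction_ids)) {
    xml2::xml_add_child(lop, "parameter",
                        id = paste0("lb_", model$reaction_ids[j]),
                        value = num(model$lower_bounds[j]),
                        constant = "true")
    xml2::xml_add_child(lop, "parameter",
                        id = paste0("ub_", model$reaction_ids[j]),
                        value = num(model$upper_bounds[j]),
                        constant = "true")
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_along(model$reaction_ids)) {
    rid <- model$reaction_ids[j]
    rx <- xml2::xml_add_child(
      lor, "reaction", id = rid,
      reversible = if (model$reversible[j]) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", rid),
      "fbc:upperFluxBound" = paste0("ub_", rid))
    col <- model$stoichiometry[, j]
    neg <- which(col < 0); pos <- which(col > 0)
    if (length(neg)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in neg)
        xml2::xml_add_child(lr, "speciesReference",
                            species = model$metabolite_ids[i],
                            stoichiometry = num(-col[i]), constant = "true")
    }
    if (length(pos)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in pos)
        xml2::xml_add_child(lp, "speciesReference",
                            species = model$metabolite_ids[i],
                            stoichiometry = num(col[i]), constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a flux distribution to CSV or JSON
#'
#' CSV columns `reaction_id,flux`; JSON carries fluxes, objective value
#' and solver status.
#'
#' @param fd a `flux_distribution`.
#' @param path output path; format chosen by extension (`.json` or CSV).
#' @return `path`, invisibly.
#' @export
write_flux_distribution <- function(fd, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(status = fd$status,
                              objective_value = fd$objective_value,
                              fluxes = as.list(fd$fluxes)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(reaction_id = names(fd$fluxes),
                                flux = unname(fd$fluxes)),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
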