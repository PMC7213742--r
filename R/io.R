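# Model I/O: SBML Level 3 + flux-balance-constraints (fbc v2), and a flat
# JSON dialect. Both carry exactly the information the solver needs: ids,
# stoichiometry, explicit finite bounds, GPR rules, objective. SBML files
# without explicit flux-bound annotations are rejected — silently assuming
# default bounds changes simulation results.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
JSON_SCHEMA_VERSION <- 1L

#' Read a metabolic model from SBML or JSON
#'
#' @param path File path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (default: from the file
#'   extension, `.xml`/`.sbml` vs `.json`).
#' @return A validated `metabolic_model`.
#' @seealso [write_model()]
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  model <- switch(format,
    json = read_model_json(path),
    sbml = read_model_sbml(path)
  )
  validate_metabolic_model(model)
  model
}

#' Write a metabolic model to SBML or JSON
#'
#' Bounds, stoichiometric coefficients and objective weights are written at
#' full double precision so a write/read round trip reproduces the model
#' exactly.
#'
#' @param model A validated `metabolic_model`.
#' @param path Output file path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  validate_metabolic_model(model)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    json = write_model_json(model, path),
    sbml = write_model_sbml(model, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xml", "sbml")) return("sbml")
  if (ext == "json") return("json")
  stop("cannot infer model format from extension: ", path, call. = FALSE)
}

# --- JSON dialect --------------------------------------------------------

write_model_json <- function(model, path) {
  doc <- list(
    schema = "gemsemble-model",
    version = JSON_SCHEMA_VERSION,
    id = model$id,
    metabolites = purrr::pmap(
      model$metabolites[, c("id", "name", "compartment")], list),
    genes = purrr::map(model$genes$id, ~ list(id = .x)),
    reactions = purrr::map(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      list(id = r$id,
           stoichiometry = as.list(r$stoichiometry[[1]]),
           lower_bound = r$lower_bound,
           upper_bound = r$upper_bound,
           gene_rule = r$gene_rule)
    }),
    objective = as.list(model$objective)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (!identical(doc$schema, "gemsemble-model")) {
    stop("not a gemsemble model JSON file: ", path, call. = FALSE)
  }
  mets <- purrr::map_dfr(doc$metabolites, function(m)
    tibble::tibble(id = m$id, name = m$name %||% m$id,
                   compartment = m$compartment %||% "c"))
  genes <- tibble::tibble(
    id = purrr::map_chr(doc$genes %||% list(), "id"))
  rxns <- purrr::map_dfr(doc$reactions, function(r) {
    for (f in c("id", "lower_bound", "upper_bound")) {
      if (is.null(r[[f]])) {
        stop("reaction ", r$id %||% "<no id>", " missing field ", f,
             call. = FALSE)
      }
    }
    tibble::tibble(
      id = r$id,
      lower_bound = as.numeric(r$lower_bound),
      upper_bound = as.numeric(r$upper_bound),
      gene_rule = r$gene_rule %||% "",
      stoichiometry = list(unlist(r$stoichiometry)))
  })
  metabolic_model(id = doc$id %||% "model", metabolites = mets,
                  reactions = rxns, genes = genes,
                  objective = unlist(doc$objective) %||% numeric())
}

# --- SBML L3 + fbc -------------------------------------------------------

num_attr <- function(x) sprintf("%.17g", x)

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, `xmlns:fbc` = FBC_NS,
    level = "3", version = "1", `fbc:required` = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = sbml_id(model$id),
                               `fbc:strict` = "true")

  comps <- unique(model$metabolites$compartment)
  cnode <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cm in comps) {
    xml2::xml_add_child(cnode, "compartment", id = sbml_id(cm),
                        constant = "true")
  }

  snode <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(snode, "species", id = paste0("M_", sbml_id(m$id)),
                        name = m$name, compartment = sbml_id(m$compartment),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  # one shared parameter per distinct bound value
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  bid <- stats::setNames(sprintf("bnd_%d", seq_along(bounds) - 1L),
                         num_attr(bounds))
  pnode <- xml2::xml_add_child(mnode, "listOfParameters")
  for (k in seq_along(bounds)) {
    xml2::xml_add_child(pnode, "parameter", id = unname(bid[k]),
                        value = num_attr(bounds[k]), constant = "true",
                        `sboTerm` = "SBO:0000626")
  }

  if (nrow(model$genes)) {
    gnode <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in model$genes$id) {
      xml2::xml_add_child(gnode, "fbc:geneProduct",
                          `fbc:id` = paste0("G_", sbml_id(g)),
                          `fbc:label` = g)
    }
  }

  rnode <- xml2::xml_add_child(mnode, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rx <- xml2::xml_add_child(
      rnode, "reaction", id = paste0("R_", sbml_id(r$id)),
      reversible = tolower(as.character(r$lower_bound < 0)), fast = "false",
      `fbc:lowerFluxBound` = unname(bid[num_attr(r$lower_bound)]),
      `fbc:upperFluxBound` = unname(bid[num_attr(r$upper_bound)]))
    st <- r$stoichiometry[[1]]
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      ln <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(reac)) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = paste0("M_", sbml_id(m)),
                            stoichiometry = num_attr(-reac[[m]]),
                            constant = "true")
      }
    }
    if (length(prod)) {
      ln <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(prod)) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = paste0("M_", sbml_id(m)),
                            stoichiometry = num_attr(prod[[m]]),
                            constant = "true")
      }
    }
    if (nzchar(r$gene_rule)) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_gpr_xml(ga, parse_gene_rule(r$gene_rule))
    }
  }

  onode <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                               `fbc:activeObjective` = "obj")
  ob <- xml2::xml_add_child(onode, "fbc:objective", `fbc:id` = "obj",
                            `fbc:type` = "maximize")
  if (length(model$objective)) {
    fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (rid in names(model$objective)) {
      xml2::xml_add_child(fl, "fbc:fluxObjective",
                          `fbc:reaction` = paste0("R_", sbml_id(rid)),
                          `fbc:coefficient` = num_attr(model$objective[[rid]]))
    }
  }
  xml2::write_xml(doc, path)
}

add_gpr_xml <- function(parent, node) {
  if (node$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        `fbc:geneProduct` = paste0("G_", sbml_id(node$id)))
  } else {
    sub <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
    add_gpr_xml(sub, node$args[[1]])
    add_gpr_xml(sub, node$args[[2]])
  }
}

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mnode <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mnode, "xml_missing")) {
    stop("no <model> element in ", path, call. = FALSE)
  }

  params <- xml2::xml_find_all(mnode, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(mnode, ".//s:listOfSpecies/s:species", ns)
  mets <- tibble::tibble(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           strip_prefix(xml2::xml_attr(sp, "id"), "M_")),
    compartment = xml2::xml_attr(sp, "compartment"))

  gp <- xml2::xml_find_all(mnode, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                           ns)
  gid_by_sid <- if (length(gp) == 0L) {
    stats::setNames(character(), character())
  } else {
    stats::setNames(
      dplyr::coalesce(xml2::xml_attr(gp, "label"),
                      strip_prefix(xml2::xml_attr(gp, "id"), "G_")),
      xml2::xml_attr(gp, "id"))
  }

  rnodes <- xml2::xml_find_all(mnode, ".//s:listOfReactions/s:reaction", ns)
  rxns <- purrr::map_dfr(rnodes, function(rx) {
    rid_raw <- xml2::xml_attr(rx, "id")
    rid <- strip_prefix(rid_raw, "R_")
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref)) {
      stop("reaction ", rid, " lacks explicit flux-bound annotations ",
           "(fbc:lowerFluxBound/fbc:upperFluxBound); refusing to guess ",
           "default bounds", call. = FALSE)
    }
    if (!lb_ref %in% names(pvals) || !ub_ref %in% names(pvals)) {
      stop("reaction ", rid, " references undefined bound parameter",
           call. = FALSE)
    }
    reac <- xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      strip_prefix(xml2::xml_attr(reac, "species"), "M_")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      strip_prefix(xml2::xml_attr(prod, "species"), "M_")))
    ga <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation/*", ns)
    rule <- if (inherits(ga, "xml_missing")) "" else gpr_xml_to_rule(ga, gid_by_sid)
    tibble::tibble(id = rid, lower_bound = unname(pvals[lb_ref]),
                   upper_bound = unname(pvals[ub_ref]),
                   gene_rule = rule, stoichiometry = list(st))
  })

  fo <- xml2::xml_find_all(
    mnode, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- stats::setNames(
    as.numeric(xml2::xml_attr(fo, "coefficient")),
    strip_prefix(xml2::xml_attr(fo, "reaction"), "R_"))

  genes <- tibble::tibble(id = unique(unname(gid_by_sid)))
  metabolic_model(id = xml2::xml_attr(mnode, "id") %||% "model",
                  metabolites = mets, reactions = rxns, genes = genes,
                  objective = objective)
}

gpr_xml_to_rule <- function(node, gid_by_sid, top = TRUE) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    sid <- xml2::xml_attr(node, "geneProduct")
    gid <- unname(gid_by_sid[sid])
    return(if (is.na(gid)) strip_prefix(sid, "G_") else gid)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, gpr_xml_to_rule, character(1),
                  gid_by_sid = gid_by_sid, top = FALSE)
  body <- paste(parts, collapse = paste0(" ", nm, " "))
  if (top) body else paste0("(", body, ")")
}
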