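#' Read a metabolic model from JSON
#'
#' The JSON dialect is: `{"id", "metabolites":[{"id","name","compartment"}],
#' "reactions":[{"id","name","stoichiometry":{met:coef},"lower_bound",
#' "upper_bound","gpr","subsystem"}], "genes":[...], "objective": id,
#' "gam", "ngam"}`. Writing then reading reproduces an equal model.
#'
#' @param path File path.
#' @return A [MetabolicModel-class].
#' @seealso [writeModelJson()], [readModelSbml()]
#' @export
readModelJson <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (fld in c("id", "metabolites", "reactions", "objective"))
    if (is.null(doc[[fld]]))
      stop("model JSON is missing required field '", fld, "'")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite record without 'id'")
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "c" else m$compartment)
  }))
  rxn_rows <- list()
  sto <- list()
  for (r in doc$reactions) {
    if (is.null(r$id)) stop("reaction record without 'id'")
    rxn_rows[[length(rxn_rows) + 1L]] <- data.frame(
      id = r$id,
      name = if (is.null(r$name)) r$id else r$name,
      lower_bound = if (is.null(r$lower_bound)) 0 else as.numeric(r$lower_bound),
      upper_bound = if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound),
      gpr = if (is.null(r$gpr)) "" else r$gpr,
      subsystem = if (is.null(r$subsystem)) "" else r$subsystem
    )
    st <- unlist(r$stoichiometry)
    sto[[r$id]] <- if (is.null(st)) numeric() else st
  }
  rxns <- do.call(rbind, rxn_rows)
  model <- newMetabolicModel(
    id = doc$id, metabolites = mets, reactions = rxns, stoichiometry = sto,
    objective = doc$objective,
    gam = if (is.null(doc$gam)) 55.3 else doc$gam,
    ngam = if (is.null(doc$ngam)) 0.7 else doc$ngam
  )
  if (!is.null(doc$genes) &&
      !identical(sort(unlist(doc$genes)), model@genes))
    stop("model JSON gene list does not equal the union of GPR leaves")
  model
}

#' Write a metabolic model to JSON
#'
#' @param model A [MetabolicModel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeModelJson <- function(model, path) {
  sto <- reactionStoichiometry(model)
  doc <- list(
    id = jsonlite::unbox(model@id),
    metabolites = lapply(seq_len(nrow(model@metabolites)), function(i)
      lapply(as.list(model@metabolites[i, ]), jsonlite::unbox)),
    reactions = lapply(seq_len(nrow(model@reactions)), function(j) {
      r <- model@reactions[j, ]
      list(id = jsonlite::unbox(r$id), name = jsonlite::unbox(r$name),
           stoichiometry = lapply(as.list(sto[[r$id]]), jsonlite::unbox),
           lower_bound = jsonlite::unbox(r$lower_bound),
           upper_bound = jsonlite::unbox(r$upper_bound),
           gpr = jsonlite::unbox(r$gpr),
           subsystem = jsonlite::unbox(r$subsystem))
    }),
    genes = model@genes,
    objective = jsonlite::unbox(model@objective),
    gam = jsonlite::unbox(model@gam),
    ngam = jsonlite::unbox(model@ngam)
  )
  jsonlite::write_json(doc, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an SBML Level 3 + FBC model
#'
#' Minimal reader for the constraint-based subset: species, reactions
#' with stoichiometries, flux bounds resolved through FBC
#' `lowerFluxBound`/`upperFluxBound` parameters, gene-product
#' associations (fbc:and / fbc:or / fbc:geneProductRef) and the first
#' active FBC objective. Write support is not provided.
#'
#' @param path SBML file path.
#' @param gam,ngam Maintenance parameters to attach (not encoded in
#'   plain SBML FBC; defaults 55.3 and 0.7).
#' @return A [MetabolicModel-class].
#' @export
readModelSbml <- function(path, gam = 55.3, ngam = 0.7) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_attr(mdl, "id"))) model_id <- "sbml_model"
  else model_id <- xml2::xml_attr(mdl, "id")

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- data.frame(id = xml2::xml_attr(sp, "id"),
                     name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                                   xml2::xml_attr(sp, "id"),
                                   xml2::xml_attr(sp, "name")),
                     compartment = xml2::xml_attr(sp, "compartment"))
  mets <- mets[!boundary, , drop = FALSE]

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gplab <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")), xml2::xml_attr(gps, "id"),
           xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))

  assoc_to_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lab <- gplab[ref]
      return(if (is.na(lab)) ref else unname(lab))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_text, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxn_rows <- list(); sto <- list()
  met_ids <- mets$id
  for (node in rx) {
    rid <- xml2::xml_attr(node, "id")
    st <- numeric()
    for (sr in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      sid <- xml2::xml_attr(sr, "species")
      if (!sid %in% met_ids) next  # boundary species drop out
      st[sid] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      sid <- xml2::xml_attr(sr, "species")
      if (!sid %in% met_ids) next
      st[sid] <- as.numeric(xml2::xml_attr(sr, "stoichiometry")) +
        if (is.na(st[sid])) 0 else st[sid]
    }
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    rev <- xml2::xml_attr(node, "reversible") %in% "true"
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    ga <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(ga, "xml_missing")) ""
           else assoc_to_text(xml2::xml_child(ga))
    rxn_rows[[length(rxn_rows) + 1L]] <- data.frame(
      id = rid,
      name = ifelse(is.na(xml2::xml_attr(node, "name")), rid,
                    xml2::xml_attr(node, "name")),
      lower_bound = lb, upper_bound = ub, gpr = gpr, subsystem = "")
    sto[[rid]] <- st
  }
  obj <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(obj, "xml_missing"))
    stop("SBML model has no FBC objective")
  objective <- xml2::xml_attr(obj, "reaction")
  newMetabolicModel(id = model_id, metabolites = mets,
                    reactions = do.call(rbind, rxn_rows), stoichiometry = sto,
                    objective = objective, gam = gam, ngam = ngam)
}
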