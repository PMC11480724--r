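#' Read a metabolic model from file
#'
#' Supports two on-disk formats: the package's flat JSON dialect (written
#' by [write_model()], lossless round-trip) and SBML Level 3 with the
#' `fbc` flux-bounds extension (read-only, for externally published
#' genome-scale models).
#'
#' The JSON dialect is
#' \preformatted{
#' {"metabolites":[{"id":"ch4[e]","compartment":"e"}, ...],
#'  "reactions":[{"id":"BIO_M","stoich":{"ch4[e]":-40, ...},
#'                "lb":0,"ub":1000}, ...],
#'  "biomass_id":"BIO_M","maintenance_id":"ATPM",
#'  "gam":0,"ngam":0,"species":"M"}
#' }
#'
#' @param path file path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by file extension).
#' @param ... passed to the format-specific reader (e.g. `biomass_id`
#'   override for SBML files without an fbc objective).
#' @return a [stoich_model()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path, ...))
}

read_model_json <- function(path) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("parse error in '", path, "': ",
                                         conditionMessage(e)))
  for (f in c("metabolites", "reactions", "biomass_id", "maintenance_id"))
    if (is.null(j[[f]])) stop("parse error: missing element '", f, "'")
  mets <- data.frame(
    id = vapply(j$metabolites, function(x) x$id, ""),
    compartment = vapply(j$metabolites, function(x) x$compartment, ""),
    stringsAsFactors = FALSE)
  rxns <- vapply(j$reactions, function(x) x$id, "")
  S <- matrix(0, nrow(mets), length(rxns), dimnames = list(mets$id, rxns))
  for (r in j$reactions) {
    for (met in names(r$stoich)) {
      if (!met %in% mets$id)
        stop("parse error: reaction '", r$id,
             "' references undeclared metabolite '", met, "'")
      S[met, r$id] <- as.numeric(r$stoich[[met]])
    }
  }
  lb <- vapply(j$reactions, function(x) as.numeric(x$lb), 0)
  ub <- vapply(j$reactions, function(x) as.numeric(x$ub), 0)
  stoich_model(mets, rxns, S, lb, ub,
               biomass_id = j$biomass_id, maintenance_id = j$maintenance_id,
               gam = if (is.null(j$gam)) 0 else j$gam,
               ngam = if (is.null(j$ngam)) 0 else j$ngam,
               species = if (is.null(j$species)) "X" else j$species)
}

#' Write a model in the JSON dialect
#' @param m a [stoich_model()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model <- function(m, path) {
  rx <- lapply(seq_along(m$rxns), function(k) {
    nz <- which(m$S[, k] != 0)
    list(id = m$rxns[k],
         stoich = as.list(stats::setNames(m$S[nz, k], rownames(m$S)[nz])),
         lb = unname(m$lb[k]), ub = unname(m$ub[k]))
  })
  j <- list(
    metabolites = lapply(seq_len(nrow(m$mets)), function(i)
      list(id = m$mets$id[i], compartment = m$mets$compartment[i])),
    reactions = rx,
    biomass_id = m$biomass_id, maintenance_id = m$maintenance_id,
    gam = m$gam, ngam = m$ngam, species = m$species)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Minimal SBML Level 3 (+fbc) reader
#'
#' Parses species, reactions with stoichiometry, and flux bounds given
#' either as fbc `upperFluxBound`/`lowerFluxBound` parameter references or
#' as a legacy per-reaction `kineticLaw` with LOWER_BOUND/UPPER_BOUND local
#' parameters. The biomass reaction is taken from the active fbc objective
#' when present, else from `biomass_id`.
#'
#' @param path SBML file.
#' @param biomass_id,maintenance_id optional reaction-id overrides;
#'   `maintenance_id` defaults to the first reaction matching `ATPM` or
#'   `maintenance` (case-insensitive).
#' @param species species label.
#' @keywords internal
read_model_sbml <- function(path, biomass_id = NULL, maintenance_id = NULL,
                            species = "X") {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("parse error: no <species> elements found")
  sid <- xml2::xml_attr(sp, "id")
  scomp <- xml2::xml_attr(sp, "compartment")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  # global parameters (fbc bound values)
  par <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(par, "value")),
                            xml2::xml_attr(par, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("parse error: no <reaction> elements found")
  rid <- xml2::xml_attr(rx, "id")
  keep <- !boundary
  ids <- sid[keep]
  S <- matrix(0, length(ids), length(rx), dimnames = list(ids, rid))
  lb <- numeric(length(rx)); ub <- numeric(length(rx))
  for (k in seq_along(rx)) {
    r <- rx[[k]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(r, paste0("./s:", side, "/s:speciesReference"),
                                 ns)
      if (!length(refs)) next
      smet <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      for (i in seq_along(smet))
        if (smet[i] %in% ids) S[smet[i], k] <- S[smet[i], k] + st[i]
    }
    lbref <- xml2::xml_attr(r, "lowerFluxBound")
    ubref <- xml2::xml_attr(r, "upperFluxBound")
    if (!is.na(lbref) && lbref %in% names(parval)) {
      lb[k] <- parval[[lbref]]; ub[k] <- parval[[ubref]]
    } else {
      loc <- xml2::xml_find_all(
        r, ".//s:localParameter | .//s:parameter", ns)
      lid <- xml2::xml_attr(loc, "id")
      lval <- as.numeric(xml2::xml_attr(loc, "value"))
      lb[k] <- if ("LOWER_BOUND" %in% lid) lval[match("LOWER_BOUND", lid)] else
        if (xml2::xml_attr(r, "reversible") %in% "false") 0 else -1000
      ub[k] <- if ("UPPER_BOUND" %in% lid) lval[match("UPPER_BOUND", lid)] else 1000
    }
  }
  # fbc objective -> biomass
  if (is.null(biomass_id)) {
    ofl <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (!inherits(ofl, "xml_missing"))
      biomass_id <- xml2::xml_attr(ofl, "reaction")
  }
  if (is.null(biomass_id) || is.na(biomass_id))
    stop("validation error: no biomass reaction (no fbc objective; ",
         "pass biomass_id explicitly)")
  if (is.null(maintenance_id)) {
    hit <- grep("atpm|maintenance", rid, ignore.case = TRUE, value = TRUE)
    maintenance_id <- if (length(hit)) hit[1] else biomass_id
  }
  # normalise metabolite ids to the tagged convention id[compartment]
  tag <- paste0(ids, "[", scomp[keep], "]")
  has_tag <- grepl("\\[[A-Za-z0-9]+\\]$", ids)
  tag[has_tag] <- ids[has_tag]
  mets <- data.frame(id = tag, compartment = scomp[keep],
                     stringsAsFactors = FALSE)
  rownames(S) <- tag
  stoich_model(mets, rid, S, lb, ub, biomass_id = biomass_id,
               maintenance_id = maintenance_id, species = species)
}

#' Write / read a scenario as YAML
#' @param scenario a scenario from [make_scenario()].
#' @param path file path.
#' @return `write_scenario`: invisibly `path`; `read_scenario`: the
#'   scenario list.
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  x$init <- as.list(unclass(x$init))
  x$params <- lapply(unclass(x$params), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  if (!is.null(x$refeeds)) x$refeeds <- as.list(x$refeeds)
  x$dfba$kinetics <- as.list(as.data.frame(unclass(x$dfba$kinetics)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  x$params <- do.call(kinetic_params, lapply(x$params, function(v)
    if (is.list(v)) unlist(v) else v))
  x$init <- do.call(reactor_state, x$init)
  if (!is.null(x$refeeds)) x$refeeds <- as.data.frame(x$refeeds)
  x$dfba$kinetics <- uptake_kinetics(as.data.frame(x$dfba$kinetics))
  structure(x, class = "coflux_scenario")
}
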