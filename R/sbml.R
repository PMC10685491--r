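#' Read a metabolic model from SBML
#'
#' Parses SBML Level 3 with the FBC (flux balance constraints) extension:
#' species formulas/charges, reaction stoichiometry, and flux bounds resolved
#' from FBC bound parameters. The conventional `M_`/`R_` id prefixes are
#' stripped. The biomass reaction is taken from the active FBC objective when
#' present; a reaction named `ATPM` or `NGAM` is designated as the
#' maintenance reaction.
#'
#' @param path path to an SBML file.
#' @param biomass_id,ngam_id override the auto-detected designations.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path, biomass_id = NULL, ngam_id = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  model_node <- xml_find1(doc, "model")
  if (is.null(model_node)) stop("SBML parse error: no <model> element in ", path)

  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (length(sp) == 0) stop("SBML parse error: no <species> elements")
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    formula = fbc_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.numeric(fbc_attr(sp, "charge"))),
    compartment = xml2::xml_attr(sp, "compartment"))
  mets$charge[is.na(mets$charge)] <- 0

  pars <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (length(rx) == 0) stop("SBML parse error: no <reaction> elements")
  n <- length(rx)
  rids <- strip_prefix(xml2::xml_attr(rx, "id"), "R_")
  lb <- ub <- numeric(n)
  S <- Matrix::Matrix(0, nrow(mets), n, sparse = TRUE)
  rownames(S) <- mets$id
  for (k in seq_len(n)) {
    node <- rx[[k]]
    lbref <- fbc_attr(node, "lowerFluxBound")
    ubref <- fbc_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[k] <- if (!is.na(lbref) && lbref %in% names(parval)) parval[[lbref]]
             else if (rev) -1000 else 0
    ub[k] <- if (!is.na(ubref) && ubref %in% names(parval)) parval[[ubref]] else 1000
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        node, paste0("./*[local-name()='", side, "']/*[local-name()='speciesReference']"))
      if (length(refs) == 0) next
      sids <- strip_prefix(xml2::xml_attr(refs, "species"), "M_")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      if (side == "listOfReactants") coef <- -coef
      i <- match(sids, mets$id)
      if (anyNA(i)) stop("SBML parse error: reaction ", rids[k],
                         " references unknown species ",
                         paste(sids[is.na(i)], collapse = ", "))
      S[i, k] <- S[i, k] + coef
    }
  }

  if (is.null(biomass_id)) {
    fo <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
    if (length(fo) >= 1)
      biomass_id <- strip_prefix(fbc_attr(fo[[1]], "reaction"), "R_")
  }
  if (is.null(ngam_id)) {
    hit <- intersect(c("ATPM", "NGAM"), rids)
    if (length(hit)) ngam_id <- hit[[1]]
  }
  metabolic_model(id = xml2::xml_attr(model_node, "id") %||% "model",
                  mets = mets,
                  rxns = data.frame(id = rids, lb = lb, ub = ub),
                  S = S, biomass_id = biomass_id, ngam_id = ngam_id)
}

#' Write a metabolic model to SBML
#'
#' Emits SBML Level 3 Version 1 with FBC v2: species with formula/charge,
#' bound parameters, and an active maximization objective on the biomass
#' reaction when designated. Ids are prefixed `M_`/`R_` per the BiGG
#' convention so that the files round-trip through other SBML/FBC readers.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
  fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) vapply(x, function(v) formatC(v, digits = 15, format = "g"), "")

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            sbml_ns, fbc_ns),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>')
  for (cp in unique(model$mets$compartment))
    lines <- c(lines, sprintf('      <compartment id="%s" constant="true"/>', esc(cp)))
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    fml <- if (is.na(m$formula)) "" else
      sprintf(' fbc:chemicalFormula="%s"', esc(m$formula))
    lines <- c(lines, sprintf(
      '      <species id="M_%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" fbc:charge="%d"%s/>',
      esc(m$id), esc(m$compartment), as.integer(m$charge), fml))
  }
  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bid <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)), num(bounds))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (b in bounds)
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true" sboTerm="SBO:0000625"/>',
      bid[[num(b)]], num(b)))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (k in seq_len(nrow(model$rxns))) {
    r <- model$rxns[k, ]
    st <- model$S[, k]
    nzi <- which(st != 0)
    lines <- c(lines, sprintf(
      '      <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(r$id), if (r$lb < 0) "true" else "false",
      bid[[num(r$lb)]], bid[[num(r$ub)]]))
    for (side in c(-1, 1)) {
      idx <- nzi[sign(st[nzi]) == side]
      if (!length(idx)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, sprintf('        <%s>', tag))
      for (i in idx)
        lines <- c(lines, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          esc(model$mets$id[i]), num(abs(st[i]))))
      lines <- c(lines, sprintf('        </%s>', tag))
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (!is.null(model$biomass_id)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
              esc(model$biomass_id)),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

xml_find1 <- function(doc, name) {
  hit <- xml2::xml_find_all(doc, paste0(".//*[local-name()='", name, "']"))
  if (length(hit) == 0) NULL else hit[[1]]
}

fbc_attr <- function(node, name) {
  v <- xml2::xml_attr(node, paste0("fbc:", name))
  bad <- is.na(v)
  if (any(bad)) v[bad] <- xml2::xml_attr(node, name)[bad]
  v
}

strip_prefix <- function(x, prefix) {
  sub(paste0("^", prefix), "", x)
}
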