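# Model serialization: a COBRA-style JSON document (lossless) and SBML
# Level 3 (species/reactions/compartment in core; bounds, gene
# associations, objective weights and carbon bookkeeping carried in a
# package annotation namespace).

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.ANN_NS <- "https://example.org/starchfba/annotation"

#' Write a model to JSON or SBML
#'
#' JSON is the lossless interchange format (documented in the README);
#' SBML Level 3 uses one compartment and encodes bounds, gene ids, EC
#' numbers, objective weights and per-metabolite carbon counts as
#' annotations.
#'
#' @param model a `starch_model`.
#' @param path output file.
#' @param format `"json"` or `"sbml"`; default inferred from the
#'   extension (`.json` / `.xml` / `.sbml`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  format <- .model_format(path, format)
  if (format == "json") .write_model_json(model, path)
  else .write_model_sbml(model, path)
  invisible(path)
}

#' Read a model from JSON or SBML
#'
#' Inverse of [write_model()]: `write %>% read` is the identity on all
#' model fields for JSON, and on everything the annotation scheme carries
#' for SBML. The reconstructed model is re-validated.
#'
#' @param path input file.
#' @param format `"json"` or `"sbml"` (default from extension).
#' @return A `starch_model`.
#' @export
read_model <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- .model_format(path, format)
  model <- if (format == "json") .read_model_json(path)
           else .read_model_sbml(path)
  validate_starch_model(model)
  model
}

.model_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "sbml")))
  switch(tolower(tools::file_ext(path)),
         json = "json", sbml = "sbml", xml = "sbml",
         stop("cannot infer model format from extension of ", path))
}

.write_model_json <- function(model, path) {
  rx <- model$reactions
  doc <- list(
    format = "starchfba-model",
    version = 1L,
    metabolites = model$metabolites,
    reactions = lapply(seq_len(nrow(rx)), function(j) list(
      id = rx$id[j], name = rx$name[j], ec = rx$ec[j],
      metabolites = as.list(rx$stoichiometry[[j]]),
      lower_bound = rx$lower_bound[j], upper_bound = rx$upper_bound[j],
      default_lower = rx$default_lower[j], default_upper = rx$default_upper[j],
      reversible = rx$reversible[j], is_exchange = rx$is_exchange[j],
      gene_ids = rx$gene_ids[[j]]
    )),
    gene_table = model$gene_table,
    objective = as.list(model$objective),
    co2_upper = model$co2_upper
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

.read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed model JSON in ", path,
                                           ": ", conditionMessage(e)))
  need <- c("metabolites", "reactions", "gene_table", "objective")
  miss <- setdiff(need, names(doc))
  if (length(miss)) stop("model JSON ", path, " lacks element(s): ",
                         paste(miss, collapse = ", "))
  mets <- do.call(rbind, lapply(doc$metabolites, function(m)
    data.frame(id = m$id, name = m$name, carbons = m$carbons,
               currency = m$currency, compartment = m$compartment,
               stringsAsFactors = FALSE)))
  rx <- do.call(rbind, lapply(doc$reactions, function(r)
    data.frame(id = r$id, name = r$name, ec = r$ec,
               lower_bound = r$lower_bound, upper_bound = r$upper_bound,
               default_lower = r$default_lower,
               default_upper = r$default_upper,
               reversible = r$reversible, is_exchange = r$is_exchange,
               stringsAsFactors = FALSE)))
  rx$stoichiometry <- lapply(doc$reactions, function(r)
    unlist(lapply(r$metabolites, as.numeric)))
  rx$gene_ids <- lapply(doc$reactions, function(r)
    as.character(unlist(r$gene_ids)))
  gt <- do.call(rbind, lapply(doc$gene_table, function(g)
    data.frame(ec = g$ec, enzyme = g$enzyme, gene_name = g$gene_name,
               orf = g$orf, expression_available = g$expression_available,
               stringsAsFactors = FALSE)))
  structure(list(metabolites = mets, reactions = rx, gene_table = gt,
                 objective = unlist(lapply(doc$objective, as.numeric)),
                 co2_upper = as.numeric(doc$co2_upper)),
            class = "starch_model")
}

.sbml_id <- function(x, prefix) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", x))

.xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.write_model_sbml <- function(model, path) {
  mets <- model$metabolites
  rx <- model$reactions
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:sf="%s" level="3" version="1">',
            .SBML_NS, .ANN_NS),
    '  <model id="otauri_starch" name="O. tauri chloroplast starch metabolism">',
    '    <listOfCompartments>',
    '      <compartment id="chloroplast" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(mets))) {
    lines <- c(lines, sprintf(
      '      <species id="%s" name="%s" compartment="chloroplast" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false" sf:origId="%s" sf:carbons="%s" sf:currency="%s"/>',
      .sbml_id(mets$id[i], "M_"), .xml_esc(mets$name[i]), mets$id[i],
      num(mets$carbons[i]), tolower(mets$currency[i])))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfReactions>')
  for (j in seq_len(nrow(rx))) {
    st <- rx$stoichiometry[[j]]
    reac <- st[st < 0]; prod <- st[st > 0]
    w <- if (rx$id[j] %in% names(model$objective))
      model$objective[[rx$id[j]]] else 0
    lines <- c(lines, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false" sf:origId="%s" sf:lowerBound="%s" sf:upperBound="%s" sf:defaultLower="%s" sf:defaultUpper="%s" sf:exchange="%s" sf:ec="%s" sf:genes="%s" sf:objectiveWeight="%s">',
      .sbml_id(rx$id[j], "R_"), .xml_esc(rx$name[j]),
      tolower(rx$reversible[j]), rx$id[j],
      num(rx$lower_bound[j]), num(rx$upper_bound[j]),
      num(rx$default_lower[j]), num(rx$default_upper[j]),
      tolower(rx$is_exchange[j]), rx$ec[j],
      paste(rx$gene_ids[[j]], collapse = " "), num(w)))
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>')
      for (mid in names(reac)) lines <- c(lines, sprintf(
        '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        .sbml_id(mid, "M_"), num(-reac[[mid]])))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>')
      for (mid in names(prod)) lines <- c(lines, sprintf(
        '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        .sbml_id(mid, "M_"), num(prod[[mid]])))
      lines <- c(lines, '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  gt <- model$gene_table
  lines <- c(lines, '    </listOfReactions>', '    <annotation>',
             sprintf('      <sf:geneTable xmlns:sf="%s">', .ANN_NS))
  for (i in seq_len(nrow(gt))) lines <- c(lines, sprintf(
    '        <sf:gene orf="%s" ec="%s" enzyme="%s" geneName="%s" expressionAvailable="%s"/>',
    gt$orf[i], gt$ec[i], .xml_esc(gt$enzyme[i]), .xml_esc(gt$gene_name[i]),
    tolower(gt$expression_available[i])))
  lines <- c(lines,
             sprintf('        <sf:co2Upper value="%s"/>', num(model$co2_upper)),
             '      </sf:geneTable>', '    </annotation>',
             '  </model>', '</sbml>')
  writeLines(lines, path)
  # parse once so malformed output can never be shipped silently
  invisible(xml2::read_xml(path))
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in ", path, ": ",
                                           conditionMessage(e)))
  ns <- c(s = .SBML_NS, sf = .ANN_NS)
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  if (!length(sp)) stop("no species found in ", path)
  att <- function(nodes, a) xml2::xml_attr(nodes, a)
  mets <- data.frame(
    id = att(sp, "origId"), name = att(sp, "name"),
    carbons = as.numeric(att(sp, "carbons")),
    currency = att(sp, "currency") == "true",
    compartment = att(sp, "compartment"), stringsAsFactors = FALSE)
  rns <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  if (!length(rns)) stop("no reactions found in ", path)
  sp_map <- stats::setNames(mets$id, .sbml_id(mets$id, "M_"))
  parse_rx <- function(node) {
    refs <- function(xp, sgn) {
      rr <- xml2::xml_find_all(node, xp, ns)
      if (!length(rr)) return(numeric(0))
      stats::setNames(sgn * as.numeric(xml2::xml_attr(rr, "stoichiometry")),
                      sp_map[xml2::xml_attr(rr, "species")])
    }
    st0 <- refs(".//s:listOfReactants/s:speciesReference", -1)
    st1 <- refs(".//s:listOfProducts/s:speciesReference", +1)
    st <- st0
    for (id in names(st1)) st[id] <- (if (id %in% names(st)) st[id] else 0) + st1[id]
    g <- xml2::xml_attr(node, "genes")
    list(id = xml2::xml_attr(node, "origId"),
         name = xml2::xml_attr(node, "name"),
         ec = xml2::xml_attr(node, "ec"),
         lower = as.numeric(xml2::xml_attr(node, "lowerBound")),
         upper = as.numeric(xml2::xml_attr(node, "upperBound")),
         dlower = as.numeric(xml2::xml_attr(node, "defaultLower")),
         dupper = as.numeric(xml2::xml_attr(node, "defaultUpper")),
         reversible = xml2::xml_attr(node, "reversible") == "true",
         exchange = xml2::xml_attr(node, "exchange") == "true",
         w = as.numeric(xml2::xml_attr(node, "objectiveWeight")),
         genes = if (is.na(g) || !nzchar(g)) character(0)
                 else strsplit(g, " ", fixed = TRUE)[[1]],
         st = st)
  }
  pr <- lapply(rns, parse_rx)
  rx <- data.frame(
    id = vapply(pr, `[[`, "", "id"), name = vapply(pr, `[[`, "", "name"),
    ec = vapply(pr, `[[`, "", "ec"),
    lower_bound = vapply(pr, `[[`, 0, "lower"),
    upper_bound = vapply(pr, `[[`, 0, "upper"),
    default_lower = vapply(pr, `[[`, 0, "dlower"),
    default_upper = vapply(pr, `[[`, 0, "dupper"),
    reversible = vapply(pr, `[[`, TRUE, "reversible"),
    is_exchange = vapply(pr, `[[`, TRUE, "exchange"),
    stringsAsFactors = FALSE)
  rx$stoichiometry <- lapply(pr, `[[`, "st")
  rx$gene_ids <- lapply(pr, `[[`, "genes")
  wts <- vapply(pr, `[[`, 0, "w")
  objective <- stats::setNames(wts[wts != 0], rx$id[wts != 0])
  gn <- xml2::xml_find_all(doc, ".//sf:geneTable/sf:gene", ns)
  gt <- data.frame(
    ec = att(gn, "ec"), enzyme = att(gn, "enzyme"),
    gene_name = att(gn, "geneName"), orf = att(gn, "orf"),
    expression_available = att(gn, "expressionAvailable") == "true",
    stringsAsFactors = FALSE)
  co2 <- xml2::xml_find_first(doc, ".//sf:co2Upper", ns)
  structure(list(metabolites = mets, reactions = rx, gene_table = gt,
                 objective = objective,
                 co2_upper = as.numeric(xml2::xml_attr(co2, "value"))),
            class = "starch_model")
}
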