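# Readers and writers for standard model formats (SBML Level 3 + FBC,
# COBRA JSON) and for PM matrices (TSV).

#' Read a metabolic network from SBML or COBRA JSON
#'
#' Ids are clipped of the conventional `M_`/`R_`/`G_` prefixes used in SBML
#' encodings.  Missing flux bounds default to `[-1000, 1000]` for reversible
#' and `[0, 1000]` for irreversible reactions.  Gene associations are
#' collected as the set of reactions each gene appears in (isoenzyme
#' structure is not interpreted beyond membership).
#'
#' @param path file path (`.xml`, `.sbml`, `.json`; `.gz`-compressed SBML is
#'   accepted).
#' @param format `"sbml"` or `"cobra_json"`; guessed from the extension when
#'   omitted.
#' @return a [metabolic_network()].
#' @export
read_network <- function(path, format = c("auto", "sbml", "cobra_json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "cobra_json" else "sbml"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         sbml = read_sbml(path),
         cobra_json = read_cobra_json(path))
}

#' Write a metabolic network to SBML or COBRA JSON
#'
#' @param net a [metabolic_network()].
#' @param path output file path.
#' @param format `"sbml"` or `"cobra_json"`; guessed from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "sbml", "cobra_json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "cobra_json" else "sbml"
  }
  net <- validate_metnet(net)
  switch(format,
         sbml = write_sbml(net, path),
         cobra_json = write_cobra_json(net, path))
  invisible(path)
}

clip_prefix <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

read_cobra_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("not a COBRA JSON model (missing 'metabolites' or 'reactions'): ", path)
  }
  mets <- tibble::tibble(
    id = vapply(doc$metabolites, function(x) x$id, character(1)),
    name = vapply(doc$metabolites, function(x) x$name %||% x$id, character(1)),
    compartment = vapply(doc$metabolites, function(x) x$compartment %||% "", character(1))
  )
  stoich <- lapply(doc$reactions, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s) || !length(s)) {
      stop("reaction '", r$id, "' has no metabolites")
    }
    s
  })
  rx <- tibble::tibble(
    id = vapply(doc$reactions, function(r) r$id, character(1)),
    name = vapply(doc$reactions, function(r) r$name %||% r$id, character(1)),
    stoich = stoich,
    lb = vapply(doc$reactions, function(r) r$lower_bound %||% -1000, numeric(1)),
    ub = vapply(doc$reactions, function(r) r$upper_bound %||% 1000, numeric(1))
  )
  genes <- list()
  for (k in seq_along(doc$reactions)) {
    rule <- doc$reactions[[k]]$gene_reaction_rule %||% ""
    for (g in gene_rule_ids(rule)) {
      genes[[g]] <- union(genes[[g]], rx$id[k])
    }
  }
  metabolic_network(mets, rx, genes,
                    id = doc$id %||% sub("\\.json$", "", basename(path)))
}

gene_rule_ids <- function(rule) {
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  setdiff(toks[nzchar(toks)], c("and", "or", "AND", "OR"))
}

write_cobra_json <- function(net, path) {
  rules <- rep("", nrow(net$reactions))
  if (length(net$genes)) {
    for (g in names(net$genes)) {
      idx <- match(net$genes[[g]], net$reactions$id)
      for (i in idx) rules[i] <- if (nzchar(rules[i])) paste(rules[i], "or", g) else g
    }
  }
  reactions <- lapply(seq_len(nrow(net$reactions)), function(j) {
    st <- reaction_stoich(net, net$reactions$id[j])
    list(id = net$reactions$id[j], name = net$reactions$name[j],
         metabolites = as.list(st),
         lower_bound = net$reactions$lb[j], upper_bound = net$reactions$ub[j],
         gene_reaction_rule = rules[j])
  })
  metabolites <- lapply(seq_len(nrow(net$metabolites)), function(i) {
    comp <- net$metabolites$compartment[i]
    list(id = net$metabolites$id[i], name = net$metabolites$name[i],
         compartment = if (nzchar(comp)) comp else "c")
  })
  genes <- lapply(names(net$genes), function(g) list(id = g, name = g))
  jsonlite::write_json(
    list(id = net$id, metabolites = metabolites, reactions = reactions,
         genes = genes, version = "1"),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_sbml <- function(path) {
  txt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, open = "rb")
    on.exit(close(con))
    rawToChar(readBin(con, "raw", n = 64 * 1024^2))
  } else {
    path
  }
  doc <- tryCatch(xml2::read_xml(txt), error = function(e) {
    stop("SBML parse failure in '", path, "': ", conditionMessage(e))
  })
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model, "xml_missing")) {
    stop("SBML parse failure: no <model> element in ", path)
  }

  sp <- xml2::xml_find_all(model, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp)) stop("SBML parse failure: no species in ", path)
  mets <- tibble::tibble(
    id = clip_prefix(xml2::xml_attr(sp, "id"), "M"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"), clip_prefix(xml2::xml_attr(sp, "id"), "M")),
    compartment = dplyr::coalesce(xml2::xml_attr(sp, "compartment"), "")
  )

  pars <- xml2::xml_find_all(model, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rxn_nodes <- xml2::xml_find_all(model, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rxn_nodes)) stop("SBML parse failure: no reactions in ", path)
  n <- length(rxn_nodes)
  ids <- clip_prefix(xml2::xml_attr(rxn_nodes, "id"), "R")
  nms <- dplyr::coalesce(xml2::xml_attr(rxn_nodes, "name"), ids)
  rev <- xml2::xml_attr(rxn_nodes, "reversible") %in% c("true", "1")
  lb_ref <- xml2::xml_attr(rxn_nodes, "lowerFluxBound")
  ub_ref <- xml2::xml_attr(rxn_nodes, "upperFluxBound")
  lb <- ifelse(!is.na(lb_ref) & lb_ref %in% names(parval), parval[lb_ref],
               ifelse(rev, -1000, 0))
  ub <- ifelse(!is.na(ub_ref) & ub_ref %in% names(parval), parval[ub_ref], 1000)

  stoich <- vector("list", n)
  genes <- list()
  for (j in seq_len(n)) {
    node <- rxn_nodes[[j]]
    rs <- xml2::xml_find_all(node, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    ps <- xml2::xml_find_all(node, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    sid <- c(clip_prefix(xml2::xml_attr(rs, "species"), "M"),
             clip_prefix(xml2::xml_attr(ps, "species"), "M"))
    coef <- c(-as_stoich(xml2::xml_attr(rs, "stoichiometry")),
              as_stoich(xml2::xml_attr(ps, "stoichiometry")))
    if (!length(sid)) stop("SBML parse failure: reaction '", ids[j], "' has no participants")
    st <- tapply(coef, sid, sum) # merge duplicate species references
    st <- st[st != 0]
    stoich[[j]] <- stats::setNames(as.numeric(st), names(st))
    gp <- xml2::xml_find_all(node, ".//*[local-name()='geneProductRef']")
    if (length(gp)) {
      gids <- clip_prefix(xml2::xml_attr(gp, "geneProduct"), "G")
      for (g in unique(gids)) genes[[g]] <- union(genes[[g]], ids[j])
    }
  }
  rx <- tibble::tibble(id = ids, name = nms, stoich = stoich, lb = lb, ub = ub)
  mid <- xml2::xml_attr(model, "id")
  metabolic_network(mets, rx, genes,
                    id = if (is.na(mid)) sub("\\.(xml|sbml)(\\.gz)?$", "", basename(path)) else mid)
}

as_stoich <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[is.na(out)] <- 1
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_sbml <- function(net, path) {
  comp <- unique(net$metabolites$compartment)
  comp[!nzchar(comp)] <- "c"
  comp <- unique(comp)
  bounds <- sort(unique(c(net$reactions$lb, net$reactions$ub)))
  bid <- stats::setNames(paste0("pm_bound_", seq_along(bounds)), format(bounds, digits = 15))
  bound_id <- function(v) unname(bid[format(v, digits = 15)])

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', xml_escape(net$id), '" fbc:strict="true">'),
    "    <listOfCompartments>",
    paste0('      <compartment id="', xml_escape(comp), '" constant="true"/>'),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  mc <- net$metabolites$compartment
  mc[!nzchar(mc)] <- "c"
  out <- c(out, paste0(
    '      <species id="M_', xml_escape(net$metabolites$id),
    '" name="', xml_escape(net$metabolites$name),
    '" compartment="', xml_escape(mc),
    '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>'))
  out <- c(out, "    </listOfSpecies>", "    <listOfParameters>",
           paste0('      <parameter id="', bid, '" value="',
                  format(bounds, digits = 15), '" constant="true"/>'),
           "    </listOfParameters>", "    <listOfReactions>")
  for (j in seq_len(nrow(net$reactions))) {
    st <- reaction_stoich(net, net$reactions$id[j])
    subs <- st[st < 0]; prods <- st[st > 0]
    out <- c(out, paste0(
      '      <reaction id="R_', xml_escape(net$reactions$id[j]),
      '" name="', xml_escape(net$reactions$name[j]),
      '" reversible="', tolower(net$reactions$lb[j] < 0),
      '" fast="false" fbc:lowerFluxBound="', bound_id(net$reactions$lb[j]),
      '" fbc:upperFluxBound="', bound_id(net$reactions$ub[j]), '">'))
    if (length(subs)) {
      out <- c(out, "        <listOfReactants>",
               paste0('          <speciesReference species="M_', xml_escape(names(subs)),
                      '" stoichiometry="', format(-unname(subs), digits = 15),
                      '" constant="true"/>'),
               "        </listOfReactants>")
    }
    if (length(prods)) {
      out <- c(out, "        <listOfProducts>",
               paste0('          <speciesReference species="M_', xml_escape(names(prods)),
                      '" stoichiometry="', format(unname(prods), digits = 15),
                      '" constant="true"/>'),
               "        </listOfProducts>")
    }
    gs <- names(net$genes)[vapply(net$genes, function(rr) net$reactions$id[j] %in% rr, logical(1))]
    if (length(gs)) {
      out <- c(out, "        <fbc:geneProductAssociation>", "          <fbc:or>",
               paste0('            <fbc:geneProductRef fbc:geneProduct="G_', xml_escape(gs), '"/>'),
               "          </fbc:or>", "        </fbc:geneProductAssociation>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>")
  if (length(net$genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
             paste0('      <fbc:geneProduct fbc:id="G_', xml_escape(names(net$genes)),
                    '" fbc:label="', xml_escape(names(net$genes)), '"/>'),
             "    </fbc:listOfGeneProducts>")
  }
  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path)
}

#' Write / read a PM matrix as TSV
#'
#' Organisms are rows, metabolites columns; the first column holds organism
#' ids.  Values round-trip exactly (full double precision).
#'
#' @param m a matrix as returned by [pm_matrix()].
#' @param path TSV file path.
#' @return `write_pm_matrix` returns `path` invisibly; `read_pm_matrix`
#'   returns the matrix (class `pm_matrix`).
#' @export
write_pm_matrix <- function(m, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(m)), rownames = "organism")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_pm_matrix
#' @export
read_pm_matrix <- function(path) {
  df <- suppressWarnings(readr::read_tsv(path, show_col_types = FALSE,
                                         progress = FALSE, name_repair = "minimal"))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop("malformed PM matrix TSV (", nrow(probs), " parsing problem(s)) in ", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  class(m) <- c("pm_matrix", class(m))
  m
}
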