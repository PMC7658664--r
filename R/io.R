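SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from file
#'
#' Supports SBML Level 3 Version 1 (with fbc-style flux-bound parameters and
#' COBRA-convention \code{GENE_ASSOCIATION} notes) and the package's
#' tab-separated reaction-table dialect (see \code{\link{write_model}}).
#'
#' @param path file path.
#' @param format \code{"sbml"} or \code{"table"}.
#' @return a validated \code{\link{metabolic_model}}. Reactions without
#'   declared bounds get the conventional defaults of -1000/1000 (0 lower
#'   bound if declared irreversible).
#' @export
read_model <- function(path, format = c("sbml", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format, sbml = read_sbml(path), table = read_table_model(path))
}

#' Write a metabolic model to file
#'
#' The SBML writer emits Level 3 Version 1 with compartments, species
#' (including chemical formula and charge), reactions with flux bounds as
#' global parameters, gene associations as COBRA-style notes, and the model
#' objective. The table writer emits one tab-separated row per reaction with
#' arrow-syntax equations (\code{"->"} irreversible, \code{"<=>"} reversible)
#' and \code{#!} directive lines carrying model id, compartments and
#' metabolite formulas so that \code{read_model} round-trips the model.
#'
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @param format \code{"sbml"} or \code{"table"}.
#' @return invisibly \code{path}.
#' @export
write_model <- function(model, path, format = c("sbml", "table")) {
  format <- match.arg(format)
  validate_model(model)
  switch(format, sbml = write_sbml(model, path),
         table = write_table_model(model, path))
  invisible(path)
}

## ---- SBML ----

write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "false")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in names(model$compartments)) {
    xml2::xml_add_child(lc, "compartment", id = cid,
                        name = model$compartments[[cid]], constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    met <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = met$id, name = met$name,
                              compartment = met$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(met$formula) && nzchar(met$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula)
    }
    if (!is.na(met$charge)) {
      xml2::xml_set_attr(sp, "fbc:charge", as.character(met$charge))
    }
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    xml2::xml_add_child(lp, "parameter", id = paste0(r$id, "_lower"),
                        value = format(r$lb, digits = 17), constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0(r$id, "_upper"),
                        value = format(r$ub, digits = 17), constant = "true")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rn <- xml2::xml_add_child(lr, "reaction", id = r$id, name = r$name,
                              reversible = tolower(as.character(r$lb < 0)),
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0(r$id, "_lower"),
                              "fbc:upperFluxBound" = paste0(r$id, "_upper"))
    notes <- character(0)
    if (nzchar(r$genes)) notes <- c(notes, paste0("GENE_ASSOCIATION: ", r$genes))
    if (r$is_biomass) notes <- c(notes, "BIOMASS: true")
    if (r$is_exchange) notes <- c(notes, "EXCHANGE: true")
    if (length(notes)) {
      nd <- xml2::xml_add_child(rn, "notes")
      bd <- xml2::xml_add_child(nd, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
      for (p in notes) xml2::xml_add_child(bd, "p", p)
    }
    s <- model$stoich[[r$id]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (k in seq_along(reac)) {
        xml2::xml_add_child(lre, "speciesReference", species = names(reac)[k],
                            stoichiometry = format(-unname(reac[k]),
                                                   digits = 17),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (k in seq_along(prod)) {
        xml2::xml_add_child(lpr, "speciesReference", species = names(prod)[k],
                            stoichiometry = format(unname(prod[k]),
                                                   digits = 17),
                            constant = "true")
      }
    }
  }
  if (!is.na(model$objective$reaction)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = paste0(model$objective$direction,
                                                  "imize"))
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = model$objective$reaction,
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
}

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) {
    stop("SBML parse error in '", path, "': no <model> element", call. = FALSE)
  }
  mid <- xml2::xml_attr(mdl, "id")
  comp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment",
                                   ns)
  compartments <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
           xml2::xml_attr(comp_nodes, "id"),
           xml2::xml_attr(comp_nodes, "name")),
    xml2::xml_attr(comp_nodes, "id"))
  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  metabolites <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), xml2::xml_attr(sp, "id"),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns),
    charge = suppressWarnings(as.integer(
      xml2::xml_attr(sp, "fbc:charge", ns = ns))),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rnodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rid <- xml2::xml_attr(rnodes, "id")
  stoich <- vector("list", length(rnodes))
  rows <- vector("list", length(rnodes))
  for (i in seq_along(rnodes)) {
    rn <- rnodes[[i]]
    reac <- xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)
    s <- c(stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                           xml2::xml_attr(reac, "species")),
           stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                           xml2::xml_attr(prod, "species")))
    ## merge duplicate species references
    if (anyDuplicated(names(s))) s <- tapply(s, names(s), sum)
    stoich[[i]] <- s
    lbp <- xml2::xml_attr(rn, "fbc:lowerFluxBound", ns = ns)
    ubp <- xml2::xml_attr(rn, "fbc:upperFluxBound", ns = ns)
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else
      if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    notes <- xml2::xml_text(xml2::xml_find_all(
      rn, "./s:notes//*[local-name()='p']", ns))
    ga <- grep("^GENE_ASSOCIATION:", notes, value = TRUE)
    genes <- if (length(ga)) trimws(sub("^GENE_ASSOCIATION:", "", ga[1])) else ""
    rows[[i]] <- data.frame(
      id = rid[i],
      name = ifelse(is.na(xml2::xml_attr(rn, "name")), rid[i],
                    xml2::xml_attr(rn, "name")),
      lb = lb, ub = ub, genes = genes,
      is_exchange = any(grepl("^EXCHANGE: true", notes)),
      is_biomass = any(grepl("^BIOMASS: true", notes)),
      stringsAsFactors = FALSE)
  }
  reactions <- do.call(rbind, rows)
  names(stoich) <- rid
  obj <- list(reaction = NA_character_, direction = "max")
  fo <- xml2::xml_find_first(mdl, ".//fbc:fluxObjective", ns)
  if (!inherits(fo, "xml_missing")) {
    obj$reaction <- xml2::xml_attr(fo, "fbc:reaction", ns = ns)
    typ <- xml2::xml_attr(xml2::xml_find_first(mdl, ".//fbc:objective", ns),
                          "fbc:type", ns = ns)
    if (identical(typ, "minimize")) obj$direction <- "min"
  }
  ## infer exchange flags if the file carried no notes
  if (!any(reactions$is_exchange)) {
    comp_of <- stats::setNames(metabolites$compartment, metabolites$id)
    reactions$is_exchange <- vapply(seq_len(nrow(reactions)), function(i) {
      s <- stoich[[i]]
      length(s) == 1 && identical(unname(comp_of[names(s)]), "e")
    }, logical(1))
  }
  metabolic_model(mid, compartments, metabolites, reactions, stoich, obj)
}

## ---- tab-separated reaction tables ----

format_equation <- function(s, reversible) {
  side <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(abs(v) == 1, names(v),
                 paste(format(abs(v), digits = 10), names(v))),
          collapse = " + ")
  }
  arrow <- if (reversible) "<=>" else "->"
  paste(side(s[s < 0]), arrow, side(s[s > 0]))
}

parse_equation <- function(eq) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else
    if (grepl("->", eq, fixed = TRUE)) "->" else
      stop("equation without arrow ('->' or '<=>'): ", eq, call. = FALSE)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  sides <- c(sides, rep("", 2 - length(sides)))
  term <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(stats::setNames(numeric(0), character(0)))
    toks <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tk in toks) {
      p <- strsplit(tk, "\\s+")[[1]]
      if (length(p) == 2) {
        out[p[2]] <- sign * as.numeric(p[1])
      } else if (length(p) == 1) {
        out[p[1]] <- sign * 1
      } else stop("cannot parse term: '", tk, "'", call. = FALSE)
    }
    out
  }
  lhs <- term(sides[1], -1)
  rhs <- term(sides[2], 1)
  s <- c(lhs, rhs)
  if (anyDuplicated(names(s))) s <- tapply(s, names(s), sum)
  list(stoich = s, reversible = arrow == "<=>")
}

write_table_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#! model\t", model$id), con)
  for (cid in names(model$compartments)) {
    writeLines(paste0("#! compartment\t", cid, "\t",
                      model$compartments[[cid]]), con)
  }
  for (i in seq_len(nrow(model$metabolites))) {
    met <- model$metabolites[i, ]
    writeLines(paste0("#! metabolite\t", met$id, "\t", met$compartment, "\t",
                      ifelse(is.na(met$formula), "", met$formula), "\t",
                      ifelse(is.na(met$charge), "", met$charge), "\t",
                      met$name), con)
  }
  if (!is.na(model$objective$reaction)) {
    writeLines(paste0("#! objective\t", model$objective$reaction, "\t",
                      model$objective$direction), con)
  }
  writeLines("id\tname\tequation\tlb\tub\tgenes\tbiomass\texchange", con)
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    eq <- format_equation(model$stoich[[r$id]], r$lb < 0)
    writeLines(paste(r$id, r$name, eq,
                     format(r$lb, digits = 17), format(r$ub, digits = 17),
                     r$genes, as.integer(r$is_biomass),
                     as.integer(r$is_exchange), sep = "\t"), con)
  }
}

read_table_model <- function(path) {
  lines <- readLines(path)
  dirs <- grep("^#!", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  mid <- "model"
  compartments <- character(0)
  met_rows <- list()
  obj <- list(reaction = NA_character_, direction = "max")
  for (d in dirs) {
    f <- strsplit(sub("^#!\\s*", "", d), "\t", fixed = TRUE)[[1]]
    if (f[1] == "model") mid <- f[2]
    if (f[1] == "compartment") compartments[f[2]] <- f[3]
    if (f[1] == "metabolite") {
      met_rows[[length(met_rows) + 1]] <- data.frame(
        id = f[2], compartment = f[3],
        formula = ifelse(length(f) >= 4 && nzchar(f[4]), f[4], NA_character_),
        charge = ifelse(length(f) >= 5 && nzchar(f[5]),
                        as.integer(f[5]), NA_integer_),
        name = ifelse(length(f) >= 6, f[6], f[2]), stringsAsFactors = FALSE)
    }
    if (f[1] == "objective") obj <- list(reaction = f[2], direction = f[3])
  }
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  need <- c("id", "equation")
  if (!all(need %in% header)) {
    stop("table parse error in '", path, "' (line ",
         which(lines == body[1]), "): header must contain ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  rows <- list(); stoich <- list()
  for (ln in body[-1]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    rec <- stats::setNames(as.list(f), header[seq_along(f)])
    pe <- parse_equation(rec$equation)
    lb <- if (!is.null(rec$lb) && nzchar(rec$lb)) as.numeric(rec$lb) else
      if (pe$reversible) -1000 else 0
    ub <- if (!is.null(rec$ub) && nzchar(rec$ub)) as.numeric(rec$ub) else 1000
    rows[[length(rows) + 1]] <- data.frame(
      id = rec$id, name = ifelse(is.null(rec$name), rec$id, rec$name),
      lb = lb, ub = ub,
      genes = ifelse(is.null(rec$genes), "", rec$genes),
      is_biomass = !is.null(rec$biomass) && rec$biomass == "1",
      is_exchange = !is.null(rec$exchange) && rec$exchange == "1",
      stringsAsFactors = FALSE)
    stoich[[rec$id]] <- pe$stoich
  }
  reactions <- do.call(rbind, rows)
  ## metabolites not declared via directives: infer compartment from suffix
  seen <- unique(unlist(lapply(stoich, names)))
  declared <- vapply(met_rows, function(x) x$id, character(1))
  for (mid2 in setdiff(seen, declared)) {
    comp <- sub("^.*_", "", mid2)
    compartments[comp] <- if (is.na(compartments[comp])) comp else
      compartments[comp]
    if (!nzchar(comp) || comp == mid2) comp <- "e"
    met_rows[[length(met_rows) + 1]] <- data.frame(
      id = mid2, compartment = comp, formula = NA_character_,
      charge = NA_integer_, name = mid2, stringsAsFactors = FALSE)
  }
  metabolites <- do.call(rbind, met_rows)
  compartments[is.na(compartments)] <- names(compartments)[is.na(compartments)]
  if (!any(reactions$is_exchange)) {
    comp_of <- stats::setNames(metabolites$compartment, metabolites$id)
    reactions$is_exchange <- vapply(reactions$id, function(r) {
      s <- stoich[[r]]
      length(s) == 1 && identical(unname(comp_of[names(s)]), "e")
    }, logical(1))
  }
  metabolic_model(mid, compartments,
                  metabolites[, c("id", "name", "compartment", "formula",
                                  "charge")],
                  reactions, stoich, obj)
}
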