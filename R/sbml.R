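#' SBML-qual input and output
#'
#' Reads and writes logical models in the SBML Level 3 `qual` package, the
#' exchange format used by model repositories for Boolean signaling models.
#' Only Boolean (two-level) qualitative species are supported. Transition
#' function terms may use `and`, `or`, `not` and equality comparisons of a
#' species to 0 or 1; they are normalized to sum-of-products by negation
#' push-down and distributive expansion.
#'
#' @name sbml_qual
NULL

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Write a Boolean network as SBML-qual
#'
#' @param network a [boolean_network()].
#' @param path file path or connection to write to.
#' @return Invisibly, the path.
#' @rdname sbml_qual
#' @export
write_sbml_qual <- function(network, path) {
  stopifnot(inherits(network, "boolean_network"))
  if (!length(network$nodes)) stop("cannot serialize a network with no nodes")
  bad <- validate_network(network)
  if (length(bad)) stop("invalid network: ", bad[1])

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:qual="%s" level="3" version="1" ',
                   'qual:required="true">'), SBML_NS, QUAL_NS),
    '  <model id="boolean_model">',
    '    <qual:listOfQualitativeSpecies>'
  )
  for (nm in network$nodes) {
    constant <- if (nm %in% network$inputs) "true" else "false"
    out <- c(out, sprintf(
      '      <qual:qualitativeSpecies qual:id="%s" qual:constant="%s" qual:maxLevel="1"/>',
      esc(nm), constant))
  }
  out <- c(out, "    </qual:listOfQualitativeSpecies>",
           "    <qual:listOfTransitions>")

  lit_math <- function(node, negated) {
    eqm <- sprintf(
      "<apply><eq/><ci>%s</ci><cn type=\"integer\">1</cn></apply>", esc(node))
    if (negated) paste0("<apply><not/>", eqm, "</apply>") else eqm
  }
  clause_math <- function(cl) {
    lits <- mapply(lit_math, names(cl), unname(cl))
    if (length(lits) == 1) lits[[1]]
    else paste0("<apply><and/>", paste(lits, collapse = ""), "</apply>")
  }
  for (r in network$rules) {
    cls <- vapply(r$clauses, clause_math, character(1))
    math <- if (length(cls) == 1) cls[[1]]
            else paste0("<apply><or/>", paste(cls, collapse = ""), "</apply>")
    sources <- unique(unlist(lapply(r$clauses, names)))
    ins <- sprintf(paste0(
      '        <qual:input qual:qualitativeSpecies="%s" ',
      'qual:transitionEffect="none"/>'), esc(sources))
    out <- c(out,
      sprintf('      <qual:transition qual:id="tr_%s">', esc(r$target)),
      "        <qual:listOfInputs>", ins, "        </qual:listOfInputs>",
      "        <qual:listOfOutputs>",
      sprintf(paste0('        <qual:output qual:qualitativeSpecies="%s" ',
                     'qual:transitionEffect="assignmentLevel"/>'),
              esc(r$target)),
      "        </qual:listOfOutputs>",
      "        <qual:listOfFunctionTerms>",
      '          <qual:defaultTerm qual:resultLevel="0"/>',
      '          <qual:functionTerm qual:resultLevel="1">',
      sprintf('            <math xmlns="%s">%s</math>', MATHML_NS, math),
      "          </qual:functionTerm>",
      "        </qual:listOfFunctionTerms>",
      "      </qual:transition>")
  }
  out <- c(out, "    </qual:listOfTransitions>", "  </model>", "</sbml>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a Boolean network from SBML-qual
#'
#' @param path file path (or anything [xml2::read_xml()] accepts).
#' @param max_clauses cap on the clause count produced by distributive
#'   expansion of a single transition's function term; exceeding it is an
#'   error (guards against exponential blow-up of deeply nested logic).
#' @return A [boolean_network()]. Species without a transition become inputs.
#' @rdname sbml_qual
#' @export
read_sbml_qual <- function(path, max_clauses = 1024L) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  qual_prefix <- names(ns)[ns == QUAL_NS]
  if (!length(qual_prefix)) stop("no qualitative model in SBML document")
  ns_map <- c(q = QUAL_NS, s = SBML_NS, m = MATHML_NS)

  sp <- xml2::xml_find_all(doc, ".//q:qualitativeSpecies", ns_map)
  if (!length(sp)) stop("no qualitative model: no qualitative species found")
  ids <- xml2::xml_attr(sp, "id")
  max_lvl <- xml2::xml_attr(sp, "maxLevel")
  multi <- !is.na(max_lvl) & suppressWarnings(as.numeric(max_lvl)) > 1
  if (any(multi)) {
    stop("non-Boolean (multi-valued) species: ",
         paste(ids[multi], collapse = ", "))
  }

  rules <- list()
  trans <- xml2::xml_find_all(doc, ".//q:transition", ns_map)
  for (tr in trans) {
    outs <- xml2::xml_find_all(tr, ".//q:output", ns_map)
    if (length(outs) != 1) {
      stop("unsupported construct: transition with ", length(outs), " outputs")
    }
    target <- xml2::xml_attr(outs, "qualitativeSpecies")
    terms <- xml2::xml_find_all(tr, ".//q:functionTerm", ns_map)
    lvl1 <- terms[xml2::xml_attr(terms, "resultLevel") == "1"]
    dflt <- xml2::xml_find_first(tr, ".//q:defaultTerm", ns_map)
    dflt_lvl <- xml2::xml_attr(dflt, "resultLevel")
    asts <- lapply(lvl1, function(tm) {
      math <- xml2::xml_find_first(tm, ".//m:math", ns_map)
      if (is.na(xml2::xml_name(math))) stop("functionTerm without math")
      parse_mathml(xml2::xml_children(math)[[1]])
    })
    ast <-
      if (length(asts) == 1) asts[[1]]
      else if (length(asts) > 1) list(op = "or", args = asts)
      else if (identical(dflt_lvl, "1")) {
        # level 1 only by default: rule = NOT(any level-0 term)
        lvl0 <- terms[xml2::xml_attr(terms, "resultLevel") == "0"]
        if (!length(lvl0)) stop("unsupported construct: constant-true transition")
        sub <- lapply(lvl0, function(tm) {
          math <- xml2::xml_find_first(tm, ".//m:math", ns_map)
          parse_mathml(xml2::xml_children(math)[[1]])
        })
        list(op = "not",
             args = list(if (length(sub) == 1) sub[[1]]
                         else list(op = "or", args = sub)))
      } else {
        stop("unsupported construct: transition for '", target,
             "' with no level-1 term")
      }
    clauses <- ast_to_sop(ast, max_clauses = max_clauses)
    if (!length(clauses)) {
      stop("rule for '", target, "' reduces to constant false")
    }
    rules[[target]] <- boolean_rule(target, clauses)
  }

  nodes <- ids
  referenced <- unique(unlist(lapply(rules, function(r)
    unlist(lapply(r$clauses, names)))))
  missing <- setdiff(c(names(rules), referenced), nodes)
  if (length(missing)) {
    stop("transition references undeclared species: ",
         paste(missing, collapse = ", "))
  }
  boolean_network(nodes, rules)
}

# MathML -> boolean AST. Supported: apply(and|or|not|eq ...), ci, cn in {0,1},
# true/false constants rejected (a constant rule has no SOP form).
parse_mathml <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- kids[-1]
    if (op %in% c("and", "or")) {
      list(op = op, args = lapply(args, parse_mathml))
    } else if (op == "not") {
      if (length(args) != 1) stop("unsupported construct: n-ary 'not'")
      list(op = "not", args = list(parse_mathml(args[[1]])))
    } else if (op %in% c("eq", "neq")) {
      if (length(args) != 2) stop("unsupported construct: non-binary '", op, "'")
      names_ <- vapply(args, xml2::xml_name, character(1))
      ci <- args[names_ == "ci"]
      cn <- args[names_ == "cn"]
      if (length(ci) != 1 || length(cn) != 1) {
        stop("unsupported construct: '", op, "' not comparing a species to a constant")
      }
      lvl <- suppressWarnings(as.numeric(xml2::xml_text(cn[[1]])))
      if (!lvl %in% c(0, 1)) {
        stop("unsupported construct: comparison to level ", lvl)
      }
      negated <- xor(op == "neq", lvl == 0)
      list(op = "lit", node = trimws(xml2::xml_text(ci[[1]])), negated = negated)
    } else if (op %in% c("geq", "gt", "leq", "lt")) {
      # geq(x,1) == eq(x,1) and leq(x,0) == eq(x,0) for Boolean species
      names_ <- vapply(args, xml2::xml_name, character(1))
      ci <- args[names_ == "ci"]; cn <- args[names_ == "cn"]
      if (length(ci) != 1 || length(cn) != 1) {
        stop("unsupported construct: '", op, "'")
      }
      lvl <- suppressWarnings(as.numeric(xml2::xml_text(cn[[1]])))
      ci_first <- names_[1] == "ci"
      active <- switch(op,
        geq = ci_first && lvl == 1, gt = ci_first && lvl == 0,
        leq = !ci_first && lvl == 1, lt = !ci_first && lvl == 0)
      inactive <- switch(op,
        leq = ci_first && lvl == 0, lt = ci_first && lvl == 1,
        geq = !ci_first && lvl == 0, gt = !ci_first && lvl == 1)
      if (!isTRUE(active) && !isTRUE(inactive)) {
        stop("unsupported construct: inequality '", op, "' with level ", lvl)
      }
      list(op = "lit", node = trimws(xml2::xml_text(ci[[1]])),
           negated = isTRUE(inactive))
    } else {
      stop("unsupported construct: MathML operator '", op, "'")
    }
  } else if (nm == "ci") {
    list(op = "lit", node = trimws(xml2::xml_text(node)), negated = FALSE)
  } else {
    stop("unsupported construct: MathML element '", nm, "'")
  }
}

# AST -> list of clauses (named logical vectors), with negation push-down and
# distributive expansion; contradictory clauses (x & !x) are dropped.
ast_to_sop <- function(ast, max_clauses = 1024L, negate = FALSE) {
  if (ast$op == "lit") {
    return(list(stats::setNames(xor(ast$negated, negate), ast$node)))
  }
  if (ast$op == "not") {
    return(ast_to_sop(ast$args[[1]], max_clauses, !negate))
  }
  op <- if (negate) c(and = "or", or = "and")[[ast$op]] else ast$op
  parts <- lapply(ast$args, ast_to_sop, max_clauses = max_clauses, negate = negate)
  if (op == "or") {
    clauses <- do.call(c, parts)
  } else {
    # AND: cartesian merge of clause sets; contradictory merges (a node with
    # both signs) are unsatisfiable and dropped
    merge_clause <- function(a, b) {
      common <- intersect(names(a), names(b))
      if (any(a[common] != b[common])) return(NULL)
      c(a, b[setdiff(names(b), names(a))])
    }
    clauses <- list(stats::setNames(logical(0), character(0)))
    for (p in parts) {
      merged <- list()
      for (a in clauses) for (b in p) {
        m <- merge_clause(a, b)
        if (!is.null(m)) merged[[length(merged) + 1L]] <- m
      }
      clauses <- merged
      if (length(clauses) > max_clauses) {
        stop("sum-of-products expansion exceeds ", max_clauses, " clauses")
      }
    }
  }
  clauses <- Filter(length, clauses)
  clauses[!duplicated(vapply(clauses, clause_key, character(1)))]
}
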