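#' Boolean network models in sum-of-products form
#'
#' A `boolean_network` holds named nodes, one sum-of-products (SOP) update
#' rule per regulated node, and the set of input nodes (nodes with no rule,
#' which simply hold their value). Rules are OR-of-AND-clauses over possibly
#' negated literals; this is the normal form in which signaling models are
#' usually curated, with AND gates expressing joint requirements and OR
#' expressing redundant routes into a target.
#'
#' Internally a clause is a named logical vector: names are source nodes,
#' `TRUE` marks a negated literal. Node order is first-declaration order and
#' defines the state-vector index used throughout the package.
#'
#' @param nodes character vector of node names, in declaration order.
#' @param rules named list of [boolean_rule()] objects, keyed by target.
#' @param metadata optional free-form list.
#' @return An object of class `boolean_network` with fields `nodes`, `rules`,
#'   `inputs` (nodes without a rule) and `metadata`.
#' @seealso [parse_rules()], [validate_network()], [to_interaction_graph()]
#' @export
boolean_network <- function(nodes, rules, metadata = list()) {
  stopifnot(is.character(nodes), is.list(rules))
  if (anyDuplicated(nodes)) {
    stop("duplicate node names: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (length(rules) && is.null(names(rules))) {
    names(rules) <- vapply(rules, function(r) r$target, character(1))
  }
  inputs <- setdiff(nodes, names(rules))
  structure(
    list(nodes = nodes, rules = rules, inputs = inputs, metadata = metadata),
    class = "boolean_network"
  )
}

#' Construct a sum-of-products Boolean rule
#'
#' @param target name of the regulated node.
#' @param clauses list of clauses; each clause is a named logical vector
#'   (names = source nodes, value `TRUE` = negated literal). Duplicate
#'   literals within a clause are collapsed; duplicate clauses are dropped.
#' @return An object of class `boolean_rule`.
#' @export
boolean_rule <- function(target, clauses) {
  stopifnot(is.character(target), length(target) == 1, is.list(clauses))
  if (!length(clauses)) stop("rule for '", target, "' has no clauses")
  clauses <- lapply(clauses, function(cl) {
    if (!length(cl)) stop("empty clause in rule for '", target, "'")
    if (is.null(names(cl)) || any(!nzchar(names(cl)))) {
      stop("clause literals must be named by source node")
    }
    # collapse exact duplicates (same node, same sign), keep first-seen order
    keep <- !duplicated(paste0(names(cl), cl))
    cl[keep]
  })
  clauses <- clauses[!duplicated(vapply(clauses, clause_key, character(1)))]
  structure(list(target = target, clauses = clauses), class = "boolean_rule")
}

clause_key <- function(cl) {
  lits <- paste0(ifelse(cl, "!", ""), names(cl))
  paste(sort(lits), collapse = "&")
}

#' @export
format.boolean_rule <- function(x, ...) {
  cl_txt <- vapply(x$clauses, function(cl) {
    paste(paste0(ifelse(cl, "!", ""), names(cl)), collapse = " & ")
  }, character(1))
  paste0(x$target, " = ", paste(cl_txt, collapse = " | "))
}

#' @export
print.boolean_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.boolean_network <- function(x, ...) {
  c(
    sprintf("<boolean_network> %d nodes (%d inputs), %d rules",
            length(x$nodes), length(x$inputs), length(x$rules)),
    vapply(x$rules, format, character(1))
  )
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

node_token <- "[A-Za-z][A-Za-z0-9_.]*"

#' Parse a rule-text Boolean model
#'
#' One rule per non-empty line, `TARGET = lit [& lit]* [| lit [& lit]*]*`,
#' with `!` marking negation and `#` starting a comment. Nodes that are
#' referenced but never appear as a target become input nodes.
#'
#' @param text character scalar (or vector of lines) of rule text.
#' @return A [boolean_network()].
#' @examples
#' net <- parse_rules("C = A | B\nD = A & !C")
#' input_nodes(net)
#' @export
parse_rules <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines_clean <- sub("#.*$", "", lines)
  nodes <- character(0)
  rules <- list()
  declare <- function(nm) {
    if (!nm %in% nodes) nodes <<- c(nodes, nm)
  }
  lit_re <- paste0("^!?", node_token, "$")
  for (i in seq_along(lines_clean)) {
    line <- trimws(lines_clean[i])
    if (!nzchar(line)) next
    parts <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("syntax error at line ", i, ": expected 'TARGET = expression'")
    }
    target <- trimws(parts[1])
    if (!grepl(paste0("^", node_token, "$"), target)) {
      stop("syntax error at line ", i, ": invalid target name '", target, "'")
    }
    if (target %in% names(rules)) {
      stop("duplicate target '", target, "' at line ", i)
    }
    rhs <- trimws(parts[2])
    if (!nzchar(rhs)) stop("empty rule at line ", i)
    declare(target)
    clause_txt <- strsplit(rhs, "|", fixed = TRUE)[[1]]
    clauses <- lapply(clause_txt, function(ct) {
      lit_txt <- trimws(strsplit(ct, "&", fixed = TRUE)[[1]])
      if (!length(lit_txt) || any(!nzchar(lit_txt))) {
        stop("syntax error at line ", i, ": empty literal")
      }
      bad <- lit_txt[!grepl(lit_re, lit_txt)]
      if (length(bad)) {
        stop("syntax error at line ", i, ": invalid literal '", bad[1], "'")
      }
      neg <- startsWith(lit_txt, "!")
      src <- sub("^!", "", lit_txt)
      for (s in src) declare(s)
      stats::setNames(neg, src)
    })
    rules[[target]] <- boolean_rule(target, clauses)
  }
  boolean_network(nodes, rules)
}

#' Serialize a network back to rule text
#'
#' @param network a [boolean_network()].
#' @param path optional file path; when `NULL` the text is returned.
#' @return The rule text, invisibly when written to a file.
#' @export
write_rules <- function(network, path = NULL) {
  stopifnot(inherits(network, "boolean_network"))
  txt <- vapply(network$rules, format, character(1))
  if (length(network$inputs)) {
    txt <- c(paste0("# inputs: ", paste(network$inputs, collapse = ", ")), txt)
  }
  out <- paste0(paste(txt, collapse = "\n"), "\n")
  if (is.null(path)) return(out)
  writeLines(sub("\n$", "", out), path, useBytes = TRUE)
  invisible(out)
}

#' Input nodes of a network
#'
#' Input nodes have no update rule (no incoming links); they hold whatever
#' value a scenario assigns them unless clamped.
#'
#' @param network a [boolean_network()].
#' @return Character vector of input node names.
#' @export
input_nodes <- function(network) {
  stopifnot(inherits(network, "boolean_network"))
  network$inputs
}

#' Validate a Boolean network
#'
#' Checks the structural invariants: rules and inputs partition the declared
#' nodes, every literal references a declared node, every rule has at least
#' one clause with at least one literal, and no clause contains both a
#' literal and its negation.
#'
#' @param network a [boolean_network()].
#' @return Character vector of violation messages; empty for a valid model.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "boolean_network"))
  v <- character(0)
  declared <- network$nodes
  ruled <- names(network$rules)
  if (!setequal(c(ruled, network$inputs), declared) ||
      length(intersect(ruled, network$inputs))) {
    v <- c(v, "rules and inputs do not partition the declared nodes")
  }
  extra <- setdiff(ruled, declared)
  if (length(extra)) {
    v <- c(v, paste0("rule target not declared: ", paste(extra, collapse = ", ")))
  }
  for (r in network$rules) {
    if (!length(r$clauses)) {
      v <- c(v, paste0("rule for '", r$target, "' has no clauses"))
      next
    }
    for (cl in r$clauses) {
      if (!length(cl)) {
        v <- c(v, paste0("empty clause in rule for '", r$target, "'"))
        next
      }
      undeclared <- setdiff(names(cl), declared)
      if (length(undeclared)) {
        v <- c(v, paste0("rule for '", r$target, "' references undeclared node: ",
                         paste(undeclared, collapse = ", ")))
      }
      both <- names(cl)[duplicated(names(cl))]
      if (length(both)) {
        v <- c(v, paste0("clause in rule for '", r$target,
                         "' contains a literal and its negation: ",
                         paste(unique(both), collapse = ", ")))
      }
    }
  }
  v
}

#' Signed interaction graph of a Boolean model
#'
#' Flattens the logic: every literal occurrence source -> target becomes a
#' signed directed edge (`+` plain, `-` negated); duplicate (source, target,
#' sign) triples are merged. A node that regulates a target both positively
#' and negatively yields two parallel edges of opposite sign. AND gates are
#' not represented.
#'
#' @param network a [boolean_network()].
#' @return An `interaction_graph`: list with `nodes` (character) and `edges`
#'   (data.frame with columns `source`, `target`, `sign`).
#' @export
to_interaction_graph <- function(network) {
  stopifnot(inherits(network, "boolean_network"))
  src <- tgt <- sgn <- character(0)
  for (r in network$rules) {
    for (cl in r$clauses) {
      src <- c(src, names(cl))
      tgt <- c(tgt, rep(r$target, length(cl)))
      sgn <- c(sgn, ifelse(cl, "-", "+"))
    }
  }
  edges <- unique(data.frame(source = src, target = tgt, sign = sgn,
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$source, edges$target, edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = network$nodes, edges = edges),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d signed links\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Materialize AND gates as explicit nodes
#'
#' Expands the hypergraph view: each multi-literal clause becomes one AND-gate
#' node receiving one signed edge per literal and emitting a single positive
#' edge to the clause's target; single-literal clauses become direct signed
#' edges. This reproduces the drawn form of curated models, where gate nodes
#' count toward the node total.
#'
#' @param network a [boolean_network()].
#' @return A `gate_graph`: list with `nodes` (data.frame `name`, `type` in
#'   {"species", "gate"}) and `links` (data.frame `source`, `target`, `sign`).
#' @export
materialize_and_gates <- function(network) {
  stopifnot(inherits(network, "boolean_network"))
  gate_names <- character(0)
  src <- tgt <- sgn <- character(0)
  gate_i <- 0L
  for (r in network$rules) {
    for (cl in r$clauses) {
      if (length(cl) == 1L) {
        src <- c(src, names(cl)); tgt <- c(tgt, r$target)
        sgn <- c(sgn, if (cl[[1]]) "-" else "+")
      } else {
        gate_i <- gate_i + 1L
        g <- sprintf("AND_%03d_%s", gate_i, r$target)
        gate_names <- c(gate_names, g)
        src <- c(src, names(cl), g)
        tgt <- c(tgt, rep(g, length(cl)), r$target)
        sgn <- c(sgn, ifelse(cl, "-", "+"), "+")
      }
    }
  }
  nodes <- data.frame(
    name = c(network$nodes, gate_names),
    type = c(rep("species", length(network$nodes)),
             rep("gate", length(gate_names))),
    stringsAsFactors = FALSE
  )
  links <- data.frame(source = src, target = tgt, sign = sgn,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, links = links), class = "gate_graph")
}

#' @export
print.gate_graph <- function(x, ...) {
  cat(sprintf("<gate_graph> %d nodes (%d species + %d gates), %d links\n",
              nrow(x$nodes), sum(x$nodes$type == "species"),
              sum(x$nodes$type == "gate"), nrow(x$links)))
  invisible(x)
}

# Evaluate a rule on a 0/1 state vector (named). Returns 0 or 1.
eval_rule <- function(rule, state) {
  for (cl in rule$clauses) {
    vals <- state[names(cl)]
    if (all(ifelse(cl, 1 - vals, vals) == 1)) return(1L)
  }
  0L
}
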