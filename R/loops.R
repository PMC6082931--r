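#' Structural loop analysis of signed interaction graphs
#'
#' Feedback loops (simple directed cycles) concentrate the dynamical
#' repertoire of a signaling network; nodes lying on many loops are strong
#' perturbation candidates. This module enumerates cycles, computes loop
#' statistics and per-node loop participation, and ranks nodes not in a
#' known-disease set as candidates.
#'
#' @name loop_analysis
NULL

# interaction_graph -> igraph with a sign edge attribute
ig_to_igraph <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  igraph::graph_from_data_frame(
    graph$edges[, c("source", "target", "sign")],
    directed = TRUE,
    vertices = data.frame(name = graph$nodes)
  )
}

#' Strongly connected components of an interaction graph
#'
#' @param graph an `interaction_graph` from [to_interaction_graph()].
#' @return List of components sorted by size descending; each has `nodes`,
#'   `n_nodes` and `n_edges` (signed links with both endpoints inside the
#'   component).
#' @export
strongly_connected_components <- function(graph) {
  g <- ig_to_igraph(graph)
  comp <- igraph::components(g, mode = "strong")
  members <- split(names(comp$membership), comp$membership)
  out <- lapply(members, function(nds) {
    inside <- graph$edges$source %in% nds & graph$edges$target %in% nds
    list(nodes = sort(nds), n_nodes = length(nds), n_edges = sum(inside))
  })
  out[order(-vapply(out, `[[`, numeric(1), "n_nodes"),
            vapply(out, function(x) x$nodes[1], character(1)))]
}

#' Enumerate simple directed cycles (feedback loops)
#'
#' Johnson-style enumeration: cycles are anchored at their smallest vertex
#' (by node-order index) and searched in the subgraph of vertices with equal
#' or larger index, so each cycle is produced exactly once. Parallel edges of
#' opposite sign between the same pair count as one arc for enumeration; such
#' a loop's sign is reported as `NA` (ambiguous).
#'
#' @param graph an `interaction_graph`.
#' @param max_length maximum loop length in nodes (default 26).
#' @param include_self_loops whether length-1 loops are reported.
#' @param max_results hard cap on the number of loops; exceeding it is an
#'   error (guards against combinatorial blow-up).
#' @return A `loop_set`: list with `loops` (list of node-name cycles in
#'   canonical rotation, smallest node name first), `length` (integer vector)
#'   and `sign` (`"+"`, `"-"` or `NA`), ordered by length then lexicographic
#'   node sequence.
#' @export
enumerate_cycles <- function(graph, max_length = 26, include_self_loops = FALSE,
                             max_results = 1e6) {
  stopifnot(inherits(graph, "interaction_graph"), max_length >= 1)
  if (!include_self_loops && max_length < 2) {
    stop("max_length must be >= 2 when self-loops are excluded")
  }
  nodes <- graph$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  e <- graph$edges
  # per ordered pair: aggregate sign (+1, -1, or 0 = both signs present)
  pair_key <- paste(e$source, e$target, sep = "\r")
  sgn_num <- ifelse(e$sign == "+", 1L, -1L)
  agg <- tapply(sgn_num, pair_key, function(s) {
    u <- unique(s); if (length(u) == 1) u else 0L
  })
  uniq <- !duplicated(pair_key)
  us <- idx[e$source[uniq]]; ut <- idx[e$target[uniq]]
  usign <- as.integer(agg[pair_key[uniq]])
  adj <- rep(list(integer(0)), n)
  sign_of <- rep(list(integer(0)), n)
  for (i in seq_along(us)) {
    adj[[us[i]]] <- c(adj[[us[i]]], ut[i])
    sign_of[[us[i]]] <- c(sign_of[[us[i]]], usign[i])
  }
  # sort adjacency for deterministic discovery order
  for (i in seq_len(n)) {
    o <- order(adj[[i]])
    adj[[i]] <- adj[[i]][o]; sign_of[[i]] <- sign_of[[i]][o]
  }

  loops <- list()
  lens <- integer(0)
  signs <- integer(0)
  count <- 0L
  add_loop <- function(path, sgn) {
    count <<- count + 1L
    if (count > max_results) {
      stop("cycle enumeration exceeded the cap of ", max_results, " loops")
    }
    loops[[count]] <<- path
    lens[count] <<- length(path)
    signs[count] <<- sgn
  }

  for (start in seq_len(n)) {
    # DFS over vertices >= start; cycle closes back at start
    path <- integer(0)
    on_path <- logical(n)
    dfs <- function(v, sgn) {
      path <<- c(path, v); on_path[v] <<- TRUE
      nbrs <- adj[[v]]; sgs <- sign_of[[v]]
      for (j in seq_along(nbrs)) {
        w <- nbrs[j]
        s2 <- if (sgn == 0L || sgs[j] == 0L) 0L else sgn * sgs[j]
        if (w == start) {
          if (length(path) > 1 || include_self_loops) add_loop(path, s2)
        } else if (w > start && !on_path[w] && length(path) < max_length) {
          dfs(w, s2)
        }
      }
      on_path[v] <<- FALSE; path <<- path[-length(path)]
    }
    if (max_length >= 1) dfs(start, 1L)
  }

  loops_named <- lapply(loops, function(p) {
    nms <- nodes[p]
    shift <- which.min(match(nms, sort(nms)))  # smallest node name first
    nms[c(seq(shift, length(nms)), seq_len(shift - 1))]
  })
  ord <- order(lens, vapply(loops_named, paste, character(1), collapse = "\r"))
  structure(
    list(loops = loops_named[ord], length = lens[ord],
         sign = c("-", NA, "+")[signs[ord] + 2L]),
    class = "loop_set"
  )
}

#' @export
print.loop_set <- function(x, ...) {
  if (!length(x$length)) {
    cat("<loop_set> 0 loops\n")
  } else {
    cat(sprintf("<loop_set> %d loops, lengths %d-%d (mean %.2f)\n",
                length(x$length), min(x$length), max(x$length),
                mean(x$length)))
  }
  invisible(x)
}

#' Loop statistics and per-node participation
#'
#' @param loops a `loop_set` from [enumerate_cycles()].
#' @param nodes node universe over which participation is reported (nodes on
#'   no loop get 0).
#' @return A `loop_stats` list: `count`, `longest`, `shortest`, `mean_length`,
#'   and `participation` (named fraction-of-loops vector, one entry per node).
#' @export
loop_stats <- function(loops, nodes) {
  stopifnot(inherits(loops, "loop_set"))
  count <- length(loops$loops)
  participation <- stats::setNames(numeric(length(nodes)), nodes)
  if (count == 0) {
    return(structure(list(count = 0L, longest = NA_integer_,
                          shortest = NA_integer_, mean_length = NA_real_,
                          participation = participation, empty = TRUE),
                     class = "loop_stats"))
  }
  tab <- table(unlist(loops$loops))
  participation[names(tab)] <- as.numeric(tab) / count
  structure(
    list(count = count, longest = max(loops$length),
         shortest = min(loops$length), mean_length = mean(loops$length),
         participation = participation, empty = FALSE),
    class = "loop_stats"
  )
}

#' @export
print.loop_stats <- function(x, ...) {
  if (x$empty) {
    cat("<loop_stats> no loops\n")
    return(invisible(x))
  }
  cat(sprintf("<loop_stats> %d loops; length %d-%d, mean %.2f\n",
              x$count, x$shortest, x$longest, x$mean_length))
  top <- utils::head(sort(x$participation, decreasing = TRUE), 5)
  cat("top participation:",
      paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", "), "\n")
  invisible(x)
}

#' Rank loop-participation candidates outside a known set
#'
#' Nodes appearing in at least `threshold` of all loops, excluding an already
#' known (e.g. disease-associated) set, sorted by participation descending
#' with ties broken by node name.
#'
#' @param stats a `loop_stats` from [loop_stats()].
#' @param known_pids character vector of nodes to exclude.
#' @param threshold minimum participation fraction in (0, 1].
#' @return data.frame with columns `node` and `participation`.
#' @export
rank_candidates <- function(stats, known_pids = character(0), threshold = 0.1) {
  stopifnot(inherits(stats, "loop_stats"), threshold > 0, threshold <= 1)
  p <- stats$participation
  p <- p[p >= threshold & !(names(p) %in% known_pids)]
  ord <- order(-p, names(p))
  data.frame(node = names(p)[ord], participation = unname(p)[ord],
             stringsAsFactors = FALSE)
}

#' Per-node essentiality summary
#'
#' Ranks nodes by loop participation and annotates whether each lies on any
#' directed path from a source (receptor) node to a target (transcription
#' factor) node.
#'
#' @param loops a `loop_set`.
#' @param graph the `interaction_graph` the loops came from.
#' @param sources,targets character vectors of source/target node names.
#' @return data.frame with columns `node`, `participation`, `on_path`,
#'   sorted by participation descending.
#' @export
essentiality_report <- function(loops, graph, sources, targets) {
  stopifnot(inherits(graph, "interaction_graph"))
  unknown <- setdiff(c(sources, targets), graph$nodes)
  if (length(unknown)) {
    stop("unknown source/target node: ", paste(unknown, collapse = ", "))
  }
  st <- loop_stats(loops, graph$nodes)
  g <- ig_to_igraph(graph)
  fwd <- unique(unlist(lapply(sources, function(s)
    names(igraph::subcomponent(g, s, mode = "out")))))
  bwd <- unique(unlist(lapply(targets, function(s)
    names(igraph::subcomponent(g, s, mode = "in")))))
  on_path <- graph$nodes %in% intersect(fwd, bwd)
  df <- data.frame(node = graph$nodes,
                   participation = unname(st$participation[graph$nodes]),
                   on_path = on_path, stringsAsFactors = FALSE)
  df[order(-df$participation, df$node), , drop = FALSE]
}

#' Write a loop set as TSV (one loop per row: length, sign, node list)
#'
#' @param loops a `loop_set`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_loops_tsv <- function(loops, path) {
  df <- data.frame(
    length = loops$length,
    sign = ifelse(is.na(loops$sign), "±", loops$sign),
    nodes = vapply(loops$loops, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
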