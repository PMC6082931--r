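# Independent oracles used across the suite. These deliberately take the
# naive/exhaustive route so they share no code path with the package
# implementations they check.

# Explicit 2^m corner-sum BooleCube: sum over every Boolean corner of
# rule value times the multilinear tent weight.
corner_sum_boolecube <- function(rule, state) {
  sources <- unique(unlist(lapply(rule$clauses, names)))
  m <- length(sources)
  total <- 0
  for (i in seq_len(2^m) - 1L) {
    corner <- as.integer(intToBits(i)[seq_len(m)])
    names(corner) <- sources
    b <- 0L
    for (cl in rule$clauses) {
      v <- corner[names(cl)]
      if (all(ifelse(cl, 1L - v, v) == 1L)) { b <- 1L; break }
    }
    if (b == 0L) next
    w <- prod(ifelse(corner == 1L, state[sources], 1 - state[sources]))
    total <- total + w
  }
  total
}

# Evaluate a rule (0/1) on a discrete corner, bypassing package internals.
eval_rule_naive <- function(rule, corner) {
  for (cl in rule$clauses) {
    v <- corner[names(cl)]
    if (all(ifelse(cl, 1L - v, v) == 1L)) return(1L)
  }
  0L
}

# Naive exhaustive simple-cycle enumeration on an edge list: try every
# vertex as a start, DFS over all vertices, collect node sequences, and
# deduplicate by canonical rotation. Quadratic-overkill on purpose.
naive_simple_cycles <- function(edges, nodes, max_length = length(nodes)) {
  adj <- split(edges$target, factor(edges$source, levels = nodes))
  found <- new.env(parent = emptyenv())
  canon <- function(path) {
    shift <- which.min(match(path, sort(path)))
    paste(path[c(seq(shift, length(path)), seq_len(shift - 1))],
          collapse = "\r")
  }
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in unique(adj[[v]])) {
      if (w == path[1] && length(path) >= 2) {
        assign(canon(path), TRUE, envir = found)
      } else if (!w %in% path && length(path) < max_length) {
        dfs(c(path, w))
      }
    }
  }
  for (v in nodes) dfs(v)
  sort(strsplit(ls(found), "\r") |> vapply(paste, character(1), collapse = ","))
}

# Random SOP rule over a given source pool (independent of the package's
# network generator).
random_rule <- function(sources, max_clauses = 3, max_lits = 3) {
  n_cl <- sample.int(max_clauses, 1)
  clauses <- lapply(seq_len(n_cl), function(i) {
    sz <- sample.int(min(max_lits, length(sources)), 1)
    src <- sample(sources, sz)
    stats::setNames(stats::runif(sz) < 0.4, src)
  })
  boolean_rule("T", clauses)
}

# Random signed edge list on n nodes (for cycle-oracle tests).
random_digraph <- function(n, p = 0.25) {
  nodes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  edges$sign <- sample(c("+", "-"), nrow(edges), replace = TRUE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "interaction_graph")
}

expect_same_rules <- function(a, b) {
  keyset <- function(n) {
    lapply(n$rules[sort(names(n$rules))], function(r)
      sort(vapply(r$clauses, function(cl) {
        paste(sort(paste0(ifelse(cl, "!", ""), names(cl))), collapse = "&")
      }, character(1))))
  }
  expect_true(setequal(a$nodes, b$nodes))
  expect_true(setequal(a$inputs, b$inputs))
  expect_identical(keyset(a), keyset(b))
}
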