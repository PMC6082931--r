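triangle <- structure(list(
  nodes = c("A", "B", "C"),
  edges = data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                     sign = c("+", "+", "-"))),
  class = "interaction_graph")

test_that("strongly connected components are found and sized", {
  comps <- strongly_connected_components(triangle)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_nodes, 3)
  expect_equal(comps[[1]]$n_edges, 3)

  dag <- structure(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(source = c("A", "B"), target = c("B", "C"),
                       sign = "+")), class = "interaction_graph")
  expect_length(strongly_connected_components(dag), 3)
  expect_true(all(vapply(strongly_connected_components(dag),
                         `[[`, numeric(1), "n_nodes") == 1))
})

test_that("cycle enumeration finds canonical loops with signs", {
  loops <- enumerate_cycles(triangle)
  expect_length(loops$loops, 1)
  expect_equal(loops$length, 3L)
  expect_equal(loops$loops[[1]][1], "A")  # canonical rotation
  expect_equal(loops$sign, "-")           # one inhibiting edge

  # complete bidirectional 3-node graph: three 2-cycles + two 3-cycles
  bidir <- structure(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(
      source = c("A", "B", "B", "C", "A", "C"),
      target = c("B", "A", "C", "B", "C", "A"), sign = "+")),
    class = "interaction_graph")
  l5 <- enumerate_cycles(bidir)
  expect_length(l5$loops, 5)
  expect_equal(sort(l5$length), c(2L, 2L, 2L, 3L, 3L))

  # max_length prunes
  expect_length(enumerate_cycles(bidir, max_length = 2)$loops, 3)

  # self loops excluded by default, included on request
  selfy <- structure(list(
    nodes = "A",
    edges = data.frame(source = "A", target = "A", sign = "+")),
    class = "interaction_graph")
  expect_length(enumerate_cycles(selfy)$loops, 0)
  expect_length(enumerate_cycles(selfy, max_length = 2,
                                 include_self_loops = TRUE)$loops, 1)

  # a both-signs pair gives one loop with ambiguous sign
  ambi <- structure(list(
    nodes = c("A", "B"),
    edges = data.frame(source = c("A", "A", "B"), target = c("B", "B", "A"),
                       sign = c("+", "-", "+"))),
    class = "interaction_graph")
  la <- enumerate_cycles(ambi)
  expect_length(la$loops, 1)
  expect_true(is.na(la$sign))

  # result cap refuses instead of exploding
  big <- random_digraph(8, p = 0.9)
  expect_error(enumerate_cycles(big, max_length = 8, max_results = 10),
               "cap")
})

test_that("enumeration matches the naive DFS oracle on random digraphs", {
  set.seed(17)
  for (i in 1:100) {
    g <- random_digraph(sample(3:8, 1), p = stats::runif(1, 0.1, 0.5))
    mine <- vapply(enumerate_cycles(g, max_length = length(g$nodes))$loops,
                   paste, character(1), collapse = ",")
    oracle <- naive_simple_cycles(g$edges, g$nodes)
    expect_setequal(mine, oracle)
  }
})

test_that("loop enumeration is invariant to node ordering", {
  set.seed(3)
  g <- random_digraph(7, p = 0.35)
  perm <- sample(seq_along(g$nodes))
  g2 <- structure(list(nodes = g$nodes[perm], edges = g$edges),
                  class = "interaction_graph")
  key <- function(ls) sort(vapply(ls$loops, paste, character(1), collapse = ","))
  expect_identical(key(enumerate_cycles(g, max_length = 7)),
                   key(enumerate_cycles(g2, max_length = 7)))
})

test_that("every loop lies inside one strongly connected component", {
  set.seed(8)
  for (i in 1:10) {
    g <- random_digraph(8, p = 0.3)
    loops <- enumerate_cycles(g, max_length = 8)
    comps <- strongly_connected_components(g)
    membership <- unlist(lapply(seq_along(comps), function(ci)
      stats::setNames(rep(ci, comps[[ci]]$n_nodes), comps[[ci]]$nodes)))
    for (lp in loops$loops) {
      expect_length(unique(membership[lp]), 1)
    }
  }
})

test_that("loop statistics and participation balance", {
  loops <- enumerate_cycles(triangle)
  st <- loop_stats(loops, triangle$nodes)
  expect_equal(st$count, 1)
  expect_equal(unname(st$participation), rep(1, 3))

  # two disjoint triangles: each node in half the loops
  two <- structure(list(
    nodes = c("A", "B", "C", "D", "E", "F"),
    edges = data.frame(
      source = c("A", "B", "C", "D", "E", "F"),
      target = c("B", "C", "A", "E", "F", "D"), sign = "+")),
    class = "interaction_graph")
  st2 <- loop_stats(enumerate_cycles(two), two$nodes)
  expect_equal(unname(st2$participation), rep(0.5, 6))
  # sum(participation) * count == total loop length
  set.seed(14)
  g <- random_digraph(7, 0.35)
  loops_g <- enumerate_cycles(g, max_length = 7)
  st_g <- loop_stats(loops_g, g$nodes)
  if (st_g$count > 0) {
    expect_equal(sum(st_g$participation) * st_g$count, sum(loops_g$length))
    expect_gte(st_g$mean_length, st_g$shortest)
    expect_lte(st_g$mean_length, st_g$longest)
  }
  # empty loop set is flagged
  st0 <- loop_stats(enumerate_cycles(structure(list(
    nodes = c("A", "B"),
    edges = data.frame(source = "A", target = "B", sign = "+")),
    class = "interaction_graph")), c("A", "B"))
  expect_equal(st0$count, 0)
  expect_true(st0$empty)
})

test_that("candidate ranking excludes known nodes and orders by participation", {
  st <- loop_stats(enumerate_cycles(triangle), triangle$nodes)
  expect_equal(nrow(rank_candidates(st, known_pids = c("A", "B", "C"))), 0)
  ranked <- rank_candidates(st, known_pids = "A", threshold = 0.5)
  expect_equal(ranked$node, c("B", "C"))  # ties broken by name

  fake <- st
  fake$participation <- c(A = 0.2, B = 0.05, C = 0.5)
  expect_equal(rank_candidates(fake, character(0), 0.1)$node, c("C", "A"))
})

test_that("essentiality report annotates receptor-to-TF path membership", {
  chain <- structure(list(
    nodes = c("S", "X", "T", "ISO"),
    edges = data.frame(source = c("S", "X"), target = c("X", "T"),
                       sign = "+")), class = "interaction_graph")
  rep <- essentiality_report(enumerate_cycles(chain), chain, "S", "T")
  expect_true(rep$on_path[rep$node == "X"])
  expect_false(rep$on_path[rep$node == "ISO"])
  expect_equal(rep$participation[rep$node == "ISO"], 0)
  expect_error(essentiality_report(enumerate_cycles(chain), chain, "NOPE", "T"),
               "unknown")
})

test_that("loops export as TSV with length, sign and node list", {
  f <- tempfile(fileext = ".tsv")
  write_loops_tsv(enumerate_cycles(triangle), f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$length, 3)
  expect_equal(tab$nodes, "A,B,C")
})
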