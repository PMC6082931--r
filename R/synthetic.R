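#' Synthetic Boolean networks and a toy receptor-signaling fixture
#'
#' Seeded generators for sum-of-products Boolean networks with the structural
#' features the analysis assumes — signed regulation, AND gates, input nodes
#' and controllable feedback content — plus a small hand-built fixture that
#' mimics the shape of a two-signal receptor cascade (relay layer with an AND
#' gate, an inhibitory modulator, a structural negative feedback loop, and
#' transcription-factor readouts) with attractors verified by exhaustive
#' enumeration.
#'
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' @param n_nodes total node count.
#' @param n_inputs number of input nodes (`< n_nodes`).
#' @param max_clauses maximum OR-clauses per rule.
#' @param max_literals_per_clause maximum AND-literals per clause.
#' @param negation_prob probability a literal is negated.
#' @param feedback_enrichment probability that a non-input node receives an
#'   extra back-edge literal, creating a cycle.
#' @param seed integer RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_nodes, n_inputs, max_clauses = 2,
                             max_literals_per_clause = 3,
                             negation_prob = 0.25,
                             feedback_enrichment = 0.3, seed = 1) {
  stopifnot(n_nodes >= 2, n_inputs >= 0, n_inputs < n_nodes,
            max_clauses >= 1, max_literals_per_clause >= 1,
            negation_prob >= 0, negation_prob <= 1,
            feedback_enrichment >= 0, feedback_enrichment <= 1)
  structure(list(n_nodes = as.integer(n_nodes), n_inputs = as.integer(n_inputs),
                 max_clauses = as.integer(max_clauses),
                 max_literals_per_clause = as.integer(max_literals_per_clause),
                 negation_prob = negation_prob,
                 feedback_enrichment = feedback_enrichment,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# evaluate expr under a private RNG stream, restoring the caller's state
# (expr is a promise: it only runs after set.seed)
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a random sum-of-products Boolean network
#'
#' Wires a random DAG first (each regulated node draws its regulators from
#' nodes earlier in the order), then adds back-edge literals with probability
#' `feedback_enrichment`, which is what creates feedback loops. Identical
#' seeds give identical networks.
#'
#' @param config a [generator_config()].
#' @return A [boolean_network()] with exactly `n_nodes` nodes of which
#'   `n_inputs` are inputs.
#' @export
random_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_reg <- config$n_nodes - config$n_inputs
  if (n_reg < 1) stop("infeasible config: no regulated nodes")
  inputs <- sprintf("I%02d", seq_len(config$n_inputs))
  genes <- sprintf("G%02d", seq_len(n_reg))
  nodes <- c(inputs, genes)
  with_seed(config$seed, {
    rules <- list()
    for (gi in seq_len(n_reg)) {
      target <- genes[gi]
      pool <- c(inputs, genes[seq_len(gi - 1)])
      if (!length(pool)) pool <- target  # first node with no predecessors: self-loop
      n_cl <- sample.int(config$max_clauses, 1)
      clauses <- lapply(seq_len(n_cl), function(ci) {
        sz <- sample.int(min(config$max_literals_per_clause, length(pool)), 1)
        src <- sample(pool, sz)
        stats::setNames(stats::runif(sz) < config$negation_prob, src)
      })
      # feedback: literal from a node later in the order (or itself)
      if (stats::runif(1) < config$feedback_enrichment) {
        later <- genes[seq(gi, n_reg)]
        back <- sample(later, 1)
        ci <- sample.int(length(clauses), 1)
        if (!back %in% names(clauses[[ci]])) {
          clauses[[ci]] <- c(clauses[[ci]],
                             stats::setNames(stats::runif(1) < config$negation_prob, back))
        }
      }
      rules[[target]] <- boolean_rule(target, clauses)
    }
    boolean_network(nodes, rules,
                    metadata = list(generator = unclass(config)))
  })
}

#' Draw random kinetic parameters for a network
#'
#' Per-edge Hill pairs and per-node lifetimes sampled uniformly from the
#' given ranges (collapsed ranges reproduce the defaults n = 3, k = 0.5,
#' tau = 1). Deterministic per seed.
#'
#' @param network a [boolean_network()].
#' @param seed integer RNG seed.
#' @param n_range,k_range,tau_range length-2 numeric ranges.
#' @return A [kinetic_parameters()].
#' @export
random_parameters <- function(network, seed = 1, n_range = c(1, 32),
                              k_range = c(0.5, 0.9), tau_range = c(1, 16)) {
  stopifnot(n_range[1] >= 1, k_range[1] > 0, k_range[2] < 1, tau_range[1] > 0,
            n_range[1] <= n_range[2], k_range[1] <= k_range[2],
            tau_range[1] <= tau_range[2])
  ig <- to_interaction_graph(network)
  pairs <- unique(ig$edges[, c("source", "target")])
  regulated <- names(network$rules)
  with_seed(seed, {
    edges <- data.frame(
      source = pairs$source, target = pairs$target,
      n = stats::runif(nrow(pairs), n_range[1], n_range[2]),
      k = stats::runif(nrow(pairs), k_range[1], k_range[2])
    )
    tau <- stats::setNames(
      stats::runif(length(regulated), tau_range[1], tau_range[2]), regulated)
    kinetic_parameters(tau = tau, edges = edges)
  })
}

#' Toy two-signal receptor-cascade fixture
#'
#' A 13-node model with the structural motifs of a receptor signaling
#' network: two signal inputs, a coreceptor arm, a relay with an AND gate, an
#' inhibitory modulator (regulated by a quiescent input so a transient clamp
#' decays after release), a structurally present (but at rest inactive)
#' negative feedback loop, a calcium-like second messenger, and three
#' transcription-factor readouts. The rules are:
#'
#' ```
#' MODULATOR = MOD_IN
#' REC   = SIG1 & !MODULATOR
#' COREC = SIG2
#' RELAY = REC
#' KIN   = RELAY & !INH
#' INH   = KIN & MODULATOR
#' CA    = KIN & COREC
#' TF1   = KIN
#' TF2   = CA
#' TF3   = COREC | CA
#' ```
#'
#' Documented discrete attractors (verified by exhaustive enumeration, and
#' exact continuous equilibria because all inputs sit at Boolean corners):
#' * both signals on: unique fixed point with TF1 = TF2 = TF3 = 1;
#' * signal 1 off: only the costimulation-driven TF3 is on;
#' * signal 2 off: TF1 on, TF2 = TF3 = 0;
#' * RELAY knocked out (both signals on): the relay-dependent readouts TF1
#'   and TF2 are off; TF3 stays on through the costimulation arm.
#'
#' @return List with `network`, `params` (defaults n = 3, k = 0.5, tau = 1),
#'   `scenarios` (named list: `both_on`, `signal1_off`, `signal2_off`),
#'   `modulators` (the transient-clamp node set for the basin protocol),
#'   `tf_nodes`, `relay_dependent_tfs` and `relay`.
#' @export
toy_bcr_network <- function() {
  txt <- "
# two-signal receptor cascade fixture
MODULATOR = MOD_IN
REC   = SIG1 & !MODULATOR
COREC = SIG2
RELAY = REC
KIN   = RELAY & !INH
INH   = KIN & MODULATOR
CA    = KIN & COREC
TF1   = KIN
TF2   = CA
TF3   = COREC | CA
"
  network <- parse_rules(txt)
  params <- kinetic_parameters()
  scenarios <- list(
    both_on = scenario("both_on",
                       input_values = c(SIG1 = 1, SIG2 = 1, MOD_IN = 0),
                       t_end = 120),
    signal1_off = scenario("signal1_off",
                           input_values = c(SIG1 = 0, SIG2 = 1, MOD_IN = 0),
                           t_end = 120),
    signal2_off = scenario("signal2_off",
                           input_values = c(SIG1 = 1, SIG2 = 0, MOD_IN = 0),
                           t_end = 120)
  )
  list(network = network, params = params, scenarios = scenarios,
       modulators = "MODULATOR",
       tf_nodes = c("TF1", "TF2", "TF3"),
       relay_dependent_tfs = c("TF1", "TF2"),
       relay = "RELAY")
}
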