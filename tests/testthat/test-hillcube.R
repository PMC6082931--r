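defaults <- kinetic_parameters()

# initial state of the fixture's both-signals scenario without running it
scenario_initial_for_test <- function(fx) {
  init <- stats::setNames(numeric(length(fx$network$nodes)), fx$network$nodes)
  init[names(fx$scenarios$both_on$input_values)] <-
    fx$scenarios$both_on$input_values
  init
}

test_that("hill is the standard activation function", {
  expect_equal(hill(0.5, 3, 0.5), 0.5)     # x = k is half-maximal
  expect_equal(hill(0, 3, 0.5), 0)
  expect_equal(hill(0, 7, 0.2), 0)
  expect_equal(hill(1, 3, 0.5), 1 / (1 + 0.5^3))
  # monotone
  xs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(hill(xs, 4, 0.3)) > 0))
  expect_error(hill(1.2, 3, 0.5), "\\[0, 1\\]")
  expect_error(hill(0.5, 0.5, 0.5), "n must be")
  expect_error(hill(0.5, 3, 1), "k must lie")
})

test_that("boolecube interpolates OR/AND as expected and matches corners", {
  or_rule <- parse_rules("T = A | B")$rules$T
  and_rule <- parse_rules("T = A & B")$rules$T
  expect_equal(boolecube(or_rule, c(A = 0.3, B = 0.5)),
               corner_sum_boolecube(or_rule, c(A = 0.3, B = 0.5)))
  expect_equal(boolecube(or_rule, c(A = 0.3, B = 0.5)), 0.65)
  expect_equal(boolecube(and_rule, c(A = 0.5, B = 0.5)), 0.25)
  # corner fidelity for a messy rule
  rule <- parse_rules("T = A & !B | C & B | !A & !C")$rules$T
  for (i in 0:7) {
    corner <- stats::setNames(as.numeric(intToBits(i)[1:3]), c("A", "B", "C"))
    expect_equal(boolecube(rule, corner), eval_rule_naive(rule, corner))
  }
})

test_that("boolecube equals the explicit corner-sum oracle at interior points", {
  set.seed(4)
  sources <- c("A", "B", "C", "D", "E", "F")
  for (i in 1:200) {
    rule <- random_rule(sources, max_clauses = 4, max_lits = 4)
    x <- stats::setNames(stats::runif(length(sources)), sources)
    expect_equal(boolecube(rule, x), corner_sum_boolecube(rule, x),
                 tolerance = 1e-12)
  }
})

test_that("normalized HillCube is exact at Boolean corners for any parameters", {
  set.seed(11)
  sources <- c("A", "B", "C", "D")
  for (i in 1:50) {
    rule <- random_rule(sources)
    params <- kinetic_parameters(
      edges = data.frame(source = sources, target = "T",
                         n = stats::runif(4, 1, 30),
                         k = stats::runif(4, 0.05, 0.95)))
    corner_bits <- sample(0:15, 1)
    corner <- stats::setNames(as.numeric(intToBits(corner_bits)[1:4]), sources)
    expect_equal(normalized_hillcube(rule, corner, params, target = "T"),
                 eval_rule_naive(rule, corner))
  }
})

test_that("normalized HillCube matches closed-form single-activator values", {
  rule <- parse_rules("T = A")$rules$T
  # f(0.5)/f(1) with n=3, k=0.5: 0.5 / (1/(1+0.125)) = 0.5625
  expect_equal(normalized_hillcube(rule, c(A = 0.5), defaults), 0.5625)
  steep <- kinetic_parameters(edges = data.frame(
    source = "A", target = "T", n = 32, k = 0.9))
  val <- normalized_hillcube(rule, c(A = 0.5), steep, target = "T")
  expect_lt(val, 1e-4)  # far below a steep high threshold
})

test_that("normalized HillCube converges to the Boolean rule as n grows", {
  set.seed(21)
  steep <- kinetic_parameters(default_n = 200, default_k = 0.5)
  sources <- c("A", "B", "C")
  for (i in 1:50) {
    rule <- random_rule(sources)
    x <- stats::runif(3)
    x <- ifelse(x < 0.5, x * 0.8, 0.6 + (x - 0.5) * 0.8)  # outside [0.4, 0.6]
    names(x) <- sources
    target_bool <- eval_rule_naive(rule, round(x))
    expect_lt(abs(normalized_hillcube(rule, x, steep, "T") - target_bool), 1e-3)
  }
})

test_that("monotone rules give a HillCube monotone in each input", {
  set.seed(31)
  rule <- parse_rules("T = A & B | C")$rules$T
  for (i in 1:20) {
    x <- stats::setNames(stats::runif(3), c("A", "B", "C"))
    for (v in c("A", "B", "C")) {
      lo <- x; hi <- x
      lo[v] <- max(0, x[v] - 0.2); hi[v] <- min(1, x[v] + 0.2)
      expect_lte(normalized_hillcube(rule, lo, defaults, "T"),
                 normalized_hillcube(rule, hi, defaults, "T") + 1e-12)
    }
  }
})

test_that("ode_rhs follows the relaxation form with clamp and input rates zero", {
  net <- parse_rules("T = A")
  # at a self-consistent state the rate vanishes
  b <- normalized_hillcube(net$rules$T, c(A = 0.7), defaults, "T")
  r <- ode_rhs(net, defaults, c(A = 0.7, T = b))
  expect_equal(unname(r["T"]), 0, tolerance = 1e-12)
  expect_equal(unname(r["A"]), 0)  # input
  # doubling tau halves that node's rate
  r1 <- ode_rhs(net, defaults, c(A = 0.7, T = 0.2))
  slow <- kinetic_parameters(tau = c(T = 2))
  r2 <- ode_rhs(net, slow, c(A = 0.7, T = 0.2))
  expect_equal(unname(r2["T"]), unname(r1["T"]) / 2)
  # clamped node has rate zero
  r3 <- ode_rhs(net, defaults, c(A = 0.7, T = 0.2), clamps = "T")
  expect_equal(unname(r3["T"]), 0)
  expect_error(ode_rhs(net, defaults, c(A = 0.7, T = 0.2), clamps = "Z"),
               "unknown node")
})

test_that("integration matches the closed-form linear response", {
  net <- parse_rules("T = A")
  traj <- integrate_network(net, defaults, c(A = 1, T = 0), t_end = 10)
  xT <- traj$states[traj$times == 10, "T"]
  expect_equal(unname(xT), 1 - exp(-10), tolerance = 1e-6)
  # slower lifetime
  slow <- kinetic_parameters(tau = c(T = 4))
  traj2 <- integrate_network(net, slow, c(A = 1, T = 0), t_end = 10)
  expect_equal(unname(traj2$states[traj2$times == 10, "T"]),
               1 - exp(-10 / 4), tolerance = 1e-6)
  # trajectories stay within the unit cube
  fx <- toy_bcr_network()
  tr <- integrate_network(fx$network, fx$params,
                          scenario_initial_for_test(fx), t_end = 60)
  expect_true(all(tr$states >= 0 & tr$states <= 1))
})

test_that("clamp windows act as breakpoints: jump, hold, release", {
  net <- parse_rules("T = A")
  sched <- clamp_schedule("T", 1, 5, 10)
  traj <- integrate_network(net, defaults, c(A = 0, T = 0), schedule = sched,
                            t_end = 20)
  at <- function(t) unname(traj$states[traj$times == t, "T"])
  expect_equal(at(4), 0)          # before window: rule value is 0
  expect_equal(at(7), 1)          # clamped
  expect_equal(at(10 + 3), exp(-3), tolerance = 1e-4)  # released, decays
  expect_error(clamp_schedule(c("T", "T"), 1, c(0, 5), c(6, 10)),
               "overlapping")
  expect_error(clamp_schedule("T", 1, 5, 5), "start < end")
})

test_that("steady-state detection finds the earliest sustained quiet window", {
  net <- parse_rules("T = A")
  traj <- integrate_network(net, defaults, c(A = 1, T = 0), t_end = 40)
  ss <- find_steady_state(traj, net, defaults, tol = 1e-6, window = 10)
  expect_false(is.null(ss))
  expect_equal(unname(ss$state["T"]), 1, tolerance = 1e-4)
  # a constant trajectory qualifies at its first sample
  traj0 <- integrate_network(net, defaults, c(A = 0, T = 0), t_end = 20)
  ss0 <- find_steady_state(traj0, net, defaults, tol = 1e-6, window = 10)
  expect_equal(ss0$entered_at, 0)
})

test_that("a genuinely oscillating ring never passes a tight tolerance", {
  # 3-node negative-feedback ring at steep n: sustained oscillation
  ring <- parse_rules("X1 = !X3\nX2 = X1\nX3 = X2")
  steep <- kinetic_parameters(default_n = 20)
  traj <- integrate_network(ring, steep, c(X1 = 0, X2 = 0, X3 = 0),
                            t_end = 300)
  expect_null(find_steady_state(traj, ring, steep, tol = 1e-6, window = 10))
})

test_that("discrete fixed points are continuous steady states at steep n", {
  set.seed(5)
  steep <- kinetic_parameters(default_n = 20)
  for (seed in 1:10) {
    net <- random_network(generator_config(8, 2, seed = seed,
                                           feedback_enrichment = 0.5))
    atts <- enumerate_attractors_exhaustive(net)
    fps <- atts[vapply(atts, `[[`, numeric(1), "period") == 1]
    for (fp in fps) {
      x0 <- fp$states[1, ]
      traj <- integrate_network(net, steep, x0, t_end = 60)
      final <- traj$states[nrow(traj$states), ]
      expect_lt(max(abs(final - x0)), 0.05)
    }
  }
})

test_that("kinetic parameters round-trip through the JSON schema", {
  p <- kinetic_parameters(
    tau = c(LYN = 10, PIP2_2 = 16),
    edges = data.frame(source = c("PTPRC", "PTPN6"), target = c("LYN", "BCR"),
                       n = c(20, 32), k = c(0.9, 0.9)))
  f <- tempfile(fileext = ".json")
  write_parameters_json(p, f)
  q <- read_parameters_json(f)
  expect_equal(q$defaults, p$defaults)
  expect_equal(q$tau, p$tau)
  expect_equal(q$edges[order(q$edges$source), ],
               p$edges[order(p$edges$source), ], ignore_attr = TRUE)
  expect_error(kinetic_parameters(tau = c(A = -1)), "tau")
  expect_error(kinetic_parameters(edges = data.frame(
    source = "A", target = "B", n = 0.5, k = 0.5)), "n must be")
})
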