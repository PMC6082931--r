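fx <- toy_bcr_network()

test_that("the both-signals scenario activates every TF readout", {
  res <- run_scenario(fx$network, fx$params, fx$scenarios$both_on)
  expect_true(all(res$attractor$state[fx$tf_nodes] > 0.5))
  expect_equal(nrow(res$trajectory$events), 1)
})

test_that("signal ablations reproduce the documented fixture attractors", {
  s1 <- run_scenario(fx$network, fx$params, fx$scenarios$signal1_off)
  expect_lt(s1$attractor$state["TF1"], 0.5)
  expect_lt(s1$attractor$state["TF2"], 0.5)
  expect_gt(s1$attractor$state["TF3"], 0.5)  # costimulation-driven readout

  s2 <- run_scenario(fx$network, fx$params, fx$scenarios$signal2_off)
  expect_gt(s2$attractor$state["TF1"], 0.5)
  expect_lt(s2$attractor$state["TF2"], 0.5)
})

test_that("a scenario that cannot settle raises 'no convergence'", {
  ring <- parse_rules("X1 = !X3\nX2 = X1\nX3 = X2")
  steep <- kinetic_parameters(default_n = 20)
  scn <- scenario("ring", t_end = 120)
  expect_error(run_scenario(ring, steep, scn), "no convergence.*residual")
})

test_that("scenario construction validates inputs", {
  expect_error(scenario("bad", input_values = c(SIG1 = 2)), "\\[0, 1\\]")
  scn <- scenario("x", input_values = c(NOT_AN_INPUT = 1))
  expect_error(run_scenario(fx$network, fx$params, scn), "non-input")
})

test_that("the transient modulator protocol returns to the original attractor", {
  scn <- scenario("basin", input_values = c(SIG1 = 1, SIG2 = 1, MOD_IN = 0),
                  t_end = 320)
  res <- run_basin_protocol(fx$network, fx$params, scn, fx$modulators,
                            window = c(110, 210))
  expect_equal(res$trajectory$events$label,
               c("activating_attractor", "modulated_attractor",
                 "released_attractor"))
  expect_true(res$reentered)
  # during modulation the relay-dependent TFs are silenced
  mod <- res$attractors$modulated$state
  expect_true(all(mod[fx$relay_dependent_tfs] < 0.5))
  # empty modulator set: one attractor, no basin excursion
  res0 <- run_basin_protocol(fx$network, fx$params, scn, character(0),
                             window = c(110, 210))
  states <- lapply(res0$attractors, `[[`, "state")
  expect_lt(max(abs(states$activating - states$released)), 1e-3)
  expect_error(run_basin_protocol(fx$network, fx$params, scn, "NOPE",
                                  window = c(110, 210)), "not in network")
})

test_that("the knockout panel clamps dominate and wild-type is reproducible", {
  panel <- list(perturbation("RELAY-KO", "RELAY", 0),
                perturbation("COREC-KI", "COREC", 1),
                perturbation("INH-KI", "INH", 1))
  mat <- run_pid_panel(fx$network, fx$params, fx$scenarios$both_on, panel)
  expect_true("wild-type" %in% rownames(mat))
  expect_equal(mat["RELAY-KO", "RELAY"], 0)
  expect_equal(mat["COREC-KI", "COREC"], 1)
  # relay KO silences the relay-dependent TF columns
  expect_true(all(mat["RELAY-KO", fx$relay_dependent_tfs] < 0.5))
  # wild-type row identical to a standalone run
  wt <- run_scenario(fx$network, fx$params, fx$scenarios$both_on)
  expect_equal(unname(mat["wild-type", ]),
               unname(wt$attractor$state[colnames(mat)]))
  # knockin of a node already active in the wild type changes nothing much
  expect_equal(mat["COREC-KI", ], mat["wild-type", ], tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(
    run_pid_panel(fx$network, fx$params, fx$scenarios$both_on,
                  list(perturbation("X-KO", "NOPE", 0))),
    "unknown node")
})

test_that("wild-type comparison reports dysregulated nodes and flips", {
  panel <- list(perturbation("RELAY-KO", "RELAY", 0))
  mat <- run_pid_panel(fx$network, fx$params, fx$scenarios$both_on, panel)
  rep <- compare_to_wildtype(mat, threshold = 0.1)
  # oracle: exhaustive discrete attractors with and without the clamp
  clamps_wt <- c(SIG1 = 1, SIG2 = 1, MOD_IN = 0)
  wt_att <- enumerate_attractors_exhaustive(fx$network, clamps = clamps_wt)
  ko_att <- enumerate_attractors_exhaustive(fx$network,
                                            clamps = c(clamps_wt, RELAY = 0))
  expect_length(wt_att, 1); expect_length(ko_att, 1)
  diff_nodes <- names(which(wt_att[[1]]$states[1, ] != ko_att[[1]]$states[1, ]))
  expect_setequal(rep$node, diff_nodes)
  expect_true(all(rep$flipped))

  # identical rows produce an empty report
  mat2 <- mat
  mat2["RELAY-KO", ] <- mat2["wild-type", ]
  expect_equal(nrow(compare_to_wildtype(mat2)), 0)

  # single-column difference reported with its flip
  mat3 <- mat
  mat3["RELAY-KO", ] <- mat3["wild-type", ]
  mat3["RELAY-KO", "TF1"] <- 0.1
  mat3["wild-type", "TF1"] <- 0.9
  r3 <- compare_to_wildtype(mat3, threshold = 0.1)
  expect_equal(r3$node, "TF1")
  expect_true(r3$flipped)
})

test_that("the default PID panel matches the published perturbation set", {
  panel <- default_pid_panel()
  expect_gte(length(panel), 22)
  names_ <- vapply(panel, `[[`, character(1), "name")
  nodes_ <- vapply(panel, `[[`, character(1), "node")
  clamp_ <- vapply(panel, `[[`, numeric(1), "clamp_value")
  # CARD11 appears as LOF (0) and GOF (1)
  expect_setequal(clamp_[nodes_ == "CARD11"], c(0, 1))
  expect_setequal(clamp_[nodes_ == "NFKBIA"], c(0, 1))
  # knockins per the published panel
  expect_equal(sort(nodes_[clamp_ == 1]),
               sort(c("CARD11", "KRAS", "NFKBIA", "PI3K")))
  expect_true(all(c("BTK", "BLNK", "CD19", "WIPF1", "PTPRC", "LYN") %in%
                  nodes_[clamp_ == 0]))
  # filtering against a network lacking the panel nodes warns and drops
  w <- testthat::capture_warnings(small <- default_pid_panel(fx$network))
  expect_true(length(w) > 0 && all(grepl("not in network; dropped", w)))
  expect_length(small, 0)
})
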