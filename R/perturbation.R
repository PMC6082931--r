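#' In silico perturbation pipeline
#'
#' Wild-type, signal-ablation and knockout/knockin simulations of a logic
#' model under the normalized HillCube dynamics, with attractor comparison.
#' A knockout clamps a node to 0 for the whole run, a knockin to 1 — the node
#' is effectively converted to an input and held, while all kinetic
#' parameters stay at their wild-type values.
#'
#' @name perturbation_pipeline
NULL

#' Define a simulation scenario
#'
#' @param name scenario label.
#' @param input_values named activities for the network's input nodes
#'   (unlisted inputs default to 0).
#' @param initial_overrides named initial activities for non-input nodes
#'   (everything else starts at 0).
#' @param schedule a [clamp_schedule()] applied during the run, or `NULL`.
#' @param t_end simulation end time.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, input_values = numeric(0),
                     initial_overrides = numeric(0), schedule = NULL,
                     t_end = 200) {
  if (is.list(input_values)) input_values <- unlist(input_values)
  if (is.list(initial_overrides)) initial_overrides <- unlist(initial_overrides)
  if (length(input_values) && any(input_values < 0 | input_values > 1)) {
    stop("input values must lie in [0, 1]")
  }
  structure(list(name = name, input_values = input_values,
                 initial_overrides = initial_overrides,
                 schedule = schedule, t_end = t_end),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> '%s', t_end=%g", x$name, x$t_end))
  if (length(x$input_values)) {
    cat("; inputs:", paste(sprintf("%s=%g", names(x$input_values),
                                   x$input_values), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Read a scenario from JSON
#'
#' Schema: `{"name":.., "input_values":{..}, "initial_overrides":{..},
#' "t_end":.., "clamps":[{"node":..,"value":..,"start":..,"end":..}]}`
#' (an `end` of `null` or `"Inf"` means until the end of the run).
#'
#' @param path JSON file path.
#' @return A [scenario()].
#' @export
read_scenario_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  sched <- NULL
  if (!is.null(j$clamps) && length(j$clamps)) {
    ends <- j$clamps$end
    if (is.null(ends)) ends <- rep(Inf, nrow(j$clamps))
    ends <- suppressWarnings(as.numeric(ends))
    ends[is.na(ends)] <- Inf
    sched <- clamp_schedule(j$clamps$node, j$clamps$value, j$clamps$start, ends)
  }
  scenario(
    name = if (is.null(j$name)) "scenario" else j$name,
    input_values = unlist(j$input_values),
    initial_overrides = unlist(j$initial_overrides),
    schedule = sched,
    t_end = if (is.null(j$t_end)) 200 else j$t_end
  )
}

scenario_initial <- function(network, scn) {
  init <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  iv <- scn$input_values
  if (length(iv)) {
    bad <- setdiff(names(iv), network$inputs)
    if (length(bad)) {
      stop("input_values for non-input node: ", paste(bad, collapse = ", "))
    }
    init[names(iv)] <- iv
  }
  ov <- scn$initial_overrides
  if (length(ov)) {
    unknown <- setdiff(names(ov), network$nodes)
    if (length(unknown)) stop("initial override for unknown node: ",
                              paste(unknown, collapse = ", "))
    init[names(ov)] <- ov
  }
  init
}

#' Run a scenario to its point attractor
#'
#' Integrates the normalized HillCube system with inputs held at the
#' scenario's values and returns the detected point attractor; errors with
#' the final residual if none is reached by `t_end`.
#'
#' @param network a [boolean_network()].
#' @param params a [kinetic_parameters()].
#' @param scn a [scenario()].
#' @param tol,window steady-state detection settings (see
#'   [find_steady_state()]).
#' @param sample_dt sampling interval.
#' @return List with `trajectory` and `attractor`.
#' @export
run_scenario <- function(network, params, scn, tol = 1e-6, window = 10,
                         sample_dt = 1) {
  stopifnot(inherits(scn, "scenario"))
  init <- scenario_initial(network, scn)
  traj <- integrate_network(network, params, init, schedule = scn$schedule,
                            t_end = scn$t_end, sample_dt = sample_dt)
  att <- find_steady_state(traj, network, params, tol = tol, window = window)
  if (is.null(att)) {
    compiled <- compile_model(network, params)
    final <- traj$states[nrow(traj$states), ]
    clamps <- active_clamps(traj$schedule, max(traj$times))
    resid <- max(abs(rhs_compiled(compiled, final, compiled$idx[names(clamps)])))
    stop(sprintf("no convergence in scenario '%s' by t=%g (final residual %.3g)",
                 scn$name, scn$t_end, resid))
  }
  traj$events <- rbind(traj$events,
                       data.frame(time = att$entered_at, label = "attractor"))
  list(trajectory = traj, attractor = att)
}

#' Transient-modulator basin protocol
#'
#' Three phases: (1) free run into the activating attractor; (2) the
#' modulator nodes clamped to 1 during `[window[1], window[2]]`, driving the
#' system into a modulated attractor; (3) release and continued run until an
#' attractor is re-entered. The returned trajectory's `events` records every
#' attractor entry, so re-entry into the original basin can be checked.
#'
#' @inheritParams run_scenario
#' @param modulators character vector of nodes transiently clamped to 1.
#' @param window numeric length-2: clamp start and end times.
#' @param tol,ss_window steady-state detection settings.
#' @return List with `trajectory` (events annotated), `attractors` (one per
#'   phase; `NULL` where none detected) and `reentered` (logical: final
#'   attractor within 0.05 per node of the phase-1 attractor).
#' @export
run_basin_protocol <- function(network, params, scn, modulators, window,
                               tol = 1e-6, ss_window = 10, sample_dt = 1) {
  stopifnot(length(window) == 2, window[1] < window[2],
            window[2] < scn$t_end)
  bad <- setdiff(modulators, network$nodes)
  if (length(bad)) stop("modulators not in network: ", paste(bad, collapse = ", "))
  sched <- scn$schedule
  if (length(modulators)) {
    mod_sched <- clamp_schedule(modulators, 1, window[1], window[2])
    sched <- if (is.null(sched)) mod_sched else
      clamp_schedule(c(sched$node, mod_sched$node),
                     c(sched$value, mod_sched$value),
                     c(sched$start, mod_sched$start),
                     c(sched$end, mod_sched$end))
  }
  init <- scenario_initial(network, scn)
  traj <- integrate_network(network, params, init, schedule = sched,
                            t_end = scn$t_end, sample_dt = sample_dt)
  phases <- list(activating = c(0, window[1]),
                 modulated = c(window[1], window[2]),
                 released = c(window[2], scn$t_end))
  atts <- lapply(phases, function(ph) {
    find_steady_state(traj, network, params, tol = tol, window = ss_window,
                      from = ph[1], to = ph[2])
  })
  ev <- data.frame(time = numeric(0), label = character(0))
  for (nm in names(atts)) {
    if (!is.null(atts[[nm]])) {
      ev <- rbind(ev, data.frame(time = atts[[nm]]$entered_at,
                                 label = paste0(nm, "_attractor")))
    }
  }
  traj$events <- ev
  reentered <- !is.null(atts$activating) && !is.null(atts$released) &&
    max(abs(atts$activating$state - atts$released$state)) < 0.05
  list(trajectory = traj, attractors = atts, reentered = reentered)
}

#' Define a single knockout/knockin perturbation
#'
#' @param name label, e.g. `"BTK-KO"` or `"CARD11-GOF"`.
#' @param node the clamped node.
#' @param clamp_value 0 (knockout, loss of function) or 1 (knockin,
#'   constitutive activity).
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(name, node, clamp_value) {
  stopifnot(clamp_value %in% c(0, 1))
  structure(list(name = name, node = node, clamp_value = clamp_value),
            class = "perturbation")
}

#' The default primary-immunodeficiency perturbation panel
#'
#' Knockouts (clamp 0): BCL10, BLNK, BTK, CARD11 (LOF), CD19, CD21, CD40,
#' CD81, IKKB, LYN, MALT1, MS4A1, NEMO, NFKB1, NFKBIA (LOF), ORAI1, PLCG2,
#' PTPRC, STIM1, WIPF1. Knockins (clamp 1): CARD11 (GOF), KRAS, NFKBIA (GOF),
#' PI3K. LYN stands in for the Src-family kinases (BLK).
#'
#' @param network optional [boolean_network()]; when given, entries whose
#'   node is absent are dropped with a warning each.
#' @return List of [perturbation()] objects (24 when unfiltered).
#' @export
default_pid_panel <- function(network = NULL) {
  ko <- c(BCL10 = "BCL10", BLNK = "BLNK", BTK = "BTK",
          `CARD11-LOF` = "CARD11", CD19 = "CD19", CD21 = "CD21",
          CD40 = "CD40", CD81 = "CD81", IKKB = "IKKB", LYN = "LYN",
          MALT1 = "MALT1", MS4A1 = "MS4A1", NEMO = "NEMO", NFKB1 = "NFKB1",
          `NFKBIA-LOF` = "NFKBIA", ORAI1 = "ORAI1", PLCG2 = "PLCG2",
          PTPRC = "PTPRC", STIM1 = "STIM1", WIPF1 = "WIPF1")
  ki <- c(`CARD11-GOF` = "CARD11", KRAS = "KRAS", `NFKBIA-GOF` = "NFKBIA",
          PI3K = "PI3K")
  panel <- c(
    lapply(seq_along(ko), function(i)
      perturbation(paste0(names(ko)[i], if (!grepl("-", names(ko)[i])) "-KO" else ""),
                   ko[[i]], 0)),
    lapply(seq_along(ki), function(i)
      perturbation(paste0(names(ki)[i], if (!grepl("-", names(ki)[i])) "-KI" else ""),
                   ki[[i]], 1))
  )
  if (!is.null(network)) {
    keep <- vapply(panel, function(p) {
      ok <- p$node %in% network$nodes
      if (!ok) warning("panel node '", p$node, "' not in network; dropped",
                       call. = FALSE)
      ok
    }, logical(1))
    panel <- panel[keep]
  }
  panel
}

#' Run a perturbation panel and collect the attractor matrix
#'
#' Row 0 is the wild-type attractor of the base scenario; each subsequent row
#' is the attractor with one node clamped for the entire run (same kinetic
#' parameters throughout). Rows that fail to converge are kept as `NA` with a
#' note; the remaining rows are still computed.
#'
#' @inheritParams run_scenario
#' @param base_scenario the wild-type [scenario()].
#' @param panel list of [perturbation()] objects.
#' @return An `attractor_matrix`: numeric matrix (rows = "wild-type" +
#'   perturbation labels, columns = nodes) with attribute `notes` (character
#'   vector of per-row convergence problems, if any).
#' @export
run_pid_panel <- function(network, params, base_scenario, panel,
                          tol = 1e-6, window = 10, sample_dt = 1) {
  stopifnot(length(panel) >= 1)
  for (p in panel) {
    if (!p$node %in% network$nodes) {
      stop("perturbation '", p$name, "' targets unknown node '", p$node, "'")
    }
  }
  labels <- c("wild-type", vapply(panel, `[[`, character(1), "name"))
  mat <- matrix(NA_real_, nrow = length(labels), ncol = length(network$nodes),
                dimnames = list(labels, network$nodes))
  notes <- character(0)
  wt <- run_scenario(network, params, base_scenario, tol = tol,
                     window = window, sample_dt = sample_dt)
  mat["wild-type", ] <- wt$attractor$state[network$nodes]
  for (p in panel) {
    scn_p <- base_scenario
    extra <- clamp_schedule(p$node, p$clamp_value, 0, Inf)
    sched <- scn_p$schedule
    scn_p$schedule <- if (is.null(sched)) extra else
      clamp_schedule(c(sched$node, extra$node), c(sched$value, extra$value),
                     c(sched$start, extra$start), c(sched$end, extra$end))
    scn_p$name <- paste0(base_scenario$name, "/", p$name)
    row <- tryCatch({
      res <- run_scenario(network, params, scn_p, tol = tol, window = window,
                          sample_dt = sample_dt)
      res$attractor$state[network$nodes]
    }, error = function(e) {
      notes <<- c(notes, paste0(p$name, ": ", conditionMessage(e)))
      rep(NA_real_, length(network$nodes))
    })
    mat[p$name, ] <- row
  }
  structure(mat, notes = notes, class = c("attractor_matrix", "matrix", "array"))
}

#' @export
print.attractor_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<attractor_matrix> %d rows x %d nodes\n", nrow(x), ncol(x)))
  print(round(unclass(x), digits))
  notes <- attr(x, "notes")
  if (length(notes)) cat("notes:", paste(notes, collapse = "; "), "\n")
  invisible(x)
}

#' Compare perturbed attractors with the wild type
#'
#' Reports, per perturbation, the nodes whose attractor activity differs from
#' the wild type by more than `threshold`, and whether the node flips across
#' the 0.5 on/off cut.
#'
#' @param matrix an `attractor_matrix` from [run_pid_panel()].
#' @param threshold continuous dysregulation threshold (default 0.1).
#' @return data.frame with columns `perturbation`, `node`, `wildtype`,
#'   `perturbed`, `delta`, `flipped`; zero rows if nothing is dysregulated.
#' @export
compare_to_wildtype <- function(matrix, threshold = 0.1) {
  stopifnot(inherits(matrix, "attractor_matrix"),
            "wild-type" %in% rownames(matrix))
  wt <- matrix["wild-type", ]
  rows <- setdiff(rownames(matrix), "wild-type")
  out <- list()
  for (r in rows) {
    v <- matrix[r, ]
    if (anyNA(v)) next
    delta <- v - wt
    hit <- which(abs(delta) > threshold)
    if (!length(hit)) next
    out[[r]] <- data.frame(
      perturbation = r, node = colnames(matrix)[hit],
      wildtype = unname(wt[hit]), perturbed = unname(v[hit]),
      delta = unname(delta[hit]),
      flipped = unname((wt[hit] >= 0.5) != (v[hit] >= 0.5)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(perturbation = character(0), node = character(0),
                      wildtype = numeric(0), perturbed = numeric(0),
                      delta = numeric(0), flipped = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an attractor matrix as TSV
#'
#' @param matrix an `attractor_matrix`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_attractor_matrix_tsv <- function(matrix, path) {
  df <- data.frame(perturbation = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
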