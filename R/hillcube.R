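#' Continuous semi-quantitative dynamics (normalized HillCube)
#'
#' The logic model is relaxed to ODEs: each rule B_i is interpolated over the
#' unit hypercube (the BooleCube), each regulator activity is first passed
#' through a normalized Hill function f(x)/f(1) with f(x) = x^n / (x^n + k^n),
#' and every node relaxes toward its rule value with lifetime tau:
#' dx_i/dt = (B_i(x) - x_i) / tau_i. At Boolean corner inputs the normalized
#' HillCube reproduces the discrete rule exactly, so discrete fixed points are
#' continuous equilibria when the logic is steep.
#'
#' @name hillcube_dynamics
NULL

#' Hill activation function
#'
#' `f(x) = x^n / (x^n + k^n)`: monotone increasing, `f(0) = 0`, `f(k) = 1/2`.
#'
#' @param x activity in \[0, 1\].
#' @param n Hill coefficient (cooperativity), `n >= 1`.
#' @param k half-maximal activation threshold, strictly inside (0, 1).
#' @return Activity in \[0, 1\].
#' @export
hill <- function(x, n, k) {
  if (any(x < 0 | x > 1)) stop("hill(): x must lie in [0, 1]")
  if (any(n < 1)) stop("hill(): n must be >= 1")
  if (any(k <= 0 | k >= 1)) stop("hill(): k must lie strictly in (0, 1)")
  xn <- x^n
  xn / (xn + k^n)
}

#' Kinetic parameters for the HillCube transform
#'
#' Hill pairs (n, k) are per regulatory edge (source -> target) and lifetimes
#' tau are per target node; anything unlisted falls back to the defaults
#' n = 3, k = 0.5, tau = 1 (arbitrary time units).
#'
#' @param tau named numeric vector of per-node lifetimes (> 0).
#' @param edges data.frame with columns `source`, `target`, `n`, `k` giving
#'   per-edge overrides.
#' @param default_n,default_k,default_tau fallback values.
#' @return An object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(tau = numeric(0), edges = NULL,
                               default_n = 3, default_k = 0.5,
                               default_tau = 1) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        n = numeric(0), k = numeric(0))
  }
  stopifnot(all(c("source", "target", "n", "k") %in% names(edges)))
  if (any(tau <= 0) || default_tau <= 0) stop("all tau must be > 0")
  if (any(edges$n < 1) || default_n < 1) stop("all n must be >= 1")
  if (any(edges$k <= 0 | edges$k >= 1) || default_k <= 0 || default_k >= 1) {
    stop("all k must lie strictly in (0, 1)")
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (source, target) parameter entries")
  structure(
    list(tau = tau, edges = edges,
         n_lookup = stats::setNames(edges$n, key),
         k_lookup = stats::setNames(edges$k, key),
         defaults = list(n = default_n, k = default_k, tau = default_tau)),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf("<kinetic_parameters> defaults n=%g k=%g tau=%g; %d edge overrides, %d tau overrides\n",
              x$defaults$n, x$defaults$k, x$defaults$tau,
              nrow(x$edges), length(x$tau)))
  invisible(x)
}

get_tau <- function(params, node) {
  v <- params$tau[node]
  ifelse(is.na(v), params$defaults$tau, v)
}

get_nk <- function(params, source, target) {
  key <- paste(source, target, sep = "\r")
  n <- params$n_lookup[key]
  k <- params$k_lookup[key]
  list(n = ifelse(is.na(n), params$defaults$n, unname(n)),
       k = ifelse(is.na(k), params$defaults$k, unname(k)))
}

#' Read/write kinetic parameters as JSON
#'
#' Schema: `{"defaults": {"n":..,"k":..,"tau":..},
#' "edges": [{"source":..,"target":..,"n":..,"k":..}],
#' "nodes": [{"name":..,"tau":..}]}`.
#'
#' @param path JSON file path.
#' @return A [kinetic_parameters()] object.
#' @export
read_parameters_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  d <- j$defaults
  tau <- numeric(0)
  if (!is.null(j$nodes) && length(j$nodes)) {
    tau <- stats::setNames(j$nodes$tau, j$nodes$name)
  }
  edges <- j$edges
  if (is.null(edges) || !length(edges)) edges <- NULL
  kinetic_parameters(
    tau = tau, edges = edges,
    default_n = if (is.null(d$n)) 3 else d$n,
    default_k = if (is.null(d$k)) 0.5 else d$k,
    default_tau = if (is.null(d$tau)) 1 else d$tau
  )
}

#' @param params a [kinetic_parameters()] object.
#' @rdname read_parameters_json
#' @export
write_parameters_json <- function(params, path) {
  obj <- list(
    defaults = params$defaults,
    edges = params$edges,
    nodes = if (length(params$tau)) {
      data.frame(name = names(params$tau), tau = unname(params$tau))
    } else NULL
  )
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' BooleCube: multilinear interpolation of a Boolean rule
#'
#' Evaluates the unique multilinear polynomial agreeing with the rule at all
#' Boolean corners; equivalently, the probability the rule is true when every
#' regulator is an independent Bernoulli with the given activity. Computed by
#' Shannon expansion (conditioning on one regulator at a time), which is exact
#' and avoids enumerating corners.
#'
#' @param rule a [boolean_rule()].
#' @param state named numeric vector of activities in \[0, 1\] covering the
#'   rule's regulators.
#' @return Activity in \[0, 1\].
#' @export
boolecube <- function(rule, state) {
  if (is.list(state)) state <- unlist(state)
  sop_multilinear(rule$clauses, state)
}

# Shannon expansion over SOP clause lists. clauses: list of named logical
# vectors. Terminal cases: no clauses -> 0; any empty clause -> 1.
sop_multilinear <- function(clauses, x) {
  if (!length(clauses)) return(0)
  if (any(lengths(clauses) == 0L)) return(1)
  v <- names(clauses[[1]])[1]
  pos <- match(v, names(x))
  if (is.na(pos)) stop("state missing regulator '", v, "'")
  xv <- x[[pos]]
  if (is.na(xv)) stop("state missing regulator '", v, "'")
  cond <- function(value) {
    out <- list()
    for (cl in clauses) {
      if (v %in% names(cl)) {
        sat <- if (cl[[v]]) value == 0 else value == 1
        if (!sat) next            # literal false: clause drops
        cl <- cl[names(cl) != v]  # literal true: remove it
      }
      out[[length(out) + 1L]] <- cl
    }
    out
  }
  hi <- sop_multilinear(cond(1), x)
  if (xv == 1) return(hi)
  lo <- sop_multilinear(cond(0), x)
  xv * hi + (1 - xv) * lo
}

#' Normalized HillCube evaluation of a rule
#'
#' Each regulator activity is transformed by `hill(x, n, k) / hill(1, n, k)`
#' (so that an activity of exactly 1 maps to 1) before the BooleCube is
#' evaluated; the result therefore equals the Boolean rule at every corner.
#'
#' @inheritParams boolecube
#' @param params a [kinetic_parameters()]; Hill pairs are resolved per edge
#'   (regulator -> `target`), falling back to the defaults.
#' @param target name of the regulated node (identifies the edges).
#' @return Activity in \[0, 1\].
#' @export
normalized_hillcube <- function(rule, state, params, target = rule$target) {
  if (is.list(state)) state <- unlist(state)
  sources <- unique(unlist(lapply(rule$clauses, names)))
  tx <- state
  for (s in sources) {
    nk <- get_nk(params, s, target)
    tx[[s]] <- hill(state[[s]], nk$n, nk$k) / hill(1, nk$n, nk$k)
  }
  sop_multilinear(rule$clauses, tx)
}

# Precompile a network for fast repeated RHS evaluation: per regulated node,
# the clause list, regulator indices, Hill parameters, and 1/f(1) factors.
compile_model <- function(network, params) {
  nodes <- network$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  compiled <- lapply(network$rules, function(r) {
    sources <- unique(unlist(lapply(r$clauses, names)))
    nk <- lapply(sources, function(s) get_nk(params, s, r$target))
    n <- vapply(nk, `[[`, numeric(1), "n")
    k <- vapply(nk, `[[`, numeric(1), "k")
    list(
      target_i = idx[[r$target]],
      clauses = r$clauses,
      src = sources,
      src_i = idx[sources],
      n = n, k = k,
      inv_f1 = 1 + k^n,    # 1 / f(1)
      tau = unname(get_tau(params, r$target))
    )
  })
  list(nodes = nodes, idx = idx, rules = compiled,
       input_i = idx[network$inputs])
}

rhs_compiled <- function(compiled, x, clamped_i = integer(0)) {
  x <- pmin(pmax(x, 0), 1)
  dx <- numeric(length(x))
  for (cr in compiled$rules) {
    if (cr$target_i %in% clamped_i) next
    xs <- x[cr$src_i]
    xn <- xs^cr$n
    f <- (xn / (xn + cr$k^cr$n)) * cr$inv_f1
    names(f) <- cr$src
    b <- sop_multilinear(cr$clauses, f)
    dx[cr$target_i] <- (b - x[cr$target_i]) / cr$tau
  }
  dx
}

#' Right-hand side of the normalized HillCube ODE system
#'
#' Rate of node i is `(B_i(x) - x_i) / tau_i` where B_i is the node's
#' normalized HillCube; input nodes and clamped nodes have rate 0.
#'
#' @param network a [boolean_network()].
#' @param params a [kinetic_parameters()].
#' @param state named numeric activities covering all nodes.
#' @param clamps character vector of clamped node names (their rates are 0),
#'   or a named numeric vector (names are used).
#' @return Named numeric rate vector in node order.
#' @export
ode_rhs <- function(network, params, state, clamps = NULL) {
  if (is.list(state)) state <- unlist(state)
  compiled <- compile_model(network, params)
  clamp_names <- if (is.null(clamps)) character(0)
                 else if (!is.null(names(clamps)) && !is.character(clamps)) names(clamps)
                 else as.character(clamps)
  unknown <- setdiff(clamp_names, network$nodes)
  if (length(unknown)) stop("clamp on unknown node: ", paste(unknown, collapse = ", "))
  x <- state[network$nodes]
  dx <- rhs_compiled(compiled, x, clamped_i = compiled$idx[clamp_names])
  stats::setNames(dx, network$nodes)
}

#' Clamp schedules
#'
#' A clamp schedule holds a node at a fixed activity over a time window
#' \[start, end); `end = Inf` clamps to the end of the run. Windows for the
#' same node must not overlap.
#'
#' @param node character vector of node names.
#' @param value activities in \[0, 1\] (recycled).
#' @param start,end window bounds (recycled); `start < end`.
#' @return A `clamp_schedule` data.frame with columns `node`, `value`,
#'   `start`, `end`.
#' @export
clamp_schedule <- function(node = character(0), value = numeric(0),
                           start = numeric(0), end = numeric(0)) {
  df <- data.frame(node = node, value = value, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start >= df$end)) stop("clamp window must have start < end")
    if (any(df$value < 0 | df$value > 1)) stop("clamp values must lie in [0, 1]")
    for (nd in unique(df$node)) {
      w <- df[df$node == nd, , drop = FALSE]
      w <- w[order(w$start), , drop = FALSE]
      if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)])) {
        stop("overlapping clamp windows for node '", nd, "'")
      }
    }
  }
  class(df) <- c("clamp_schedule", "data.frame")
  df
}

active_clamps <- function(schedule, t) {
  if (is.null(schedule) || !nrow(schedule)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  act <- schedule[schedule$start <= t & t < schedule$end, , drop = FALSE]
  stats::setNames(act$value, act$node)
}

#' Integrate the normalized HillCube ODE system
#'
#' Adaptive integration (deSolve, lsoda) of the relaxed logic model, with
#' clamp windows treated as integration breakpoints: at a window start the
#' clamped node jumps to its clamp value and is frozen; at the window end it
#' resumes relaxing from that value. Sampled at multiples of `sample_dt`, so
#' one sample corresponds to one "update" of the discrete picture.
#'
#' @inheritParams ode_rhs
#' @param initial named numeric initial activities covering all nodes.
#' @param schedule a [clamp_schedule()] or `NULL`.
#' @param t_end end time (> 0).
#' @param sample_dt sampling interval (default 1 time unit).
#' @param rtol,atol integrator tolerances.
#' @return A `trajectory`: list with `times`, `states` (matrix, rows = sample
#'   times, columns = nodes), `schedule`, and an `events` data.frame that
#'   downstream protocols annotate with attractor entries.
#' @export
integrate_network <- function(network, params, initial, schedule = NULL,
                              t_end, sample_dt = 1, rtol = 1e-6, atol = 1e-6) {
  stopifnot(t_end > 0, sample_dt > 0)
  if (is.list(initial)) initial <- unlist(initial)
  missing <- setdiff(network$nodes, names(initial))
  if (length(missing)) {
    stop("initial state does not cover nodes: ", paste(missing, collapse = ", "))
  }
  if (!is.null(schedule) && nrow(schedule)) {
    unknown <- setdiff(schedule$node, network$nodes)
    if (length(unknown)) stop("clamp on unknown node: ", paste(unknown, collapse = ", "))
  }
  compiled <- compile_model(network, params)
  y <- pmin(pmax(as.numeric(initial[network$nodes]), 0), 1)
  names(y) <- network$nodes

  breaks <- sort(unique(c(0, t_end,
    if (!is.null(schedule) && nrow(schedule))
      c(schedule$start, schedule$end[is.finite(schedule$end)]))))
  breaks <- breaks[breaks >= 0 & breaks <= t_end]

  all_times <- 0
  all_states <- matrix(y, nrow = 1, dimnames = list(NULL, network$nodes))
  for (seg in seq_len(length(breaks) - 1)) {
    t0 <- breaks[seg]; t1 <- breaks[seg + 1]
    clamps <- active_clamps(schedule, t0)
    if (length(clamps)) y[names(clamps)] <- clamps
    clamped_i <- compiled$idx[names(clamps)]
    lo <- ceiling(t0 / sample_dt); hi <- floor(t1 / sample_dt)
    mids <- if (lo <= hi) seq(lo, hi) * sample_dt else numeric(0)
    times <- unique(c(t0, mids, t1))
    times <- sort(times[times >= t0 & times <= t1])
    if (length(times) < 2) times <- c(t0, t1)
    func <- function(t, y, parms) {
      list(rhs_compiled(compiled, y, clamped_i))
    }
    sol <- deSolve::ode(y = y, times = times, func = func, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("integrator failure at time ", utils::tail(sol[, 1], 1))
    }
    states <- sol[, -1, drop = FALSE]
    states <- pmin(pmax(states, 0), 1)
    y <- stats::setNames(as.numeric(states[nrow(states), ]), network$nodes)
    keep <- sol[, 1] > t0
    all_times <- c(all_times, sol[keep, 1])
    all_states <- rbind(all_states, states[keep, , drop = FALSE])
  }
  rownames(all_states) <- NULL
  structure(
    list(times = all_times, states = all_states,
         schedule = if (is.null(schedule)) clamp_schedule() else schedule,
         events = data.frame(time = numeric(0), label = character(0))),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples over [%g, %g], %d nodes",
              length(x$times), min(x$times), max(x$times), ncol(x$states)))
  if (nrow(x$events)) {
    cat("; events:", paste(sprintf("%s@%g", x$events$label, x$events$time),
                           collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Detect a point attractor on a sampled trajectory
#'
#' Finds the earliest sample time from which the residual `max |dx/dt|`
#' (computed with the clamps active at each sample) stays below `tol`
#' continuously for at least `window` time units.
#'
#' @param trajectory a `trajectory` from [integrate_network()].
#' @inheritParams ode_rhs
#' @param tol steady-state tolerance on the max-norm of the rate vector.
#' @param window duration the residual must stay below `tol`.
#' @param from,to optional restriction of the search interval.
#' @return A `continuous_attractor` (fields `state`, `entered_at`, `kind`,
#'   `residual`) or `NULL` if no window qualifies.
#' @export
find_steady_state <- function(trajectory, network, params, tol = 1e-6,
                              window = 10, from = -Inf, to = Inf) {
  stopifnot(inherits(trajectory, "trajectory"), length(trajectory$times) > 0)
  compiled <- compile_model(network, params)
  sel <- which(trajectory$times >= from & trajectory$times <= to)
  times <- trajectory$times[sel]
  res <- vapply(sel, function(i) {
    clamps <- active_clamps(trajectory$schedule, trajectory$times[i])
    x <- trajectory$states[i, ]
    max(abs(rhs_compiled(compiled, x, compiled$idx[names(clamps)])))
  }, numeric(1))
  ok <- res < tol
  n <- length(times)
  i <- 1L
  while (i <= n) {
    if (ok[i]) {
      j <- i
      while (j < n && ok[j + 1]) j <- j + 1
      if (times[j] - times[i] >= window ||
          (j == n && ok[n] && times[n] - times[i] >= window)) {
        return(structure(
          list(state = stats::setNames(trajectory$states[sel[i], ],
                                       colnames(trajectory$states)),
               entered_at = times[i], kind = "point", residual = res[i]),
          class = "continuous_attractor"))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  NULL
}

#' @export
print.continuous_attractor <- function(x, digits = 3, ...) {
  cat(sprintf("<continuous_attractor> point attractor entered at t=%g (residual %.2g)\n",
              x$entered_at, x$residual))
  print(round(x$state, digits))
  invisible(x)
}
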