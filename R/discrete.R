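#' Discrete synchronous Boolean dynamics
#'
#' The synchronous update maps a 0/1 state vector x(t) to x(t+1) by evaluating
#' every rule on the old state at once. Input nodes (no rule) hold their
#' value; clamped nodes are overridden with the clamp value. These exact
#' discrete semantics serve as the oracle against which the continuous
#' HillCube engine is validated.
#'
#' @name discrete_dynamics
NULL

as_discrete_state <- function(network, state) {
  if (is.list(state)) state <- unlist(state)
  missing <- setdiff(network$nodes, names(state))
  if (length(missing)) {
    stop("state does not cover nodes: ", paste(missing, collapse = ", "))
  }
  s <- as.integer(state[network$nodes])
  if (any(is.na(s)) || any(!s %in% c(0L, 1L))) {
    stop("discrete state values must be 0 or 1")
  }
  stats::setNames(s, network$nodes)
}

check_clamps <- function(network, clamps) {
  if (is.null(clamps) || !length(clamps)) return(stats::setNames(integer(0), character(0)))
  if (is.list(clamps)) clamps <- unlist(clamps)
  unknown <- setdiff(names(clamps), network$nodes)
  if (length(unknown)) {
    stop("clamp on unknown node: ", paste(unknown, collapse = ", "))
  }
  clamps
}

#' One synchronous Boolean update step
#'
#' @param network a [boolean_network()].
#' @param state named 0/1 vector covering all nodes.
#' @param clamps optional named 0/1 vector; clamped nodes override their rule
#'   (and input nodes their held value).
#' @return The successor state (named integer 0/1 vector in node order).
#' @export
sync_step <- function(network, state, clamps = NULL) {
  state <- as_discrete_state(network, state)
  clamps <- check_clamps(network, clamps)
  new <- state
  for (r in network$rules) {
    new[r$target] <- eval_rule(r, state)
  }
  if (length(clamps)) new[names(clamps)] <- as.integer(clamps)
  new
}

#' Simulate the synchronous dynamics until a state revisit
#'
#' Iterates [sync_step()] and detects the first revisited state; the segment
#' between the two visits is the attractor (a fixed point when the period
#' is 1).
#'
#' @inheritParams sync_step
#' @param initial named 0/1 starting state.
#' @param max_steps maximum number of update steps; default guarantees
#'   detection for networks with at most 20 nodes.
#' @return A list with `trajectory` (matrix, rows = time 0..t, columns =
#'   nodes) and `attractor` (a `discrete_attractor` or `NULL` if `max_steps`
#'   was exhausted without a revisit).
#' @export
simulate_discrete <- function(network, initial, clamps = NULL,
                              max_steps = 2^min(length(network$nodes), 20) + 1) {
  stopifnot(max_steps >= 1)
  state <- as_discrete_state(network, initial)
  clamps <- check_clamps(network, clamps)
  if (length(clamps)) state[names(clamps)] <- as.integer(clamps)
  traj <- matrix(state, nrow = 1, dimnames = list(NULL, network$nodes))
  seen <- stats::setNames(0L, paste(state, collapse = ""))
  attractor <- NULL
  for (t in seq_len(max_steps)) {
    state <- sync_step(network, state, clamps)
    traj <- rbind(traj, state)
    key <- paste(state, collapse = "")
    if (!is.null(seen[key]) && !is.na(seen[key])) {
      first <- seen[[key]]
      cycle <- traj[(first + 1):t, , drop = FALSE]
      attractor <- discrete_attractor(cycle)
      break
    }
    seen[key] <- t
  }
  rownames(traj) <- NULL
  list(trajectory = traj, attractor = attractor)
}

# cycle: matrix of states (rows in temporal order). Canonical rotation puts
# the lexicographically smallest state string first.
discrete_attractor <- function(cycle) {
  keys <- apply(cycle, 1, paste, collapse = "")
  shift <- which.min(match(keys, sort(keys)))
  idx <- c(seq(shift, nrow(cycle)), seq_len(shift - 1))
  structure(list(states = cycle[idx, , drop = FALSE], period = nrow(cycle)),
            class = "discrete_attractor")
}

#' @export
print.discrete_attractor <- function(x, ...) {
  kind <- if (x$period == 1) "fixed point" else paste0("cycle of period ", x$period)
  cat("<discrete_attractor>", kind, "\n")
  print(x$states)
  invisible(x)
}

attractor_key <- function(a) {
  paste(apply(a$states, 1, paste, collapse = ""), collapse = "|")
}

#' Exhaustive synchronous attractor enumeration
#'
#' Sweeps all 2^N assignments of the free (unclamped) nodes, follows each to
#' its attractor, and returns every attractor of the synchronous
#' state-transition graph once, in canonical rotation. Intended as a ground
#' truth for small models; refuses more than 20 free nodes.
#'
#' @inheritParams sync_step
#' @return List of `discrete_attractor` objects, sorted by their canonical
#'   state strings.
#' @export
enumerate_attractors_exhaustive <- function(network, clamps = NULL) {
  clamps <- check_clamps(network, clamps)
  free <- setdiff(network$nodes, names(clamps))
  nf <- length(free)
  if (nf > 20) {
    stop("exhaustive enumeration refuses networks with more than 20 free nodes (got ",
         nf, ")")
  }
  found <- list()
  base <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (length(clamps)) base[names(clamps)] <- as.integer(clamps)
  # state -> attractor id memo so each trajectory is walked once
  memo <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(2^nf) - 1L) {
    state <- base
    if (nf) state[free] <- as.integer(intToBits(i)[seq_len(nf)])
    path_keys <- character(0)
    repeat {
      key <- paste(state, collapse = "")
      hit <- get0(key, envir = memo)
      if (!is.null(hit)) {
        for (k in path_keys) assign(k, hit, envir = memo)
        break
      }
      if (key %in% path_keys) {
        cyc_start <- match(key, path_keys)
        cyc_keys <- path_keys[cyc_start:length(path_keys)]
        cycle <- t(vapply(cyc_keys, function(k)
          as.integer(strsplit(k, "")[[1]]), integer(length(network$nodes))))
        colnames(cycle) <- network$nodes
        a <- discrete_attractor(cycle)
        id <- attractor_key(a)
        found[[id]] <- a
        for (k in path_keys) assign(k, id, envir = memo)
        break
      }
      path_keys <- c(path_keys, key)
      state <- sync_step(network, state, clamps)
    }
  }
  found[order(names(found))]
}

#' Write a discrete or continuous trajectory as TSV
#'
#' Rows are time points, columns the named nodes.
#'
#' @param trajectory matrix (discrete) or `trajectory` object (continuous).
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  if (inherits(trajectory, "trajectory")) {
    df <- data.frame(time = trajectory$times, trajectory$states,
                     check.names = FALSE)
  } else {
    df <- data.frame(time = seq_len(nrow(trajectory)) - 1L, trajectory,
                     check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
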