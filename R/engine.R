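# Simulation engine: synchronous weighted-sum updates, vectorized over a
# matrix of network states (rows = states, columns = nodes in file order).

# Resolve the clamping structure implied by a profile + config.
clamp_spec <- function(net, profile, config) {
  nn <- node_names(net)
  prof <- as.character(profile)[match(nn, names(profile))]
  if (anyNA(prof)) stop_schema("profile does not cover all network nodes")
  inp <- which(net$nodes$role == "input")
  clamp_vals <- stats::setNames(rep(0L, length(inp)), nn[inp])
  ic <- config$input_clamp
  if (!is.null(ic)) {
    unknown <- setdiff(names(ic), nn[inp])
    if (length(unknown)) stop_schema("input clamp names non-input node: %s", unknown[1L])
    clamp_vals[names(ic)] <- as.integer(ic)
  }
  A_idx <- setdiff(which(prof == "A"), inp)
  I_idx <- setdiff(which(prof == "I"), inp)
  free_idx <- setdiff(which(prof == "N"), inp)
  list(A_idx = A_idx, I_idx = I_idx,
       input_idx = inp, input_vals = as.numeric(clamp_vals),
       free_idx = free_idx)
}

apply_clamps <- function(S, cl) {
  if (length(cl$A_idx)) S[, cl$A_idx] <- 1
  if (length(cl$I_idx)) S[, cl$I_idx] <- 0
  if (length(cl$input_idx))
    S[, cl$input_idx] <- matrix(cl$input_vals, nrow(S), length(cl$input_idx), byrow = TRUE)
  S
}

# Matrix of initial states honoring all clamps. Exhaustive enumeration counts
# in binary over the free nodes in file order, first free node varying
# fastest, so state indices are stable across runs.
init_states <- function(net, profile, config, allow_sample = TRUE) {
  cl <- clamp_spec(net, profile, config)
  k <- length(cl$free_idx)
  n_nodes <- nrow(net$nodes)
  if (!is.null(config$sample_states) && allow_sample) {
    m <- config$sample_states
    out <- matrix(0, m, n_nodes, dimnames = list(NULL, node_names(net)))
    if (k) out[, cl$free_idx] <- with_seed(
      derive_seed(config$seed, 777L),
      matrix(as.numeric(stats::runif(m * k) < 0.5), m, k))
    return(apply_clamps(out, cl))
  }
  if (k > config$enumeration_cap)
    stop_twin("therawin_enumeration_error",
              paste0("state space has ", k, " free nodes (> cap ",
                     config$enumeration_cap,
                     "); set sample_states in sim_config() to switch to sampled mode"))
  m <- 2L^k
  out <- matrix(0, m, n_nodes, dimnames = list(NULL, node_names(net)))
  if (k) {
    idx <- 0:(m - 1)
    for (j in seq_len(k)) out[, cl$free_idx[j]] <- (idx %/% 2^(j - 1)) %% 2
  }
  apply_clamps(out, cl)
}

# Resolve perturbation components against the network: list with parallel
# vectors describing node and link targets, and the component order used for
# the RNG draw sequence.
resolve_components <- function(net, perturbation) {
  if (is.null(perturbation)) return(list())
  comps <- perturbation$components
  lapply(comps, function(cmp) {
    if (cmp$kind == "node") {
      list(kind = "node", idx = node_idx(net, cmp$node), dose = cmp$dose)
    } else {
      si <- node_idx(net, cmp$source); ti <- node_idx(net, cmp$target)
      w <- net$W[si, ti]
      if (w == 0L)
        stop_schema("link %s -> %s does not exist in the network", cmp$source, cmp$target)
      list(kind = "link", src = si, tgt = ti, w = as.numeric(w), dose = cmp$dose)
    }
  })
}

# Core synchronous run over a state matrix. draws: NULL for stochastic
# Bernoulli(dose) per component/step/state, or a logical matrix
# (total_steps x n_components) giving an explicit suppression schedule
# (recycled across rows/states).
run_states <- function(net, profile, states, config, perturbation = NULL,
                       draws = NULL, keep_trajectory = FALSE) {
  cl <- clamp_spec(net, profile, config)
  comps <- resolve_components(net, perturbation)
  n <- nrow(states)
  p <- nrow(net$nodes)
  W <- net$W
  storage.mode(W) <- "double"
  B <- matrix(as.numeric(net$basal), n, p, byrow = TRUE)
  total <- config$transient_steps + config$steady_steps
  stochastic <- length(comps) > 0 && is.null(draws) &&
    any(vapply(comps, function(c) c$dose > 0 && c$dose < 1, TRUE))
  if (!is.null(draws) && nrow(draws) < total)
    stop_schema("suppression schedule shorter than transient + steady steps")
  S <- states
  acc <- matrix(0, n, p)
  traj <- if (keep_trajectory) array(0, c(total + 1L, n, p)) else NULL
  if (keep_trajectory) traj[1L, , ] <- S
  out_idx <- node_idx(net, net$death_readout)
  for (t in seq_len(total)) {
    # component suppression indicators for this step, in component order
    D <- NULL
    if (length(comps)) {
      D <- vector("list", length(comps))
      for (k in seq_along(comps)) {
        d <- comps[[k]]$dose
        if (d <= 0) { D[[k]] <- FALSE }
        else if (d >= 1) { D[[k]] <- TRUE }
        else if (!is.null(draws)) { D[[k]] <- draws[t, k] }
        else { D[[k]] <- stats::runif(n) < d }
      }
    }
    M <- S %*% W
    if (length(comps)) for (k in seq_along(comps)) {
      cmp <- comps[[k]]
      if (cmp$kind != "link") next
      rows <- D[[k]]
      if (isFALSE(rows[1L]) && length(rows) == 1L) next
      if (length(rows) == 1L) {
        if (rows) M[, cmp$tgt] <- M[, cmp$tgt] - S[, cmp$src] * cmp$w
      } else if (any(rows)) {
        M[rows, cmp$tgt] <- M[rows, cmp$tgt] - S[rows, cmp$src] * cmp$w
      }
    }
    nxt <- if (config$strict) (M + B) > 0 else (M + B) >= 0
    storage.mode(nxt) <- "double"
    nxt <- apply_clamps(nxt, cl)
    if (length(comps)) for (k in seq_along(comps)) {
      cmp <- comps[[k]]
      if (cmp$kind != "node") next
      rows <- D[[k]]
      if (length(rows) == 1L) {
        if (rows) nxt[, cmp$idx] <- 0
      } else if (any(rows)) {
        nxt[rows, cmp$idx] <- 0
      }
    }
    S <- nxt
    if (t > config$transient_steps) acc <- acc + S
    if (keep_trajectory) traj[t + 1L, , ] <- S
  }
  activity <- acc / config$steady_steps
  colnames(activity) <- node_names(net)
  list(activity = activity,
       death = activity[, out_idx] > config$death_threshold,
       trajectory = traj)
}

#' Single synchronous update of a network state
#'
#' Applies the weighted-sum rule once: for every input-dependent, unclamped
#' node i the next bit is 1 iff `sum_j w_ji s_j + b_i > 0` (suppressed links
#' contribute weight 0), after which suppressed nodes and `I`-status nodes
#' are forced to 0, `A`-status nodes to 1, and input nodes re-clamped.
#'
#' @param net a [network_definition()].
#' @param profile a [status_profile()].
#' @param state named 0/1 vector over all nodes.
#' @param suppressed_nodes character vector of node names forced OFF this step.
#' @param suppressed_links two-column matrix/data.frame of (source, target)
#'   links whose weight is zeroed this step.
#' @param config a [sim_config()] (supplies input clamps and strictness).
#' @return Named 0/1 vector: the successor state.
#' @export
step <- function(net, profile, state, suppressed_nodes = character(),
                 suppressed_links = NULL, config = sim_config()) {
  nn <- node_names(net)
  s <- as.numeric(state[match(nn, names(state))])
  if (anyNA(s)) stop_schema("state must assign a bit to every node")
  comps <- c(
    lapply(suppressed_nodes, function(x) target_node(x)),
    if (!is.null(suppressed_links)) {
      sl <- as.data.frame(suppressed_links, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(sl)), function(i) target_link(sl[[1L]][i], sl[[2L]][i]))
    }
  )
  pert <- if (length(comps)) perturbation(comps, dose = 1) else NULL
  cfg <- config
  cfg$transient_steps <- 1L; cfg$steady_steps <- 1L
  # one update: run a 2-step config is overkill; do it directly
  res <- run_states(net, profile, matrix(s, 1L, length(s), dimnames = list(NULL, nn)),
                    modifyList(cfg, list(transient_steps = 0L, steady_steps = 1L),
                               keep.null = TRUE),
                    perturbation = pert, keep_trajectory = TRUE)
  stats::setNames(as.numeric(res$trajectory[2L, 1L, ]), nn)
}

#' Simulate one trajectory and summarize its steady dynamics
#'
#' Runs `transient_steps` then `steady_steps` synchronous updates from one
#' initial state. Node activity is the mean state over the steady window
#' only; the trajectory has the death phenotype when the death-readout
#' activity exceeds `config$death_threshold`.
#'
#' @inheritParams step
#' @param initial named 0/1 vector over all nodes.
#' @param perturbation optional [perturbation()] applied stochastically
#'   (per-step Bernoulli(dose) suppression draws) unless `schedule` is given.
#' @param schedule optional logical matrix (steps x components) giving an
#'   explicit per-step suppression schedule for the perturbation components.
#' @param keep_trajectory logical; retain the full state trajectory.
#' @return List of class `simulation_result`: `activity` (named, in [0,1]),
#'   `death` (logical), and optionally `trajectory`
#'   (steps+1 x nodes matrix).
#' @export
simulate <- function(net, profile, initial, config = sim_config(),
                     perturbation = NULL, schedule = NULL,
                     keep_trajectory = FALSE) {
  nn <- node_names(net)
  s <- as.numeric(initial[match(nn, names(initial))])
  if (anyNA(s)) stop_schema("initial state must assign a bit to every node")
  st <- apply_clamps(matrix(s, 1L, length(s), dimnames = list(NULL, nn)),
                     clamp_spec(net, profile, config))
  run1 <- function() run_states(net, profile, st, config, perturbation,
                                draws = schedule, keep_trajectory = keep_trajectory)
  res <- if (is.null(schedule)) with_seed(config$seed, run1()) else run1()
  structure(list(
    activity = stats::setNames(as.numeric(res$activity[1L, ]), nn),
    death = unname(res$death[1L]),
    trajectory = if (keep_trajectory) {
      tr <- res$trajectory[, 1L, , drop = TRUE]
      colnames(tr) <- nn
      tr
    }
  ), class = "simulation_result")
}

#' Enumerate (or sample) the initial states of a network
#'
#' Yields every assignment of the free nodes (status `N`, non-input) with all
#' clamped nodes fixed at their forced values, in a deterministic order:
#' binary counting over the free nodes in file order, first free node varying
#' fastest. Beyond `config$enumeration_cap` free nodes an error instructs the
#' caller to switch to sampled mode (`sample_states`).
#'
#' @inheritParams step
#' @return Numeric 0/1 matrix, one row per initial state, columns named by node.
#' @export
enumerate_initial_states <- function(net, profile, config = sim_config()) {
  init_states(net, profile, config)
}

# Deterministic attractor-landscape pass over all (or sampled) initial
# states: successor-table composition for the transient, explicit stepping of
# the unique steady-entry states for the activity window.
det_landscape <- function(net, profile, config) {
  cl <- clamp_spec(net, profile, config)
  k <- length(cl$free_idx)
  states <- init_states(net, profile, config)
  n <- nrow(states)
  sampled <- !is.null(config$sample_states)
  if (sampled || k > 25L) {
    res <- run_states(net, profile, states, config)
    return(list(death = res$death, activity = res$activity, states = states))
  }
  succ <- run_states(net, profile, states,
                     modifyList(config, list(transient_steps = 0L, steady_steps = 1L),
                                keep.null = TRUE),
                     keep_trajectory = TRUE)$trajectory[2L, , , drop = FALSE]
  succ <- matrix(succ, n, nrow(net$nodes))
  encode <- function(S) {
    if (k == 0L) return(rep(1L, nrow(S)))
    as.integer(S[, cl$free_idx, drop = FALSE] %*% 2^(seq_len(k) - 1)) + 1L
  }
  Fmap <- encode(succ)
  # position after `transient_steps` applications of the successor map
  P <- seq_len(n); G <- Fmap; e <- config$transient_steps
  while (e > 0L) {
    if (e %% 2L == 1L) P <- G[P]
    e <- e %/% 2L
    if (e > 0L) G <- G[G]
  }
  u <- unique(P)
  res_u <- run_states(net, profile, states[u, , drop = FALSE],
                      modifyList(config, list(transient_steps = 0L), keep.null = TRUE))
  m <- match(P, u)
  list(death = res_u$death[m], activity = res_u$activity[m, , drop = FALSE],
       states = states, state_index = P, succ = Fmap)
}

#' Basin of apoptosis
#'
#' Fraction of initial states whose unperturbed deterministic trajectory
#' reaches the cell-death phenotype (death-readout activity above the
#' threshold over the steady window). This is the attractor-landscape summary
#' used to exclude spontaneously dying networks during cohort mapping.
#'
#' @inheritParams step
#' @return Fraction in [0,1].
#' @export
basin_of_apoptosis <- function(net, profile, config = sim_config()) {
  mean(det_landscape(net, profile, config)$death)
}

# TRUE when every trajectory has entered a recurrent state (its attractor)
# within the transient window; exact, via successor-table composition.
converges_within_transient <- function(net, profile, config = sim_config()) {
  dl <- det_landscape(net, profile, config)
  if (is.null(dl$succ)) stop_schema("convergence check requires enumerable mode")
  Fmap <- dl$succ
  k <- length(Fmap)
  G <- Fmap
  reps <- ceiling(log2(max(2, k)))
  for (i in seq_len(reps)) G <- G[G]
  recurrent <- unique(G)
  all(dl$state_index %in% recurrent)
}

#' Ergodic set of a stochastically perturbed trajectory
#'
#' Under partial (dose in (0,1)) inhibition the trajectory keeps shuttling
#' between the perturbed and unperturbed attractor regions; the ergodic set
#' is the set of distinct states visited during the steady window of a long
#' stochastic run. At dose 0 it equals the deterministic attractor states.
#'
#' @inheritParams simulate
#' @return 0/1 matrix of distinct visited states (steady window), one row per
#'   state, in order of first visit.
#' @export
ergodic_set <- function(net, profile, perturbation, initial,
                        config = sim_config()) {
  res <- simulate(net, profile, initial, config, perturbation = perturbation,
                  keep_trajectory = TRUE)
  steady <- res$trajectory[(config$transient_steps + 2L):(config$transient_steps +
                                                            config$steady_steps + 1L), , drop = FALSE]
  steady[!duplicated(apply(steady, 1L, paste, collapse = "")), , drop = FALSE]
}
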