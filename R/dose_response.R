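#' Drug targets and perturbations
#'
#' A drug is modeled as probabilistic inhibition of one or more targets. A
#' target is either a node (full target inhibition blocks every outgoing
#' regulatory function) or a single directed link (edgetic inhibition, e.g.
#' blocking only the MDM2 -> p53 interaction). The dose x in [0,1] is the
#' per-simulation-step probability that the target is forced OFF (node state,
#' or link weight, set to 0) at that step; dose 1 is permanent inhibition and
#' dose 0 leaves the original dynamics untouched.
#'
#' @param name,source,target node names.
#' @return `target_node()`/`target_link()` return target descriptors;
#'   `perturbation()` a validated set of dosed components.
#' @export
target_node <- function(name) {
  structure(list(kind = "node", node = as.character(name)), class = "twin_target")
}

#' @rdname target_node
#' @export
target_link <- function(source, target) {
  structure(list(kind = "link", source = as.character(source),
                 target = as.character(target)), class = "twin_target")
}

target_id <- function(t) {
  if (t$kind == "node") t$node else paste0(t$source, ">", t$target)
}

# "AKT" or "MDM2>p53" -> target object
parse_target_id <- function(id) {
  if (grepl(">", id, fixed = TRUE)) {
    parts <- strsplit(id, ">", fixed = TRUE)[[1L]]
    target_link(parts[1L], parts[2L])
  } else target_node(id)
}

#' @rdname target_node
#' @param targets list of targets built with `target_node()`/`target_link()`
#'   (a single target may be passed unwrapped).
#' @param dose dose(s) in [0,1], recycled over the targets.
#' @export
perturbation <- function(targets, dose) {
  if (inherits(targets, "twin_target")) targets <- list(targets)
  if (!length(targets)) stop_schema("perturbation needs at least one target")
  dose <- rep_len(as.numeric(dose), length(targets))
  if (any(dose < 0 | dose > 1)) stop_schema("doses must lie in [0,1]")
  comps <- Map(function(t, d) c(t, list(dose = d)), targets, dose)
  ids <- vapply(targets, target_id, "")
  if (anyDuplicated(ids)) stop_schema("duplicate perturbation target: %s",
                                      ids[duplicated(ids)][1L])
  structure(list(components = comps, ids = ids), class = "perturbation")
}

#' Cell-death ratio under a dosed perturbation
#'
#' For every initial state (enumerated or sampled per `config`) an
#' independent per-step Bernoulli(dose) suppression schedule is drawn for
#' each perturbation component; the trajectory is simulated and the fraction
#' of (state, replicate) runs reaching the death phenotype is returned. With
#' all doses 0 this equals the unperturbed [basin_of_apoptosis()].
#'
#' @inheritParams step
#' @param perturbation a [perturbation()].
#' @param states optional precomputed initial-state matrix (rows reused as-is).
#' @return Fraction in [0,1].
#' @export
death_ratio <- function(net, profile, perturbation, config = sim_config(),
                        states = NULL) {
  doses <- vapply(perturbation$components, `[[`, 0, "dose")
  if (all(doses == 0)) {
    if (is.null(states)) return(basin_of_apoptosis(net, profile, config))
    return(mean(run_states(net, profile, states, config)$death))
  }
  if (is.null(states)) states <- init_states(net, profile, config)
  if (config$n_replicates > 1L)
    states <- states[rep(seq_len(nrow(states)), each = config$n_replicates), , drop = FALSE]
  res <- with_seed(config$seed,
                   run_states(net, profile, states, config, perturbation))
  mean(res$death)
}

#' Dose-response curve of a target set
#'
#' Simulates the perturbation over the dose grid (all components share the
#' common dose, the convention used for 1-D combination curves) and records
#' the death ratio f(x) at each dose. The raw curve is normalized with
#' [normalize_curve()] before metric extraction.
#'
#' @inheritParams death_ratio
#' @param targets a target, list of targets, or [perturbation()] (doses in a
#'   perturbation object are ignored; the grid dose is applied).
#' @param doses strictly increasing dose grid in [0,1].
#' @return Object of class `dose_response_curve`: list with `doses`,
#'   `values`, `normalized`, `meta`.
#' @export
dose_sweep <- function(net, profile, targets, config = sim_config(),
                       doses = seq(0, 1, by = 0.1)) {
  if (inherits(targets, "perturbation")) targets <- lapply(targets$components,
                                                           function(c) structure(c[setdiff(names(c), "dose")], class = "twin_target"))
  if (inherits(targets, "twin_target")) targets <- list(targets)
  if (any(diff(doses) <= 0)) stop_schema("dose grid must be strictly increasing")
  if (length(targets) == 0L) {
    basin <- basin_of_apoptosis(net, profile, config)
    return(curve_like(doses, rep(basin, length(doses))))
  }
  states <- init_states(net, profile, config)
  vals <- vapply(seq_along(doses), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    death_ratio(net, profile, perturbation(targets, dose = doses[i]), cfg,
                states = states)
  }, 0)
  structure(list(
    doses = doses, values = vals, normalized = FALSE,
    meta = list(targets = vapply(targets, target_id, ""),
                seed = config$seed, n_replicates = config$n_replicates)
  ), class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("Dose-response curve [%s]%s\n", paste(x$meta$targets, collapse = " + "),
              if (x$normalized) " (normalized)" else " (raw)"))
  print(stats::setNames(round(x$values, 3), format(x$doses)))
  invisible(x)
}

#' @export
plot.dose_response_curve <- function(x, ..., col = "firebrick") {
  graphics::plot(x$doses, x$values, type = "b", col = col, ylim = c(0, 1),
                 xlab = "dose", ylab = "cell-death ratio", ...)
  invisible(x)
}

curve_like <- function(doses, values, normalized = FALSE, targets = character()) {
  structure(list(doses = doses, values = values, normalized = normalized,
                 meta = list(targets = targets)), class = "dose_response_curve")
}

#' Normalize a dose-response curve
#'
#' Shifts the curve so that the value at dose 0 is 0 (subtracting the
#' baseline death ratio f(0)) and clips the result into [0,1].
#'
#' @param curve a raw `dose_response_curve`.
#' @return The normalized curve; double normalization is rejected.
#' @export
normalize_curve <- function(curve) {
  if (isTRUE(curve$normalized)) stop_schema("curve is already normalized")
  curve$values <- pmin(pmax(curve$values - curve$values[1L], 0), 1)
  curve$normalized <- TRUE
  curve
}

assert_normalized <- function(curve) {
  if (!isTRUE(curve$normalized))
    stop_schema("metric requires a normalized curve (see normalize_curve())")
  invisible(curve)
}

#' Dose-response metrics: efficacy, toxicity, IC50, AUC
#'
#' Efficacy is the maximal effect max f(x) of a normalized curve; toxicity is
#' the efficacy of the control-network curve g. IC50 interpolates the dose at
#' which the curve crosses 0.5: in `"scaled"` mode (default)
#' `x1 + (0.5 - f(x1)) / (f(x2) - f(x1)) * (x2 - x1)` with x1/x2 the grid
#' doses bracketing the crossing; `"literal"` mode applies the published
#' formula verbatim, `(0.5 - f(x1)) / (f(x2) - f(x1)) + x1`, which omits the
#' grid-spacing factor and may exceed the bracketing interval. When efficacy
#' is below 0.5 the IC50 is reported as 1. AUC is the trapezoidal area of the
#' normalized curve over the dose axis.
#'
#' @param curve,g_curve normalized `dose_response_curve` objects.
#' @param mode IC50 interpolation mode, `"scaled"` or `"literal"`.
#' @return Scalar metric value.
#' @export
efficacy <- function(curve) {
  assert_normalized(curve)
  max(curve$values)
}

#' @rdname efficacy
#' @export
toxicity <- function(g_curve) efficacy(g_curve)

#' @rdname efficacy
#' @export
ic50 <- function(curve, mode = c("scaled", "literal")) {
  assert_normalized(curve)
  mode <- match.arg(mode)
  if (efficacy(curve) < 0.5) return(1)
  j <- which(curve$values >= 0.5)[1L]
  if (j == 1L) return(curve$doses[1L])
  x1 <- curve$doses[j - 1L]; x2 <- curve$doses[j]
  f1 <- curve$values[j - 1L]; f2 <- curve$values[j]
  if (f2 == f1) stop_twin("therawin_degenerate_crossing",
                          "flat segment at the 0.5 crossing; IC50 undefined")
  if (mode == "scaled") x1 + (0.5 - f1) / (f2 - f1) * (x2 - x1)
  else (0.5 - f1) / (f2 - f1) + x1
}

#' @rdname efficacy
#' @export
auc <- function(curve) {
  assert_normalized(curve)
  d <- curve$doses; v <- curve$values
  sum(diff(d) * (v[-1L] + v[-length(v)]) / 2)
}

#' Simulated MED, MTD and therapeutic window
#'
#' The simulated minimum effective dose (sMED) is the interpolated dose at
#' which the cancer-network curve f first reaches the response threshold; the
#' simulated maximum tolerated dose (sMTD) is the dose at which the
#' control-network curve g first reaches the same threshold (`Inf` when g
#' never does). The therapeutic window is `sMTD - sMED`; it is `NA` when the
#' cancer network never responds.
#'
#' @param f_curve,g_curve normalized curves on the same dose grid for the
#'   cancer and control network.
#' @param threshold response threshold (default 0.25).
#' @return List with `smed`, `smtd`, `window`.
#' @export
smed_smtd <- function(f_curve, g_curve, threshold = 0.25) {
  assert_normalized(f_curve); assert_normalized(g_curve)
  if (!isTRUE(all.equal(f_curve$doses, g_curve$doses)))
    stop_schema("curves must share a dose grid")
  smed <- first_crossing(f_curve$doses, f_curve$values, threshold)
  smtd <- first_crossing(g_curve$doses, g_curve$values, threshold)
  if (is.na(smtd)) smtd <- Inf
  window <- if (is.na(smed)) NA_real_ else smtd - smed
  list(smed = smed, smtd = smtd, window = window)
}

#' Two-drug dose-response landscape
#'
#' Simulates a pair of targets over the full (x, y) dose grid in the cancer
#' and control network. The optimality surface f(x,y) - g(x,y) visualizes the
#' therapeutic window of the combination: positive cells are dose pairs
#' killing the cancer network but sparing the control.
#'
#' @inheritParams death_ratio
#' @param cancer_profile,control_profile status profiles for the two networks.
#' @param target_a,target_b two distinct targets (x and y axis).
#' @param x_doses,y_doses dose grids.
#' @param normalize subtract the (0,0) cell from each surface and clip to
#'   [0,1] before computing optimality.
#' @return Object of class `dose_response_landscape` with matrices `f`, `g`,
#'   `optimality` (rows = x doses, columns = y doses).
#' @export
landscape <- function(net, cancer_profile, control_profile, target_a, target_b,
                      config = sim_config(), x_doses = seq(0, 1, by = 0.1),
                      y_doses = seq(0, 1, by = 0.1), normalize = TRUE) {
  if (identical(target_id(target_a), target_id(target_b)))
    stop_schema("landscape requires two distinct targets")
  surf <- function(profile) {
    states <- init_states(net, profile, config)
    out <- matrix(0, length(x_doses), length(y_doses),
                  dimnames = list(format(x_doses), format(y_doses)))
    for (i in seq_along(x_doses)) for (j in seq_along(y_doses)) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, i, j - 1L)
      out[i, j] <- death_ratio(net, profile,
                               perturbation(list(target_a, target_b),
                                            dose = c(x_doses[i], y_doses[j])),
                               cfg, states = states)
    }
    out
  }
  f <- surf(cancer_profile)
  g <- surf(control_profile)
  if (normalize) {
    f <- pmin(pmax(f - f[1L, 1L], 0), 1)
    g <- pmin(pmax(g - g[1L, 1L], 0), 1)
  }
  structure(list(x_doses = x_doses, y_doses = y_doses, f = f, g = g,
                 optimality = f - g, normalized = normalize,
                 meta = list(targets = c(target_id(target_a), target_id(target_b)),
                             seed = config$seed)),
            class = "dose_response_landscape")
}

#' Combination index of a two-drug perturbation
#'
#' `CI = IC50_AB / IC50_A + IC50_AB / IC50_B`, computed from the simulated
#' IC50 of each single drug and of the equal-dose combination. CI < 1
#' indicates synergy, CI = 1 additivity, CI > 1 antagonism.
#'
#' @param ic50_a,ic50_b,ic50_ab IC50 values in (0, 1].
#' @return The combination index.
#' @export
combination_index <- function(ic50_a, ic50_b, ic50_ab) {
  vals <- c(ic50_a, ic50_b, ic50_ab)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals > 1))
    stop_schema("IC50 inputs must lie in (0, 1]")
  ic50_ab / ic50_a + ic50_ab / ic50_b
}
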