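#' Classification thresholds
#'
#' All cutoffs used in response categorization and database-style
#' sensitivity classification: the efficacy test `max f(x) > 0.8`, the
#' toxicity test `max f - max g > 0.5`, the potency test (some dose with
#' `f(x) - g(x) > 0.5`), the 0.25 sMED/sMTD threshold, the 0.9 death
#' threshold, and the 0.5/0.8 sensitive-vs-resistant cutoffs. Comparisons
#' are strict.
#'
#' @param efficacy_cut,toxicity_gap,potency_gap,window_threshold,death_threshold,sens_cut_ic50,sens_cut_auc,sens_cut_efficacy thresholds in (0,1).
#' @return List of class `threshold_config`.
#' @export
threshold_config <- function(efficacy_cut = 0.8, toxicity_gap = 0.5,
                             potency_gap = 0.5, window_threshold = 0.25,
                             death_threshold = 0.9, sens_cut_ic50 = 0.5,
                             sens_cut_auc = 0.5, sens_cut_efficacy = 0.8) {
  th <- list(efficacy_cut = efficacy_cut, toxicity_gap = toxicity_gap,
             potency_gap = potency_gap, window_threshold = window_threshold,
             death_threshold = death_threshold, sens_cut_ic50 = sens_cut_ic50,
             sens_cut_auc = sens_cut_auc, sens_cut_efficacy = sens_cut_efficacy)
  if (any(unlist(th) <= 0) || any(unlist(th) >= 1))
    stop_schema("all thresholds must lie in (0,1)")
  structure(th, class = "threshold_config")
}

outgoing_links <- function(net, node) {
  lk <- net$links[net$links$source == node, , drop = FALSE]
  lapply(seq_len(nrow(lk)), function(i) target_link(lk$source[i], lk$target[i]))
}

#' Enumerate the drug-perturbation screening set
#'
#' Builds the full screening set for a panel of target nodes: single nodes,
#' their single outgoing links, all node pairs, all link pairs except pairs
#' of links leaving the same node, and all node-link pairs except a node
#' combined with one of its own outgoing links. For the 16-node p53 model
#' with its 6 designated targets (27 outgoing links) this yields
#' 6 + 27 + 15 + 297 + 135 = 480 perturbations.
#'
#' @param net a [network_definition()].
#' @param target_nodes character vector of designated drug-target nodes.
#' @return List of entries `list(id, kind, targets)` in deterministic order;
#'   `kind` is one of `node`, `link`, `node_pair`, `link_pair`, `node_link`.
#' @export
enumerate_perturbations <- function(net, target_nodes) {
  idx <- node_idx(net, target_nodes)  # validates
  links <- unlist(lapply(target_nodes, outgoing_links, net = net), recursive = FALSE)
  link_src <- vapply(links, `[[`, "", "source")
  entry <- function(kind, targets)
    list(id = paste(vapply(targets, target_id, ""), collapse = "+"),
         kind = kind, targets = targets)
  out <- list()
  for (n in target_nodes) out[[length(out) + 1L]] <- entry("node", list(target_node(n)))
  for (l in links) out[[length(out) + 1L]] <- entry("link", list(l))
  if (length(target_nodes) >= 2L) {
    cmb <- utils::combn(length(target_nodes), 2L)
    for (c in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <- entry("node_pair",
                                       list(target_node(target_nodes[cmb[1L, c]]),
                                            target_node(target_nodes[cmb[2L, c]])))
  }
  if (length(links) >= 2L) {
    cmb <- utils::combn(length(links), 2L)
    for (c in seq_len(ncol(cmb))) {
      i <- cmb[1L, c]; j <- cmb[2L, c]
      if (link_src[i] == link_src[j]) next
      out[[length(out) + 1L]] <- entry("link_pair", list(links[[i]], links[[j]]))
    }
  }
  for (n in target_nodes) for (l in links) {
    if (l$source == n) next
    out[[length(out) + 1L]] <- entry("node_link", list(target_node(n), l))
  }
  out
}

#' Selective-control classification (S1-S4)
#'
#' Classifies the efficacy side of a response: S1 when both the node-side
#' and the link-side efficacy tests pass, S2 when only the node side passes,
#' S3 when only the link side, S4 when neither. The inputs are the maximal
#' responses (efficacies) of the relevant single-target sweeps; an empty
#' side fails its test.
#'
#' @param node_effs,link_effs numeric efficacies of node-side and link-side
#'   curves (possibly empty).
#' @param th a [threshold_config()].
#' @return `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @export
selective_class <- function(node_effs, link_effs, th = threshold_config()) {
  if (length(node_effs) == 0L && length(link_effs) == 0L)
    stop_schema("no curves supplied for the selective-control test")
  node_pass <- length(node_effs) > 0L && any(node_effs > th$efficacy_cut)
  link_pass <- length(link_effs) > 0L && any(link_effs > th$efficacy_cut)
  if (node_pass) { if (link_pass) "S1" else "S2" } else { if (link_pass) "S3" else "S4" }
}

#' Optimal-control classification (O1-O3)
#'
#' Classifies the toxicity/potency side of a response by comparing the
#' normalized cancer curve f with the control curve g: O1 when the toxicity
#' test passes (`max f - max g > toxicity_gap`, low toxicity at all doses);
#' otherwise O2 when some dose has `f(x) - g(x) > potency_gap` (a window via
#' higher potency); otherwise O3 (no therapeutic window).
#'
#' @param f_curve,g_curve normalized curves on the same grid.
#' @param th a [threshold_config()].
#' @return `"O1"`, `"O2"` or `"O3"`.
#' @export
optimal_class <- function(f_curve, g_curve, th = threshold_config()) {
  assert_normalized(f_curve); assert_normalized(g_curve)
  if (!isTRUE(all.equal(f_curve$doses, g_curve$doses)))
    stop_schema("curves must share a dose grid")
  if (max(f_curve$values) - max(g_curve$values) > th$toxicity_gap) return("O1")
  if (any(f_curve$values - g_curve$values > th$potency_gap)) return("O2")
  "O3"
}

# Single-target sweeps needed for the S test of a perturbation.
# Single-target drugs follow the node-and-its-links reading: a link drug is
# judged against its source node. Combinations follow the "at least one drug
# of the combination" wording: the node side only counts node components.
s_test_sides <- function(net, targets) {
  is_node <- vapply(targets, function(t) t$kind == "node", TRUE)
  if (length(targets) == 1L) {
    t <- targets[[1L]]
    if (t$kind == "node") {
      list(node = list(t), link = outgoing_links(net, t$node))
    } else {
      list(node = list(target_node(t$source)), link = list(t))
    }
  } else {
    nodes <- targets[is_node]
    links <- targets[!is_node]
    side_links <- c(links, unlist(lapply(nodes, function(t)
      outgoing_links(net, t$node)), recursive = FALSE))
    list(node = nodes, link = side_links)
  }
}

new_sweep_cache <- function() new.env(parent = emptyenv())

cached_single_efficacy <- function(net, profile, target, config, doses, th, cache) {
  key <- target_id(target)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  eff <- efficacy(normalize_curve(dose_sweep(net, profile, list(target), config, doses)))
  if (!is.null(cache)) cache[[key]] <- eff
  eff
}

#' Categorize a perturbation response
#'
#' Runs the dose sweeps a perturbation requires (its own combined curve in
#' the cancer and control network, plus the single-target curves of the
#' selective-control test), normalizes them, and assigns the (S_n, O_m)
#' response category with its desirable/undesirable flag. Desirable (D)
#' responses are those in S1-S3 combined with O1-O2; any S4 or O3 response
#' is undesirable (U). Categorization is performed under the therapeutic
#' scenario (input node, e.g. DNA damage, clamped ON via `config`).
#'
#' @inheritParams dose_sweep
#' @param cancer_profile,control_profile status profiles of the cancer and
#'   control network.
#' @param targets target list or single target (the perturbation).
#' @param th a [threshold_config()].
#' @param cache optional environment from [new_sweep_cache()] reusing
#'   single-target cancer sweeps across calls (as in [triangle_map()]).
#' @return Object of class `response_category`: `s`, `o`, `desirable`, and
#'   the underlying metrics (efficacy, ic50, auc, toxicity, smed, smtd,
#'   window).
#' @export
categorize <- function(net, cancer_profile, control_profile, targets,
                       config = sim_config(), th = threshold_config(),
                       doses = seq(0, 1, by = 0.1), cache = NULL) {
  if (inherits(targets, "twin_target")) targets <- list(targets)
  f <- normalize_curve(dose_sweep(net, cancer_profile, targets, config, doses))
  g <- normalize_curve(dose_sweep(net, control_profile, targets, config, doses))
  sides <- s_test_sides(net, targets)
  node_effs <- vapply(sides$node, cached_single_efficacy, 0, net = net,
                      profile = cancer_profile, config = config, doses = doses,
                      th = th, cache = cache)
  link_effs <- vapply(sides$link, cached_single_efficacy, 0, net = net,
                      profile = cancer_profile, config = config, doses = doses,
                      th = th, cache = cache)
  s <- selective_class(node_effs, link_effs, th)
  o <- optimal_class(f, g, th)
  win <- smed_smtd(f, g, th$window_threshold)
  structure(list(
    s = s, o = o, desirable = s != "S4" && o != "O3",
    efficacy = efficacy(f), ic50 = ic50(f), auc = auc(f),
    toxicity = toxicity(g),
    smed = win$smed, smtd = win$smtd, window = win$window,
    targets = vapply(targets, target_id, "")
  ), class = "response_category")
}

#' @export
print.response_category <- function(x, ...) {
  cat(sprintf("(%s,%s) %s  [%s]  eff=%.2f ic50=%.2f tox=%.2f window=%s\n",
              x$s, x$o, if (x$desirable) "desirable" else "undesirable",
              paste(x$targets, collapse = "+"), x$efficacy, x$ic50, x$toxicity,
              format(x$window)))
  invisible(x)
}

#' Triangle map of a network's screening set
#'
#' Categorizes every perturbation in the screening set of `target_nodes` for
#' one cancer network and lays the results out as the long-format triangle
#' map: the diagonal holds single targets, the off-diagonal regions node
#' pairs, link pairs and node-link pairs. Same-source link pairs and
#' node-with-own-link pairs are structurally `NA`; the NA pattern depends on
#' topology only.
#'
#' @inheritParams categorize
#' @param target_nodes designated drug-target nodes.
#' @return A data.frame of class `triangle_map` with one row per entry
#'   (including NA entries): `id`, `kind`, `comp1`, `comp2`, `s`, `o`,
#'   `desirable`, `efficacy`, `ic50`, `toxicity`, `smed`, `smtd`, `window`.
#' @export
triangle_map <- function(net, cancer_profile, control_profile, target_nodes,
                         config = sim_config(), th = threshold_config(),
                         doses = seq(0, 1, by = 0.1)) {
  perts <- enumerate_perturbations(net, target_nodes)
  links <- unlist(lapply(target_nodes, outgoing_links, net = net), recursive = FALSE)
  link_ids <- vapply(links, target_id, "")
  link_src <- vapply(links, `[[`, "", "source")
  all_ids <- c(target_nodes, link_ids)
  cache <- new_sweep_cache()
  rows <- list()
  add_row <- function(id, kind, comp1, comp2, cat) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, kind = kind, comp1 = comp1, comp2 = comp2,
      s = if (is.null(cat)) NA_character_ else cat$s,
      o = if (is.null(cat)) NA_character_ else cat$o,
      desirable = if (is.null(cat)) NA else cat$desirable,
      efficacy = if (is.null(cat)) NA_real_ else cat$efficacy,
      ic50 = if (is.null(cat)) NA_real_ else cat$ic50,
      toxicity = if (is.null(cat)) NA_real_ else cat$toxicity,
      smed = if (is.null(cat)) NA_real_ else cat$smed,
      smtd = if (is.null(cat)) NA_real_ else cat$smtd,
      window = if (is.null(cat)) NA_real_ else cat$window,
      stringsAsFactors = FALSE)
  }
  done <- new.env(parent = emptyenv())
  for (p in perts) {
    cat <- categorize(net, cancer_profile, control_profile, p$targets, config,
                      th, doses, cache = cache)
    comp <- vapply(p$targets, target_id, "")
    add_row(p$id, p$kind, comp[1L], if (length(comp) > 1L) comp[2L] else NA_character_, cat)
    done[[p$id]] <- TRUE
  }
  # structural NA entries
  if (length(link_ids) >= 2L) {
    cmb <- utils::combn(length(link_ids), 2L)
    for (c in seq_len(ncol(cmb))) {
      i <- cmb[1L, c]; j <- cmb[2L, c]
      if (link_src[i] == link_src[j])
        add_row(paste(link_ids[i], link_ids[j], sep = "+"), "link_pair",
                link_ids[i], link_ids[j], NULL)
    }
  }
  for (n in target_nodes) for (i in seq_along(links))
    if (link_src[i] == n)
      add_row(paste(n, link_ids[i], sep = "+"), "node_link", n, link_ids[i], NULL)
  out <- do.call(rbind, rows)
  class(out) <- c("triangle_map", "data.frame")
  attr(out, "target_nodes") <- target_nodes
  attr(out, "links") <- link_ids
  out
}

#' Sensitive/resistant classification and agreement rate
#'
#' Applies the fixed sensitivity rules used when benchmarking simulated
#' responses against drug-response databases. Simulated IC50 below 0.5 is
#' sensitive; simulated AUC above 0.5 sensitive; simulated efficacy above
#' 0.8 sensitive. Experimental IC50 must be pre-normalized to [0,1]
#' (min-max over tested concentrations; below 0.5 sensitive); experimental
#' (viability) AUC is compared against the cohort mean (below mean
#' sensitive); GR50 below 0.5 sensitive, with infinite GR50 excluded;
#' GRmax below 0.5 sensitive; GR_AOC above 0.5 sensitive.
#'
#' @param value metric value (pre-normalized where the rule requires it).
#' @param metric one of `"sim_ic50"`, `"sim_auc"`, `"sim_efficacy"`,
#'   `"exp_ic50"`, `"exp_auc"`, `"gr50"`, `"grmax"`, `"gr_aoc"`.
#' @param th a [threshold_config()].
#' @param cohort_mean cohort mean, required for `"exp_auc"`.
#' @param exclude_infinite allow non-finite GR50 values to be excluded
#'   (returns `"excluded"`) instead of raising an error.
#' @return `"sensitive"`, `"resistant"` or `"excluded"`.
#' @export
sensitivity_classify <- function(value,
                                 metric = c("sim_ic50", "sim_auc", "sim_efficacy",
                                            "exp_ic50", "exp_auc", "gr50",
                                            "grmax", "gr_aoc"),
                                 th = threshold_config(), cohort_mean = NULL,
                                 exclude_infinite = FALSE) {
  metric <- match.arg(metric)
  if (!is.finite(value)) {
    if (metric == "gr50" && exclude_infinite) return("excluded")
    stop_schema("non-finite %s value without an exclusion flag", metric)
  }
  sens <- switch(metric,
    sim_ic50 = value < th$sens_cut_ic50,
    sim_auc = value > th$sens_cut_auc,
    sim_efficacy = value > th$sens_cut_efficacy,
    exp_ic50 = value < 0.5,
    exp_auc = {
      if (is.null(cohort_mean)) stop_schema("exp_auc rule requires cohort_mean")
      value < cohort_mean
    },
    gr50 = value < 0.5,
    grmax = value < 0.5,
    gr_aoc = value > 0.5)
  if (sens) "sensitive" else "resistant"
}

#' @rdname sensitivity_classify
#' @param simulated,experimental character vectors of labels from
#'   `sensitivity_classify()`; `"excluded"` pairs are dropped.
#' @export
agreement_rate <- function(simulated, experimental) {
  if (length(simulated) != length(experimental))
    stop_schema("label vectors must have equal length")
  keep <- simulated != "excluded" & experimental != "excluded"
  if (!any(keep)) return(NA_real_)
  mean(simulated[keep] == experimental[keep])
}
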