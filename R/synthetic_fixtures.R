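#' Specification for generated fixtures
#'
#' Parameters of the random-network and random-cohort generators used to
#' test every pipeline stage without external downloads. Generation is a
#' pure function of (spec, seed).
#'
#' @param n_nodes node count (>= 3; one input and one output are always
#'   included).
#' @param link_density probability of each extra directed link beyond the
#'   input-to-output backbone chain.
#' @param weight_range inclusive integer bounds for link weights (0 is never
#'   drawn).
#' @param n_profiles cohort size for profile generation.
#' @param alterations_min,alterations_max per-profile alteration count range
#'   (uniform draw).
#' @param seed integer seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_nodes = 10L, link_density = 0.15,
                         weight_range = c(-2L, 2L), n_profiles = 100L,
                         alterations_min = 1L, alterations_max = 4L,
                         seed = 1L) {
  if (n_nodes < 3L) stop_schema("random networks need at least 3 nodes")
  if (alterations_min < 0L || alterations_max < alterations_min)
    stop_schema("invalid alteration count range")
  structure(list(n_nodes = as.integer(n_nodes), link_density = link_density,
                 weight_range = as.integer(weight_range),
                 n_profiles = as.integer(n_profiles),
                 alterations_min = as.integer(alterations_min),
                 alterations_max = as.integer(alterations_max),
                 seed = as.integer(seed)), class = "fixture_spec")
}

sample_weight <- function(n, range) {
  pool <- setdiff(seq(range[1L], range[2L]), 0L)
  pool[sample.int(length(pool), n, replace = TRUE)]
}

#' Generate a random weighted-sum Boolean network
#'
#' Draws a connected directed network with one input (`IN`), one output
#' death readout (`OUT`) reachable from the input through a backbone chain
#' over a random permutation of the internal nodes, extra random links at
#' the requested density, one feedback link (when the topology permits), and
#' integer weights/basal levels. The result always passes
#' [network_definition()] validation.
#'
#' @param spec a [fixture_spec()].
#' @return A [network_definition()].
#' @export
random_network <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_nodes
    internal <- paste0("N", seq_len(n - 2L))
    nodes <- data.frame(
      name = c("IN", internal, "OUT"),
      basal = c(0L, sample(c(-1L, 0L, 1L), n - 2L, replace = TRUE), 0L),
      role = c("input", rep("internal", n - 2L), "output"),
      stringsAsFactors = FALSE)
    chain <- c("IN", sample(internal), "OUT")
    links <- data.frame(source = chain[-n], target = chain[-1L],
                        weight = sample_weight(n - 1L, spec$weight_range),
                        stringsAsFactors = FALSE)
    # keep the backbone excitatory so OUT is dynamically reachable
    links$weight <- abs(links$weight)
    # one feedback link from late to early internal node
    if (n >= 5L) {
      links <- rbind(links, data.frame(source = chain[n - 1L], target = chain[2L],
                                       weight = sample_weight(1L, spec$weight_range),
                                       stringsAsFactors = FALSE))
    }
    # extra random links (no self loops, no duplicates, nothing into IN)
    for (s in c("IN", internal)) for (t in c(internal, "OUT")) {
      if (s == t) next
      if (any(links$source == s & links$target == t)) next
      if (stats::runif(1) < spec$link_density)
        links <- rbind(links, data.frame(source = s, target = t,
                                         weight = sample_weight(1L, spec$weight_range),
                                         stringsAsFactors = FALSE))
    }
    network_definition(nodes, links, "OUT",
                       version = paste0("random-", spec$seed))
  })
}

#' Full gene-node alteration map for a network
#'
#' Deterministic map giving every non-input, non-output node an activating
#' (`<node>_act` -> A) and an inactivating (`<node>_inact` -> I) alteration,
#' the node-level analog of curated functional-alteration tables.
#'
#' @param net a [network_definition()].
#' @return A [gene_node_map()].
#' @export
full_gene_node_map <- function(net) {
  nodes <- net$nodes$name[net$nodes$role == "internal"]
  gene_node_map(data.frame(
    alteration_id = c(paste0(nodes, "_act"), paste0(nodes, "_inact")),
    node = c(nodes, nodes),
    status = rep(c("A", "I"), each = length(nodes)),
    stringsAsFactors = FALSE), net)
}

#' Random alteration profiles for a network
#'
#' Draws `n` sample profiles with 1-4 alterations each (uniform count by
#' default, configurable through the spec), sampling distinct nodes and then
#' an activating or inactivating alteration per node, so a profile never
#' contradicts itself.
#'
#' @param net a [network_definition()].
#' @param n number of profiles.
#' @param spec a [fixture_spec()] (supplies the count range and seed).
#' @param map optional [gene_node_map()]; defaults to [full_gene_node_map()].
#' @param source profile source tag.
#' @return List of [alteration_profile()] objects.
#' @export
random_alteration_profiles <- function(net, n = 100L, spec = fixture_spec(),
                                       map = full_gene_node_map(net),
                                       source = "patient") {
  nodes <- unique(map$node)
  with_seed(derive_seed(spec$seed, 31L), {
    lapply(seq_len(n), function(i) {
      k <- if (spec$alterations_max == spec$alterations_min) spec$alterations_min
           else sample(spec$alterations_min:spec$alterations_max, 1L)
      k <- min(k, length(nodes))
      picked <- if (k > 0L) sample(nodes, k) else character()
      alts <- vapply(picked, function(nd) {
        cand <- map$alteration_id[map$node == nd]
        cand[sample.int(length(cand), 1L)]
      }, "")
      alteration_profile(sprintf("S%03d", i), unname(alts), source = source)
    })
  })
}

# -- determinant test-bed -----------------------------------------------------

#' Hand-designed determinant test-bed network
#'
#' A 8-node network built so that critical-determinant identification has
#' known ground truth for the drug that inhibits node `T`:
#' the control network never dies under the drug (node `C` is required for
#' the kill path and is OFF unless constitutively activated); activating
#' `C` (`C_act`) makes the drug fully effective; activating `Dm` (`Dm_act`)
#' caps the response at half of the initial states (a memory node `M` holds
#' its initial bit and breaks the tie), which dominates `C_act`; `P` is an
#' isolated passenger node whose alterations never change the dynamics.
#'
#' @return A [network_definition()].
#' @export
testbed_network <- function() {
  nodes <- data.frame(
    name = c("IN", "T", "C", "Dm", "M", "K", "P", "OUT"),
    basal = c(0L, 0L, -1L, -1L, 0L, 0L, -1L, -1L),
    role = c("input", rep("internal", 6L), "output"),
    stringsAsFactors = FALSE)
  links <- data.frame(
    source = c("IN", "T", "C", "M", "K", "Dm", "M"),
    target = c("T",  "K", "K", "OUT", "OUT", "OUT", "M"),
    weight = c(1L,  -2L,  1L,  1L,   3L,   -2L,   1L),
    stringsAsFactors = FALSE)
  # the M -> M self loop makes M hold its initial bit (a bistable memory)
  network_definition(nodes, links, "OUT", version = "testbed-1")
}

#' Cohort with an implanted, confounded ground truth
#'
#' Builds a cohort over the test-bed network (or any compatible network) in
#' which a causal alteration flips the drug response, a dominant alteration
#' overrides it, and a passenger alteration co-occurs with the causal one
#' without any dynamical effect. Cell counts follow the design frequencies
#' deterministically (rounded, then shuffled by seed), so every
#' response stratum is populated. Ground-truth D/U labels are produced by de
#' novo simulation of each distinct alteration combination, never assumed.
#'
#' @param net network; default [testbed_network()].
#' @param causal_plan list naming the `target` (a target object), `causal`,
#'   `dominant` (optional) and `passenger` alteration ids, the
#'   `co_occurrence` rate of passenger given causal, and the marginal
#'   frequencies `p_causal`, `p_dominant`.
#' @param n cohort size.
#' @param seed integer seed for the shuffle.
#' @param config,th simulation and threshold configuration.
#' @param map gene-node map; default [full_gene_node_map()].
#' @return List with `profiles`, `labels` (simulated D/U per profile),
#'   `truth` (causal/dominant/passenger ids and control response).
#' @export
confounded_cohort <- function(net = testbed_network(),
                              causal_plan = list(target = target_node("T"),
                                                 causal = "C_act",
                                                 dominant = "Dm_act",
                                                 passenger = "P_act",
                                                 co_occurrence = 0.6,
                                                 p_causal = 0.55,
                                                 p_dominant = 0.3),
                              n = 60L, seed = 1L,
                              config = sim_config(input_clamp = c(IN = 1L)),
                              th = threshold_config(),
                              map = full_gene_node_map(net)) {
  if (n == 0L) return(list(profiles = list(), labels = character(),
                           truth = causal_plan))
  plan <- causal_plan
  ctrl <- control_profile(net)
  respond <- function(alts) {
    cat0 <- categorize(net, alterations_to_status(alts, map, net), ctrl,
                       plan$target, config, th)
    if (cat0$desirable) "D" else "U"
  }
  control_response <- respond(character())
  causal_response <- respond(plan$causal)
  if (causal_response == control_response)
    stop_twin("therawin_infeasible_plan",
              "causal alteration %s does not change the drug response",
              plan$causal)
  # deterministic cell counts from the design frequencies
  has_dom <- !is.null(plan$dominant)
  p_c <- plan$p_causal; p_d <- if (has_dom) plan$p_dominant else 0
  cells <- list(
    c0d0 = (1 - p_c) * (1 - p_d), c1d0 = p_c * (1 - p_d),
    c0d1 = (1 - p_c) * p_d, c1d1 = p_c * p_d)
  counts <- vapply(cells, function(p)
    as.integer(max(if (p > 0) 1 else 0, round(p * n))), 0L)
  counts[["c0d0"]] <- counts[["c0d0"]] + (n - sum(counts))
  combos <- list()
  for (cell in names(counts)) for (i in seq_len(counts[[cell]])) {
    alts <- character()
    if (grepl("c1", cell)) alts <- c(alts, plan$causal)
    if (grepl("d1", cell)) alts <- c(alts, plan$dominant)
    combos[[length(combos) + 1L]] <- alts
  }
  # passenger co-occurs with the causal alteration at the design rate
  with_seed(derive_seed(seed, 97L), {
    combos <- lapply(combos, function(alts) {
      rate <- if (plan$causal %in% alts) plan$co_occurrence
              else (1 - plan$co_occurrence) / 2
      if (stats::runif(1) < rate) c(alts, plan$passenger) else alts
    })
    combos <- sample(combos)
  })
  labels_by_key <- new.env(parent = emptyenv())
  labels <- vapply(combos, function(alts) {
    key <- subset_id(alts)
    if (is.null(labels_by_key[[key]])) labels_by_key[[key]] <- respond(alts)
    labels_by_key[[key]]
  }, "")
  profiles <- lapply(seq_along(combos), function(i)
    alteration_profile(sprintf("C%03d", i), combos[[i]], source = "cell_line"))
  list(profiles = profiles, labels = labels,
       truth = c(plan, list(control_response = control_response,
                            causal_response = causal_response)))
}

#' Search a random network for an implantable causal alteration
#'
#' Screens candidate single alterations of a network for one whose presence
#' moves the drug's efficacy-potency point far from the control point
#' (distance >= `effect_min`), plus passenger alterations that move it less
#' than `passenger_max`. Used to build parameter-recovery fixtures with
#' verified ground truth.
#'
#' @param net a [network_definition()].
#' @param target drug target (default: inhibit the first internal node on
#'   the backbone).
#' @param config,doses simulation settings.
#' @param map gene-node map.
#' @param effect_min,passenger_max Euclidean distance thresholds in the
#'   efficacy-potency plane.
#' @param n_passengers passengers required.
#' @return List `list(target, causal, passengers)` or `NULL` when the
#'   network admits no plan.
#' @export
implant_causal_plan <- function(net, target = NULL,
                                config = sim_config(input_clamp = c(IN = 1L)),
                                doses = seq(0, 1, by = 0.1),
                                map = full_gene_node_map(net),
                                effect_min = 0.3, passenger_max = 0.05,
                                n_passengers = 2L) {
  point <- function(alts, tgt) {
    f <- normalize_curve(dose_sweep(net, alterations_to_status(alts, map, net),
                                    tgt, config, doses))
    c(efficacy(f), ic50(f))
  }
  # cheap deterministic screen: the normalized full-dose effect of a node
  # drug equals basin(profile + target I-clamp) - basin(profile), both exact
  # through the attractor-landscape path
  rough <- function(alts, tgt) {
    prof <- alterations_to_status(alts, map, net)
    clamped <- as.character(prof)
    names(clamped) <- names(prof)
    clamped[tgt$node] <- "I"
    d0 <- basin_of_apoptosis(net, prof, config)
    d1 <- basin_of_apoptosis(net, status_profile(net, clamped[clamped != "N"]),
                             config)
    c(eff = max(d1 - d0, 0), base = d0)
  }
  targets <- if (!is.null(target)) list(target) else
    lapply(net$nodes$name[net$nodes$role == "internal"], target_node)
  for (tgt in targets) {
    if (tgt$kind != "node") stop_schema("implant search screens node targets")
    # alterations on the target's own node would be confounded with the drug
    usable <- map$alteration_id[map$node != tgt$node]
    r0 <- rough(character(), tgt)
    rr <- vapply(usable, function(a) rough(a, tgt), c(eff = 0, base = 0))
    causal_cand <- usable[abs(rr["eff", ] - r0[["eff"]]) >= effect_min &
                            abs(rr["base", ] - r0[["base"]]) < 0.05]
    pass_cand <- usable[abs(rr["eff", ] - r0[["eff"]]) < passenger_max / 2 &
                          abs(rr["base", ] - r0[["base"]]) < passenger_max / 2]
    if (!length(causal_cand) || length(pass_cand) < n_passengers) next
    # confirm with full dose-response points
    p0 <- point(character(), tgt)
    effs <- vapply(causal_cand, function(a)
      sqrt(sum((point(a, tgt) - p0)^2)), 0)
    causal <- causal_cand[effs >= effect_min]
    if (!length(causal)) next
    ca <- causal[1L]
    pc <- point(ca, tgt)
    # a passenger must be inert both alone and alongside the causal alteration
    passengers <- character()
    for (p in pass_cand) {
      if (map$node[match(p, map$alteration_id)] ==
          map$node[match(ca, map$alteration_id)]) next
      if (sqrt(sum((point(p, tgt) - p0)^2)) < passenger_max &&
          sqrt(sum((point(c(ca, p), tgt) - pc)^2)) < passenger_max)
        passengers <- c(passengers, p)
      if (length(passengers) >= n_passengers) break
    }
    if (length(passengers) >= n_passengers)
      return(list(target = tgt, causal = ca, passengers = passengers))
  }
  NULL
}
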