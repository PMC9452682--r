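#' All subnetworks of a cancer network
#'
#' Generates every subset of a sample's genomic alterations (including the
#' empty set, i.e. the control network, and the full set, i.e. the original
#' cancer network). Each subset defines a subnetwork whose dose-response is
#' simulated independently during critical-determinant identification.
#'
#' @param alterations character vector of alteration ids.
#' @param cap largest allowed alteration count (2^cap subsets).
#' @return List of character vectors in binary-counting order over the
#'   alteration list (first alteration toggling fastest); element 1 is the
#'   empty subset.
#' @export
subnetworks <- function(alterations, cap = 12L) {
  alterations <- as.character(alterations)
  k <- length(alterations)
  if (k > cap)
    stop_twin("therawin_enumeration_error",
              "profile has %d alterations (> cap %d subsets would be 2^%d)",
              k, cap, k)
  lapply(0:(2^k - 1), function(m) alterations[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
}

subset_id <- function(alts) if (length(alts)) paste(sort(alts), collapse = ";") else "(control)"

#' Efficacy-potency map of all subnetworks
#'
#' Simulates the drug perturbation in every subnetwork of a cancer profile
#' and places each on the two-dimensional efficacy-potency plane (efficacy =
#' maximal normalized response; potency = IC50, with non-responding networks
#' at IC50 = 1). The control network is subset 1 and the original cancer
#' network the last subset.
#'
#' @inheritParams categorize
#' @param alterations alteration ids of the cancer profile.
#' @param map a [gene_node_map()].
#' @param targets the drug perturbation (target or list of targets).
#' @return data.frame with columns `subset_id`, `n_alterations`, `efficacy`,
#'   `potency`, plus the subsets as attribute `"subsets"`.
#' @export
efficacy_potency_map <- function(net, alterations, map, targets,
                                 config = sim_config(),
                                 doses = seq(0, 1, by = 0.1)) {
  subs <- subnetworks(alterations)
  pts <- lapply(subs, function(alt) {
    prof <- alterations_to_status(alt, map, net)
    f <- normalize_curve(dose_sweep(net, prof, targets, config, doses))
    c(efficacy = efficacy(f), potency = ic50(f))
  })
  out <- data.frame(
    subset_id = vapply(subs, subset_id, ""),
    n_alterations = vapply(subs, length, 0L),
    efficacy = vapply(pts, `[[`, 0, "efficacy"),
    potency = vapply(pts, `[[`, 0, "potency"),
    stringsAsFactors = FALSE)
  attr(out, "subsets") <- subs
  out
}

#' Critical determinant of a drug response
#'
#' The critical determinant is the minimal set of genomic alterations that
#' dominantly fixes the network's drug response. Operationally: take the
#' subnetworks whose Euclidean distance to the original cancer network in
#' the efficacy-potency plane is below `radius` (the neighbor set, which
#' always contains the original); intersect their alteration subsets; the
#' intersection is the determinant provided it is non-empty and is itself a
#' neighbor. Otherwise no determinant exists and the network responds like
#' the control network.
#'
#' @param points output of [efficacy_potency_map()] (its last row is the
#'   original cancer network).
#' @param radius neighborhood radius in the efficacy-potency plane.
#' @return List with `alterations` and the neighbor `subset_id`s, or `NULL`
#'   when no determinant exists.
#' @export
critical_determinant <- function(points, radius = 0.1) {
  subs <- attr(points, "subsets")
  if (is.null(subs)) stop_schema("points must come from efficacy_potency_map()")
  orig <- nrow(points)
  d <- sqrt((points$efficacy - points$efficacy[orig])^2 +
              (points$potency - points$potency[orig])^2)
  nb <- which(d < radius)
  common <- Reduce(intersect, subs[nb])
  if (length(common) == 0L) return(NULL)
  is_nb <- any(vapply(subs[nb], function(s) set_equal(s, common), TRUE))
  if (!is_nb) return(NULL)
  list(alterations = sort(common),
       neighbors = vapply(subs[nb], subset_id, ""))
}

#' Identify the critical determinant of one cancer network
#'
#' Convenience wrapper: builds the efficacy-potency map of all subnetworks,
#' extracts the critical determinant, and labels it with the desirable (D) /
#' undesirable (U) response of the original cancer network under the
#' perturbation.
#'
#' @inheritParams efficacy_potency_map
#' @param control control-network profile used for the D/U call.
#' @param radius neighborhood radius.
#' @param th a [threshold_config()].
#' @return List of class `critical_determinant` (`alterations`, `response`,
#'   `level` initialized to NA) or `NULL`.
#' @export
find_critical_determinant <- function(net, alterations, map, targets,
                                      control = control_profile(net),
                                      config = sim_config(),
                                      th = threshold_config(),
                                      doses = seq(0, 1, by = 0.1),
                                      radius = 0.1) {
  pts <- efficacy_potency_map(net, alterations, map, targets, config, doses)
  cd <- critical_determinant(pts, radius)
  if (is.null(cd)) return(NULL)
  cat0 <- categorize(net, alterations_to_status(alterations, map, net),
                     control, targets, config, th, doses)
  structure(list(alterations = cd$alterations,
                 response = if (cat0$desirable) "D" else "U",
                 level = NA_integer_),
            class = "critical_determinant")
}

#' Dominance hierarchy of critical determinants
#'
#' For every pair of one desirable and one undesirable critical determinant,
#' simulates the test network carrying both alteration sets; the determinant
#' whose label matches the test network's D/U response dominates the pair.
#' Determinants are then layered so that a determinant sits one level above
#' the highest determinant it dominates (level 1 is the lowest). An
#' inconsistent set of pairwise results that forms a cycle is reported as an
#' error.
#'
#' @inheritParams efficacy_potency_map
#' @param determinants list of `critical_determinant` objects (labelled D/U).
#' @param control control profile for the D/U calls.
#' @param th a [threshold_config()].
#' @return Object of class `dominance_hierarchy`: `determinants` (with
#'   levels filled in), `pairwise` data.frame.
#' @export
dominance <- function(determinants, net, map, targets,
                      control = control_profile(net),
                      config = sim_config(), th = threshold_config(),
                      doses = seq(0, 1, by = 0.1)) {
  k <- length(determinants)
  labels <- vapply(determinants, `[[`, "", "response")
  ids <- vapply(determinants, function(d) subset_id(d$alterations), "")
  if (anyDuplicated(ids)) stop_schema("duplicate determinants supplied")
  beats <- matrix(FALSE, k, k, dimnames = list(ids, ids))
  pair_rows <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j || labels[i] == labels[j]) next
    union_alts <- union(determinants[[i]]$alterations, determinants[[j]]$alterations)
    cat_u <- categorize(net, alterations_to_status(union_alts, map, net),
                        control, targets, config, th, doses)
    outcome <- if (cat_u$desirable) "D" else "U"
    win <- if (labels[i] == outcome) i else j
    lose <- if (win == i) j else i
    beats[win, lose] <- TRUE
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      d_i = ids[i], d_j = ids[j], outcome = outcome, winner = ids[win],
      stringsAsFactors = FALSE)
  }
  # layering: level = 1 + max level among dominated determinants
  level <- rep(NA_integer_, k)
  remaining <- seq_len(k)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      dom <- which(beats[i, ])
      all(!dom %in% remaining)
    }, TRUE)]
    if (!length(ready)) {
      if (length(remaining))
        stop_twin("therawin_dominance_cycle",
                  "cyclic dominance among determinants: %s",
                  paste(ids[remaining], collapse = ", "))
      break
    }
    for (i in ready) {
      dom <- which(beats[i, ])
      level[i] <- if (length(dom)) max(level[dom]) + 1L else 1L
    }
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  dets <- lapply(seq_len(k), function(i) {
    d <- determinants[[i]]; d$level <- level[i]; d
  })
  structure(list(determinants = dets,
                 pairwise = if (length(pair_rows)) do.call(rbind, pair_rows)
                            else data.frame(d_i = character(), d_j = character(),
                                            outcome = character(), winner = character())),
            class = "dominance_hierarchy")
}

#' @export
print.dominance_hierarchy <- function(x, ...) {
  lv <- vapply(x$determinants, `[[`, 0L, "level")
  for (l in sort(unique(lv), decreasing = TRUE)) {
    ds <- x$determinants[lv == l]
    cat(sprintf("Lv%d: %s\n", l,
                paste(vapply(ds, function(d)
                  sprintf("%s (%s)", subset_id(d$alterations), d$response), ""),
                  collapse = "; ")))
  }
  invisible(x)
}

#' Predict the drug response of a profile from a dominance hierarchy
#'
#' Among the determinants whose alteration set is contained in the profile,
#' the one at the highest dominance level dictates the response; profiles
#' carrying no determinant respond like the control network. Conflicting
#' labels at the governing level raise an error.
#'
#' @param alterations alteration ids of the profile (or an
#'   [alteration_profile()]).
#' @param hierarchy a [dominance()] result.
#' @param control_response `"D"` or `"U"`: the control network's response.
#' @return `"D"` or `"U"`.
#' @export
predict_response <- function(alterations, hierarchy, control_response) {
  if (inherits(alterations, "alteration_profile"))
    alterations <- alterations$alterations
  present <- Filter(function(d) all(d$alterations %in% alterations),
                    hierarchy$determinants)
  if (!length(present)) return(control_response)
  lv <- vapply(present, `[[`, 0L, "level")
  top <- present[lv == max(lv)]
  lab <- unique(vapply(top, `[[`, "", "response"))
  if (length(lab) > 1L)
    stop_twin("therawin_dominance_conflict",
              "conflicting determinants at level %d", max(lv))
  lab
}

# governing determinant of a profile, or NA when none applies
governing_determinant <- function(alterations, hierarchy) {
  present <- which(vapply(hierarchy$determinants, function(d)
    all(d$alterations %in% alterations), TRUE))
  if (!length(present)) return(NA_integer_)
  lv <- vapply(hierarchy$determinants[present], `[[`, 0L, "level")
  present[which.max(lv)]
}

#' Enrichment-based conventional biomarkers (baseline)
#'
#' The conventional single-biomarker baseline: rank individual alterations
#' by the two-sided Fisher's exact p-value of their association with the
#' D/U response split, keep the top k, and predict the enriched class for
#' profiles carrying the marker (the other class otherwise).
#'
#' @param profiles list of alteration-id vectors (or [alteration_profile()]s).
#' @param labels character vector of `"D"`/`"U"` responses, one per profile.
#' @param k number of markers to keep.
#' @return data.frame of class `marker_set`: `alteration`, `p_value`,
#'   `enriched_class`.
#' @export
marker_enrichment_baseline <- function(profiles, labels, k = 5L) {
  profiles <- lapply(profiles, function(p)
    if (inherits(p, "alteration_profile")) p$alterations else as.character(p))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop_schema("both D and U responses are required to rank markers")
  alts <- sort(unique(unlist(profiles)))
  rows <- lapply(alts, function(a) {
    present <- vapply(profiles, function(p) a %in% p, TRUE)
    tab <- table(factor(present, levels = c(TRUE, FALSE)),
                 factor(labels, levels = c("D", "U")))
    p <- stats::fisher.test(tab)$p.value
    prop_d <- mean(present[labels == "D"])
    prop_u <- mean(present[labels == "U"])
    data.frame(alteration = a, p_value = p,
               enriched_class = if (prop_d >= prop_u) "D" else "U",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$alteration), , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  class(out) <- c("marker_set", "data.frame")
  out
}

#' @rdname marker_enrichment_baseline
#' @param marker one row of the marker table (or its `alteration` and
#'   `enriched_class`).
#' @export
predict_by_marker <- function(profiles, marker) {
  profiles <- lapply(profiles, function(p)
    if (inherits(p, "alteration_profile")) p$alterations else as.character(p))
  other <- if (marker$enriched_class == "D") "U" else "D"
  vapply(profiles, function(p)
    if (marker$alteration %in% p) marker$enriched_class else other, "")
}

#' Prediction performance against simulated truth
#'
#' @param predicted,actual character vectors of `"D"`/`"U"` labels.
#' @param positive class treated as positive (default `"D"`).
#' @return List with `sensitivity`, `specificity`, `accuracy`.
#' @export
evaluate_prediction <- function(predicted, actual, positive = "D") {
  if (length(predicted) != length(actual))
    stop_schema("label vectors must have equal length")
  tp <- sum(predicted == positive & actual == positive)
  tn <- sum(predicted != positive & actual != positive)
  fp <- sum(predicted == positive & actual != positive)
  fn <- sum(predicted != positive & actual == positive)
  list(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(actual))
}

#' Stratify profiles by their governing determinant
#'
#' Partitions a cohort by the highest-level critical determinant each
#' profile carries; profiles without any determinant form their own cluster
#' (`"none"`). By construction every cluster is response-pure: all members
#' share the predicted D/U response.
#'
#' @inheritParams predict_response
#' @param profiles list of alteration-id vectors or [alteration_profile()]s.
#' @return data.frame with `sample`, `cluster` (determinant id or "none"),
#'   `predicted` response.
#' @export
stratify <- function(profiles, hierarchy, control_response) {
  ids <- vapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    if (inherits(p, "alteration_profile")) p$sample_id else paste0("sample_", i)
  }, "")
  alts <- lapply(profiles, function(p)
    if (inherits(p, "alteration_profile")) p$alterations else as.character(p))
  gov <- vapply(alts, governing_determinant, 0L, hierarchy = hierarchy)
  cluster <- ifelse(is.na(gov), "none",
                    vapply(gov, function(i)
                      if (is.na(i)) "none"
                      else subset_id(hierarchy$determinants[[i]]$alterations), ""))
  predicted <- vapply(alts, predict_response, "", hierarchy = hierarchy,
                      control_response = control_response)
  data.frame(sample = ids, cluster = cluster, predicted = predicted,
             stringsAsFactors = FALSE)
}
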