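#' Alteration profiles and gene-to-node maps
#'
#' An alteration profile is the binarized functional-genomic description of
#' one sample: a set of alteration identifiers (e.g. `AKT_act`), each of
#' which the gene-node map projects onto a network node with a resulting
#' clamp status (`A` constantly activated, `I` constantly inactivated).
#'
#' @param sample_id sample identifier.
#' @param source `"cell_line"` or `"patient"`.
#' @param alterations character vector of alteration ids (unique).
#' @return `alteration_profile()` returns an object of class
#'   `alteration_profile`; `gene_node_map()` a validated map data.frame.
#' @export
alteration_profile <- function(sample_id, alterations = character(),
                               source = c("cell_line", "patient")) {
  source <- match.arg(source)
  alterations <- as.character(alterations)
  if (anyDuplicated(alterations))
    stop_schema("duplicated alteration id in profile %s", sample_id)
  structure(list(sample_id = as.character(sample_id), source = source,
                 alterations = alterations), class = "alteration_profile")
}

#' @rdname alteration_profile
#' @param map data.frame with columns `alteration_id`, `node`, `status`.
#' @param net network the map targets (node names validated against it).
#' @export
gene_node_map <- function(map, net) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("alteration_id", "node", "status")
  if (!all(need %in% names(map)))
    stop_schema("gene-node map must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(map$alteration_id))
    stop_schema("duplicated alteration_id in gene-node map")
  unknown <- setdiff(map$node, node_names(net))
  if (length(unknown)) stop_schema("map targets unknown node: %s", unknown[1L])
  if (!all(map$status %in% c("A", "I")))
    stop_schema("map status must be A or I (N is not an alteration)")
  structure(map, class = c("gene_node_map", "data.frame"))
}

#' Project an alteration profile onto node statuses
#'
#' Every alteration in the profile clamps its mapped node to the mapped
#' status; all remaining nodes stay input-dependent (`N`). The empty profile
#' yields the control network. Two alterations assigning conflicting statuses
#' to the same node raise a conflict error (or, in `"I_over_A"` mode,
#' resolve in favor of inactivation).
#'
#' @param profile an [alteration_profile()] or character vector of ids.
#' @param map a [gene_node_map()].
#' @param net the [network_definition()].
#' @param on_unknown `"error"` (default) or `"skip"` for alteration ids
#'   absent from the map.
#' @param on_conflict `"error"` (default) or `"I_over_A"`.
#' @return A [status_profile()].
#' @export
alterations_to_status <- function(profile, map, net,
                                  on_unknown = c("error", "skip"),
                                  on_conflict = c("error", "I_over_A")) {
  on_unknown <- match.arg(on_unknown)
  on_conflict <- match.arg(on_conflict)
  alts <- if (inherits(profile, "alteration_profile")) profile$alterations
          else as.character(profile)
  idx <- match(alts, map$alteration_id)
  if (anyNA(idx)) {
    missing <- alts[is.na(idx)]
    if (on_unknown == "error")
      stop_schema("alteration id not in map: %s", paste(missing, collapse = ", "))
    idx <- idx[!is.na(idx)]
  }
  hits <- map[idx, , drop = FALSE]
  statuses <- character()
  for (nd in unique(hits$node)) {
    st <- unique(hits$status[hits$node == nd])
    if (length(st) > 1L) {
      if (on_conflict == "error")
        stop_twin("therawin_conflict_error",
                  "conflicting statuses for node %s from alterations: %s", nd,
                  paste(hits$alteration_id[hits$node == nd], collapse = ", "))
      st <- "I"
    }
    statuses[nd] <- st
  }
  status_profile(net, statuses)
}

profile_key <- function(status) paste(as.character(status), collapse = "")

#' Collapse samples into unique differentially wired networks
#'
#' Samples whose alteration profiles map to byte-identical status profiles
#' describe the same rewired network; they are merged into one unique network
#' whose member list records every contributing sample. Network ids are
#' assigned in first-member order.
#'
#' @param mapped list of entries `list(sample_id, source, status)` where
#'   `status` is a [status_profile()] (see [map_cohort()]).
#' @param id_prefix prefix for generated network ids.
#' @return List of `unique_network` objects: `network_id`, `profile`,
#'   `members`, `sources`.
#' @export
dedupe_profiles <- function(mapped, id_prefix = "UN") {
  keys <- vapply(mapped, function(e) profile_key(e$status), "")
  uniq <- !duplicated(keys)
  out <- vector("list", sum(uniq))
  ids <- paste0(id_prefix, "_", seq_len(sum(uniq)))
  ukeys <- keys[uniq]
  for (i in seq_along(ukeys)) {
    members <- which(keys == ukeys[i])
    srcs <- vapply(mapped[members], `[[`, "", "source")
    out[[i]] <- structure(list(
      network_id = ids[i],
      profile = mapped[[members[1L]]]$status,
      members = vapply(mapped[members], `[[`, "", "sample_id"),
      sources = table(factor(srcs, levels = c("cell_line", "patient")))
    ), class = "unique_network")
  }
  out
}

#' Map a cohort of alteration profiles
#'
#' Convenience wrapper producing the input of [dedupe_profiles()] from a list
#' of [alteration_profile()] objects.
#'
#' @inheritParams alterations_to_status
#' @param profiles list of [alteration_profile()] objects.
#' @return List of `list(sample_id, source, status)` entries.
#' @export
map_cohort <- function(profiles, map, net, on_unknown = "error") {
  lapply(profiles, function(p) list(
    sample_id = p$sample_id, source = p$source,
    status = alterations_to_status(p, map, net, on_unknown = on_unknown)))
}

#' Exclude networks that die spontaneously
#'
#' Computes the unperturbed basin of apoptosis of each unique network and
#' retains those whose basin does not exceed the cutoff ("larger than half
#' are excluded", so a basin of exactly 0.5 is kept). The audit table of all
#' decisions is attached as attribute `"audit"`.
#'
#' @param networks list of `unique_network` objects from [dedupe_profiles()].
#' @param net the [network_definition()].
#' @param config a [sim_config()]; its `input_clamp` sets the baseline
#'   scenario (DNA damage OFF by default).
#' @param cutoff basin cutoff (default 0.5).
#' @return Filtered list, with attribute `audit` (data.frame network_id,
#'   basin, kept).
#' @export
filter_by_basin <- function(networks, net, config = sim_config(), cutoff = 0.5) {
  basins <- vapply(networks, function(u)
    basin_of_apoptosis(net, u$profile, config), 0)
  keep <- basins <= cutoff
  audit <- data.frame(
    network_id = vapply(networks, `[[`, "", "network_id"),
    basin = basins, kept = keep, stringsAsFactors = FALSE)
  structure(networks[keep], audit = audit)
}

#' Network similarity of two status profiles
#'
#' Pearson correlation of the ternary encodings A=+1, N=0, I=-1 over the
#' shared node universe, ranging from -1 to 1. When either profile has no
#' variance (e.g. the all-N control network) the similarity is undefined and
#' `NA` is returned.
#'
#' @param a,b [status_profile()] objects over the same nodes.
#' @return Correlation in [-1, 1], or `NA`.
#' @export
similarity <- function(a, b) {
  if (!identical(names(a), names(b)))
    stop_schema("profiles are defined over different node sets")
  enc <- c(A = 1, N = 0, I = -1)
  x <- enc[as.character(a)]; y <- enc[as.character(b)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  unname(stats::cor(x, y))
}

#' Networks common to the cell-line and patient cohorts
#'
#' Extracts the unique networks whose status profile occurs in both sources,
#' merging member lists. The matched networks are labelled `NT_1 ...` in
#' descending order of total member count (ties broken by the lexicographic
#' profile key), a documented deterministic rule.
#'
#' @param cell_nets,patient_nets lists of `unique_network` objects derived
#'   from the same network definition.
#' @return List of merged `unique_network` objects with ids `NT_i`.
#' @export
common_networks <- function(cell_nets, patient_nets) {
  ck <- vapply(cell_nets, function(u) profile_key(u$profile), "")
  pk <- vapply(patient_nets, function(u) profile_key(u$profile), "")
  shared <- intersect(ck, pk)
  if (!length(shared)) return(list())
  merged <- lapply(shared, function(key) {
    a <- cell_nets[[match(key, ck)]]
    b <- patient_nets[[match(key, pk)]]
    list(profile = a$profile,
         members = c(a$members, b$members),
         sources = a$sources + b$sources,
         key = key)
  })
  ord <- order(-vapply(merged, function(m) length(m$members), 0L),
               vapply(merged, `[[`, "", "key"))
  merged <- merged[ord]
  lapply(seq_along(merged), function(i) {
    m <- merged[[i]]
    structure(list(network_id = paste0("NT_", i), profile = m$profile,
                   members = m$members, sources = m$sources),
              class = "unique_network")
  })
}

#' @export
print.unique_network <- function(x, ...) {
  alt <- names(x$profile)[x$profile != "N"]
  cat(sprintf("%s: %d member(s); clamped nodes: %s\n", x$network_id,
              length(x$members),
              if (length(alt)) paste0(alt, "=", x$profile[alt], collapse = ", ")
              else "(none: control)"))
  invisible(x)
}
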