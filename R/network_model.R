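#' Weighted-sum Boolean network definition
#'
#' Builds the core model object: a set of named nodes, each with an integer
#' basal level and a role (`input`, `output` or `internal`), and weighted
#' directed links between them. A node's next binary state is 1 exactly when
#' the weighted sum of its regulators' current states plus its basal level is
#' positive (see [step()]). One output node is designated as the death
#' readout: the phenotype of a trajectory is "cell death" when the steady
#' activity of that node exceeds the death threshold.
#'
#' @param nodes data.frame with columns `name`, `basal` (integer), `role`
#'   (one of `"input"`, `"output"`, `"internal"`).
#' @param links data.frame with columns `source`, `target`, `weight`
#'   (nonzero integer).
#' @param death_readout name of the output node whose activity defines the
#'   death phenotype.
#' @param version free-form model version string kept in metadata.
#' @return An object of class `network_definition` with components `nodes`,
#'   `links`, `death_readout`, the weight matrix `W` (`W[j, i]` = weight of
#'   the link j -> i) and the basal-level vector `basal`.
#' @seealso [load_network()], [write_network()], [step()], [simulate()]
#' @export
network_definition <- function(nodes, links, death_readout, version = "1") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  need <- c("name", "basal", "role")
  if (!all(need %in% names(nodes)))
    stop_schema("node table must have columns %s", paste(need, collapse = ", "))
  need <- c("source", "target", "weight")
  if (nrow(links) > 0 && !all(need %in% names(links)))
    stop_schema("link table must have columns %s", paste(need, collapse = ", "))
  nodes$name <- as.character(nodes$name)
  nodes$role <- as.character(nodes$role)
  if (anyDuplicated(nodes$name))
    stop_schema("duplicated node name: %s",
                paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  if (!all(nodes$role %in% c("input", "output", "internal")))
    stop_schema("unknown node role: %s",
                paste(setdiff(nodes$role, c("input", "output", "internal")), collapse = ", "))
  bad <- nodes$name[nodes$basal != round(nodes$basal)]
  if (length(bad)) stop_schema("non-integer basal level for node %s", bad[1L])
  nodes$basal <- as.integer(nodes$basal)
  if (nrow(links) > 0) {
    links$source <- as.character(links$source)
    links$target <- as.character(links$target)
    for (col in c("source", "target")) {
      unknown <- setdiff(links[[col]], nodes$name)
      if (length(unknown))
        stop_schema("link %s node '%s' is not a declared node", col, unknown[1L])
    }
    if (any(links$weight != round(links$weight)) || any(links$weight == 0)) {
      bad <- which(links$weight == 0 | links$weight != round(links$weight))[1L]
      stop_schema("link %s -> %s has invalid weight %s (nonzero integer required)",
                  links$source[bad], links$target[bad], format(links$weight[bad]))
    }
    links$weight <- as.integer(links$weight)
    if (anyDuplicated(paste(links$source, links$target)))
      stop_schema("duplicated link definition")
  }
  if (length(death_readout) != 1L || !death_readout %in% nodes$name)
    stop_schema("death readout '%s' is not a declared node", as.character(death_readout)[1L])
  if (nodes$role[nodes$name == death_readout] != "output")
    stop_schema("death readout '%s' must have role 'output'", death_readout)

  n <- nrow(nodes)
  W <- matrix(0L, n, n, dimnames = list(nodes$name, nodes$name))
  if (nrow(links) > 0)
    W[cbind(match(links$source, nodes$name), match(links$target, nodes$name))] <- links$weight
  structure(list(
    nodes = nodes, links = links,
    death_readout = as.character(death_readout),
    version = as.character(version),
    W = W, basal = stats::setNames(nodes$basal, nodes$name)
  ), class = "network_definition")
}

#' @export
print.network_definition <- function(x, ...) {
  cat(sprintf("Weighted-sum Boolean network (v%s): %d nodes, %d links\n",
              x$version, nrow(x$nodes), nrow(x$links)))
  cat(sprintf("  inputs: %s\n",
              paste(x$nodes$name[x$nodes$role == "input"], collapse = ", ")))
  cat(sprintf("  death readout: %s\n", x$death_readout))
  invisible(x)
}

node_names <- function(net) net$nodes$name
node_idx <- function(net, names) {
  i <- match(names, net$nodes$name)
  if (anyNA(i)) stop_schema("unknown node: %s", paste(names[is.na(i)], collapse = ", "))
  i
}
input_nodes <- function(net) net$nodes$name[net$nodes$role == "input"]

#' Read a network definition file
#'
#' Parses the plain-text sectioned format used for packaged and generated
#' models. The file has three tab/whitespace-separated sections introduced by
#' `[nodes]` (columns `name basal role`), `[links]` (`source target weight`)
#' and `[metadata]` (`key value` pairs; `death_readout` is required). Lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path path to a network file.
#' @return A validated [network_definition()].
#' @examples
#' net <- load_network(system.file("extdata", "toy3.net", package = "therawin"))
#' net
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop_schema("network file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  section <- NA_character_
  rows <- list(nodes = list(), links = list(), metadata = list())
  for (ln in raw) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(rows))
        stop_schema("unknown section [%s] in %s", section, path)
      next
    }
    if (is.na(section)) stop_schema("content before first section in %s", path)
    rows[[section]][[length(rows[[section]]) + 1L]] <- strsplit(ln, "[\t ]+")[[1]]
  }
  parse_tab <- function(entries, cols, what) {
    if (length(entries) == 0L) {
      out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols))
      return(out)
    }
    header <- entries[[1L]]
    body <- entries[-1L]
    if (!identical(header, cols))
      stop_schema("%s section header must be '%s'", what, paste(cols, collapse = " "))
    bad <- which(vapply(body, length, 1L) != length(cols))
    if (length(bad))
      stop_schema("malformed %s record: '%s'", what, paste(body[[bad[1L]]], collapse = " "))
    out <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
    names(out) <- cols
    out
  }
  nd <- parse_tab(rows$nodes, c("name", "basal", "role"), "nodes")
  lk <- parse_tab(rows$links, c("source", "target", "weight"), "links")
  nd$basal <- suppressWarnings(as.numeric(nd$basal))
  if (anyNA(nd$basal)) stop_schema("non-numeric basal level in %s", path)
  if (nrow(lk)) {
    lk$weight <- suppressWarnings(as.numeric(lk$weight))
    if (anyNA(lk$weight)) stop_schema("non-numeric link weight in %s", path)
  }
  meta <- rows$metadata
  kv <- list()
  for (m in meta) {
    if (length(m) != 2L) stop_schema("malformed metadata record in %s", path)
    kv[[m[1L]]] <- m[2L]
  }
  if (is.null(kv$death_readout))
    stop_schema("metadata section of %s must designate a death_readout", path)
  network_definition(nd, lk, kv$death_readout, version = kv$version %||% "1")
}

#' Write a network definition file
#'
#' Inverse of [load_network()]; emits the sectioned plain-text format.
#'
#' @param net a [network_definition()].
#' @param path output path.
#' @param header optional comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, header = character()) {
  out <- c(
    paste0("# ", c("therawin network definition", header)),
    "[nodes]", "name\tbasal\trole",
    sprintf("%s\t%d\t%s", net$nodes$name, net$nodes$basal, net$nodes$role),
    "[links]", "source\ttarget\tweight",
    if (nrow(net$links))
      sprintf("%s\t%s\t%d", net$links$source, net$links$target, net$links$weight),
    "[metadata]",
    sprintf("death_readout\t%s", net$death_readout),
    sprintf("version\t%s", net$version)
  )
  writeLines(out, path)
  invisible(path)
}

#' Ternary node-status profile
#'
#' A status profile clamps each node as constantly activated (`A`, forced ON),
#' constantly inactivated (`I`, forced OFF) or input-dependent (`N`, free to
#' follow the weighted-sum logic). Genomic alterations of a sample are
#' expressed as A/I clamps on the nominal network; the all-`N` profile is the
#' control network without alterations.
#'
#' @param net a [network_definition()].
#' @param statuses named character vector of `"A"`/`"I"` entries; nodes not
#'   mentioned default to `"N"`.
#' @return Named character vector over all nodes, class `status_profile`.
#' @export
status_profile <- function(net, statuses = character()) {
  prof <- stats::setNames(rep("N", nrow(net$nodes)), net$nodes$name)
  if (length(statuses)) {
    if (is.null(names(statuses)) || any(!nzchar(names(statuses))))
      stop_schema("statuses must be a named vector")
    unknown <- setdiff(names(statuses), net$nodes$name)
    if (length(unknown)) stop_schema("status for unknown node: %s", unknown[1L])
    if (!all(statuses %in% c("A", "I", "N")))
      stop_schema("status values must be A, I or N")
    prof[names(statuses)] <- statuses
  }
  structure(prof, class = "status_profile")
}

#' @rdname status_profile
#' @export
control_profile <- function(net) status_profile(net)

#' Simulation configuration
#'
#' Bundles the dynamics parameters: 100 transient update steps followed by
#' 100 steady steps over which node activities are averaged, a death
#' threshold of 0.9 on the death-readout activity, and the scenario-level
#' clamp of input nodes (e.g. DNA damage ON for therapeutic-window runs, OFF
#' for baseline basin filtering).
#'
#' @param transient_steps,steady_steps positive step counts.
#' @param death_threshold death-phenotype cutoff on steady activity, in (0,1).
#' @param input_clamp named 0/1 vector over input nodes; inputs not named are
#'   clamped to 0.
#' @param seed integer seed governing every stochastic draw downstream.
#' @param n_replicates independent per-step suppression schedules simulated
#'   per initial state (the published procedure corresponds to 1).
#' @param enumeration_cap largest number of free nodes for which the initial
#'   state space is enumerated exhaustively.
#' @param sample_states if non-NULL, sample this many initial states
#'   uniformly instead of enumerating (required beyond the cap).
#' @param strict logical; TRUE uses the strict update rule (sum > 0), FALSE
#'   the non-strict variant (sum >= 0), kept for sensitivity checks.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(transient_steps = 100L, steady_steps = 100L,
                       death_threshold = 0.9, input_clamp = NULL,
                       seed = 1L, n_replicates = 1L,
                       enumeration_cap = 22L, sample_states = NULL,
                       strict = TRUE) {
  if (transient_steps < 1L || steady_steps < 1L)
    stop_schema("step counts must be positive")
  if (death_threshold <= 0 || death_threshold >= 1)
    stop_schema("death_threshold must lie in (0,1)")
  structure(list(
    transient_steps = as.integer(transient_steps),
    steady_steps = as.integer(steady_steps),
    death_threshold = death_threshold,
    input_clamp = input_clamp,
    seed = as.integer(seed),
    n_replicates = as.integer(n_replicates),
    enumeration_cap = as.integer(enumeration_cap),
    sample_states = if (!is.null(sample_states)) as.integer(sample_states),
    strict = isTRUE(strict)
  ), class = "sim_config")
}
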