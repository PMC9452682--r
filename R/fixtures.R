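#' Packaged example networks
#'
#' `toy_network()` is the minimal three-node teaching model: X (basal 1,
#' constitutively ON) activates the death readout Z, Y (basal 0, OFF)
#' inhibits it. It has a single fixed-point attractor with Z ON, so its
#' basin of apoptosis is 1 and inhibiting X at dose 1 abolishes death.
#'
#' `p53_network()` loads the packaged 16-node p53-signaling model, a
#' *synthetic reconstruction*: node set (DNA damage input, ATM, p53, WIP1,
#' MDM2, MDMX, CYCG, PTEN, AKT, CYCE, RB, E2F1, ARF, BCL2, BAX and the CASP3
#' death readout), the canonical regulatory links of the p53 literature
#' (among them MDM2-|p53, MDM2->E2F1, CYCE-|RB, WIP1-|ARF, AKT->MDMX) and
#' the six designated drug-target nodes (AKT, BCL2, CYCE, MDM2, WIP1, ATM)
#' carrying 27 outgoing links with the screening-set combinatorics of the
#' published model (15 node pairs, 297 link pairs, 135 node-link pairs, 480
#' perturbations in total). Its weights and basal levels are package-chosen
#' minimal integers, so quantitative dynamics are illustrative, not a
#' transcription of any published parameter set.
#'
#' @return A [network_definition()].
#' @export
toy_network <- function() {
  load_network(system.file("extdata", "toy3.net", package = "therawin"))
}

#' @rdname toy_network
#' @export
p53_network <- function() {
  load_network(system.file("extdata", "p53_synthetic.net", package = "therawin"))
}

#' @rdname toy_network
#' @param net network returned by `p53_network()` (kept as an argument so
#'   the map can be validated against it).
#' @export
p53_gene_node_map <- function(net = p53_network()) {
  read_map(system.file("extdata", "p53_synthetic_map.csv", package = "therawin"),
           net)
}

#' @rdname toy_network
#' @export
p53_target_nodes <- function() c("AKT", "BCL2", "CYCE", "MDM2", "WIP1", "ATM")
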