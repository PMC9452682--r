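# Networks built in code for the test suite.

# memory network: OUT follows the OR of k self-sustaining memory nodes, so the
# basin of apoptosis is 1 - 2^-k (0.5 for k = 1, 0.75 for k = 2).
memory_net <- function(k = 1L) {
  mem <- paste0("M", seq_len(k))
  nodes <- data.frame(name = c(mem, "OUT"),
                      basal = c(rep(0L, k), 0L),
                      role = c(rep("internal", k), "output"),
                      stringsAsFactors = FALSE)
  links <- rbind(
    data.frame(source = mem, target = mem, weight = 1L, stringsAsFactors = FALSE),
    data.frame(source = mem, target = "OUT", weight = 1L, stringsAsFactors = FALSE))
  network_definition(nodes, links, "OUT")
}

# screening toy: two always-on target nodes A (links to P, Q) and B (link to
# R); OUT is the AND of P, Q, R, so inhibiting any single target kills OUT.
link_toy <- function() {
  nodes <- data.frame(
    name = c("A", "B", "P", "Q", "R", "OUT"),
    basal = c(1L, 1L, 0L, 0L, 0L, -2L),
    role = c(rep("internal", 5L), "output"),
    stringsAsFactors = FALSE)
  links <- data.frame(
    source = c("A", "A", "B", "P", "Q", "R"),
    target = c("P", "Q", "R", "OUT", "OUT", "OUT"),
    weight = 1L, stringsAsFactors = FALSE)
  network_definition(nodes, links, "OUT")
}

# build a normalized curve object directly (for metric unit tests)
mk_curve <- function(values, doses = seq(0, 1, length.out = length(values)),
                     normalized = TRUE) {
  structure(list(doses = doses, values = values, normalized = normalized,
                 meta = list(targets = "synthetic")),
            class = "dose_response_curve")
}

testbed_cfg <- function(seed = 1L, ...) {
  sim_config(input_clamp = c(IN = 1L), seed = seed, ...)
}

p53_cfg_on <- function(seed = 1L, ...) {
  sim_config(input_clamp = c(DNA_damage = 1L), seed = seed, ...)
}

p53_cfg_off <- function(seed = 1L, ...) {
  sim_config(input_clamp = c(DNA_damage = 0L), seed = seed, ...)
}

write_net_tempfile <- function(lines) {
  tf <- tempfile(fileext = ".net")
  writeLines(lines, tf)
  tf
}
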