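test_that("alteration profiles project onto node statuses", {
  net <- p53_network()
  map <- p53_gene_node_map(net)

  ctrl <- alterations_to_status(character(), map, net)
  expect_identical(unclass(ctrl), unclass(control_profile(net)))

  p <- alterations_to_status("AKT_act", map, net)
  expect_equal(unname(p["AKT"]), "A")
  expect_true(all(p[setdiff(names(p), "AKT")] == "N"))

  # conflicting statuses for one node
  expect_error(alterations_to_status(c("AKT_act", "AKT_inact"), map, net),
               "AKT", class = "therawin_conflict_error")
  resolved <- alterations_to_status(c("AKT_act", "AKT_inact"), map, net,
                                    on_conflict = "I_over_A")
  expect_equal(unname(resolved["AKT"]), "I")

  expect_error(alterations_to_status("NOPE_act", map, net),
               "NOPE_act", class = "therawin_schema_error")
  skipped <- alterations_to_status(c("NOPE_act", "AKT_act"), map, net,
                                   on_unknown = "skip")
  expect_equal(unname(skipped["AKT"]), "A")
})

test_that("dedupe collapses identical status profiles deterministically", {
  net <- p53_network()
  map <- p53_gene_node_map(net)
  mk <- function(id, alts, src) list(
    sample_id = id, source = src,
    status = alterations_to_status(alts, map, net))

  mapped <- list(mk("a", "AKT_act", "patient"),
                 mk("b", "AKT_act", "cell_line"),
                 mk("c", "BAX_inact", "patient"))
  uniq <- dedupe_profiles(mapped)
  expect_length(uniq, 2L)
  expect_equal(uniq[[1L]]$members, c("a", "b"))
  expect_equal(unname(uniq[[1L]]$sources[["patient"]]), 1L)
  expect_equal(unname(uniq[[1L]]$sources[["cell_line"]]), 1L)

  # n all-distinct profiles give n networks
  distinct <- list(mk("a", "AKT_act", "patient"),
                   mk("b", "MDM2_act", "patient"),
                   mk("c", "BCL2_act", "patient"))
  expect_length(dedupe_profiles(distinct), 3L)

  # idempotent and order-insensitive up to id relabeling
  shuffled <- dedupe_profiles(mapped[c(3L, 1L, 2L)])
  key <- function(u) therawin:::profile_key(u$profile)
  expect_setequal(vapply(uniq, key, ""), vapply(shuffled, key, ""))
  expect_setequal(
    vapply(uniq, function(u) paste(sort(u$members), collapse = ","), ""),
    vapply(shuffled, function(u) paste(sort(u$members), collapse = ","), ""))
})

test_that("basin filter retains 'basin <= half' and audits every decision", {
  # memory networks give exact basins of 0.5 and 0.75
  net <- memory_net(2L)
  cfg <- sim_config()
  ctrl <- control_profile(net)
  half <- status_profile(net, c(M2 = "I"))   # OUT follows M1 only -> basin 0.5
  mk <- function(id, status) structure(
    list(network_id = id, profile = status, members = id,
         sources = table(factor("patient", levels = c("cell_line", "patient")))),
    class = "unique_network")
  nets <- list(mk("UN_1", half), mk("UN_2", ctrl))
  kept <- filter_by_basin(nets, net, cfg, cutoff = 0.5)
  audit <- attr(kept, "audit")
  expect_equal(audit$basin, c(0.5, 0.75))
  expect_equal(audit$kept, c(TRUE, FALSE))   # boundary 0.5 retained
  expect_length(kept, 1L)
  expect_equal(kept[[1L]]$network_id, "UN_1")
})

test_that("network similarity is a ternary Pearson correlation", {
  net <- toy_network()
  a <- status_profile(net, c(X = "A", Y = "I"))
  expect_equal(similarity(a, a), 1)

  mirror <- status_profile(net, c(X = "I", Y = "A", Z = "A"))
  full <- status_profile(net, c(X = "A", Y = "I", Z = "I"))
  expect_equal(similarity(full, mirror), -1)

  # frozen hand computation: (A,A,I) vs (A,I,I) encodes to r = 1/2
  b <- status_profile(net, c(X = "A", Y = "A", Z = "I"))
  c_ <- status_profile(net, c(X = "A", Y = "I", Z = "I"))
  expect_equal(similarity(b, c_), 0.5)

  # orthogonal alteration patterns: (A,N,I,N) vs (N,A,N,I) has zero covariance
  net4 <- network_definition(
    data.frame(name = c("a", "b", "c", "d"), basal = 0L,
               role = c("internal", "internal", "internal", "output")),
    data.frame(source = "a", target = "d", weight = 1L), "d")
  p1 <- status_profile(net4, c(a = "A", c = "I"))
  p2 <- status_profile(net4, c(b = "A", d = "I"))
  expect_equal(similarity(p1, p2), 0)

  # undefined against the zero-variance control profile
  expect_true(is.na(similarity(control_profile(net), a)))
  # symmetry
  expect_equal(similarity(a, full), similarity(full, a))
  expect_error(similarity(a, p1), class = "therawin_schema_error")
})

test_that("common networks are matched, merged and labelled NT_i", {
  net <- p53_network()
  map <- p53_gene_node_map(net)
  mk <- function(id, alts, src) list(
    sample_id = id, source = src,
    status = alterations_to_status(alts, map, net))

  cells <- dedupe_profiles(list(mk("c1", "AKT_act", "cell_line"),
                                mk("c2", "MDM2_act", "cell_line")))
  pats_disjoint <- dedupe_profiles(list(mk("p1", "BCL2_act", "patient")))
  expect_length(common_networks(cells, pats_disjoint), 0L)

  pats <- dedupe_profiles(list(mk("p1", "AKT_act", "patient"),
                               mk("p2", "MDM2_act", "patient"),
                               mk("p3", "MDM2_act", "patient")))
  common <- common_networks(cells, pats)
  expect_length(common, 2L)
  # NT_1 is the larger merged network (MDM2_act: 3 members)
  expect_equal(common[[1L]]$network_id, "NT_1")
  expect_equal(sort(common[[1L]]$members), c("c2", "p2", "p3"))
  expect_equal(sort(common[[2L]]$members), c("c1", "p1"))
  expect_equal(unname(common[[1L]]$sources[["cell_line"]]), 1L)
  expect_equal(unname(common[[1L]]$sources[["patient"]]), 2L)
})

test_that("a generated cohort maps, dedupes and filters end to end", {
  net <- testbed_network()
  map <- full_gene_node_map(net)
  spec <- fixture_spec(seed = 5L, alterations_min = 1L, alterations_max = 2L)
  profiles <- random_alteration_profiles(net, 30L, spec, map)
  mapped <- map_cohort(profiles, map, net)
  uniq <- dedupe_profiles(mapped)
  expect_equal(sum(lengths(lapply(uniq, `[[`, "members"))), 30L)
  kept <- filter_by_basin(uniq, net, sim_config(input_clamp = c(IN = 0L)))
  audit <- attr(kept, "audit")
  expect_equal(nrow(audit), length(uniq))
  expect_true(all(vapply(kept, function(u)
    audit$basin[audit$network_id == u$network_id] <= 0.5, TRUE)))
})
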