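# fabricate an efficacy-potency map (bypassing simulation) for unit tests
fake_points <- function(subsets, eff, pot) {
  out <- data.frame(subset_id = vapply(subsets, therawin:::subset_id, ""),
                    n_alterations = lengths(subsets),
                    efficacy = eff, potency = pot, stringsAsFactors = FALSE)
  attr(out, "subsets") <- subsets
  out
}

test_that("subnetworks enumerate the full powerset", {
  subs <- subnetworks(c("a1", "a2"))
  expect_length(subs, 4L)
  expect_identical(subs[[1L]], character(0))
  expect_setequal(vapply(subs, paste, "", collapse = "+"),
                  c("", "a1", "a2", "a1+a2"))
  expect_identical(subnetworks(character()), list(character(0)))
  expect_length(subnetworks(c("a", "b", "c")), 8L)
  expect_error(subnetworks(letters[1:13]), class = "therawin_enumeration_error")
})

test_that("critical determinants are the common, minimal neighbor subsets", {
  subs <- list(character(0), "a1", "a2", c("a1", "a2"))

  # {a1} and the full set are neighbors; {a2} and the control are not
  pts <- fake_points(subs, eff = c(0, 0.95, 0.05, 1), pot = c(1, 0.4, 1, 0.42))
  cd <- critical_determinant(pts, radius = 0.1)
  expect_equal(cd$alterations, "a1")

  # control profile: single subset, intersection is empty
  expect_null(critical_determinant(fake_points(list(character(0)), 0, 1)))

  # alterations irrelevant to the drug: every subset is a neighbor,
  # the intersection is empty -> none
  flat <- fake_points(subs, eff = rep(0.5, 4), pot = rep(0.6, 4))
  expect_null(critical_determinant(flat))

  # intersection not itself a neighbor -> none (two incomparable drivers)
  pts2 <- fake_points(subs, eff = c(0, 0.9, 0.9, 0.95), pot = c(1, 0.4, 0.4, 0.4))
  expect_null(critical_determinant(pts2))

  # minimality: dropping any alteration from the reported determinant breaks
  # neighbor membership (exhaustive over the toy powerset)
  cd_alts <- cd$alterations
  d_orig <- sqrt((pts$efficacy - pts$efficacy[4L])^2 +
                   (pts$potency - pts$potency[4L])^2)
  for (drop in cd_alts) {
    reduced <- setdiff(cd_alts, drop)
    i <- which(vapply(subs, function(s) setequal(s, reduced), TRUE))
    expect_gte(d_orig[i], 0.1)
  }
})

test_that("efficacy-potency maps anchor the control and original networks", {
  net <- testbed_network()
  map <- full_gene_node_map(net)
  cfg <- testbed_cfg(seed = 2L)
  alts <- c("C_act", "P_act")
  pts <- efficacy_potency_map(net, alts, map, target_node("T"), cfg)
  expect_equal(nrow(pts), 4L)

  ctrl_curve <- normalize_curve(dose_sweep(net, control_profile(net),
                                           target_node("T"), cfg))
  expect_equal(pts$efficacy[1L], efficacy(ctrl_curve))
  expect_equal(pts$potency[1L], ic50(ctrl_curve))

  cancer <- alterations_to_status(alts, map, net)
  cancer_curve <- normalize_curve(dose_sweep(net, cancer, target_node("T"), cfg))
  expect_equal(pts$efficacy[4L], efficacy(cancer_curve))
  expect_equal(pts$potency[4L], ic50(cancer_curve))
})

test_that("determinants are recovered with their D/U label on the test bed", {
  net <- testbed_network()
  map <- full_gene_node_map(net)
  cfg <- testbed_cfg(seed = 2L)

  cd <- find_critical_determinant(net, c("C_act", "P_act"), map,
                                  target_node("T"), config = cfg)
  expect_equal(cd$alterations, "C_act")
  expect_equal(cd$response, "D")

  # the dominant resistance alteration joins the determinant set
  cd2 <- find_critical_determinant(net, c("C_act", "Dm_act"), map,
                                   target_node("T"), config = cfg)
  expect_equal(cd2$alterations, c("C_act", "Dm_act"))
  expect_equal(cd2$response, "U")

  # passenger-only profile: responds like the control, no determinant
  expect_null(find_critical_determinant(net, "P_act", map, target_node("T"),
                                        config = cfg))
})

test_that("dominance layers determinants by simulated pairwise outcomes", {
  net <- testbed_network()
  map <- full_gene_node_map(net)
  cfg <- testbed_cfg(seed = 2L)
  d_c <- structure(list(alterations = "C_act", response = "D", level = NA_integer_),
                   class = "critical_determinant")
  d_cd <- structure(list(alterations = c("C_act", "Dm_act"), response = "U",
                         level = NA_integer_), class = "critical_determinant")

  h1 <- dominance(list(d_c), net, map, target_node("T"), config = cfg)
  expect_equal(h1$determinants[[1L]]$level, 1L)

  h <- dominance(list(d_c, d_cd), net, map, target_node("T"), config = cfg)
  lv <- stats::setNames(vapply(h$determinants, `[[`, 0L, "level"),
                        vapply(h$determinants, function(d)
                          therawin:::subset_id(d$alterations), ""))
  # the union carries Dm: its U response wins, putting it one level above
  expect_gt(lv[["C_act;Dm_act"]], lv[["C_act"]])
  expect_equal(unname(lv[["C_act"]]), 1L)
  expect_equal(h$pairwise$winner, "C_act;Dm_act")
})

test_that("response prediction walks the hierarchy top-down", {
  mk_det <- function(alts, resp, lv) structure(
    list(alterations = alts, response = resp, level = lv),
    class = "critical_determinant")
  h <- list(determinants = list(mk_det("u1", "U", 3L), mk_det("d1", "D", 2L),
                                mk_det("d2", "D", 2L), mk_det("u2", "U", 1L)))

  expect_equal(predict_response(c("u1", "d1"), h, "U"), "U")   # Lv3 beats Lv2
  expect_equal(predict_response("d2", h, "U"), "D")
  expect_equal(predict_response(character(), h, "U"), "U")     # control fallback
  expect_equal(predict_response("x9", h, "D"), "D")

  # monotone: adding alterations changes the call only via a higher level
  base <- predict_response("d1", h, "U")
  expect_equal(base, "D")
  expect_equal(predict_response(c("d1", "u2"), h, "U"), "D")   # lower level loses
  expect_equal(predict_response(c("d1", "u1"), h, "U"), "U")   # higher level wins

  h_conflict <- list(determinants = list(mk_det("a", "D", 2L),
                                         mk_det("b", "U", 2L)))
  expect_error(predict_response(c("a", "b"), h_conflict, "U"),
               class = "therawin_dominance_conflict")
})

test_that("enrichment baseline ranks markers by Fisher association", {
  profiles <- list(c("m1", "z"), "m1", c("m1", "m2"), "m2", "z", character())
  labels <- c("D", "D", "D", "U", "U", "U")
  mk <- marker_enrichment_baseline(profiles, labels, k = 2L)
  expect_s3_class(mk, "marker_set")
  expect_equal(mk$alteration[1L], "m1")       # perfect association ranks first
  expect_equal(mk$enriched_class[1L], "D")

  pred <- predict_by_marker(profiles, mk[1L, ])
  ev <- evaluate_prediction(pred, labels)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$accuracy, 1)

  expect_error(marker_enrichment_baseline(profiles, rep("D", 6)),
               class = "therawin_schema_error")
})

test_that("stratification yields deterministic, response-pure clusters", {
  mk_det <- function(alts, resp, lv) structure(
    list(alterations = alts, response = resp, level = lv),
    class = "critical_determinant")
  h <- list(determinants = list(mk_det("u1", "U", 2L), mk_det("d1", "D", 1L)))
  profiles <- list(c("u1", "d1"), "d1", "d1", character(), "u1", "noise")
  st <- stratify(profiles, h, control_response = "U")
  expect_equal(st$cluster, c("u1", "d1", "d1", "none", "u1", "none"))
  # clusters are response-pure
  for (cl in unique(st$cluster))
    expect_length(unique(st$predicted[st$cluster == cl]), 1L)
  expect_equal(st$predicted, c("U", "D", "D", "U", "U", "U"))
})
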