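spec_small <- function(seed = 1, planted_overlap = 20,
                       graph_params = list(n = 20, p = 0.2), ...) {
  synthetic_spec(seed = seed, n_compounds = 30,
                 n_compound_targets = 60, n_disease_targets = 50,
                 planted_overlap = planted_overlap,
                 graph_params = graph_params, ...)
}

test_that("generators are bit-identical under a fixed seed", {
  s <- spec_small(seed = 42)
  expect_identical(sim_compound_table(s), sim_compound_table(s))
  expect_identical(sim_target_sets(s), sim_target_sets(s))
  expect_identical(igraph::as_edgelist(sim_ppi(s)),
                   igraph::as_edgelist(sim_ppi(s)))
  bg <- sprintf("G%06d", 1:100)
  expect_identical(sim_annotations(s, bg[1:20], bg),
                   sim_annotations(s, bg[1:20], bg))
  expect_identical(sim_trajectory(s), sim_trajectory(s))
  expect_identical(sim_energy_table(s), sim_energy_table(s))
  expect_identical(sim_docking_poses(s), sim_docking_poses(s))
})

test_that("spec validation names the offending field", {
  expect_error(synthetic_spec(planted_overlap = 700), "planted_overlap")
  expect_error(synthetic_spec(n_terms = -1), "n_terms")
  expect_error(spec_small(trajectory_params = list(noise_sd = -0.1)),
               "noise_sd")
  expect_error(spec_small(compound_params = list(pass_tcmsp = 1.5)),
               "pass_tcmsp")
})

test_that("compound table pass fractions are forced by construction", {
  none <- sim_compound_table(spec_small(
    seed = 3, compound_params = list(pass_tcmsp = 0, n_duplicates = 0)))
  expect_equal(nrow(screen_tcmsp(none)), 0)
  all_pass <- sim_compound_table(spec_small(
    seed = 3, compound_params = list(pass_tcmsp = 1, n_duplicates = 0)))
  expect_equal(nrow(screen_tcmsp(all_pass)), nrow(all_pass))
})

test_that("planted duplicates are recovered by merge_compounds", {
  tbl <- sim_compound_table(spec_small(seed = 5))  # 30 rows, 3 duplicates
  expect_equal(nrow(tbl), 30)
  expect_equal(nrow(merge_compounds(tbl)), 27)
})

test_that("planted target overlap is exact, including boundaries", {
  s <- spec_small(seed = 2)
  sets <- sim_target_sets(s)
  ov <- intersect_targets(sets$compound, sets$disease)
  expect_equal(unname(ov$venn["common"]), 20)
  expect_equal(nrow(sets$compound), 60)
  expect_equal(nrow(sets$disease), 50)

  none <- sim_target_sets(spec_small(seed = 2, planted_overlap = 0))
  expect_equal(nrow(intersect_targets(none$compound, none$disease)$common), 0)

  full <- sim_target_sets(spec_small(seed = 2, planted_overlap = 50))
  ov_full <- intersect_targets(full$compound, full$disease)
  expect_equal(unname(ov_full$venn["common"]), 50)
  expect_equal(unname(ov_full$venn["b_only"]), 0)
})

test_that("graph generators honor their models", {
  iso <- sim_ppi(spec_small(graph_params = list(n = 10, p = 0)))
  expect_equal(igraph::vcount(iso), 10)
  expect_equal(igraph::ecount(iso), 0)

  k5 <- sim_ppi(spec_small(graph_params = list(n = 5, p = 1)))
  expect_equal(igraph::ecount(k5), 10)

  edges <- data.frame(from = c("a", "b"), to = c("b", "c"))
  fixed <- sim_ppi(spec_small(graph_model = "fixed_edge_list",
                              graph_params = list(edges = edges)))
  expect_setequal(igraph::V(fixed)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(fixed), 2)

  expect_error(sim_ppi(spec_small(graph_model = "small_world")))
})

test_that("planted annotation terms over-draw from the study set", {
  bg <- sprintf("G%06d", 1:200)
  study <- bg[1:30]
  s <- spec_small(planted_terms = list(
    list(term_id = "T1", size = 50, effect = 1)))
  coll <- sim_annotations(s, study, bg)
  planted <- coll$genes[[which(coll$term_id == "T1")]]
  expect_true(all(study %in% planted))  # term size >= study size, effect 1
  expect_error(sim_annotations(s, c(study, "NOT_IN_BG"), bg), "subset")
})

test_that("null annotations draw independently of the study set", {
  bg <- sprintf("G%06d", 1:200)
  s <- spec_small(planted_terms = list(), n_terms = 30)
  coll <- sim_annotations(s, bg[1:30], bg)
  expect_equal(nrow(coll), 30)
  expect_true(all(map_lgl <- vapply(coll$genes,
                                    function(g) all(g %in% bg), logical(1))))
})

test_that("trajectory plateau and equilibration are planted exactly", {
  s <- spec_small(trajectory_params = list(noise_sd = 0))
  traj <- sim_trajectory(s)
  post <- traj$value[traj$time >= 13]
  expect_true(all(post == 0.35))
  s0 <- spec_small(trajectory_params = list(noise_sd = 0,
                                            equilibration_time = 0))
  st <- assess_stability(sim_trajectory(s0))
  expect_true(st$stable)
  expect_equal(st$equilibration_time, 0)
})

test_that("energy rows carry only base components and sum exactly", {
  tbl <- sim_energy_table(spec_small(seed = 9))
  expect_false(any(c("mm", "delta_h", "delta_g") %in% names(tbl)))
  filled <- mmpbsa_totals(tbl)
  expect_equal(filled$delta_g,
               tbl$vdw + tbl$cou + tbl$pb + tbl$sa + tbl$minus_t_delta_s)
})
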