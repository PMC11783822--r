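test_that("initial grading conditions on all fracture states and matches enumeration", {
  mdl <- tiny_grading_model()
  g <- initial_grade(mdl$spec, mdl$cpds, c("psd", "sacral_diastatic"))
  ev <- c(psd = 1L, si_anterior_divergent = 0L, sacral_diastatic = 1L)
  expect_equal(g$p_R, oracle_marginal(mdl$spec, mdl$cpds, ev, "R"), tolerance = 1e-9)
  expect_equal(g$p_T, oracle_marginal(mdl$spec, mdl$cpds, ev, "T"), tolerance = 1e-9)
  expect_true(g$p_R >= 0 && g$p_R <= 1)
  expect_true(g$p_T >= 0 && g$p_T <= 1)
  expect_equal(g$tile, tile_from_instability(g$p_R >= 0.5, g$p_T >= 0.5))
})

test_that("no findings in a stability-favouring model grade A", {
  mdl <- tiny_grading_model()
  g <- initial_grade(mdl$spec, mdl$cpds, character())
  expect_lt(g$p_R, 0.5); expect_lt(g$p_T, 0.5)
  expect_equal(g$tile, "A")
})

test_that("the default model requires an age flag and uses it", {
  spec <- default_structure()
  cpds <- default_generator_cpds(spec)
  expect_error(initial_grade(spec, cpds, "psd"), "age")
  g_young <- initial_grade(spec, cpds, "psd", age60 = 0L)
  g_old <- initial_grade(spec, cpds, "psd", age60 = 1L)
  expect_false(identical(g_young$p_T, g_old$p_T))
})

test_that("candidate probabilities are leave-one-out conditionals", {
  mdl <- tiny_grading_model()
  ev <- c(psd = 1L, si_anterior_divergent = 0L, sacral_diastatic = 0L)
  q <- candidate_probabilities(mdl$spec, mdl$cpds, ev,
                               c("si_anterior_divergent", "sacral_diastatic"))
  expect_equal(unname(q["si_anterior_divergent"]),
               oracle_marginal(mdl$spec, mdl$cpds,
                               ev[c("psd", "sacral_diastatic")],
                               "si_anterior_divergent"),
               tolerance = 1e-9)
  expect_equal(unname(q["sacral_diastatic"]),
               oracle_marginal(mdl$spec, mdl$cpds,
                               ev[c("psd", "si_anterior_divergent")],
                               "sacral_diastatic"),
               tolerance = 1e-9)
  expect_error(candidate_probabilities(mdl$spec, mdl$cpds, ev, "psd"),
               "disjoint")
})

test_that("a candidate independent of the evidence keeps its prior", {
  spec <- network_spec(c("R", "psd", "ring_fx"),
                       data.frame(from = "R", to = "psd"))
  cpds <- list(R = cpd_table("R", character(), 0.4),
               psd = cpd_table("psd", "R", c(0.1, 0.9)),
               ring_fx = cpd_table("ring_fx", character(), 0.27))
  q <- candidate_probabilities(spec, cpds, c(psd = 1L, ring_fx = 0L), "ring_fx")
  expect_equal(unname(q), 0.27, tolerance = 1e-12)
})

test_that("deterministic coupling forces retrieval probability one", {
  spec <- network_spec(c("R", "psd", "ring_fx"),
                       data.frame(from = c("R", "R"), to = c("psd", "ring_fx")))
  cpds <- list(R = cpd_table("R", character(), 0.5),
               psd = cpd_table("psd", "R", c(0, 1)),     # psd <=> R
               ring_fx = cpd_table("ring_fx", "R", c(0, 1)))
  q <- candidate_probabilities(spec, cpds, c(psd = 1L, ring_fx = 0L), "ring_fx")
  expect_equal(unname(q), 1)
})

test_that("refinement with no extra candidates reduces to the initial grade", {
  mdl <- tiny_grading_model()
  r <- refine(mdl$spec, mdl$cpds, "psd", "psd")
  expect_equal(nrow(r$added), 0L)
  g <- initial_grade(mdl$spec, mdl$cpds, "psd")
  expect_equal(r$p_R_final, g$p_R)
  expect_equal(r$p_T_final, g$p_T)
  expect_equal(r$tile_final, g$tile)
})

test_that("a strongly co-occurring low-confidence fracture is retrieved", {
  # si_anterior_divergent is near-certain once psd has pushed R up
  spec <- tiny_grading_model()$spec
  cpds <- list(
    R = cpd_table("R", character(), 0.4),
    T = cpd_table("T", character(), 0.3),
    psd = cpd_table("psd", c("R", "T"), c(0.01, 0.95, 0.5, 0.95)),
    si_anterior_divergent = cpd_table("si_anterior_divergent", c("R", "T"),
                                      c(0.05, 0.95, 0.05, 0.95)),
    sacral_diastatic = cpd_table("sacral_diastatic", "T", c(0.05, 0.8)))
  r <- refine(spec, cpds, "psd", c("psd", "si_anterior_divergent"),
              th = thresholds(z_star = 0.5))
  expect_equal(r$added$fracture_type, "si_anterior_divergent")
  # the promoted q matches the enumeration oracle at the time of addition
  expect_equal(r$added$q,
               oracle_marginal(spec, cpds, c(psd = 1L, sacral_diastatic = 0L),
                               "si_anterior_divergent"),
               tolerance = 1e-9)
  expect_gt(r$p_R_final, r$p_R_initial)
  # audit record carries the per-instability-state conditionals
  expect_equal(unname(r$audit$si_anterior_divergent$per_state),
               c(0.05, 0.95, 0.05, 0.95))
})

test_that("high-confidence findings are never removed", {
  set.seed(77)
  spec <- default_structure()
  for (rep in 1:25) {
    cpds <- random_cpds(spec)
    low <- sample(fracture_types(), sample(7, 1))
    high <- low[seq_len(sample(0:length(low), 1))]
    r <- refine(spec, cpds, high, low, age60 = sample(0:1, 1),
                th = thresholds(z_star = runif(1)))
    init_pos <- names(r$initial_evidence)[r$initial_evidence == 1L]
    final_pos <- names(r$final_evidence)[r$final_evidence == 1L]
    expect_true(all(setdiff(init_pos, "age60") %in% final_pos))
    expect_lte(nrow(r$added), 7L)
    expect_true(all(r$added$fracture_type %in% setdiff(low, high)))
  }
})

test_that("an unattainable acceptance threshold means no additions", {
  mdl <- tiny_grading_model()
  r <- refine(mdl$spec, mdl$cpds, "psd",
              c("psd", "si_anterior_divergent", "sacral_diastatic"),
              th = thresholds(z_star = 1 + 1e-9))
  expect_equal(nrow(r$added), 0L)
  g <- initial_grade(mdl$spec, mdl$cpds, "psd")
  expect_equal(r$p_R_final, g$p_R)
  expect_equal(r$tile_final, g$tile)
})

test_that("refinement is deterministic with canonical tie-breaking", {
  spec <- default_structure(include_age = FALSE)
  # all fracture CPDs identical -> every candidate ties; the canonical
  # fracture-type order must decide
  cpds <- c(list(R = cpd_table("R", character(), 0.5),
                 T = cpd_table("T", character(), 0.5)),
            lapply(setNames(fracture_types(), fracture_types()), function(t)
              cpd_table(t, c("R", "T"), c(0.5, 0.7, 0.7, 0.9))))
  r1 <- refine(spec, cpds, character(), fracture_types(),
               th = thresholds(z_star = 0.5))
  r2 <- refine(spec, cpds, character(), rev(fracture_types()),
               th = thresholds(z_star = 0.5))
  expect_identical(r1$added, r2$added)
  expect_equal(r1$added$fracture_type[1], "psd")  # first in canonical order
})

test_that("refinement results serialize with their explanation surface", {
  mdl <- tiny_grading_model()
  r <- refine(mdl$spec, mdl$cpds, "psd",
              c("psd", "si_anterior_divergent"), th = thresholds(z_star = 0))
  js <- jsonlite::fromJSON(refinement_to_json(r))
  expect_equal(js$initial$tile, r$tile_initial)
  expect_equal(js$final$tile, r$tile_final)
  expect_equal(js$added$fracture_type, r$added$fracture_type)
  expect_equal(js$added$q, r$added$q, tolerance = 1e-12)
})
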