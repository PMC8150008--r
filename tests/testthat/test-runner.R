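test_that("shrinkage uses the estimate-minus-truth sign convention", {
  expect_identical(shrinkage(0.5, 0.5), 0)
  # pulled up toward a meta mean above the focal value: positive
  expect_equal(shrinkage(-0.5, -0.2), 0.3)
  # pulled down toward a meta mean below the focal value: negative
  expect_equal(shrinkage(0.5, 0.45), -0.05)
  expect_equal(shrinkage(c(0, 1), c(1, 0)), c(1, -1))
  expect_error(shrinkage(NA_real_, 1))
})

test_that("grid corners span the design extremes", {
  grid <- sim_grid()
  corners <- grid_corners(grid)
  expect_equal(nrow(corners), 8)
  expect_setequal(unique(corners$k), range(grid$k))
  expect_setequal(unique(corners$delta_mu), range(grid$delta_mu))
  expect_setequal(unique(corners$tau2), range(grid$tau2))
  expect_setequal(unique(corners$delta_n), range(grid$delta_n))
  expect_true(all(corners$condition %in% grid$condition))
})

test_that("run_condition keeps per-replication bookkeeping", {
  grid <- sim_grid(levels_k = 3, levels_dn = -100, levels_dmu = 0.5,
                   levels_tau2 = 0.05, n_reps = 2)
  cr <- run_condition(grid[1, ], sim_params(), arms = "pooled",
                      mcmc = mcmc_fast(seed = 110))
  expect_equal(cr$n_completed, 2)
  expect_equal(length(cr$failures), 0)
  expect_equal(sort(unique(cr$estimates$rep)), 1:2)
  # aggregate has one row per term for the single arm
  expect_equal(nrow(cr$aggregate), 5) # intercept + 3 coefficients + sigma
  expect_true(all(c("estimate", "std.error", "shrinkage") %in%
                    names(cr$aggregate)))
  # SE aggregation is the root of the mean squared SE
  x1 <- cr$estimates[cr$estimates$term == "x1", ]
  expect_equal(cr$aggregate$std.error[cr$aggregate$term == "x1"],
               sqrt(mean(x1$std.error^2)))
  expect_equal(cr$aggregate$estimate[cr$aggregate$term == "x1"],
               mean(x1$estimate))
  g <- glance(cr)
  expect_equal(g$n_completed, 2)
  expect_s3_class(tidy(cr), "tbl_df")
})

test_that("run_condition is deterministic and order-independent in its seeds", {
  grid <- sim_grid(levels_k = 3, levels_dn = 100, levels_dmu = 1,
                   levels_tau2 = 0.1, n_reps = 2)
  a <- run_condition(grid[1, ], sim_params(), arms = "pooled",
                     mcmc = mcmc_fast(seed = 111))
  b <- run_condition(grid[1, ], sim_params(), arms = "pooled",
                     mcmc = mcmc_fast(seed = 111))
  expect_identical(a$estimates, b$estimates)
})

test_that("a run over a small grid aggregates across conditions", {
  grid <- sim_grid(levels_k = 3, levels_dn = -100, levels_dmu = c(0.25, 3),
                   levels_tau2 = c(0.025, 0.5), n_reps = 1)
  study <- run_study(grid, sim_params(), arms = "swip",
                     mcmc = mcmc_fast(seed = 112))
  expect_equal(nrow(study$conditions), 4)
  expect_setequal(unique(study$aggregate$condition), grid$condition)
  expect_equal(nrow(study$similarity), 4 * 3)
  expect_true(is.finite(study$max_rhat))
  expect_s3_class(autoplot(study), "ggplot")
  expect_s3_class(plot_shrinkage(study), "ggplot")

  # omega responds to the design: most-similar corner beats least-similar
  om <- study$similarity |>
    dplyr::group_by(condition) |>
    dplyr::summarise(omega = mean(omega))
  best <- grid$condition[grid$delta_mu == 0.25 & grid$tau2 == 0.025]
  worst <- grid$condition[grid$delta_mu == 3 & grid$tau2 == 0.5]
  expect_gt(om$omega[om$condition == best], om$omega[om$condition == worst])
})

test_that("behavior models recover a flat relation when omega is constant", {
  # synthetic study object with constant omega across the grid
  grid <- sim_grid(levels_k = 3, levels_dn = -100, levels_dmu = c(0.5, 1, 2),
                   levels_tau2 = c(0.05, 0.1), n_reps = 1)
  study <- structure(list(
    conditions = grid,
    similarity = tidyr::expand_grid(condition = grid$condition,
                                    predictor = 1:3) |>
      dplyr::mutate(omega = 0.5),
    aggregate = tibble::tibble(condition = rep(grid$condition, each = 3),
                               arm = "swip",
                               term = rep(paste0("x", 1:3), nrow(grid)),
                               shrinkage = 0.1),
    max_rhat = 1, failures = character(0)
  ), class = "swip_study")
  bm <- behavior_models(study)
  slopes <- bm[bm$model == "omega ~ total_het + delta_mu" &
                 bm$term != "(Intercept)", ]
  expect_equal(slopes$estimate, c(0, 0), tolerance = 1e-12)
})

test_that("failed replications are logged and excluded, not fatal", {
  # previous-study sizes collapse to the p + 4 floor, below the minimum the
  # effect-size step accepts, so replications fail inside the pipeline
  grid <- sim_grid(levels_k = 3, levels_dn = -195, levels_dmu = 0.5,
                   levels_tau2 = 0.05, n_reps = 2)
  cr <- suppressWarnings(
    run_condition(grid[1, ], sim_params(), arms = "swip",
                  mcmc = mcmc_fast(seed = 113))
  )
  expect_equal(cr$n_completed + length(cr$failures), 2)
  expect_gt(length(cr$failures), 0)
})
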