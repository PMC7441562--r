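test_that("eigengene reduction captures rank-2 sinusoidal structure", {
  theta <- seq(0, 2 * pi, length.out = 41)[-41]
  panel <- rbind(toy_panel(rep(c(3, 15), each = 5))) # two antiphase groups
  X <- cosine_matrix(panel, theta)
  eg <- prepare_eigengenes(X, panel$gene_id, var_fraction = 0.85)
  expect_gte(sum(eg$var_explained[1:2]), 0.99)
  ## var_fraction = 1 keeps every available component
  eg_full <- prepare_eigengenes(X, panel$gene_id, var_fraction = 1)
  expect_identical(nrow(eg_full$scores), min(nrow(X), ncol(X) - 1L))
  expect_error(prepare_eigengenes(X, c("T01")), "fewer than 2")
})

test_that("eigengene scores match an independent eigendecomposition oracle", {
  set.seed(17)
  X <- matrix(rnorm(20 * 200), 20, 200,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%03d", 1:200)))
  eg <- prepare_eigengenes(X, rownames(X), var_fraction = 0.85)
  Xs <- t(scale(t(X)))
  ev <- eigen(tcrossprod(Xs), symmetric = TRUE)
  for (k in seq_len(nrow(eg$scores))) {
    oracle_scores <- drop(t(ev$vectors[, k]) %*% Xs)
    ## equal up to the sign of the component
    expect_lt(min(max(abs(eg$scores[k, ] - oracle_scores)),
                  max(abs(eg$scores[k, ] + oracle_scores))), 1e-8)
  }
})

test_that("samples on an exact ellipse are ordered with near-zero error", {
  set.seed(2)
  true_angle <- sort(runif(100, 0, 2 * pi))
  E <- rbind(e1 = 3 * cos(true_angle) + 0.5,
             e2 = 1.2 * sin(true_angle) - 1)
  colnames(E) <- sprintf("s%03d", 1:100)
  ord <- fit_circular_ordering(E, n_restarts = 5, seed = 3)
  expect_lt(ord$reconstruction_error, 1e-3)
  ## recovered phases are a monotone circular function of the true angle
  d <- diff(circaskin::wrap_angle(ord$theta - ord$theta[1]))
  expect_true(all(d > 0) || all(d < 0))
})

test_that("ordering is deterministic under a fixed seed", {
  set.seed(4)
  E <- matrix(rnorm(5 * 60), 5, 60, dimnames = list(NULL, sprintf("s%d", 1:60)))
  o1 <- fit_circular_ordering(E, n_restarts = 3, seed = 9)
  o2 <- fit_circular_ordering(E, n_restarts = 3, seed = 9)
  expect_identical(o1$theta, o2$theta)
  expect_identical(o1$reconstruction_error, o2$reconstruction_error)
  expect_error(fit_circular_ordering(E[1, , drop = FALSE]), "2 eigengenes")
})

test_that("phase registration rotates the anchor peak to zero and is idempotent", {
  panel <- rbind(panel_row("ARNTL", 20.5, rAMP = 0.4, is_clock = TRUE),
                 toy_panel(c(3, 7, 11, 15, 19, 23)))
  sim <- simulate_population(panel, n_participants = 80, sites = "arm",
                             layers = "epidermis", seed = 5)
  truth <- setNames(sim$truth$theta_rad, sim$truth$sample_id)
  ## build an ordering at a known rotation from the truth
  ord <- structure(list(theta = circaskin::wrap_angle(truth + 1.1),
                        reconstruction_error = 0), class = "circular_ordering")
  reg <- register_phase(ord, sim$expr, direction_ref = truth[1:10])
  ## ARNTL peaks at theta 0 after registration: cosinor against the
  ## registered phases puts the anchor peak at 0 (or 24)
  f <- fit_cosinor(rad_to_hours(reg$theta), sim$expr["ARNTL", names(reg$theta)])
  expect_lt(min(f$peak_phase_h, 24 - f$peak_phase_h), 0.2)
  reg2 <- register_phase(reg, sim$expr, direction_ref = truth[1:10])
  expect_lt(max(abs_err_hours(reg2$theta, reg$theta)), 0.05)
})

test_that("a reflected ordering is direction-corrected by the reference", {
  panel <- rbind(panel_row("ARNTL", 20.5, rAMP = 0.4, is_clock = TRUE),
                 toy_panel(c(3, 8, 13, 18, 23)))
  sim <- simulate_population(panel, n_participants = 80, sites = "arm",
                             layers = "epidermis", seed = 6)
  truth <- setNames(sim$truth$theta_rad, sim$truth$sample_id)
  ord <- structure(list(theta = circaskin::wrap_angle(-truth + 0.4),
                        reconstruction_error = 0), class = "circular_ordering")
  reg <- register_phase(ord, sim$expr, direction_ref = truth[1:12])
  expect_true(reg$reflected)
  expect_gt(circ_corr(reg$theta, truth[names(reg$theta)]), 0.9)
})

test_that("registration demands a rhythmic anchor", {
  panel <- rbind(panel_row("ARNTL", 0, rAMP = 0, noise_sd = 1),
                 toy_panel(c(3, 9, 15, 21)))
  sim <- simulate_population(panel, n_participants = 40, sites = "arm",
                             layers = "epidermis", seed = 7)
  ord <- structure(list(theta = setNames(sim$truth$theta_rad,
                                         sim$truth$sample_id),
                        reconstruction_error = 0), class = "circular_ordering")
  expect_error(register_phase(ord, sim$expr), "not rhythmic")
})

test_that("ordering quality applies the dual criteria and the 8-gene rule", {
  clock_tab <- clock_gene_panel()
  ref_phases <- setNames((20.5 + clock_tab$rel_phase_h) %% 24,
                         clock_tab$gene_id)
  ## perfect stamped phases give time_corr 1
  panel <- make_gene_panel(n_genes = 40, frac_rhythmic = 0.8, indiv_cv = 0,
                           mesor_range = c(17, 20), seed = 8)
  sim <- simulate_longitudinal(panel, n_participants = 10,
                               chronotype_sd_h = 0, seed = 9)
  theta <- hours_to_rad(sim$meta$collection_time_h)
  ord <- structure(list(theta = setNames(theta, sim$meta$sample_id),
                        reconstruction_error = 1), class = "circular_ordering")
  q <- score_ordering(ord, sim$meta, sim$expr, ref_phases)
  expect_equal(q$time_corr, 1, tolerance = 1e-9)
  expect_gte(q$n_clock_passing, 8)
  expect_gt(q$clock_corr, 0.9)
  ## with only 7 clock genes in the data, clock_corr is zeroed
  seven <- panel$gene_id[panel$is_clock][1:7]
  keep <- c(seven, panel$gene_id[!panel$is_clock])
  q7 <- score_ordering(ord, sim$meta, sim$expr[keep, ], ref_phases)
  expect_identical(q7$clock_corr, 0)
  expect_lte(q7$n_clock_passing, 7)
})
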