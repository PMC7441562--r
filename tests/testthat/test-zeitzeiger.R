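train_fixture <- function(seed = 21, n_train = 400, n_genes = 200) {
  panel <- make_gene_panel(n_genes = n_genes, frac_rhythmic = 0.2, seed = seed)
  sim <- simulate_population(panel, n_participants = n_train, sites = "arm",
                             layers = "epidermis", seed = seed + 1)
  theta <- setNames(sim$truth$theta_rad, sim$truth$sample_id)
  scan <- cosinor_scan(sim$expr, rad_to_hours(theta))
  dyn <- select_dynamic_genes(scan)
  nz <- normalize_expression(sim$expr[union(dyn, c("GPKOW", "BMS1", "ANKFY1")), ])
  list(panel = panel, sim = sim, theta = theta, dyn = dyn, nz = nz)
}

test_that("normalization bounds, centering invariance and stored constants", {
  fx <- train_fixture(n_train = 100, n_genes = 60)
  x <- fx$nz$expr
  expect_true(all(abs(x) <= 1 + 1e-12))
  expect_true(all(abs(apply(abs(x), 1, max) - 1) < 1e-12))
  ## a constant added to every gene of one sample is removed by step 1
  raw <- fx$sim$expr[rownames(x), ]
  shifted <- raw
  shifted[, 3] <- shifted[, 3] + 5
  renorm <- apply_normalization(fx$nz$spec, shifted)
  base <- apply_normalization(fx$nz$spec, raw)
  expect_equal(renorm[, 3], base[, 3], tolerance = 1e-12)
  ## missing reference gene is an error
  expect_error(normalize_expression(raw[setdiff(rownames(raw), "GPKOW"), ]),
               "GPKOW")
})

test_that("outliers are clipped at the stored training quantiles", {
  set.seed(3)
  expr <- rbind(GPKOW = rnorm(300, 10, 0.1), BMS1 = rnorm(300, 10, 0.1),
                ANKFY1 = rnorm(300, 10, 0.1), G1 = rnorm(300, 12, 1))
  colnames(expr) <- sprintf("s%03d", 1:300)
  nz <- normalize_expression(expr)
  ## plant a 10-sd outlier in a new sample: it cannot exceed the stored
  ## upper winsorization bound
  new <- expr[, 1, drop = FALSE]
  new["G1", 1] <- 12 + 10
  out <- apply_normalization(nz$spec, new)
  centered_bound <- nz$spec$hi["G1"] / nz$spec$max["G1"]
  expect_equal(unname(out["G1", 1]), unname(centered_bound), tolerance = 1e-12)
  ## the bound is the empirical 99.5th percentile of the training data
  ref_mean <- colMeans(expr[c("GPKOW", "BMS1", "ANKFY1"), ])
  expect_equal(unname(nz$spec$hi["G1"]),
               unname(quantile(expr["G1", ] - ref_mean, 0.995)),
               tolerance = 1e-12)
})

test_that("normalization is idempotent given the stored spec", {
  fx <- train_fixture(n_train = 80, n_genes = 50)
  once <- apply_normalization(fx$nz$spec, fx$sim$expr[rownames(fx$nz$expr), ])
  twice <- apply_normalization(fx$nz$spec, once)
  expect_identical(once, twice)
})

test_that("dynamic-gene selection uses a strict R-squared threshold", {
  scan <- data.frame(gene_id = c("a", "b", "c"), rsq = c(0.1, 0.100001, 0.5))
  expect_identical(select_dynamic_genes(scan), c("b", "c"))
  expect_error(select_dynamic_genes(data.frame(gene_id = "a", rsq = 0.01)),
               "threshold")
})

test_that("dynamic genes recover the rhythmic panel on ordered data", {
  panel <- make_gene_panel(n_genes = 500, frac_rhythmic = 0.094,
                           clock_panel_size = 0, seed = 13)
  ## ~50 rhythmic of 500
  sim <- simulate_population(panel, n_participants = 200, sites = "arm",
                             layers = "epidermis", seed = 14)
  scan <- cosinor_scan(sim$expr, rad_to_hours(sim$truth$theta_rad))
  dyn <- select_dynamic_genes(scan)
  rhythmic <- panel$gene_id[panel$is_rhythmic]
  recall <- mean(rhythmic %in% dyn)
  false_incl <- mean(!(dyn %in% rhythmic))
  expect_gte(recall, 0.9)
  expect_lte(false_incl, 0.1)
})

test_that("sumabsv = 1 concentrates each sparse component on one gene", {
  fx <- train_fixture(n_train = 150, n_genes = 80)
  m <- train_phase_model(fx$nz$expr[fx$dyn, ], fx$theta, sumabsv = 1,
                         norm_spec = fx$nz$spec)
  U <- coef(m)
  expect_true(all(colSums(abs(U) > 1e-8) == 1))
})

test_that("duplicating a gene splits its loading, leaving SPC curves stable", {
  fx <- train_fixture(n_train = 150, n_genes = 80)
  X <- fx$nz$expr[fx$dyn, ]
  m1 <- train_phase_model(X, fx$theta, sumabsv = 2)
  top <- rownames(coef(m1))[which.max(abs(coef(m1)[, 1]))]
  X2 <- rbind(X, X[top, , drop = FALSE])
  rownames(X2)[nrow(X2)] <- paste0(top, "_dup")
  m2 <- train_phase_model(X2, fx$theta, sumabsv = 2)
  u1 <- coef(m1)[top, 1]
  u2a <- coef(m2)[top, 1]
  u2b <- coef(m2)[paste0(top, "_dup"), 1]
  ## identical rows receive identical loadings: the mass splits evenly
  expect_equal(unname(abs(u2a)), unname(abs(u2b)), tolerance = 1e-6)
  expect_gte(sqrt(u2a^2 + u2b^2) + 1e-6, abs(u1))
  ## the component time-courses barely move
  agree <- min(max(abs(m2$spc_curves[1, ] - m1$spc_curves[1, ])),
               max(abs(m2$spc_curves[1, ] + m1$spc_curves[1, ])))
  expect_lt(agree / diff(range(m1$spc_curves[1, ])), 0.15)
})

test_that("training rejects bad phase coverage and invalid budgets", {
  fx <- train_fixture(n_train = 100, n_genes = 50)
  half <- fx$theta[fx$theta < pi]
  expect_error(train_phase_model(fx$nz$expr[fx$dyn, names(half)], half),
               "coverage gap")
  expect_error(train_phase_model(fx$nz$expr[fx$dyn, ], fx$theta,
                                 sumabsv = 0.5), "sumabsv")
  expect_error(train_phase_model(fx$nz$expr[fx$dyn, 1:20], fx$theta[1:20]),
               "training samples")
})

test_that("noise-free round trip recovers training phases to grid resolution", {
  panel <- make_gene_panel(n_genes = 60, frac_rhythmic = 0.6, indiv_cv = 0,
                           seed = 41)
  sim <- simulate_population(panel, n_participants = 120, sites = "arm",
                             layers = "epidermis", noise = FALSE, seed = 42)
  theta <- setNames(sim$truth$theta_rad, sim$truth$sample_id)
  scan <- cosinor_scan(sim$expr, rad_to_hours(theta))
  dyn <- select_dynamic_genes(scan)
  nz <- normalize_expression(sim$expr[union(dyn, c("GPKOW", "BMS1", "ANKFY1")), ])
  m <- train_phase_model(nz$expr[dyn, ], theta, sumabsv = 2, norm_spec = nz$spec)
  pred <- predict(m, sim$expr)
  err <- circ_align_err_h(pred$theta_hat, theta)
  expect_lte(median(err), 24 / length(m$time_grid))
  ## the sample nearest theta = pi is itself recovered within one grid step
  i <- which.min(abs(theta - pi))
  expect_lte(err[i], 24 / length(m$time_grid) + 1e-9)
})

test_that("prediction ignores genes outside the selected biomarker set", {
  fx <- train_fixture(n_train = 150, n_genes = 80)
  m <- train_phase_model(fx$nz$expr[fx$dyn, ], fx$theta, sumabsv = 2,
                         norm_spec = fx$nz$spec)
  test <- simulate_longitudinal(fx$panel, n_participants = 3, seed = 77)
  p1 <- predict(m, test$expr)
  perturbed <- test$expr
  untouched <- setdiff(rownames(perturbed),
                       c(m$gene_ids, fx$nz$spec$ref_genes))
  perturbed[untouched, ] <- perturbed[untouched, ] + 100
  p2 <- predict(m, perturbed)
  expect_equal(p1$theta_hat, p2$theta_hat, tolerance = 1e-12)
})

test_that("degenerate samples yield a flat profile and mle_ok = FALSE", {
  fx <- train_fixture(n_train = 150, n_genes = 80)
  m <- train_phase_model(fx$nz$expr[fx$dyn, ], fx$theta, sumabsv = 2,
                         norm_spec = fx$nz$spec)
  flat_sample <- matrix(7, nrow = nrow(fx$sim$expr), ncol = 1,
                        dimnames = list(rownames(fx$sim$expr), "flat"))
  p <- predict(m, flat_sample, return_profile = TRUE)
  expect_false(p$mle_ok)
  prof <- attr(p, "loglik_profile")
  expect_lt(diff(range(prof)), 1e-8)
  ## a missing model gene is an error naming it
  drop1 <- m$gene_ids[1]
  bad <- fx$sim$expr[setdiff(rownames(fx$sim$expr), drop1), 1:2]
  expect_error(predict(m, bad), drop1)
})

test_that("phase models survive JSON round-trips unchanged", {
  fx <- train_fixture(n_train = 120, n_genes = 60)
  m <- train_phase_model(fx$nz$expr[fx$dyn, ], fx$theta, sumabsv = 2,
                         norm_spec = fx$nz$spec)
  path <- withr::local_tempfile(fileext = ".json")
  circaskin:::phase_model_to_json(m, path)
  m2 <- circaskin:::phase_model_from_json(path)
  test <- fx$sim$expr[, 1:5]
  expect_equal(predict(m, test)$theta_hat, predict(m2, test)$theta_hat,
               tolerance = 1e-9)
})
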