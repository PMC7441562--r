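test_that("panels are reproducible and respect degenerate settings", {
  p1 <- make_gene_panel(n_genes = 100, frac_rhythmic = 0.3, seed = 5)
  p2 <- make_gene_panel(n_genes = 100, frac_rhythmic = 0.3, seed = 5)
  expect_identical(p1, p2)
  ## no rhythmic genes at all when the clock panel is switched off
  p0 <- make_gene_panel(n_genes = 100, frac_rhythmic = 0, clock_panel_size = 0,
                        seed = 1)
  expect_true(all(p0$rAMP == 0))
  expect_true(all(!p0$is_rhythmic))
  ## clock genes are always rhythmic
  expect_true(all(p1$rAMP[p1$is_clock] > 0))
  ## reference housekeeping genes present and flat
  expect_true(all(c("GPKOW", "BMS1", "ANKFY1") %in% p1$gene_id))
  expect_true(all(p1$rAMP[p1$gene_id %in% c("GPKOW", "BMS1", "ANKFY1")] == 0))
  expect_error(make_gene_panel(n_genes = 50, frac_rhythmic = 1.5),
               "frac_rhythmic")
})

test_that("rhythmic peak phases form the bimodal morning/evening pattern", {
  p <- make_gene_panel(n_genes = 5000, frac_rhythmic = 0.1,
                       clock_panel_size = 0, seed = 9)
  peaks <- p$peak_phase_h[p$is_rhythmic]
  breaks <- seq(0, 24, by = 1)
  h <- hist(peaks, breaks = breaks, plot = FALSE)
  ## two modes: highest bins in the two halves split at 14.5
  morning <- h$mids[h$mids < 14.5][which.max(h$counts[h$mids < 14.5])]
  evening <- h$mids[h$mids >= 14.5][which.max(h$counts[h$mids >= 14.5])]
  expect_lt(abs(morning - 8.5), 1.5)
  expect_lt(abs(evening - 20.5), 1.5)
})

test_that("noise-free longitudinal expression peaks at the gene's peak time", {
  panel <- toy_panel(c(6, 12, 18))
  sim <- simulate_longitudinal(panel, n_participants = 5,
                               chronotype_sd_h = 0, noise = FALSE, seed = 2)
  for (pid in unique(sim$meta$participant_id)) {
    idx <- which(sim$meta$participant_id == pid)
    vals <- sim$expr["T01", idx]    # peak at 6 h
    expect_equal(sim$meta$collection_time_h[idx][which.max(vals)], 6)
  }
  expect_identical(ncol(sim$expr), 20L)
  expect_identical(nrow(sim$truth), 20L)
})

test_that("flat genes have sample variance near noise_sd^2", {
  panel <- rbind(panel_row("FLAT", 0, rAMP = 0, noise_sd = 0.4),
                 panel_row("R1", 8))
  sim <- simulate_longitudinal(panel, n_participants = 20, seed = 3)
  v <- var(sim$expr["FLAT", ])
  se <- 0.4^2 * sqrt(2 / (80 - 1))   # se of a variance estimate
  expect_lt(abs(v - 0.16), 3 * se)
})

test_that("population design: shared phases, attenuation, bookkeeping", {
  panel <- toy_panel(c(3, 9, 15, 21), layer_atten = 0.5)
  sim <- simulate_population(panel, n_participants = 12, noise = FALSE, seed = 6)
  expect_identical(ncol(sim$expr), 12L * 6L)
  tab <- table(sim$meta$body_site, sim$meta$layer)
  expect_true(all(tab == 12))
  ## one hidden phase per participant, shared across sites and layers
  th <- tapply(sim$truth$theta_rad, sim$truth$participant_id,
               function(x) diff(range(x)))
  expect_true(all(th == 0))
  ## dermis amplitude is exactly layer_atten times the epidermis amplitude
  ## (noise-free, same participant phases in both layers)
  epi <- sim$expr[, sim$meta$layer == "epidermis"]
  der <- sim$expr[, sim$meta$layer == "dermis"]
  g <- "T02"
  mes <- panel$mesor[panel$gene_id == g]
  dev_e <- epi[g, sim$meta$body_site[sim$meta$layer == "epidermis"] == "arm"] - mes
  dev_d <- der[g, sim$meta$body_site[sim$meta$layer == "dermis"] == "arm"] - mes
  expect_equal(unname(dev_d), unname(0.5 * dev_e), tolerance = 1e-10)
  ## population metadata never carries collection times
  expect_true(all(is.na(sim$meta$collection_time_h)))
})

test_that("uniform population phases show no spurious clustering", {
  panel <- toy_panel(c(3, 9))
  sim <- simulate_population(panel, n_participants = 154, sites = "arm",
                             layers = "epidermis", seed = 8)
  r_obs <- circaskin:::resultant_length(sim$truth$theta_rad)
  ## 99th percentile of the Rayleigh null, by direct simulation
  set.seed(1)
  r_null <- replicate(2000, circaskin:::resultant_length(runif(154, 0, 2 * pi)))
  expect_lt(r_obs, quantile(r_null, 0.99))
})

test_that("same seed gives byte-identical simulations", {
  panel <- make_gene_panel(n_genes = 50, frac_rhythmic = 0.3, seed = 2)
  a <- simulate_population(panel, n_participants = 10, seed = 11)
  b <- simulate_population(panel, n_participants = 10, seed = 11)
  expect_identical(a, b)
})

test_that("expression stays within the mesor +/- amplitude + 6 sd envelope", {
  panel <- make_gene_panel(n_genes = 80, frac_rhythmic = 0.5, indiv_cv = 0,
                           seed = 3)
  sim <- simulate_population(panel, n_participants = 100, sites = "arm",
                             layers = "epidermis", seed = 4)
  bound <- panel$mesor * panel$rAMP + 6 * panel$noise_sd
  frac_in <- mean(abs(sim$expr - panel$mesor) <= bound)
  expect_gte(frac_in, 0.9999)
})

test_that("marker phases follow the anchor with the configured lags", {
  panel <- rbind(panel_row("ARNTL", 4, is_clock = TRUE), panel_row("X", 9))
  sim <- simulate_longitudinal(panel, n_participants = 20,
                               chronotype_sd_h = 0, seed = 5)
  tr <- marker_phases(sim$truth, panel, jitter_sd_h = 0)
  expect_equal(unique(tr$melatonin_phase_h), 11)   # 4 + 7
  expect_equal(unique(tr$cortisol_phase_h), 14)    # 4 + 10
  ## with chronotypes, anchor and marker phases correlate perfectly...
  sim2 <- simulate_longitudinal(panel, n_participants = 20,
                                chronotype_sd_h = 1.5, seed = 6)
  tr2 <- marker_phases(sim2$truth, panel, jitter_sd_h = 0)
  pp <- !duplicated(tr2$participant_id)
  anchor <- hours_to_rad((4 - tr2$chronotype_h[pp]) %% 24)
  expect_equal(circ_corr(anchor, hours_to_rad(tr2$melatonin_phase_h[pp])), 1,
               tolerance = 1e-9)
  ## ... and still strongly with 1 h jitter
  tr3 <- marker_phases(sim2$truth, panel, jitter_sd_h = 1, seed = 7)
  expect_gt(circ_corr(anchor, hours_to_rad(tr3$melatonin_phase_h[pp])), 0.8)
})

test_that("the synthetic clock reference matches a dense-sampling oracle", {
  panel <- rbind(panel_row("A", 2, is_clock = TRUE),
                 panel_row("B", 14, is_clock = TRUE),   # antiphase to A
                 panel_row("C", 8, is_clock = TRUE),
                 panel_row("D", 5, is_clock = TRUE),
                 panel_row("E", 20, is_clock = TRUE),
                 panel_row("F", 11, is_clock = TRUE),
                 panel_row("G", 23, is_clock = TRUE),
                 panel_row("H", 17, is_clock = TRUE))
  ref <- reference_matrix_from_panel(panel, noise = FALSE, seed = 3)
  expect_equal(unname(diag(ref)), rep(1, 8))
  expect_lt(ref["A", "B"], -0.99)
  expect_equal(ref, t(ref))
  ## oracle: rank-then-Pearson on an independent dense phase grid
  theta <- seq(0, 2 * pi, length.out = 5000)[-5000]
  X <- cosine_matrix(panel, theta)
  oracle <- cor(apply(t(X), 2, rank))
  expect_equal(unname(ref), unname(oracle[rownames(ref), colnames(ref)]),
               tolerance = 0.02)
})

test_that("simulations write and re-read as the standard TSV trio", {
  panel <- toy_panel(c(2, 10, 18))
  sim <- simulate_longitudinal(panel, n_participants = 3, seed = 1)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "meta.tsv"))
  expect_equal(back$expr, sim$expr, tolerance = 1e-12)
  tr <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(tr$theta_rad, sim$truth$theta_rad, tolerance = 1e-12)
})
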