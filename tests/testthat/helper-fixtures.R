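# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; nothing is read from disk except files the tests write.

# Hand-built gene panel rows with full control over every spec field.
panel_row <- function(gene_id, peak_h, rAMP = 0.3, mesor = 15, noise_sd = 0.5,
                      is_clock = FALSE, layer_atten = 0.5, indiv_sd = 0) {
  data.frame(gene_id = gene_id, is_rhythmic = rAMP > 0, mesor = mesor,
             rAMP = rAMP, peak_phase_h = peak_h, noise_sd = noise_sd,
             indiv_sd = indiv_sd, is_clock = is_clock,
             layer_atten = layer_atten, stringsAsFactors = FALSE)
}

toy_panel <- function(peaks_h, ...) {
  do.call(rbind, lapply(seq_along(peaks_h), function(i)
    panel_row(sprintf("T%02d", i), peaks_h[i], ...)))
}

# Cosine expression at given phases, no noise: the generator's mean model.
cosine_matrix <- function(panel, theta) {
  out <- panel$mesor * (1 + outer(panel$rAMP, rep(1, length(theta))) *
                          cos(outer(-circaskin::hours_to_rad(panel$peak_phase_h),
                                    theta, "+")))
  dimnames(out) <- list(panel$gene_id,
                        sprintf("S%03d", seq_along(theta)))
  out
}

# Independent dense grid-search cosinor oracle: for each candidate peak
# phase, mesor and amplitude are the least-squares solution; the global
# optimum is refined by a second, finer pass around the best phase.
grid_cosinor_oracle <- function(times_h, values, period = 24) {
  rss_for <- function(phi) {
    X <- cbind(1, cos(2 * pi * times_h / period - phi))
    f <- lm.fit(X, values)
    c(rss = sum(f$residuals^2), M = f$coefficients[1], A = f$coefficients[2])
  }
  search <- function(phis) {
    res <- vapply(phis, rss_for, c(rss = 0, M = 0, A = 0))
    i <- which.min(res["rss", ])
    list(phi = phis[i], M = res["M", i], A = res["A", i])
  }
  coarse <- search(seq(0, 2 * pi, length.out = 2001)[-2001])
  fine <- search(coarse$phi + seq(-0.005, 0.005, length.out = 4001))
  A <- fine$A
  phi <- fine$phi
  if (A < 0) {
    A <- -A
    phi <- phi + pi
  }
  list(fitmean = unname(fine$M), amplitude = unname(A),
       peak_phase_h = unname((phi %% (2 * pi)) * period / (2 * pi)))
}

# All permutations of seq_len(n), built by a method independent of the
# package's internal enumerator (recursive insertion vs. interleaving).
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  prev <- perms_oracle(n - 1L)
  out <- list()
  for (p in prev)
    for (k in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = k)
  out
}

# Exhaustive sign-flip null for the Wilcoxon signed-rank two-tailed p.
signflip_wilcoxon_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
}

circ_align_err_h <- function(pred, true) {
  rot <- circaskin:::align_rotation(pred, true)
  if (!is.finite(rot)) rot <- 0
  circaskin::abs_err_hours(pred - rot, true)
}

# Reduced pipeline configuration for fast integration tests.
small_config <- function(seed = 1) {
  cfg <- circaskin::default_config(seed)
  cfg$panel$n_genes <- 120
  cfg$panel$frac_rhythmic <- 0.3
  cfg$population$n_participants <- 60
  cfg$downsample$n_iter <- 30
  cfg$order$n_restarts <- 6
  cfg$train$n_test_participants <- 5
  cfg
}
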