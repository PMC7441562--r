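## Synthetic two-layer skin expression data with known ground-truth phases,
## emulating the hybrid study design: 20 stamped longitudinal participants
## sampled at 6 AM / 12 PM / 6 PM / 12 AM, and ~154 unstamped population
## participants contributing one biopsy per body site (arm, buttock, cheek)
## split into epidermis and dermis.

#' Canonical clock-gene panel with relative peak phases
#'
#' The 17 clock and clock-associated genes used throughout, with their
#' canonical peak phases in hours relative to the ARNTL peak (set to 0 by
#' convention: E-box repressors and PAR-bZip factors peak in antiphase,
#' roughly 10-13 h later). The table is editable: pass a modified copy to
#' [make_gene_panel()].
#'
#' @return data.frame with `gene_id` and `rel_phase_h`.
#' @export
clock_gene_panel <- function() {
  data.frame(
    gene_id = c("ARNTL", "ARNTL2", "NPAS2", "CLOCK", "RORC", "NR1D1",
                "NR1D2", "PER1", "PER2", "PER3", "CRY1", "CRY2", "DBP",
                "TEF", "HLF", "NFIL3", "CIPC"),
    rel_phase_h = c(0, 0.5, 1, 1.5, 2.5, 10, 10.5, 11, 12.5, 12, 16, 13,
                    11, 11.5, 12, 22, 13.5),
    stringsAsFactors = FALSE)
}

## Reference housekeeping genes guaranteed non-rhythmic in every panel; used
## by the predictor's step-1 normalization.
REF_GENES <- c("GPKOW", "BMS1", "ANKFY1")

## Von Mises sampler (Best & Fisher 1979 rejection scheme); base R has none.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_angle(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1
    }
  }
  out
}

## Sample angles from a phase distribution spec: "uniform" or
## list(type = "vonmises_mixture", mu = <radians>, kappa, weights).
sample_phase_dist <- function(n, phase_dist) {
  if (identical(phase_dist, "uniform")) return(stats::runif(n, 0, 2 * pi))
  fail_unless(is.list(phase_dist) &&
                identical(phase_dist$type, "vonmises_mixture"),
              "phase_dist must be \"uniform\" or a vonmises_mixture list")
  k <- length(phase_dist$mu)
  w <- phase_dist$weights %||% rep(1 / k, k)
  comp <- sample.int(k, n, replace = TRUE, prob = w)
  kap <- rep_len(phase_dist$kappa, k)
  vapply(seq_len(n),
         function(i) rvonmises(1, phase_dist$mu[comp[i]], kap[comp[i]]),
         0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a synthetic gene panel
#'
#' Draws per-gene simulation parameters. Rhythmic peak phases come from a
#' two-component circular mixture centred on the study's bimodal morning /
#' evening modes; the clock genes receive fixed canonical relative phases
#' anchored at the evening ARNTL peak; the three reference housekeeping
#' genes are always present and non-rhythmic.
#'
#' @param n_genes total number of genes (>= clock panel + 3 references).
#' @param frac_rhythmic fraction of non-clock genes that are rhythmic.
#' @param bimodal_peaks two peak-time modes in hours (default 8.5 and 20.5).
#' @param peak_sd_h circular spread (h) around each mode.
#' @param clock_panel_size number of clock genes taken from
#'   [clock_gene_panel()] (default all 17).
#' @param clock_table clock panel table (gene_id, rel_phase_h).
#' @param arntl_peak_h clock-time of the ARNTL peak (default 20.5 h, about
#'   7 h before a typical melatonin peak).
#' @param mesor_range range of mesors (log2 units); straddles the abundance
#'   filter at 16 so population-mode thresholds are exercised.
#' @param clock_mesor_range mesor range for the clock panel; clock genes are
#'   abundantly expressed in skin, so their default sits above the
#'   abundance filter.
#' @param rAMP_range relative-amplitude range for rhythmic non-clock genes.
#' @param clock_rAMP_range relative-amplitude range for clock genes.
#' @param noise_cv per-gene measurement-noise sd as a fraction of the mesor.
#' @param indiv_cv per-gene inter-individual sd as a fraction of the mesor:
#'   each participant carries a persistent per-gene expression offset shared
#'   by all of their samples, emulating the interpersonal variability of
#'   population skin data.
#' @param layer_atten multiplier on rAMP in the attenuated (dermis) layer.
#' @param seed RNG seed.
#' @return data.frame of gene specifications (one row per gene) with columns
#'   `gene_id`, `is_rhythmic`, `mesor`, `rAMP`, `peak_phase_h`, `noise_sd`,
#'   `indiv_sd`, `is_clock`, `layer_atten`.
#' @export
make_gene_panel <- function(n_genes = 500, frac_rhythmic = 0.15,
                            bimodal_peaks = c(8.5, 20.5), peak_sd_h = 1.5,
                            clock_panel_size = 17,
                            clock_table = clock_gene_panel(),
                            arntl_peak_h = 20.5,
                            mesor_range = c(12, 20),
                            clock_mesor_range = c(16.5, 20),
                            rAMP_range = c(0.1, 0.5),
                            clock_rAMP_range = c(0.25, 0.5),
                            noise_cv = 0.1, indiv_cv = 0.1,
                            layer_atten = 0.5, seed = 1) {
  fail_unless(frac_rhythmic >= 0 && frac_rhythmic <= 1,
              "frac_rhythmic must be in [0, 1]")
  fail_unless(clock_panel_size <= nrow(clock_table),
              "clock_panel_size exceeds the clock table (%d)", nrow(clock_table))
  fail_unless(n_genes >= clock_panel_size + length(REF_GENES),
              "n_genes must cover the clock panel plus %d reference genes",
              length(REF_GENES))
  with_seed(seed, {
    clock <- clock_table[seq_len(clock_panel_size), , drop = FALSE]
    n_other <- n_genes - nrow(clock) - length(REF_GENES)
    other_ids <- sprintf("G%05d", seq_len(n_other))
    gene_id <- c(clock$gene_id, REF_GENES, other_ids)
    is_clock <- c(rep(TRUE, nrow(clock)), rep(FALSE, n_genes - nrow(clock)))
    is_rhythmic <- is_clock
    if (n_other > 0 && frac_rhythmic > 0) {
      n_r <- round(frac_rhythmic * n_other)
      idx <- nrow(clock) + length(REF_GENES) + seq_len(n_other)
      is_rhythmic[sample(idx, n_r)] <- TRUE
    }
    mesor <- stats::runif(n_genes, mesor_range[1], mesor_range[2])
    mesor[is_clock] <- stats::runif(sum(is_clock), clock_mesor_range[1],
                                    clock_mesor_range[2])
    rAMP <- numeric(n_genes)
    rAMP[is_rhythmic] <- stats::runif(sum(is_rhythmic), rAMP_range[1],
                                      rAMP_range[2])
    rAMP[is_clock] <- stats::runif(sum(is_clock), clock_rAMP_range[1],
                                   clock_rAMP_range[2])
    peak <- numeric(n_genes)
    peak[is_clock] <- (arntl_peak_h + clock$rel_phase_h) %% 24
    free <- is_rhythmic & !is_clock
    if (any(free)) {
      mode_pick <- sample(bimodal_peaks, sum(free), replace = TRUE)
      peak[free] <- (mode_pick + stats::rnorm(sum(free), 0, peak_sd_h)) %% 24
    }
    data.frame(gene_id = gene_id, is_rhythmic = is_rhythmic, mesor = mesor,
               rAMP = rAMP, peak_phase_h = peak,
               noise_sd = pmax(noise_cv * mesor, 1e-8),
               indiv_sd = indiv_cv * mesor,
               is_clock = is_clock, layer_atten = layer_atten,
               stringsAsFactors = FALSE)
  })
}

## Expression for a panel at hidden phases theta (radians), one value per
## gene x sample: mesor * (1 + rAMP_eff * cos(theta - peak)) + noise.
panel_expression <- function(panel, theta, layer = "epidermis",
                             noise = TRUE) {
  atten <- ifelse(layer == "dermis", panel$layer_atten, 1)
  ramp_eff <- panel$rAMP * atten
  phase_rad <- hours_to_rad(panel$peak_phase_h)
  base <- panel$mesor * (1 + outer(ramp_eff, rep(1, length(theta))) *
                           cos(outer(-phase_rad, theta, "+")))
  if (noise)
    base <- base + matrix(stats::rnorm(length(base), 0, panel$noise_sd),
                          nrow = nrow(panel))
  rownames(base) <- panel$gene_id
  base
}

## Per-participant, per-gene persistent expression offsets (genes x
## participants); zero matrix when the panel has no indiv_sd.
indiv_offsets <- function(panel, n_participants) {
  sdv <- if ("indiv_sd" %in% names(panel)) panel$indiv_sd else 0
  matrix(stats::rnorm(nrow(panel) * n_participants, 0, sdv),
         nrow = nrow(panel))
}

empty_truth <- function(sample_id, theta, participant_id, chronotype_h) {
  data.frame(sample_id = sample_id, theta_rad = wrap_angle(theta),
             participant_id = participant_id, chronotype_h = chronotype_h,
             melatonin_phase_h = NA_real_, cortisol_phase_h = NA_real_,
             stringsAsFactors = FALSE)
}

#' Simulate the stamped longitudinal cohort
#'
#' Each participant donates one biopsy at each of the four clock times; a
#' per-participant chronotype offset (a pure circular shift) moves their
#' internal phase relative to clock time.
#'
#' @param panel gene panel from [make_gene_panel()].
#' @param n_participants number of participants (default 20).
#' @param times_h collection times in hours (default 6, 12, 18, 24).
#' @param chronotype_sd_h sd of the chronotype offset in hours.
#' @param layer `"epidermis"` or `"dermis"`.
#' @param body_site collection site (default `"arm"`).
#' @param noise add Gaussian noise (disable for oracle checks).
#' @param seed RNG seed.
#' @param id_prefix prefix for participant ids.
#' @return list with `expr`, `meta`, `truth`.
#' @export
simulate_longitudinal <- function(panel, n_participants = 20,
                                  times_h = c(6, 12, 18, 24),
                                  chronotype_sd_h = 1, layer = "epidermis",
                                  body_site = "arm", noise = TRUE, seed = 1,
                                  id_prefix = "L") {
  fail_unless(all(diff(times_h) > 0) && all(times_h >= 0 & times_h <= 24),
              "times_h must be strictly increasing in [0, 24]")
  with_seed(seed, {
    pid <- sprintf("%s%03d", id_prefix, seq_len(n_participants))
    chrono <- stats::rnorm(n_participants, 0, chronotype_sd_h)
    grid <- expand.grid(p = seq_len(n_participants), t = times_h,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$p, grid$t), ]
    sample_id <- sprintf("%s_%s_%02dh_%s", pid[grid$p], body_site,
                         as.integer(grid$t) %% 24L, substr(layer, 1, 3))
    theta <- hours_to_rad(grid$t + chrono[grid$p])
    expr <- panel_expression(panel, theta, layer = layer, noise = noise)
    if (noise) expr <- expr + indiv_offsets(panel, n_participants)[, grid$p]
    colnames(expr) <- sample_id
    meta <- data.frame(sample_id = sample_id, participant_id = pid[grid$p],
                       layer = layer, body_site = body_site,
                       collection_time_h = grid$t %% 24, cohort = "longitudinal",
                       batch = "b1", stringsAsFactors = FALSE)
    truth <- empty_truth(sample_id, theta, pid[grid$p], chrono[grid$p])
    list(expr = expr, meta = meta, truth = truth)
  })
}

#' Simulate the unstamped population cohort
#'
#' One hidden circadian phase per participant, shared by all of that
#' participant's biopsies across body sites and layers; dermis amplitudes
#' are attenuated by the panel's `layer_atten`. Collection times are not
#' recorded (missing in the metadata), mirroring the population study.
#'
#' @param panel gene panel from [make_gene_panel()].
#' @param n_participants number of participants (default 154).
#' @param sites body sites sampled per participant.
#' @param layers skin layers per biopsy.
#' @param phase_dist `"uniform"` or a list
#'   `list(type = "vonmises_mixture", mu =, kappa =, weights =)`.
#' @param noise add Gaussian noise.
#' @param seed RNG seed.
#' @param id_prefix prefix for participant ids.
#' @return list with `expr`, `meta`, `truth` (one truth row per sample).
#' @export
simulate_population <- function(panel, n_participants = 154,
                                sites = c("arm", "buttock", "cheek"),
                                layers = c("epidermis", "dermis"),
                                phase_dist = "uniform", noise = TRUE,
                                seed = 1, id_prefix = "P") {
  with_seed(seed, {
    pid <- sprintf("%s%03d", id_prefix, seq_len(n_participants))
    theta_p <- sample_phase_dist(n_participants, phase_dist)
    grid <- expand.grid(p = seq_len(n_participants), site = sites,
                        layer = layers, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$p, grid$site, grid$layer), ]
    sample_id <- sprintf("%s_%s_%s", pid[grid$p], grid$site,
                         substr(grid$layer, 1, 3))
    expr <- matrix(NA_real_, nrow(panel), nrow(grid),
                   dimnames = list(panel$gene_id, sample_id))
    offsets <- indiv_offsets(panel, n_participants)
    for (ly in layers) {
      idx <- grid$layer == ly
      expr[, idx] <- panel_expression(panel, theta_p[grid$p[idx]],
                                      layer = ly, noise = noise)
      if (noise) expr[, idx] <- expr[, idx] + offsets[, grid$p[idx]]
    }
    meta <- data.frame(sample_id = sample_id, participant_id = pid[grid$p],
                       layer = grid$layer, body_site = grid$site,
                       collection_time_h = NA_real_, cohort = "population",
                       batch = "b1", stringsAsFactors = FALSE)
    truth <- empty_truth(sample_id, theta_p[grid$p], pid[grid$p],
                         NA_real_)
    list(expr = expr, meta = meta, truth = truth)
  })
}

#' Fill per-participant melatonin and cortisol marker phases
#'
#' The melatonin peak sits a fixed lag after each participant's ARNTL peak
#' (the study anchor: ARNTL peaks about 7 h before melatonin), cortisol at a
#' configurable offset, both with optional jitter.
#'
#' @param truth truth table from [simulate_longitudinal()] (chronotypes
#'   required).
#' @param panel the gene panel (for the ARNTL peak time).
#' @param arntl_to_melatonin_h lag from ARNTL peak to melatonin phase.
#' @param arntl_to_cortisol_h lag from ARNTL peak to cortisol phase.
#' @param jitter_sd_h sd of per-participant jitter (h).
#' @param seed RNG seed.
#' @return the truth table with `melatonin_phase_h` / `cortisol_phase_h`
#'   filled.
#' @export
marker_phases <- function(truth, panel, arntl_to_melatonin_h = 7,
                          arntl_to_cortisol_h = 10, jitter_sd_h = 0,
                          seed = 1) {
  fail_unless(all(is.finite(truth$chronotype_h)),
              "marker_phases: chronotypes missing from truth table")
  fail_unless("ARNTL" %in% panel$gene_id, "marker_phases: panel lacks ARNTL")
  arntl_h <- panel$peak_phase_h[panel$gene_id == "ARNTL"]
  with_seed(seed, {
    pid <- unique(truth$participant_id)
    jit_m <- stats::rnorm(length(pid), 0, jitter_sd_h)
    jit_c <- stats::rnorm(length(pid), 0, jitter_sd_h)
    i <- match(truth$participant_id, pid)
    ## theta = 2*pi*(t + chronotype)/24, so a participant's ARNTL peaks at
    ## clock time arntl_h - chronotype
    peak_p <- (arntl_h - truth$chronotype_h) %% 24
    truth$melatonin_phase_h <- (peak_p + arntl_to_melatonin_h + jit_m[i]) %% 24
    truth$cortisol_phase_h <- (peak_p + arntl_to_cortisol_h + jit_c[i]) %% 24
    truth
  })
}

#' Synthetic multi-tissue clock reference correlation matrix
#'
#' Stand-in for a multi-tissue clock-gene benchmark (the published mouse
#' 12-tissue reference is not reproduced here): each virtual tissue is
#' sampled densely and uniformly around the cycle, all tissues are pooled,
#' and the Spearman correlation matrix over the clock genes is returned.
#'
#' @param panel gene panel containing the clock genes.
#' @param n_virtual_tissues number of pooled virtual tissues (default 12).
#' @param n_phases phases sampled per tissue (default 24).
#' @param noise add Gaussian noise (default TRUE).
#' @param seed RNG seed.
#' @return symmetric Spearman correlation matrix over the clock genes.
#' @export
reference_matrix_from_panel <- function(panel, n_virtual_tissues = 12,
                                        n_phases = 24, noise = TRUE,
                                        seed = 1) {
  clock <- panel[panel$is_clock, , drop = FALSE]
  fail_unless(nrow(clock) >= 2, "reference_matrix_from_panel: no clock genes")
  with_seed(seed, {
    mats <- lapply(seq_len(n_virtual_tissues), function(i) {
      offset <- stats::runif(1, 0, 2 * pi)
      theta <- wrap_angle(offset + 2 * pi * (seq_len(n_phases) - 1) / n_phases)
      panel_expression(clock, theta, layer = "epidermis", noise = noise)
    })
    pooled <- do.call(cbind, mats)
    colnames(pooled) <- sprintf("vt%03d", seq_len(ncol(pooled)))
    clock_corr(pooled, clock$gene_id, min_samples = n_phases)
  })
}

#' Write a simulated dataset as the standard TSV trio
#' @param sim list with `expr`, `meta`, `truth`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  write_sample_meta(sim$meta, file.path(dir, "meta.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

#' Merge two simulated cohorts (shared gene panel)
#' @param a,b lists with `expr`, `meta`, `truth`.
#' @return merged list.
#' @export
combine_simulations <- function(a, b) {
  list(expr = assemble_hybrid(a$expr, b$expr),
       meta = rbind(a$meta, b$meta),
       truth = rbind(a$truth, b$truth))
}
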