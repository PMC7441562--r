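## End-to-end orchestration: simulate -> downsample -> order -> detect ->
## train -> predict -> evaluate, with per-stage artifacts, derived seeds and
## a manifest. Stages never read the hidden truth table except simulation
## (which writes it) and evaluation (which scores against it).

#' Default pipeline configuration
#'
#' The default scenario mirrors the study design: 20 stamped longitudinal
#' participants at four timepoints and 154 unstamped population
#' participants across three body sites, one skin layer ordered at a time
#' (epidermis by default). Every stochastic stage derives its seed from the
#' master seed deterministically.
#'
#' @param seed master seed.
#' @return nested configuration list for [run_pipeline()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    panel = list(n_genes = 400, frac_rhythmic = 0.2, arntl_peak_h = 20.5,
                 noise_cv = 0.1, layer_atten = 0.5),
    longitudinal = list(n_participants = 20, times_h = c(6, 12, 18, 24),
                        chronotype_sd_h = 1),
    population = list(n_participants = 154,
                      sites = c("arm", "buttock", "cheek")),
    layer = "epidermis",
    markers = list(arntl_to_melatonin_h = 7, arntl_to_cortisol_h = 10,
                   jitter_sd_h = 1),
    downsample = list(keep_frac = 0.97, n_iter = 300, n_perm = 99),
    order = list(var_fraction = 0.85, n_restarts = 20, max_epochs = 2000,
                 tol = 1e-6, anchor_gene = "ARNTL"),
    detect = list(mode = "population"),
    train = list(sumabsv = 2, n_grid = 48, rsq_threshold = 0.1,
                 n_test_participants = 9)
  )
}

read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[circaskin] ", fmt), ...))
}

## Reference clock phases implied by the configuration (canonical panel
## anchored at the configured ARNTL peak) -- config knowledge, not truth.
config_clock_phases <- function(cfg) {
  tab <- clock_gene_panel()
  stats::setNames((cfg$panel$arntl_peak_h + tab$rel_phase_h) %% 24,
                  tab$gene_id)
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes, in order: simulation of the hybrid design, clock-signal
#' down-sampling, circular ordering with anchor registration, cosinor
#' detection on the ordering, sparse phase-model training on the ordered
#' training samples (test participants held out by participant, never by
#' sample), single-sample prediction for the held-out stamped samples, and
#' circular-error evaluation. Each stage writes TSV/JSON artifacts into
#' `outdir`; a manifest records the configuration, derived seeds and
#' artifact checksums.
#'
#' @param config configuration list, see [default_config()].
#' @param outdir output directory (created).
#' @param resume_from optional stage name (`"downsample"`, `"order"`,
#'   `"detect"`, `"train"`, `"predict"`, `"evaluate"`): earlier stages
#'   reload their artifacts from `outdir` instead of recomputing.
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory stage results (`ordering`,
#'   `model`, `predictions`, `eval`, `manifest`, ...).
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         resume_from = NULL, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- c("simulate", "downsample", "order", "detect", "train",
              "predict", "evaluate")
  start_i <- 1
  if (!is.null(resume_from)) {
    fail_unless(resume_from %in% stages[-1],
                "resume_from must be one of: %s",
                paste(stages[-1], collapse = ", "))
    start_i <- match(resume_from, stages)
  }
  st <- list(cfg = config, dir = outdir)
  for (i in seq_along(stages)) {
    stage <- stages[i]
    fun <- get(paste0("stage_", stage), mode = "function")
    loader <- get(paste0("load_", stage), mode = "function")
    st <- tryCatch({
      if (i < start_i) loader(st) else {
        pipeline_log(quiet, "stage %s", stage)
        fun(st)
      }
    }, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed (artifacts in %s): %s",
                   stage, outdir, conditionMessage(e)), call. = FALSE)
    })
  }
  ## manifest: configuration, seeds, artifact checksums (no timestamps, so
  ## identical runs produce identical manifests)
  arts <- sort(setdiff(list.files(outdir), "manifest.json"))
  sums <- as.list(unname(tools::md5sum(file.path(outdir, arts))))
  names(sums) <- arts
  manifest <- list(package = "circaskin",
                   version = as.character(utils::packageVersion("circaskin")),
                   config = config,
                   checksums = sums)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  st$manifest <- manifest
  invisible(st)
}

## -- simulate ---------------------------------------------------------------

stage_simulate <- function(st) {
  cfg <- st$cfg
  panel <- do.call(make_gene_panel,
                   c(cfg$panel, list(seed = derive_seed(cfg$seed, "panel"))))
  long <- simulate_longitudinal(
    panel, n_participants = cfg$longitudinal$n_participants,
    times_h = cfg$longitudinal$times_h,
    chronotype_sd_h = cfg$longitudinal$chronotype_sd_h,
    layer = cfg$layer, seed = derive_seed(cfg$seed, "longitudinal"))
  long$truth <- marker_phases(
    long$truth, panel,
    arntl_to_melatonin_h = cfg$markers$arntl_to_melatonin_h,
    arntl_to_cortisol_h = cfg$markers$arntl_to_cortisol_h,
    jitter_sd_h = cfg$markers$jitter_sd_h,
    seed = derive_seed(cfg$seed, "markers"))
  pop <- simulate_population(
    panel, n_participants = cfg$population$n_participants,
    sites = cfg$population$sites, layers = cfg$layer,
    seed = derive_seed(cfg$seed, "population"))
  sim <- combine_simulations(long, pop)
  benchmark <- reference_matrix_from_panel(
    panel, seed = derive_seed(cfg$seed, "reference"))
  write_simulation(sim, st$dir)
  utils::write.table(panel, file.path(st$dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(benchmark), benchmark,
                                check.names = FALSE),
                     file.path(st$dir, "benchmark.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  st$expr <- sim$expr
  st$meta <- sim$meta
  st$benchmark <- benchmark
  st
}

load_simulate <- function(st) {
  x <- read_expression(file.path(st$dir, "expression.tsv"),
                       file.path(st$dir, "meta.tsv"))
  b <- utils::read.delim(file.path(st$dir, "benchmark.tsv"),
                         check.names = FALSE)
  bm <- as.matrix(b[, -1])
  rownames(bm) <- b[[1]]
  st$expr <- x$expr
  st$meta <- x$meta
  st$benchmark <- bm
  st
}

## -- downsample -------------------------------------------------------------

stage_downsample <- function(st) {
  cfg <- st$cfg$downsample
  sel <- downsample_select(st$expr, st$benchmark, keep_frac = cfg$keep_frac,
                           n_iter = cfg$n_iter, n_perm = cfg$n_perm,
                           seed = derive_seed(st$cfg$seed, "downsample"))
  writeLines(sel$sample_ids, file.path(st$dir, "selected_samples.txt"))
  jsonlite::write_json(list(z = sel$mantel$z, z_full = sel$z_full,
                            n_selected = length(sel$sample_ids)),
                       file.path(st$dir, "downsample.json"),
                       auto_unbox = TRUE, digits = NA)
  st$selected <- sel$sample_ids
  st
}

load_downsample <- function(st) {
  st$selected <- readLines(file.path(st$dir, "selected_samples.txt"))
  st
}

## -- order ------------------------------------------------------------------

stage_order <- function(st) {
  cfg <- st$cfg$order
  expr_sel <- st$expr[, st$selected, drop = FALSE]
  seed_genes <- intersect(clock_gene_panel()$gene_id, rownames(expr_sel))
  eg <- prepare_eigengenes(expr_sel, seed_genes,
                           var_fraction = cfg$var_fraction)
  ord <- fit_circular_ordering(eg$scores, n_restarts = cfg$n_restarts,
                               max_epochs = cfg$max_epochs, tol = cfg$tol,
                               seed = derive_seed(st$cfg$seed, "order"))
  m <- st$meta[match(names(ord$theta), st$meta$sample_id), ]
  stamped <- m$sample_id[is.finite(m$collection_time_h)]
  dref <- stats::setNames(hours_to_rad(
    m$collection_time_h[match(stamped, m$sample_id)]), stamped)
  ord <- register_phase(ord, expr_sel, anchor_gene = cfg$anchor_gene,
                        direction_ref = dref)
  quality <- score_ordering(ord, st$meta, expr_sel,
                            config_clock_phases(st$cfg))
  d <- data.frame(sample_id = names(ord$theta), theta_rad = unname(ord$theta),
                  cohort = m$cohort, stringsAsFactors = FALSE)
  utils::write.table(d, file.path(st$dir, "ordering.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(time_corr = quality$time_corr,
                            clock_corr = quality$clock_corr,
                            n_clock_passing = quality$n_clock_passing,
                            reconstruction_error = quality$reconstruction_error),
                       file.path(st$dir, "quality.json"),
                       auto_unbox = TRUE, digits = NA)
  st$ordering <- ord
  st$quality <- quality
  st
}

load_order <- function(st) {
  d <- utils::read.delim(file.path(st$dir, "ordering.tsv"),
                         stringsAsFactors = FALSE)
  st$ordering <- structure(
    list(theta = stats::setNames(d$theta_rad, d$sample_id)),
    class = "circular_ordering")
  st
}

## -- detect -----------------------------------------------------------------

stage_detect <- function(st) {
  theta <- st$ordering$theta
  scan <- cosinor_scan(st$expr[, names(theta), drop = FALSE],
                       rad_to_hours(theta))
  scan$circadian_flag <- classify_circadian(scan, mode = st$cfg$detect$mode)
  utils::write.table(scan, file.path(st$dir, "cosinor_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  st$scan <- scan
  st
}

load_detect <- function(st) {
  st$scan <- utils::read.delim(file.path(st$dir, "cosinor_results.tsv"),
                               stringsAsFactors = FALSE)
  st
}

## -- train ------------------------------------------------------------------

split_participants <- function(meta, n_test, seed) {
  stamped <- unique(meta$participant_id[meta$cohort == "longitudinal"])
  fail_unless(n_test <= length(stamped),
              "n_test_participants (%d) exceeds stamped participants (%d)",
              n_test, length(stamped))
  if (n_test == 0) return(character(0))
  with_seed(seed, sort(sample(stamped, n_test)))
}

stage_train <- function(st) {
  cfg <- st$cfg$train
  theta <- st$ordering$theta
  test_p <- split_participants(st$meta, cfg$n_test_participants,
                               derive_seed(st$cfg$seed, "split"))
  test_ids <- st$meta$sample_id[st$meta$participant_id %in% test_p]
  train_ids <- setdiff(names(theta), test_ids)
  dyn <- select_dynamic_genes(st$scan, cfg$rsq_threshold)
  rows <- union(dyn, c("GPKOW", "BMS1", "ANKFY1"))
  nz <- normalize_expression(st$expr[rows, train_ids, drop = FALSE])
  model <- train_phase_model(nz$expr[dyn, , drop = FALSE],
                             theta[train_ids], sumabsv = cfg$sumabsv,
                             n_grid = cfg$n_grid, norm_spec = nz$spec)
  phase_model_to_json(model, file.path(st$dir, "model.json"))
  writeLines(dyn, file.path(st$dir, "dynamic_genes.txt"))
  writeLines(train_ids, file.path(st$dir, "train_samples.txt"))
  writeLines(test_ids, file.path(st$dir, "test_samples.txt"))
  st$model <- model
  st$test_ids <- test_ids
  st
}

load_train <- function(st) {
  st$model <- phase_model_from_json(file.path(st$dir, "model.json"))
  st$test_ids <- readLines(file.path(st$dir, "test_samples.txt"))
  st
}

## -- predict ----------------------------------------------------------------

stage_predict <- function(st) {
  if (length(st$test_ids) == 0) {
    pipeline_log(FALSE, "no held-out participants; prediction stage writes an empty table")
    pred <- data.frame(sample_id = character(0), theta_hat = numeric(0),
                       theta_hours = numeric(0), mle_ok = logical(0))
  } else {
    pred <- predict(st$model, st$expr[, st$test_ids, drop = FALSE])
  }
  utils::write.table(pred, file.path(st$dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  st$predictions <- pred
  st
}

load_predict <- function(st) {
  st$predictions <- utils::read.delim(file.path(st$dir, "predictions.tsv"),
                                      stringsAsFactors = FALSE)
  st
}

## -- evaluate ---------------------------------------------------------------

#' Evaluate phase predictions against a truth table
#'
#' Predicted phases are registered to the anchor-gene peak; hidden truth
#' phases are absolute. A single global rotation (the circular mean of the
#' prediction-minus-truth differences) aligns the two before the absolute
#' circular errors are computed, so the error reflects phase differences,
#' which chronotype does not affect. Also reports per-participant order
#' recall over stamped samples, the circular time correlation, and
#' correlations of the implied per-participant anchor peak with the
#' melatonin / cortisol markers.
#'
#' @param pred data.frame with `sample_id`, `theta_hat` (radians).
#' @param truth truth table (`sample_id`, `theta_rad`, `participant_id`,
#'   marker columns).
#' @param meta sample metadata (collection times for order recall).
#' @return list of class `"phase_eval"`.
#' @export
evaluate_predictions <- function(pred, truth, meta) {
  i <- match(pred$sample_id, truth$sample_id)
  fail_unless(!any(is.na(i)), "evaluate_predictions: samples missing from truth")
  true_theta <- truth$theta_rad[i]
  rot <- align_rotation(pred$theta_hat, true_theta)
  if (!is.finite(rot)) rot <- 0
  err <- abs_err_hours(pred$theta_hat - rot, true_theta)
  m <- meta[match(pred$sample_id, meta$sample_id), ]
  recalls <- c()
  for (p in unique(m$participant_id)) {
    idx <- which(m$participant_id == p & is.finite(m$collection_time_h))
    if (length(idx) >= 3)
      recalls[p] <- order_recall(pred$theta_hat[idx],
                                 m$collection_time_h[idx])
  }
  time_corr <- NA_real_
  stamped <- is.finite(m$collection_time_h)
  if (sum(stamped) >= 8)
    time_corr <- circ_corr(pred$theta_hat[stamped],
                           hours_to_rad(m$collection_time_h[stamped]))
  ## implied anchor (ARNTL) peak clock-time per participant: collection
  ## time minus predicted phase, averaged on the circle
  anchor_h <- c()
  for (p in unique(m$participant_id)) {
    idx <- which(m$participant_id == p & is.finite(m$collection_time_h))
    if (length(idx) >= 2) {
      a <- circular_mean(hours_to_rad(m$collection_time_h[idx]) -
                           pred$theta_hat[idx])
      if (is.finite(a)) anchor_h[p] <- rad_to_hours(a)
    }
  }
  marker <- if (length(anchor_h) >= 5) {
    suppressWarnings(marker_phase_corr(anchor_h, truth))
  } else list(melatonin = NA_real_, cortisol = NA_real_)
  per_participant <- vapply(split(err, m$participant_id), mean, 0)
  structure(list(mean_abs_err_h = mean(err), sd_abs_err_h = stats::sd(err),
                 per_sample_err_h = stats::setNames(err, pred$sample_id),
                 per_participant_err_h = per_participant,
                 order_recalled = recalls,
                 frac_order_recalled = if (length(recalls)) mean(recalls) else NA_real_,
                 time_corr = time_corr, marker_corrs = marker,
                 rotation_rad = rot),
            class = "phase_eval")
}

#' @export
print.phase_eval <- function(x, ...) {
  cat(sprintf(
    "Phase prediction evaluation (%d samples)\n  mean |error| %.2f h (sd %.2f)\n  order recalled in %d/%d participants\n  time correlation %.3f\n  marker correlation: melatonin %.3f, cortisol %.3f\n",
    length(x$per_sample_err_h), x$mean_abs_err_h, x$sd_abs_err_h,
    sum(x$order_recalled), length(x$order_recalled), x$time_corr,
    x$marker_corrs$melatonin, x$marker_corrs$cortisol))
  invisible(x)
}

stage_evaluate <- function(st) {
  if (length(st$test_ids) == 0 || nrow(st$predictions) == 0) {
    pipeline_log(FALSE, "evaluation skipped: no held-out participants")
    jsonlite::write_json(list(skipped = TRUE),
                         file.path(st$dir, "eval_report.json"),
                         auto_unbox = TRUE)
    return(st)
  }
  truth <- read_truth(file.path(st$dir, "truth.tsv"))
  ev <- evaluate_predictions(st$predictions, truth, st$meta)
  jsonlite::write_json(
    list(mean_abs_err_h = ev$mean_abs_err_h, sd_abs_err_h = ev$sd_abs_err_h,
         per_participant_err_h = as.list(ev$per_participant_err_h),
         order_recalled = as.list(ev$order_recalled),
         frac_order_recalled = ev$frac_order_recalled,
         time_corr = ev$time_corr, marker_corrs = ev$marker_corrs),
    file.path(st$dir, "eval_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(sample_id = names(ev$per_sample_err_h),
               abs_err_h = unname(ev$per_sample_err_h)),
    file.path(st$dir, "per_sample_errors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  st$eval <- ev
  st
}

load_evaluate <- function(st) st
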