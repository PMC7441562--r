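## Cosinor rhythm detection: single-series fits, a vectorized whole-matrix
## scan, Fisher meta-integration across participants, BH correction, and the
## threshold rules used to call circadian genes.

## Shared least-squares engine. Y: genes x samples matrix; t in hours.
## Returns a data.frame, one row per row of Y.
cosinor_engine <- function(times_h, Y, period = 24) {
  n <- ncol(Y)
  fail_unless(n >= 4, "cosinor: need >= 4 observations, got %d", n)
  w <- 2 * pi * times_h / period
  X <- cbind(1, cos(w), sin(w))
  qrX <- qr(X)
  fail_unless(qrX$rank == 3,
              "cosinor: design is rank-deficient (times alias the %g-h cycle)",
              period)
  B <- qr.coef(qrX, t(Y))                      # 3 x genes
  fitted <- X %*% B
  res <- t(Y) - fitted
  rss <- colSums(res^2)
  tss <- colSums((t(Y) - matrix(colMeans(t(Y)), n, nrow(Y), byrow = TRUE))^2)
  amplitude <- sqrt(B[2, ]^2 + B[3, ]^2)
  peak <- (period / (2 * pi)) * atan2(B[3, ], B[2, ]) %% (2 * pi)
  peak <- peak %% period
  rsq <- ifelse(tss > 0, pmax(0, 1 - rss / tss), 0)
  df2 <- n - 3
  Fstat <- ((tss - rss) / 2) / (rss / df2)
  p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  ## degenerate series: no variance around the mean
  flat <- tss <= .Machine$double.eps * n * pmax(1, colMeans(t(Y))^2)
  amplitude[flat] <- 0
  p[flat | !is.finite(p)] <- 1
  rsq[flat] <- 0
  fitmean <- B[1, ]
  ramp <- ifelse(fitmean > 0, amplitude / fitmean, NA_real_)
  data.frame(fitmean = fitmean, amplitude = amplitude, rAMP = ramp,
             peak_phase_h = ifelse(amplitude > 0, peak, 0),
             rsq = rsq, pvalue = pmin(1, pmax(p, .Machine$double.xmin)),
             row.names = NULL)
}

#' Fit a single-component cosinor to one series
#'
#' Least-squares fit of `y = M + a cos(2 pi t / period) + b sin(2 pi t /
#' period)`. The amplitude is `sqrt(a^2 + b^2)`, the peak phase (acrophase)
#' `(period / 2 pi) * atan2(b, a)` modulo the period, and the p-value comes
#' from the F test of `(a, b)` jointly zero.
#'
#' @param times_h observation times in hours (>= 4 values not aliasing the
#'   cycle). For phase-ordered data pass `rad_to_hours(theta)`.
#' @param values numeric expression values (log2 scale).
#' @param period period in hours, fixed to 24 for circadian fits.
#' @return an object of class `"cosinor_fit"` with components `fitmean`,
#'   `amplitude`, `rAMP`, `peak_phase_h`, `rsq`, `pvalue`, `n`, `period`.
#' @examples
#' t <- c(0, 6, 12, 18)
#' fit_cosinor(t, 10 + 2 * cos(2 * pi * t / 24))
#' @export
fit_cosinor <- function(times_h, values, period = 24) {
  fail_unless(length(times_h) == length(values), "fit_cosinor: lengths differ")
  keep <- is.finite(values) & is.finite(times_h)
  r <- cosinor_engine(times_h[keep], matrix(values[keep], nrow = 1), period)
  out <- as.list(r[1, ])
  out$n <- sum(keep)
  out$period <- period
  class(out) <- "cosinor_fit"
  out
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "Cosinor fit (period %g h, n = %d)\n  mesor %.4g  amplitude %.4g  rAMP %.3g\n  peak %.2f h  R^2 %.3f  p %.3g\n",
    x$period, x$n, x$fitmean, x$amplitude, x$rAMP, x$peak_phase_h, x$rsq,
    x$pvalue))
  invisible(x)
}

#' @export
coef.cosinor_fit <- function(object, ...) {
  c(fitmean = object$fitmean, amplitude = object$amplitude,
    peak_phase_h = object$peak_phase_h)
}

#' Cosinor scan of every gene in an expression matrix
#'
#' Fits [fit_cosinor()] to every row of a genes-by-samples matrix against a
#' common time (or ordering-phase) vector, sharing one design decomposition.
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param times_h per-sample times in hours (length `ncol(expr)`).
#' @param period period in hours (default 24).
#' @param add_q add BH q-values (default TRUE).
#' @return data.frame with columns `gene_id`, `fitmean`, `amplitude`,
#'   `rAMP`, `peak_phase_h`, `rsq`, `pvalue` and optionally `qvalue`.
#' @export
cosinor_scan <- function(expr, times_h, period = 24, add_q = TRUE) {
  fail_unless(length(times_h) == ncol(expr),
              "cosinor_scan: %d times for %d samples", length(times_h),
              ncol(expr))
  r <- cosinor_engine(times_h, expr, period)
  r <- cbind(data.frame(gene_id = rownames(expr), stringsAsFactors = FALSE), r)
  if (add_q) r$qvalue <- bh_fdr(r$pvalue)
  r
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment, delegated to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvalues numeric p-values in (0, 1].
#' @return q-values, same length.
#' @export
bh_fdr <- function(pvalues) {
  fail_unless(all(is.finite(pvalues) & pvalues > 0 & pvalues <= 1),
              "bh_fdr: p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Integrate per-participant cosinor fits for each gene
#'
#' Combines the per-participant rhythm evidence for each gene: p-values by
#' Fisher's method (chi-squared with 2k df on `-2 sum log p`), peak phases by
#' the amplitude-weighted circular mean, and relative amplitude by the
#' median. Genes fit in fewer than two participants are dropped with a
#' warning.
#'
#' @param fits data.frame with columns `gene_id`, `participant_id`,
#'   `pvalue`, `peak_phase_h`, `amplitude`, `rAMP` (one row per gene x
#'   participant), e.g. stacked [cosinor_scan()] results.
#' @return data.frame with `gene_id`, `combined_p`, `qvalue`,
#'   `integrated_phase_h`, `median_rAMP`, `n_participants`.
#' @export
meta_integrate <- function(fits) {
  need <- c("gene_id", "participant_id", "pvalue", "peak_phase_h",
            "amplitude", "rAMP")
  fail_unless(all(need %in% names(fits)),
              "meta_integrate: missing columns: %s",
              paste(setdiff(need, names(fits)), collapse = ", "))
  fits <- fits[is.finite(fits$pvalue), , drop = FALSE]
  sp <- split(fits, fits$gene_id)
  keep <- vapply(sp, nrow, 0L) >= 2
  if (any(!keep)) {
    warning(sprintf("meta_integrate: dropping %d gene(s) with < 2 participants",
                    sum(!keep)))
    sp <- sp[keep]
  }
  fail_unless(length(sp) > 0, "meta_integrate: no gene has >= 2 participants")
  rows <- lapply(sp, function(d) {
    k <- nrow(d)
    stat <- -2 * sum(log(pmax(d$pvalue, .Machine$double.xmin)))
    cp <- stats::pchisq(stat, df = 2 * k, lower.tail = FALSE)
    ph <- circular_mean(hours_to_rad(d$peak_phase_h), w = d$amplitude)
    data.frame(gene_id = d$gene_id[1], combined_p = max(cp, .Machine$double.xmin),
               integrated_phase_h = if (is.finite(ph)) rad_to_hours(ph) else NA_real_,
               median_rAMP = stats::median(d$rAMP), n_participants = k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$qvalue <- bh_fdr(out$combined_p)
  out[, c("gene_id", "combined_p", "qvalue", "integrated_phase_h",
          "median_rAMP", "n_participants")]
}

#' Call circadian genes by the mode-specific threshold conjunction
#'
#' Longitudinal mode: `p < 0.05 & rAMP > 0.1`. Relaxed mode: `p < 0.1 &
#' rAMP > 0.1`. Population mode (CYCLOPS-ordered data): `FDR < 0.05 &
#' fitmean > 16 & rAMP > 0.1 & rsq > 0.1`. All cutoffs overridable.
#'
#' @param results data.frame from [cosinor_scan()] or [meta_integrate()]
#'   (`combined_p` is accepted as `pvalue`).
#' @param mode one of `"longitudinal"`, `"relaxed"`, `"population"`.
#' @param thresholds optional named list overriding any of `p`, `q`,
#'   `rAMP`, `fitmean`, `rsq`.
#' @return logical vector, one flag per row of `results`.
#' @export
classify_circadian <- function(results,
                               mode = c("longitudinal", "relaxed", "population"),
                               thresholds = list()) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    longitudinal = list(p = 0.05, rAMP = 0.1),
    relaxed      = list(p = 0.1, rAMP = 0.1),
    population   = list(q = 0.05, fitmean = 16, rAMP = 0.1, rsq = 0.1))
  th <- utils::modifyList(defaults, thresholds)
  p <- if ("pvalue" %in% names(results)) results$pvalue else results$combined_p
  ramp <- if ("rAMP" %in% names(results)) results$rAMP else results$median_rAMP
  flag <- rep(TRUE, nrow(results))
  if (!is.null(th$p)) flag <- flag & p < th$p
  if (!is.null(th$q)) {
    fail_unless("qvalue" %in% names(results),
                "classify_circadian: population mode requires qvalues")
    flag <- flag & results$qvalue < th$q
  }
  if (!is.null(th$rAMP)) flag <- flag & !is.na(ramp) & ramp > th$rAMP
  if (!is.null(th$fitmean)) flag <- flag & results$fitmean > th$fitmean
  if (!is.null(th$rsq)) flag <- flag & results$rsq > th$rsq
  flag
}
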