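## Sparse periodic phase predictor: three-step expression normalization
## with a stored spec, dynamic-gene selection, periodic curve fitting,
## sparse principal components by penalized matrix decomposition, and
## maximum-likelihood single-sample phase prediction.

norm_spec_hash <- function(spec) {
  num <- sum(round(spec$lo, 8)) + sum(round(spec$hi, 8)) +
    sum(round(spec$max, 8))
  chr <- sum(utf8ToInt(paste(c(spec$ref_genes, names(spec$max)),
                             collapse = "")))
  paste(format(num, digits = 15), chr, length(spec$max), sep = "_")
}

#' Three-step expression normalization for phase prediction
#'
#' Training-time normalization: (1) subtract from every gene, per sample,
#' the mean of three non-circadian reference genes (log scale); (2)
#' winsorize each gene at stated quantiles of its training distribution;
#' (3) divide each gene by its post-winsorization maximum magnitude, so
#' every value lies in `[-1, 1]` and each gene attains magnitude 1 (the
#' centering in step 1 makes values signed). All constants
#' are stored in a spec so test samples can be normalized identically with
#' [apply_normalization()].
#'
#' @param expr genes x samples matrix (log2 scale).
#' @param ref_genes the three reference gene ids (default GPKOW, BMS1,
#'   ANKFY1).
#' @param outlier_quantiles lower/upper winsorization quantiles.
#' @return list with `expr` (normalized matrix) and `spec` (constants:
#'   `ref_genes`, `lo`, `hi`, `max` per gene).
#' @export
normalize_expression <- function(expr, ref_genes = c("GPKOW", "BMS1", "ANKFY1"),
                                 outlier_quantiles = c(0.005, 0.995)) {
  missing_ref <- setdiff(ref_genes, rownames(expr))
  fail_unless(length(missing_ref) == 0,
              "normalize_expression: reference gene(s) absent: %s",
              paste(missing_ref, collapse = ", "))
  ref_mean <- colMeans(expr[ref_genes, , drop = FALSE])
  x <- sweep(expr, 2, ref_mean)
  lo <- apply(x, 1, stats::quantile, probs = outlier_quantiles[1])
  hi <- apply(x, 1, stats::quantile, probs = outlier_quantiles[2])
  x <- pmax(pmin(x, hi), lo)
  ## reference centering leaves signed values, so the scale is the maximum
  ## magnitude (for all-positive data this is the plain maximum)
  mx <- apply(abs(x), 1, max)
  fail_unless(all(mx != 0), "normalize_expression: zero post-winsorization maximum for %s",
              paste(rownames(expr)[mx == 0], collapse = ", "))
  x <- x / mx
  spec <- list(ref_genes = ref_genes, lo = lo, hi = hi, max = mx,
               outlier_quantiles = outlier_quantiles)
  spec$hash <- norm_spec_hash(spec)
  attr(x, "circaskin_norm") <- spec$hash
  list(expr = x, spec = spec)
}

#' Apply a stored normalization spec to new samples
#'
#' Normalizes test samples with the training constants: per-sample
#' reference-gene centering, winsorization at the stored training bounds,
#' division by the stored training maxima. A matrix already normalized
#' under the same spec is returned unchanged, making the operation
#' idempotent given the stored spec.
#'
#' @param spec normalization spec from [normalize_expression()].
#' @param expr genes x samples matrix (a single sample may be a one-column
#'   matrix).
#' @return normalized matrix over the spec's genes.
#' @export
apply_normalization <- function(spec, expr) {
  if (identical(attr(expr, "circaskin_norm"), spec$hash)) return(expr)
  missing_ref <- setdiff(spec$ref_genes, rownames(expr))
  fail_unless(length(missing_ref) == 0,
              "apply_normalization: reference gene(s) absent: %s",
              paste(missing_ref, collapse = ", "))
  genes <- names(spec$max)
  missing <- setdiff(genes, rownames(expr))
  fail_unless(length(missing) == 0,
              "apply_normalization: gene(s) absent: %s",
              paste(missing, collapse = ", "))
  ref_mean <- colMeans(expr[spec$ref_genes, , drop = FALSE])
  x <- sweep(expr[genes, , drop = FALSE], 2, ref_mean)
  x <- pmax(pmin(x, spec$hi[genes]), spec$lo[genes])
  x <- x / spec$max[genes]
  attr(x, "circaskin_norm") <- spec$hash
  x
}

#' Select dynamic genes from an ordering-based cosinor scan
#'
#' Dynamic genes are those whose expression varies sufficiently over the
#' (CYCLOPS-ordered) cycle: cosinor R-squared strictly above the threshold.
#'
#' @param scan data.frame from [cosinor_scan()] run against ordered phases.
#' @param rsq_threshold R-squared cutoff (default 0.1, strict inequality).
#' @return character vector of gene ids.
#' @export
select_dynamic_genes <- function(scan, rsq_threshold = 0.1) {
  genes <- scan$gene_id[scan$rsq > rsq_threshold]
  fail_unless(length(genes) > 0,
              "select_dynamic_genes: no gene exceeds rsq > %g; lower the threshold",
              rsq_threshold)
  genes
}

## Soft-threshold x so that the normalized vector has L1 norm <= c
## (penalized matrix decomposition update; binary search on the threshold).
l1_constrained_unit <- function(x, c1) {
  soft <- function(v, l) sign(v) * pmax(abs(v) - l, 0)
  unitize <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) v else v / nv
  }
  u <- unitize(x)
  if (sum(abs(u)) <= c1 + 1e-12) return(u)
  lo <- 0
  hi <- max(abs(x))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    u <- unitize(soft(x, mid))
    if (sum(abs(u)) > c1) lo <- mid else hi <- mid
  }
  unitize(soft(x, hi))
}

## Rank-K penalized matrix decomposition of M (genes x T): u_k unit L2 with
## L1 <= sumabsv, v_k unit; deterministic init from the dense SVD.
## Deflation projects out the fitted time-course direction (R <- R(I-vv'))
## rather than subtracting the sparse rank-1 term: with a sparse u the
## subtractive residual keeps the dominant-axis variance of the unselected
## genes, and the second component then duplicates the first axis instead
## of finding the quadrature time-course that phase prediction needs.
spca_pmd <- function(M, K, sumabsv, max_iter = 200, tol = 1e-8) {
  U <- matrix(0, nrow(M), K, dimnames = list(rownames(M), NULL))
  V <- matrix(0, ncol(M), K)
  d <- numeric(K)
  R <- M
  for (k in seq_len(K)) {
    sv <- svd(R, nu = 1, nv = 1)
    v <- sv$v[, 1]
    u <- rep(0, nrow(R))
    for (it in seq_len(max_iter)) {
      u_new <- l1_constrained_unit(drop(R %*% v), sumabsv)
      rv <- drop(crossprod(R, u_new))
      nv <- sqrt(sum(rv^2))
      v_new <- if (nv == 0) v else rv / nv
      if (sum((u_new - u)^2) + sum((v_new - v)^2) < tol) {
        u <- u_new; v <- v_new
        break
      }
      u <- u_new; v <- v_new
    }
    d[k] <- drop(t(u) %*% R %*% v)
    U[, k] <- u
    V[, k] <- v
    R <- R - (R %*% v) %*% t(v)
  }
  list(u = U, v = V, d = d)
}

## Periodic (harmonic) least-squares fit of each gene against theta,
## evaluated on a T-point grid. Returns curves (genes x T).
periodic_curves <- function(expr, theta, grid, n_harmonics) {
  basis <- function(th) {
    cols <- lapply(seq_len(n_harmonics), function(k) cbind(cos(k * th), sin(k * th)))
    cbind(1, do.call(cbind, cols))
  }
  G <- basis(theta)
  B <- t(qr.solve(G, t(expr)))
  B %*% t(basis(grid))
}

## Linear circular interpolation of curve rows at angles theta.
interp_curves <- function(curves, grid, theta) {
  T_ <- length(grid)
  step <- 2 * pi / T_
  pos <- wrap_angle(theta) / step
  j0 <- floor(pos) %% T_ + 1
  j1 <- j0 %% T_ + 1
  w <- pos - floor(pos)
  curves[, j0, drop = FALSE] * rep(1 - w, each = nrow(curves)) +
    curves[, j1, drop = FALSE] * rep(w, each = nrow(curves))
}

#' Train the sparse periodic phase predictor
#'
#' For each gene a periodic harmonic smoother of normalized expression
#' against training phase is evaluated on a T-point grid and centred; the
#' gene-by-time curve matrix is decomposed into K = 2 sparse principal
#' components (penalized matrix decomposition with an L1 budget `sumabsv`
#' per component). Genes with any `|loading| > coef_cutoff` on the first
#' two SPCs form the biomarker set; the stored model is restricted to those
#' genes, so predictions depend on them alone. Per-SPC residual sds are
#' estimated from the training projections around the SPC time-courses.
#'
#' @param expr normalized genes x samples training matrix (use
#'   [normalize_expression()] first; candidate genes only, e.g. dynamic
#'   genes).
#' @param theta training phases in radians (from a registered ordering, 0 =
#'   anchor-gene peak), length `ncol(expr)`, covering the circle with no
#'   gap >= pi/2.
#' @param sumabsv L1 budget per sparse component (>= 1).
#' @param n_grid number of time-grid points (default 48).
#' @param n_harmonics harmonics in the periodic smoother (default 4).
#' @param K number of sparse components retained (default 2).
#' @param coef_cutoff absolute-loading cutoff for the biomarker set
#'   (default 0.05).
#' @param norm_spec optional normalization spec stored with the model.
#' @param min_samples minimum training samples (default 50).
#' @return object of class `"phase_model"`.
#' @export
train_phase_model <- function(expr, theta, sumabsv = 2, n_grid = 48,
                              n_harmonics = 4, K = 2, coef_cutoff = 0.05,
                              norm_spec = NULL, min_samples = 50) {
  fail_unless(ncol(expr) == length(theta),
              "train_phase_model: %d samples vs %d phases", ncol(expr),
              length(theta))
  fail_unless(ncol(expr) >= min_samples,
              "train_phase_model: need >= %d training samples, got %d",
              min_samples, ncol(expr))
  fail_unless(sumabsv >= 1, "train_phase_model: sumabsv must be >= 1")
  th <- sort(wrap_angle(theta))
  gaps <- diff(c(th, th[1] + 2 * pi))
  fail_unless(max(gaps) < pi / 2,
              "train_phase_model: phase coverage gap %.2f rad >= pi/2", max(gaps))
  grid <- 2 * pi * (seq_len(n_grid) - 1) / n_grid
  curves <- periodic_curves(expr, wrap_angle(theta), grid, n_harmonics)
  center <- rowMeans(curves)
  curves_c <- curves - center
  pmd <- spca_pmd(curves_c, K = K, sumabsv = sumabsv)
  selected <- rownames(expr)[rowSums(abs(pmd$u) > coef_cutoff) > 0]
  fail_unless(length(selected) > 0,
              "train_phase_model: no gene passes |loading| > %g", coef_cutoff)
  U <- pmd$u[selected, , drop = FALSE]
  spc_curves <- t(U) %*% curves_c[selected, , drop = FALSE]   # K x T
  proj <- t(U) %*% (expr[selected, , drop = FALSE] - center[selected])
  fitted_at_theta <- interp_curves(spc_curves, grid, theta)
  resid_sd <- sqrt(rowMeans((proj - fitted_at_theta)^2))
  resid_sd <- pmax(resid_sd, 1e-6)
  structure(list(gene_ids = selected, time_grid = grid,
                 fitted_curves = curves_c[selected, , drop = FALSE],
                 center = center[selected],
                 spc_coefs = U, spc_curves = spc_curves,
                 spc_resid_sd = resid_sd, sumabsv = sumabsv,
                 n_harmonics = n_harmonics, coef_cutoff = coef_cutoff,
                 norm_spec = norm_spec, n_train = ncol(expr)),
            class = "phase_model")
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf(
    "Sparse periodic phase model\n  %d biomarker genes (|loading| > %g), %d SPCs, sumabsv %g\n  trained on %d samples, %d-point time grid\n  genes: %s\n",
    length(x$gene_ids), x$coef_cutoff, ncol(x$spc_coefs), x$sumabsv,
    x$n_train, length(x$time_grid),
    paste(x$gene_ids, collapse = ", ")))
  invisible(x)
}

#' @export
coef.phase_model <- function(object, ...) object$spc_coefs

#' Predict circadian phase for single samples
#'
#' Projects each (normalized) sample onto the sparse component loadings and
#' maximizes the Gaussian log-likelihood of the projections around the SPC
#' time-courses over the phase grid, with local quadratic refinement.
#' Phases are reported in `[0, 2 pi)` on the training registration (0 = the
#' anchor gene's peak). Information-free samples (constant across the model
#' genes) yield a flat profile and `mle_ok = FALSE`.
#'
#' @param object a `"phase_model"`.
#' @param newdata genes x samples matrix (or a named vector for one
#'   sample). Normalized with the model's stored spec automatically when
#'   one is attached and the data are not already normalized.
#' @param return_profile attach the log-likelihood profiles as an
#'   attribute.
#' @param ... unused.
#' @return data.frame: `sample_id`, `theta_hat`, `theta_hours`, `mle_ok`.
#' @export
predict.phase_model <- function(object, newdata, return_profile = FALSE, ...) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(names(newdata), "sample1"))
  raw <- newdata
  if (!is.null(object$norm_spec))
    newdata <- apply_normalization(object$norm_spec, newdata)
  missing <- setdiff(object$gene_ids, rownames(newdata))
  fail_unless(length(missing) == 0,
              "predict.phase_model: model gene(s) absent: %s",
              paste(missing, collapse = ", "))
  X <- newdata[object$gene_ids, , drop = FALSE]
  proj <- t(object$spc_coefs) %*% (X - object$center)      # K x n
  K <- nrow(proj)
  grid <- object$time_grid
  T_ <- length(grid)
  n <- ncol(proj)
  ## loglik over grid: n x T
  ll <- matrix(0, n, T_)
  for (k in seq_len(K)) {
    ll <- ll + outer(proj[k, ], object$spc_curves[k, ], function(p, m)
      stats::dnorm(p, m, object$spc_resid_sd[k], log = TRUE))
  }
  j <- max.col(ll, ties.method = "first")
  jm <- ifelse(j == 1, T_, j - 1)
  jp <- ifelse(j == T_, 1, j + 1)
  idx <- seq_len(n)
  l0 <- ll[cbind(idx, j)]
  lm_ <- ll[cbind(idx, jm)]
  lp <- ll[cbind(idx, jp)]
  denom <- lm_ - 2 * l0 + lp
  delta <- ifelse(denom < -1e-12, 0.5 * (lm_ - lp) / denom, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  theta_hat <- wrap_angle(grid[j] + delta * (2 * pi / T_))
  raw_const <- if (all(object$gene_ids %in% rownames(raw))) {
    apply(raw[object$gene_ids, , drop = FALSE], 2,
          function(col) stats::sd(col) == 0)
  } else rep(FALSE, ncol(X))
  const <- raw_const | apply(X, 2, function(col) stats::sd(col) == 0)
  flat <- (apply(ll, 1, max) - apply(ll, 1, min)) < 1e-8
  mle_ok <- !(const | flat)
  theta_hat[const] <- 0
  if (any(const)) ll[const, ] <- 0
  out <- data.frame(sample_id = colnames(X), theta_hat = theta_hat,
                    theta_hours = rad_to_hours(theta_hat), mle_ok = mle_ok,
                    stringsAsFactors = FALSE)
  if (return_profile) attr(out, "loglik_profile") <- ll
  out
}

## JSON (de)serialization of a phase model, for pipeline artifacts.
phase_model_to_json <- function(model, path) {
  obj <- unclass(model)
  obj$spc_coefs <- list(genes = rownames(model$spc_coefs),
                        values = unname(model$spc_coefs))
  obj$fitted_curves <- list(genes = rownames(model$fitted_curves),
                            values = unname(model$fitted_curves))
  if (!is.null(obj$norm_spec)) {
    ## keep gene names: named atomic vectors drop names in JSON arrays
    for (f in c("lo", "hi", "max"))
      obj$norm_spec[[f]] <- as.list(obj$norm_spec[[f]])
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

phase_model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(x) {
    m <- as.matrix(x$values)
    rownames(m) <- x$genes
    m
  }
  obj$spc_coefs <- rebuild(obj$spc_coefs)
  obj$fitted_curves <- rebuild(obj$fitted_curves)
  obj$spc_curves <- as.matrix(obj$spc_curves)
  obj$center <- stats::setNames(as.numeric(obj$center), rownames(obj$fitted_curves))
  if (!is.null(obj$norm_spec)) {
    for (f in c("lo", "hi", "max"))
      obj$norm_spec[[f]] <- unlist(obj$norm_spec[[f]])
  }
  class(obj) <- "phase_model"
  obj
}
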