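## Circular ordering of unstamped samples: seed-gene eigengene reduction,
## a circular-bottleneck autoencoder fitted by alternating least squares,
## anchor-gene phase registration, and the dual quality criteria.

#' Reduce seed-gene expression to eigengenes
#'
#' Standardizes each seed gene (center, scale by sd across samples; genes
#' below a dispersion floor are dropped) and returns the principal-component
#' scores retaining a target fraction of variance, capped at a maximum
#' component count.
#'
#' @param expr genes x samples matrix.
#' @param seed_genes seed gene ids (>= 2 usable after filtering).
#' @param var_fraction variance fraction to retain (default 0.85).
#' @param max_components cap on the number of eigengenes (default 10).
#' @param dispersion_floor minimum per-gene sd (default 1e-8).
#' @return list with `scores` (eigengenes x samples), `sdev`,
#'   `var_explained`, `genes_used`, `rotation`.
#' @export
prepare_eigengenes <- function(expr, seed_genes, var_fraction = 0.85,
                               max_components = 10,
                               dispersion_floor = 1e-8) {
  present <- seed_genes[seed_genes %in% rownames(expr)]
  fail_unless(length(present) >= 2,
              "prepare_eigengenes: fewer than 2 seed genes present")
  X <- expr[present, , drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  X <- X[sds > dispersion_floor, , drop = FALSE]
  fail_unless(nrow(X) >= 2,
              "prepare_eigengenes: fewer than 2 seed genes above the dispersion floor")
  Xs <- (X - rowMeans(X)) / apply(X, 1, stats::sd)
  sv <- svd(Xs)
  var_exp <- sv$d^2 / sum(sv$d^2)
  k_max <- min(nrow(Xs), ncol(Xs) - 1)
  if (var_fraction >= 1) {
    k <- k_max
  } else {
    k <- which(cumsum(var_exp) >= var_fraction)[1]
    k <- min(max(k, 2), max_components, k_max)
  }
  scores <- diag(sv$d[seq_len(k)], k, k) %*% t(sv$v[, seq_len(k), drop = FALSE])
  dimnames(scores) <- list(sprintf("EG%02d", seq_len(k)), colnames(expr))
  list(scores = scores, sdev = sv$d[seq_len(k)],
       var_explained = var_exp[seq_len(k)],
       genes_used = rownames(Xs),
       rotation = sv$u[, seq_len(k), drop = FALSE])
}

## One alternating-least-squares fit of the circular autoencoder from a
## given initial angle assignment. X: K x n (eigengenes), theta0: n angles.
## Model: x_i ~ m + a cos(theta_i) + b sin(theta_i); the angle update is the
## exact encoder step (projection of each sample onto the fitted circle),
## done on a grid with parabolic refinement.
circular_als <- function(X, theta0, max_epochs, tol, grid_n = 720) {
  n <- ncol(X)
  theta <- theta0
  grid <- 2 * pi * (seq_len(grid_n) - 1) / grid_n
  cg <- cos(grid); sg <- sin(grid)
  loss_prev <- Inf
  loss <- Inf
  converged <- FALSE
  for (epoch in seq_len(max_epochs)) {
    G <- cbind(1, cos(theta), sin(theta))
    B <- tryCatch(t(qr.solve(G, t(X))), error = function(e) NULL)
    if (is.null(B)) break  # degenerate angle assignment
    P <- B %*% rbind(1, cg, sg)                     # K x grid_n
    cross <- crossprod(X, P)                        # n x grid_n
    pn <- colSums(P^2)
    cost <- -2 * cross + matrix(pn, n, grid_n, byrow = TRUE)
    j <- max.col(-cost, ties.method = "first")
    ## parabolic refinement on the circular grid
    jm <- ifelse(j == 1, grid_n, j - 1)
    jp <- ifelse(j == grid_n, 1, j + 1)
    idx <- seq_len(n)
    c0 <- cost[cbind(idx, j)]
    cm <- cost[cbind(idx, jm)]
    cp <- cost[cbind(idx, jp)]
    denom <- cm - 2 * c0 + cp
    delta <- ifelse(denom > 1e-12, 0.5 * (cm - cp) / denom, 0)
    delta <- pmax(pmin(delta, 0.5), -0.5)
    theta <- wrap_angle(grid[j] + delta * (2 * pi / grid_n))
    resid <- X - B %*% rbind(1, cos(theta), sin(theta))
    loss <- sum(resid^2)
    if (is.finite(loss_prev) &&
        abs(loss_prev - loss) <= tol * max(loss_prev, 1e-12)) {
      converged <- TRUE
      break
    }
    loss_prev <- loss
  }
  list(theta = theta, loss = loss, converged = converged, epochs = epoch)
}

#' Fit a circular ordering of samples (circular-bottleneck autoencoder)
#'
#' Each sample's eigengene profile is encoded to a point on the unit circle
#' and decoded back linearly; the total squared reconstruction error is
#' minimized by alternating least squares (exact decoder update, exact
#' per-sample circular projection on a fine grid with parabolic
#' refinement). The best of `n_restarts` deterministic random restarts is
#' kept; restart 1 is initialized from the first two eigengenes.
#'
#' @param eigengenes eigengene x sample matrix (>= 2 eigengenes), e.g.
#'   `prepare_eigengenes()$scores`.
#' @param n_restarts number of restarts (default 40).
#' @param max_epochs maximum ALS epochs per restart (default 5000).
#' @param tol relative loss-change convergence tolerance (default 1e-6).
#' @param seed RNG seed for the restart initializations.
#' @return object of class `"circular_ordering"`: `theta` (named phases in
#'   `[0, 2 pi)`), `reconstruction_error`, `n_restarts`,
#'   `best_restart`, `eigengene_count`, `converged`.
#' @export
fit_circular_ordering <- function(eigengenes, n_restarts = 40,
                                  max_epochs = 5000, tol = 1e-6, seed = 1) {
  X <- as.matrix(eigengenes)
  fail_unless(nrow(X) >= 2, "fit_circular_ordering: need >= 2 eigengenes")
  n <- ncol(X)
  best <- NULL
  best_restart <- NA_integer_
  for (r in seq_len(n_restarts)) {
    theta0 <- if (r == 1) {
      wrap_angle(atan2(X[2, ], X[1, ]))
    } else {
      with_seed(derive_seed(seed, paste0("restart", r)),
                stats::runif(n, 0, 2 * pi))
    }
    fit <- circular_als(X, theta0, max_epochs, tol)
    if (is.null(best) || fit$loss < best$loss) {
      best <- fit
      best_restart <- r
    }
  }
  fail_unless(!is.null(best) && is.finite(best$loss),
              "fit_circular_ordering: no restart converged; check the eigengenes")
  theta <- stats::setNames(best$theta, colnames(X))
  structure(list(theta = theta, reconstruction_error = best$loss,
                 n_restarts = n_restarts, best_restart = best_restart,
                 eigengene_count = nrow(X), converged = best$converged,
                 seed = seed),
            class = "circular_ordering")
}

#' @export
print.circular_ordering <- function(x, ...) {
  cat(sprintf(
    "Circular ordering of %d samples (%d eigengenes)\n  reconstruction error %.4g, best of %d restarts (#%d)%s\n",
    length(x$theta), x$eigengene_count, x$reconstruction_error,
    x$n_restarts, x$best_restart,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Register an ordering to an anchor gene's peak
#'
#' Rotates all phases so the anchor gene (ARNTL by default) peaks at phase
#' 0, the study's phase convention. If a direction reference is supplied
#' (known phases for a stamped subset of samples, in radians) and the
#' circular correlation with it is negative, the ordering is reflected
#' first. Registration is idempotent.
#'
#' @param ordering a `"circular_ordering"` object.
#' @param expr genes x samples matrix covering the ordered samples.
#' @param anchor_gene anchor gene id (default `"ARNTL"`); must be rhythmic
#'   against the ordering (cosinor p < `anchor_p`).
#' @param direction_ref optional named vector of reference phases (radians)
#'   for >= 3 ordered samples.
#' @param anchor_p rhythmicity cutoff for the anchor (default 0.01).
#' @return the ordering with rotated (and possibly reflected) `theta`.
#' @export
register_phase <- function(ordering, expr, anchor_gene = "ARNTL",
                           direction_ref = NULL, anchor_p = 0.01) {
  fail_unless(anchor_gene %in% rownames(expr),
              "register_phase: anchor gene %s absent", anchor_gene)
  theta <- ordering$theta
  ids <- names(theta)
  anchor_fit <- function(th) {
    fit_cosinor(rad_to_hours(th), expr[anchor_gene, ids])
  }
  reflected <- FALSE
  if (!is.null(direction_ref)) {
    common <- intersect(names(direction_ref), ids)
    fail_unless(length(common) >= 3,
                "register_phase: direction_ref covers < 3 ordered samples")
    if (circ_corr(theta[common], direction_ref[common]) < 0) {
      theta <- wrap_angle(-theta)
      reflected <- TRUE
    }
  }
  fit <- anchor_fit(theta)
  if (fit$pvalue >= anchor_p) {
    alt <- rownames(expr)[rownames(expr) %in% clock_gene_panel()$gene_id]
    stop(sprintf(
      "register_phase: anchor %s not rhythmic in the ordering (p = %.3g); try another clock gene (available: %s)",
      anchor_gene, fit$pvalue, paste(setdiff(alt, anchor_gene), collapse = ", ")),
      call. = FALSE)
  }
  theta <- wrap_angle(theta - hours_to_rad(fit$peak_phase_h))
  ordering$theta <- theta
  ordering$anchor_gene <- anchor_gene
  ordering$reflected <- isTRUE(ordering$reflected) != reflected
  ordering
}

#' Score an ordering by the two circular-correlation quality criteria
#'
#' Quality criterion 1 (`time_corr`): circular correlation between ordered
#' phases and known collection times over the stamped samples (needs >= 8;
#' otherwise `NA`). Criterion 2 (`clock_corr`): clock genes are fit by
#' cosinor against the ordering, filtered by the cutoff (p < 0.01,
#' fitmean > 16, rAMP > 0.1, rsq > 0.1), and the passing genes' fitted peak
#' phases are circularly correlated with their reference phases; with fewer
#' than 8 passing clock genes the value is set to 0.
#'
#' @param ordering a `"circular_ordering"` object.
#' @param meta sample metadata (for stamped collection times).
#' @param expr genes x samples matrix.
#' @param reference_clock_phases named vector of reference clock peak
#'   phases in hours (e.g. from the panel or [clock_gene_panel()]).
#' @param cutoffs named list: `p`, `fitmean`, `rAMP`, `rsq`.
#' @param min_clock_passing minimum passing clock genes (default 8).
#' @return list of class `"ordering_quality"`: `time_corr`, `clock_corr`,
#'   `n_clock_passing`, `reconstruction_error`.
#' @export
score_ordering <- function(ordering, meta, expr, reference_clock_phases,
                           cutoffs = list(p = 0.01, fitmean = 16,
                                          rAMP = 0.1, rsq = 0.1),
                           min_clock_passing = 8) {
  theta <- ordering$theta
  ids <- names(theta)
  m <- meta[match(ids, meta$sample_id), ]
  stamped <- which(is.finite(m$collection_time_h))
  time_corr <- NA_real_
  if (length(stamped) >= 8) {
    time_corr <- circ_corr(theta[stamped],
                           hours_to_rad(m$collection_time_h[stamped]))
  }
  clock <- intersect(names(reference_clock_phases), rownames(expr))
  fits <- cosinor_scan(expr[clock, ids, drop = FALSE], rad_to_hours(theta),
                       add_q = FALSE)
  pass <- fits$pvalue < cutoffs$p & fits$fitmean > cutoffs$fitmean &
    !is.na(fits$rAMP) & fits$rAMP > cutoffs$rAMP & fits$rsq > cutoffs$rsq
  n_pass <- sum(pass)
  clock_corr_val <- 0
  if (n_pass >= min_clock_passing) {
    g <- fits$gene_id[pass]
    clock_corr_val <- circ_corr(hours_to_rad(fits$peak_phase_h[pass]),
                                hours_to_rad(reference_clock_phases[g]))
  }
  structure(list(time_corr = time_corr, clock_corr = clock_corr_val,
                 n_clock_passing = n_pass,
                 reconstruction_error = ordering$reconstruction_error),
            class = "ordering_quality")
}

#' @export
print.ordering_quality <- function(x, ...) {
  cat(sprintf(
    "Ordering quality\n  time correlation %.3f\n  clock-phase correlation %.3f (%d clock genes passing)\n  reconstruction error %.4g\n",
    x$time_corr, x$clock_corr, x$n_clock_passing, x$reconstruction_error))
  invisible(x)
}
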