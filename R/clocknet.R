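## Clock-strength scoring: Spearman correlation matrices over a clock-gene
## panel, permutation Mantel statistics against a reference matrix, and the
## oscillation-maximizing down-sampling selector.

#' Clock-gene correlation matrix for a sample group
#'
#' Pairwise Spearman correlation over samples for a fixed, ordered list of
#' clock genes. Missing genes are dropped with a warning; at least 8 must
#' remain.
#'
#' @param expr genes x samples matrix (>= `min_samples` samples).
#' @param gene_list ordered clock-gene ids.
#' @param method correlation method (default `"spearman"`).
#' @param min_genes minimum usable genes (default 8).
#' @param min_samples minimum samples (default 10).
#' @return symmetric correlation matrix in `gene_list` order.
#' @export
clock_corr <- function(expr, gene_list, method = "spearman", min_genes = 8,
                       min_samples = 10) {
  fail_unless(ncol(expr) >= min_samples,
              "clock_corr: %d samples < required %d", ncol(expr), min_samples)
  present <- gene_list[gene_list %in% rownames(expr)]
  if (length(present) < length(gene_list))
    warning(sprintf("clock_corr: dropping %d absent gene(s)",
                    length(gene_list) - length(present)))
  fail_unless(length(present) >= min_genes,
              "clock_corr: only %d clock genes available (< %d)",
              length(present), min_genes)
  stats::cor(t(expr[present, , drop = FALSE]), method = method)
}

mantel_stat <- function(a_lt, B, lt) sum(a_lt * B[lt])

## All permutations of 1..n (n small), as a matrix with one row per
## permutation. Used for the exhaustive Mantel mode.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutation Mantel statistic between two correlation matrices
#'
#' The statistic is the sum over the lower triangle of the entrywise product
#' of the two matrices. Permutations relabel rows and columns of `B`
#' jointly; `z` standardizes the observed statistic by the permutation mean
#' and sd, and the two-tailed p counts permutations at least as far from the
#' permutation mean as the observation. With `method = "exhaustive"` all
#' `n!` relabelings are enumerated (small panels only) and the p-value is
#' the exact proportion.
#'
#' @param A,B symmetric correlation matrices with matching dimnames (`B` is
#'   reordered to `A`'s gene order).
#' @param n_perm number of sampled permutations (>= 99).
#' @param seed RNG seed for the permutation draw.
#' @param method `"sampled"` (default) or `"exhaustive"`.
#' @return object of class `"mantel_result"`: `statistic`, `z`, `pvalue`,
#'   `n_perm`, `seed`, `method`. When the permutation sd is 0 the z is
#'   defined as 0 and p as 1.
#' @export
mantel_z <- function(A, B, n_perm = 999, seed = 1,
                     method = c("sampled", "exhaustive")) {
  method <- match.arg(method)
  fail_unless(!is.null(rownames(A)) && !is.null(rownames(B)),
              "mantel_z: matrices need gene dimnames")
  fail_unless(setequal(rownames(A), rownames(B)),
              "mantel_z: gene sets differ")
  B <- B[rownames(A), rownames(A)]
  n <- nrow(A)
  lt <- lower.tri(A)
  a_lt <- A[lt]
  obs <- mantel_stat(a_lt, B, lt)
  if (method == "exhaustive") {
    perms <- all_permutations(n)
    stats_perm <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      mantel_stat(a_lt, B[p, p], lt)
    }, 0)
    n_perm <- nrow(perms)
    m <- mean(stats_perm)
    s <- stats::sd(stats_perm)
    pv <- mean(abs(stats_perm - m) >= abs(obs - m) - 1e-12)
  } else {
    fail_unless(n_perm >= 99, "mantel_z: n_perm must be >= 99")
    stats_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      mantel_stat(a_lt, B[p, p], lt)
    }, 0))
    m <- mean(stats_perm)
    s <- stats::sd(stats_perm)
    pv <- (sum(abs(stats_perm - m) >= abs(obs - m) - 1e-12) + 1) / (n_perm + 1)
  }
  z <- if (!is.finite(s) || s < 1e-12) 0 else (obs - m) / s
  if (!is.finite(s) || s < 1e-12) pv <- 1
  structure(list(statistic = obs, z = z, pvalue = pv, n_perm = n_perm,
                 seed = seed, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test (%s, %d permutations)\n  statistic %.4g  Z %.3f  p %.4g\n",
    x$method, x$n_perm, x$statistic, x$z, x$pvalue))
  invisible(x)
}

#' Oscillation-maximizing down-sampling of a sample group
#'
#' Serially draws random subsets of a fixed fraction of the samples and
#' keeps the subset whose clock-gene correlation matrix has the highest
#' Mantel z against the benchmark, discarding samples that disrupt the
#' clock correlation structure before circular ordering.
#'
#' @param expr genes x samples matrix.
#' @param benchmark reference clock correlation matrix (its rownames define
#'   the clock panel).
#' @param keep_frac fraction of samples retained per draw, in (0, 1].
#' @param n_iter number of random subsets scored (>= 1).
#' @param n_perm permutations per Mantel z during the search.
#' @param seed RNG seed (each iteration's subset and permutations derive
#'   from it deterministically).
#' @return list with `sample_ids` (the winning subset), `mantel` (its
#'   [mantel_z()] result) and `z_full` (the all-sample z for reference).
#' @export
downsample_select <- function(expr, benchmark, keep_frac = 0.97,
                              n_iter = 10000, n_perm = 99, seed = 1) {
  fail_unless(keep_frac > 0 && keep_frac <= 1, "keep_frac must be in (0, 1]")
  fail_unless(n_iter >= 1, "n_iter must be >= 1")
  n <- ncol(expr)
  k <- round(keep_frac * n)
  fail_unless(k >= 10, "downsample_select: subset size %d < 10", k)
  genes <- rownames(benchmark)
  score <- function(ids, perm_seed) {
    cm <- suppressWarnings(clock_corr(expr[, ids, drop = FALSE], genes,
                                      min_samples = 10))
    mantel_z(benchmark, cm, n_perm = n_perm, seed = perm_seed)
  }
  full <- score(colnames(expr), derive_seed(seed, "full"))
  if (k == n)
    return(list(sample_ids = colnames(expr), mantel = full, z_full = full$z))
  subsets <- with_seed(seed, lapply(seq_len(n_iter),
                                    function(i) sort(sample.int(n, k))))
  best <- NULL
  best_z <- -Inf
  for (i in seq_len(n_iter)) {
    ids <- colnames(expr)[subsets[[i]]]
    m <- score(ids, derive_seed(seed, paste0("iter", i)))
    if (m$z > best_z) {
      best_z <- m$z
      best <- list(sample_ids = ids, mantel = m, z_full = full$z)
    }
  }
  best
}
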