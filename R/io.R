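## Reading, writing and assembling expression matrices and sample metadata.
## Matrices are plain numeric matrices (genes x samples, log2 scale by
## contract) with unique rownames/colnames; metadata is a data.frame.

META_COLS <- c("sample_id", "participant_id", "layer", "body_site",
               "collection_time_h", "cohort", "batch")

validate_expression <- function(expr, what = "expression matrix") {
  fail_unless(is.matrix(expr) && is.numeric(expr), "%s: not a numeric matrix", what)
  fail_unless(!is.null(rownames(expr)) && !is.null(colnames(expr)),
              "%s: gene and sample ids required as dimnames", what)
  dup_g <- rownames(expr)[duplicated(rownames(expr))]
  fail_unless(length(dup_g) == 0, "%s: duplicate gene ids: %s", what,
              paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(expr)[duplicated(colnames(expr))]
  fail_unless(length(dup_s) == 0, "%s: duplicate sample ids: %s", what,
              paste(unique(dup_s), collapse = ", "))
  fail_unless(all(is.finite(expr)), "%s: non-finite values present", what)
  invisible(expr)
}

validate_meta <- function(meta) {
  fail_unless(all(META_COLS %in% names(meta)),
              "metadata: missing columns: %s",
              paste(setdiff(META_COLS, names(meta)), collapse = ", "))
  fail_unless(!any(duplicated(meta$sample_id)), "metadata: duplicate sample ids")
  bad_layer <- setdiff(unique(meta$layer), c("epidermis", "dermis"))
  fail_unless(length(bad_layer) == 0, "metadata: unknown layer(s): %s",
              paste(bad_layer, collapse = ", "))
  long <- meta$cohort == "longitudinal"
  fail_unless(all(is.finite(meta$collection_time_h[long])),
              "metadata: longitudinal samples lack collection_time_h: %s",
              paste(meta$sample_id[long & !is.finite(meta$collection_time_h)],
                    collapse = ", "))
  fail_unless(all(is.na(meta$collection_time_h[!long])),
              "metadata: population samples must not carry collection times")
  invisible(meta)
}

#' Read an expression matrix and its sample metadata
#'
#' Expression files are tab-delimited with a `gene_id` first column and one
#' column per sample; metadata files carry `sample_id`, `participant_id`,
#' `layer`, `body_site`, `collection_time_h` (empty for unstamped samples),
#' `cohort`, `batch`. Every sample in the matrix must appear in the
#' metadata; both are validated and cross-referenced.
#'
#' @param matrix_path path to the expression TSV.
#' @param meta_path optional path to the metadata TSV.
#' @return list with `expr` (matrix) and `meta` (data.frame or NULL).
#' @export
read_expression <- function(matrix_path, meta_path = NULL) {
  d <- utils::read.delim(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  fail_unless(ncol(d) >= 2, "read_expression: %s has no sample columns",
              matrix_path)
  ids <- as.character(d[[1]])
  dup <- ids[duplicated(ids)]
  fail_unless(length(dup) == 0, "read_expression: duplicate gene ids: %s",
              paste(unique(dup), collapse = ", "))
  expr <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(expr) <- "double"
  rownames(expr) <- ids
  validate_expression(expr)
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- read_sample_meta(meta_path)
    missing <- setdiff(colnames(expr), meta$sample_id)
    fail_unless(length(missing) == 0,
                "read_expression: samples absent from metadata: %s",
                paste(missing, collapse = ", "))
    extra <- setdiff(meta$sample_id, colnames(expr))
    if (length(extra) > 0)
      message(sprintf("read_expression: %d metadata sample(s) not in matrix",
                      length(extra)))
  }
  list(expr = expr, meta = meta)
}

#' Write an expression matrix as TSV
#' @param expr genes x samples matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  d <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata TSV
#' @param path metadata path.
#' @return validated data.frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  meta$collection_time_h <- suppressWarnings(as.numeric(meta$collection_time_h))
  validate_meta(meta)
  meta
}

#' Write sample metadata as TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_sample_meta <- function(meta, path) {
  validate_meta(meta)
  utils::write.table(meta[, META_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a probe-to-gene map
#' @param path two-column TSV (`probe_id`, `gene_symbol`).
#' @return data.frame with those columns.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  fail_unless(ncol(pm) >= 2, "probe map needs two columns")
  names(pm)[1:2] <- c("probe_id", "gene_symbol")
  fail_unless(!any(duplicated(pm$probe_id)),
              "probe map: probes mapped more than once: %s",
              paste(unique(pm$probe_id[duplicated(pm$probe_id)]), collapse = ", "))
  pm[, 1:2]
}

#' Collapse probe-level rows to one representative row per gene
#'
#' For each gene the retained row is the probe with the largest median
#' absolute deviation across samples; ties go to the lexicographically
#' smallest probe id. Idempotent on gene-level matrices (a gene mapping to
#' itself collapses to itself).
#'
#' @param expr probes x samples matrix.
#' @param probe_map data.frame mapping `probe_id` to `gene_symbol`; every
#'   probe in `expr` must be mapped.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(expr, probe_map) {
  validate_expression(expr, "probe matrix")
  unmapped <- setdiff(rownames(expr), probe_map$probe_id)
  fail_unless(length(unmapped) == 0, "collapse_probes: unmapped probes: %s",
              paste(unmapped, collapse = ", "))
  gene <- probe_map$gene_symbol[match(rownames(expr), probe_map$probe_id)]
  mads <- apply(expr, 1, stats::mad)
  ## order by gene, then -MAD, then probe id: first row per gene wins
  ord <- order(gene, -mads, rownames(expr))
  pick <- ord[!duplicated(gene[ord])]
  out <- expr[pick, , drop = FALSE]
  rownames(out) <- gene[pick]
  out[order(rownames(out)), , drop = FALSE]
}

#' Column-concatenate longitudinal and population matrices
#'
#' Builds the hybrid design matrix. Gene universes are intersected with a
#' warning when unequal; disjoint universes are an error. Sample ids must
#' not collide.
#'
#' @param longitudinal,population genes x samples matrices.
#' @return combined matrix on the common gene set.
#' @export
assemble_hybrid <- function(longitudinal, population) {
  validate_expression(longitudinal, "longitudinal matrix")
  validate_expression(population, "population matrix")
  common <- intersect(rownames(longitudinal), rownames(population))
  fail_unless(length(common) > 0, "assemble_hybrid: empty gene intersection")
  if (length(common) < nrow(longitudinal) || length(common) < nrow(population))
    warning(sprintf("assemble_hybrid: gene universes differ; using %d common genes",
                    length(common)))
  clash <- intersect(colnames(longitudinal), colnames(population))
  fail_unless(length(clash) == 0, "assemble_hybrid: sample ids collide: %s",
              paste(clash, collapse = ", "))
  cbind(longitudinal[common, , drop = FALSE], population[common, , drop = FALSE])
}
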