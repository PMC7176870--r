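#' Construct a paired two-condition expression dataset
#'
#' Bundles a log2 expression matrix (genes x samples) with gene annotation
#' (biotype: protein-coding gene or lncRNA) and paired sample metadata, and
#' validates the pairing invariants every downstream stage relies on: unique
#' ids, every pair having exactly one normal and one tumour sample, and at
#' least 4 pairs (the Fisher-z variance 1/(n-3) needs n > 3).
#'
#' @param exprs Numeric matrix of log2 expression, rows named by `gene_id`,
#'   columns named by `sample_id`. No missing values.
#' @param genes Data frame with columns `gene_id` and `biotype`
#'   (`"PCG"` or `"lncRNA"`), one row per expression row.
#' @param samples Data frame with columns `sample_id`, `pair_id` and
#'   `condition` (`"normal"` or `"tumour"`), one row per expression column.
#'
#' @return An object of class `expr_dataset`: a list with elements `exprs`,
#'   `genes` (tibble) and `samples` (tibble), columns of `exprs` ordered as
#'   in `samples`.
#' @export
expr_dataset <- function(exprs, genes, samples) {
  genes <- as_tibble(genes)
  samples <- as_tibble(samples)
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    abort("`exprs` must be a numeric matrix.")
  }
  if (anyNA(exprs)) abort("Expression matrix contains missing values.")
  if (is.null(rownames(exprs)) || is.null(colnames(exprs))) {
    abort("`exprs` must carry gene_id rownames and sample_id colnames.")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf(
      "Duplicate gene ids: %s",
      paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort(sprintf(
      "Duplicate sample ids: %s",
      paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", ")
    ))
  }
  if (!all(genes$biotype %in% c("PCG", "lncRNA"))) {
    abort("`biotype` must be 'PCG' or 'lncRNA'.")
  }
  if (!all(samples$condition %in% c("normal", "tumour"))) {
    abort("`condition` must be 'normal' or 'tumour'.")
  }
  missing_ann <- setdiff(rownames(exprs), genes$gene_id)
  if (length(missing_ann)) {
    abort(sprintf(
      "Genes in expression but not in annotation: %s",
      paste(head(missing_ann, 10), collapse = ", ")
    ))
  }
  missing_meta <- setdiff(colnames(exprs), samples$sample_id)
  if (length(missing_meta)) {
    abort(sprintf(
      "Samples in expression but not in metadata: %s",
      paste(head(missing_meta, 10), collapse = ", ")
    ))
  }
  genes <- genes[match(rownames(exprs), genes$gene_id), , drop = FALSE]
  samples <- samples[match(colnames(exprs), samples$sample_id), , drop = FALSE]

  by_pair <- split(samples$condition, samples$pair_id)
  bad <- names(by_pair)[!vapply(
    by_pair,
    function(x) length(x) == 2L && setequal(x, c("normal", "tumour")),
    logical(1)
  )]
  if (length(bad)) {
    abort(sprintf(
      "Pairs without exactly one normal and one tumour sample: %s",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  if (length(by_pair) < 4L) {
    abort("At least 4 sample pairs are required (correlation variance 1/(n-3)).")
  }
  structure(
    list(exprs = exprs, genes = genes, samples = samples),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> %d genes (%d PCG, %d lncRNA) x %d samples (%d pairs)\n",
    nrow(x$exprs), sum(x$genes$biotype == "PCG"),
    sum(x$genes$biotype == "lncRNA"),
    ncol(x$exprs), length(unique(x$samples$pair_id))
  ))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$exprs)

#' Tidy an expression dataset into long format
#'
#' @param x An `expr_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per gene/sample measurement, carrying
#'   biotype, pair and condition columns.
#' @export
tidy.expr_dataset <- function(x, ...) {
  long <- as_tibble(x$exprs, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "log2_expr")
  long %>%
    left_join(x$genes, by = "gene_id") %>%
    left_join(x$samples, by = "sample_id")
}

#' @export
glance.expr_dataset <- function(x, ...) {
  tibble(
    n_genes = nrow(x$exprs),
    n_pcg = sum(x$genes$biotype == "PCG"),
    n_lncrna = sum(x$genes$biotype == "lncRNA"),
    n_samples = ncol(x$exprs),
    n_pairs = length(unique(x$samples$pair_id))
  )
}

# Expression submatrix for one condition, columns ordered by pair_id so the
# k-th normal column and the k-th tumour column always belong to one pair.
condition_matrix <- function(ds, condition) {
  meta <- ds$samples[ds$samples$condition == condition, , drop = FALSE]
  meta <- meta[order(meta$pair_id), , drop = FALSE]
  ds$exprs[, meta$sample_id, drop = FALSE]
}

#' Load an expression dataset from delimited text files
#'
#' Reads the standard three-file layout: an expression table (first column
#' `gene_id`, remaining columns one per sample), a two-column annotation table
#' (`gene_id`, `biotype`) and a three-column sample metadata table
#' (`sample_id`, `pair_id`, `condition`). Tab- and comma-delimited files are
#' both accepted (delimiter is sniffed per file).
#'
#' Samples whose pair is incomplete (e.g. a tumour sample without its normal
#' partner) are dropped with a message; genes missing from the annotation are
#' an error naming the offenders.
#'
#' @param expression_path,annotation_path,metadata_path File paths.
#' @return A validated [expr_dataset()]. Dropped samples, if any, are
#'   recorded in the `dropped_samples` attribute.
#' @export
load_dataset <- function(expression_path, annotation_path, metadata_path) {
  for (p in c(expression_path, annotation_path, metadata_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  read_any <- function(path) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE, comment = "#")
  }
  expr_tbl <- read_any(expression_path)
  ann <- read_any(annotation_path)
  meta <- read_any(metadata_path)
  names(expr_tbl)[1] <- "gene_id"
  if (!all(c("gene_id", "biotype") %in% names(ann))) {
    abort("Annotation needs columns gene_id, biotype.")
  }
  if (!all(c("sample_id", "pair_id", "condition") %in% names(meta))) {
    abort("Metadata needs columns sample_id, pair_id, condition.")
  }
  exprs <- as.matrix(expr_tbl[, -1, drop = FALSE])
  rownames(exprs) <- expr_tbl$gene_id
  storage.mode(exprs) <- "double"

  meta <- meta[meta$sample_id %in% colnames(exprs), , drop = FALSE]
  counts <- meta %>%
    group_by(.data$pair_id) %>%
    summarise(
      ok = n() == 2L && setequal(.data$condition, c("normal", "tumour")),
      .groups = "drop"
    )
  bad_pairs <- counts$pair_id[!counts$ok]
  dropped <- meta$sample_id[meta$pair_id %in% bad_pairs]
  if (length(dropped)) {
    inform(sprintf(
      "Dropping %d sample(s) without a complete normal/tumour pair: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
    meta <- meta[!meta$pair_id %in% bad_pairs, , drop = FALSE]
  }
  exprs <- exprs[, meta$sample_id, drop = FALSE]
  ds <- expr_dataset(exprs, ann, meta)
  attr(ds, "dropped_samples") <- dropped
  ds
}

#' Remove invariantly expressed genes
#'
#' Filters genes whose coefficient of variation (sample sd / mean, computed
#' over all samples of both conditions pooled) falls below a threshold.
#' Genes with mean 0, where the CV is undefined, are removed as well.
#'
#' @param ds An [expr_dataset()].
#' @param cv_threshold Non-negative CV cutoff; genes with CV strictly below
#'   it are dropped. Default 0.05.
#' @return The filtered `expr_dataset`, gene order preserved. Removed gene
#'   ids are recorded in the `removed_genes` attribute.
#' @export
filter_low_variance <- function(ds, cv_threshold = 0.05) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!is_scalar_number(cv_threshold) || cv_threshold < 0) {
    abort("`cv_threshold` must be a non-negative number.")
  }
  m <- rowMeans(ds$exprs)
  s <- apply(ds$exprs, 1L, sd)
  cv <- s / m
  undefined <- m == 0
  keep <- !undefined & cv >= cv_threshold
  removed <- rownames(ds$exprs)[!keep]
  if (any(undefined)) {
    inform(sprintf(
      "%d gene(s) with mean 0 (undefined CV) removed.", sum(undefined)
    ))
  }
  out <- expr_dataset(
    ds$exprs[keep, , drop = FALSE],
    ds$genes[keep, , drop = FALSE],
    ds$samples
  )
  attr(out, "removed_genes") <- removed
  out
}

#' Call differentially expressed genes between tumour and normal samples
#'
#' Runs a paired two-tailed t-test per gene on the tumour minus normal log2
#' differences, BH-adjusts the p-values across all testable genes, and calls
#' status by the joint rule: `up` if adjusted p < 0.05 and fold change > 2,
#' `down` if adjusted p < 0.05 and fold change < 0.5, otherwise `ns`. The
#' fold change is `2^(mean log2 tumour - mean log2 normal)`.
#'
#' Genes whose paired differences have zero variance but nonzero mean carry
#' no finite t-statistic; they are flagged `degenerate`, excluded from the
#' BH correction and reported as `ns`.
#'
#' @param ds An [expr_dataset()].
#' @return A tibble with columns `gene_id`, `biotype`, `t_statistic`,
#'   `p_raw`, `p_adj`, `fold_change`, `status`, `degenerate`.
#' @export
call_differential_expression <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  tum <- condition_matrix(ds, "tumour")
  nor <- condition_matrix(ds, "normal")
  k <- ncol(tum)
  d <- tum - nor
  dbar <- rowMeans(d)
  dsd <- apply(d, 1L, sd)
  tstat <- ifelse(dsd == 0 & dbar == 0, 0, dbar / (dsd / sqrt(k)))
  degenerate <- dsd == 0 & dbar != 0
  tstat[degenerate] <- NA_real_
  p_raw <- ifelse(is.na(tstat), NA_real_, 2 * pt(-abs(tstat), df = k - 1))
  p_raw[dsd == 0 & dbar == 0] <- 1
  p_adj <- rep(NA_real_, length(p_raw))
  testable <- !is.na(p_raw)
  p_adj[testable] <- p.adjust(p_raw[testable], method = "BH")
  fc <- 2^(rowMeans(tum) - rowMeans(nor))
  status <- rep("ns", nrow(ds$exprs))
  status[!degenerate & p_adj < 0.05 & fc > 2] <- "up"
  status[!degenerate & p_adj < 0.05 & fc < 0.5] <- "down"
  if (any(degenerate)) {
    inform(sprintf(
      "%d gene(s) with zero-variance paired differences excluded from DE calls.",
      sum(degenerate)
    ))
  }
  tibble(
    gene_id = rownames(ds$exprs),
    biotype = ds$genes$biotype,
    t_statistic = unname(tstat),
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    fold_change = unname(fc),
    status = unname(status),
    degenerate = unname(degenerate)
  )
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline with the defaults used
#' throughout: adjusted-p thresholds of 1e-7 for both co-expression networks
#' and the z-test, greedy-search parameters d_max = 2, improvement rate 0.1,
#' alpha = 0.7, and 100 permutations for the significance tests.
#'
#' @param t_n,t_t,t_z BH-adjusted p-value thresholds in (0, 1) for the normal
#'   network, tumour network and the correlation-difference z-test.
#' @param d_max Positive integer: maximum hop distance from the seed.
#' @param improvement_rate Positive relative score gain required to accept a
#'   node addition.
#' @param alpha Weight in \[0, 1\] on the differential-expression part of the
#'   subnetwork score.
#' @param n_permutations Number of permutations / random subnetworks for the
#'   significance tests.
#' @param rng_seed Integer seed driving all randomized steps.
#' @param bh_universe `"union_edges"` (z-test p-values BH-corrected over the
#'   pairs that are edges in NCN or TCN, the only pairs eligible for the DCN)
#'   or `"all_pairs"`.
#' @param improvement_mode `"relative"` or `"absolute"` score improvement.
#' @param p1_scheme `"paired"` (within-pair label swaps) or `"free"`
#'   (unrestricted label shuffle) for the label-permutation test.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(t_n = 1e-7, t_t = 1e-7, t_z = 1e-7,
                            d_max = 2L, improvement_rate = 0.1, alpha = 0.7,
                            n_permutations = 100L, rng_seed = 1L,
                            bh_universe = c("union_edges", "all_pairs"),
                            improvement_mode = c("relative", "absolute"),
                            p1_scheme = c("paired", "free")) {
  for (nm in c("t_n", "t_t", "t_z")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0 || v >= 1) {
      abort(sprintf("`%s` must lie strictly in (0, 1).", nm))
    }
  }
  if (!is_scalar_number(d_max) || d_max < 1) abort("`d_max` must be >= 1.")
  if (!is_scalar_number(improvement_rate) || improvement_rate <= 0) {
    abort("`improvement_rate` must be positive.")
  }
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].")
  }
  if (!is_scalar_number(n_permutations) || n_permutations < 1) {
    abort("`n_permutations` must be a positive integer.")
  }
  structure(
    list(
      t_n = t_n, t_t = t_t, t_z = t_z,
      d_max = as.integer(d_max), improvement_rate = improvement_rate,
      alpha = alpha, n_permutations = as.integer(n_permutations),
      rng_seed = as.integer(rng_seed),
      bh_universe = match.arg(bh_universe),
      improvement_mode = match.arg(improvement_mode),
      p1_scheme = match.arg(p1_scheme)
    ),
    class = "analysis_config"
  )
}
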