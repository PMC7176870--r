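#' Specify a planted differentially co-expressed module
#'
#' Describes one block of genes to plant in a synthetic cohort: within the
#' block, expression follows a compound-symmetry correlation `rho_normal` in
#' normal samples and `rho_tumour` in tumour samples, with an optional log2
#' mean shift added in tumour (differential expression). The first gene is
#' the module hub and is assigned the lncRNA biotype; the rest are
#' protein-coding.
#'
#' @param gene_ids Character vector of member gene ids (hub first).
#' @param rho_normal,rho_tumour Within-module correlations in (-1, 1); each
#'   must exceed `-1/(m - 1)` for a module of size m (positive definiteness
#'   of the compound-symmetry matrix).
#' @param de_shift Log2 mean shift added to tumour samples (default 0).
#' @param noise_sd Marginal standard deviation (default 1).
#' @return A list of class `planted_module_spec`.
#' @export
planted_module_spec <- function(gene_ids, rho_normal, rho_tumour,
                                de_shift = 0, noise_sd = 1) {
  m <- length(gene_ids)
  stopifnot(m >= 1L, noise_sd > 0)
  for (rho in c(rho_normal, rho_tumour)) {
    if (abs(rho) >= 1 || (m > 1L && rho <= -1 / (m - 1))) {
      abort(sprintf(
        "Correlation %.3f is not positive definite for a module of %d genes.",
        rho, m
      ))
    }
  }
  structure(
    list(gene_ids = gene_ids, rho_normal = rho_normal,
         rho_tumour = rho_tumour, de_shift = de_shift, noise_sd = noise_sd),
    class = "planted_module_spec"
  )
}

cs_sigma <- function(m, rho, sd) {
  s <- matrix(rho, m, m)
  diag(s) <- 1
  s * sd^2
}

#' Generate a paired two-condition synthetic cohort
#'
#' Emulates a paired normal/tumour expression study on the log2 scale:
#' planted modules are drawn from multivariate normals with per-condition
#' compound-symmetry correlation (strongly co-expressed in one condition,
#' decorrelated in the other, optionally mean-shifted in tumour), against a
#' background of independent-noise genes. Per-gene baseline means are drawn
#' once (N(8, 2), a typical quantile-normalized log2 microarray range) and
#' shared between conditions, so only the planted shifts are differentially
#' expressed. Regeneration from the same seed is bit-identical.
#'
#' @param specs List of [planted_module_spec()] objects (may be empty).
#' @param n_background_genes Number of independent background genes.
#' @param n_pairs Number of sample pairs (> 3).
#' @param seed Integer RNG seed.
#' @param background_lncrna_prop Fraction of background genes labelled
#'   lncRNA (default 0.2), so seeds exist outside planted modules too.
#' @return A list: `dataset` (an [expr_dataset()]) and `truth` (module
#'   specs, background gene ids, seed, n_pairs).
#' @export
generate_cohort <- function(specs, n_background_genes, n_pairs, seed,
                            background_lncrna_prop = 0.2) {
  if (n_pairs <= 3L) abort("`n_pairs` must exceed 3.")
  specs <- purrr::map(specs, function(s) {
    if (inherits(s, "planted_module_spec")) s else do.call(planted_module_spec, s)
  })
  mod_genes <- unlist(purrr::map(specs, "gene_ids"))
  if (anyDuplicated(mod_genes)) abort("Module gene sets must be disjoint.")
  bg_genes <- sprintf("BG%04d", seq_len(n_background_genes))
  if (any(bg_genes %in% mod_genes)) abort("Background ids collide with module ids.")
  set.seed(seed)
  all_genes <- c(mod_genes, bg_genes)
  base_mean <- stats::rnorm(length(all_genes), mean = 8, sd = 2)
  names(base_mean) <- all_genes

  sample_block <- function(condition) {
    blocks <- purrr::map(specs, function(s) {
      m <- length(s$gene_ids)
      rho <- if (condition == "normal") s$rho_normal else s$rho_tumour
      shift <- if (condition == "tumour") s$de_shift else 0
      x <- if (m == 1L) {
        matrix(stats::rnorm(n_pairs, sd = s$noise_sd), ncol = 1L)
      } else {
        mvrnorm(n_pairs, mu = rep(0, m), Sigma = cs_sigma(m, rho, s$noise_sd))
      }
      t(x) + base_mean[s$gene_ids] + shift
    })
    bg <- matrix(stats::rnorm(n_background_genes * n_pairs),
                 nrow = n_background_genes) + base_mean[bg_genes]
    out <- do.call(rbind, c(blocks, list(bg)))
    rownames(out) <- all_genes
    out
  }
  nor <- sample_block("normal")
  tum <- sample_block("tumour")
  pair_ids <- sprintf("P%03d", seq_len(n_pairs))
  colnames(nor) <- paste0(pair_ids, "_N")
  colnames(tum) <- paste0(pair_ids, "_T")

  hub_ids <- purrr::map_chr(specs, ~ .x$gene_ids[1L])
  n_bg_lnc <- round(background_lncrna_prop * n_background_genes)
  bg_biotype <- rep("PCG", n_background_genes)
  if (n_bg_lnc > 0) bg_biotype[seq_len(n_bg_lnc)] <- "lncRNA"
  genes <- tibble(
    gene_id = all_genes,
    biotype = c(
      ifelse(mod_genes %in% hub_ids, "lncRNA", "PCG"),
      bg_biotype
    )
  )
  samples <- tibble(
    sample_id = c(colnames(nor), colnames(tum)),
    pair_id = rep(pair_ids, 2L),
    condition = rep(c("normal", "tumour"), each = n_pairs)
  )
  ds <- expr_dataset(cbind(nor, tum), genes, samples)
  truth <- list(
    specs = specs,
    module_genes = purrr::map(specs, "gene_ids"),
    background_genes = bg_genes,
    seed = seed,
    n_pairs = n_pairs
  )
  list(dataset = ds, truth = truth)
}

#' Sample the null distribution of the delta-z statistic
#'
#' Simulates gene pairs whose true correlation is identical in both
#' conditions (the null of the difference-of-correlations test), computes
#' each pair's sample correlations in the two groups and the delta-z
#' statistic. Under the null delta-z is approximately standard normal, which
#' the calibration tests check.
#'
#' @param n_gene_pairs Number of independent pairs to simulate.
#' @param rho Common true correlation of each pair in both groups.
#' @param n_per_group Samples per group (> 3).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `delta_z` and `p_raw`.
#' @export
generate_null_delta_z <- function(n_gene_pairs, rho, n_per_group, seed) {
  if (n_per_group <= 3L) abort("`n_per_group` must exceed 3.")
  if (abs(rho) >= 1) abort("`rho` must lie in (-1, 1).")
  set.seed(seed)
  sample_group_r <- function() {
    x <- matrix(stats::rnorm(n_gene_pairs * n_per_group), nrow = n_gene_pairs)
    y <- rho * x + sqrt(1 - rho^2) *
      matrix(stats::rnorm(n_gene_pairs * n_per_group), nrow = n_gene_pairs)
    rowwise_cor(x, y)
  }
  r_n <- sample_group_r()
  r_t <- sample_group_r()
  delta_z(r_n, r_t, n_per_group, n_per_group)
}
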