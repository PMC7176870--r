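# End-to-end orchestration behind the command-line entry point: every step is
# an exported package function; this file only sequences them and writes
# artifacts with provenance.

#' Default pipeline configuration
#'
#' @return A nested list mirroring the YAML config layout: `data` (paths to
#'   the expression/annotation/metadata TSVs) or `simulate` (synthetic-cohort
#'   parameters), `cv_threshold`, `analysis` ([analysis_config()] fields),
#'   `search` (`seed_biotype`), `core` (`min_genes`, `min_capture`) and
#'   `activity_method`.
#' @export
default_pipeline_config <- function() {
  list(
    data = list(expression = NULL, annotation = NULL, metadata = NULL),
    simulate = NULL,
    cv_threshold = 0.05,
    analysis = list(),
    search = list(seed_biotype = "lncRNA"),
    core = list(min_genes = 4L, min_capture = 3L),
    activity_method = "mean"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown analysis fields are rejected by [analysis_config()] at run time;
#' missing fields fall back to the defaults.
#'
#' @param path YAML file.
#' @return The merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config not found: %s", path))
  user <- yaml::read_yaml(path)
  modifyList(default_pipeline_config(), user)
}

write_tsv_with_header <- function(df, path, meta) {
  hdr <- sprintf("# %s=%s", names(meta), unlist(lapply(meta, format)))
  writeLines(hdr, path)
  suppressMessages(readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Run the differential co-expression pipeline
#'
#' Sequences the package: obtain a dataset (load from the config's `data`
#' paths or simulate from its `simulate` block), filter invariant genes,
#' call differential expression, build NCN/TCN and the DCN, grow seeded
#' subnetworks, assess them with both permutation tests, extract core
#' modules and summarize topology. Artifacts are written to `out_dir` as
#' TSV/JSON with `# key=value` provenance headers, plus a `manifest.json`
#' (config snapshot, input digests, package version, seed, timestamp)
#' sufficient to reproduce the run.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param out_dir Output directory, created if needed.
#' @param steps Subset of `c("build", "search", "test", "topology",
#'   "classify")`; earlier stages a step needs are always run.
#' @param seed Optional integer overriding `analysis$rng_seed`.
#' @return Invisibly, a list with the in-memory results (`dataset`, `de`,
#'   `ncn`, `tcn`, `dcn`, `subnetworks`, `significance`, `core_modules`,
#'   `topology`, `classification`).
#' @export
run_pipeline <- function(config, out_dir,
                         steps = c("build", "search", "test", "topology"),
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  steps <- match.arg(steps, c("build", "search", "test", "topology", "classify"),
                     several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acfg <- do.call(analysis_config, config$analysis %||% list())
  if (!is.null(seed)) acfg$rng_seed <- as.integer(seed)

  digests <- character(0)
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    specs <- purrr::map(sim$modules %||% list(), function(m) {
      planted_module_spec(
        gene_ids = m$gene_ids %||%
          sprintf("%s_G%02d", m$name %||% "M", seq_len(m$size)),
        rho_normal = m$rho_normal, rho_tumour = m$rho_tumour,
        de_shift = m$de_shift %||% 0, noise_sd = m$noise_sd %||% 1
      )
    })
    cohort <- generate_cohort(
      specs, sim$n_background_genes %||% 200L,
      sim$n_pairs %||% 60L, seed = acfg$rng_seed
    )
    ds <- cohort$dataset
    jsonlite::write_json(
      purrr::map(cohort$truth$specs, unclass),
      file.path(out_dir, "synthetic_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  } else {
    paths <- unlist(config$data)
    if (any(vapply(paths, is.null, logical(1))) || length(paths) < 3L) {
      abort("Config must provide either `simulate` or all three `data` paths.")
    }
    ds <- load_dataset(config$data$expression, config$data$annotation,
                       config$data$metadata)
    digests <- tools::md5sum(paths)
  }

  ds <- suppressMessages(filter_low_variance(ds, config$cv_threshold %||% 0.05))
  de <- suppressMessages(call_differential_expression(ds))
  write_tsv_with_header(de, file.path(out_dir, "de_genes.tsv"),
                        list(rule = "BH p<0.05 & FC>2 or FC<0.5"))

  res <- list(dataset = ds, de = de, config = acfg)
  corr_n <- suppressMessages(correlation_table(ds, "normal"))
  corr_t <- suppressMessages(correlation_table(ds, "tumour"))
  ncn <- build_network(corr_n, acfg$t_n, annotation = ds$genes)
  tcn <- build_network(corr_t, acfg$t_t, annotation = ds$genes)
  dcn <- build_dcn(corr_n, corr_t, ncn, tcn, acfg, de)
  res$ncn <- ncn; res$tcn <- tcn; res$dcn <- dcn
  write_edge_list(ncn, file.path(out_dir, "ncn_edges.tsv"))
  write_edge_list(tcn, file.path(out_dir, "tcn_edges.tsv"))
  write_edge_list(dcn, file.path(out_dir, "dcn_edges.tsv"))
  write_tsv_with_header(dcn$nodes, file.path(out_dir, "dcn_nodes.tsv"),
                        list(t_z = acfg$t_z, bh_universe = acfg$bh_universe))

  if (any(c("search", "test", "classify") %in% steps) && nrow(dcn$edges) > 0) {
    params <- search_params(acfg$d_max, acfg$improvement_rate, acfg$alpha,
                            acfg$improvement_mode)
    subs <- search_all_seeds(dcn, params,
                             config$search$seed_biotype %||% "lncRNA")
    res$subnetworks <- subs
    if (length(subs)) {
      write_subnetworks_json(subs, file.path(out_dir, "subnetworks.json"))
      write_tsv_with_header(
        tidy(subs), file.path(out_dir, "subnetwork_summary.tsv"),
        list(d_max = params$d_max, improvement_rate = params$improvement_rate,
             alpha = params$alpha)
      )
    }
    if ("test" %in% steps && length(subs)) {
      sig <- assess_subnetworks(subs, ds, dcn, de, acfg)
      res$significance <- sig
      write_tsv_with_header(
        sig %>% select(-all_of(c("null_p1", "null_p2"))),
        file.path(out_dir, "significance.tsv"),
        list(n_permutations = acfg$n_permutations, rng_seed = acfg$rng_seed)
      )
      keep <- sig$seed[sig$significant]
      cm <- find_core_modules(
        structure(unclass(subs)[keep], class = "dc_subnetwork_set"),
        config$core$min_genes %||% 4L, config$core$min_capture %||% 3L
      )
      res$core_modules <- cm
      jsonlite::write_json(
        purrr::pmap(cm, function(module_id, hub, n_genes, n_capture,
                                 genes, subnetworks) {
          list(module_id = module_id, hub = hub, genes = genes,
               subnetworks = subnetworks)
        }),
        file.path(out_dir, "core_modules.json"), auto_unbox = TRUE, digits = NA
      )
    }
    if ("classify" %in% steps && length(subs)) {
      act <- activity_matrix(subs, ds, config$activity_method %||% "mean")
      cls <- classify_subnetworks(act, act, seed = acfg$rng_seed)
      res$classification <- cls
      write_tsv_with_header(
        cls$coefficients, file.path(out_dir, "classifier_coefficients.tsv"),
        list(method = config$activity_method %||% "mean",
             auc_train = cls$auc_train)
      )
    }
  }

  if ("topology" %in% steps) {
    tops <- purrr::map_dfr(
      list(NCN = ncn, TCN = tcn, DCN = dcn),
      function(nw) {
        if ((inherits(nw, "dcn") && nrow(nw$edges) == 0) ||
            (inherits(nw, "coexpr_network") && nrow(nw$edges) == 0)) {
          return(tibble())
        }
        glance(network_summary(nw))
      },
      .id = "network"
    )
    res$topology <- tops
    if (nrow(tops)) {
      write_tsv_with_header(tops, file.path(out_dir, "topology.tsv"),
                            list(package = "dcnet"))
    }
  }

  manifest <- list(
    package = "dcnet",
    version = as.character(packageVersion("dcnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rng_seed = acfg$rng_seed,
    steps = steps,
    config = config,
    analysis = unclass(acfg),
    input_digests = as.list(digests)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
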