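#' Assemble a pipeline configuration
#'
#' @param expression,phenotype,seeds,network,gmt Paths to the five inputs.
#' @param profiles Directory of per-instance profile TSVs.
#' @param manifest Instance manifest path.
#' @param benchmark Optional benchmark path (`NULL` skips the precision
#'   stage).
#' @param out_dir Output directory for all artifacts.
#' @param cutoff,p_max,min_count,epsilon,ease,normalize_pathways Stage
#'   parameters (see the stage functions).
#' @param eval_at Cut depths for the precision table.
#' @param rng_seed Seed recorded in the run manifest.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(expression, phenotype, seeds, network, gmt,
                            profiles, manifest, benchmark = NULL,
                            out_dir = "tspath_out", cutoff = 0.1,
                            p_max = 0.001, min_count = 5, epsilon = 0,
                            ease = FALSE, normalize_pathways = FALSE,
                            eval_at = c(10, 20, 30), rng_seed = 1L) {
  structure(list(
    expression = expression, phenotype = phenotype, seeds = seeds,
    network = network, gmt = gmt, profiles = profiles, manifest = manifest,
    benchmark = benchmark, out_dir = out_dir, cutoff = cutoff, p_max = p_max,
    min_count = min_count, epsilon = epsilon, ease = ease,
    normalize_pathways = normalize_pathways, eval_at = eval_at,
    rng_seed = rng_seed
  ), class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Relative input paths are resolved against the YAML file's directory.
#' @param path Path to the YAML config.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) NULL
    else if (startsWith(p, "/")) p
    else file.path(base, p)
  }
  for (f in c("expression", "phenotype", "seeds", "network", "gmt",
              "profiles", "manifest", "benchmark", "out_dir")) {
    if (!is.null(raw[[f]])) raw[[f]] <- resolve(raw[[f]])
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s (check the stage's inputs and thresholds)",
                 name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full drug-repositioning pipeline from files
#'
#' Executes every stage in order: read inputs, logFC and disease signature,
#' subnetwork extraction, pathway enrichment, pathway signatures, per-drug
#' therapeutic scores, ranking, and (when a benchmark is configured)
#' precision-at-k. Writes `subnetwork.tsv`, `subnetwork_stats.tsv`,
#' `enrichment.tsv`, `signatures/`, `ranked_drugs.tsv`, `precision.tsv` and
#' `run_manifest.tsv` under `out_dir`. Identical config and inputs produce
#' identical outputs.
#'
#' @param config A `PipelineConfig`.
#' @return A list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)

  expr <- stage("read_expression", read_expression(config$expression, config$phenotype))
  seeds <- stage("read_seeds", read_seeds(config$seeds))
  network <- stage("read_network", read_network(config$network))
  db <- stage("read_gmt", read_gmt(config$gmt))
  instances <- stage("read_drug_instances",
                     read_drug_instances(config$profiles, config$manifest))
  bench <- if (is.null(config$benchmark)) NULL else {
    stage("read_benchmark", read_benchmark(config$benchmark))
  }

  logfc <- stage("logfc", compute_logfc(expr, epsilon = config$epsilon))
  disease <- stage("disease_signature", build_disease_signature(logfc))

  sub <- stage("subnetwork", extract_subnetwork(network, seeds, config$cutoff))
  write_subnetwork(sub, file.path(config$out_dir, "subnetwork.tsv"))
  stats_ <- topology_stats(sub)
  utils::write.table(as.data.frame(stats_),
                     file.path(config$out_dir, "subnetwork_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  hits <- stage("enrichment", enrich(sub$nodes, db, p_max = config$p_max,
                                     min_count = config$min_count, ease = config$ease))
  utils::write.table(hits, file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(hits) == 0) {
    stop("pipeline stage 'enrichment' failed: no pathway passed the thresholds ",
         "(consider relaxing p_max/min_count)", call. = FALSE)
  }

  sigs <- stage("signatures", build_signatures(hits, db, disease))
  write_signatures(sigs, file.path(config$out_dir, "signatures"))

  results <- stage("scoring", score_drugs(instances, sigs,
                                          normalize_pathways = config$normalize_pathways))
  ranked <- write_ranked_drugs(results, bench,
                               file.path(config$out_dir, "ranked_drugs.tsv"))

  prec <- NULL
  if (!is.null(bench)) {
    prec <- stage("precision", precision_curve(rank_drugs(results), bench, config$eval_at))
    utils::write.table(prec, file.path(config$out_dir, "precision.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    message("no benchmark configured; precision stage skipped")
  }

  manifest <- data.frame(
    key = c("package_version", "rng_seed", "cutoff", "p_max", "min_count",
            "epsilon", "ease", "normalize_pathways", "n_drugs_scored",
            "n_signatures", "config_hash"),
    value = c(as.character(utils::packageVersion("tspath")),
              config$rng_seed, config$cutoff, config$p_max, config$min_count,
              config$epsilon, config$ease, config$normalize_pathways,
              length(results), length(sigs),
              config_hash(config)),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(config$out_dir, "run_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(expression = expr, disease = disease, subnetwork = sub,
                 topology = stats_, enrichment = hits, signatures = sigs,
                 results = results, ranked = ranked, precision = prec))
}

config_hash <- function(config) {
  flat <- paste(names(config), vapply(config, function(x) paste(format(x), collapse = ","),
                                      character(1)),
                sep = "=", collapse = ";")
  # small rolling hash; enough to detect config drift between runs
  h <- 0
  for (ch in utf8ToInt(flat)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%d", h)
}
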