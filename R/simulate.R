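#' Default simulation configuration
#'
#' Scaled-down study conditions with planted ground truth: a lognormal
#' expression baseline with differential genes concentrated in a few pathway
#' modules, a tissue network with a dense module around the seed genes, drug
#' profiles that reverse (positive strength), mimic (negative strength) or
#' ignore (zero strength) the disease signature, and a benchmark derived from
#' the planted truth.
#'
#' Defaults: 500 genes; 30 tumor and 12 control samples; 4 planted pathways
#' of 25 genes (plus as many decoy pathways); 8 seed genes; module edge
#' probability 0.4 vs background 0.01; planted log2 effect size 2 with
#' expression noise sd 0.25; 20 drugs with 3 instances each, 5 reversers at
#' strength +0.9 and 15 nulls at 0; drug profile noise sd 0.2. The
#' connectivity statistic is rank-based and therefore scale-free: any nonzero
#' mimic strength clearly above the profile noise yields the same |TS| as a
#' reverser of equal signal-to-noise, so mimicking drugs (negative strengths)
#' are not part of the default conditions and are exercised through explicit
#' `reversal_strengths` overrides instead.
#'
#' @param ... Named overrides of any field.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 500L,
    n_tumor = 30L,
    n_control = 12L,
    n_pathways = 4L,
    pathway_size = 25L,
    n_decoy_pathways = 4L,
    n_seed_genes = 8L,
    module_edge_prob = 0.4,
    background_edge_prob = 0.01,
    effect_size = 2,
    expression_noise_sd = 0.25,
    noise_sd = 0.2,
    n_drugs = 20L,
    k_instances = 3L,
    reversal_strengths = NULL,
    rng_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  if (is.null(cfg$reversal_strengths)) {
    n <- cfg$n_drugs
    s <- numeric(n)
    s[seq_len(min(5, n))] <- 0.9
    cfg$reversal_strengths <- stats::setNames(s, sprintf("drug%02d", seq_len(n)))
  }
  counts <- c(cfg$n_genes, cfg$n_tumor, cfg$n_control, cfg$n_pathways,
              cfg$pathway_size, cfg$n_seed_genes, cfg$n_drugs, cfg$k_instances)
  if (any(counts < 1)) stop("all config counts must be positive", call. = FALSE)
  probs <- c(cfg$module_edge_prob, cfg$background_edge_prob)
  if (any(probs < 0 | probs > 1)) stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  if (any(abs(cfg$reversal_strengths) > 1)) stop("reversal strengths must lie in [-1, 1]", call. = FALSE)
  if (length(cfg$reversal_strengths) != cfg$n_drugs) {
    stop("need one reversal strength per drug", call. = FALSE)
  }
  structure(cfg, class = "SimulationConfig")
}

#' Simulate all five pipeline inputs with planted ground truth
#'
#' Planted differential genes fill the `n_pathways` planted pathways (half up,
#' half down per pathway) and, together with the seed genes drawn from them,
#' form a dense network module; decoy pathways are drawn from the non-planted
#' genes. Tumor samples shift planted genes by +/- `effect_size` on the log2
#' scale over a lognormal baseline. Drug instance values are
#' `-strength(drug) * logFC(gene) + Normal(0, noise_sd)` against the realized
#' disease logFC, so a strength of +1 with zero noise reproduces the exact
#' reverse of the disease ranking. The benchmark marks planted therapeutic
#' drugs (strength > 0) as `inferred` and omits all others.
#'
#' @param config A `SimulationConfig` from [sim_config()].
#' @return A list with `expression` (`ExpressionMatrix`), `seeds`, `network`
#'   (`TissueNetwork`), `db` (`PathwayDB`), `instances` (list of
#'   `DrugInstanceProfile`), `benchmark` (`Benchmark`), and `truth` (list with
#'   `planted_up`, `planted_down`, `therapeutic_drugs`, `enriched_pathways`,
#'   `reversal_strengths`).
#' @export
simulate_all <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  n_planted <- config$n_pathways * config$pathway_size
  if (n_planted > config$n_genes) stop("planted gene sets larger than n_genes", call. = FALSE)
  if (config$n_seed_genes > n_planted) stop("more seeds than planted genes", call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$rng_seed)

  genes <- sprintf("g%04d", seq_len(config$n_genes))
  planted <- genes[seq_len(n_planted)]
  pathway_of <- split(planted, rep(seq_len(config$n_pathways), each = config$pathway_size))
  names(pathway_of) <- sprintf("planted_pw%02d", seq_len(config$n_pathways))

  # within each planted pathway: first half up, second half down
  half <- ceiling(config$pathway_size / 2)
  planted_up <- unlist(lapply(pathway_of, function(p) p[seq_len(half)]), use.names = FALSE)
  planted_down <- setdiff(planted, planted_up)

  delta <- stats::setNames(numeric(config$n_genes), genes)
  delta[planted_up] <- config$effect_size
  delta[planted_down] <- -config$effect_size

  # lognormal baseline expression with tumor shift on the log2 scale
  n_samp <- config$n_tumor + config$n_control
  samples <- sprintf("s%03d", seq_len(n_samp))
  group <- c(rep("tumor", config$n_tumor), rep("control", config$n_control))
  mu <- stats::rnorm(config$n_genes, mean = 6, sd = 1)
  log2expr <- matrix(stats::rnorm(config$n_genes * n_samp, sd = config$expression_noise_sd),
                     nrow = config$n_genes)
  log2expr <- log2expr + mu
  log2expr[, group == "tumor"] <- log2expr[, group == "tumor"] + delta
  values <- 2^log2expr
  dimnames(values) <- list(genes, samples)
  pheno <- data.frame(sample_id = samples, group = group, stringsAsFactors = FALSE)
  expr <- new_expression_matrix(values, pheno)

  seeds <- sample(planted, config$n_seed_genes)

  # network: dense module over planted genes, sparse background elsewhere
  module <- planted
  edges <- rbind(
    random_edges(module, config$module_edge_prob, conf_min = 0.5, conf_max = 1),
    random_edges(genes, config$background_edge_prob, conf_min = 0, conf_max = 1,
                 exclude_within = module)
  )
  network <- new_tissue_network(edges)

  # decoy pathways drawn from non-planted genes
  nonplanted <- setdiff(genes, planted)
  decoys <- lapply(seq_len(config$n_decoy_pathways), function(i) {
    sample(nonplanted, min(config$pathway_size, length(nonplanted)))
  })
  names(decoys) <- sprintf("decoy_pw%02d", seq_len(config$n_decoy_pathways))
  db <- new_pathway_db(c(pathway_of, decoys), background = genes)

  # drug instances reverse/mimic the realized disease logFC
  logfc <- compute_logfc(expr)
  drug_names <- names(config$reversal_strengths)
  instances <- list()
  for (d in seq_along(drug_names)) {
    strength <- config$reversal_strengths[[d]]
    for (j in seq_len(config$k_instances)) {
      vals <- -strength * logfc + stats::rnorm(config$n_genes, sd = config$noise_sd)
      names(vals) <- genes
      instances[[length(instances) + 1L]] <- new_drug_instance(
        sprintf("%s_inst%02d", drug_names[d], j), drug_names[d], vals
      )
    }
  }

  therapeutic <- drug_names[config$reversal_strengths > 0]
  ev <- stats::setNames(rep("inferred", length(therapeutic)), therapeutic)
  benchmark <- new_benchmark(ev)

  list(
    expression = expr,
    seeds = seeds,
    network = network,
    db = db,
    instances = instances,
    benchmark = benchmark,
    truth = list(
      planted_up = planted_up,
      planted_down = planted_down,
      therapeutic_drugs = therapeutic,
      enriched_pathways = names(pathway_of),
      reversal_strengths = config$reversal_strengths
    )
  )
}

# Bernoulli edges among `nodes`; optionally skip pairs already covered by the
# dense module to avoid double-draws
random_edges <- function(nodes, prob, conf_min, conf_max, exclude_within = NULL) {
  n <- length(nodes)
  if (n < 2 || prob == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < prob
  if (!is.null(exclude_within)) {
    inside <- nodes[pairs[1, ]] %in% exclude_within & nodes[pairs[2, ]] %in% exclude_within
    keep <- keep & !inside
  }
  pairs <- pairs[, keep, drop = FALSE]
  data.frame(
    gene_a = nodes[pairs[1, ]],
    gene_b = nodes[pairs[2, ]],
    confidence = stats::runif(ncol(pairs), conf_min, conf_max),
    stringsAsFactors = FALSE
  )
}

#' Write simulated inputs as pipeline-ready files
#'
#' Writes every simulated object in the file dialects the readers expect:
#' `expression.tsv` + `phenotype.tsv`, `seeds.txt`, `network.tsv`,
#' `pathways.gmt`, `profiles/<instance>.tsv` + `manifest.tsv`,
#' `benchmark.tsv`, and `truth.tsv` (planted gene directions and drug
#' strengths).
#'
#' @param sim Output of [simulate_all()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- sim$expression$values
  utils::write.table(data.frame(gene = rownames(v), v, check.names = FALSE),
                     file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$expression$groups, file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$seeds, file.path(dir, "seeds.txt"))
  utils::write.table(as.data.frame(sim$network), file.path(dir, "network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gmt <- vapply(names(sim$db$pathways), function(id) {
    paste(c(id, "synthetic", sim$db$pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(dir, "pathways.gmt"))

  prof_dir <- file.path(dir, "profiles")
  if (!dir.exists(prof_dir)) dir.create(prof_dir)
  man <- data.frame(
    instance_id = vapply(sim$instances, `[[`, character(1), "instance_id"),
    drug_name = vapply(sim$instances, `[[`, character(1), "drug_name"),
    stringsAsFactors = FALSE
  )
  utils::write.table(man, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (inst in sim$instances) {
    utils::write.table(
      data.frame(gene = names(inst$values), value = unname(inst$values)),
      file.path(prof_dir, paste0(inst$instance_id, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  utils::write.table(
    data.frame(drug_name = names(sim$benchmark$evidence),
               evidence = unname(sim$benchmark$evidence),
               stringsAsFactors = FALSE),
    file.path(dir, "benchmark.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- data.frame(
    item = c(sim$truth$planted_up, sim$truth$planted_down,
             names(sim$truth$reversal_strengths)),
    kind = c(rep("planted_up", length(sim$truth$planted_up)),
             rep("planted_down", length(sim$truth$planted_down)),
             rep("drug_strength", length(sim$truth$reversal_strengths))),
    value = c(rep(NA_real_, length(sim$truth$planted_up) + length(sim$truth$planted_down)),
              unname(sim$truth$reversal_strengths)),
    stringsAsFactors = FALSE
  )
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
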