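small_cfg <- function(...) {
  sim_config(n_genes = 80L, n_tumor = 6L, n_control = 6L, n_pathways = 2L,
             pathway_size = 10L, n_decoy_pathways = 2L, n_seed_genes = 4L,
             n_drugs = 4L, k_instances = 2L,
             reversal_strengths = setNames(c(0.9, 0.9, 0, 0), paste0("drug0", 1:4)),
             ...)
}

test_that("simulation is fully determined by the rng seed", {
  s1 <- simulate_all(small_cfg(rng_seed = 3L))
  s2 <- simulate_all(small_cfg(rng_seed = 3L))
  expect_identical(s1, s2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(s1, d1); write_fixture(s2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  s3 <- simulate_all(small_cfg(rng_seed = 4L))
  expect_false(identical(s1$expression$values, s3$expression$values))
})

test_that("fixtures round-trip through the format readers", {
  sim <- simulate_all(small_cfg(rng_seed = 3L))
  d <- withr::local_tempdir()
  write_fixture(sim, d)

  em <- read_expression(file.path(d, "expression.tsv"), file.path(d, "phenotype.tsv"))
  expect_equal(em$values, sim$expression$values, tolerance = 1e-12)
  expect_identical(em$groups, sim$expression$groups)

  expect_identical(read_seeds(file.path(d, "seeds.txt")), sim$seeds)

  net <- read_network(file.path(d, "network.tsv"))
  expect_equal(as.data.frame(net), as.data.frame(sim$network), tolerance = 1e-12)

  db <- read_gmt(file.path(d, "pathways.gmt"))
  expect_identical(db$pathways, sim$db$pathways)

  inst <- read_drug_instances(file.path(d, "profiles"), file.path(d, "manifest.tsv"))
  expect_identical(vapply(inst, `[[`, character(1), "instance_id"),
                   vapply(sim$instances, `[[`, character(1), "instance_id"))
  expect_identical(inst[[1]]$ranked_genes, sim$instances[[1]]$ranked_genes)

  bench <- read_benchmark(file.path(d, "benchmark.tsv"))
  expect_identical(bench$evidence, sim$benchmark$evidence)
})

test_that("zero strength and zero noise produce all-zero profiles and TS = 0", {
  cfg <- small_cfg(rng_seed = 2L, noise_sd = 0,
                   reversal_strengths = setNames(numeric(4), paste0("drug0", 1:4)))
  sim <- simulate_all(cfg)
  expect_true(all(vapply(sim$instances, function(i) all(i$values == 0), logical(1))))

  dis <- build_disease_signature(compute_logfc(sim$expression))
  sigs <- build_signatures(names(sim$db$pathways)[1:2], sim$db, dis)
  res <- score_drugs(sim$instances, sigs)
  expect_true(all(vapply(res, `[[`, numeric(1), "ts") == 0))
  expect_length(sim$truth$therapeutic_drugs, 0)
})

test_that("a noise-free full-strength reverser inverts the disease ranking", {
  cfg <- small_cfg(rng_seed = 6L, noise_sd = 0,
                   reversal_strengths = setNames(c(1, 0, 0, 0), paste0("drug0", 1:4)))
  sim <- simulate_all(cfg)
  dis <- build_disease_signature(compute_logfc(sim$expression))
  rev_inst <- sim$instances[[1]]
  expect_equal(rev_inst$drug_name, "drug01")
  # drug values are -logFC exactly, so the drug ranking reverses the disease
  # ranking wherever logFC values are distinct
  expect_identical(rev_inst$ranked_genes, rev(dis$ranked_genes))

  sigs <- build_signatures(sim$truth$enriched_pathways, sim$db, dis)
  ts <- therapeutic_score(sim$instances[1:2], sigs)
  expect_lt(ts$ts, 0)
})

test_that("planted pathways are recovered by enrichment under the default config", {
  sim <- simulate_all(sim_config(rng_seed = 1L))
  sub <- extract_subnetwork(sim$network, sim$seeds, 0.1)
  hits <- enrich(sub$nodes, sim$db, p_max = 0.001, min_count = 5)
  expect_setequal(hits$pathway_id, sim$truth$enriched_pathways)
})

test_that("planted reversal drugs are recovered across seeds", {
  # effect 2, noise 0.2, strengths +0.9 x5 / 0 x15: the five planted
  # therapeutic drugs should occupy the top five |TS| ranks with TS < 0 in
  # at least 9 of 10 seeds
  hits <- vapply(1:10, function(seed) {
    sim <- simulate_all(sim_config(rng_seed = seed))
    dis <- build_disease_signature(compute_logfc(sim$expression))
    full <- run_baseline("full", dis, sim$instances, network = sim$network,
                         seeds = sim$seeds, db = sim$db)
    ranked <- rank_drugs(full$results)
    top5 <- ranked[1:5, ]
    setequal(top5$drug_name, sim$truth$therapeutic_drugs) && all(top5$ts < 0)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("config validation rejects impossible settings", {
  expect_error(simulate_all(sim_config(n_genes = 10L)), "larger than n_genes")
  expect_error(sim_config(bogus = 1), "unknown config field")
  expect_error(small_cfg(module_edge_prob = 1.5), "\\[0, 1\\]")
  expect_error(small_cfg(reversal_strengths = setNames(c(2, 0, 0, 0),
                                                       paste0("drug0", 1:4))),
               "strengths")
})
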