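test_that("rank_drugs orders by |TS| with alphabetical tie-break", {
  res <- list(make_result("d2", 0.7), make_result("d1", -1.5), make_result("d3", -0.2))
  expect_equal(rank_drugs(res)$drug_name, c("d1", "d2", "d3"))

  tied <- list(make_result("b", -0.5), make_result("a", 0.5))
  expect_equal(rank_drugs(tied)$drug_name, c("a", "b"))

  expect_equal(nrow(rank_drugs(list())), 0)
})

test_that("precision_at counts any non-NA evidence among the top-x", {
  ranked <- rank_drugs(lapply(1:12, function(i) {
    make_result(sprintf("d%02d", i), ts = -(13 - i) / 10)
  }))
  # d01 has the largest |TS|; mark all but d05 in the benchmark
  bench <- new_benchmark(setNames(rep("inferred", 9),
                                  sprintf("d%02d", setdiff(1:10, 5))))
  p <- precision_at(ranked, bench, 10)
  expect_equal(p$hits, 9L)
  expect_equal(p$precision, 0.9)

  none <- new_benchmark(c(zzz = "T"))
  expect_equal(precision_at(ranked, none, 5)$precision, 0)

  expect_error(precision_at(ranked, bench, 0), "at least 1")
  expect_error(precision_at(ranked, bench, 99), "exceeds")

  # invariant to benchmark rows outside the top-x
  bench2 <- new_benchmark(c(setNames(rep("inferred", 9),
                                     sprintf("d%02d", setdiff(1:10, 5))),
                            d12 = "M&T"))
  expect_equal(precision_at(ranked, bench2, 10), p)
})

test_that("classification is strictly TS < 0", {
  res <- list(make_result("a", -0.01), make_result("b", 0), make_result("c", 2.3))
  expect_equal(classify_therapeutic(res), c(a = TRUE, b = FALSE, c = FALSE))
})

test_that("subnetKS reduces to seedKS when the subnetwork spans all genes", {
  sim <- simulate_all(sim_config(n_genes = 60L, n_pathways = 2L,
                                 pathway_size = 10L, n_decoy_pathways = 1L,
                                 n_drugs = 4L, k_instances = 1L,
                                 n_tumor = 6L, n_control = 6L,
                                 module_edge_prob = 1, background_edge_prob = 1,
                                 reversal_strengths = setNames(c(0.9, 0.9, 0, 0),
                                                               paste0("drug0", 1:4)),
                                 rng_seed = 5L))
  dis <- build_disease_signature(compute_logfc(sim$expression))
  seed_res <- run_baseline("seedKS", dis, sim$instances)
  sub_res <- run_baseline("subnetKS", dis, sim$instances,
                          network = sim$network, seeds = sim$seeds, cutoff = 0)
  # with edge probability 1 and cutoff 0 the subnetwork spans every gene
  expect_setequal(sub_res$signatures[[1]]$up_genes, dis$up_set)
  expect_equal(rank_drugs(sub_res$results)$ts, rank_drugs(seed_res$results)$ts)
})

test_that("seedPathKS reports an explicit empty status when nothing enriches", {
  sim <- simulate_all(sim_config(n_genes = 80L, n_pathways = 2L,
                                 pathway_size = 10L, n_drugs = 2L,
                                 k_instances = 1L, n_tumor = 5L, n_control = 5L,
                                 reversal_strengths = setNames(c(0.9, 0),
                                                               c("drug01", "drug02")),
                                 rng_seed = 9L))
  dis <- build_disease_signature(compute_logfc(sim$expression))
  # whole-genome DEG query: every pathway overlap equals its size, p = 1
  res <- run_baseline("seedPathKS", dis, sim$instances, db = sim$db)
  expect_equal(res$status, "no_enriched_pathways")
  expect_length(res$results, 0)
})

test_that("full pipeline beats or ties seedKS on pathway-concentrated signal", {
  sim <- simulate_all(sim_config(rng_seed = 7L))
  dis <- build_disease_signature(compute_logfc(sim$expression))
  p_at_5 <- function(res) {
    precision_at(rank_drugs(res$results), sim$benchmark, 5)$precision
  }
  full <- run_baseline("full", dis, sim$instances, network = sim$network,
                       seeds = sim$seeds, db = sim$db)
  seed <- run_baseline("seedKS", dis, sim$instances)
  expect_equal(full$status, "ok")
  expect_gte(p_at_5(full), p_at_5(seed))
  expect_equal(p_at_5(full), 1)
})
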