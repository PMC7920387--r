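instance_from_order <- function(genes, drug = "d", id = "i1") {
  # descending values so the ranked order equals `genes` as given
  new_drug_instance(id, drug, setNames(rev(seq_along(genes)), genes))
}

test_that("intersect_and_rerank returns drug-list positions of common genes", {
  inst <- instance_from_order(c("D", "B", "E", "A"))
  ks <- intersect_and_rerank(c("A", "B"), inst)
  expect_equal(ks$m, 2)
  expect_equal(ks$positions, c(2, 4))
  expect_equal(ks$n, 4)

  expect_equal(intersect_and_rerank(c("X", "Y"), inst)$m, 0)
  expect_equal(intersect_and_rerank(c("D", "B", "E", "A"), inst)$positions, 1:4)
})

test_that("ks_score reproduces hand-derived small cases", {
  expect_equal(ks_score(make_ks_input(1, 10)), 0.9)
  expect_equal(ks_score(make_ks_input(10, 10)), -1.0)
  expect_equal(ks_score(make_ks_input(c(1, 10), 10)), -0.5)
  expect_equal(ks_score(make_ks_input(1, 2)), 0)  # a = b = 0.5 tie
  expect_equal(ks_score(make_ks_input(integer(0), 10)), 0)
  expect_error(ks_score(make_ks_input(c(0, 3), 10)), "position")
  expect_error(ks_score(make_ks_input(c(3, 11), 10)), "position")
})

test_that("ks_score agrees with the empirical-CDF oracle on randomized inputs", {
  set.seed(101)
  # exhaustive: every position subset with m <= 3, n <= 10
  for (n in 2:10) {
    for (m in 1:min(3, n)) {
      subsets <- combn(n, m)
      for (j in seq_len(ncol(subsets))) {
        v <- subsets[, j]
        expect_equal(ks_score(make_ks_input(v, n)), ks_oracle(v, n),
                     tolerance = 1e-12)
      }
    }
  }
  # randomized larger inputs; one aggregate assertion to keep the loop fast
  dev <- replicate(2000, {
    n <- sample(5:400, 1)
    m <- sample.int(min(n, 30), 1)
    v <- random_positions(m, n)
    abs(ks_score(make_ks_input(v, n)) - ks_oracle(v, n))
  })
  expect_lt(max(dev), 1e-12)
})

test_that("ks_score is bounded in [-1, 1] and monotone under downward shifts", {
  set.seed(202)
  bound_violations <- 0L
  monotone_violations <- 0L
  for (i in 1:10000) {
    n <- sample(3:200, 1)
    m <- sample.int(min(n, 25), 1)
    v <- random_positions(m, n)
    cs <- ks_score(make_ks_input(v, n))
    if (cs < -1 || cs > 1) bound_violations <- bound_violations + 1L
    # push every position toward the bottom of the list
    room <- n - v[m]
    if (room > 0) {
      shift <- sample.int(room, 1)
      cs2 <- ks_score(make_ks_input(v + shift, n))
      if (cs2 > cs + 1e-12) monotone_violations <- monotone_violations + 1L
    }
  }
  expect_equal(bound_violations, 0L)
  expect_equal(monotone_violations, 0L)
})

test_that("score_instance combines components and is antisymmetric under swap", {
  inst <- instance_from_order(c("u1", "u2", "x1", "x2", "d1", "d2"))
  sig <- make_signature("pw", up = c("u1", "u2"), down = c("d1", "d2"))
  rec <- score_instance(sig, inst)
  expect_equal(rec$cs, rec$cs_up - rec$cs_down)
  expect_gt(rec$cs, 0) # up genes on top, down at bottom: mimicking pattern

  swapped <- score_instance(make_signature("pw", up = sig$down_genes,
                                           down = sig$up_genes), inst)
  expect_equal(swapped$cs, -rec$cs)

  empty <- score_instance(make_signature("pw", character(0), character(0)), inst)
  expect_equal(empty$cs, 0)

  # one empty side contributes 0 to its component
  up_only <- score_instance(make_signature("pw", c("u1", "u2"), character(0)), inst)
  expect_equal(up_only$cs_down, 0)
  expect_equal(up_only$cs, up_only$cs_up)

  # randomized antisymmetry
  set.seed(303)
  genes <- paste0("g", 1:50)
  for (i in 1:50) {
    inst <- new_drug_instance("i", "d", setNames(rnorm(50), genes))
    up <- sample(genes, 8); down <- sample(setdiff(genes, up), 8)
    s <- make_signature("pw", up, down)
    sw <- make_signature("pw", down, up)
    expect_equal(score_instance(sw, inst)$cs, -score_instance(s, inst)$cs)
  }
})

test_that("therapeutic_score averages over instances and sums over pathways", {
  genes <- paste0("g", 1:20)
  sigs <- list(make_signature("p1", genes[1:3], genes[18:20]),
               make_signature("p2", genes[4:6], genes[15:17]))
  vals <- setNames(seq(2, -2, length.out = 20), genes)
  i1 <- new_drug_instance("i1", "d", vals)
  i2 <- new_drug_instance("i2", "d", vals + 0) # identical

  one <- therapeutic_score(list(i1), sigs)
  two <- therapeutic_score(list(i1, i2), sigs)
  expect_equal(two$ts, one$ts)          # k-fold duplication leaves ts unchanged
  expect_equal(two$k, 2)
  expect_equal(nrow(two$records), 2 * 2)
  expect_equal(one$ts, sum(one$records$cs))

  # normalize_pathways divides by the signature count
  expect_equal(therapeutic_score(list(i1), sigs, normalize_pathways = TRUE)$ts,
               one$ts / 2)

  expect_error(therapeutic_score(list(), sigs), "instance")
  expect_error(therapeutic_score(list(i1), list()), "signature")
  i_other <- new_drug_instance("i3", "other", vals)
  expect_error(therapeutic_score(list(i1, i_other), sigs), "single drug")
})

test_that("drug_drug_score is positive on self and negative on a reversed profile", {
  genes <- paste0("g", 1:30)
  vals <- setNames(seq(3, -3, length.out = 30), genes)
  a <- new_drug_instance("a1", "A", vals)
  expect_gt(drug_drug_score(a, list(a)), 0)

  reversed <- new_drug_instance("b1", "B", -vals)
  expect_lt(drug_drug_score(a, list(reversed)), 0)

  expect_error(drug_drug_score(a, list()), "instances")
})
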