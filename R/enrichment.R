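#' Upper-tail hypergeometric p-value for a pathway overlap
#'
#' Probability of drawing at least `overlap` pathway members when
#' `query_size` genes are sampled without replacement from a universe of
#' `universe_size` genes containing `pathway_size` pathway members:
#' P(X >= overlap) with X ~ Hypergeometric(universe_size, pathway_size,
#' query_size).
#'
#' With `ease = TRUE` the EASE-score variant is computed: the overlap is
#' decremented by one before taking the tail, a conservative penalty on
#' single-gene overlaps.
#'
#' @param overlap Observed overlap count.
#' @param query_size Number of query genes in the universe.
#' @param pathway_size Number of pathway members in the universe.
#' @param universe_size Size of the background universe.
#' @param ease Use the EASE variant (default `FALSE`).
#' @return The upper-tail p-value.
#' @export
hypergeom_pvalue <- function(overlap, query_size, pathway_size, universe_size,
                             ease = FALSE) {
  if (overlap > min(query_size, pathway_size)) {
    stop("overlap cannot exceed min(query_size, pathway_size)", call. = FALSE)
  }
  if (pathway_size > universe_size || query_size > universe_size) {
    stop("pathway and query sizes cannot exceed the universe size", call. = FALSE)
  }
  if (overlap < 0) stop("overlap must be non-negative", call. = FALSE)
  q <- if (ease) max(overlap - 1, 0) else overlap
  # P(X >= q) = 1 - P(X <= q - 1)
  stats::phyper(q - 1, pathway_size, universe_size - pathway_size, query_size,
                lower.tail = FALSE)
}

#' Hypergeometric pathway enrichment with count and p-value filters
#'
#' Tests every pathway in the database for over-representation of the query
#' gene set and keeps pathways with `overlap_count >= min_count` and
#' `p_value <= p_max`. Query genes outside the universe are ignored for the
#' test. No multiple-testing correction is applied to the filter (raw
#' thresholds); a Benjamini-Hochberg column is reported for information.
#'
#' @param query Character vector of query gene ids.
#' @param db A `PathwayDB`.
#' @param p_max Raw p-value threshold (default 0.001).
#' @param min_count Minimum overlap count (default 5).
#' @param ease Use the EASE p-value variant.
#' @return Data frame with columns `pathway_id`, `overlap_count`,
#'   `pathway_size`, `query_size`, `p_value`, `p_adjust_bh`, sorted by
#'   ascending p-value then pathway id. Zero rows when nothing passes.
#' @export
enrich <- function(query, db, p_max = 0.001, min_count = 5, ease = FALSE) {
  stopifnot(inherits(db, "PathwayDB"), length(query) > 0)
  query <- unique(as.character(query))
  query_in <- intersect(query, db$universe)
  n_univ <- length(db$universe)
  ids <- names(db$pathways)
  if (length(ids) == 0) return(empty_enrichment())
  overlap <- vapply(db$pathways, function(p) length(intersect(p, query_in)), integer(1))
  psize <- lengths(db$pathways)
  pval <- vapply(seq_along(ids), function(i) {
    hypergeom_pvalue(overlap[i], length(query_in), psize[i], n_univ, ease = ease)
  }, numeric(1))
  res <- data.frame(
    pathway_id = ids,
    overlap_count = as.integer(overlap),
    pathway_size = as.integer(psize),
    query_size = length(query_in),
    p_value = pval,
    p_adjust_bh = stats::p.adjust(pval, method = "BH"),
    stringsAsFactors = FALSE
  )
  res <- res[res$overlap_count >= min_count & res$p_value <= p_max, , drop = FALSE]
  res <- res[order(res$p_value, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_enrichment <- function() {
  data.frame(pathway_id = character(0), overlap_count = integer(0),
             pathway_size = integer(0), query_size = integer(0),
             p_value = numeric(0), p_adjust_bh = numeric(0),
             stringsAsFactors = FALSE)
}

#' Random-gene-set significance of a seed-anchored gene set
#'
#' Null procedure for the functional coherence of an extracted gene set: each
#' null draw keeps the seed genes and replaces the remaining members with a
#' uniform sample (without replacement) of non-seed network genes of the same
#' size. The statistic per draw is the number of distinct draw genes covered
#' by pathways passing [enrich()] at the given thresholds. The empirical
#' p-value uses the add-one rule (1 + #draws >= observed) / (1 + n_draws).
#'
#' @param network_genes Character vector of genes eligible for random draws.
#' @param seeds Seed genes retained in every draw.
#' @param observed_set The real gene set being tested (e.g. the subnetwork
#'   node set).
#' @param draw_size Number of non-seed genes sampled per draw.
#' @param n_draws Number of random draws (default 1000).
#' @param db A `PathwayDB`.
#' @param p_max,min_count,ease Passed to [enrich()].
#' @param rng_seed Integer seed; fixed seed gives identical output.
#' @return A list with `draws` (integer vector), `observed`, `empirical_p`.
#' @export
random_set_significance <- function(network_genes, seeds, observed_set,
                                    draw_size, n_draws = 1000, db,
                                    p_max = 0.001, min_count = 5, ease = FALSE,
                                    rng_seed = 1L) {
  pool <- setdiff(unique(as.character(network_genes)), seeds)
  if (draw_size > length(pool)) {
    stop("draw_size exceeds the number of non-seed network genes", call. = FALSE)
  }
  covered <- function(gene_set) {
    hits <- enrich(gene_set, db, p_max = p_max, min_count = min_count, ease = ease)
    if (nrow(hits) == 0) return(0L)
    members <- unique(unlist(db$pathways[hits$pathway_id], use.names = FALSE))
    length(intersect(gene_set, members))
  }
  observed <- covered(unique(as.character(observed_set)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(rng_seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    covered(c(seeds, sample(pool, draw_size)))
  }, integer(1))
  list(
    draws = draws,
    observed = observed,
    empirical_p = (1 + sum(draws >= observed)) / (1 + n_draws)
  )
}
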