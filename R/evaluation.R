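#' Rank drugs by absolute therapeutic score
#'
#' Most drug-disease associations in benchmarks are unsigned, so candidate
#' drugs are ranked by the magnitude of their therapeutic score; the sign
#' (therapeutic vs mimicking) is kept in the `ts` column. Ties are broken
#' alphabetically by drug name.
#'
#' @param results List of `TherapeuticResult` objects.
#' @return Data frame with columns `rank`, `drug_name`, `k`, `ts`, `abs_ts`.
#' @export
rank_drugs <- function(results) {
  if (length(results) == 0) {
    return(data.frame(rank = integer(0), drug_name = character(0), k = integer(0),
                      ts = numeric(0), abs_ts = numeric(0), stringsAsFactors = FALSE))
  }
  tab <- data.frame(
    drug_name = vapply(results, `[[`, character(1), "drug_name"),
    k = vapply(results, `[[`, numeric(1), "k"),
    ts = vapply(results, `[[`, numeric(1), "ts"),
    stringsAsFactors = FALSE
  )
  tab$abs_ts <- abs(tab$ts)
  tab <- tab[order(-tab$abs_ts, tab$drug_name, method = "radix"), , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Precision of the top-x ranked drugs against a benchmark
#'
#' precision = P_bench / x, where P_bench is the number of top-x drugs with
#' any benchmark evidence other than `"NA"` (curated or inferred).
#'
#' @param ranked Ranked drug data frame from [rank_drugs()].
#' @param bench A `Benchmark`.
#' @param x Cut depth; must be between 1 and the number of ranked drugs.
#' @return A one-row data frame with `x`, `hits`, `precision`.
#' @export
precision_at <- function(ranked, bench, x) {
  stopifnot(inherits(bench, "Benchmark"))
  if (x < 1) stop("x must be at least 1", call. = FALSE)
  if (x > nrow(ranked)) stop("x exceeds the number of ranked drugs", call. = FALSE)
  ev <- benchmark_evidence(bench, ranked$drug_name[seq_len(x)])
  hits <- sum(ev != "NA")
  data.frame(x = as.integer(x), hits = as.integer(hits), precision = hits / x)
}

#' Precision curve at several cut depths
#' @param ranked Ranked drug data frame from [rank_drugs()].
#' @param bench A `Benchmark`.
#' @param xs Integer vector of cut depths (default 10, 20, 30, capped at the
#'   number of ranked drugs).
#' @return Data frame with one row per cut depth.
#' @export
precision_curve <- function(ranked, bench, xs = c(10, 20, 30)) {
  xs <- xs[xs <= nrow(ranked)]
  do.call(rbind, lapply(xs, function(x) precision_at(ranked, bench, x)))
}

#' Classify drugs as therapeutic by the sign of their score
#'
#' A drug is called therapeutic when its expression profile reverses the
#' disease signature, i.e. TS is strictly negative.
#'
#' @param results List of `TherapeuticResult` objects.
#' @return Named logical vector (drug -> therapeutic).
#' @export
classify_therapeutic <- function(results) {
  ts <- vapply(results, `[[`, numeric(1), "ts")
  stats::setNames(ts < 0, vapply(results, `[[`, character(1), "drug_name"))
}

#' Run the full method or one of its ablation baselines
#'
#' All variants share the connectivity core and differ only in the signatures
#' the drugs are scored against:
#' \describe{
#'   \item{`full`}{the complete pipeline: seed-anchored subnetwork, pathway
#'     enrichment of its genes, one signature per enriched pathway.}
#'   \item{`seedKS`}{one signature = the disease-wide up/down DEG sets; no
#'     network, no pathways.}
#'   \item{`subnetKS`}{one signature = the disease up/down sets restricted to
#'     the extracted subnetwork's genes; no pathways.}
#'   \item{`seedPathKS`}{pathways enriched directly from the disease DEG sets
#'     (network ignored), then scored per pathway as in `full`.}
#' }
#' For `seedKS` and `seedPathKS` the DEG sets default to all up and all down
#' genes; `q` restricts them to the top-q up and top-q down genes by |logFC|.
#'
#' @param method One of `"full"`, `"seedKS"`, `"subnetKS"`, `"seedPathKS"`.
#' @param disease A `DiseaseSignature`.
#' @param instances List of `DrugInstanceProfile` objects.
#' @param network A `TissueNetwork` (needed for `full`, `subnetKS`).
#' @param seeds Seed genes (needed for `full`, `subnetKS`).
#' @param db A `PathwayDB` (needed for `full`, `seedPathKS`).
#' @param cutoff Network confidence cutoff (default 0.1).
#' @param p_max,min_count,ease Enrichment thresholds (defaults 0.001, 5).
#' @param q Optional DEG set size bound for `seedKS`/`seedPathKS`.
#' @param normalize_pathways Passed to the scoring core.
#' @return A list with `method`, `results` (list of `TherapeuticResult`;
#'   empty for `seedPathKS` with no enriched pathway), `status` (`"ok"` or
#'   `"no_enriched_pathways"`), and `signatures`.
#' @export
run_baseline <- function(method = c("full", "seedKS", "subnetKS", "seedPathKS"),
                         disease, instances, network = NULL, seeds = NULL,
                         db = NULL, cutoff = 0.1, p_max = 0.001, min_count = 5,
                         ease = FALSE, q = NULL, normalize_pathways = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(disease, "DiseaseSignature"))

  deg_sets <- function(up, down) {
    if (!is.null(q)) {
      up <- up[seq_len(min(q, length(up)))]
      # down_set is in descending-logFC order; strongest down genes are last
      down <- rev(rev(down)[seq_len(min(q, length(down)))])
    }
    list(up = up, down = down)
  }
  whole_sig <- function(up, down, id) {
    structure(list(pathway_id = id, up_genes = up, down_genes = down),
              class = "PathwaySignature")
  }

  sigs <- switch(method,
    full = {
      if (is.null(network) || is.null(seeds) || is.null(db)) {
        stop("'full' needs network, seeds and db", call. = FALSE)
      }
      sub <- extract_subnetwork(network, seeds, cutoff)
      hits <- enrich(sub$nodes, db, p_max = p_max, min_count = min_count, ease = ease)
      if (nrow(hits) == 0) list() else build_signatures(hits, db, disease)
    },
    seedKS = {
      s <- deg_sets(disease$up_set, disease$down_set)
      list(whole_sig(s$up, s$down, "disease_DEGs"))
    },
    subnetKS = {
      if (is.null(network) || is.null(seeds)) {
        stop("'subnetKS' needs network and seeds", call. = FALSE)
      }
      sub <- extract_subnetwork(network, seeds, cutoff)
      list(whole_sig(intersect(disease$up_set, sub$nodes),
                     intersect(disease$down_set, sub$nodes),
                     "subnetwork_DEGs"))
    },
    seedPathKS = {
      if (is.null(db)) stop("'seedPathKS' needs db", call. = FALSE)
      s <- deg_sets(disease$up_set, disease$down_set)
      hits <- enrich(c(s$up, s$down), db, p_max = p_max, min_count = min_count, ease = ease)
      if (nrow(hits) == 0) list() else build_signatures(hits, db, disease)
    }
  )

  if (length(sigs) == 0) {
    return(list(method = method, results = list(),
                status = "no_enriched_pathways", signatures = list()))
  }
  list(method = method,
       results = score_drugs(instances, sigs, normalize_pathways = normalize_pathways),
       status = "ok",
       signatures = sigs)
}
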