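#' Intersect a gene set with a drug profile and take drug-list positions
#'
#' The m genes common to the query set and the drug's ranked list are
#' re-ranked by descending differential expression under the drug (the same
#' order as the drug list), and their 1-based positions in the full drug list
#' are returned. Because the common genes are taken in drug-list order the
#' position vector is strictly increasing.
#'
#' @param gene_set Character vector of query genes.
#' @param instance A `DrugInstanceProfile`.
#' @return A `KSInput`: list with `m`, `positions` (increasing integer
#'   vector), `n` (drug list length).
#' @export
intersect_and_rerank <- function(gene_set, instance) {
  stopifnot(inherits(instance, "DrugInstanceProfile"))
  n <- length(instance$ranked_genes)
  hit <- instance$ranked_genes %in% gene_set
  positions <- which(hit)
  structure(list(m = length(positions), positions = positions, n = n),
            class = "KSInput")
}

#' Kolmogorov-Smirnov-style connectivity score of a position set
#'
#' For m query-gene positions V(1) < ... < V(m) in a drug list of n genes,
#' computes
#' \deqn{a = \max_{p=1..m} (p/m - V(p)/n), \quad
#'       b = \max_{p=1..m} (V(p)/n - (p-1)/m)}
#' and returns `a` if `a > b`, `-b` if `a < b`, and 0 on a tie (within 1e-12,
#' the null-connectivity convention) or when m = 0. A score near +1 means the
#' query genes sit at the top of the drug list (most upregulated by the
#' drug); near -1, at the bottom.
#'
#' @param input A `KSInput` from [intersect_and_rerank()].
#' @return The connectivity score, in \[-1, 1\].
#' @export
ks_score <- function(input) {
  stopifnot(inherits(input, "KSInput"))
  m <- input$m
  n <- input$n
  if (m == 0) return(0)
  v <- as.numeric(input$positions)
  if (any(v < 1 | v > n)) stop("drug-list position outside [1, n]", call. = FALSE)
  if (is.unsorted(v, strictly = TRUE)) stop("positions must be strictly increasing", call. = FALSE)
  p <- seq_len(m)
  a <- max(p / m - v / n)
  b <- max(v / n - (p - 1) / m)
  if (abs(a - b) <= 1e-12) 0 else if (a > b) a else -b
}

#' Connectivity score of one pathway signature against one drug instance
#'
#' cs_up and cs_down are the KS connectivity scores of the signature's up-
#' and downregulated gene lists against the drug list; cs = cs_up - cs_down.
#' An empty up or down list contributes 0 to its component, and a constant
#' instance profile (all differential values identical, e.g. all zero) carries
#' no ranking information, so both components are set to the null connectivity
#' 0. A strongly negative cs (up genes at the drug's bottom, down genes at its
#' top) is the therapeutic, signature-reversing pattern.
#'
#' @param sig A `PathwaySignature`.
#' @param instance A `DrugInstanceProfile`.
#' @return A `ConnectivityRecord`: list with `pathway_id`, `instance_id`,
#'   `cs_up`, `cs_down`, `cs`.
#' @export
score_instance <- function(sig, instance) {
  stopifnot(inherits(sig, "PathwaySignature"), inherits(instance, "DrugInstanceProfile"))
  if (length(instance$values) > 0 && length(unique(instance$values)) == 1) {
    # no differential signal: the ranking is an artifact of tie-breaking
    cs_up <- cs_down <- 0
  } else {
    cs_up <- ks_score(intersect_and_rerank(sig$up_genes, instance))
    cs_down <- ks_score(intersect_and_rerank(sig$down_genes, instance))
  }
  structure(list(
    pathway_id = sig$pathway_id,
    instance_id = instance$instance_id,
    cs_up = cs_up,
    cs_down = cs_down,
    cs = cs_up - cs_down
  ), class = "ConnectivityRecord")
}

#' Therapeutic score of one drug across its instances and all signatures
#'
#' TS = (1/k) * sum over pathways i and instances j of CS(i, j): the
#' connectivity scores are averaged over the k instances of the drug but
#' summed over pathways, so TS magnitude grows with the number of pathway
#' signatures. `normalize_pathways = TRUE` divides additionally by the number
#' of signatures, off by default.
#'
#' @param instances List of `DrugInstanceProfile` objects, all of one drug
#'   (k = length).
#' @param sigs List of `PathwaySignature` objects.
#' @param normalize_pathways Also average over pathways (default `FALSE`).
#' @return A `TherapeuticResult`: list with `drug_name`, `k`, `ts`, `records`
#'   (data frame of per-(pathway, instance) components).
#' @export
therapeutic_score <- function(instances, sigs, normalize_pathways = FALSE) {
  if (length(instances) == 0) stop("a drug needs at least one instance", call. = FALSE)
  if (length(sigs) == 0) stop("at least one pathway signature is required", call. = FALSE)
  drug <- unique(vapply(instances, `[[`, character(1), "drug_name"))
  if (length(drug) != 1) {
    stop("therapeutic_score expects instances of a single drug, got: ",
         paste(drug, collapse = ", "), call. = FALSE)
  }
  k <- length(instances)
  recs <- vector("list", k * length(sigs))
  idx <- 1L
  for (sig in sigs) {
    for (inst in instances) {
      recs[[idx]] <- score_instance(sig, inst)
      idx <- idx + 1L
    }
  }
  records <- data.frame(
    pathway_id = vapply(recs, `[[`, character(1), "pathway_id"),
    instance_id = vapply(recs, `[[`, character(1), "instance_id"),
    cs_up = vapply(recs, `[[`, numeric(1), "cs_up"),
    cs_down = vapply(recs, `[[`, numeric(1), "cs_down"),
    cs = vapply(recs, `[[`, numeric(1), "cs"),
    stringsAsFactors = FALSE
  )
  ts <- sum(records$cs) / k
  if (normalize_pathways) ts <- ts / length(sigs)
  structure(list(drug_name = drug, k = k, ts = ts, records = records),
            class = "TherapeuticResult")
}

#' @export
print.TherapeuticResult <- function(x, ...) {
  cat(sprintf("TherapeuticResult '%s': k = %d, TS = %.4f\n", x$drug_name, x$k, x$ts))
  invisible(x)
}

#' Score every drug in an instance library against pathway signatures
#'
#' Groups instances by drug and applies [therapeutic_score()] to each group.
#'
#' @param instances List of `DrugInstanceProfile` objects (any drugs).
#' @param sigs List of `PathwaySignature` objects.
#' @param normalize_pathways Passed to [therapeutic_score()].
#' @return List of `TherapeuticResult`, one per drug, in alphabetical drug
#'   order.
#' @export
score_drugs <- function(instances, sigs, normalize_pathways = FALSE) {
  drugs <- vapply(instances, `[[`, character(1), "drug_name")
  by_drug <- split(instances, drugs)
  lapply(by_drug[order(names(by_drug))], therapeutic_score,
         sigs = sigs, normalize_pathways = normalize_pathways)
}

#' Drug-drug connectivity via one drug's profile as the signature
#'
#' Treats drug A's own differential profile as a single disease-like
#' signature (up = genes with positive values, down = negative, each ordered
#' by descending value) and computes the TS-style score of drug B's instances
#' against it: the average over B's instances of cs_up - cs_down. Positive
#' scores mean similar action; negative, opposite action.
#'
#' @param reference_instance A `DrugInstanceProfile` of drug A providing the
#'   reference up/down sets.
#' @param target_instances List of `DrugInstanceProfile` objects of drug B.
#' @return The average connectivity score.
#' @export
drug_drug_score <- function(reference_instance, target_instances) {
  stopifnot(inherits(reference_instance, "DrugInstanceProfile"))
  if (length(target_instances) == 0) stop("target drug has no instances", call. = FALSE)
  vals <- reference_instance$values
  sig <- structure(list(
    pathway_id = paste0("drug:", reference_instance$drug_name),
    up_genes = names(vals)[vals > 0],
    down_genes = names(vals)[vals < 0]
  ), class = "PathwaySignature")
  mean(vapply(target_instances, function(inst) score_instance(sig, inst)$cs, numeric(1)))
}
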