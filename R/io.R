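#' Read a tab-separated table, skipping '#' comment lines
#'
#' All pipeline files share one dialect: tab-separated, UTF-8, lines starting
#' with '#' ignored.
#' @noRd
read_tsv_strict <- function(path, header = TRUE, col.names = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  args <- list(
    file = path, sep = "\t", header = header, comment.char = "#",
    stringsAsFactors = FALSE, quote = "", check.names = FALSE,
    fileEncoding = "UTF-8", blank.lines.skip = TRUE
  )
  if (!is.null(col.names) && !header) args$col.names <- col.names
  do.call(utils::read.delim, args)
}

#' Read a disease expression matrix with phenotype labels
#'
#' Reads a gene-by-sample expression TSV (gene ids in the first column, sample
#' ids in the header) together with a phenotype table assigning every sample to
#' the `tumor` or `control` group. Rows sharing a gene id are collapsed by
#' averaging their expression values; rows with a blank gene id are dropped.
#'
#' @param path Path to the expression TSV.
#' @param phenotype_path Path to a phenotype TSV with columns `sample_id` and
#'   `group` (values `tumor` or `control`).
#' @return An `ExpressionMatrix`: a list with `values` (numeric gene x sample
#'   matrix) and `groups` (the phenotype data frame).
#' @export
read_expression <- function(path, phenotype_path) {
  pheno <- read_phenotype(phenotype_path)
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2) stop("expression file needs a gene column and >=1 sample column", call. = FALSE)
  gene_ids <- as.character(tab[[1]])
  samples <- colnames(tab)[-1]

  missing <- setdiff(samples, pheno$sample_id)
  if (length(missing) > 0) {
    stop("sample(s) in expression header absent from phenotype table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2, as.numeric))) &
                   !is.na(tab[, -1, drop = FALSE]), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                   gene_ids[bad[1, 1]], samples[bad[1, 2]]), call. = FALSE)
    }
    stop("non-numeric expression values", call. = FALSE)
  }
  if (anyNA(vals)) stop("missing expression values are not allowed", call. = FALSE)

  keep <- !is.na(gene_ids) & nzchar(trimws(gene_ids))
  vals <- vals[keep, , drop = FALSE]
  gene_ids <- trimws(gene_ids[keep])
  if (nrow(vals) == 0) stop("no usable gene rows in expression file", call. = FALSE)

  # probes mapping to the same gene are averaged
  if (anyDuplicated(gene_ids)) {
    vals <- rowsum(vals, group = gene_ids) / as.vector(table(gene_ids)[sort(unique(gene_ids))])
    gene_ids <- rownames(vals)
  }
  ord <- order(gene_ids)
  vals <- vals[ord, , drop = FALSE]
  rownames(vals) <- gene_ids[ord]

  pheno <- pheno[pheno$sample_id %in% samples, , drop = FALSE]
  new_expression_matrix(vals, pheno)
}

read_phenotype <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(tab))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab$group <- as.character(tab$group)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in phenotype table", call. = FALSE)
  if (!all(tab$group %in% c("tumor", "control"))) {
    stop("phenotype group must be 'tumor' or 'control'", call. = FALSE)
  }
  if (!all(c("tumor", "control") %in% tab$group)) {
    stop("phenotype table needs at least one sample per group", call. = FALSE)
  }
  tab[, need]
}

new_expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (!all(colnames(values) %in% groups$sample_id)) {
    stop("every sample must have a phenotype group", call. = FALSE)
  }
  structure(list(values = values, groups = groups), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  grp <- table(x$groups$group[match(colnames(x$values), x$groups$sample_id)])
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", grp, names(grp)), collapse = ", ")))
  invisible(x)
}

#' Read a GMT pathway gene-set file
#'
#' Standard GMT: one pathway per line with name, description, then member
#' genes, tab-separated. Duplicate members within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @param background Optional character vector of gene ids to use as the
#'   enrichment universe instead of the union of all pathway members.
#' @return A `PathwayDB`: list with `pathways` (named list of character
#'   vectors) and `universe` (character vector).
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(new_pathway_db(list(), background %||% character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields", call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop("duplicate pathway name in GMT: ", names_[duplicated(names_)][1], call. = FALSE)
  }
  pathways <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(pathways) <- names_
  new_pathway_db(pathways, background)
}

new_pathway_db <- function(pathways, background = NULL) {
  if (any(lengths(pathways) == 0)) stop("empty pathway in database", call. = FALSE)
  universe <- sort(unique(c(unlist(pathways, use.names = FALSE), background)))
  structure(list(pathways = pathways, universe = universe), class = "PathwayDB")
}

#' @export
print.PathwayDB <- function(x, ...) {
  cat(sprintf("PathwayDB: %d pathways, %d genes in universe\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a weighted tissue interaction network
#'
#' Edge-list TSV with columns `gene_a`, `gene_b`, `confidence` (in \[0, 1\]).
#' The network is undirected: a duplicate edge in either orientation keeps the
#' maximum confidence; self-loops are dropped with a warning.
#'
#' @param path Path to the edge-list TSV.
#' @return A `TissueNetwork`: a data frame of unique undirected edges with the
#'   endpoint columns in canonical (sorted) order.
#' @export
read_network <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("gene_a", "gene_b", "confidence")
  if (!all(need %in% colnames(tab))) {
    stop("network file must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  new_tissue_network(data.frame(
    gene_a = as.character(tab$gene_a),
    gene_b = as.character(tab$gene_b),
    confidence = as.numeric(tab$confidence),
    stringsAsFactors = FALSE
  ))
}

new_tissue_network <- function(edges) {
  if (anyNA(edges$confidence)) stop("non-numeric confidence in network", call. = FALSE)
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("network confidence outside [0, 1]", call. = FALSE)
  }
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from network", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical orientation, then max confidence per unordered pair
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(edges$confidence, key, max)
  keys <- strsplit(names(conf), "\r", fixed = TRUE)
  out <- data.frame(
    gene_a = vapply(keys, `[[`, character(1), 1),
    gene_b = vapply(keys, `[[`, character(1), 2),
    confidence = as.numeric(conf),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("TissueNetwork", "data.frame"))
}

#' Read drug perturbation instance profiles
#'
#' Each instance is one drug-treatment expression profile stored as a
#' two-column TSV (`gene`, `value` = differential expression under the drug).
#' The manifest maps instance ids to drug names. Genes are ranked descending by
#' value (rank 1 = most upregulated under the drug), ties broken
#' lexicographically by gene id.
#'
#' @param profile_dir Directory containing `<instance_id>.tsv` files.
#' @param manifest_path Manifest TSV with columns `instance_id`, `drug_name`
#'   and optionally `cell_line`.
#' @return A list of `DrugInstanceProfile` objects.
#' @export
read_drug_instances <- function(profile_dir, manifest_path) {
  man <- read_tsv_strict(manifest_path)
  need <- c("instance_id", "drug_name")
  if (!all(need %in% colnames(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(man) == 0) {
    warning("empty instance manifest", call. = FALSE)
    return(list())
  }
  man$instance_id <- as.character(man$instance_id)
  man$drug_name <- as.character(man$drug_name)
  if (anyDuplicated(man$instance_id)) stop("duplicate instance ids in manifest", call. = FALSE)

  lapply(seq_len(nrow(man)), function(i) {
    id <- man$instance_id[i]
    f <- file.path(profile_dir, paste0(id, ".tsv"))
    if (!file.exists(f)) stop("instance file missing for manifest entry '", id, "': ", f, call. = FALSE)
    tab <- read_tsv_strict(f)
    if (!all(c("gene", "value") %in% colnames(tab))) {
      stop("instance file ", f, " must have columns gene, value", call. = FALSE)
    }
    genes <- as.character(tab$gene)
    if (anyDuplicated(genes)) {
      stop("duplicate gene '", genes[duplicated(genes)][1], "' in instance ", id, call. = FALSE)
    }
    vals <- as.numeric(tab$value)
    if (anyNA(vals)) stop("non-numeric value in instance ", id, call. = FALSE)
    new_drug_instance(id, man$drug_name[i], stats::setNames(vals, genes),
                      cell_line = if ("cell_line" %in% colnames(man)) as.character(man$cell_line[i]) else NA_character_)
  })
}

#' Construct a drug instance profile from named differential values
#'
#' @param instance_id,drug_name Identifiers.
#' @param values Named numeric vector of differential expression values.
#' @param cell_line Optional cell line annotation.
#' @return A `DrugInstanceProfile` with genes ranked descending by value,
#'   ties broken lexicographically (rank 1 = most upregulated).
#' @export
new_drug_instance <- function(instance_id, drug_name, values, cell_line = NA_character_) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (anyDuplicated(names(values))) stop("duplicate gene in instance ", instance_id, call. = FALSE)
  ord <- order(-values, names(values), method = "radix")
  values <- values[ord]
  structure(list(
    instance_id = instance_id,
    drug_name = drug_name,
    cell_line = cell_line,
    ranked_genes = names(values),
    values = values
  ), class = "DrugInstanceProfile")
}

#' @export
print.DrugInstanceProfile <- function(x, ...) {
  cat(sprintf("DrugInstanceProfile '%s' (drug '%s'): %d ranked genes\n",
              x$instance_id, x$drug_name, length(x$ranked_genes)))
  invisible(x)
}

#' Read a benchmark of known drug-disease associations
#'
#' TSV with columns `drug_name` and `evidence`; evidence codes are `M`
#' (marker/mechanism), `T` (therapeutic), `M&T`, `inferred`, or `NA` (no
#' association). Lookups for drugs absent from the table return `"NA"`.
#' Drug names are matched case-insensitively after trimming.
#'
#' @param path Path to the benchmark TSV.
#' @return A `Benchmark` object.
#' @export
read_benchmark <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("drug_name", "evidence")
  if (!all(need %in% colnames(tab))) {
    stop("benchmark must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  new_benchmark(stats::setNames(as.character(tab$evidence), as.character(tab$drug_name)))
}

#' Construct a benchmark from a named evidence vector
#' @param evidence Named character vector: names are drug names, values are
#'   evidence codes in `M`, `T`, `M&T`, `inferred`, `NA`.
#' @export
new_benchmark <- function(evidence) {
  codes <- c("M", "T", "M&T", "inferred", "NA")
  evidence[is.na(evidence)] <- "NA"
  if (!all(evidence %in% codes)) {
    stop("benchmark evidence must be one of: ", paste(codes, collapse = ", "), call. = FALSE)
  }
  names(evidence) <- tolower(trimws(names(evidence)))
  if (anyDuplicated(names(evidence))) stop("duplicate drug in benchmark", call. = FALSE)
  structure(list(evidence = evidence), class = "Benchmark")
}

#' Look up benchmark evidence for drug names
#' @param bench A `Benchmark`.
#' @param drugs Character vector of drug names.
#' @return Character vector of evidence codes (`"NA"` for absent drugs).
#' @export
benchmark_evidence <- function(bench, drugs) {
  stopifnot(inherits(bench, "Benchmark"))
  out <- unname(bench$evidence[tolower(trimws(drugs))])
  out[is.na(out)] <- "NA"
  out
}

#' Read a seed gene list (one gene id per line)
#' @param path Path to the text file.
#' @return Character vector of unique gene ids.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) stop("empty seed gene list: ", path, call. = FALSE)
  unique(x)
}

#' Write the ranked drug table
#'
#' Writes a TSV with columns `rank`, `drug_name`, `k`, `TS`, `abs_TS`,
#' `evidence`, ordered by descending absolute therapeutic score (ties broken
#' by drug name). The evidence column is `"NA"` throughout when no benchmark
#' is given.
#'
#' @param results List of `TherapeuticResult` objects (see
#'   [therapeutic_score()]).
#' @param benchmark A `Benchmark` or `NULL`.
#' @param path Output path.
#' @return The written data frame, invisibly.
#' @export
write_ranked_drugs <- function(results, benchmark = NULL, path) {
  tab <- rank_drugs(results)
  tab$evidence <- if (is.null(benchmark)) "NA" else benchmark_evidence(benchmark, tab$drug_name)
  out <- data.frame(
    rank = tab$rank, drug_name = tab$drug_name, k = tab$k,
    TS = tab$ts, abs_TS = tab$abs_ts, evidence = tab$evidence,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
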