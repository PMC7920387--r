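#' Build tissue-specific pathway signatures
#'
#' For each enriched pathway, takes the pathway members present in the disease
#' signature, splits them by the disease up/down partition, and orders each
#' list by the disease ranking (descending logFC). Pathway members absent from
#' the expression data are excluded; pathways with no member in the disease
#' signature are dropped with a warning.
#'
#' @param pathways Character vector of pathway ids, or an enrichment data
#'   frame from [enrich()] (its `pathway_id` column is used).
#' @param db A `PathwayDB`.
#' @param disease A `DiseaseSignature`.
#' @return A list of `PathwaySignature` objects: each a list with
#'   `pathway_id`, `up_genes`, `down_genes` (both in disease rank order).
#' @export
build_signatures <- function(pathways, db, disease) {
  stopifnot(inherits(db, "PathwayDB"), inherits(disease, "DiseaseSignature"))
  if (is.data.frame(pathways)) pathways <- pathways$pathway_id
  pathways <- as.character(pathways)
  missing <- setdiff(pathways, names(db$pathways))
  if (length(missing) > 0) {
    stop("pathway id(s) not in database: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rank_of <- stats::setNames(seq_along(disease$ranked_genes), disease$ranked_genes)
  sigs <- lapply(pathways, function(pid) {
    members <- intersect(db$pathways[[pid]], disease$ranked_genes)
    if (length(members) == 0) return(NULL)
    members <- members[order(rank_of[members])]
    structure(list(
      pathway_id = pid,
      up_genes = members[members %in% disease$up_set],
      down_genes = members[members %in% disease$down_set]
    ), class = "PathwaySignature")
  })
  dropped <- pathways[vapply(sigs, is.null, logical(1))]
  if (length(dropped) > 0) {
    warning("pathway(s) with no gene in the disease signature dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  Filter(Negate(is.null), sigs)
}

#' @export
print.PathwaySignature <- function(x, ...) {
  cat(sprintf("PathwaySignature '%s': %d up, %d down\n",
              x$pathway_id, length(x$up_genes), length(x$down_genes)))
  invisible(x)
}

#' Write pathway signatures as two-column TSVs (gene, direction)
#' @param sigs List of `PathwaySignature` objects.
#' @param dir Output directory; one `<pathway_id>.tsv` per signature.
#' @export
write_signatures <- function(sigs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in sigs) {
    out <- data.frame(
      gene = c(s$up_genes, s$down_genes),
      direction = c(rep("up", length(s$up_genes)), rep("down", length(s$down_genes))),
      stringsAsFactors = FALSE
    )
    utils::write.table(out, file.path(dir, paste0(s$pathway_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(sigs)
}
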