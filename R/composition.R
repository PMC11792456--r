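#' Aggregate community composition at a taxonomic rank
#'
#' Collapses an OTU table to the `top_k` taxa at a given rank (ranked by
#' overall mean relative abundance across all samples, so every group shares
#' one taxon set) plus an `"Others"` bucket, and reports per-group relative
#' abundances. Grouping is by any metadata column, typically `site` or
#' `season`.
#'
#' @param otu Wide OTU tibble.
#' @param taxonomy Tibble with `otu_id` and rank columns
#'   (e.g. `kingdom` ... `species`).
#' @param metadata Sample metadata (see [read_metadata()]).
#' @param rank Taxonomic rank column to aggregate at (default `"phylum"`).
#' @param top_k Number of named taxa to keep (default 10).
#' @param by Metadata column defining groups (default `"site"`).
#' @param weight `"reads"` (proportions of reads, default) or `"otus"`
#'   (proportions of OTU richness).
#' @return A tibble with columns `group`, `taxon`, `rel_abundance`; within
#'   each group the abundances sum to 1.
#' @export
aggregate_composition <- function(otu, taxonomy, metadata, rank = "phylum",
                                  top_k = 10, by = "site",
                                  weight = c("reads", "otus")) {
  weight <- match.arg(weight)
  if (top_k < 1) abort("top_k must be >= 1.")
  taxonomy <- as_tibble(taxonomy)
  if (!rank %in% names(taxonomy)) {
    abort(paste0("Rank '", rank, "' not present in taxonomy table."))
  }
  metadata <- validate_metadata(metadata, otu)
  if (!by %in% names(metadata)) {
    abort(paste0("Grouping column '", by, "' not present in metadata."))
  }
  m <- otu_counts(otu)
  lineage <- taxonomy[[rank]][match(rownames(m), taxonomy$otu_id)]
  if (any(is.na(lineage))) {
    abort(paste0("OTU(s) missing from taxonomy: ",
                 paste(head(rownames(m)[is.na(lineage)], 5), collapse = ", ")))
  }
  if (weight == "otus") m <- (m > 0) * 1

  rel <- sweep(m, 2, colSums(m), "/")
  overall <- tapply(rowMeans(rel), lineage, sum)
  top <- names(sort(overall, decreasing = TRUE))[seq_len(min(top_k, length(overall)))]

  groups <- metadata[[by]][match(colnames(m), metadata$sample_id)]
  taxon <- ifelse(lineage %in% top, lineage, "Others")
  out <- purrr::map_dfr(unique(groups), function(g) {
    sub <- m[, groups == g, drop = FALSE]
    tot <- tapply(rowSums(sub), taxon, sum)
    tot <- tot / sum(tot)
    lv <- c(top, if ("Others" %in% names(tot)) "Others")
    tibble(group = g, taxon = factor(lv, levels = lv),
           rel_abundance = as.numeric(tot[lv]))
  })
  out$rel_abundance[is.na(out$rel_abundance)] <- 0
  out
}

#' Stacked-bar plot of a composition summary
#'
#' @param x Output of [aggregate_composition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_composition <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$group, y = .data$rel_abundance,
                                  fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative abundance", fill = NULL) +
    ggplot2::theme_minimal()
}
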