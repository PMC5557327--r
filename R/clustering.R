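#' Detect chromosomal gene clusters of a family
#'
#' A cluster is a maximal run of two or more family genes on one chromosome
#' whose consecutive genomic distances are all strictly below `max_gap_bp`
#' (10 kb by default). Family genes are sorted by start per chromosome and
#' chained transitively; singletons are not clusters. Intervening non-family
#' genes do not break a cluster — the rule is positional within the family.
#'
#' @param family_genes gene-model data.frame (any subset of an annotation);
#'   must carry `chromosome`, `start`, `end`.
#' @param max_gap_bp strict distance threshold in bp, default 10000.
#' @param gap_mode `"intergenic"` (default): distance between neighbours is
#'   `max(0, next_start - prev_end - 1)`, clamped at 0 for overlapping genes;
#'   `"start"`: start-to-start distance, for sensitivity analysis.
#' @return data.frame, one row per cluster: `cluster_id`, `chromosome`,
#'   `span_start`, `span_end`, `size`, `member_ids` (comma-separated, in
#'   start order). Ordered by chromosome then span start.
#' @export
detect_clusters <- function(family_genes, max_gap_bp = 10000,
                            gap_mode = c("intergenic", "start")) {
  gap_mode <- match.arg(gap_mode)
  need <- c("gene_id", "chromosome", "start", "end")
  if (!all(need %in% names(family_genes))) {
    stop("family_genes must have columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(family_genes$start) || anyNA(family_genes$end)) {
    stop("genes lacking coordinates")
  }
  out <- list()
  for (chrom in sort(unique(family_genes$chromosome))) {
    g <- family_genes[family_genes$chromosome == chrom, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    if (nrow(g) < 2) next
    gap <- if (gap_mode == "intergenic") {
      pmax(0, g$start[-1] - g$end[-nrow(g)] - 1)
    } else {
      g$start[-1] - g$start[-nrow(g)]
    }
    linked <- gap < max_gap_bp
    run_id <- cumsum(c(TRUE, !linked))
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      if (length(idx) < 2) next
      out[[length(out) + 1]] <- data.frame(
        chromosome = chrom,
        span_start = min(g$start[idx]),
        span_end = max(g$end[idx]),
        size = length(idx),
        member_ids = paste(g$gene_id[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(cluster_id = character(0), chromosome = character(0),
                      span_start = numeric(0), span_end = numeric(0),
                      size = integer(0), member_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$span_start), , drop = FALSE]
  res <- cbind(cluster_id = sprintf("cluster_%03d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Census of a cluster set
#'
#' Reproduces the family-census columns: cluster count, clusters with more
#' than two members, clustered-gene count and the clustered fraction of the
#' family total (percent, rounded half-up to two decimals).
#'
#' @param clusters data.frame from [detect_clusters()].
#' @param family_total total family size (`>=` clustered genes, `> 0`).
#' @return one-row data.frame: `n_clusters`, `n_clusters_gt2`,
#'   `n_clustered_genes`, `fraction_clustered`.
#' @export
cluster_summary <- function(clusters, family_total) {
  if (!is.numeric(family_total) || family_total <= 0) {
    stop("family_total must be > 0")
  }
  n_genes <- sum(clusters$size)
  if (family_total < n_genes) {
    stop("family_total (", family_total, ") smaller than clustered genes (",
         n_genes, ")")
  }
  data.frame(n_clusters = nrow(clusters),
             n_clusters_gt2 = sum(clusters$size > 2),
             n_clustered_genes = n_genes,
             fraction_clustered = round_half_up(100 * n_genes / family_total, 2))
}
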