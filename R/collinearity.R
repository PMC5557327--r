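# Collinear-block chaining and duplicate-gene classification.
#
# Homolog pairs become anchors in (rank_A, rank_B) space per chromosome
# pair; a maximum-weight rank-monotone chain (weight = anchor count) is
# extracted by dynamic programming, its anchors removed, and the extraction
# repeated — a greedy iterated best-chain approximation to MCScanX-style
# block finding. Genes are then classified by the standard precedence:
# WGD/segmental > tandem > proximal > dispersed > singleton.

DUPLICATION_CLASSES <- c("wgd_segmental", "tandem", "proximal",
                         "dispersed", "singleton")

# chain comparator: longer wins; then lexicographically smaller
# (rank_A, rank_B) sequence (implies earlier rank_A start); then parallel
# before antiparallel. Returns TRUE if chain x beats chain y.
#' @keywords internal
chain_better <- function(x, y) {
  if (is.null(y)) return(TRUE)
  if (is.null(x)) return(FALSE)
  if (length(x$ra) != length(y$ra)) return(length(x$ra) > length(y$ra))
  vx <- as.vector(rbind(x$ra, x$rb))
  vy <- as.vector(rbind(y$ra, y$rb))
  d <- which(vx != vy)
  if (length(d)) return(vx[d[1]] < vy[d[1]])
  x$orientation == "parallel" && y$orientation != "parallel"
}

# best chain among anchors (ra, rb vectors) for one orientation by DP.
# Step rule: 0 < delta(rank_A) <= max_gap and the rank_B step in the
# orientation's direction with 0 < |delta| <= max_gap.
#' @keywords internal
best_chain_dp <- function(ra, rb, orientation, max_gap) {
  n <- length(ra)
  if (!n) return(NULL)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  dir <- if (orientation == "parallel") 1 else -1
  chains <- vector("list", n)
  for (j in seq_len(n)) {
    best_pred <- NULL
    for (i in seq_len(j - 1)) {
      da <- ra[j] - ra[i]
      db <- dir * (rb[j] - rb[i])
      if (da > 0 && da <= max_gap && db > 0 && db <= max_gap) {
        if (chain_better(chains[[i]], best_pred)) best_pred <- chains[[i]]
      }
    }
    chains[[j]] <- if (is.null(best_pred)) {
      list(ra = ra[j], rb = rb[j], idx = ord[j], orientation = orientation)
    } else {
      list(ra = c(best_pred$ra, ra[j]), rb = c(best_pred$rb, rb[j]),
           idx = c(best_pred$idx, ord[j]), orientation = orientation)
    }
  }
  best <- NULL
  for (j in seq_len(n)) {
    if (chain_better(chains[[j]], best)) best <- chains[[j]]
  }
  best
}

#' Chain homolog anchors into collinear blocks
#'
#' Per chromosome pair and orientation, anchors are chained by dynamic
#' programming under the rank-gap rule (consecutive anchors at most
#' `max_gap_ranks` apart on both chromosomes, strictly monotone); the
#' heaviest chain (most anchors) is reported as a block when it reaches
#' `min_anchors`, its anchors are removed, and extraction repeats. Ties are
#' broken towards the earlier rank-A start, then parallel orientation.
#'
#' @param pairs homolog-pair data.frame (`gene_a`, `gene_b`; see
#'   [homolog_pairs()]); every id must exist in `annotation`.
#' @param annotation full gene-model data.frame (ranks are full-annotation
#'   ranks).
#' @param max_gap_ranks maximum rank gap between consecutive anchors,
#'   default 25.
#' @param min_anchors minimum anchors per reported block, default 5.
#' @return data.frame, one row per block: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_anchors`, `anchor_pairs` (`"geneA|geneB"` entries
#'   separated by `";"`, in chain order).
#' @export
chain_anchors <- function(pairs, annotation, max_gap_ranks = 25,
                          min_anchors = 5) {
  empty <- data.frame(block_id = character(0), chrom_a = character(0),
                      chrom_b = character(0), orientation = character(0),
                      n_anchors = integer(0), anchor_pairs = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  unknown <- setdiff(c(pairs$gene_a, pairs$gene_b), annotation$gene_id)
  if (length(unknown)) {
    stop("homolog pair references unknown gene: ", unknown[1])
  }
  look <- annotation[match(c(pairs$gene_a, pairs$gene_b),
                           annotation$gene_id), ]
  n <- nrow(pairs)
  a <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                  chrom_a = look$chromosome[1:n],
                  rank_a = look$rank[1:n],
                  chrom_b = look$chromosome[(n + 1):(2 * n)],
                  rank_b = look$rank[(n + 1):(2 * n)],
                  stringsAsFactors = FALSE)
  # canonical orientation of each anchor: (chrom_a, rank_a) is the smaller end
  swap <- (a$chrom_a > a$chrom_b) |
    (a$chrom_a == a$chrom_b & a$rank_a > a$rank_b)
  a[swap, c("gene_a", "gene_b", "chrom_a", "rank_a", "chrom_b", "rank_b")] <-
    a[swap, c("gene_b", "gene_a", "chrom_b", "rank_b", "chrom_a", "rank_a")]
  blocks <- list()
  keys <- unique(paste(a$chrom_a, a$chrom_b, sep = "\r"))
  for (key in sort(keys)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- a[a$chrom_a == parts[1] & a$chrom_b == parts[2], , drop = FALSE]
    repeat {
      cand_par <- best_chain_dp(g$rank_a, g$rank_b, "parallel", max_gap_ranks)
      cand_anti <- best_chain_dp(g$rank_a, g$rank_b, "antiparallel",
                                 max_gap_ranks)
      best <- if (chain_better(cand_par, cand_anti)) cand_par else cand_anti
      if (is.null(best) || length(best$idx) < min_anchors) break
      rows <- g[best$idx, , drop = FALSE]
      blocks[[length(blocks) + 1]] <- data.frame(
        chrom_a = parts[1], chrom_b = parts[2],
        orientation = best$orientation,
        n_anchors = nrow(rows),
        anchor_pairs = paste(paste(rows$gene_a, rows$gene_b, sep = "|"),
                             collapse = ";"),
        stringsAsFactors = FALSE)
      g <- g[-best$idx, , drop = FALSE]
      if (!nrow(g)) break
    }
  }
  if (!length(blocks)) return(empty)
  res <- do.call(rbind, blocks)
  res <- cbind(block_id = sprintf("block_%03d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Genes anchoring any collinear block
#'
#' @param blocks data.frame from [chain_anchors()].
#' @return character vector of unique gene ids.
#' @export
block_anchor_genes <- function(blocks) {
  if (!nrow(blocks)) return(character(0))
  unique(unlist(strsplit(unlist(strsplit(blocks$anchor_pairs, ";",
                                         fixed = TRUE)),
                         "|", fixed = TRUE)))
}

#' Classify family genes by duplication type
#'
#' Precedence per gene: (1) `wgd_segmental` if the gene anchors any
#' collinear block; else (2) `tandem` if it has a homolog at the adjacent
#' full-annotation rank on the same chromosome; else (3) `proximal` if a
#' same-chromosome homolog lies within `proximal_window_ranks` ranks; else
#' (4) `dispersed` if it has any homolog at all; else (5) `singleton`.
#'
#' @param family_ids gene ids of the family under study.
#' @param pairs homolog-pair data.frame.
#' @param blocks collinear blocks from [chain_anchors()] (within-genome
#'   blocks for duplication typing).
#' @param annotation full gene-model data.frame.
#' @param proximal_window_ranks rank window for the proximal call, default 20.
#' @return data.frame `gene_id`, `class`.
#' @export
classify_duplicates <- function(family_ids, pairs, blocks, annotation,
                                proximal_window_ranks = 20) {
  family_ids <- as.character(family_ids)
  missing <- setdiff(family_ids, annotation$gene_id)
  if (length(missing)) stop("family gene not in annotation: ", missing[1])
  anchor_genes <- block_anchor_genes(blocks)
  chrom <- stats::setNames(annotation$chromosome, annotation$gene_id)
  rank <- stats::setNames(annotation$rank, annotation$gene_id)
  neigh <- split(c(pairs$gene_b, pairs$gene_a),
                 c(pairs$gene_a, pairs$gene_b))
  cls <- character(length(family_ids))
  for (i in seq_along(family_ids)) {
    g <- family_ids[i]
    if (g %in% anchor_genes) { cls[i] <- "wgd_segmental"; next }
    hom <- unique(neigh[[g]])
    if (is.null(hom) || !length(hom)) { cls[i] <- "singleton"; next }
    same <- hom[chrom[hom] == chrom[g]]
    drank <- abs(rank[same] - rank[g])
    if (length(drank) && any(drank == 1)) { cls[i] <- "tandem"; next }
    if (length(drank) && any(drank > 1 & drank <= proximal_window_ranks)) {
      cls[i] <- "proximal"; next
    }
    cls[i] <- "dispersed"
  }
  data.frame(gene_id = family_ids, class = cls, stringsAsFactors = FALSE)
}

#' Duplication-type census
#'
#' @param classification data.frame from [classify_duplicates()].
#' @return data.frame `class`, `count`, `percent` (half-up, 2 decimals),
#'   one row per duplication class in fixed order; counts sum to the family
#'   size.
#' @export
duplication_census <- function(classification) {
  if (!nrow(classification)) stop("empty family: nothing to census")
  counts <- table(factor(classification$class, levels = DUPLICATION_CLASSES))
  data.frame(class = DUPLICATION_CLASSES,
             count = as.integer(counts),
             percent = round_half_up(100 * as.integer(counts) /
                                       nrow(classification), 2),
             stringsAsFactors = FALSE)
}
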