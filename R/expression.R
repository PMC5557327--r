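# Expression divergence and coordination of duplicate genes.
#
# Divergence of a duplicate pair is 1 - r where r is the signed Pearson
# correlation of the two genes' RPKM profiles across developmental stages
# (anti-correlated duplicates are maximally divergent, divergence 2).
# Within-cluster coordination uses |r| with a t-distribution p-value, the
# convention of coordinated-expression tables.

#' Expression divergence of duplicate pairs
#'
#' Signed Pearson correlation across stages on the raw expression values;
#' divergence = 1 - r. Pairs with a zero-variance profile are skipped and
#' counted in the `skipped` attribute.
#'
#' @param matrix genes x stages expression matrix (rownames = gene ids,
#'   >= 3 stage columns).
#' @param pairs data.frame with `gene_a`, `gene_b`; both genes must be rows
#'   of `matrix`.
#' @param class_map optional data.frame `gene_id`, `class` (from
#'   [classify_duplicates()]); when given, each pair is annotated with its
#'   duplication class (the class shared by its genes, else the first
#'   gene's).
#' @param log2p1 apply `log2(x + 1)` before correlating, default FALSE.
#' @return data.frame `gene_a`, `gene_b`, `correlation`, `divergence`
#'   (and `duplication_class` when `class_map` is given), with attribute
#'   `skipped` (zero-variance pair count).
#' @export
expression_divergence <- function(matrix, pairs, class_map = NULL,
                                  log2p1 = FALSE) {
  if (ncol(matrix) < 3) stop("need >= 3 stages to correlate profiles")
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(matrix))
  if (length(missing)) {
    stop("gene absent from expression matrix: ", missing[1])
  }
  m <- if (log2p1) log2(matrix + 1) else matrix
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    x <- m[pairs$gene_a[i], ]; y <- m[pairs$gene_b[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      skipped <- skipped + 1L
      next
    }
    r <- stats::cor(x, y)
    rows[[length(rows) + 1]] <- data.frame(
      gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
      correlation = r, divergence = 1 - r, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               correlation = numeric(0), divergence = numeric(0),
               stringsAsFactors = FALSE)
  if (!is.null(class_map)) {
    cls <- stats::setNames(class_map$class, class_map$gene_id)
    ca <- unname(cls[res$gene_a]); cb <- unname(cls[res$gene_b])
    res$duplication_class <- ifelse(!is.na(ca), ca, cb)
  }
  if (skipped) {
    message("expression_divergence: skipped ", skipped,
            " zero-variance pair(s)")
  }
  attr(res, "skipped") <- skipped
  res
}

#' Divergence distribution by duplication class
#'
#' Summarises divergence per class (n, quartiles, median) and formats a
#' class ordering by descending median divergence, joining classes whose
#' medians differ by less than `tie_tol` with an approximately-equal sign.
#'
#' @param records data.frame from [expression_divergence()] carrying a
#'   `duplication_class` column.
#' @param tie_tol median difference below which classes are reported as
#'   approximately equal, default 0.05.
#' @return list with `summary` (data.frame `class`, `n`, `q1`, `median`,
#'   `q3`, ordered by descending median) and `ordering` (string such as
#'   `"singleton > tandem > wgd_segmental ~ proximal > dispersed"`, with
#'   U+2248 as the approximately-equal sign).
#' @export
divergence_by_class <- function(records, tie_tol = 0.05) {
  if (!nrow(records)) stop("no divergence records")
  if (is.null(records$duplication_class)) {
    stop("records lack a duplication_class column")
  }
  sp <- split(records$divergence, records$duplication_class)
  summ <- do.call(rbind, lapply(names(sp), function(cl) {
    q <- stats::quantile(sp[[cl]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(class = cl, n = length(sp[[cl]]), q1 = q[1], median = q[2],
               q3 = q[3], stringsAsFactors = FALSE)
  }))
  summ <- summ[order(-summ$median, summ$class), , drop = FALSE]
  rownames(summ) <- NULL
  sep <- character(0)
  if (nrow(summ) > 1) {
    gaps <- -diff(summ$median)
    sep <- ifelse(gaps < tie_tol, " ≈ ", " > ")
  }
  ordering <- paste0(summ$class,
                     c(sep, ""), collapse = "")
  list(summary = summ, ordering = ordering)
}

#' Coordinated expression within a gene cluster
#'
#' All within-cluster gene pairs are correlated across stages; the absolute
#' Pearson r is reported with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and
#' the star convention `*` (p < 0.05) / `**` (p < 0.01). Members absent from
#' the matrix are skipped and counted in the `skipped` attribute.
#'
#' @param member_ids gene ids of one cluster (>= 2 present in the matrix).
#' @param matrix genes x stages expression matrix, >= 3 stages.
#' @return data.frame `gene_a`, `gene_b`, `abs_r`, `p_value`, `stars`, with
#'   attribute `skipped`.
#' @export
coordinated_expression <- function(member_ids, matrix) {
  if (ncol(matrix) < 3) stop("need >= 3 stages to correlate profiles")
  member_ids <- as.character(member_ids)
  present <- member_ids[member_ids %in% rownames(matrix)]
  skipped <- length(member_ids) - length(present)
  if (skipped) {
    message("coordinated_expression: ", skipped,
            " member(s) absent from matrix, skipped")
  }
  if (length(present) < 2) {
    stop("fewer than 2 cluster members present in the expression matrix")
  }
  cmb <- utils::combn(present, 2)
  n <- ncol(matrix)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    x <- matrix[cmb[1, k], ]; y <- matrix[cmb[2, k], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(gene_a = cmb[1, k], gene_b = cmb[2, k],
                        abs_r = NA_real_, p_value = NA_real_, stars = "",
                        stringsAsFactors = FALSE))
    }
    r <- stats::cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
    }
    stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    data.frame(gene_a = cmb[1, k], gene_b = cmb[2, k],
               abs_r = abs(r), p_value = p, stars = stars,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "skipped") <- skipped
  res
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate threshold cycles are averaged per condition, then
#' `ddCt = (Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_calibrator - Ct_ref_calibrator)` and the fold change is
#' `2^-ddCt`.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   numeric vectors of replicate Ct values (finite, > 0; no missing
#'   replicates).
#' @return fold change (numeric scalar).
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator,
                                     ct_ref_calibrator) {
  cts <- list(ct_target_sample, ct_ref_sample, ct_target_calibrator,
              ct_ref_calibrator)
  for (ct in cts) {
    if (!length(ct) || anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0)) {
      stop("all Ct replicates must be finite, positive and non-missing")
    }
  }
  means <- vapply(cts, mean, numeric(1))
  ddct <- (means[1] - means[2]) - (means[3] - means[4])
  2^(-ddct)
}
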