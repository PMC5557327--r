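# End-to-end orchestration: reads the configured inputs, runs
# clustering -> collinearity -> duplication typing -> Ka/Ks -> Ks peaks ->
# expression stages in order, and writes fixed-column TSV reports plus a
# JSON run manifest. Everything is a pure function of inputs + config
# (the seed covers all randomness), so reruns are byte-identical.

#' Family census across identification sources
#'
#' Totals per-source family counts and formats each source's share of the
#' total (the arithmetic of identification-census tables).
#'
#' @param counts named numeric vector or list, source -> count (`>= 0`).
#' @return list `total` and `fractions` (named character percentages).
#' @export
family_census <- function(counts) {
  counts <- unlist(counts)
  if (any(counts < 0)) stop("counts must be >= 0")
  total <- sum(counts)
  fr <- vapply(counts, function(k) percentage(k, total), character(1))
  list(total = total, fractions = fr)
}

#' Build a pipeline configuration
#'
#' @param annotation path to the GFF3 annotation (required).
#' @param pairs path to the homolog-pair TSV (required).
#' @param family_ids optional path to a one-column/first-column TSV of
#'   family gene ids; default: all annotated genes.
#' @param codon_pairs optional paired FASTA of aligned CDS pairs for Ka/Ks.
#' @param expression optional expression-matrix TSV.
#' @param site_model_fits optional TSV of site-model -ln L values.
#' @param out_dir output directory for reports.
#' @param max_gap_bp,max_evalue,min_anchors,max_gap_ranks,proximal_window_ranks,alpha,max_ks
#'   stage thresholds (cluster gap, pair E-value screen, block chaining,
#'   proximal rank window, selection significance, Ks dating filter).
#' @param feature_type GFF feature anchoring coordinates, default "gene".
#' @param seed master seed; stage-local seeds derive from it.
#' @return config list (class `crpevol_config`).
#' @export
pipeline_config <- function(annotation, pairs, family_ids = NULL,
                            codon_pairs = NULL, expression = NULL,
                            site_model_fits = NULL, out_dir = "results",
                            max_gap_bp = 10000, max_evalue = 0.01,
                            min_anchors = 5, max_gap_ranks = 25,
                            proximal_window_ranks = 20, alpha = 0.05,
                            max_ks = 2.0, feature_type = "gene", seed = 1) {
  cfg <- list(annotation = annotation, pairs = pairs,
              family_ids = family_ids, codon_pairs = codon_pairs,
              expression = expression, site_model_fits = site_model_fits,
              out_dir = out_dir, max_gap_bp = max_gap_bp,
              max_evalue = max_evalue, min_anchors = min_anchors,
              max_gap_ranks = max_gap_ranks,
              proximal_window_ranks = proximal_window_ranks,
              alpha = alpha, max_ks = max_ks, feature_type = feature_type,
              seed = as.integer(seed))
  for (thr in c("max_gap_bp", "max_evalue", "min_anchors", "max_gap_ranks",
                "proximal_window_ranks", "alpha", "max_ks")) {
    if (!is.numeric(cfg[[thr]]) || cfg[[thr]] <= 0) {
      stop("threshold ", thr, " must be positive")
    }
  }
  class(cfg) <- "crpevol_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file path; keys as in [pipeline_config()].
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Validates the configuration (all referenced inputs must exist before any
#' stage runs), then executes the stages in order and writes the reports:
#' `clusters.tsv`, `cluster_stats.tsv`, `blocks.tsv`, `classification.tsv`,
#' `duplication_census.tsv`, and — when the optional inputs are configured —
#' `kaks.tsv`, `ks_peaks.tsv`, `lrt.tsv`, `divergence.tsv`,
#' `coordination.tsv`; always `manifest.json` and `run.log`.
#'
#' @param config list from [pipeline_config()] or [read_pipeline_config()].
#' @return invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  required <- c("annotation", "pairs")
  for (key in required) {
    if (is.null(config[[key]])) stop("config missing required path: ", key)
  }
  optional <- c("family_ids", "codon_pairs", "expression", "site_model_fits")
  for (key in c(required, optional)) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input does not exist: ", key, " = ", p)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "run.log")
  loglines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message("[crpevol] ", msg)
    loglines <<- c(loglines, msg)
  }
  results <- list()

  note("stage genome_io: reading annotation ", config$annotation)
  annotation <- read_gff(config$annotation, config$feature_type)
  pairs <- read_pairs_table(config$pairs, config$max_evalue)
  note("read ", nrow(annotation), " genes, ", nrow(pairs),
       " homolog pairs at E < ", config$max_evalue)
  family <- if (is.null(config$family_ids)) annotation$gene_id else {
    as.character(utils::read.delim(config$family_ids,
                                   stringsAsFactors = FALSE)[[1]])
  }
  results$annotation <- annotation
  results$pairs <- pairs

  note("stage clustering: max_gap_bp = ", config$max_gap_bp)
  fam_genes <- annotation[annotation$gene_id %in% family, , drop = FALSE]
  clusters <- detect_clusters(fam_genes, config$max_gap_bp)
  stats <- cluster_summary(clusters, length(family))
  write_report_tsv(clusters, file.path(config$out_dir, "clusters.tsv"))
  write_report_tsv(stats, file.path(config$out_dir, "cluster_stats.tsv"))
  note(nrow(clusters), " clusters covering ", stats$n_clustered_genes,
       " genes (", stats$fraction_clustered, "% of family)")
  results$clusters <- clusters
  results$cluster_stats <- stats

  note("stage collinearity: min_anchors = ", config$min_anchors,
       ", max_gap_ranks = ", config$max_gap_ranks)
  blocks <- chain_anchors(pairs, annotation, config$max_gap_ranks,
                          config$min_anchors)
  classification <- classify_duplicates(family, pairs, blocks, annotation,
                                        config$proximal_window_ranks)
  census <- duplication_census(classification)
  write_report_tsv(blocks, file.path(config$out_dir, "blocks.tsv"))
  write_report_tsv(classification,
                   file.path(config$out_dir, "classification.tsv"))
  write_report_tsv(census,
                   file.path(config$out_dir, "duplication_census.tsv"))
  note(nrow(blocks), " collinear blocks; census: ",
       paste(census$class, census$count, sep = "=", collapse = ", "))
  results$blocks <- blocks
  results$classification <- classification
  results$duplication_census <- census

  if (!is.null(config$codon_pairs)) {
    note("stage kaks_evolution: alpha = ", config$alpha)
    cp <- read_codon_pairs(config$codon_pairs)
    kaks <- compute_kaks_table(cp, alpha = config$alpha)
    write_report_tsv(kaks, file.path(config$out_dir, "kaks.tsv"))
    n_undef <- sum(is.na(kaks$ks))
    note(nrow(kaks), " pairs; ", n_undef, " with undefined Ks removed ",
         "from dating")
    ks_ok <- kaks$ks[!is.na(kaks$ks)]
    if (sum(ks_ok > 0 & ks_ok < config$max_ks) >= 10) {
      peaks <- ks_density_peaks(ks_ok, config$max_ks)
      write_report_tsv(peaks, file.path(config$out_dir, "ks_peaks.tsv"))
      results$ks_peaks <- peaks
      note(nrow(peaks), " Ks density peak(s)")
    } else {
      note("too few Ks values in (0, ", config$max_ks, ") for dating")
    }
    results$kaks <- kaks
  }

  if (!is.null(config$site_model_fits)) {
    fits <- read_site_model_fits(config$site_model_fits)
    if (all(c("M7", "M8") %in% names(fits))) {
      lrt <- likelihood_ratio_test(fits$M7, fits$M8, df = 2)
      write_report_tsv(data.frame(null_model = "M7", alt_model = "M8",
                                  statistic = lrt$statistic, df = lrt$df,
                                  p_value = lrt$p_value),
                       file.path(config$out_dir, "lrt.tsv"))
      note("M8 vs M7 LRT statistic = ", format(lrt$statistic))
      results$lrt <- lrt
    }
  }

  if (!is.null(config$expression)) {
    note("stage expression")
    mat <- read_expression_table(config$expression)
    pres <- pairs[pairs$gene_a %in% rownames(mat) &
                    pairs$gene_b %in% rownames(mat), , drop = FALSE]
    if (nrow(pres)) {
      div <- expression_divergence(mat, pres, classification)
      write_report_tsv(div, file.path(config$out_dir, "divergence.tsv"))
      results$divergence <- div
      note(nrow(div), " divergence records")
    }
    coord <- list()
    for (i in seq_len(nrow(clusters))) {
      members <- strsplit(clusters$member_ids[i], ",", fixed = TRUE)[[1]]
      if (sum(members %in% rownames(mat)) < 2) next
      cc <- coordinated_expression(members, mat)
      coord[[length(coord) + 1]] <- cbind(cluster_id = clusters$cluster_id[i],
                                          cc, stringsAsFactors = FALSE)
    }
    if (length(coord)) {
      coord <- do.call(rbind, coord)
      write_report_tsv(coord, file.path(config$out_dir, "coordination.tsv"))
      results$coordination <- coord
      note(nrow(coord), " within-cluster coordination records")
    }
  }

  manifest <- list(
    package = "crpevol",
    version = as.character(utils::packageVersion("crpevol")),
    seed = config$seed,
    thresholds = config[c("max_gap_bp", "max_evalue", "min_anchors",
                          "max_gap_ranks", "proximal_window_ranks",
                          "alpha", "max_ks")],
    inputs = config[c("annotation", "pairs", "family_ids", "codon_pairs",
                      "expression", "site_model_fits")])
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(loglines, logfile)
  invisible(results)
}
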