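# Synthetic genomes, codon pairs and expression matrices with a ground-truth
# ledger. The generators emulate the structures the downstream analyses
# count — gene clusters under the 10 kb rule, tandem arrays at consecutive
# ranks, rank-preserving collinear segments, codon pairs with known
# synonymous/nonsynonymous edit counts, expression profiles with a known
# pairwise correlation — so every stage has a recovery test that needs no
# external genome download. Every generator is a pure function of its
# arguments including the seed.

#' Simulate an annotated genome with planted structures
#'
#' Background genes are spaced with intergenic gaps drawn uniformly in
#' 10,001–50,000 bp (guaranteeing no accidental clusters under the 10 kb
#' rule); planted clusters have all internal gaps equal to `cluster_gap_bp`;
#' tandem arrays are homolog runs at consecutive ranks (all-vs-all homolog
#' edges within an array); collinear segments are rank-preserving duplicated
#' blocks with one homolog edge per anchor position.
#'
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome genes per chromosome.
#' @param n_clusters planted clusters (positional, no homology implied).
#' @param cluster_gap_bp internal gap of planted clusters; must be below
#'   10,000 bp so the clusters are detectable under the census rule.
#' @param n_tandem_arrays planted tandem arrays.
#' @param n_collinear_segments planted duplicated segments (two runs on
#'   different chromosomes where possible).
#' @param segment_length_anchors anchors per segment, `>= 5`.
#' @param seed integer seed; identical seeds give identical output.
#' @param cluster_size genes per planted cluster, default 3.
#' @param tandem_array_size genes per tandem array, default 3 (kept small so
#'   the within-array anchor diagonal stays below the block threshold).
#' @return list with `annotation` (gene-model data.frame), `pairs`
#'   (homolog-pair data.frame) and `truth` (planted-structure ledger:
#'   `planted_clusters`, `planted_tandem_arrays`,
#'   `planted_collinear_segments`, `seed`).
#' @export
simulate_genome <- function(n_chromosomes, genes_per_chromosome,
                            n_clusters = 0, cluster_gap_bp = 2000,
                            n_tandem_arrays = 0, n_collinear_segments = 0,
                            segment_length_anchors = 6, seed = 1,
                            cluster_size = 3, tandem_array_size = 3) {
  stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 1)
  if (n_clusters > 0 && cluster_gap_bp >= 10000) {
    stop("cluster_gap_bp must be < 10000 so planted clusters are detectable")
  }
  if (n_collinear_segments > 0 && segment_length_anchors < 5) {
    stop("segment_length_anchors must be >= 5")
  }
  withr::with_seed(as.integer(seed), {
    # allocate contiguous index ranges per chromosome for each structure
    free_from <- rep(1L, n_chromosomes)    # next free gene index per chrom
    capacity <- rep(as.integer(genes_per_chromosome), n_chromosomes)
    take_run <- function(len, avoid = 0L) {
      ord <- order(free_from)              # fill least-used chromosome first
      for (c in ord) {
        if (c == avoid) next
        if (free_from[c] + len - 1L <= capacity[c]) {
          run <- list(chrom = c, idx = free_from[c]:(free_from[c] + len - 1L))
          free_from[c] <<- free_from[c] + len
          return(run)
        }
      }
      stop("requested planted structures exceed chromosome capacity")
    }
    clusters <- replicate(n_clusters, take_run(cluster_size),
                          simplify = FALSE)
    arrays <- replicate(n_tandem_arrays, take_run(tandem_array_size),
                        simplify = FALSE)
    segments <- vector("list", n_collinear_segments)
    for (s in seq_len(n_collinear_segments)) {
      run_a <- take_run(segment_length_anchors)
      run_b <- take_run(segment_length_anchors, avoid = run_a$chrom)
      segments[[s]] <- list(a = run_a, b = run_b)
    }
    # lay out coordinates chromosome by chromosome
    gid <- function(c, i) sprintf("g%02d_%04d", c, i)
    cluster_gap_at <- matrix(FALSE, n_chromosomes, genes_per_chromosome)
    for (cl in clusters) {
      cluster_gap_at[cl$chrom, cl$idx[-1]] <- TRUE  # gap *before* gene i
    }
    ann <- list()
    for (c in seq_len(n_chromosomes)) {
      n <- genes_per_chromosome
      len <- sample(500:2000, n, replace = TRUE)
      gap <- sample(10001:50000, n, replace = TRUE)
      gap[cluster_gap_at[c, seq_len(n)]] <- cluster_gap_bp
      start <- integer(n); end <- integer(n)
      pos <- 1L
      for (i in seq_len(n)) {
        pos <- pos + gap[i] + 1L   # intergenic gap = start - prev_end - 1
        start[i] <- pos
        end[i] <- pos + len[i] - 1L
        pos <- end[i]
      }
      ann[[c]] <- data.frame(gene_id = gid(c, seq_len(n)),
                             chromosome = sprintf("chr%02d", c),
                             start = start, end = end,
                             strand = sample(c("+", "-"), n, replace = TRUE),
                             stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, ann)
    annotation <- gene_models(ann$gene_id, ann$chromosome, ann$start,
                              ann$end, ann$strand)
    # homolog edges
    pa <- character(0); pb <- character(0)
    truth_arrays <- lapply(arrays, function(ar) gid(ar$chrom, ar$idx))
    for (ids in truth_arrays) {
      cmb <- utils::combn(ids, 2)
      pa <- c(pa, cmb[1, ]); pb <- c(pb, cmb[2, ])
    }
    truth_segments <- lapply(segments, function(sg) {
      ids_a <- gid(sg$a$chrom, sg$a$idx)
      ids_b <- gid(sg$b$chrom, sg$b$idx)
      data.frame(gene_a = ids_a, gene_b = ids_b, stringsAsFactors = FALSE)
    })
    for (sg in truth_segments) {
      pa <- c(pa, sg$gene_a); pb <- c(pb, sg$gene_b)
    }
    pairs <- if (length(pa)) {
      homolog_pairs(pa, pb, score = 500, evalue = 1e-50)
    } else empty_pairs()
    truth <- list(
      planted_clusters = lapply(clusters, function(cl) gid(cl$chrom, cl$idx)),
      planted_tandem_arrays = truth_arrays,
      planted_collinear_segments = truth_segments,
      seed = as.integer(seed))
    list(annotation = annotation, pairs = pairs, truth = truth)
  })
}

#' Write a simulated genome to disk
#'
#' Emits the same dialects the readers consume: GFF3 annotation, 4-column
#' homolog-pair TSV, a truth ledger TSV per structure type and a small JSON
#' manifest.
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_synthetic_genome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotation = file.path(dir, "annotation.gff3"),
             pairs = file.path(dir, "pairs.tsv"),
             truth_clusters = file.path(dir, "truth_clusters.tsv"),
             truth_tandem = file.path(dir, "truth_tandem_arrays.tsv"),
             truth_segments = file.path(dir, "truth_segments.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_gff(sim$annotation, paths[["annotation"]])
  write_report_tsv(sim$pairs, paths[["pairs"]])
  flat <- function(lst) {
    if (!length(lst)) {
      return(data.frame(structure_id = integer(0), gene_id = character(0)))
    }
    do.call(rbind, lapply(seq_along(lst), function(i) {
      data.frame(structure_id = i, gene_id = unlist(lst[[i]],
                                                    use.names = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  write_report_tsv(flat(sim$truth$planted_clusters), paths[["truth_clusters"]])
  write_report_tsv(flat(sim$truth$planted_tandem_arrays),
                   paths[["truth_tandem"]])
  seg <- if (length(sim$truth$planted_collinear_segments)) {
    do.call(rbind, lapply(seq_along(sim$truth$planted_collinear_segments),
                          function(i) {
      cbind(structure_id = i, sim$truth$planted_collinear_segments[[i]])
    }))
  } else data.frame(structure_id = integer(0), gene_a = character(0),
                    gene_b = character(0))
  write_report_tsv(seg, paths[["truth_segments"]])
  jsonlite::write_json(list(seed = sim$truth$seed,
                            n_genes = nrow(sim$annotation),
                            n_pairs = nrow(sim$pairs),
                            files = as.list(basename(paths))),
                       paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

# one-step (single nucleotide) codon neighbours with classification
#' @keywords internal
codon_neighbours <- function(codon) {
  out <- character(0); syn <- logical(0)
  aa <- translate_codon(codon)
  for (posn in 1:3) {
    for (b in setdiff(BASES, substr(codon, posn, posn))) {
      mut <- codon
      substr(mut, posn, posn) <- b
      if (mut %in% STOP_CODONS) next
      out <- c(out, mut)
      syn <- c(syn, translate_codon(mut) == aa)
    }
  }
  data.frame(codon = out, synonymous = syn, stringsAsFactors = FALSE)
}

#' Simulate a coding pair with known difference counts
#'
#' Builds a random coding sequence and applies exactly `syn_changes`
#' synonymous and `nonsyn_changes` nonsynonymous single-nucleotide edits,
#' each at a distinct codon, never creating a stop codon. Because every
#' edited codon differs at a single position, NG86 difference counting
#' recovers `(Sd, Nd) = (syn_changes, nonsyn_changes)` exactly — the
#' generator deliberately avoids multi-hit codons so the planted truth is
#' unambiguous.
#'
#' @param n_codons sequence length in codons.
#' @param syn_changes,nonsyn_changes planted edit counts;
#'   `syn_changes + nonsyn_changes <= n_codons`.
#' @param seed integer seed.
#' @return list `id_a`, `id_b`, `cds_a`, `cds_b`, `truth` (with `Sd_true`,
#'   `Nd_true`, `seed`).
#' @export
simulate_codon_pair <- function(n_codons, syn_changes, nonsyn_changes,
                                seed = 1) {
  stopifnot(n_codons >= 1, syn_changes >= 0, nonsyn_changes >= 0)
  if (syn_changes + nonsyn_changes > n_codons) {
    stop("infeasible request: ", syn_changes + nonsyn_changes,
         " edits need distinct codons but n_codons = ", n_codons)
  }
  sense <- setdiff(gsub("U", "T", names(Biostrings::GENETIC_CODE)),
                   STOP_CODONS)
  has_syn <- vapply(sense, function(cd) any(codon_neighbours(cd)$synonymous),
                    logical(1))
  has_nonsyn <- vapply(sense,
                       function(cd) any(!codon_neighbours(cd)$synonymous),
                       logical(1))
  withr::with_seed(as.integer(seed), {
    codons_a <- sample(sense, n_codons, replace = TRUE)
    edit_pos <- sample.int(n_codons, syn_changes + nonsyn_changes)
    syn_pos <- edit_pos[seq_len(syn_changes)]
    nonsyn_pos <- setdiff(edit_pos, syn_pos)
    for (p in syn_pos) {
      if (!has_syn[codons_a[p]]) {
        codons_a[p] <- sample(sense[has_syn], 1)
      }
    }
    for (p in nonsyn_pos) {
      if (!has_nonsyn[codons_a[p]]) {
        codons_a[p] <- sample(sense[has_nonsyn], 1)
      }
    }
    codons_b <- codons_a
    for (p in syn_pos) {
      nb <- codon_neighbours(codons_a[p])
      opts <- nb$codon[nb$synonymous]
      codons_b[p] <- if (length(opts) == 1) opts else sample(opts, 1)
    }
    for (p in nonsyn_pos) {
      nb <- codon_neighbours(codons_a[p])
      opts <- nb$codon[!nb$synonymous]
      codons_b[p] <- if (length(opts) == 1) opts else sample(opts, 1)
    }
    list(id_a = "sim_a", id_b = "sim_b",
         cds_a = paste(codons_a, collapse = ""),
         cds_b = paste(codons_b, collapse = ""),
         truth = list(Sd_true = syn_changes, Nd_true = nonsyn_changes,
                      seed = as.integer(seed)))
  })
}

#' Simulate expression profiles with a planted pairwise correlation
#'
#' For each gene pair the second profile is built from the first by an
#' empirically orthogonalised bivariate construction, so that at
#' `noise_sd = 0` the *sample* Pearson correlation equals
#' `target_correlation` exactly (not just in expectation); independent
#' Gaussian noise of sd `noise_sd` is then added to both profiles. The whole
#' matrix is affinely shifted to be non-negative and scaled to RPKM-like
#' magnitudes — both transforms preserve Pearson correlation, so the planted
#' truth survives.
#'
#' @param gene_pairs data.frame with `gene_a`, `gene_b` (ids must be unique
#'   across pairs).
#' @param target_correlation scalar or per-pair vector in `[-1, 1]`.
#' @param n_stages number of developmental stages, `>= 3`.
#' @param noise_sd additive Gaussian noise sd on the latent scale.
#' @param seed integer seed.
#' @return list `matrix` (genes x stages, non-negative), `truth`
#'   (data.frame `gene_a`, `gene_b`, `target_correlation`), `seed`.
#' @export
simulate_expression <- function(gene_pairs, target_correlation, n_stages = 6,
                                noise_sd = 0, seed = 1) {
  if (n_stages < 3) stop("n_stages must be >= 3")
  r <- rep_len(target_correlation, nrow(gene_pairs))
  if (any(abs(r) > 1)) stop("|target_correlation| must be <= 1")
  withr::with_seed(as.integer(seed), {
    profiles <- list()
    for (i in seq_len(nrow(gene_pairs))) {
      z <- stats::rnorm(n_stages)
      zs <- (z - mean(z)) / stats::sd(z)
      eta <- stats::rnorm(n_stages)
      res <- stats::residuals(stats::lm(eta ~ zs))
      es <- (res - mean(res)) / stats::sd(res)
      b <- r[i] * zs + sqrt(1 - r[i]^2) * es
      profiles[[gene_pairs$gene_a[i]]] <- zs + noise_sd * stats::rnorm(n_stages)
      profiles[[gene_pairs$gene_b[i]]] <- b + noise_sd * stats::rnorm(n_stages)
    }
    m <- do.call(rbind, profiles)
    colnames(m) <- sprintf("stage_%02d", seq_len(n_stages))
    m <- (m - min(m)) * 10          # affine: Pearson-preserving, RPKM-like
    list(matrix = m,
         truth = data.frame(gene_a = gene_pairs$gene_a,
                            gene_b = gene_pairs$gene_b,
                            target_correlation = r,
                            stringsAsFactors = FALSE),
         seed = as.integer(seed))
  })
}
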