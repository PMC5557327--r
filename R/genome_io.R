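#' Gene model table constructor
#'
#' Builds the canonical gene-model data frame used throughout the pipeline:
#' one row per gene with chromosome placement and the per-chromosome rank
#' (ordinal position among *all* genes of the annotation on that chromosome,
#' sorted by ascending start, ties broken by ascending end then gene id).
#' Ranks always reflect the full annotation set: tandem/proximal typing
#' depends on genome-wide adjacency, so ranks must never be recomputed on a
#' family subset.
#'
#' @param gene_id character vector, unique.
#' @param chromosome character vector.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand one of `"+"`, `"-"`, `"unknown"`; recycled if length 1.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `rank`.
#' @export
gene_models <- function(gene_id, chromosome, start, end, strand = "unknown") {
  gene_id <- as.character(gene_id)
  chromosome <- as.character(chromosome)
  start <- as.numeric(start)
  end <- as.numeric(end)
  strand <- rep_len(as.character(strand), length(gene_id))
  strand[!strand %in% c("+", "-")] <- "unknown"
  if (anyDuplicated(gene_id)) {
    dup <- gene_id[duplicated(gene_id)][1]
    stop("duplicate gene_id in annotation: ", dup)
  }
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("gene coordinates must be finite")
  }
  if (any(end < start)) stop("gene end < start for: ",
                             gene_id[which(end < start)[1]])
  df <- data.frame(gene_id = gene_id, chromosome = chromosome,
                   start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  df$rank <- assign_ranks(df)
  df
}

# Per-chromosome 1-based rank by (start, end, gene_id); bijection per chrom.
#' @keywords internal
assign_ranks <- function(df) {
  rank <- integer(nrow(df))
  for (chrom in unique(df$chromosome)) {
    idx <- which(df$chromosome == chrom)
    ord <- idx[order(df$start[idx], df$end[idx], df$gene_id[idx])]
    rank[ord] <- seq_along(ord)
  }
  rank
}

#' Read gene models from a GFF3 annotation
#'
#' Parses a GFF3 file, keeps the requested feature type and returns a
#' gene-model table with per-chromosome ranks (see [gene_models()]).
#' The gene id is taken from the `ID` attribute. A light pre-scan reports
#' the line number of any malformed (non-9-column) row.
#'
#' @param path GFF3 file path.
#' @param feature_type feature to extract; default `"gene"` (annotations that
#'   anchor coordinates on mRNA features can override).
#' @return gene-model data.frame.
#' @export
read_gff <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body)) {
    nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nfield != 9]
    if (length(bad)) {
      stop("malformed GFF3 line ", bad[1], ": expected 9 tab-separated fields")
    }
  }
  if (!length(body)) {
    return(gene_models(character(0), character(0), numeric(0), numeric(0)))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
  if (!length(gr)) {
    return(gene_models(character(0), character(0), numeric(0), numeric(0)))
  }
  ids <- as.character(gr$ID)
  if (any(is.na(ids) | ids == "")) {
    stop("GFF3 feature without an ID attribute (feature_type = ",
         feature_type, ")")
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "unknown"
  gene_models(ids, as.character(GenomicRanges::seqnames(gr)),
              BiocGenerics::start(gr), BiocGenerics::end(gr), strand)
}

#' Write gene models as GFF3
#'
#' @param genes gene-model data.frame.
#' @param path output path.
#' @param feature_type feature column value, default `"gene"`.
#' @param source source column value.
#' @return the path, invisibly.
#' @export
write_gff <- function(genes, path, feature_type = "gene", source = "crpevol") {
  strand <- genes$strand
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = strand)
  gr$source <- source
  gr$type <- feature_type
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a homolog-pair table
#'
#' Accepts either the minimal 4-column TSV (`gene_a`, `gene_b`, `score`,
#' `evalue`, with or without header) or 12-column BLAST tabular output
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Rows are filtered at `evalue < max_evalue` (strict, the
#' collinearity-screen convention), self-pairs dropped, and unordered
#' duplicates collapsed keeping the smallest E-value (with its score).
#'
#' @param path TSV path.
#' @param max_evalue retention threshold, default 0.01.
#' @return data.frame with `gene_a`, `gene_b` (canonical order,
#'   `gene_a < gene_b`), `score`, `evalue`.
#' @export
read_pairs_table <- function(path, max_evalue = 0.01) {
  if (!file.exists(path)) stop("pairs file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!nrow(raw)) return(empty_pairs())
  # tolerate a header row on the 4-column dialect
  if (ncol(raw) >= 4 && is.character(raw[[4]]) &&
      is.na(suppressWarnings(as.numeric(raw[1, 4])))) {
    raw <- raw[-1, , drop = FALSE]
    if (!nrow(raw)) return(empty_pairs())
  }
  if (ncol(raw) >= 12) {
    df <- data.frame(gene_a = as.character(raw[[1]]),
                     gene_b = as.character(raw[[2]]),
                     score = suppressWarnings(as.numeric(raw[[12]])),
                     evalue = suppressWarnings(as.numeric(raw[[11]])),
                     stringsAsFactors = FALSE)
  } else if (ncol(raw) >= 4) {
    df <- data.frame(gene_a = as.character(raw[[1]]),
                     gene_b = as.character(raw[[2]]),
                     score = suppressWarnings(as.numeric(raw[[3]])),
                     evalue = suppressWarnings(as.numeric(raw[[4]])),
                     stringsAsFactors = FALSE)
  } else {
    stop("pairs table must have 4 (minimal TSV) or 12 (BLAST tabular) columns")
  }
  if (anyNA(df$evalue)) {
    stop("non-numeric E-value in pairs table at data row ",
         which(is.na(df$evalue))[1])
  }
  homolog_pairs(df$gene_a, df$gene_b, df$score, df$evalue,
                max_evalue = max_evalue)
}

#' Canonicalise homolog pairs
#'
#' @param gene_a,gene_b gene id vectors.
#' @param score,evalue numeric vectors.
#' @param max_evalue strict retention threshold; `Inf` keeps everything.
#' @return canonical pairs data.frame (self-pairs dropped, ids sorted within
#'   a pair, unordered duplicates collapsed to the best E-value).
#' @export
homolog_pairs <- function(gene_a, gene_b, score = NA_real_, evalue = 0,
                          max_evalue = Inf) {
  df <- data.frame(gene_a = as.character(gene_a),
                   gene_b = as.character(gene_b),
                   score = rep_len(as.numeric(score), length(gene_a)),
                   evalue = rep_len(as.numeric(evalue), length(gene_a)),
                   stringsAsFactors = FALSE)
  df <- df[df$gene_a != df$gene_b & df$evalue < max_evalue, , drop = FALSE]
  if (!nrow(df)) return(empty_pairs())
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  df <- df[order(df$gene_a, df$gene_b, df$evalue), , drop = FALSE]
  df <- df[!duplicated(paste(df$gene_a, df$gene_b)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @keywords internal
empty_pairs <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             score = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Cysteine spacing signature of a peptide
#'
#' The conserved-cysteine array of a CRP subfamily is summarised as
#' `C-Xk1-C-Xk2-...-C` where `ki` counts residues between consecutive
#' cysteines. A single cysteine gives `"C"`; no cysteine gives `""`.
#'
#' @param sequence amino-acid string (20 standard residues plus X;
#'   lowercase upper-cased on entry).
#' @return list with `signature` (string) and `n_cys` (count).
#' @export
cys_signature <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq <- toupper(sequence)
  if (nchar(seq) == 0) stop("empty peptide sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seq)) {
    stop("peptide alphabet restricted to the 20 amino acids plus X")
  }
  pos <- gregexpr("C", seq, fixed = TRUE)[[1]]
  if (pos[1] == -1) return(list(signature = "", n_cys = 0L))
  n <- length(pos)
  if (n == 1) return(list(signature = "C", n_cys = 1L))
  spacers <- diff(pos) - 1L
  list(signature = paste0("C", paste0("-X", spacers, "-C", collapse = "")),
       n_cys = n)
}

#' Read a peptide FASTA with optional annotations
#'
#' @param path FASTA path.
#' @param signal_peptide optional named logical vector (supplied flag, not
#'   computed here).
#' @param subfamily optional named character vector of subfamily labels.
#' @return data.frame `peptide_id`, `sequence`, `has_signal_peptide`,
#'   `subfamily`.
#' @export
read_peptides <- function(path, signal_peptide = NULL, subfamily = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) == 0)) stop("empty peptide sequence in ", path)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad)) {
    stop("peptide ", ids[which(bad)[1]],
         ": alphabet restricted to the 20 amino acids plus X")
  }
  sp <- if (is.null(signal_peptide)) rep(NA, length(ids)) else
    unname(signal_peptide[ids])
  fam <- if (is.null(subfamily)) rep("", length(ids)) else {
    f <- unname(subfamily[ids]); f[is.na(f)] <- ""; f
  }
  data.frame(peptide_id = ids, sequence = seqs,
             has_signal_peptide = sp, subfamily = fam,
             stringsAsFactors = FALSE)
}

#' Read aligned coding-sequence pairs from FASTA
#'
#' Records are taken two at a time (pair member A, then member B); sequences
#' must be pre-aligned. Codon columns containing a gap in either member are
#' dropped codon-wise and the dropped-codon count is recorded in the
#' `dropped_codons` attribute. The cleaned pairs satisfy the coding-pair
#' invariants (equal length, multiple of 3, ACGT only, no internal stop).
#'
#' @param path FASTA path with an even number of records.
#' @return data.frame `id_a`, `id_b`, `cds_a`, `cds_b` with attribute
#'   `dropped_codons`.
#' @export
read_codon_pairs <- function(path) {
  dna <- Biostrings::readBStringSet(path)
  if (length(dna) %% 2 != 0) {
    stop("paired FASTA must contain an even number of records")
  }
  ids <- sub("\\s.*$", "", names(dna))
  seqs <- toupper(as.character(dna))
  ia <- seq(1, length(seqs), by = 2)
  dropped <- 0L
  out <- vector("list", length(ia))
  for (k in seq_along(ia)) {
    a <- seqs[ia[k]]; b <- seqs[ia[k] + 1]
    if (nchar(a) != nchar(b)) {
      stop("aligned pair ", ids[ia[k]], "/", ids[ia[k] + 1],
           " has unequal lengths")
    }
    if (nchar(a) %% 3 != 0) {
      stop("aligned pair ", ids[ia[k]], ": length not divisible by 3")
    }
    ca <- codon_split(a); cb <- codon_split(b)
    gap <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
    dropped <- dropped + sum(gap)
    out[[k]] <- data.frame(id_a = ids[ia[k]], id_b = ids[ia[k] + 1],
                           cds_a = paste(ca[!gap], collapse = ""),
                           cds_b = paste(cb[!gap], collapse = ""),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  for (i in seq_len(nrow(res))) {
    validate_coding_pair(res$cds_a[i], res$cds_b[i],
                         paste(res$id_a[i], res$id_b[i]))
  }
  if (dropped > 0) {
    message("read_codon_pairs: dropped ", dropped, " gapped codon column(s)")
  }
  attr(res, "dropped_codons") <- dropped
  res
}

#' @keywords internal
codon_split <- function(s) {
  substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
}

#' @keywords internal
validate_coding_pair <- function(cds_a, cds_b, label = "") {
  for (s in c(cds_a, cds_b)) {
    if (nchar(s) != nchar(cds_a)) stop("coding pair ", label,
                                       ": unequal lengths")
    if (nchar(s) %% 3 != 0) stop("coding pair ", label,
                                 ": length not divisible by 3")
    if (grepl("[^ACGT]", s)) stop("coding pair ", label,
                                  ": alphabet must be ACGT only")
    cods <- codon_split(s)
    if (any(cods %in% STOP_CODONS)) {
      stop("coding pair ", label, ": internal stop codon")
    }
  }
  invisible(TRUE)
}

#' Read an expression matrix (genes x stages of RPKM)
#'
#' Header row holds stage ids; first column holds gene ids; all values must
#' be finite and non-negative. Ragged rows are an error.
#'
#' @param path TSV path.
#' @return numeric matrix with gene-id rownames and stage-id colnames.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2) stop("expression table needs a header row and data rows")
  if (length(unique(nf)) != 1) {
    stop("ragged expression table: row ", which(nf != nf[1])[1],
         " has ", nf[which(nf != nf[1])[1]], " fields, expected ", nf[1])
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("expression table needs at least one stage column")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric expression value in ", path)
  if (any(m < 0)) stop("negative expression value (RPKM must be >= 0)")
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#'
#' @param matrix numeric matrix with rownames (genes) and colnames (stages).
#' @param path output path.
#' @param id_column header for the gene-id column.
#' @return path, invisibly.
#' @export
write_expression_table <- function(matrix, path, id_column = "gene_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(matrix))
  write_report_tsv(df, path)
}
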