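write_test_gff <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chromosome, genes$start, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  path
}

test_that("read_gff assigns per-chromosome ranks by ascending start", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_test_gff(data.frame(gene_id = c("a", "b", "c"),
                            chromosome = "chr1",
                            start = c(100L, 5000L, 900L),
                            end = c(200L, 5100L, 1000L),
                            strand = "+"), path)
  gm <- read_gff(path)
  expect_equal(gm$rank[match(c("a", "b", "c"), gm$gene_id)], c(1L, 3L, 2L))
})

test_that("read_gff handles empty files, duplicates and malformed lines", {
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(read_gff(empty)), 0)

  dup <- withr::local_tempfile(fileext = ".gff3")
  write_test_gff(data.frame(gene_id = c("a", "a"), chromosome = "chr1",
                            start = c(1L, 500L), end = c(100L, 600L),
                            strand = "+"), dup)
  expect_error(read_gff(dup), "duplicate gene_id")

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=a",
               "chr1\tbroken line"), bad)
  expect_error(read_gff(bad), "line 3")
})

test_that("rank assignment is a bijection per chromosome", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(5:40, 1)
      gm <- gene_models(sprintf("g%02d", 1:n),
                        sample(c("c1", "c2", "c3"), n, replace = TRUE),
                        start <- sample.int(1e6, n),
                        start + sample.int(2000, n))
      for (chrom in unique(gm$chromosome)) {
        r <- gm$rank[gm$chromosome == chrom]
        expect_setequal(r, seq_along(r))
      }
    }
  })
})

test_that("gene-model round-trip through GFF3 is lossless", {
  gm <- gene_models(c("x1", "x2", "x3"), c("chr1", "chr1", "chr2"),
                    c(10L, 5000L, 77L), c(900L, 6200L, 800L),
                    c("+", "-", "unknown"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff(gm, path)
  back <- read_gff(path)
  back <- back[match(gm$gene_id, back$gene_id), ]
  rownames(back) <- NULL
  expect_equal(back, gm)
})

test_that("read_pairs_table screens E-values strictly and deduplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2\t100\t1e-5",
               "g3\tg4\t80\t0.5",
               "g5\tg5\t99\t1e-30",
               "g6\tg7\t50\t1e-3",
               "g7\tg6\t70\t1e-6"), path)
  pairs <- read_pairs_table(path, max_evalue = 0.01)
  expect_equal(nrow(pairs), 2)                       # 0.5 filtered, self dropped
  expect_false("g5" %in% c(pairs$gene_a, pairs$gene_b))
  g67 <- pairs[pairs$gene_a == "g6", ]
  expect_equal(g67$evalue, 1e-6)                     # best E kept on dedup

  boundary <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\tg2\t100\t0.01", boundary)
  expect_equal(nrow(read_pairs_table(boundary, 0.01)), 0)  # strict <

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2\t100\t1e-5", "g3\tg4\t80\tnot_a_number"), bad)
  expect_error(read_pairs_table(bad), "non-numeric E-value")
})

test_that("cysteine signatures follow the spacing definition", {
  # cysteines at positions 2, 6, 9: spacers are D,E,F (3) and G,H (2)
  expect_equal(cys_signature("ACDEFCGHC"),
               list(signature = "C-X3-C-X2-C", n_cys = 3L))
  expect_equal(cys_signature("CC"), list(signature = "C-X0-C", n_cys = 2L))
  expect_equal(cys_signature("AAAA"), list(signature = "", n_cys = 0L))
  expect_equal(cys_signature("AACAA"), list(signature = "C", n_cys = 1L))
  expect_error(cys_signature("ACB*"), "alphabet")
})

test_that("signature of concatenated peptides merges the junction spacer", {
  withr::with_seed(5, {
    aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")
    for (rep in 1:20) {
      s1 <- paste0(paste(sample(aas, 3, TRUE), collapse = ""), "C",
                   paste(sample(aas, sample(0:4, 1), TRUE), collapse = ""))
      s2 <- paste0(paste(sample(aas, sample(0:4, 1), TRUE), collapse = ""),
                   "C", paste(sample(aas, 2, TRUE), collapse = ""))
      trail <- nchar(sub(".*C", "", s1))
      lead <- nchar(sub("C.*", "", s2))
      sig <- cys_signature(paste0(s1, s2))$signature
      first_spacer <- as.integer(sub("^C-X(\\d+)-C.*", "\\1", sig))
      expect_equal(first_spacer, trail + lead)
    }
  })
})

test_that("expression tables round-trip and enforce invariants", {
  m <- matrix(c(0, 1.5, 2.25, 10, 0.5, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m, path)
  expect_equal(read_expression_table(path), m)

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3", "gA\t1\t-1.0\t2"), neg)
  expect_error(read_expression_table(neg), "negative")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3", "gA\t1\t2\t3", "gB\t1\t2"), ragged)
  expect_error(read_expression_table(ragged), "ragged")

  headerless <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gA\t1\t2\t3", headerless)
  expect_error(read_expression_table(headerless))
})

test_that("aligned codon pairs drop gapped columns codon-wise", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">pa", "GCTGC---TAAA", ">pb", "GCAGCGTCAAAA"), path)
  expect_message(cp <- read_codon_pairs(path), "dropped 2")
  expect_equal(attr(cp, "dropped_codons"), 2L)
  expect_equal(cp$cds_a, "GCTAAA")
  expect_equal(cp$cds_b, "GCAAAA")
})
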