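# helper: annotation with one gene per rank on each of two chromosomes,
# plus a pair list from (rank_a, rank_b) anchors
rank_grid_fixture <- function(ra, rb, n_ranks = 40) {
  ann <- gene_models(
    c(sprintf("A%02d", 1:n_ranks), sprintf("B%02d", 1:n_ranks)),
    rep(c("chrA", "chrB"), each = n_ranks),
    rep(seq(1, by = 20000, length.out = n_ranks), 2),
    rep(seq(1, by = 20000, length.out = n_ranks) + 1000, 2))
  pairs <- homolog_pairs(sprintf("A%02d", ra), sprintf("B%02d", rb))
  list(annotation = ann, pairs = pairs)
}

test_that("a perfect diagonal chains into one parallel block", {
  fx <- rank_grid_fixture(1:6, 1:6)
  blocks <- chain_anchors(fx$pairs, fx$annotation, min_anchors = 5)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$orientation, "parallel")
  expect_equal(blocks$n_anchors, 6)
  expect_equal(blocks$anchor_pairs,
               paste(sprintf("A%02d|B%02d", 1:6, 1:6), collapse = ";"))

  short <- rank_grid_fixture(1:4, 1:4)
  expect_equal(nrow(chain_anchors(short$pairs, short$annotation,
                                  min_anchors = 5)), 0)

  anti <- rank_grid_fixture(1:5, 9:5)
  ab <- chain_anchors(anti$pairs, anti$annotation, min_anchors = 5)
  expect_equal(ab$orientation, "antiparallel")
  expect_equal(ab$n_anchors, 5)
})

test_that("anchors beyond the rank-gap limit do not chain", {
  fx <- rank_grid_fixture(c(1, 2, 3, 4, 31), c(1, 2, 3, 4, 31))
  expect_equal(nrow(chain_anchors(fx$pairs, fx$annotation,
                                  max_gap_ranks = 25, min_anchors = 5)), 0)
  fx2 <- rank_grid_fixture(c(1, 2, 3, 4, 29), c(1, 2, 3, 4, 29))
  expect_equal(chain_anchors(fx2$pairs, fx2$annotation, max_gap_ranks = 25,
                             min_anchors = 5)$n_anchors, 5)
})

test_that("unknown gene ids in pairs are reported by name", {
  fx <- rank_grid_fixture(1:5, 1:5)
  bad <- rbind(fx$pairs, data.frame(gene_a = "A01", gene_b = "ghost",
                                    score = 1, evalue = 0))
  expect_error(chain_anchors(bad, fx$annotation), "ghost")
})

test_that("greedy DP chains match exhaustive enumeration on small instances", {
  withr::with_seed(2024, {
    for (rep in 1:200) {
      n <- sample(6:12, 1)
      ra <- sample.int(40, n, replace = TRUE)   # ties exercise strictness
      rb <- sample.int(40, n, replace = TRUE)
      keep <- !duplicated(paste(ra, rb))
      ra <- ra[keep]; rb <- rb[keep]
      min_anchors <- sample(2:4, 1)
      max_gap <- sample(c(5, 10, 25), 1)
      fx <- rank_grid_fixture(ra, rb)
      got <- chain_anchors(fx$pairs, fx$annotation, max_gap_ranks = max_gap,
                           min_anchors = min_anchors)
      want <- oracle_chains(ra, rb, max_gap, min_anchors)
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        want_strings <- vapply(want, function(ch) {
          paste(sprintf("A%02d|B%02d", ch$ra, ch$rb), collapse = ";")
        }, character(1))
        expect_equal(got$anchor_pairs, want_strings)
        expect_equal(got$orientation,
                     vapply(want, function(ch) {
                       if (ch$dir == 1) "parallel" else "antiparallel"
                     }, character(1)))
      }
    }
  })
})

test_that("blocks never share anchors and anchors come from the input", {
  sim <- simulate_genome(3, 40, n_collinear_segments = 3,
                         segment_length_anchors = 6, seed = 13)
  blocks <- chain_anchors(sim$pairs, sim$annotation)
  anchors <- unlist(strsplit(blocks$anchor_pairs, ";", fixed = TRUE))
  expect_false(any(duplicated(anchors)))
  in_pairs <- paste(sim$pairs$gene_a, sim$pairs$gene_b, sep = "|")
  expect_true(all(anchors %in% c(in_pairs,
                                 paste(sim$pairs$gene_b, sim$pairs$gene_a,
                                       sep = "|"))))
})

test_that("duplicate classification follows the stated precedence", {
  ann <- gene_models(sprintf("g%02d", 1:20), "chr1",
                     seq(1, by = 20000, length.out = 20),
                     seq(1, by = 20000, length.out = 20) + 500)
  no_blocks <- chain_anchors(empty_pairs <- homolog_pairs(character(0),
                                                          character(0)), ann)

  tandem <- classify_duplicates(c("g07", "g08"),
                                homolog_pairs("g07", "g08"), no_blocks, ann)
  expect_equal(tandem$class, c("tandem", "tandem"))

  prox <- classify_duplicates(c("g07", "g12"),
                              homolog_pairs("g07", "g12"), no_blocks, ann)
  expect_equal(prox$class, c("proximal", "proximal"))

  # beyond the proximal window: dispersed
  prox20 <- classify_duplicates(c("g01", "g20"),
                                homolog_pairs("g01", "g20"), no_blocks, ann,
                                proximal_window_ranks = 20)
  expect_equal(prox20$class, c("proximal", "proximal"))  # delta = 19 <= 20
  far <- classify_duplicates(c("g01", "g20"), homolog_pairs("g01", "g20"),
                             no_blocks, ann, proximal_window_ranks = 10)
  expect_equal(far$class, c("dispersed", "dispersed"))

  # block anchor wins over tandem membership
  sim <- simulate_genome(2, 30, n_collinear_segments = 1,
                         segment_length_anchors = 6, seed = 5)
  blocks <- chain_anchors(sim$pairs, sim$annotation)
  seg <- sim$truth$planted_collinear_segments[[1]]
  extra <- homolog_pairs(c(sim$pairs$gene_a, seg$gene_a[1]),
                         c(sim$pairs$gene_b, seg$gene_a[2]))
  cls <- classify_duplicates(seg$gene_a, extra, blocks, sim$annotation)
  expect_true(all(cls$class == "wgd_segmental"))
})

test_that("planted duplication structures classify exactly by type", {
  sim <- simulate_genome(4, 30, n_tandem_arrays = 3,
                         n_collinear_segments = 3,
                         segment_length_anchors = 6, seed = 77)
  blocks <- chain_anchors(sim$pairs, sim$annotation)
  cls <- classify_duplicates(sim$annotation$gene_id, sim$pairs, blocks,
                             sim$annotation)
  lbl <- setNames(cls$class, cls$gene_id)
  tandem_ids <- unlist(sim$truth$planted_tandem_arrays)
  seg_ids <- unlist(lapply(sim$truth$planted_collinear_segments,
                           function(s) c(s$gene_a, s$gene_b)))
  other <- setdiff(sim$annotation$gene_id, c(tandem_ids, seg_ids))
  expect_true(all(lbl[tandem_ids] == "tandem"))
  expect_true(all(lbl[seg_ids] == "wgd_segmental"))
  expect_true(all(lbl[other] == "singleton"))

  census <- duplication_census(cls)
  expect_equal(census$count[census$class == "wgd_segmental"], 36)
  expect_equal(sum(census$count), nrow(sim$annotation))
})

test_that("lowering min_anchors never loses wgd_segmental genes", {
  sim <- simulate_genome(3, 40, n_collinear_segments = 2,
                         segment_length_anchors = 7, seed = 8)
  counts <- vapply(c(8, 7, 6, 5, 3, 2), function(m) {
    blocks <- chain_anchors(sim$pairs, sim$annotation, min_anchors = m)
    cls <- classify_duplicates(sim$annotation$gene_id, sim$pairs, blocks,
                               sim$annotation)
    sum(cls$class == "wgd_segmental")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("duplication census percentages sum and round as reported", {
  cls <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    class = rep("singleton", 10))
  cen <- duplication_census(cls)
  expect_equal(cen$percent[cen$class == "singleton"], 100)
  expect_equal(sum(cen$count), 10)
  expect_error(duplication_census(cls[0, ]), "empty")
})
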