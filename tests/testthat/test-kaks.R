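test_that("site counting matches one-step enumeration for all sense codons", {
  for (codon in ORACLE_SENSE) {
    expect_equal(unname(count_sites(codon)),
                 unname(oracle_codon_sites(codon)),
                 info = codon)
  }
  # additivity over codons, and S + N = 3 * n_codons
  expect_equal(unname(count_sites("GCTGCT")), c(2, 4))
  withr::with_seed(3, {
    for (rep in 1:10) {
      cds <- paste(sample(ORACLE_SENSE, 30, replace = TRUE), collapse = "")
      sn <- count_sites(cds)
      expect_equal(unname(sn[1] + sn[2]), 90)
    }
  })
  expect_error(count_sites("GCTAA"), "divisible")
  expect_error(count_sites("GCTTAA"), "stop")
})

test_that("difference counting classifies single and multi-step codons", {
  expect_equal(unname(count_differences("TTT", "TTA")), c(0, 1))  # Phe->Leu
  expect_equal(unname(count_differences("TTT", "CTA")), c(1, 1))
  expect_equal(unname(count_differences("GCTGCT", "GCTGCT")), c(0, 0))
  # three-position difference averages over the six pathways
  d3 <- count_differences("TTT", "GAC")
  expect_equal(unname(d3[1] + d3[2]), 3)
  # pathway through a stop is excluded: AGA <-> TGG passes TGA (stop) or
  # AGG; only the AGG route (syn Arg-Arg step + nonsyn Arg-Trp step) counts
  d <- count_differences("AGA", "TGG")
  expect_equal(unname(d), c(1, 1))
})

test_that("Jukes-Cantor correction has the closed form and its domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), 0.1073256, tolerance = 1e-6)
  expect_true(is.na(jukes_cantor(0.75)))
  expect_true(is.na(jukes_cantor(0.9)))
  p <- seq(0.01, 0.74, by = 0.01)
  expect_true(all(jukes_cantor(p) >= p))          # correction only inflates
  expect_equal(jukes_cantor(1e-9), 1e-9, tolerance = 1e-3)
})

test_that("the worked NG86 example reproduces hand-counted values", {
  a <- strrep("GCT", 10)
  b <- paste0(strrep("GCT", 9), "GCA")
  res <- compute_kaks(a, b)
  expect_equal(res$S, 10)
  expect_equal(res$N, 20)
  expect_equal(res$Sd, 1)
  expect_equal(res$Nd, 0)
  expect_equal(res$ks, 0.1073256, tolerance = 1e-6)
  expect_equal(res$ka, 0)
  expect_equal(res$ratio, 0)

  ident <- compute_kaks(strrep("ATGGCT", 50), strrep("ATGGCT", 50))
  expect_equal(c(ident$ka, ident$ks), c(0, 0))
  expect_equal(ident$selection_class, "undetermined")
})

test_that("Ka/Ks is symmetric in the pair", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      sim <- simulate_codon_pair(60, sample(0:5, 1), sample(0:5, 1),
                                 seed = rep)
      expect_equal(compute_kaks(sim$cds_a, sim$cds_b),
                   compute_kaks(sim$cds_b, sim$cds_a))
    }
  })
})

test_that("planted (Sd, Nd) are recovered exactly over the simulation grid", {
  for (n in c(50, 100, 300)) {
    for (syn in 0:10) {
      sim <- simulate_codon_pair(n, syn, nonsyn_changes = 4,
                                 seed = 1000 + n + syn)
      d <- count_differences(sim$cds_a, sim$cds_b)
      expect_equal(unname(d), c(syn, 4))
    }
    for (nonsyn in 0:10) {
      sim <- simulate_codon_pair(n, 3, nonsyn, seed = 2000 + n + nonsyn)
      expect_equal(unname(count_differences(sim$cds_a, sim$cds_b)),
                   c(3, nonsyn))
    }
  }
})

test_that("Ks rises strictly with each added synonymous edit", {
  # fixed backbone: start from a 10-syn-edit pair and re-apply the edits
  # one at a time, so only the synonymous difference count grows
  for (n in c(50, 100, 300)) {
    sim <- simulate_codon_pair(n, 10, 0, seed = 300 + n)
    ca <- substring(sim$cds_a, seq(1, nchar(sim$cds_a), 3),
                    seq(3, nchar(sim$cds_a), 3))
    cb <- substring(sim$cds_b, seq(1, nchar(sim$cds_b), 3),
                    seq(3, nchar(sim$cds_b), 3))
    syn_idx <- which(ca != cb)
    last_ks <- -1
    for (k in 0:10) {
      bk <- ca
      bk[syn_idx[seq_len(k)]] <- cb[syn_idx[seq_len(k)]]
      res <- compute_kaks(sim$cds_a, paste(bk, collapse = ""))
      expect_equal(res$Sd, k)
      expect_gt(res$ks, last_ks)
      last_ks <- res$ks
    }
  }
})

test_that("Fisher significance equals hypergeometric tail enumeration", {
  cases <- list(c(Sd = 1, Nd = 0, S = 10, N = 20),
                c(Sd = 5, Nd = 0, S = 5, N = 20),
                c(Sd = 2, Nd = 9, S = 12, N = 30),
                c(Sd = 7, Nd = 3, S = 20, N = 41))
  for (cs in cases) {
    got <- kaks_significance(cs[["S"]], cs[["N"]], cs[["Sd"]], cs[["Nd"]])
    m <- matrix(c(cs[["Sd"]], cs[["S"]] - cs[["Sd"]],
                  cs[["Nd"]], cs[["N"]] - cs[["Nd"]]), nrow = 2)
    expect_equal(got, oracle_fisher2x2(m), tolerance = 1e-10)
  }
  expect_equal(kaks_significance(10, 20, 0, 0), 1)
  expect_lt(kaks_significance(5, 20, 5, 0), 0.05)  # extreme table
  # fractional counts are rounded half-up before the exact test
  expect_equal(kaks_significance(10.4, 20.6, 1.5, 0.2),
               oracle_fisher2x2(matrix(c(2, 9, 0, 20), nrow = 2)))
})

test_that("Ks density finds planted mixture modes and rejects thin input", {
  withr::with_seed(6, {
    ks <- c(rnorm(250, 0.3, 0.05), rnorm(250, 1.2, 0.05))
    peaks <- ks_density_peaks(ks)
    top2 <- sort(peaks$location[1:2])
    expect_lt(abs(top2[1] - 0.3), 0.1)
    expect_lt(abs(top2[2] - 1.2), 0.1)

    single <- rnorm(120, 0.5, 0.03)
    p1 <- ks_density_peaks(single)
    expect_lt(abs(p1$location[1] - 0.5), 0.05)

    # peak count invariant under permutation
    perm <- sample(ks)
    expect_equal(nrow(ks_density_peaks(perm)), nrow(peaks))
  })
  expect_error(ks_density_peaks(c(2.5, 3, 4, 2.2)), "values")
  expect_error(ks_density_peaks(rep(2, 50)), "values")  # all at/above max_ks
})

test_that("likelihood-ratio arithmetic matches the printed site-model fits", {
  fits <- read_site_model_fits(system.file("extdata", "site_model_fits.tsv",
                                           package = "crpevol"))
  lrt <- likelihood_ratio_test(fits$M7, fits$M8, df = 2)
  expect_equal(lrt$statistic, 165.74218, tolerance = 1e-5)
  expect_lt(lrt$p_value, 0.01)
  expect_equal(lrt$p_value, oracle_chisq_upper(lrt$statistic, 2),
               tolerance = 1e-12)

  same <- likelihood_ratio_test(site_model_fit("a", 100),
                                site_model_fit("b", 100), df = 2)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  worse <- likelihood_ratio_test(site_model_fit("a", 100),
                                 site_model_fit("b", 101), df = 2)
  expect_equal(worse$statistic, 0)
  expect_error(likelihood_ratio_test(fits$M7, fits$M8, df = 0), "df")
})

test_that("rate-group comparison matches the direct Bartlett formula", {
  withr::with_seed(10, {
    groups <- list(rnorm(10, 0.3, 0.1), rnorm(10, 0.4, 0.1),
                   rnorm(10, 0.2, 0.1))
    got <- rate_group_test(groups)
    expect_equal(got$statistic, oracle_bartlett(groups), tolerance = 1e-10)
    expect_equal(got$p_value,
                 pchisq(got$statistic, 2, lower.tail = FALSE))
  })
  expect_error(rate_group_test(list(c(1, 1, 1), rnorm(5))), "variance")
  expect_error(rate_group_test(list(rnorm(5))), "two groups")
})
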