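# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive route: exhaustive enumeration, direct formula
# evaluation, or graph components — never the code path under test.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")
ORACLE_CODE <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}
ORACLE_SENSE <- setdiff(names(ORACLE_CODE), ORACLE_STOPS)

# Synonymous-site count of one codon by brute enumeration of its 9 one-step
# neighbours; stop-creating changes count as nonsynonymous.
oracle_codon_sites <- function(codon) {
  s <- 0
  for (i in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, i, i)) next
      mut <- codon
      substr(mut, i, i) <- b
      if (!(mut %in% ORACLE_STOPS) &&
          ORACLE_CODE[[mut]] == ORACLE_CODE[[codon]]) {
        s <- s + 1
      }
    }
  }
  c(S = s / 3, N = 3 - s / 3)
}

# Union-find connected components of the "adjacent in sorted order and
# gap < threshold" graph; returns list of member-id vectors (size >= 2),
# ordered by chromosome then leftmost start.
oracle_clusters <- function(genes, max_gap_bp) {
  parent <- seq_len(nrow(genes))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) parent[find(i)] <<- find(j)
  for (chrom in unique(genes$chromosome)) {
    idx <- which(genes$chromosome == chrom)
    idx <- idx[order(genes$start[idx], genes$end[idx], genes$gene_id[idx])]
    if (length(idx) < 2) next
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]; j <- idx[k + 1]
      gap <- max(0, genes$start[j] - genes$end[i] - 1)
      if (gap < max_gap_bp) union_(i, j)
    }
  }
  roots <- vapply(seq_len(nrow(genes)), find, integer(1))
  comps <- split(seq_len(nrow(genes)), roots)
  comps <- Filter(function(v) length(v) >= 2, comps)
  out <- lapply(comps, function(v) {
    v <- v[order(genes$start[v], genes$end[v], genes$gene_id[v])]
    genes$gene_id[v]
  })
  key <- vapply(comps, function(v) {
    sprintf("%s_%012.0f", genes$chromosome[v[1]], min(genes$start[v]))
  }, character(1))
  out[order(key)]
}

# Exhaustive chain enumeration: all rank-monotone chains among <= 12
# anchors, both orientations; best chain under (length desc, (ra, rb)
# sequence lexicographic asc, parallel first). Iterated with removal like
# the implementation, yielding the full block list.
oracle_chains <- function(ra, rb, max_gap, min_anchors) {
  stopifnot(length(ra) <= 14)
  seq_cmp <- function(x, y) {  # TRUE if x strictly better
    if (length(x$ord) != length(y$ord)) return(length(x$ord) > length(y$ord))
    vx <- as.vector(rbind(x$ra, x$rb)); vy <- as.vector(rbind(y$ra, y$rb))
    d <- which(vx != vy)
    if (length(d)) return(vx[d[1]] < vy[d[1]])
    x$dir == 1 && y$dir != 1
  }
  blocks <- list()
  alive <- seq_along(ra)
  repeat {
    best <- NULL
    for (dir in c(1, -1)) {
      extend <- function(chain) {
        cand <- list(ord = chain, ra = ra[chain], rb = rb[chain], dir = dir)
        if (is.null(best) || seq_cmp(cand, best)) best <<- cand
        last <- chain[length(chain)]
        for (j in alive) {
          da <- ra[j] - ra[last]
          db <- dir * (rb[j] - rb[last])
          if (da > 0 && da <= max_gap && db > 0 && db <= max_gap) {
            extend(c(chain, j))
          }
        }
      }
      for (s in alive) extend(s)
    }
    if (is.null(best) || length(best$ord) < min_anchors) break
    blocks[[length(blocks) + 1]] <- best
    alive <- setdiff(alive, best$ord)
    if (!length(alive)) break
  }
  blocks
}

# Two-sided Fisher exact probability for a 2x2 table by hypergeometric
# enumeration: sum of P(tables with the same margins) <= P(observed),
# with the conventional relative tolerance.
oracle_fisher2x2 <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Bartlett statistic from the direct textbook formula.
oracle_bartlett <- function(groups) {
  k <- length(groups)
  ni <- vapply(groups, length, numeric(1))
  si2 <- vapply(groups, var, numeric(1))
  N <- sum(ni)
  sp2 <- sum((ni - 1) * si2) / (N - k)
  num <- (N - k) * log(sp2) - sum((ni - 1) * log(si2))
  den <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  num / den
}

# Upper chi-square tail; closed form for df = 2, power series for even df.
oracle_chisq_upper <- function(x, df) {
  stopifnot(df %% 2 == 0)
  m <- df / 2
  term <- 1
  acc <- 1
  for (j in seq_len(m - 1)) {
    term <- term * (x / 2) / j
    acc <- acc + term
  }
  exp(-x / 2) * acc
}
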