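# Nei-Gojobori (1986) Ka/Ks estimation.
#
# Counting method: every one-nucleotide change from each codon is classified
# synonymous or nonsynonymous against the standard genetic code; the
# synonymous fraction of the three changes at each position accumulates into
# the synonymous site count S, the rest into N. Differences between two
# codons are resolved by averaging over all mutational pathways (orderings of
# the differing positions), excluding pathways through stop codons.
# Proportions pS = Sd/S and pN = Nd/N are corrected for multiple hits with
# the one-parameter Jukes-Cantor formula.

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

#' @keywords internal
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), NA_character_, unname(aa))
}

# Per-codon (s, n) site fractions for one stop policy, cached per session.
.ng_cache <- new.env(parent = emptyenv())

#' @keywords internal
ng_codon_site_table <- function(stop_policy = c("nonsyn", "exclude")) {
  stop_policy <- match.arg(stop_policy)
  key <- stop_policy
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  codons <- names(Biostrings::GENETIC_CODE)
  codons <- gsub("U", "T", codons)
  tab <- matrix(NA_real_, nrow = length(codons), ncol = 2,
                dimnames = list(codons, c("s", "n")))
  for (codon in codons) {
    if (codon %in% STOP_CODONS) next
    aa <- translate_codon(codon)
    s <- 0
    n <- 0
    for (posn in 1:3) {
      for (b in setdiff(BASES, substr(codon, posn, posn))) {
        mut <- codon
        substr(mut, posn, posn) <- b
        if (mut %in% STOP_CODONS) {
          if (stop_policy == "nonsyn") n <- n + 1
          # "exclude": change to stop contributes to neither class; the
          # position's site total is then renormalised below
        } else if (translate_codon(mut) == aa) {
          s <- s + 1
        } else {
          n <- n + 1
        }
      }
    }
    if (stop_policy == "nonsyn") {
      tab[codon, ] <- c(s / 3, n / 3)
    } else {
      # each codon still carries 3 sites, split by the syn:nonsyn ratio
      # among non-stop-creating changes (every sense codon has >= 1 such)
      tab[codon, ] <- 3 * c(s, n) / (s + n)
    }
  }
  .ng_cache[[key]] <- tab
  tab
}

#' Synonymous and nonsynonymous site counts of a coding sequence
#'
#' For each codon position, the fraction of the three possible
#' single-nucleotide changes that are synonymous contributes to `S`; the
#' remainder to `N`. Under the default `stop_policy = "nonsyn"`, changes that
#' create a stop codon count as nonsynonymous, so `S + N = 3 * n_codons`
#' exactly; under `"exclude"` they are removed and the codon's three sites
#' are split by the remaining syn:nonsyn ratio.
#'
#' @param cds nucleotide string (ACGT, length a multiple of 3, no internal
#'   stop codon).
#' @param stop_policy `"nonsyn"` (default) or `"exclude"`.
#' @return named numeric vector `c(S = ..., N = ...)`.
#' @export
count_sites <- function(cds, stop_policy = c("nonsyn", "exclude")) {
  stop_policy <- match.arg(stop_policy)
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  if (grepl("[^ACGT]", cds)) stop("CDS alphabet must be ACGT only")
  codons <- codon_split(cds)
  if (any(codons %in% STOP_CODONS)) stop("internal stop codon in CDS")
  tab <- ng_codon_site_table(stop_policy)
  s <- sum(tab[codons, "s"])
  n <- sum(tab[codons, "n"])
  c(S = s, N = n)
}

# All orderings of k positions (k <= 3).
#' @keywords internal
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Pathway-averaged (sd, nd) between two codons. Pathways through stop codons
# are excluded; if every pathway passes through a stop, all are included
# (stops translate to "*" and a step is synonymous iff translation is equal).
#' @keywords internal
codon_pair_diff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  path_counts <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0; through_stop <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt != c2 && nxt %in% STOP_CODONS) through_stop <- TRUE
      aa_cur <- if (cur %in% STOP_CODONS) "*" else unname(code[cur])
      aa_nxt <- if (nxt %in% STOP_CODONS) "*" else unname(code[nxt])
      if (identical(aa_cur, aa_nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, through_stop = through_stop)
  }
  paths <- lapply(perms(pos), path_counts)
  ok <- !vapply(paths, `[[`, logical(1), "through_stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))   # all-stop fallback
  use <- paths[ok]
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

#' Synonymous and nonsynonymous differences between two coding sequences
#'
#' Codons differing at one position are classified directly; codons differing
#' at two (three) positions average the per-step classifications over the 2
#' (6) mutational pathways with equal weights, excluding pathways through
#' stop codons (all-stop pairs fall back to including them).
#'
#' @param cds_a,cds_b aligned coding sequences (equal length, multiple of 3,
#'   ACGT, no internal stops).
#' @return named numeric vector `c(Sd = ..., Nd = ...)` (possibly fractional).
#' @export
count_differences <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  validate_coding_pair(cds_a, cds_b)
  ca <- codon_split(cds_a); cb <- codon_split(cds_b)
  sd <- 0; nd <- 0
  for (i in which(ca != cb)) {
    d <- codon_pair_diff(ca[i], cb[i])
    sd <- sd + d[["sd"]]; nd <- nd + d[["nd"]]
  }
  c(Sd = sd, Nd = nd)
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - 4p/3)`. For `p >= 3/4` the distance is undefined
#' and `NA` is returned (the pair's Ka or Ks is marked undefined downstream,
#' not aborted).
#'
#' @param p observed substitution proportion(s) in `[0, 1]`.
#' @return corrected distance(s); `NA` where undefined.
#' @export
jukes_cantor <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportion must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

#' Fisher-exact significance of a Ka/Ks contrast
#'
#' Two-sided Fisher exact probability on the 2x2 table
#' `[[Sd, Nd], [S - Sd, N - Nd]]`, with fractional entries rounded half-up
#' to integers for the exact test. No differences (`Sd + Nd = 0`) gives
#' `p = 1`.
#'
#' @param S,N site counts (`> 0`).
#' @param Sd,Nd difference counts.
#' @return p-value in `[0, 1]`.
#' @export
kaks_significance <- function(S, N, Sd, Nd) {
  if (S <= 0 || N <= 0) stop("site counts must be positive")
  if (Sd + Nd == 0) return(1)
  m <- matrix(pmax(0, floor(c(Sd, S - Sd, Nd, N - Nd) + 0.5)), nrow = 2)
  stats::fisher.test(m)$p.value
}

#' NG86 Ka/Ks estimate for one coding pair
#'
#' Sites are averaged across the two sequences; differences are
#' pathway-averaged; proportions are Jukes-Cantor corrected. The ratio is
#' defined only when Ks is defined and positive (with the special case
#' Ka = 0, Ks > 0 giving ratio 0). A pair is called under positive selection
#' when ratio > 1 with `p < alpha`, under negative (purifying) selection when
#' ratio < 1 with `p < alpha`, otherwise undetermined.
#'
#' @param cds_a,cds_b aligned coding sequences (coding-pair invariants).
#' @param alpha significance level for the selection call, default 0.05.
#' @param stop_policy site-counting stop-codon policy, see [count_sites()].
#' @return one-row data.frame: `S`, `N`, `Sd`, `Nd`, `ka`, `ks`, `ratio`,
#'   `p_value`, `selection_class`.
#' @export
compute_kaks <- function(cds_a, cds_b, alpha = 0.05,
                         stop_policy = c("nonsyn", "exclude")) {
  stop_policy <- match.arg(stop_policy)
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  validate_coding_pair(cds_a, cds_b)
  sa <- count_sites(cds_a, stop_policy)
  sb <- count_sites(cds_b, stop_policy)
  S <- (sa[["S"]] + sb[["S"]]) / 2
  N <- (sa[["N"]] + sb[["N"]]) / 2
  d <- count_differences(cds_a, cds_b)
  Sd <- d[["Sd"]]; Nd <- d[["Nd"]]
  ks <- if (S > 0) jukes_cantor(Sd / S) else NA_real_
  ka <- if (N > 0) jukes_cantor(Nd / N) else NA_real_
  ratio <- if (!is.na(ks) && ks > 0 && !is.na(ka)) ka / ks else NA_real_
  p <- kaks_significance(S, N, Sd, Nd)
  cls <- "undetermined"
  if (!is.na(ratio) && p < alpha) {
    if (ratio > 1) cls <- "positive" else if (ratio < 1) cls <- "negative"
  }
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, ka = ka, ks = ks,
             ratio = ratio, p_value = p, selection_class = cls,
             stringsAsFactors = FALSE)
}

#' NG86 Ka/Ks over a table of coding pairs
#'
#' @param pairs data.frame with `id_a`, `id_b`, `cds_a`, `cds_b` (e.g. from
#'   [read_codon_pairs()]).
#' @inheritParams compute_kaks
#' @return data.frame, one row per pair, ids plus the [compute_kaks()]
#'   columns.
#' @export
compute_kaks_table <- function(pairs, alpha = 0.05,
                               stop_policy = c("nonsyn", "exclude")) {
  stop_policy <- match.arg(stop_policy)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    cbind(data.frame(id_a = pairs$id_a[i], id_b = pairs$id_b[i],
                     stringsAsFactors = FALSE),
          compute_kaks(pairs$cds_a[i], pairs$cds_b[i], alpha, stop_policy))
  })
  do.call(rbind, rows)
}

#' Peaks of a Ks density (duplication-burst dating)
#'
#' Ks values are filtered to the open interval `(0, max_ks)` (distant,
#' saturated pairs are uninformative for dating); a Gaussian kernel density
#' is evaluated on a 512-point grid over `(0, max_ks]` and strict local
#' maxima are returned, highest density first. Each mode is read as a burst
#' of duplication, e.g. a whole-genome duplication event.
#'
#' @param ks_values numeric vector of Ks estimates (NAs dropped).
#' @param max_ks upper filter, default 2.
#' @param bandwidth `"silverman"` (default, `bw.nrd0`) or a positive number.
#' @param min_values minimum retained values, default 10.
#' @return data.frame `location`, `density`, ordered by descending density.
#' @export
ks_density_peaks <- function(ks_values, max_ks = 2.0, bandwidth = "silverman",
                             min_values = 10) {
  x <- ks_values[!is.na(ks_values) & ks_values > 0 & ks_values < max_ks]
  if (length(x) < min_values) {
    stop("only ", length(x), " Ks values in (0, ", max_ks,
         "); need at least ", min_values)
  }
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(x) else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  grid_from <- max_ks / 512
  den <- stats::density(x, bw = bw, kernel = "gaussian",
                        from = grid_from, to = max_ks, n = 512)
  y <- den$y
  i <- 2:(length(y) - 1)
  peak <- i[y[i] > y[i - 1] & y[i] > y[i + 1]]
  out <- data.frame(location = den$x[peak], density = y[peak])
  out[order(-out$density), , drop = FALSE]
}

#' Site-model fit record
#'
#' Container for an externally fitted codon site model (e.g. M0/M7/M8):
#' only the negative log-likelihood and parameter count are consumed here,
#' for likelihood-ratio arithmetic; the model fitting itself is upstream.
#'
#' @param model_name label, e.g. `"M7"`.
#' @param neg_log_likelihood `-ln L`, finite.
#' @param n_free_params number of free parameters.
#' @return list of class `site_model_fit`.
#' @export
site_model_fit <- function(model_name, neg_log_likelihood, n_free_params = NA) {
  if (!is.finite(neg_log_likelihood)) stop("-ln L must be finite")
  structure(list(model_name = as.character(model_name),
                 neg_log_likelihood = as.numeric(neg_log_likelihood),
                 n_free_params = n_free_params),
            class = "site_model_fit")
}

#' Read site-model fits from TSV
#'
#' Columns: `model`, `neg_log_likelihood`, optional `n_free_params`.
#'
#' @param path TSV path.
#' @return named list of [site_model_fit()] records.
#' @export
read_site_model_fits <- function(path) {
  df <- read_report_tsv(path)
  fits <- lapply(seq_len(nrow(df)), function(i) {
    site_model_fit(df$model[i], df$neg_log_likelihood[i],
                   if ("n_free_params" %in% names(df)) df$n_free_params[i]
                   else NA)
  })
  names(fits) <- df$model
  fits
}

#' Likelihood-ratio test between nested site models
#'
#' `statistic = 2 * (-ln L_null - (-ln L_alt))`, clamped at 0 when the
#' alternative fits worse; p-value from the upper chi-square tail with `df`
#' degrees of freedom.
#'
#' @param fit_null,fit_alt [site_model_fit()] records (or lists with a
#'   `neg_log_likelihood` element).
#' @param df degrees of freedom (difference in free parameters), `> 0`.
#' @return list `statistic`, `p_value`, `df`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt, df) {
  if (!is.numeric(df) || length(df) != 1 || df <= 0) {
    stop("df must be a positive count")
  }
  stat <- 2 * (fit_null$neg_log_likelihood - fit_alt$neg_log_likelihood)
  stat <- max(0, stat)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df)
}

#' Bartlett homogeneity test across evolutionary-rate groups
#'
#' Compares Ka/Ks dispersion between duplicate classes (e.g. tandem vs
#' proximal vs dispersed) with Bartlett's homogeneity-of-variance statistic
#' and its chi-square p-value on k-1 degrees of freedom.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2 with
#'   positive variance.
#' @return list `statistic`, `p_value`, `df`.
#' @export
rate_group_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups")
  }
  for (k in seq_along(groups)) {
    g <- groups[[k]][!is.na(groups[[k]])]
    if (length(g) < 2) stop("group ", k, " has fewer than 2 values")
    if (stats::var(g) <= 0) stop("group ", k, " has zero variance")
    groups[[k]] <- g
  }
  bt <- stats::bartlett.test(groups)
  list(statistic = unname(bt$statistic), p_value = bt$p.value,
       df = unname(bt$parameter))
}
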