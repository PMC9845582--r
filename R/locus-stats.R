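#' Polymorphism information content of a biallelic locus
#'
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2` with `q = 1 - p`. For a biallelic
#' marker PIC is symmetric in the two alleles and maximal (0.375) at
#' `p = 0.5`.
#'
#' @param p Allele frequency (either allele), in `[0, 1]`. Vectorized.
#' @return PIC value(s) in `[0, 0.375]`.
#' @export
pic <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Unbiased expected heterozygosity
#'
#' Nei's unbiased estimator for a biallelic locus:
#' `He = 2 p q * 2n / (2n - 1)`, where `n` is the number of diploid
#' individuals.
#'
#' @param p Allele frequency in `[0, 1]`.
#' @param n Diploid sample size, `>= 1`.
#' @return Unbiased expected heterozygosity.
#' @export
expected_heterozygosity <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1))
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  2 * p * (1 - p) * 2 * n / (2 * n - 1)
}

#' Observed heterozygosity from genotype counts
#'
#' @param n_dd,n_di,n_ii Genotype counts. Vectorized.
#' @return Proportion of heterozygotes, `n_di / total`.
#' @export
observed_heterozygosity <- function(n_dd, n_di, n_ii) {
  total <- n_dd + n_di + n_ii
  if (any(total < 1)) stop("undefined statistic: zero genotype total", call. = FALSE)
  n_di / total
}

#' Matching probability and power of discrimination
#'
#' `PM` is the sum of squared observed genotype proportions over the three
#' genotype classes and `PD = 1 - PM`. Observed (not HWE-expected)
#' proportions are used, matching common forensic-software convention; see
#' [match_probability_expected()] for the HWE-expected variant.
#'
#' @param n_dd,n_di,n_ii Genotype counts. Vectorized.
#' @return Tibble with columns `pm`, `pd`.
#' @export
match_probability <- function(n_dd, n_di, n_ii) {
  total <- n_dd + n_di + n_ii
  if (any(total < 1)) stop("undefined statistic: zero genotype total", call. = FALSE)
  pm <- (n_dd / total)^2 + (n_di / total)^2 + (n_ii / total)^2
  tibble::tibble(pm = pm, pd = 1 - pm)
}

#' HWE-expected matching probability
#'
#' Variant of [match_probability()] that squares Hardy-Weinberg expected
#' genotype proportions `p^2, 2pq, q^2` instead of observed ones.
#'
#' @param p Deletion-allele frequency.
#' @return Tibble with columns `pm`, `pd`.
#' @export
match_probability_expected <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- 1 - p
  pm <- (p^2)^2 + (2 * p * q)^2 + (q^2)^2
  tibble::tibble(pm = pm, pd = 1 - pm)
}

#' Power of exclusion
#'
#' Single-locus trio exclusion probability as a function of observed
#' heterozygosity: `PE = Ho^2 * (1 - 2 Ho (1 - Ho)^2)`.
#'
#' @param ho Observed heterozygosity in `[0, 1]`. Vectorized.
#' @return PE value(s).
#' @export
power_of_exclusion <- function(ho) {
  stopifnot(all(ho >= 0 & ho <= 1))
  ho^2 * (1 - 2 * ho * (1 - ho)^2)
}

#' Typical paternity index
#'
#' `TPI = 1 / (2 (1 - Ho))`.
#'
#' @param ho Observed heterozygosity in `[0, 1)`. Vectorized.
#' @return TPI value(s), `>= 0.5`.
#' @export
typical_paternity_index <- function(ho) {
  stopifnot(all(ho >= 0 & ho <= 1))
  if (any(ho == 1)) stop("TPI is infinite at Ho = 1", call. = FALSE)
  1 / (2 * (1 - ho))
}

# Log conditional probabilities of every feasible heterozygote count given
# the allele counts (nd deletions, ni insertions among n diploids):
# P(h) proportional to n! / (n_dd! h! n_ii!) * 2^h.
hwe_het_log_probs <- function(nd, ni) {
  n <- (nd + ni) / 2
  h <- seq(nd %% 2, min(nd, ni), by = 2)
  n_dd <- (nd - h) / 2
  n_ii <- (ni - h) / 2
  lp <- lfactorial(n) - lfactorial(n_dd) - lfactorial(h) - lfactorial(n_ii) +
    h * log(2)
  lp <- lp - max(lp)
  pr <- exp(lp)
  list(h = h, prob = pr / sum(pr))
}

#' Hardy-Weinberg exact test for a biallelic locus
#'
#' Exact test conditioning on the observed allele counts: all heterozygote
#' counts of matching parity are enumerated, their conditional probabilities
#' computed, and the p-value is the sum of probabilities not exceeding that
#' of the observed configuration (the standard two-sided exact formulation).
#' A monomorphic locus returns `p = 1` by convention.
#'
#' @param n_dd,n_di,n_ii Genotype counts (scalars).
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_dd, n_di, n_ii) {
  stopifnot(n_dd >= 0, n_di >= 0, n_ii >= 0)
  if (n_dd + n_di + n_ii < 1) stop("undefined test: zero genotype total", call. = FALSE)
  nd <- 2 * n_dd + n_di
  ni <- 2 * n_ii + n_di
  if (nd == 0 || ni == 0) return(1)
  dist <- hwe_het_log_probs(nd, ni)
  p_obs <- dist$prob[dist$h == n_di]
  # tolerance absorbs floating-point ties between equal-probability tails
  sum(dist$prob[dist$prob <= p_obs * (1 + 1e-9)])
}

#' Bonferroni significance threshold
#'
#' Two conventions: for `m` single-locus tests the threshold is `alpha / m`;
#' for all pairwise tests among `m` loci it is `2 * alpha / (m * (m - 1))`
#' (the per-pair share of `alpha` over the `m(m-1)/2` pairs).
#'
#' @param m Number of loci.
#' @param alpha Family-wise error rate (default 0.05).
#' @param mode `"single"` (per-locus tests) or `"pairwise"` (LD tests).
#' @return The per-test significance threshold.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05, mode = c("single", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(m >= 1)
  switch(mode,
    single = alpha / m,
    pairwise = 2 * alpha / (m * (m - 1))
  )
}

# EM estimation of the four haplotype frequencies (DB, Db, dB, db written as
# deletion/insertion at locus 1 x locus 2) from unphased two-locus genotype
# counts. `tab` is the 3x3 table of counts indexed by deletion dosage + 1 at
# each locus.
em_haplotypes <- function(tab, max_iter = 1000, tol = 1e-12) {
  n <- sum(tab)
  # allele counts at each locus fix the marginal frequencies
  pd1 <- sum(tab * matrix(c(0, 1, 2)[row(tab)], 3)) / (2 * n)
  pd2 <- sum(tab * matrix(c(0, 1, 2)[col(tab)], 3)) / (2 * n)
  h <- c(
    dd = pd1 * pd2, di = pd1 * (1 - pd2),
    id = (1 - pd1) * pd2, ii = (1 - pd1) * (1 - pd2)
  )
  h <- pmax(h, 1e-12); h <- h / sum(h)
  n_dh <- tab[2, 2]  # double heterozygotes: phase-ambiguous
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E step: split double hets between cis (dd/ii) and trans (di/id)
    cis <- unname(h["dd"] * h["ii"])
    trans <- unname(h["di"] * h["id"])
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    # M step: haplotype counting; unambiguous contributions are linear in tab
    c_dd <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + w * n_dh
    c_di <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + (1 - w) * n_dh
    c_id <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3] + (1 - w) * n_dh
    c_ii <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + w * n_dh
    h_new <- c(dd = c_dd, di = c_di, id = c_id, ii = c_ii) / (2 * n)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      converged <- TRUE
      break
    }
    h <- h_new
  }
  list(h = h, p1 = pd1, p2 = pd2, converged = converged)
}

# Log-likelihood of a 3x3 genotype table under haplotype frequencies h
# (multinomial coefficient omitted; it cancels in likelihood ratios).
loglik_haplotypes <- function(tab, h) {
  # genotype probability at (i,j): sum over phase assignments
  gp <- matrix(0, 3, 3)
  # dosage at locus1 = r - 1, locus2 = c - 1; haplotype pairs consistent
  hs <- c(h["ii"], h["id"], h["di"], h["dd"])  # (d1,d2) = (0,0),(0,1),(1,0),(1,1)
  d1 <- c(0, 0, 1, 1); d2 <- c(0, 1, 0, 1)
  for (a in 1:4) for (b in 1:4) {
    r <- d1[a] + d1[b] + 1
    cc <- d2[a] + d2[b] + 1
    gp[r, cc] <- gp[r, cc] + hs[a] * hs[b]
  }
  keep <- tab > 0
  sum(tab[keep] * log(pmax(gp[keep], 1e-300)))
}

ld_lr_statistic <- function(tab) {
  fit <- em_haplotypes(tab)
  l_full <- loglik_haplotypes(tab, fit$h)
  h0 <- c(
    dd = fit$p1 * fit$p2, di = fit$p1 * (1 - fit$p2),
    id = (1 - fit$p1) * fit$p2, ii = (1 - fit$p1) * (1 - fit$p2)
  )
  l_indep <- loglik_haplotypes(tab, h0)
  list(stat = 2 * (l_full - l_indep), converged = fit$converged)
}

#' Permutation test of linkage disequilibrium between two biallelic loci
#'
#' Haplotype frequencies are estimated from unphased two-locus genotypes by
#' EM; the likelihood-ratio statistic `2 (lnL_full - lnL_independent)` is
#' compared with its permutation distribution obtained by shuffling one
#' locus's genotype column, `p = (#{perm >= observed} + 1) / (B + 1)`.
#'
#' @param g1,g2 Genotype vectors for the two loci (codes `DD`/`DI`/`II` or
#'   deletion dosages 0-2); pairs with a missing value at either locus are
#'   dropped.
#' @param n_perm Number of permutations `B` (default 10000).
#' @param seed Integer RNG seed for the permutations.
#' @return Tibble with columns `statistic`, `p_value`, `n`, `n_perm`,
#'   `em_converged`.
#' @export
ld_test_pair <- function(g1, g2, n_perm = 10000, seed = 1L) {
  to_dosage <- function(g) {
    if (is.character(g)) match(g, GENOTYPE_CODES) - 1L else as.integer(g)
  }
  d1 <- to_dosage(g1)
  d2 <- to_dosage(g2)
  keep <- !is.na(d1) & !is.na(d2)
  d1 <- d1[keep]; d2 <- d2[keep]
  if (length(d1) < 2) stop("need >= 2 complete two-locus genotypes", call. = FALSE)
  tabulate2 <- function(a, b) {
    m <- matrix(0, 3, 3)
    t0 <- table(factor(a, 0:2), factor(b, 0:2))
    m[] <- as.numeric(t0)
    m
  }
  obs <- ld_lr_statistic(tabulate2(d1, d2))
  set_sim_seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(d2)
    s <- ld_lr_statistic(tabulate2(d1, perm))$stat
    if (s >= obs$stat - 1e-12) exceed <- exceed + 1L
  }
  tibble::tibble(
    statistic = obs$stat,
    p_value = (exceed + 1) / (n_perm + 1),
    n = length(d1),
    n_perm = n_perm,
    em_converged = obs$converged
  )
}

#' Pairwise linkage-disequilibrium scan over a panel
#'
#' Runs [ld_test_pair()] for every locus pair within each population and
#' flags pairs significant at the pairwise Bonferroni threshold.
#'
#' @param data A genotype tibble.
#' @param n_perm Permutations per pair.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @param seed Integer base seed; each pair uses a distinct derived seed.
#' @return Tibble with columns `population`, `locus1`, `locus2`,
#'   `statistic`, `p_value`, `significant`.
#' @export
ld_scan <- function(data, n_perm = 10000, alpha = 0.05, seed = 1L) {
  validate_genotypes(data)
  loci <- locus_names(data)
  m <- length(loci)
  thr <- bonferroni_threshold(m, alpha, "pairwise")
  pops <- unique(data$population)
  out <- list()
  idx <- 0L
  for (pop in pops) {
    sub <- data[data$population == pop, ]
    for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) {
      idx <- idx + 1L
      res <- ld_test_pair(
        sub[[loci[i]]], sub[[loci[j]]],
        n_perm = n_perm, seed = (seed + idx) %% .Machine$integer.max
      )
      out[[idx]] <- tibble::tibble(
        population = pop, locus1 = loci[i], locus2 = loci[j],
        statistic = res$statistic, p_value = res$p_value
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res$significant <- res$p_value < thr
  res
}

#' Per-locus forensic parameter table
#'
#' Computes, per locus and population, the full set of single-locus
#' forensic parameters: deletion frequency, observed and unbiased expected
#' heterozygosity, PIC, matching probability, powers of discrimination and
#' exclusion, typical paternity index, and the Hardy-Weinberg exact-test
#' p-value with its Bonferroni flag across the panel.
#'
#' @param data A genotype tibble.
#' @param alpha Family-wise error rate for the HWE Bonferroni flag.
#' @return Tibble with one row per locus x population and columns
#'   `locus`, `population`, `p_del`, `n`, `ho`, `he`, `pic`, `pm`, `pd`,
#'   `pe`, `tpi`, `hwe_p`, `hwe_flag`.
#' @export
locus_stats <- function(data, alpha = 0.05) {
  counts <- genotype_counts(data)
  m <- length(locus_names(data))
  thr <- bonferroni_threshold(m, alpha, "single")
  counts |>
    dplyr::mutate(
      n = .data$n_dd + .data$n_di + .data$n_ii,
      p_del = (2 * .data$n_dd + .data$n_di) / (2 * .data$n),
      ho = observed_heterozygosity(.data$n_dd, .data$n_di, .data$n_ii),
      he = expected_heterozygosity(.data$p_del, .data$n),
      pic = pic(.data$p_del),
      pm = match_probability(.data$n_dd, .data$n_di, .data$n_ii)$pm,
      pd = 1 - .data$pm,
      pe = power_of_exclusion(.data$ho),
      # Inf (not an error) for the degenerate all-heterozygote table, so a
      # single extreme locus cannot abort a whole panel report
      tpi = ifelse(.data$ho < 1, 1 / (2 * (1 - .data$ho)), Inf),
      hwe_p = purrr::pmap_dbl(
        list(.data$n_dd, .data$n_di, .data$n_ii), hwe_exact_test
      ),
      hwe_flag = .data$hwe_p < thr
    ) |>
    dplyr::select(
      "locus", "population", "p_del", "n", "ho", "he", "pic",
      "pm", "pd", "pe", "tpi", "hwe_p", "hwe_flag"
    )
}

#' Round half-up for report display
#'
#' Report-style rounding to match printed forensic tables (R's `round()`
#' rounds half to even). Internal computation is always full precision;
#' this helper is for display only.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 4).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 4) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
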