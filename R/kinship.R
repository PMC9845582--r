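#' Kinship hypotheses by IBD coefficients
#'
#' A kinship hypothesis is a triple `(k0, k1, k2)` of probabilities that a
#' pair of individuals shares 0, 1 or 2 alleles identical by descent at an
#' autosomal locus. Named shortcuts: `"full_sibling"` (1/4, 1/2, 1/4),
#' `"half_sibling"` (1/2, 1/2, 0) — the same class as avuncular and
#' grandparent-grandchild pairs — and `"unrelated"` (1, 0, 0).
#'
#' @param name Label for the hypothesis, or one of the shortcuts above.
#' @param k0,k1,k2 IBD-sharing probabilities; must be nonnegative and sum
#'   to 1. Omitted when `name` is a shortcut.
#' @return A `kinship_hypothesis` object (named list with `name`, `k0`,
#'   `k1`, `k2`).
#' @export
kinship_hypothesis <- function(name, k0 = NULL, k1 = NULL, k2 = NULL) {
  presets <- list(
    full_sibling = c(0.25, 0.5, 0.25),
    half_sibling = c(0.5, 0.5, 0),
    unrelated = c(1, 0, 0)
  )
  if (is.null(k0)) {
    if (!name %in% names(presets)) {
      stop("unknown hypothesis '", name, "'; supply k0, k1, k2", call. = FALSE)
    }
    k <- presets[[name]]
  } else {
    k <- c(k0, k1, k2)
  }
  if (any(k < 0) || abs(sum(k) - 1) > 1e-12) {
    stop("k0, k1, k2 must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(
    list(name = name, k0 = k[1], k1 = k[2], k2 = k[3]),
    class = "kinship_hypothesis"
  )
}

as_kinship_hypothesis <- function(x) {
  if (inherits(x, "kinship_hypothesis")) return(x)
  if (is.character(x) && length(x) == 1L) return(kinship_hypothesis(x))
  stop("not a kinship hypothesis", call. = FALSE)
}

#' @export
print.kinship_hypothesis <- function(x, ...) {
  cat(sprintf(
    "<kinship_hypothesis> %s: k0 = %g, k1 = %g, k2 = %g\n",
    x$name, x$k0, x$k1, x$k2
  ))
  invisible(x)
}

# HWE genotype probabilities indexed by deletion dosage 0:2 (II, DI, DD).
hwe_probs <- function(p) {
  q <- 1 - p
  c(q^2, 2 * p * q, p^2)
}

# One-IBD-allele transition matrix T[g1+1, g2+1]: the pair shares one allele
# drawn uniformly from g1's two alleles, the other allele of g2 is a fresh
# population draw. Rows/cols indexed by deletion dosage.
ibd1_transition <- function(p) {
  q <- 1 - p
  rbind(
    c(q,     p,     0),     # from II: shared I, new allele I (q) or D (p)
    c(q / 2, 1 / 2, p / 2), # from DI
    c(0,     q,     p)      # from DD
  )
}

#' Joint probability of a genotype pair under a kinship hypothesis
#'
#' `P(g1, g2 | k) = P(g1) * (k0 P(g2) + k1 T(g2 | g1) + k2 1(g1 = g2))`,
#' with `P` the HWE genotype probabilities at deletion frequency `p` and
#' `T` the one-shared-allele transition kernel.
#'
#' @param g1,g2 Genotype codes (`"DD"`, `"DI"`, `"II"`) or deletion dosages
#'   (0, 1, 2).
#' @param p Deletion-allele frequency, strictly inside (0, 1).
#' @param hypothesis A [kinship_hypothesis()] or shortcut name.
#' @return The joint probability.
#' @export
pair_likelihood <- function(g1, g2, p, hypothesis) {
  hyp <- as_kinship_hypothesis(hypothesis)
  if (any(p <= 0 | p >= 1)) stop("degenerate locus: p must be in (0,1)", call. = FALSE)
  d1 <- if (is.character(g1)) match(g1, GENOTYPE_CODES) + 1L else as.integer(g1) + 1L
  d2 <- if (is.character(g2)) match(g2, GENOTYPE_CODES) + 1L else as.integer(g2) + 1L
  pr <- hwe_probs(p)
  tr <- ibd1_transition(p)
  pr[d1] * (hyp$k0 * pr[d2] + hyp$k1 * tr[cbind(d1, d2)] + hyp$k2 * (d1 == d2))
}

# 3x3 matrices of log10 LR contributions per (g1 dosage + 1, g2 dosage + 1)
# for one locus; used to vectorize multi-locus LR computation.
lr_table <- function(p, h1, h2) {
  g <- 0:2
  grid <- expand.grid(g1 = g, g2 = g)
  num <- pair_likelihood(grid$g1, grid$g2, p, h1)
  den <- pair_likelihood(grid$g1, grid$g2, p, h2)
  matrix(log10(num) - log10(den), 3, 3)
}

#' Multi-locus kinship likelihood ratio
#'
#' `LR = prod over loci of P(pair | H1) / P(pair | H2)`, accumulated as a
#' log10 sum. Loci where either individual is missing are skipped and
#' counted.
#'
#' @param g1,g2 Per-locus genotype vectors for the two individuals (codes
#'   or deletion dosages, same locus order as `freqs`).
#' @param freqs Frequency tibble (`locus`, `p_del`) or numeric vector of
#'   deletion frequencies, all strictly inside (0, 1).
#' @param h1,h2 Kinship hypotheses (objects or shortcut names); defaults
#'   full sibling versus unrelated.
#' @return Tibble with columns `log10_lr`, `lr`, `n_loci_used`,
#'   `n_loci_skipped`.
#' @export
kinship_lr <- function(g1, g2, freqs, h1 = "full_sibling", h2 = "unrelated") {
  freqs <- as_freq_tbl(freqs)
  h1 <- as_kinship_hypothesis(h1)
  h2 <- as_kinship_hypothesis(h2)
  stopifnot(length(g1) == nrow(freqs), length(g2) == nrow(freqs))
  d1 <- if (is.character(g1)) match(g1, GENOTYPE_CODES) - 1L else as.integer(g1)
  d2 <- if (is.character(g2)) match(g2, GENOTYPE_CODES) - 1L else as.integer(g2)
  keep <- !is.na(d1) & !is.na(d2)
  log10_lr <- 0
  for (j in which(keep)) {
    num <- pair_likelihood(d1[j], d2[j], freqs$p_del[j], h1)
    den <- pair_likelihood(d1[j], d2[j], freqs$p_del[j], h2)
    if (den == 0) {
      log10_lr <- Inf
      break
    }
    log10_lr <- log10_lr + log10(num) - log10(den)
  }
  tibble::tibble(
    log10_lr = log10_lr,
    lr = 10^log10_lr,
    n_loci_used = sum(keep),
    n_loci_skipped = sum(!keep)
  )
}

# Vectorized log10 LR for dosage matrices (pairs x loci).
log10_lr_matrix <- function(g1, g2, p, h1, h2) {
  h1 <- as_kinship_hypothesis(h1)
  h2 <- as_kinship_hypothesis(h2)
  out <- numeric(nrow(g1))
  for (j in seq_along(p)) {
    tab <- lr_table(p[j], h1, h2)
    out <- out + tab[cbind(g1[, j] + 1L, g2[, j] + 1L)]
  }
  out
}

#' Expected likelihood ratio under the defense hypothesis
#'
#' Analytic calibration identity: summing `P(pair | H2) * LR(pair)` over
#' all nine genotype pairs at one locus gives exactly 1 for any valid
#' hypothesis pair and any frequency. Exposed as a numerical check.
#'
#' @param p Deletion-allele frequency in (0, 1).
#' @param h1,h2 Kinship hypotheses (objects or shortcut names).
#' @return The expectation (should equal 1 to floating-point accuracy).
#' @export
mean_lr_check <- function(p, h1 = "full_sibling", h2 = "unrelated") {
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  num <- pair_likelihood(grid$g1, grid$g2, p, h1)
  den <- pair_likelihood(grid$g1, grid$g2, p, h2)
  sum(den * (num / den))
}

#' Simulated kinship-discrimination study
#'
#' For each claimed relationship, simulates `n_pairs` related pairs (the
#' prosecution hypothesis H1) and `n_pairs` unrelated pairs (the defense
#' hypothesis H2) at the supplied locus frequencies, computes the per-pair
#' multi-locus LR of H1 versus unrelated, and tabulates, per LR limit `t`,
#' the accuracy `P(LR > t | related)` and false-positive rate
#' `P(LR > t | unrelated)`. Calls use strict `LR > t`; ties are negative.
#'
#' @param freqs Frequency tibble (`locus`, `p_del`) or numeric vector; any
#'   locus with `p` of 0 or 1 is excluded with a warning.
#' @param n_pairs Pairs per class (default 1000).
#' @param relationships Character vector of H1 relationships.
#' @param thresholds Ascending positive LR limits.
#' @param seed Integer RNG seed.
#' @return A `dip_lr_study` object: list with `rates` (tibble:
#'   `relationship`, `threshold`, `accuracy`, `false_positive`, both as
#'   percentages), `log10_lr` (tibble of per-pair values by class),
#'   `n_pairs`, `thresholds`, `seed`.
#' @export
run_lr_study <- function(freqs, n_pairs = 1000,
                         relationships = c("full_sibling", "half_sibling"),
                         thresholds = c(1, 10, 100, 1000, 10000),
                         seed = 1L) {
  freqs <- as_freq_tbl(freqs)
  stopifnot(n_pairs >= 1, all(thresholds > 0), !is.unsorted(thresholds))
  degenerate <- freqs$p_del <= 0 | freqs$p_del >= 1
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate locus/loci (p of 0 or 1) excluded",
            call. = FALSE)
    freqs <- freqs[!degenerate, ]
  }
  if (nrow(freqs) == 0L) stop("no usable loci", call. = FALSE)
  rates <- list()
  lls <- list()
  for (i in seq_along(relationships)) {
    rel <- relationships[i]
    h1 <- kinship_hypothesis(rel)
    rel_seed <- (seed + 7919L * i) %% .Machine$integer.max
    related <- simulate_kin_pairs(freqs, n_pairs, h1, seed = rel_seed)
    unrel <- simulate_kin_pairs(
      freqs, n_pairs, "unrelated", seed = (rel_seed + 1L) %% .Machine$integer.max
    )
    ll_rel <- log10_lr_matrix(related$g1, related$g2, freqs$p_del, h1, "unrelated")
    ll_unr <- log10_lr_matrix(unrel$g1, unrel$g2, freqs$p_del, h1, "unrelated")
    lt <- log10(thresholds)
    rates[[i]] <- tibble::tibble(
      relationship = rel,
      threshold = thresholds,
      accuracy = vapply(lt, function(t) 100 * mean(ll_rel > t), numeric(1)),
      false_positive = vapply(lt, function(t) 100 * mean(ll_unr > t), numeric(1))
    )
    lls[[i]] <- tibble::tibble(
      relationship = rel,
      class = rep(c("related", "unrelated"), each = n_pairs),
      log10_lr = c(ll_rel, ll_unr)
    )
  }
  structure(
    list(
      rates = dplyr::bind_rows(rates),
      log10_lr = dplyr::bind_rows(lls),
      n_pairs = n_pairs,
      thresholds = thresholds,
      seed = seed
    ),
    class = "dip_lr_study"
  )
}

#' @export
print.dip_lr_study <- function(x, ...) {
  cat(sprintf(
    "<dip_lr_study> %d pairs per class, thresholds: %s\n",
    x$n_pairs, paste(x$thresholds, collapse = ", ")
  ))
  print(x$rates, n = nrow(x$rates))
  invisible(x)
}
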