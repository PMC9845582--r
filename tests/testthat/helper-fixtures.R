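# Shared fixtures and independent oracles used across the suite.

# Tiny well-formed genotype tibble: 3 samples, 2 loci.
tiny_genotypes <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    population = c("popA", "popA", "popB"),
    continent = c("X", "X", "Y"),
    rs001 = c("DD", "DI", "II"),
    rs002 = c("DI", "DI", "DD")
  )
}

# Genotype tibble realizing exact genotype counts for one locus/population.
counts_genotypes <- function(n_dd, n_di, n_ii, locus = "rs1", population = "pop") {
  g <- c(rep("DD", n_dd), rep("DI", n_di), rep("II", n_ii))
  out <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_along(g)),
    population = population,
    continent = NA_character_
  )
  out[[locus]] <- g
  out
}

# Independent HWE exact-test oracle: conditional heterozygote-count
# distribution built by the upward recurrence
#   P(h + 2) / P(h) = 4 n_dd n_ii / ((h + 1)(h + 2))
# (a different route than the package's direct log-multinomial evaluation).
hwe_oracle <- function(n_dd, n_di, n_ii) {
  nd <- 2 * n_dd + n_di
  ni <- 2 * n_ii + n_di
  if (nd == 0 || ni == 0) return(1)
  h_min <- nd %% 2
  h_max <- min(nd, ni)
  hs <- seq(h_min, h_max, by = 2)
  pr <- numeric(length(hs))
  pr[1] <- 1
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1]
    ndd <- (nd - h) / 2
    nii <- (ni - h) / 2
    pr[i] <- pr[i - 1] * 4 * ndd * nii / ((h + 1) * (h + 2))
  }
  pr <- pr / sum(pr)
  p_obs <- pr[hs == n_di]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# Gene-dropping oracle for full siblings: enumerate both parents' ordered
# genotypes and all four inheritance patterns, independent of the package's
# IBD-coefficient formulation.
fullsib_joint_oracle <- function(p, g1, g2) {
  q <- 1 - p
  total <- 0
  for (f1 in 0:1) for (f2 in 0:1) for (m1 in 0:1) for (m2 in 0:1) {
    # allele coded 1 = deletion, drawn Bernoulli(p)
    w <- prod(ifelse(c(f1, f2, m1, m2) == 1, p, q))
    for (i1 in 1:2) for (j1 in 1:2) for (i2 in 1:2) for (j2 in 1:2) {
      c1 <- c(f1, f2)[i1] + c(m1, m2)[j1]
      c2 <- c(f1, f2)[i2] + c(m1, m2)[j2]
      if (c1 == g1 && c2 == g2) total <- total + w / 16
    }
  }
  total
}

# Exact distribution of the multi-locus log10 LR under a hypothesis, by
# iterated discrete convolution of the 9-outcome per-locus distribution.
# Returns a function pr_exceed(log10_t) = P(sum > log10_t).
convolution_oracle <- function(p_vec, h_sim, h1 = "full_sibling",
                               h2 = "unrelated") {
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  dist <- c(`0` = 1)
  for (p in p_vec) {
    num <- dippanel::pair_likelihood(grid$g1, grid$g2, p, h1)
    den <- dippanel::pair_likelihood(grid$g1, grid$g2, p, h2)
    vals <- log10(num) - log10(den)
    probs <- dippanel::pair_likelihood(grid$g1, grid$g2, p, h_sim)
    new_vals <- as.numeric(outer(as.numeric(names(dist)), vals, `+`))
    new_probs <- as.numeric(outer(dist, probs, `*`))
    key <- sprintf("%.8f", new_vals)
    agg <- tapply(new_probs, key, sum)
    dist <- as.numeric(agg)
    names(dist) <- names(agg)
  }
  vals <- as.numeric(names(dist))
  function(log10_t) sum(dist[vals > log10_t + 1e-9])
}
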