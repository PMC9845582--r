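test_that("Weir-Cockerham theta behaves at the null and at fixation", {
  # identical source frequencies: theta near zero (may be slightly negative)
  sp <- rep(0.5, 43)
  d1 <- simulate_population(sp, 500, seed = 41, population = "a")
  d2 <- simulate_population(sp, 500, seed = 42, population = "b")
  th <- pairwise_fst(dplyr::bind_rows(d1, d2))
  expect_lt(abs(th["a", "b"]), 0.01)
  expect_equal(th, t(th))
  expect_equal(diag(th), c(a = 0, b = 0))

  # fixed difference: theta = 1 at any sample size
  fx <- dplyr::bind_rows(
    counts_genotypes(20, 0, 0, locus = "l", population = "a"),
    counts_genotypes(0, 0, 30, locus = "l", population = "b")
  )
  expect_equal(pairwise_fst(fx)["a", "b"], 1)

  # small populations are excluded with a warning
  tiny <- dplyr::bind_rows(
    counts_genotypes(5, 5, 5, population = "big"),
    counts_genotypes(3, 4, 3, population = "big2"),
    counts_genotypes(1, 0, 0, population = "solo")
  )
  expect_warning(m <- pairwise_fst(tiny), "solo")
  expect_false("solo" %in% rownames(m))

  # clamped copy floors negatives at zero
  expect_true(all(pairwise_fst(dplyr::bind_rows(d1, d2), clamp = TRUE) >= 0))
})

test_that("Nei's standard distance matches hand evaluation and symmetry", {
  fr <- tibble::tibble(
    locus = c("l1", "l1"), population = c("x", "y"), p_del = c(0.9, 0.1)
  )
  d <- nei_distance(fr)
  expect_equal(d["x", "y"], -log(0.18 / 0.82), tolerance = 1e-10)
  expect_equal(round(d["x", "y"], 4), 1.5163)

  same <- tibble::tibble(
    locus = rep(c("l1", "l2"), 2),
    population = rep(c("x", "y"), each = 2),
    p_del = rep(c(0.3, 0.7), 2)
  )
  expect_equal(nei_distance(same)["x", "y"], 0)

  set.seed(8)
  fr2 <- tidyr::expand_grid(locus = sprintf("l%d", 1:10), population = c("x", "y"))
  fr2$p_del <- runif(nrow(fr2))
  m <- nei_distance(fr2)
  expect_equal(m["x", "y"], m["y", "x"])
  expect_true(all(m >= 0))
})

test_that("informativeness for assignment has its analytic anchors", {
  eq <- tibble::tibble(
    locus = rep("l1", 3), population = c("a", "b", "c"), p_del = rep(0.4, 3)
  )
  expect_equal(informativeness_for_assignment(eq)$in_value, 0)

  two <- tibble::tibble(
    locus = "l1", population = c("a", "b"), p_del = c(0.9, 0.1)
  )
  iv <- informativeness_for_assignment(two)$in_value
  expect_equal(iv, 0.3680642, tolerance = 1e-6)

  solo <- tibble::tibble(locus = "l1", population = "a", p_del = 0.77)
  expect_equal(informativeness_for_assignment(solo)$in_value, 0)

  # additivity over loci and invariance to allele relabeling (p -> 1 - p)
  set.seed(9)
  fr <- tidyr::expand_grid(locus = sprintf("l%d", 1:6), population = c("a", "b", "c"))
  fr$p_del <- runif(nrow(fr))
  per_locus <- informativeness_for_assignment(fr)
  total <- sum(per_locus$in_value)
  by_hand <- sum(vapply(unique(fr$locus), function(lc) {
    informativeness_for_assignment(fr[fr$locus == lc, ])$in_value
  }, numeric(1)))
  expect_equal(total, by_hand, tolerance = 1e-12)
  flipped <- dplyr::mutate(fr, p_del = 1 - p_del)
  expect_equal(
    dplyr::arrange(informativeness_for_assignment(flipped), locus)$in_value,
    dplyr::arrange(per_locus, locus)$in_value,
    tolerance = 1e-12
  )
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 taxa: closed-form three-point branch lengths
  dm <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  cp <- ape::cophenetic.phylo(tr)[rownames(dm), rownames(dm)]
  expect_equal(cp, dm, tolerance = 1e-10)

  # random additive matrices from known trees, up to 8 taxa
  set.seed(12)
  for (i in 1:15) {
    n_tip <- sample(4:8, 1)
    true_tr <- ape::rtree(n_tip, rooted = FALSE)
    true_tr$edge.length <- runif(length(true_tr$edge.length), 0.1, 2)
    dm2 <- ape::cophenetic.phylo(true_tr)
    got <- neighbor_joining(dm2)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tr), got)), 0)
    cp2 <- ape::cophenetic.phylo(got)[rownames(dm2), colnames(dm2)]
    expect_equal(cp2, dm2, tolerance = 1e-8)
  }

  # label-permutation invariance
  perm <- c(3, 1, 2)
  tr_p <- neighbor_joining(dm[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(tr, tr_p)), 0)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "square|symmetric")
  bad <- dm; bad[1, 2] <- NA; bad[2, 1] <- NA
  expect_error(neighbor_joining(bad), "NA")
})

test_that("classical MDS embeds distances self-consistently", {
  set.seed(14)
  pts <- matrix(rnorm(12), ncol = 2)
  rownames(pts) <- letters[1:6]
  dm <- as.matrix(dist(pts))
  emb <- classical_mds(dm, dims = 2)
  emb_d <- as.matrix(dist(as.matrix(emb[, c("dim1", "dim2")])))
  expect_equal(unname(emb_d), unname(dm), tolerance = 1e-8)
  vf <- attr(emb, "variance_fraction")
  expect_true(all(diff(vf) <= 1e-12))

  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  emb0 <- classical_mds(zero, dims = 2)
  expect_true(all(emb0$dim1 == 0 & emb0$dim2 == 0))

  # permutation invariance up to rotation/reflection: compare distance
  # matrices of the two embeddings (a Procrustes-free equivalent)
  perm <- sample(6)
  emb_p <- classical_mds(dm[perm, perm], dims = 2)
  d_p <- as.matrix(dist(as.matrix(emb_p[, c("dim1", "dim2")])))
  ord <- match(rownames(dm), emb_p$label)
  expect_equal(unname(d_p[ord, ord]), unname(dm), tolerance = 1e-8)
})

test_that("PCA separates structured populations and reports sane fractions", {
  sp <- rep(0.5, 43)
  ds <- simulate_structured_populations(
    sp, fst = 0.2, sizes = c(a = 60, b = 60), continents = c("A", "B"), seed = 15
  )
  pc <- pca_panel(ds, level = "individual", dims = 3)
  vf <- attr(pc, "variance_fraction")
  expect_true(all(diff(vf) <= 1e-12))
  expect_lte(sum(vf), 1 + 1e-9)
  # silhouette of the two groups on PC1
  s <- split(pc$pc1, pc$group)
  gap <- abs(mean(s$a) - mean(s$b))
  spread <- sqrt((stats::var(s$a) + stats::var(s$b)) / 2)
  expect_gt(gap / spread, 1)

  # population-level PCA on frequencies
  fr <- estimate_frequencies(ds)
  pcp <- pca_panel(fr, level = "population", dims = 1)
  expect_equal(nrow(pcp), 2L)
})
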