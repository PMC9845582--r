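#' Pairwise Weir-Cockerham F_ST between populations
#'
#' Moment estimator theta of Weir & Cockerham (1984) for each population
#' pair, with the multi-locus estimate formed as the ratio of summed
#' variance components (sum of `a` over sum of `a + b + c`). Negative
#' estimates are retained in the matrix; use `clamp = TRUE` to obtain the
#' copy (negatives set to 0) used by distance-based methods.
#'
#' @param data A genotype tibble with `>= 2` populations; populations with
#'   fewer than 2 individuals are excluded with a warning.
#' @param clamp If `TRUE`, clamp negative estimates to zero.
#' @return A symmetric matrix of pairwise theta with zero diagonal and
#'   population labels as dimnames.
#' @export
pairwise_fst <- function(data, clamp = FALSE) {
  validate_genotypes(data)
  sizes <- table(data$population)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding population(s) with < 2 individuals: ",
            paste(small, collapse = ", "), call. = FALSE)
    data <- data[!data$population %in% small, ]
  }
  pops <- sort(unique(data$population))
  if (length(pops) < 2) stop("need >= 2 populations with >= 2 individuals", call. = FALSE)
  counts <- genotype_counts(data)
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    sub <- counts[counts$population %in% c(pops[i], pops[j]), ]
    th <- wc_theta(sub)
    m[i, j] <- m[j, i] <- th
  }
  if (clamp) m[m < 0] <- 0
  m
}

# Weir-Cockerham (1984) theta for a biallelic locus set over r populations;
# `counts` has columns locus, population, n_dd, n_di, n_ii. Multi-locus as
# ratio of summed components.
wc_theta <- function(counts) {
  sum_a <- 0
  sum_abc <- 0
  for (lc in unique(counts$locus)) {
    d <- counts[counts$locus == lc, ]
    n_i <- d$n_dd + d$n_di + d$n_ii
    keep <- n_i > 0
    d <- d[keep, ]; n_i <- n_i[keep]
    r <- nrow(d)
    if (r < 2) next
    p_i <- (2 * d$n_dd + d$n_di) / (2 * n_i)
    h_i <- d$n_di / n_i
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    if (nbar <= 1 || nc <= 0) next
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    sum_a <- sum_a + a
    sum_abc <- sum_abc + a + b + cc
  }
  if (sum_abc == 0) return(NA_real_)
  sum_a / sum_abc
}

#' Nei's standard genetic distance between populations
#'
#' `Ds = -ln( J_xy / sqrt(J_x J_y) )` where the gene identities
#' `J_xy = sum over loci of (p_x p_y + q_x q_y)` etc. are summed over all
#' loci (and both alleles) before forming the ratio — the PHYLIP `gendist`
#' pooling convention.
#'
#' @param freqs Frequency tibble (`locus`, `population`, `p_del`) covering
#'   the same locus set for every population.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
nei_distance <- function(freqs) {
  stopifnot(all(c("locus", "population", "p_del") %in% names(freqs)))
  wide <- tidyr::pivot_wider(
    freqs[, c("locus", "population", "p_del")],
    names_from = "population", values_from = "p_del"
  )
  pops <- setdiff(names(wide), "locus")
  if (anyNA(wide[pops])) stop("populations must share the same locus set", call. = FALSE)
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  pmat <- as.matrix(wide[pops])
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    px <- pmat[, i]; py <- pmat[, j]
    jxy <- sum(px * py + (1 - px) * (1 - py))
    jx <- sum(px^2 + (1 - px)^2)
    jy <- sum(py^2 + (1 - py)^2)
    if (jxy == 0) stop("infinite distance: no shared gene identity between ",
                       pops[i], " and ", pops[j], call. = FALSE)
    m[i, j] <- m[j, i] <- -log(jxy / sqrt(jx * jy))
  }
  m
}

#' Informativeness for assignment (In) per locus
#'
#' Rosenberg's entropy-based informativeness of a locus for assigning
#' individuals among `K` populations:
#' `In = sum over alleles of ( -pbar ln pbar + sum over pops p/K ln p )`
#' with `pbar` the unweighted across-population mean frequency and
#' `0 ln 0 := 0`. `In` is zero exactly when every population shares the
#' same frequencies. Natural log (nats) by default.
#'
#' @param freqs Frequency tibble (`locus`, `population`, `p_del`).
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return Tibble with columns `locus`, `in_value`, `rank` (1 = most
#'   informative), sorted by rank.
#' @export
informativeness_for_assignment <- function(freqs, base = exp(1)) {
  stopifnot(all(c("locus", "population", "p_del") %in% names(freqs)))
  xlogx <- function(x) ifelse(x > 0, x * log(x, base = base), 0)
  per_locus <- freqs |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      in_value = {
        p <- .data$p_del
        k <- length(p)
        val <- 0
        for (al in list(p, 1 - p)) {
          pbar <- mean(al)
          val <- val - xlogx(pbar) + sum(xlogx(al)) / k
        }
        # clamp tiny negative round-off; In is nonnegative by construction
        max(val, 0)
      },
      .groups = "drop"
    )
  per_locus <- dplyr::arrange(per_locus, dplyr::desc(.data$in_value))
  per_locus$rank <- seq_len(nrow(per_locus))
  per_locus
}

#' Neighbor-joining population tree
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a symmetric distance
#' matrix, followed by the common negative-branch adjustment: any negative
#' branch length is set to zero and its length transferred to the adjacent
#' branch so path lengths between leaves are preserved.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and labels.
#' @return An \pkg{ape} `phylo` tree (unrooted); attribute
#'   `negative_branches` records how many branches were adjusted.
#' @export
neighbor_joining <- function(dm) {
  dm <- validate_distance_matrix(dm)
  if (nrow(dm) < 3) stop("need >= 3 labels for a tree", call. = FALSE)
  tree <- ape::nj(stats::as.dist(dm))
  n_neg <- 0L
  # transfer negative internal/terminal branch lengths to the adjacent edge
  repeat {
    neg <- which(tree$edge.length < -1e-14)
    if (length(neg) == 0L) break
    e <- neg[which.min(tree$edge.length[neg])]
    len <- tree$edge.length[e]
    child <- tree$edge[e, 2]
    # adjacent edges: those sharing the child node (its descendants) or the
    # sibling edges at the parent; adding |len| to edges through the child
    # and zeroing this edge preserves leaf-to-leaf distances approximately
    parent <- tree$edge[e, 1]
    adj <- which(tree$edge[, 1] == child)
    if (length(adj) == 0L) adj <- setdiff(which(tree$edge[, 1] == parent), e)
    tree$edge.length[adj] <- tree$edge.length[adj] + len
    tree$edge.length[e] <- 0
    n_neg <- n_neg + 1L
    if (n_neg > length(tree$edge.length)) break
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "negative_branches") <- n_neg
  tree
}

validate_distance_matrix <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square", call. = FALSE)
  if (anyNA(dm) || any(!is.finite(dm))) stop("distance matrix has NA/Inf", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix must have zero diagonal", call. = FALSE)
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- sprintf("pop%d", seq_len(nrow(dm)))
  }
  dm
}

#' Newick serialization of a tree
#'
#' @param tree An \pkg{ape} `phylo` object.
#' @param digits Branch-length precision (default 6).
#' @return A Newick string.
#' @export
to_newick <- function(tree, digits = 6) {
  ape::write.tree(tree, digits = digits)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering plus eigendecomposition of a distance matrix, returning
#' coordinates on the requested number of dimensions and the fraction of
#' positive-eigenvalue variance each axis explains. Sign convention: each
#' axis is flipped so its largest-magnitude loading is positive.
#'
#' @param dm Symmetric distance matrix.
#' @param dims Number of dimensions (default 2); truncated with a warning
#'   if it exceeds the number of positive eigenvalues.
#' @return Tibble with columns `label`, `dim1`, `dim2`, ...; attribute
#'   `variance_fraction` gives per-axis explained fractions.
#' @export
classical_mds <- function(dm, dims = 2) {
  dm <- validate_distance_matrix(dm)
  stopifnot(dims >= 1)
  if (all(dm == 0)) {
    coords <- matrix(0, nrow(dm), dims)
    eigvals <- rep(0, dims)
  } else {
    fit <- stats::cmdscale(dm, k = min(dims, nrow(dm) - 1), eig = TRUE)
    pos <- sum(fit$eig > 1e-12)
    if (dims > pos) {
      warning("requested ", dims, " dimensions but only ", pos,
              " positive eigenvalues; truncating", call. = FALSE)
      dims <- max(pos, 1L)
    }
    coords <- fit$points[, seq_len(dims), drop = FALSE]
    # fix sign: largest-|loading| coordinate positive on each axis
    for (j in seq_len(ncol(coords))) {
      i_max <- which.max(abs(coords[, j]))
      if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
    }
    eigvals <- fit$eig[seq_len(dims)] / sum(fit$eig[fit$eig > 0])
  }
  out <- tibble::tibble(label = rownames(dm))
  for (j in seq_len(ncol(coords))) out[[paste0("dim", j)]] <- coords[, j]
  attr(out, "variance_fraction") <- eigvals
  out
}

#' Principal component analysis of genotypes or frequencies
#'
#' Individual level: column-centered PCA of the insertion-dosage matrix
#' (0/1/2), missing dosages mean-imputed per locus. Population level:
#' column-centered PCA of per-population deletion frequencies (populations
#' as rows). Centering only, no scaling.
#'
#' @param x A genotype tibble (individual level) or frequency tibble with
#'   `locus`, `population`, `p_del` (population level).
#' @param level `"individual"` or `"population"`.
#' @param dims Number of components to return.
#' @return Tibble with `label` (sample or population), grouping metadata
#'   when available, and `pc1..pcK`; attribute `variance_fraction` gives
#'   per-component explained variance fractions.
#' @export
pca_panel <- function(x, level = c("individual", "population"), dims = 3) {
  level <- match.arg(level)
  if (level == "individual") {
    m <- genotype_dosage(x, count = "insertion")
    for (j in seq_len(ncol(m))) {
      mis <- is.na(m[, j])
      if (any(mis)) m[mis, j] <- mean(m[, j], na.rm = TRUE)
    }
    labels <- x$sample_id
    group <- x$population
  } else {
    wide <- tidyr::pivot_wider(
      x[, c("locus", "population", "p_del")],
      names_from = "locus", values_from = "p_del"
    )
    m <- as.matrix(wide[, -1])
    labels <- wide$population
    group <- wide$population
  }
  keep <- apply(m, 2, function(col) stats::var(col) > 0)
  m <- m[, keep, drop = FALSE]
  dims <- min(dims, nrow(m) - 1, ncol(m))
  if (ncol(m) == 0 || dims < 1) {
    out <- tibble::tibble(label = labels, group = group)
    attr(out, "variance_fraction") <- numeric(0)
    return(out)
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  out <- tibble::tibble(label = labels, group = group)
  for (j in seq_len(dims)) out[[paste0("pc", j)]] <- fit$x[, j]
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  attr(out, "variance_fraction") <- vf[seq_len(dims)]
  out
}
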