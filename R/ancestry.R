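#' Stratified train/test split
#'
#' Splits a genotype table into train and test partitions within each class
#' (default: the `continent` column), taking `round(train_fraction * n)`
#' training samples per class at random under the given seed.
#'
#' @param data A genotype tibble.
#' @param train_fraction Fraction per class assigned to training
#'   (default 0.75).
#' @param class_col Column holding the class label (default `"continent"`).
#' @param seed Integer RNG seed.
#' @return List with genotype tibbles `train` and `test`.
#' @export
stratified_split <- function(data, train_fraction = 0.75,
                             class_col = "continent", seed = 1L) {
  validate_genotypes(data)
  stopifnot(train_fraction > 0, train_fraction < 1)
  cls <- data[[class_col]]
  if (anyNA(cls)) stop("missing class labels in ", class_col, call. = FALSE)
  sizes <- table(cls)
  if (any(sizes < 2)) {
    stop("class with fewer than 2 individuals: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  set_sim_seed(seed)
  idx_train <- unlist(lapply(split(seq_len(nrow(data)), cls), function(ix) {
    n_tr <- round(train_fraction * length(ix))
    n_tr <- min(max(n_tr, 1L), length(ix) - 1L)  # both partitions non-empty
    sample(ix, n_tr)
  }), use.names = FALSE)
  list(
    train = data[sort(idx_train), ],
    test = data[setdiff(seq_len(nrow(data)), idx_train), ]
  )
}

#' Train the allele-frequency likelihood classifier
#'
#' Per class and locus, estimates the deletion-allele frequency with a
#' pseudocount of 0.5 per allele (so learned frequencies are always
#' strictly inside (0, 1) and a class can never assign zero likelihood).
#' This transparent reference classifier scores an individual by its HWE
#' genotype log-likelihood under each class's frequencies.
#'
#' @param train A genotype tibble whose class labels sit in `class_col`.
#' @param class_col Column holding the class label (default `"continent"`).
#' @return A `dip_freq_classifier` object.
#' @export
train_frequency_classifier <- function(train, class_col = "continent") {
  validate_genotypes(train)
  cls <- train[[class_col]]
  if (anyNA(cls)) stop("missing class labels in ", class_col, call. = FALSE)
  if (length(unique(cls)) < 2) stop("need >= 2 classes", call. = FALSE)
  loci <- locus_names(train)
  long <- tidyr::pivot_longer(
    dplyr::mutate(train[, loci], .class = cls),
    cols = -".class", names_to = "locus", values_to = "genotype"
  )
  freqs <- long |>
    dplyr::group_by(.data$.class, .data$locus) |>
    dplyr::summarise(
      p_del = (2 * sum(.data$genotype == "DD", na.rm = TRUE) +
                 sum(.data$genotype == "DI", na.rm = TRUE) + 0.5) /
        (2 * sum(!is.na(.data$genotype)) + 1),
      n = sum(!is.na(.data$genotype)),
      .groups = "drop"
    )
  if (any(freqs$n == 0)) {
    warning("class/locus cell(s) with no calls: pseudocount-only frequency",
            call. = FALSE)
  }
  structure(
    list(
      frequencies = dplyr::rename(freqs, class = ".class"),
      classes = sort(unique(cls)),
      loci = loci,
      class_col = class_col
    ),
    class = "dip_freq_classifier"
  )
}

#' @export
print.dip_freq_classifier <- function(x, ...) {
  cat(sprintf(
    "<dip_freq_classifier> %d classes (%s), %d loci\n",
    length(x$classes), paste(x$classes, collapse = ", "), length(x$loci)
  ))
  invisible(x)
}

#' Classify individuals by allele-frequency likelihood
#'
#' Scores each individual under each class as the sum over loci of the log
#' HWE genotype probability at the class frequencies (uniform prior),
#' assigns the argmax class (ties broken by label order) and reports
#' softmax posteriors. Individuals with all loci missing get `NA` with a
#' flag.
#'
#' @param object A `dip_freq_classifier`.
#' @param newdata A genotype tibble sharing the classifier's loci.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `predicted`, one posterior column per
#'   class, and `n_loci_used`.
#' @export
predict.dip_freq_classifier <- function(object, newdata, ...) {
  validate_genotypes(newdata)
  missing_loci <- setdiff(object$loci, locus_names(newdata))
  if (length(missing_loci) > 0) {
    stop("newdata lacks loci: ", paste(missing_loci, collapse = ", "), call. = FALSE)
  }
  dos <- genotype_dosage(newdata[, c(META_COLS[META_COLS %in% names(newdata)],
                                     object$loci)], count = "deletion")
  classes <- object$classes
  scores <- matrix(0, nrow(dos), length(classes),
                   dimnames = list(newdata$sample_id, classes))
  fr <- object$frequencies
  for (ci in seq_along(classes)) {
    pvec <- fr[fr$class == classes[ci], ]
    pvec <- pvec$p_del[match(object$loci, pvec$locus)]
    for (j in seq_along(object$loci)) {
      lp <- log(hwe_probs(pvec[j]))  # indexed by deletion dosage + 1
      g <- dos[, j]
      ok <- !is.na(g)
      scores[ok, ci] <- scores[ok, ci] + lp[g[ok] + 1L]
    }
  }
  n_used <- unname(rowSums(!is.na(dos)))
  # softmax posteriors, stable in log space
  mx <- apply(scores, 1, max)
  post <- exp(scores - mx)
  post <- post / rowSums(post)
  pred <- classes[max.col(scores, ties.method = "first")]
  pred[n_used == 0] <- NA_character_
  post[n_used == 0, ] <- NA_real_
  out <- tibble::tibble(
    sample_id = newdata$sample_id,
    predicted = pred,
    n_loci_used = n_used
  )
  for (ci in seq_along(classes)) {
    out[[paste0("post_", classes[ci])]] <- post[, ci]
  }
  out
}

#' Evaluate class assignments
#'
#' Builds the prediction-by-truth confusion matrix, overall accuracy
#' (trace over total) and its exact two-sided Clopper-Pearson 95%
#' confidence interval.
#'
#' @param truth Character vector of true class labels.
#' @param predicted Character vector of predicted labels, same length.
#' @param labels Optional fixed label set; defaults to the union observed.
#' @param conf_level Confidence level (default 0.95).
#' @return A `dip_ancestry_eval` object: list with `table` (matrix,
#'   predictions as rows), `accuracy`, `ci_low`, `ci_high`, `n`.
#' @export
evaluate_assignments <- function(truth, predicted, labels = NULL,
                                 conf_level = 0.95) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(labels)) labels <- sort(unique(c(truth, predicted)))
  if (any(!c(truth, predicted) %in% labels)) {
    stop("label outside the declared class set", call. = FALSE)
  }
  tab <- table(
    factor(predicted, levels = labels),
    factor(truth, levels = labels)
  )
  tab <- matrix(as.integer(tab), nrow = length(labels),
                dimnames = list(prediction = labels, truth = labels))
  confusion_eval(tab, conf_level)
}

#' Evaluation from a printed confusion matrix
#'
#' Computes accuracy and the exact binomial confidence interval directly
#' from a counts matrix (predictions as rows, truth as columns), e.g. a
#' published confusion table.
#'
#' @param tab Square integer matrix of counts.
#' @param conf_level Confidence level (default 0.95).
#' @return A `dip_ancestry_eval` object.
#' @export
confusion_eval <- function(tab, conf_level = 0.95) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0))
  n <- sum(tab)
  correct <- sum(diag(tab))
  ci <- stats::binom.test(correct, n, conf.level = conf_level)$conf.int
  structure(
    list(
      table = tab,
      accuracy = correct / n,
      ci_low = ci[1],
      ci_high = ci[2],
      conf_level = conf_level,
      n = n
    ),
    class = "dip_ancestry_eval"
  )
}

#' @export
print.dip_ancestry_eval <- function(x, ...) {
  cat(sprintf(
    "<dip_ancestry_eval> n = %d, accuracy = %.4f, %d%% CI (%.4f, %.4f)\n",
    x$n, x$accuracy, round(100 * x$conf_level), x$ci_low, x$ci_high
  ))
  print(x$table)
  invisible(x)
}
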