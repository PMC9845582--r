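#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinship LR study
#'
#' One row per relationship x LR limit, with accuracy and false-positive
#' rate in percent.
#'
#' @param x A `dip_lr_study`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dip_lr_study
#' @export
tidy.dip_lr_study <- function(x, ...) {
  x$rates
}

#' One-row summary of a kinship LR study
#'
#' @param x A `dip_lr_study`.
#' @param ... Unused.
#' @return A tibble with the study size, seed, and accuracy/FPR at the
#'   lowest LR limit for the first relationship.
#' @method glance dip_lr_study
#' @export
glance.dip_lr_study <- function(x, ...) {
  first <- x$rates[x$rates$threshold == min(x$thresholds), ]
  tibble::tibble(
    n_pairs = x$n_pairs,
    n_relationships = length(unique(x$rates$relationship)),
    seed = x$seed,
    accuracy_at_lr1 = first$accuracy[1],
    false_positive_at_lr1 = first$false_positive[1]
  )
}

#' Tidy an assignment evaluation
#'
#' Long form of the confusion matrix: one row per prediction x truth cell.
#'
#' @param x A `dip_ancestry_eval`.
#' @param ... Unused.
#' @return A tibble with columns `prediction`, `truth`, `count`.
#' @method tidy dip_ancestry_eval
#' @export
tidy.dip_ancestry_eval <- function(x, ...) {
  tab <- x$table
  tibble::tibble(
    prediction = rep(rownames(tab), times = ncol(tab)),
    truth = rep(colnames(tab), each = nrow(tab)),
    count = as.integer(tab)
  )
}

#' One-row summary of an assignment evaluation
#'
#' @param x A `dip_ancestry_eval`.
#' @param ... Unused.
#' @return A tibble with `n`, `accuracy`, `ci_low`, `ci_high`.
#' @method glance dip_ancestry_eval
#' @export
glance.dip_ancestry_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    accuracy = x$accuracy,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    conf_level = x$conf_level
  )
}
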