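#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @import tibble
NULL

# Reserved metadata columns of a genotype table; every other column is a locus.
META_COLS <- c("sample_id", "population", "continent")

# Valid genotype codes. "DI" is the canonical heterozygote; missing is NA.
GENOTYPE_CODES <- c("DD", "DI", "II")

#' List the locus columns of a genotype table
#'
#' A genotype table is a tibble with metadata columns `sample_id`,
#' `population`, and optionally `continent`; every remaining column is one
#' biallelic deletion/insertion locus with cells in `"DD"`, `"DI"`, `"II"`
#' or `NA` (missing).
#'
#' @param data A genotype tibble.
#' @return Character vector of locus column names, in panel order.
#' @export
locus_names <- function(data) {
  setdiff(names(data), META_COLS)
}

#' Validate a genotype table
#'
#' Checks the structural invariants of the genotype-table format: required
#' metadata columns, non-empty population labels, at least one locus column,
#' and genotype codes restricted to `DD`, `DI`, `II`, `NA`.
#'
#' @param data A genotype tibble.
#' @return `data`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_genotypes <- function(data) {
  if (!all(c("sample_id", "population") %in% names(data))) {
    stop("genotype table must have 'sample_id' and 'population' columns", call. = FALSE)
  }
  loci <- locus_names(data)
  if (length(loci) == 0L) {
    stop("genotype table has no locus columns", call. = FALSE)
  }
  if (nrow(data) > 0L) {
    if (anyNA(data$population) || any(!nzchar(data$population))) {
      stop("population labels must be nonempty", call. = FALSE)
    }
    bad <- vapply(
      data[loci],
      function(x) any(!is.na(x) & !x %in% GENOTYPE_CODES),
      logical(1)
    )
    if (any(bad)) {
      stop(
        "invalid genotype codes in loci: ",
        paste(loci[bad], collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(data)
}

#' Genotype dosage matrix
#'
#' Integer view of a genotype table for matrix work: each cell counts copies
#' of the chosen allele, so `II = 2, DI = 1, DD = 0` when counting insertion
#' alleles (the default) and the complement when counting deletions.
#'
#' @param data A genotype tibble.
#' @param count Which allele to count, `"insertion"` or `"deletion"`.
#' @return Integer matrix (samples x loci) with `NA` for missing calls;
#'   rownames are sample ids.
#' @export
genotype_dosage <- function(data, count = c("insertion", "deletion")) {
  count <- match.arg(count)
  loci <- locus_names(data)
  m <- vapply(
    data[loci],
    function(x) {
      d <- match(x, GENOTYPE_CODES) - 1L  # DD=0, DI=1, II=2 insertion copies
      d
    },
    integer(nrow(data))
  )
  m <- matrix(m, nrow = nrow(data), dimnames = list(data$sample_id, loci))
  if (count == "deletion") m <- 2L - m
  m
}

#' Read a genotype table from TSV
#'
#' Reads the package's tab-separated genotype dialect: a header row naming
#' `sample_id`, `population`, optionally `continent`, followed by one column
#' per locus. Genotype cells `"ID"` and `"DI"` both normalize to the
#' canonical heterozygote `"DI"`; `"./."` and `"NA"` (or empty cells) become
#' missing. Any other cell value also becomes missing, and the total number
#' of normalized-to-missing cells that were not already an explicit missing
#' code is reported in a warning.
#'
#' @param path Path to a TSV file.
#' @return A validated genotype tibble.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("format error: empty file, missing header", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (!all(c("sample_id", "population") %in% header)) {
    stop("format error: header must name sample_id and population", call. = FALSE)
  }
  ncol <- length(header)
  widths <- lengths(fields[-1L])
  if (any(widths != ncol)) {
    bad <- which(widths != ncol)[1L] + 1L
    stop("format error: ragged row at line ", bad, call. = FALSE)
  }
  body <- fields[-1L]
  tbl <- tibble::as_tibble(
    stats::setNames(
      lapply(seq_len(ncol), function(j) vapply(body, `[[`, character(1), j)),
      header
    )
  )
  if (!"continent" %in% names(tbl)) tbl$continent <- NA_character_
  tbl <- tbl[, c(META_COLS, setdiff(header, META_COLS))]
  tbl$continent[tbl$continent %in% c("NA", "")] <- NA_character_
  loci <- locus_names(tbl)
  n_unknown <- 0L
  for (lc in loci) {
    x <- tbl[[lc]]
    x[x == "ID"] <- "DI"
    explicit_missing <- x %in% c("NA", "./.", ".", "")
    unknown <- !explicit_missing & !x %in% GENOTYPE_CODES
    n_unknown <- n_unknown + sum(unknown)
    x[explicit_missing | unknown] <- NA_character_
    tbl[[lc]] <- x
  }
  if (n_unknown > 0L) {
    warning(n_unknown, " unrecognized genotype cell(s) set to missing", call. = FALSE)
  }
  validate_genotypes(tbl)
  tbl
}

#' Write a genotype table to TSV
#'
#' Writes the owned dialect deterministically: columns in the order
#' `sample_id`, `population`, `continent`, then loci in panel order; UTF-8;
#' tab-separated; missing genotypes serialized as `"NA"`.
#'
#' @param data A genotype tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(data, path) {
  validate_genotypes(data)
  if (!"continent" %in% names(data)) data$continent <- NA_character_
  out <- data[, c(META_COLS, locus_names(data))]
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Import biallelic indel records from a VCF file
#'
#' Convenience importer for VCF 4.x: each biallelic indel record becomes one
#' locus, with the shorter of REF/ALT taken as the deletion allele. Phased
#' and unphased GT fields are treated identically; `./.` becomes missing.
#' Multi-allelic records are skipped with a warning.
#'
#' @param path Path to a VCF file (uncompressed or bgzipped).
#' @param population Population label to attach to every sample.
#' @return A genotype tibble.
#' @export
import_vcf <- function(path, population = "unknown") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!"GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !grepl("GT", paste(v@gt[, "FORMAT"], collapse = ""))) {
    stop("format error: VCF has no GT field", call. = FALSE)
  }
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)), dimnames = dimnames(vcfR::getFIX(v)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped", call. = FALSE)
  }
  keep <- which(!multi)
  if (length(keep) == 0L) stop("no biallelic records in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  ref <- fix[keep, "REF"]
  alt <- alt[keep]
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix[keep, "CHROM"], "_", fix[keep, "POS"]
  )[is.na(ids) | ids == "."]
  # shorter allele is the deletion; count ALT copies then flip where ALT is
  # the longer (insertion) allele
  alt_is_del <- nchar(alt) < nchar(ref)
  code_one <- function(g, flip) {
    if (is.na(g)) return(NA_character_)
    al <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1L]]
    if (any(al == ".") || length(al) != 2L) return(NA_character_)
    n_alt <- sum(al == "1")
    n_del <- if (flip) n_alt else 2L - n_alt
    c("II", "DI", "DD")[n_del + 1L]
  }
  calls <- matrix(
    NA_character_, nrow = ncol(gt), ncol = nrow(gt),
    dimnames = list(colnames(gt), ids)
  )
  for (i in seq_len(nrow(gt))) {
    calls[, i] <- vapply(gt[i, ], code_one, character(1), flip = alt_is_del[i])
  }
  tbl <- tibble::tibble(
    sample_id = rownames(calls),
    population = population,
    continent = NA_character_
  )
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(calls))
  validate_genotypes(tbl)
  tbl
}

#' Estimate per-population deletion-allele frequencies
#'
#' Complete-case allele counting per locus and population: the deletion
#' frequency is `(2 * #DD + #DI) / (2 * n)` where `n` is the number of
#' individuals with a non-missing call at the locus. Locus/population cells
#' with no non-missing calls are dropped from the result with a warning
#' rather than reported as zero.
#'
#' @param data A genotype tibble.
#' @return A frequency tibble with columns `locus`, `population`, `p_del`
#'   (deletion-allele frequency) and `n` (diploid individuals counted).
#' @export
estimate_frequencies <- function(data) {
  validate_genotypes(data)
  long <- tidyr::pivot_longer(
    data[, c("population", locus_names(data))],
    cols = -"population", names_to = "locus", values_to = "genotype"
  )
  all_cells <- dplyr::distinct(long, .data$locus, .data$population)
  freqs <- long |>
    dplyr::filter(!is.na(.data$genotype)) |>
    dplyr::group_by(.data$locus, .data$population) |>
    dplyr::summarise(
      p_del = (2 * sum(.data$genotype == "DD") + sum(.data$genotype == "DI")) /
        (2 * dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
  freqs$locus <- factor(freqs$locus, levels = locus_names(data))
  freqs <- dplyr::arrange(freqs, .data$locus, .data$population)
  freqs$locus <- as.character(freqs$locus)
  n_absent <- nrow(all_cells) - nrow(freqs)
  if (n_absent > 0L) {
    warning(
      n_absent, " locus/population cell(s) with all calls missing were dropped",
      call. = FALSE
    )
  }
  freqs
}

#' Genotype counts per locus and population
#'
#' @param data A genotype tibble.
#' @return Tibble with columns `locus`, `population`, `n_dd`, `n_di`, `n_ii`.
#' @export
genotype_counts <- function(data) {
  validate_genotypes(data)
  tidyr::pivot_longer(
    data[, c("population", locus_names(data))],
    cols = -"population", names_to = "locus", values_to = "genotype"
  ) |>
    dplyr::filter(!is.na(.data$genotype)) |>
    dplyr::group_by(.data$locus, .data$population) |>
    dplyr::summarise(
      n_dd = sum(.data$genotype == "DD"),
      n_di = sum(.data$genotype == "DI"),
      n_ii = sum(.data$genotype == "II"),
      .groups = "drop"
    )
}
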