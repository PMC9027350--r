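# Post-calling filter ladder for low-coverage genotype data: per-cell
# coverage masking, minimum-called-individuals site filtering, chromosome
# attribution and per-sample missingness. The canonical order is
# mask-then-filter; masking acts on cells, site dropping happens only
# through the ladder.

#' Mask low-coverage genotype calls
#'
#' Replaces every call whose read depth is below `min_depth` by the missing
#' state (the ambiguous-nucleotide convention). All other cells are
#' untouched; the `masked` provenance channel records which cells were newly
#' ambiguated.
#'
#' @param dataset a `VariantDataset`.
#' @param min_depth minimum depth for a call to be retained (default 3:
#'   positions with coverage < 3 are ambiguated).
#' @return a `VariantDataset` with masked calls.
#' @export
mask_low_coverage <- function(dataset, min_depth = 3L) {
  stopifnot(inherits(dataset, "VariantDataset"))
  if (length(min_depth) != 1L || is.na(min_depth) || min_depth < 0)
    stop("min_depth must be a single non-negative number")
  low <- dataset$depth < min_depth
  geno <- dataset$geno
  newly <- low & !is.na(geno)
  geno[low] <- NA_integer_
  masked <- if (is.null(dataset$masked)) newly else (dataset$masked | newly)
  variant_dataset(dataset$sites, dataset$samples, geno, dataset$depth, masked)
}

#' Filter sites by number of called individuals
#'
#' Keeps sites with at least `min_called` non-missing calls. Calls
#' themselves are never modified.
#'
#' @param dataset a `VariantDataset` (conventionally already masked).
#' @param min_called minimum number of samples with a call.
#' @return a `VariantDataset` restricted to the surviving sites.
#' @export
filter_by_min_called <- function(dataset, min_called) {
  stopifnot(inherits(dataset, "VariantDataset"))
  if (min_called > n_samples(dataset))
    warning("min_called (", min_called, ") exceeds sample count (",
            n_samples(dataset), "); result is empty")
  called <- rowSums(!is.na(dataset$geno))
  dataset[called >= min_called, ]
}

#' Apply the missing-data filter ladder
#'
#' Computes surviving-site counts for a ladder of minimum-called thresholds
#' (default: all SNPs, called in at least 3, 5, 8, and all samples),
#' together with per-sample missing fractions.
#'
#' @param dataset a `VariantDataset`, conventionally masked first (the
#'   function applies [mask_low_coverage()] when `min_depth` is not `NULL`).
#' @param levels integer thresholds; `NA` means "all samples".
#' @param min_depth masking depth applied before counting (`NULL` = dataset
#'   is used as-is).
#' @return a `FilterReport`: list with `levels` (data.frame `label`,
#'   `min_called`, `n_sites`) and `sample_missingness`.
#' @export
filter_ladder <- function(dataset, levels = c(1L, 3L, 5L, 8L, NA),
                          min_depth = 3L) {
  stopifnot(inherits(dataset, "VariantDataset"))
  if (!is.null(min_depth)) dataset <- mask_low_coverage(dataset, min_depth)
  thr <- ifelse(is.na(levels), n_samples(dataset), as.integer(levels))
  called <- rowSums(!is.na(dataset$geno))
  counts <- vapply(thr, function(k) sum(called >= k), 0L)
  report <- list(
    levels = data.frame(
      label = ifelse(is.na(levels), "all samples",
                     paste0(">=", thr, " samples")),
      min_called = thr, n_sites = counts, stringsAsFactors = FALSE),
    sample_missingness = sample_missingness(dataset))
  structure(report, class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("Missing-data filter ladder:\n")
  print(x$levels, row.names = FALSE)
  cat("Per-sample missing fraction:\n")
  print(round(x$sample_missingness, 3))
  invisible(x)
}

#' Attribute SNPs to chromosomes via a scaffold map
#'
#' @param dataset a `VariantDataset`.
#' @param scaffold_map data.frame with columns `scaffold`, `chromosome`
#'   (unique scaffolds).
#' @return the dataset with `sites$chromosome` filled; unmapped scaffolds
#'   become `"unplaced"` (a message reports their count).
#' @export
attribute_chromosomes <- function(dataset, scaffold_map) {
  stopifnot(inherits(dataset, "VariantDataset"),
            all(c("scaffold", "chromosome") %in% names(scaffold_map)))
  if (anyDuplicated(scaffold_map$scaffold))
    stop("duplicate scaffold in scaffold map: ",
         paste(unique(scaffold_map$scaffold[duplicated(scaffold_map$scaffold)]),
               collapse = ", "))
  m <- match(dataset$sites$scaffold, scaffold_map$scaffold)
  chrom <- scaffold_map$chromosome[m]
  n_unplaced <- sum(is.na(m))
  if (n_unplaced > 0L)
    message("attribute_chromosomes: ", n_unplaced,
            " site(s) on unmapped scaffolds labeled 'unplaced'")
  chrom[is.na(m)] <- "unplaced"
  dataset$sites$chromosome <- chrom
  dataset
}

#' Per-sample missing fraction
#'
#' @param x a `VariantDataset` or `PanelCalls`.
#' @param type for `PanelCalls`: restrict to `"autosomal"`,
#'   `"mitochondrial"`, or use `"all"` SNPs.
#' @return named numeric vector of missing fractions in \[0, 1\].
#' @export
sample_missingness <- function(x, type = "all") {
  if (inherits(x, "VariantDataset")) {
    if (n_sites(x) == 0L) stop("cannot compute missingness with zero sites")
    return(colMeans(is.na(x$geno)))
  }
  if (inherits(x, "PanelCalls")) {
    keep <- if (type == "all") rep(TRUE, nrow(x$snps)) else x$snps$type == type
    if (!any(keep)) stop("cannot compute missingness with zero sites")
    return(rowMeans(is.na(x$calls[, keep, drop = FALSE])))
  }
  stop("x must be a VariantDataset or PanelCalls")
}
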