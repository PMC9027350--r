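# Central genotype-call container. Genotypes are coded as integer alt-allele
# doses: 0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing/ambiguous. Depths are
# non-negative integers with the same dimensions. An optional `masked` logical
# matrix records cells set to missing by coverage masking (provenance channel;
# input-missing and masked-after-the-fact share the NA state).

#' Construct a variant dataset
#'
#' Holds biallelic SNP calls for a set of samples together with per-cell read
#' depths. Genotypes are integer alt-allele doses (0/1/2) with `NA` for
#' missing or ambiguous calls.
#'
#' @param sites data.frame with columns `scaffold`, `position`, `ref`, `alt`
#'   and optionally `chromosome` (filled with `NA` when absent).
#' @param samples character vector of unique sample ids.
#' @param geno integer matrix (`n_sites x n_samples`) of alt doses in
#'   `{0, 1, 2, NA}`.
#' @param depth integer matrix of read depths, same dimensions as `geno`.
#' @param masked optional logical matrix flagging cells whose missingness was
#'   introduced by coverage masking rather than present in the input.
#' @return An object of class `VariantDataset`.
#' @export
variant_dataset <- function(sites, samples, geno, depth, masked = NULL) {
  stopifnot(is.data.frame(sites))
  required <- c("scaffold", "position", "ref", "alt")
  if (!all(required %in% names(sites)))
    stop("`sites` must have columns: ", paste(required, collapse = ", "))
  if (!"chromosome" %in% names(sites))
    sites$chromosome <- rep(NA_character_, nrow(sites))
  sites$scaffold <- as.character(sites$scaffold)
  sites$position <- as.integer(sites$position)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  samples <- as.character(samples)

  geno <- as.matrix(geno); storage.mode(geno) <- "integer"
  depth <- as.matrix(depth); storage.mode(depth) <- "integer"

  n_sites <- nrow(sites); n_samples <- length(samples)
  if (!all(dim(geno) == c(n_sites, n_samples)) ||
      !all(dim(depth) == c(n_sites, n_samples)))
    stop("genotype and depth matrices must both be n_sites x n_samples")
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  ids <- paste(sites$scaffold, sites$position, sep = ":")
  if (anyDuplicated(ids)) stop("site (scaffold, position) pairs must be unique")
  if (any(sites$position < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  if (any(geno < 0L | geno > 2L, na.rm = TRUE))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(depth < 0L, na.rm = TRUE)) stop("depths must be non-negative")
  if (anyNA(depth)) stop("depth matrix must not contain NA (use 0)")

  dimnames(geno) <- dimnames(depth) <- list(ids, samples)
  if (!is.null(masked)) {
    masked <- as.matrix(masked)
    if (!all(dim(masked) == dim(geno))) stop("`masked` has wrong dimensions")
    dimnames(masked) <- dimnames(geno)
  }
  rownames(sites) <- NULL
  structure(
    list(sites = sites, samples = samples, geno = geno, depth = depth,
         masked = masked),
    class = "VariantDataset")
}

# internal fast path for simulators whose outputs satisfy the invariants by
# construction; skips validation but keeps identical structure
.variant_dataset_fast <- function(sites, samples, geno, depth, masked = NULL) {
  ids <- paste(sites$scaffold, sites$position, sep = ":")
  dimnames(geno) <- dimnames(depth) <- list(ids, samples)
  if (!is.null(masked)) dimnames(masked) <- list(ids, samples)
  structure(list(sites = sites, samples = samples, geno = geno, depth = depth,
                 masked = masked),
            class = "VariantDataset")
}

#' @export
print.VariantDataset <- function(x, ...) {
  cat("VariantDataset:", n_sites(x), "sites x", n_samples(x), "samples\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.1f%%; mean depth: %.2f\n",
              100 * miss, mean(x$depth)))
  chrom <- x$sites$chromosome
  cat("  chromosomes assigned:", sum(!is.na(chrom)), "of", n_sites(x), "sites\n")
  invisible(x)
}

#' Number of sites / samples in a dataset
#' @param x a `VariantDataset`
#' @return integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

#' Site identifiers (`scaffold:position`)
#' @param x a `VariantDataset`
#' @return character vector of site ids.
#' @export
site_ids <- function(x) rownames(x$geno)

#' Subset a dataset by sites and/or samples
#'
#' @param x a `VariantDataset`
#' @param i site index (integer, logical, or site-id character)
#' @param j sample index (integer, logical, or sample-id character)
#' @param ... ignored
#' @return a `VariantDataset`
#' @export
`[.VariantDataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_sites(x))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(i)) i <- match(i, site_ids(x))
  if (is.character(j)) j <- match(j, x$samples)
  variant_dataset(
    sites = x$sites[i, , drop = FALSE],
    samples = x$samples[j],
    geno = x$geno[i, j, drop = FALSE],
    depth = x$depth[i, j, drop = FALSE],
    masked = if (!is.null(x$masked)) x$masked[i, j, drop = FALSE])
}
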