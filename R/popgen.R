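# Observed heterozygosity at the individual and population level, and the
# four-taxon ABBA-BABA D-statistic in frequency form with site (or block)
# bootstrap significance.

#' Individual observed heterozygosity
#'
#' Proportion of heterozygous calls among scored (non-missing) sites —
#' ambiguous positions are excluded from both numerator and denominator.
#'
#' @param x a `VariantDataset` or `PanelCalls`.
#' @param sample sample id (or `NULL` for all samples).
#' @return named numeric vector (or scalar for a single sample).
#' @export
het_individual <- function(x, sample = NULL) {
  g <- if (inherits(x, "VariantDataset")) t(x$geno)
       else if (inherits(x, "PanelCalls")) {
         aut <- x$snps$type == "autosomal"
         x$calls[, aut, drop = FALSE]
       } else as.matrix(x)
  if (!is.null(sample)) g <- g[match(sample, rownames(g)), , drop = FALSE]
  scored <- rowSums(!is.na(g))
  if (any(scored == 0L))
    stop("sample(s) with zero scored sites: ",
         paste(rownames(g)[scored == 0L], collapse = ", "))
  het <- rowSums(g == 1L, na.rm = TRUE) / scored
  if (length(het) == 1L) unname(het) else het
}

#' Population-level observed heterozygosity on panel SNPs
#'
#' Mean, over panel SNPs called in at least `min_called` members of the
#' population, of the heterozygote fraction among called members.
#'
#' @param calls a `PanelCalls`.
#' @param members sample ids of the population.
#' @param min_called minimum called members for a SNP to qualify (default 5).
#' @return observed heterozygosity (scalar).
#' @export
het_population <- function(calls, members, min_called = 5L) {
  stopifnot(inherits(calls, "PanelCalls"))
  aut <- calls$snps$type == "autosomal"
  g <- calls$calls[match(members, calls$samples), aut, drop = FALSE]
  if (anyNA(match(members, calls$samples))) stop("unknown member id(s)")
  n_called <- colSums(!is.na(g))
  qual <- n_called >= min_called
  if (!any(qual)) stop("no SNP called in >= ", min_called, " members")
  het <- colSums(g[, qual, drop = FALSE] == 1L, na.rm = TRUE) / n_called[qual]
  mean(het)
}

#' Closed-form heterozygosity deflation under allelic dropout
#'
#' At read depth d, a true heterozygote is observed heterozygous with
#' probability `1 - 2^(1-d)`. With Poisson(lambda) depth and calls retained
#' at depth >= `min_depth`, the expected ratio of observed to true
#' heterozygosity over scored sites is
#' `E[1 - 2^(1-d) | d >= min_depth]`.
#'
#' @param lambda mean depth.
#' @param min_depth minimum depth of a scored call.
#' @return expected observed/true heterozygosity ratio.
#' @export
het_dropout_factor <- function(lambda, min_depth = 1L) {
  p_scored <- stats::ppois(min_depth - 1L, lambda, lower.tail = FALSE)
  # E[2^-d 1{d >= m}] = e^(-lambda/2) P(Pois(lambda/2) >= m)
  e_half <- exp(-lambda / 2) *
    stats::ppois(min_depth - 1L, lambda / 2, lower.tail = FALSE)
  (p_scored - 2 * e_half) / p_scored
}

#' ABBA-BABA D-statistic with bootstrap significance
#'
#' Frequency-form D over four groups arranged as (((P1, P2), P3), outgroup):
#' with p_k the group alt-allele frequency at a site, the per-site numerator
#' is `(1-p1) p2 p3 (1-p4) - p1 (1-p2) p3 (1-p4)` (ABBA minus BABA) and the
#' denominator the corresponding sum; D is the ratio of their totals over
#' usable sites (those where every group has at least one call). An excess
#' of ABBA (D > 0) indicates gene flow between P2 and P3. Significance is
#' assessed by resampling sites (or consecutive-site blocks) with
#' replacement: Z = D / sd(bootstrap replicates), significant when
#' |Z| >= `z_threshold`.
#'
#' @param dataset a `VariantDataset`.
#' @param P1,P2,P3,outgroup character vectors of sample ids per group.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param block block size in consecutive usable sites (`NULL` = single-site
#'   bootstrap).
#' @param seed RNG seed for the bootstrap (`NULL` = current RNG state).
#' @param z_threshold significance threshold on |Z| (default 3).
#' @return a `DStatResult`: list with `D`, `Z`, `significant`,
#'   `n_sites_used`, `abba`, `baba`, `replicates` and the configuration.
#' @export
d_statistic <- function(dataset, P1, P2, P3, outgroup, n_boot = 1000L,
                        block = NULL, seed = NULL, z_threshold = 3) {
  stopifnot(inherits(dataset, "VariantDataset"))
  groups <- list(P1 = P1, P2 = P2, P3 = P3, outgroup = outgroup)
  for (g in groups)
    if (length(g) == 0L || !all(g %in% dataset$samples))
      stop("every group must map to >= 1 sample present in the dataset")
  freq_of <- function(ids) {
    sub <- dataset$geno[, ids, drop = FALSE]
    rowSums(sub, na.rm = TRUE) / (2 * rowSums(!is.na(sub)))
  }
  p <- vapply(groups, freq_of, numeric(n_sites(dataset)))
  usable <- rowSums(is.na(p)) == 0L  # NaN when a group has no call
  if (!any(usable)) stop("no site has calls in all four groups")
  p <- p[usable, , drop = FALSE]
  abba <- (1 - p[, 1]) * p[, 2] * p[, 3] * (1 - p[, 4])
  baba <- p[, 1] * (1 - p[, 2]) * p[, 3] * (1 - p[, 4])
  num <- abba - baba
  den <- abba + baba
  if (sum(den) == 0) {
    return(structure(list(D = NA_real_, Z = NA_real_, significant = NA,
                          undefined = TRUE, n_sites_used = sum(usable),
                          abba = sum(abba), baba = sum(baba),
                          replicates = numeric(), n_boot = n_boot,
                          block = block, seed = seed, groups = groups),
                     class = "DStatResult"))
  }
  D <- sum(num) / sum(den)

  .set_seed(seed)
  S <- length(num)
  if (is.null(block) || block <= 1L) {
    # chunked to bound memory at large site counts
    chunk <- max(1L, min(n_boot, as.integer(2e7 %/% S)))
    reps <- numeric(n_boot)
    done <- 0L
    while (done < n_boot) {
      b <- min(chunk, n_boot - done)
      idx <- sample.int(S, S * b, replace = TRUE)
      reps[done + seq_len(b)] <- .colSums(num[idx], S, b) /
        .colSums(den[idx], S, b)
      done <- done + b
    }
  } else {
    starts <- seq.int(1L, S, by = block)
    nb <- length(starts)
    reps <- vapply(seq_len(n_boot), function(b) {
      take <- starts[sample.int(nb, nb, replace = TRUE)]
      sites <- unlist(lapply(take, function(s) s:min(s + block - 1L, S)))
      sum(num[sites]) / sum(den[sites])
    }, 0)
  }
  sd_boot <- stats::sd(reps)
  Z <- if (is.na(sd_boot) || sd_boot == 0) NA_real_ else D / sd_boot
  structure(list(D = D, Z = Z,
                 significant = !is.na(Z) && abs(Z) >= z_threshold,
                 undefined = FALSE, n_sites_used = S,
                 abba = sum(abba), baba = sum(baba), replicates = reps,
                 n_boot = n_boot, block = block, seed = seed,
                 z_threshold = z_threshold, groups = groups),
            class = "DStatResult")
}

#' @export
print.DStatResult <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("D-statistic undefined (zero denominator) over", x$n_sites_used,
        "usable sites\n")
    return(invisible(x))
  }
  cat(sprintf("D = %.4f  Z = %.2f  (%s; %d usable sites, %d bootstraps)\n",
              x$D, x$Z,
              if (isTRUE(x$significant)) "significant" else "not significant",
              x$n_sites_used, x$n_boot))
  invisible(x)
}

#' Correlation between heterozygosity estimates
#'
#' Pearson and Spearman correlations between two heterozygosity vectors
#' (e.g. whole-genome individual estimates vs panel-based population
#' estimates) over their shared names.
#'
#' @param a,b named numeric vectors.
#' @return list with `pearson`, `spearman`, `n` and a `constant` flag (set
#'   when either vector is constant, leaving the correlation undefined).
#' @export
het_correlation <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) stop("need >= 3 shared units")
  x <- a[shared]; y <- b[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_,
                n = length(shared), constant = TRUE))
  list(pearson = stats::cor(x, y),
       spearman = stats::cor(x, y, method = "spearman"),
       n = length(shared), constant = FALSE)
}
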