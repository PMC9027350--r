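# Panel-based cohort analysis: missingness QC, mtDNA haplogroup assignment
# with call-rate confidence grading, supervised clade assignment under
# Hardy-Weinberg genotype likelihoods, PCA, and a neighbor-joining
# allele-sharing dendrogram.

#' QC: exclude samples by autosomal missingness
#'
#' A sample is excluded when its missing fraction over the autosomal panel
#' SNPs is strictly greater than `max_missing` (default: > 25% missing).
#'
#' @param calls a `PanelCalls`.
#' @param max_missing missingness cutoff.
#' @return list with `retained`, `excluded` (sample id vectors) and
#'   `missing` (named fractions).
#' @export
qc_exclude_missing <- function(calls, max_missing = 0.25) {
  stopifnot(inherits(calls, "PanelCalls"))
  miss <- sample_missingness(calls, type = "autosomal")
  list(retained = calls$samples[miss <= max_missing],
       excluded = calls$samples[miss > max_missing],
       missing = miss)
}

#' Assign a mitochondrial haplogroup with confidence grading
#'
#' The call rate r over the mtDNA panel SNPs determines the grade: when 40%
#' or more of the SNPs failed (r below `qual_lo`), no haplogroup is assigned
#' (grade `"unknown"`, label `"?"`). When between 60% and 85% of the SNPs
#' were called (inclusive bounds), the best-matching haplogroup is reported
#' with grade `"qualified"`. Above 85% the assignment is `"confident"`. The
#' best match maximizes agreement with the key over the called SNPs; called
#' SNPs contradicting the best match are counted as conflicts, and ties
#' between haplogroups are reported jointly with the grade forced to
#' `"qualified"`.
#'
#' @param calls character (or allele-coded) vector of mtDNA calls aligned to
#'   the key's columns; `NA` = failed call.
#' @param key haplogroup key matrix (rows = haplogroups, columns = SNPs).
#' @param fail_hi failed-fraction threshold for the unknown grade.
#' @param qual_lo,qual_hi call-rate band for the qualified grade (inclusive).
#' @return list with `label`, `grade` (one of `"confident"`, `"qualified"`,
#'   `"unknown"`), `call_rate`, `matches`, `conflicts`, `tied`.
#' @export
assign_haplogroup <- function(calls, key, fail_hi = 0.40, qual_lo = 0.60,
                              qual_hi = 0.85) {
  stopifnot(is.matrix(key), length(calls) == ncol(key))
  called <- !is.na(calls)
  r <- mean(called)
  if ((1 - r) >= fail_hi || r < qual_lo)
    return(list(label = "?", grade = "unknown", call_rate = r,
                matches = NA_integer_, conflicts = NA_integer_, tied = FALSE))
  matches <- apply(key[, called, drop = FALSE], 1L,
                   function(k) sum(k == calls[called]))
  best <- which(matches == max(matches))
  tied <- length(best) > 1L
  label <- paste(rownames(key)[best], collapse = "/")
  conflicts <- sum(called) - max(matches)
  grade <- if (tied || r <= qual_hi) "qualified" else "confident"
  list(label = label, grade = grade, call_rate = r,
       matches = max(matches), conflicts = conflicts, tied = tied)
}

#' Assign haplogroups for every sample of a panel-call table
#'
#' @param calls a `PanelCalls` with mtDNA SNPs.
#' @param key haplogroup key (alleles) over the mtDNA panel SNPs.
#' @param ... thresholds passed to [assign_haplogroup()].
#' @return data.frame with one row per sample.
#' @export
assign_haplogroups <- function(calls, key, ...) {
  stopifnot(inherits(calls, "PanelCalls"))
  mt <- calls$snps$type == "mitochondrial"
  snps <- calls$snps[mt, , drop = FALSE]
  if (!all(colnames(key) %in% snps$id))
    stop("key columns not present among the panel's mtDNA SNPs")
  code <- calls$calls[, snps$id[match(colnames(key), snps$id)], drop = FALSE]
  ord <- match(colnames(key), snps$id)
  res <- lapply(seq_along(calls$samples), function(i) {
    g <- code[i, ]
    alle <- ifelse(is.na(g), NA_character_,
                   ifelse(g == 0L, snps$ref[ord], snps$alt[ord]))
    assign_haplogroup(alle, key, ...)
  })
  data.frame(sample = calls$samples,
             haplogroup = vapply(res, `[[`, "", "label"),
             grade = vapply(res, `[[`, "", "grade"),
             call_rate = vapply(res, `[[`, 0, "call_rate"),
             conflicts = vapply(res, function(x) as.integer(x$conflicts), 0L),
             stringsAsFactors = FALSE)
}

#' Reference allele frequencies per clade
#'
#' Pseudocount-smoothed alt-allele frequencies at the autosomal panel SNPs,
#' estimated per clade from reference samples of known origin:
#' `(alt count + pseudocount) / (2 * n_called + 2 * pseudocount)`.
#'
#' @param calls a `PanelCalls`.
#' @param sheet sample sheet data.frame (`sample`, `region`).
#' @param samples optional subset of sample ids (e.g. QC-retained).
#' @param pseudocount Laplace pseudocount (default 1; with >= 1 frequencies
#'   stay inside (0, 1)).
#' @return matrix of alt frequencies, SNPs x clades.
#' @export
reference_frequencies <- function(calls, sheet, samples = NULL,
                                  pseudocount = 1) {
  stopifnot(inherits(calls, "PanelCalls"))
  if (is.null(samples)) samples <- calls$samples
  aut <- calls$snps$type == "autosomal"
  g <- calls$calls[match(samples, calls$samples), aut, drop = FALSE]
  region <- sheet$region[match(samples, sheet$sample)]
  clades <- CLADE_LEVELS
  out <- matrix(NA_real_, sum(aut), length(clades),
                dimnames = list(calls$snps$id[aut], clades))
  for (cl in clades) {
    rows <- which(region == cl)
    if (length(rows) == 0L) stop("no reference samples for clade: ", cl)
    sub <- g[rows, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    out[, cl] <- (alt + pseudocount) / (2 * n_called + 2 * pseudocount)
  }
  out
}

#' Supervised clade assignment under Hardy-Weinberg likelihoods
#'
#' For each sample, the log-likelihood of each clade is the sum over its
#' called autosomal SNPs of the log Hardy-Weinberg genotype probability
#' under that clade's reference frequency; posteriors are normalized
#' likelihoods under a uniform prior. Missing SNPs are skipped.
#'
#' @param calls a `PanelCalls`.
#' @param ref_freq SNPs x clades alt-frequency matrix from
#'   [reference_frequencies()].
#' @param samples samples to assign (default: all); samples with zero called
#'   autosomal SNPs raise an error (they should be QC-excluded first).
#' @return list with `posterior` (samples x clades matrix), `loglik` (same
#'   shape) and `assignment` (data.frame with the MAP clade and posterior).
#' @export
assign_clade <- function(calls, ref_freq, samples = NULL) {
  stopifnot(inherits(calls, "PanelCalls"))
  if (is.null(samples)) samples <- calls$samples
  aut <- calls$snps$type == "autosomal"
  ids <- calls$snps$id[aut]
  if (!all(rownames(ref_freq) %in% ids))
    stop("reference frequencies do not match the panel's autosomal SNPs")
  g <- calls$calls[match(samples, calls$samples),
                   match(rownames(ref_freq), calls$snps$id), drop = FALSE]
  clades <- colnames(ref_freq)
  ll <- matrix(0, length(samples), length(clades),
               dimnames = list(samples, clades))
  for (cl in clades) {
    f <- ref_freq[, cl]
    lp <- rbind(log((1 - f)^2), log(2 * f * (1 - f)), log(f^2))
    has <- !is.na(g)
    idx <- cbind(as.vector(g) + 1L, rep(seq_along(f), each = nrow(g)))
    contrib <- matrix(NA_real_, nrow(g), ncol(g))
    contrib[has] <- lp[idx[as.vector(has), , drop = FALSE]]
    ll[, cl] <- rowSums(contrib, na.rm = TRUE)
  }
  n_called <- rowSums(!is.na(g))
  if (any(n_called == 0L))
    stop("sample(s) with zero called autosomal SNPs: ",
         paste(samples[n_called == 0L], collapse = ", "))
  post <- exp(ll - apply(ll, 1L, max))
  post <- post / rowSums(post)
  map <- clades[max.col(post, ties.method = "first")]
  list(posterior = post, loglik = ll,
       assignment = data.frame(sample = samples, clade = map,
                               posterior = post[cbind(seq_along(samples),
                                                      max.col(post, "first"))],
                               n_called = n_called,
                               stringsAsFactors = FALSE))
}

#' PCA of panel genotypes
#'
#' Missing cells are mean-imputed per SNP; the genotype matrix is centered
#' and unit-variance scaled (monomorphic SNPs dropped) and decomposed by
#' singular value decomposition. The sign of each component is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param calls a `PanelCalls` or a numeric samples x SNPs matrix.
#' @param samples optional subset of sample ids.
#' @return list with `scores` (samples x PCs), `loadings`, and
#'   `explained` (variance fractions).
#' @export
pca_panel <- function(calls, samples = NULL) {
  if (inherits(calls, "PanelCalls")) {
    aut <- calls$snps$type == "autosomal"
    g <- calls$calls[, aut, drop = FALSE]
    if (!is.null(samples)) g <- g[match(samples, calls$samples), , drop = FALSE]
  } else g <- as.matrix(calls)
  if (nrow(g) < 2L) stop("PCA needs at least 2 samples")
  for (j in seq_len(ncol(g))) {
    mu <- mean(g[, j], na.rm = TRUE)
    g[is.na(g[, j]), j] <- if (is.nan(mu)) 0 else mu
  }
  sds <- apply(g, 2L, stats::sd)
  keep <- !is.na(sds) & sds > 0
  g <- scale(g[, keep, drop = FALSE])
  pc <- stats::prcomp(g, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  list(scores = scores, loadings = loadings,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Allele-sharing distance matrix
#'
#' Pairwise distance `1 - mean allele-sharing` over jointly called SNPs
#' (sharing is 1 for identical genotypes, 0.5 for het vs hom, 0 for
#' opposite homozygotes). Errors if any pair has no jointly called SNP.
#'
#' @param g samples x SNPs genotype matrix (alt doses 0/1/2, `NA` missing).
#' @return a `dist`-like symmetric matrix.
#' @export
allele_sharing_dist <- function(g) {
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    joint <- !is.na(g[i, ]) & !is.na(g[j, ])
    if (!any(joint))
      stop("samples ", rownames(g)[i], " and ", rownames(g)[j],
           " share no called SNPs")
    share <- 1 - abs(g[i, joint] - g[j, joint]) / 2
    d[i, j] <- d[j, i] <- 1 - mean(share)
  }
  d
}

#' Neighbor-joining tree on allele-sharing distances
#'
#' @param x a `PanelCalls`, `VariantDataset`, or samples x SNPs genotype
#'   matrix.
#' @param samples optional subset of sample ids.
#' @return an [ape::nj()] `phylo` tree (serialize with [ape::write.tree()]).
#' @export
distance_tree <- function(x, samples = NULL) {
  g <- if (inherits(x, "PanelCalls")) x$calls
       else if (inherits(x, "VariantDataset")) t(x$geno)
       else as.matrix(x)
  if (!is.null(samples)) g <- g[match(samples, rownames(g)), , drop = FALSE]
  if (nrow(g) < 3L) stop("need at least 3 samples for a tree")
  ape::nj(stats::as.dist(allele_sharing_dist(g)))
}

#' Does a tree contain a given unrooted bipartition?
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels forming one side of the split.
#' @return `TRUE` when some internal edge separates `tips` from the rest.
#' @export
tree_has_split <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  all_tips <- tree$tip.label
  if (!all(tips %in% all_tips)) stop("unknown tip label(s)")
  target <- sort(match(tips, all_tips))
  other <- sort(setdiff(seq_along(all_tips), target))
  parts <- ape::prop.part(tree)
  any(vapply(parts, function(p) {
    p <- sort(p)
    identical(p, target) || identical(p, other)
  }, TRUE))
}

#' Full panel-based assignment of a cohort
#'
#' Convenience wrapper running QC, reference-frequency estimation, clade
#' assignment and haplogroup assignment, mirroring the per-sample
#' assignment table of a panel-genotyping study.
#'
#' @param calls a `PanelCalls`.
#' @param sheet sample sheet data.frame.
#' @param key haplogroup key over the panel's mtDNA SNPs.
#' @param max_missing QC cutoff (default 0.25).
#' @param pseudocount see [reference_frequencies()].
#' @return an `AssignmentResult`: list with `table` (per-sample data.frame),
#'   `posterior`, `qc` and `ref_freq`.
#' @export
assign_cohort <- function(calls, sheet, key, max_missing = 0.25,
                          pseudocount = 1) {
  qc <- qc_exclude_missing(calls, max_missing)
  ref <- reference_frequencies(calls, sheet, samples = qc$retained,
                               pseudocount = pseudocount)
  cl <- assign_clade(calls, ref, samples = qc$retained)
  hg <- assign_haplogroups(calls, key)
  tab <- data.frame(sample = calls$samples,
                    missing_fraction = qc$missing,
                    qc = ifelse(calls$samples %in% qc$retained,
                                "retained", "excluded"),
                    stringsAsFactors = FALSE)
  m <- match(tab$sample, cl$assignment$sample)
  tab$clade <- cl$assignment$clade[m]
  tab$clade_posterior <- cl$assignment$posterior[m]
  m2 <- match(tab$sample, hg$sample)
  tab$haplogroup <- hg$haplogroup[m2]
  tab$haplogroup_grade <- hg$grade[m2]
  structure(list(table = tab, posterior = cl$posterior, qc = qc,
                 ref_freq = ref),
            class = "AssignmentResult")
}

#' @export
print.AssignmentResult <- function(x, ...) {
  cat("AssignmentResult:", nrow(x$table), "samples (",
      sum(x$table$qc == "retained"), "retained )\n")
  cat("  clades:", paste(names(table(x$table$clade)),
                         table(x$table$clade), sep = ":", collapse = " "), "\n")
  invisible(x)
}
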