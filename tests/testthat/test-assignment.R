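# Sample QC, haplogroup caller, supervised clade assignment, PCA and the
# allele-sharing NJ tree.

test_that("QC excludes samples strictly above 25% autosomal missingness", {
  pc <- random_panel_calls(3, 125, 14, miss = 0, seed = 51)
  pc$calls[1, 1:32] <- NA_integer_   # 32/125 = 25.6% -> excluded
  pc$calls[2, 1:31] <- NA_integer_   # 31/125 = 24.8% -> retained
  qc <- qc_exclude_missing(pc)
  expect_equal(qc$excluded, "ind001")
  expect_setequal(qc$retained, c("ind002", "ind003"))

  big <- random_panel_calls(150, 40, 5, miss = 0.25, seed = 53)
  qc2 <- qc_exclude_missing(big, 0.25)
  aut <- big$snps$type == "autosomal"
  oracle <- rowMeans(is.na(big$calls[, aut])) > 0.25
  expect_setequal(qc2$excluded, big$samples[oracle])
})

test_that("haplogroup grades follow the 40% failed and 60-85% called bands", {
  m <- mtdna_model(seed = 57)
  key <- haplogroup_key(m, lionpanel:::.default_mt_panel_sites(m)$id)
  full <- key["West Africa", ]
  res <- assign_haplogroup(full, key)
  expect_equal(res$label, "West Africa")
  expect_equal(res$grade, "confident")
  expect_equal(res$conflicts, 0L)

  six_failed <- full; six_failed[1:6] <- NA  # 8/14 called = 57.1% < 60%
  expect_equal(assign_haplogroup(six_failed, key)$grade, "unknown")
  expect_equal(assign_haplogroup(six_failed, key)$label, "?")

  eleven <- key["India", ]; eleven[1:3] <- NA  # 11/14 = 78.6%, in 60-85%
  res3 <- assign_haplogroup(eleven, key)
  expect_equal(res3$label, "India")
  expect_equal(res3$grade, "qualified")

  twelve <- key["India", ]; twelve[1:2] <- NA  # 12/14 = 85.7% > 85%
  expect_equal(assign_haplogroup(twelve, key)$grade, "confident")
})

test_that("conflicting calls are counted and ties reported as qualified", {
  key <- matrix(c("A", "A", "A", "A",
                  "G", "G", "A", "A",
                  "G", "G", "G", "G"),
                3, 4, byrow = TRUE,
                dimnames = list(c("h1", "h2", "h3"), paste0("s", 1:4)))
  calls <- c("A", "A", "A", "G")  # 3 matches h1, 1 conflict
  res <- assign_haplogroup(calls, key, qual_lo = 0, qual_hi = 0.5)
  expect_equal(res$label, "h1")
  expect_equal(res$conflicts, 1L)
  tie <- c("G", "G", "A", "G")    # h2 and h3 both match 3
  res2 <- assign_haplogroup(tie, key, qual_lo = 0, qual_hi = 0.5)
  expect_true(res2$tied)
  expect_equal(res2$grade, "qualified")
  expect_match(res2$label, "/")
})

test_that("reference frequencies use pseudocount smoothing", {
  snps <- data.frame(id = "s1", type = "autosomal", ref = "A", alt = "G")
  pc <- panel_calls(c("a", "b"), snps, matrix(c(2L, 2L), 2, 1))
  sheet <- data.frame(sample = c("a", "b"),
                      population = "x", region = "India")
  # a lone clade errors; replicate both samples across clades to satisfy all
  full_sheet <- data.frame(
    sample = sprintf("m%d", 1:8), population = "x",
    region = rep(lionpanel:::CLADE_LEVELS, each = 2))
  pc8 <- panel_calls(full_sheet$sample, snps, matrix(2L, 8, 1))
  f0 <- reference_frequencies(pc8, full_sheet, pseudocount = 0)
  expect_true(all(f0 == 1))
  f1 <- reference_frequencies(pc8, full_sheet, pseudocount = 1)
  expect_true(all(f1 == 5 / 6))
  expect_true(all(f1 > 0 & f1 < 1))
  expect_error(reference_frequencies(pc, sheet), "no reference samples")
})

test_that("clade posteriors equal hand-computed Hardy-Weinberg arithmetic", {
  snps <- data.frame(id = c("s1", "s2", "s3"), type = "autosomal",
                     ref = "A", alt = "G")
  pc <- panel_calls("x", snps, matrix(c(0L, 2L, 1L), 1, 3))
  fA <- c(0.2, 0.8, 0.5); fB <- c(0.6, 0.3, 0.9)
  ref <- cbind(A = fA, B = fB); rownames(ref) <- snps$id
  res <- assign_clade(pc, ref)
  llA <- log((1 - 0.2)^2) + log(0.8^2) + log(2 * 0.5 * 0.5)
  llB <- log((1 - 0.6)^2) + log(0.3^2) + log(2 * 0.9 * 0.1)
  expect_equal(unname(res$loglik[1, ]), c(llA, llB))
  expect_equal(unname(res$posterior[1, "A"]),
               exp(llA) / (exp(llA) + exp(llB)))
  expect_equal(sum(res$posterior[1, ]), 1)
})

test_that("clade assignment is decisive for separable clades, uniform for identical ones", {
  snps <- data.frame(id = paste0("s", 1:20), type = "autosomal",
                     ref = "A", alt = "G")
  pc <- panel_calls("x", snps, matrix(2L, 1, 20))
  sep <- matrix(0.01, 20, 4, dimnames = list(snps$id, lionpanel:::CLADE_LEVELS))
  sep[, "India"] <- 0.99
  res <- assign_clade(pc, sep)
  expect_gt(res$posterior[1, "India"], 0.999)
  same <- matrix(0.4, 20, 4, dimnames = dimnames(sep))
  res2 <- assign_clade(pc, same)
  expect_equal(unname(res2$posterior[1, ]), rep(0.25, 4))
  # missing SNPs skipped; all-missing errors
  pcNA <- panel_calls("x", snps, matrix(NA_integer_, 1, 20))
  expect_error(assign_clade(pcNA, sep), "zero called")
})

test_that("PCA separates degenerate clusters and is stable to sample order", {
  g <- rbind(matrix(rep(c(0L, 0L, 2L, 2L, 1L, 0L), 4), 4, 6, byrow = TRUE),
             matrix(rep(c(2L, 2L, 0L, 0L, 1L, 2L), 4), 4, 6, byrow = TRUE))
  rownames(g) <- paste0("i", 1:8)
  p <- pca_panel(g)
  expect_lt(max(abs(diff(p$scores[1:4, 1]))), 1e-8)
  expect_lt(max(abs(diff(p$scores[5:8, 1]))), 1e-8)
  expect_gt(abs(p$scores[1, 1] - p$scores[5, 1]), 1)
  expect_lte(sum(p$explained), 1 + 1e-8)

  set.seed(61)
  g2 <- matrix(sample(0:2, 30 * 40, replace = TRUE), 30, 40,
               dimnames = list(paste0("i", 1:30), NULL))
  perm <- sample(30)
  a <- pca_panel(g2)$scores[perm, 1:3]
  b <- pca_panel(g2[perm, ])$scores[, 1:3]
  for (k in 1:3)
    expect_true(isTRUE(all.equal(a[, k], b[, k], tolerance = 1e-6)) ||
                  isTRUE(all.equal(a[, k], -b[, k], tolerance = 1e-6)))
})

test_that("allele-sharing NJ recovers additive four-taxon distances", {
  g <- rbind(a = rep(0L, 12), b = rep(0L, 12), c = rep(2L, 12), d = rep(2L, 12))
  g[2, 1] <- 2L; g[4, 12] <- 0L
  d <- allele_sharing_dist(g)
  expect_equal(d["a", "a"], 0)
  tree <- distance_tree(g)
  expect_true(tree_has_split(tree, c("a", "b")))
  # identical samples sit at distance zero
  g2 <- rbind(g, a2 = g["a", ])
  expect_equal(allele_sharing_dist(g2)["a", "a2"], 0)
  # a pair with no joint calls errors
  g3 <- g
  g3[1, 1:6] <- NA_integer_; g3[3, 7:12] <- NA_integer_
  expect_error(allele_sharing_dist(g3), "no called SNPs")
})

test_that("the basal northern/southern split appears in the discovery tree", {
  b <- generate_dataset(discovery_config(seed = 67L, include_outgroup = FALSE))
  tree <- distance_tree(b$observed)
  expect_true(tree_has_split(tree, c("Benin", "Cameroon", "DRC", "India")))
})

test_that("admixed samples are assigned far less confidently than pure ones", {
  post_adm <- c(); post_pure <- c()
  for (s in 1:8) {
    co <- simulate_cohort(n_samples = 120L, n_admixed = 10L, n_highmiss = 0L,
                          seed = 300 + s)
    ref <- reference_frequencies(co$calls, co$sheet)
    cl <- assign_clade(co$calls, ref)
    adm <- co$truth$admixed[cl$assignment$sample]
    post_adm <- c(post_adm, cl$assignment$posterior[adm])
    post_pure <- c(post_pure, cl$assignment$posterior[!adm])
  }
  expect_lt(mean(post_adm), mean(post_pure))
  # intermediate ancestry shows up as a many-fold enrichment of uncertain
  # assignments relative to pure samples
  expect_gt(mean(post_adm < 0.9), 3 * mean(post_pure < 0.9))
  expect_gt(mean(post_adm < 0.9), 0.08)
})

test_that("assign_cohort produces a coherent per-sample table", {
  co <- simulate_cohort(n_samples = 80L, n_admixed = 4L, n_highmiss = 10L,
                        seed = 71)
  res <- assign_cohort(co$calls, co$sheet, co$mt_key)
  expect_equal(nrow(res$table), 80L)
  expect_true(all(res$table$qc %in% c("retained", "excluded")))
  retained <- res$table[res$table$qc == "retained", ]
  expect_true(all(!is.na(retained$clade_posterior)))
  expect_true(all(abs(rowSums(res$posterior) - 1) < 1e-9))
  excluded <- res$table[res$table$qc == "excluded", ]
  expect_true(all(excluded$missing_fraction > 0.25))
})
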