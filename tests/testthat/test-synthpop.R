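# Generator: Balding-Nichols moments, genotype and coverage models, flanks,
# mtDNA haplotypes/numts, determinism.

test_that("Balding-Nichols draws have the model's moments", {
  cfg <- demography_config(
    data.frame(id = "x", region = "India", lambda = 1),
    n_sites = 10000L, ancestral_maf_range = c(0.3, 0.3),
    F_subspecies = 0.1, F_clade = c(0.1, 0.1, 0.1, 0.1), seed = 99L)
  set.seed(99)
  p <- rep(0.3, 10000)
  draws <- lionpanel:::.rbn(p, 0.1)
  expect_equal(mean(draws), 0.3, tolerance = 0.02)
  # Var = F p (1 - p) = 0.021
  expect_equal(var(draws), 0.1 * 0.3 * 0.7, tolerance = 0.05)
})

test_that("drift limits behave: F = 0 copies, F near 1 concentrates at fixation", {
  p <- runif(2000, 0.2, 0.8)
  expect_identical(lionpanel:::.rbn(p, 0), p)
  set.seed(1)
  near_fix <- lionpanel:::.rbn(p, 0.999)
  expect_gt(mean(near_fix < 0.01 | near_fix > 0.99), 0.95)
  expect_error(lionpanel:::.rbn(p, 1), "F")
})

test_that("clade frequencies equal ancestral in the joint no-drift limit", {
  cfg <- demography_config(
    data.frame(id = "x", region = "India", lambda = 1),
    n_sites = 500L, F_subspecies = 0, F_clade = c(0, 0, 0, 0), seed = 5L)
  fr <- simulate_allele_frequencies(cfg)
  for (cl in colnames(fr$clade))
    expect_equal(unname(fr$clade[, cl]), fr$ancestral)
})

test_that("genotypes follow admixture-weighted binomial sampling", {
  samples <- data.frame(
    id = c("pure", "fixed0", "fixed1"),
    region = rep("East Africa", 3), lambda = rep(5, 3),
    haplogroup = rep("North East Africa", 3))
  cfg <- demography_config(samples, n_sites = 10000L, seed = 21L)
  fr <- simulate_allele_frequencies(cfg)
  fr$clade[, "East Africa"] <- 0.4
  tr <- simulate_genotypes(fr, cfg, seed = 22L)
  # fixed frequencies give fixed genotypes
  fr0 <- fr; fr0$clade[, ] <- 0
  expect_true(all(simulate_genotypes(fr0, cfg, seed = 1L)$geno == 0L))
  fr1 <- fr; fr1$clade[, ] <- 1
  expect_true(all(simulate_genotypes(fr1, cfg, seed = 1L)$geno == 2L))
  # heterozygosity matches 2 f (1 - f)
  expect_equal(mean(tr$geno[, "pure"] == 1L), 2 * 0.4 * 0.6, tolerance = 0.03)
})

test_that("coverage model: high depth preserves truth, single reads drop heterozygotes", {
  samples <- data.frame(id = c("deep"), region = "East Africa",
                        lambda = 500, haplogroup = "North East Africa")
  cfg <- demography_config(samples, n_sites = 2000L, seed = 31L)
  fr <- simulate_allele_frequencies(cfg)
  tr <- simulate_genotypes(fr, cfg, seed = 32L)
  ob <- simulate_coverage_and_calls(tr, cfg, seed = 33L)
  expect_identical(ob$geno, tr$geno)

  # depth 1 on a het: never observed het, both homozygotes sampled
  n <- 5000L
  truth <- variant_dataset(
    data.frame(scaffold = "s", position = seq_len(n), ref = "A", alt = "G"),
    "x", matrix(1L, n, 1), matrix(100L, n, 1))
  cfg1 <- demography_config(data.frame(id = "x", region = "India",
                                       lambda = 1e-9 + 1, haplogroup = "India"),
                            n_sites = n, seed = 1L)
  set.seed(44)
  ob1 <- simulate_coverage_and_calls(truth, cfg1, seed = NULL)
  d1 <- !is.na(ob1$geno) & ob1$depth == 1L
  expect_gt(sum(d1), 500L)
  expect_true(all(ob1$geno[d1] %in% c(0L, 2L)))
  expect_equal(mean(ob1$geno[d1] == 0L), 0.5, tolerance = 0.1)
})

test_that("heterozygote dropout at fixed depth matches the closed form 1 - 2^(1-d)", {
  n <- 20000L
  truth <- variant_dataset(
    data.frame(scaffold = "s", position = seq_len(n), ref = "A", alt = "G"),
    "x", matrix(1L, n, 1), matrix(100L, n, 1))
  cfg <- demography_config(data.frame(id = "x", region = "India", lambda = 2,
                                      haplogroup = "India"),
                           n_sites = n, seed = 1L)
  ob <- simulate_coverage_and_calls(truth, cfg, seed = 55L)
  at2 <- !is.na(ob$geno) & ob$depth == 2L
  # P(observed het | truth het, d = 2) = 1 - 2^(1-2) = 0.5
  expect_equal(mean(ob$geno[at2] == 1L), 0.5, tolerance = 0.03)
  at4 <- !is.na(ob$geno) & ob$depth == 4L
  expect_equal(mean(ob$geno[at4] == 1L), 1 - 2^(1 - 4), tolerance = 0.03)
})

test_that("flanks are 101 nt with the focal reference base at position 51", {
  d <- random_dataset(300, 4, seed = 8)
  cfg <- demography_config(data.frame(id = "x", region = "India", lambda = 1,
                                      haplogroup = "India"),
                           n_sites = 300L, flank_variant_rate = 1.2, seed = 1L)
  fl <- simulate_flanks(d, cfg, seed = 61L)
  expect_true(all(nchar(fl$flanks) == 101L))
  expect_equal(unname(substr(fl$flanks, 51, 51)), d$sites$ref)
  expect_false(any(fl$variants$flank_pos == 51L))
  # Poisson mean: 2 * rate variants per site
  expect_equal(nrow(fl$variants) / 300, 2 * 1.2, tolerance = 0.25)
  fl0 <- simulate_flanks(d, cfg, rate = 0, seed = 62L)
  expect_equal(nrow(fl0$variants), 0L)
})

test_that("mtDNA haplotypes follow the haplogroup key and numts diverge as configured", {
  m <- mtdna_model(seed = 17L)
  key <- haplogroup_key(m)
  # every pair of haplogroups separable
  for (i in 1:5) for (j in (i + 1):6)
    expect_gt(sum(key[i, ] != key[j, ]), 0L)
  samples <- data.frame(id = c("g1", "g2"), region = "India",
                        haplogroup = c("India", "India"))
  mt <- simulate_mtdna(m, samples, seed = 18L)
  expect_equal(unname(mt$calls["g1", ]), unname(key["India", ]))

  # numt divergence 0 reproduces the source segment
  m0 <- mtdna_model(seed = 19L, numt_divergence = 0)
  mt0 <- simulate_mtdna(m0, samples, seed = 20L)
  seg <- substr(m0$genome, mt0$numt_source$start[1], mt0$numt_source$end[1])
  expect_identical(unname(mt0$numts[1]), seg)

  # observed identity ~ 1 - divergence
  mdiv <- mtdna_model(seed = 23L, numt_divergence = 0.15, numt_length = 1000L)
  mtd <- simulate_mtdna(mdiv, samples, seed = 24L)
  seg <- strsplit(substr(mdiv$genome, mtd$numt_source$start[1],
                         mtd$numt_source$end[1]), "")[[1]]
  numt <- strsplit(mtd$numts[[1]], "")[[1]]
  expect_equal(mean(seg == numt), 0.85, tolerance = 0.03)
})

test_that("missing haplogroup assignments are a configuration error", {
  m <- mtdna_model(seed = 1L)
  samples <- data.frame(id = "x", region = "India", haplogroup = NA_character_)
  expect_error(simulate_mtdna(m, samples), "haplogroup")
})

test_that("generate_dataset writes a loadable, seed-deterministic bundle", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- discovery_config(n_sites = 400L, n_scaffolds = 60L, seed = 77L)
  generate_dataset(cfg, out_dir = dir1, force = TRUE)
  generate_dataset(cfg, out_dir = dir2, force = TRUE)
  d <- read_vcf(file.path(dir1, "discovery.vcf"))
  expect_equal(n_sites(d), 400L)
  expect_equal(n_samples(d), 11L)  # 10 lions + outgroup
  expect_identical(readLines(file.path(dir1, "discovery.vcf")),
                   readLines(file.path(dir2, "discovery.vcf")))
  expect_identical(readLines(file.path(dir1, "flanks.fa")),
                   readLines(file.path(dir2, "flanks.fa")))
  expect_error(generate_dataset(cfg, out_dir = dir1), "not empty")
})

test_that("subspecies divergence exceeds within-subspecies clade divergence", {
  cfg <- discovery_config(n_sites = 3000L, seed = 88L)
  set.seed(88)
  # the India clade's bottleneck inflates within-north divergence, so the
  # clean comparison uses the two equal-drift southern clades
  div <- replicate(5, {
    fr <- simulate_allele_frequencies(cfg, seed = NULL)
    c(across = mean(abs(fr$clade[, "West & Central Africa"] -
                          fr$clade[, "East Africa"])),
      within = mean(abs(fr$clade[, "East Africa"] -
                          fr$clade[, "Southern Africa"])))
  })
  expect_true(all(div["across", ] > div["within", ]))
})

test_that("low-coverage individuals underestimate heterozygosity, shrinking with depth", {
  gaps <- vapply(c(0.5, 2, 6), function(lam) {
    n <- 6000L
    cfg <- demography_config(data.frame(id = "x", region = "East Africa",
                                        lambda = lam,
                                        haplogroup = "North East Africa"),
                             n_sites = n, seed = 101L)
    set.seed(101)
    fr <- simulate_allele_frequencies(cfg, seed = NULL)
    tr <- simulate_genotypes(fr, cfg, seed = NULL)
    ob <- simulate_coverage_and_calls(tr, cfg, seed = NULL)
    called <- !is.na(ob$geno[, 1])
    truth_het <- mean(tr$geno[called, 1] == 1L)
    truth_het - het_individual(ob, "x")
  }, 0)
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) < 0))
})
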