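# Panel selection criteria, the greedy spreading rule vs a brute-force
# oracle, numt screening and the mtDNA diagnostic panel.

test_that("combined flank coverage uses the window minimum with an exact boundary", {
  fix <- make_candidates(60, seed = 101)
  cand <- fix$cand
  cand$window_depth[, ] <- 20L
  expect_true(all(check_flank_coverage(cand, 20)))
  cand$window_depth[1, 73] <- 19L
  ok <- check_flank_coverage(cand, 20)
  expect_false(ok[1]); expect_true(all(ok[-1]))
  # brute-force min scan on random profiles
  ok2 <- check_flank_coverage(fix$cand, 20)
  oracle <- apply(fix$wd, 1, function(x) min(x) >= 20)
  expect_equal(as.logical(ok2), unname(oracle))
  expect_true(any(!ok2))
})

test_that("flank-variant limit: total reading fails 1+1, per-flank reading allows it", {
  fix <- make_candidates(10, seed = 7)
  cand <- fix$cand
  cand$n_flank_var_up <- rep(0L, 10); cand$n_flank_var_down <- rep(0L, 10)
  expect_true(all(check_flank_variants(cand, 1)))
  cand$n_flank_var_up[3] <- 1L; cand$n_flank_var_down[3] <- 1L
  expect_false(check_flank_variants(cand, 1)[3])
  expect_true(check_flank_variants(cand, 1, per_flank = TRUE)[3])
  # detected counts equal generator-injected truth
  counts <- fix$cand$n_flank_var_up + fix$cand$n_flank_var_down
  truth <- as.integer(table(factor(fix$fv$site_id, levels = fix$cand$ids)))
  expect_identical(counts, truth)
})

test_that("mapping-quality proxy passes unassessed without stats and is threshold-monotone", {
  fix <- make_candidates(30, seed = 11)
  ok <- check_mapping_quality_proxy(fix$cand)
  expect_true(all(ok))
  expect_true(all(attr(ok, "unassessed")))
  stats <- data.frame(site_id = fix$cand$ids,
                      softclip_frac = runif(30, 0, 0.3),
                      indel_dist = sample(c(NA, 1:20), 30, replace = TRUE))
  stats$indel_dist[2] <- 3
  expect_false(check_mapping_quality_proxy(fix$cand, stats,
                                           max_indel_near = 5)[2])
  sweep_sizes <- vapply(c(0.05, 0.1, 0.2, 0.3), function(thr)
    sum(check_mapping_quality_proxy(fix$cand, stats,
                                    max_softclip_frac = thr,
                                    max_indel_near = 0)), 0L)
  expect_true(all(diff(sweep_sizes) >= 0L))
})

test_that("minimum-individuals criterion is exact at the 8-of-10 boundary", {
  fix <- make_candidates(50, seed = 13)
  cand <- fix$cand
  cand$calls[1, ] <- c(rep(0L, 8), NA, NA)   # 8 called
  cand$calls[2, ] <- c(rep(0L, 7), NA, NA, NA)  # 7 called
  ok <- check_min_individuals(cand, 8)
  expect_true(ok[1]); expect_false(ok[2])
  oracle <- apply(cand$calls, 1, function(x) sum(!is.na(x)) >= 8)
  expect_equal(unname(ok), unname(oracle))
})

test_that("genotype composition excludes all-het sites and rewards mixed ones", {
  fix <- make_candidates(6, seed = 17)
  cand <- fix$cand
  cand$calls[1, ] <- 1L                        # all het
  cand$calls[2, ] <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L)  # mixed
  cand$calls[3, ] <- 0L                        # all hom-ref
  comp <- check_genotype_composition(cand)
  expect_false(comp$hard_ok[1])
  expect_true(comp$hard_ok[2]); expect_equal(comp$soft_bonus[2], 1)
  expect_true(comp$hard_ok[3]); expect_equal(comp$soft_bonus[3], 0)
})

test_that("one SNP per scaffold keeps the scaffold's higher-scoring candidate", {
  fix <- make_candidates(80, seed = 19, n_scaffolds = 20)
  panel <- suppressWarnings(
    select_autosomal_panel(fix$cand, target_n = 200, min_combined = 0,
                           min_called = 0, max_variants = Inf))
  expect_false(anyDuplicated(panel$autosomal$scaffold) > 0)
  comp <- check_genotype_composition(fix$cand)
  for (s in unique(panel$autosomal$scaffold)) {
    chosen <- panel$autosomal[panel$autosomal$scaffold == s, ]
    rivals <- fix$cand$sites$scaffold == s & comp$hard_ok
    expect_equal(chosen$score,
                 max(rowSums(!is.na(fix$cand$calls[rivals, , drop = FALSE])) +
                       comp$soft_bonus[rivals]))
  }
})

test_that("selection equals the brute-force greedy oracle on synthetic candidates", {
  fix <- make_candidates(300, seed = 23, n_scaffolds = 180)
  panel <- select_autosomal_panel(fix$cand, target_n = 60)
  expect_setequal(panel$autosomal$id, oracle_autosomal_panel(fix, 60))
  # target beyond the eligible count returns everything eligible, warning
  expect_warning(all_panel <- select_autosomal_panel(fix$cand, target_n = 5000),
                 "eligible")
  expect_setequal(all_panel$autosomal$id, oracle_autosomal_panel(fix, 5000))
})

test_that("removing any hard criterion never shrinks the eligible panel", {
  fix <- make_candidates(200, seed = 29)
  n_sel <- function(...) {
    suppressWarnings(nrow(select_autosomal_panel(fix$cand, target_n = 1e4,
                                                 ...)$autosomal))
  }
  base <- n_sel()
  expect_gte(n_sel(min_combined = 0), base)
  expect_gte(n_sel(max_variants = Inf), base)
  expect_gte(n_sel(min_called = 0), base)
})

test_that("panel selection is deterministic for identical inputs", {
  fix <- make_candidates(250, seed = 31)
  p1 <- select_autosomal_panel(fix$cand, target_n = 40)
  p2 <- select_autosomal_panel(fix$cand, target_n = 40)
  expect_identical(p1, p2)
})

test_that("numt screening flags verbatim and mildly diverged copies only", {
  set.seed(37)
  bases <- c("A", "C", "G", "T")
  flank <- paste(sample(bases, 101, replace = TRUE), collapse = "")
  mutate <- function(s, rate) {
    x <- strsplit(s, "")[[1]]
    hit <- runif(length(x)) < rate
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(bases, b), 1), "")
    paste(x, collapse = "")
  }
  verbatim <- paste0(paste(sample(bases, 200, TRUE), collapse = ""), flank,
                     paste(sample(bases, 200, TRUE), collapse = ""))
  expect_true(screen_numts(flank, c(n1 = verbatim)))
  random_numt <- paste(sample(bases, 600, TRUE), collapse = "")
  expect_false(screen_numts(flank, c(n1 = random_numt)))
  near <- sub(flank, mutate(flank, 0.15), verbatim, fixed = TRUE)
  expect_true(screen_numts(flank, c(n1 = near)))
  far <- sub(flank, mutate(flank, 0.30), verbatim, fixed = TRUE)
  expect_false(screen_numts(flank, c(n1 = far)))
  unscr <- screen_numts(flank, character())
  expect_false(as.logical(unscr))
  expect_true(attr(unscr, "unscreened"))
})

test_that("the mtDNA panel separates all haplogroups with two subspecies SNPs", {
  model <- mtdna_model(seed = 41)
  samples <- data.frame(id = "x", region = "India", haplogroup = "India")
  mt <- simulate_mtdna(model, samples, seed = 42)
  panel <- select_mtdna_panel(model, mt$numts, target_n = 14)
  expect_equal(nrow(panel$mtdna), 14L)
  expect_equal(sum(panel$mtdna$branch == "subspecies"), 2L)
  expect_setequal(unique(panel$mtdna$branch),
                  c("subspecies", lionpanel:::HAPLOGROUPS))
  key <- panel$key
  for (i in 1:5) for (j in (i + 1):6)
    expect_gt(sum(key[i, ] != key[j, ]), 0)
  # the two subspecies SNPs split northern from southern haplogroups
  sub_ids <- panel$mtdna$id[panel$mtdna$branch == "subspecies"]
  for (id in sub_ids) {
    north <- key[lionpanel:::NORTHERN_HAPLOGROUPS, id]
    south <- key[setdiff(rownames(key), lionpanel:::NORTHERN_HAPLOGROUPS), id]
    expect_equal(length(unique(north)), 1L)
    expect_equal(length(unique(south)), 1L)
    expect_false(north[1] == south[1])
  }
})

test_that("mtDNA selection fails when a branch has only numt-contaminated candidates", {
  model <- mtdna_model(seed = 43)
  # numts that copy every India candidate flank verbatim
  india <- model$sites[model$sites$branch == "India", ]
  numts <- vapply(india$position, function(p)
    substr(model$genome, p - 80, p + 80), "")
  names(numts) <- paste0("numt_", seq_along(numts))
  expect_error(select_mtdna_panel(model, numts), "India")
  expect_error(select_mtdna_panel(model, character(), target_n = 7),
               "infeasible")
})

test_that("applying the designed panel to cohort-style data yields complete calls", {
  b <- generate_dataset(discovery_config(n_sites = 2500L, seed = 47L))
  masked <- attribute_chromosomes(mask_low_coverage(b$observed),
                                  b$scaffold_map)
  lions <- b$sheet$sample[b$sheet$region != "Outgroup"]
  cand <- panel_candidates(masked[, lions], b$flanks, b$flank_variants,
                           b$window_depth)
  aut <- suppressWarnings(select_autosomal_panel(cand, target_n = 50))
  mt <- select_mtdna_panel(b$mt_model, b$mtdna$numts)
  panel <- combine_panels(aut, mt)
  calls <- apply_panel(panel, b$observed[, lions], b$mtdna$calls)
  expect_s3_class(calls, "PanelCalls")
  # high-coverage samples are called at >= 95% of panel SNPs (depth >= 1)
  deep <- c("Kenya", "Namibia", "India", "Cameroon")
  miss <- sample_missingness(calls, type = "autosomal")[deep]
  expect_true(all(miss <= 0.05))
})
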