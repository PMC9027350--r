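# Independent brute-force re-implementation of the autosomal panel rule,
# written loop-style against the raw candidate components (not the package's
# vectorized evaluation), plus a builder for synthetic candidate sets.

make_candidates <- function(n, n_samples = 10, seed = 1, n_scaffolds = 300,
                            n_chrom = 19, miss = 0.2) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  scaffold_names <- sprintf("scf%03d", seq_len(n_scaffolds))
  chrom_of <- setNames(rep_len(paste0("chr", seq_len(n_chrom)), n_scaffolds),
                       scaffold_names)
  scaf <- sample(scaffold_names, n, replace = TRUE)
  pos <- sample.int(1e6, n)
  while (anyDuplicated(paste(scaf, pos))) pos <- sample.int(1e6, n)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  sites <- data.frame(scaffold = scaf, position = pos, ref = ref, alt = alt,
                      chromosome = unname(chrom_of[scaf]))
  geno <- matrix(sample(0:2, n * n_samples, replace = TRUE,
                        prob = c(0.4, 0.3, 0.3)), n, n_samples)
  geno[matrix(runif(n * n_samples) < miss, n, n_samples)] <- NA_integer_
  # a few all-het and all-hom sites to exercise composition
  geno[seq_len(max(1, n %/% 50)), ] <- 1L
  geno[seq.int(n %/% 50 + 1, length.out = max(1, n %/% 50)), ] <- 0L
  depth <- matrix(rpois(n * n_samples, 4), n, n_samples)
  d <- variant_dataset(sites, sprintf("s%02d", seq_len(n_samples)), geno, depth)

  flanks <- vapply(seq_len(n), function(i) {
    s <- sample(bases, 101, replace = TRUE); s[51] <- ref[i]
    paste(s, collapse = "")
  }, "")
  names(flanks) <- site_ids(d)
  k <- rpois(n, 0.8)
  fv <- data.frame(
    site_id = rep(site_ids(d), k),
    flank_pos = unlist(lapply(k, function(ki)
      if (ki == 0) integer() else sample(c(1:50, 52:101), ki))))
  # generous combined depth with a low-coverage dip injected at some sites
  wd <- matrix(rpois(n * 101L, 50), n, 101L)
  dip <- runif(n) < 0.15
  wd[cbind(which(dip), sample.int(101L, sum(dip), replace = TRUE))] <-
    rpois(sum(dip), 12)
  rownames(wd) <- site_ids(d)
  list(cand = panel_candidates(d, flanks, fv, wd), dataset = d,
       flanks = flanks, fv = fv, wd = wd)
}

# plain-loop oracle for the full selection rule
oracle_autosomal_panel <- function(fix, target_n, min_combined = 20,
                                   max_variants = 1, min_called = 8) {
  d <- fix$dataset
  ids <- site_ids(d)
  n <- length(ids)
  rows <- list()
  for (i in seq_len(n)) {
    ok_cov <- min(fix$wd[i, ]) >= min_combined
    nv <- sum(fix$fv$site_id == ids[i])
    ok_var <- nv <= max_variants
    calls <- d$geno[i, ]
    n_called <- sum(!is.na(calls))
    ok_ind <- n_called >= min_called
    all_het <- n_called > 0 && all(calls[!is.na(calls)] == 1L)
    has_het <- any(calls == 1L, na.rm = TRUE)
    has_hom <- any(calls %in% c(0L, 2L), na.rm = TRUE)
    if (ok_cov && ok_var && ok_ind && !all_het)
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids[i], scaffold = d$sites$scaffold[i],
        position = d$sites$position[i],
        chromosome = d$sites$chromosome[i],
        score = n_called + as.numeric(has_het && has_hom))
  }
  elig <- do.call(rbind, rows)
  # best per scaffold
  per_scaf <- list()
  for (s in unique(elig$scaffold)) {
    sub <- elig[elig$scaffold == s, ]
    sub <- sub[order(-sub$score, sub$position), ]
    per_scaf[[s]] <- sub[1, ]
  }
  elig <- do.call(rbind, per_scaf)
  chroms <- sort(unique(elig$chromosome))
  chroms <- c(setdiff(chroms, "unplaced"), intersect("unplaced", chroms))
  queues <- lapply(chroms, function(ch) {
    sub <- elig[elig$chromosome == ch, ]
    sub[order(-sub$score, sub$position, sub$scaffold), ]
  })
  picked <- character()
  repeat {
    advanced <- FALSE
    for (k in seq_along(queues)) {
      if (length(picked) >= target_n) break
      if (nrow(queues[[k]]) > 0) {
        picked <- c(picked, queues[[k]]$id[1])
        queues[[k]] <- queues[[k]][-1, , drop = FALSE]
        advanced <- TRUE
      }
    }
    if (length(picked) >= target_n || !advanced) break
  }
  picked
}
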