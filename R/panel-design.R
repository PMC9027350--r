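# SNP panel selection. Autosomal candidates are screened by six criteria:
# (1) combined coverage >= 20 across every position of the 101-nt window,
# (2) at most one extra variable position in the 50-bp flanks, (3) a mapping
# quality proxy (pass-through when no auxiliary stats are supplied, standing
# in for by-eye inspection of alignments), (4) at least eight individuals
# called at the site, (5) even spreading across chromosomes with at most
# one SNP per scaffold, (6) genotype composition (all-heterozygote sites
# excluded as likely duplications; sites showing both het and hom genotypes
# get a scoring bonus). Mitochondrial candidates are haplogroup-diagnostic
# sites screened against numt decoys by local alignment.

#' Assemble panel candidates from a filtered dataset
#'
#' Bundles, for every site of `dataset`, the genotype calls of the lion
#' samples, the 101-nt flank, the known flank-variant count and the
#' combined-depth window profile, ready for the selection criteria.
#'
#' @param dataset a `VariantDataset`, conventionally masked and
#'   chromosome-attributed.
#' @param flanks named character vector of 101-nt flank sequences (names =
#'   site ids).
#' @param flank_variants data.frame `site_id`, `flank_pos` of extra variable
#'   positions (focal position excluded).
#' @param window_depth integer matrix of combined depth per window position
#'   (rownames = site ids, 101 columns).
#' @param lion_samples samples the criteria are computed over (default: all
#'   samples of `dataset`).
#' @return an object of class `PanelCandidates`.
#' @export
panel_candidates <- function(dataset, flanks, flank_variants, window_depth,
                             lion_samples = NULL) {
  stopifnot(inherits(dataset, "VariantDataset"))
  if (is.null(lion_samples)) lion_samples <- dataset$samples
  ids <- site_ids(dataset)
  if (!all(ids %in% names(flanks))) stop("flanks missing for some sites")
  if (!all(ids %in% rownames(window_depth)))
    stop("window depth profiles missing for some sites")
  nv_up <- table(factor(flank_variants$site_id[flank_variants$flank_pos <= 50],
                        levels = ids))
  nv_dn <- table(factor(flank_variants$site_id[flank_variants$flank_pos >= 52],
                        levels = ids))
  structure(list(
    sites = dataset$sites,
    ids = ids,
    calls = dataset$geno[, lion_samples, drop = FALSE],
    flanks = flanks[ids],
    n_flank_var_up = as.integer(nv_up),
    n_flank_var_down = as.integer(nv_dn),
    window_depth = window_depth[ids, , drop = FALSE]),
    class = "PanelCandidates")
}

#' @export
print.PanelCandidates <- function(x, ...) {
  cat("PanelCandidates:", length(x$ids), "candidate sites,",
      ncol(x$calls), "samples\n")
  invisible(x)
}

#' Criterion 1: combined flank coverage
#'
#' Passes when the minimum, over all `2 * window + 1` window positions, of
#' the summed depth across samples reaches `min_combined`. Sites whose
#' window profile is truncated (scaffold edge) fail with an `edge` flag.
#'
#' @param candidates a `PanelCandidates`.
#' @param min_combined combined-depth threshold (default 20).
#' @param window flank length in bp on each side (default 50).
#' @return logical vector (attribute `edge`: truncated-window flags).
#' @export
check_flank_coverage <- function(candidates, min_combined = 20L, window = 50L) {
  prof <- candidates$window_depth
  cols <- (51L - window):(51L + window)
  edge <- rep(max(cols) > ncol(prof) | min(cols) < 1L, nrow(prof))
  if (!any(edge)) {
    sub <- prof[, cols, drop = FALSE]
    edge <- apply(is.na(sub), 1L, any)
    minimum <- suppressWarnings(apply(sub, 1L, min, na.rm = TRUE))
    ok <- !edge & is.finite(minimum) & minimum >= min_combined
  } else ok <- rep(FALSE, nrow(prof))
  structure(as.vector(ok), edge = as.vector(edge))
}

#' Criterion 2: flank variable positions
#'
#' Passes when the number of extra variable positions in the flanks does not
#' exceed `max_variants`. By default the limit applies to the total across
#' both 50-bp flanks (conservative reading); `per_flank = TRUE` applies it
#' to each flank separately.
#'
#' @param candidates a `PanelCandidates`.
#' @param max_variants maximum allowed variable positions (default 1).
#' @param per_flank apply the limit per flank instead of in total.
#' @return logical vector.
#' @export
check_flank_variants <- function(candidates, max_variants = 1L,
                                 per_flank = FALSE) {
  up <- candidates$n_flank_var_up
  dn <- candidates$n_flank_var_down
  if (per_flank) up <= max_variants & dn <= max_variants
  else (up + dn) <= max_variants
}

#' Criterion 3: mapping-quality proxy
#'
#' Automated stand-in for visual inspection of flank alignments. When
#' per-site mapping stats are supplied, a candidate fails if its soft-clip
#' fraction exceeds `max_softclip_frac` or an indel lies within
#' `max_indel_near` bp of the focal SNP. Without stats every candidate
#' passes, flagged `unassessed`.
#'
#' @param candidates a `PanelCandidates`.
#' @param stats optional data.frame `site_id`, `softclip_frac`,
#'   `indel_dist` (bp distance of nearest indel; `NA` = none observed).
#' @param max_softclip_frac maximum tolerated soft-clipped read fraction.
#' @param max_indel_near exclusion radius around the focal SNP in bp.
#' @return logical vector (attribute `unassessed`).
#' @export
check_mapping_quality_proxy <- function(candidates, stats = NULL,
                                        max_softclip_frac = 0.1,
                                        max_indel_near = 5L) {
  n <- length(candidates$ids)
  if (is.null(stats))
    return(structure(rep(TRUE, n), unassessed = rep(TRUE, n)))
  m <- match(candidates$ids, stats$site_id)
  unassessed <- is.na(m)
  clip <- stats$softclip_frac[m]
  ind <- stats$indel_dist[m]
  bad <- (!is.na(clip) & clip > max_softclip_frac) |
    (!is.na(ind) & ind <= max_indel_near)
  ok <- unassessed | !bad
  structure(as.vector(ok), unassessed = unassessed)
}

#' Criterion 4: minimum called individuals at the focal site
#'
#' @param candidates a `PanelCandidates`.
#' @param min_called minimum number of non-missing calls (default 8).
#' @return logical vector.
#' @export
check_min_individuals <- function(candidates, min_called = 8L) {
  rowSums(!is.na(candidates$calls)) >= min_called
}

#' Criterion 6: genotype composition
#'
#' Sites where every non-missing call is heterozygous are excluded outright
#' (possible gene duplications). Sites showing at least one heterozygote and
#' at least one homozygote earn a scoring bonus.
#'
#' @param candidates a `PanelCandidates`.
#' @return list with `hard_ok` (logical) and `soft_bonus` (0/1 numeric).
#' @export
check_genotype_composition <- function(candidates) {
  g <- candidates$calls
  n_called <- rowSums(!is.na(g))
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  n_hom <- rowSums(g == 0L | g == 2L, na.rm = TRUE)
  all_het <- n_called > 0L & n_het == n_called
  list(hard_ok = !all_het,
       soft_bonus = as.numeric(n_het >= 1L & n_hom >= 1L))
}

# evaluate all hard criteria + score; returns a data.frame of provenance
.evaluate_candidates <- function(candidates, min_combined = 20L, window = 50L,
                                 max_variants = 1L, per_flank = FALSE,
                                 mapping_stats = NULL, min_called = 8L) {
  cov_ok <- check_flank_coverage(candidates, min_combined, window)
  var_ok <- check_flank_variants(candidates, max_variants, per_flank)
  map_ok <- check_mapping_quality_proxy(candidates, mapping_stats)
  ind_ok <- check_min_individuals(candidates, min_called)
  comp <- check_genotype_composition(candidates)
  n_called <- rowSums(!is.na(candidates$calls))
  data.frame(
    id = candidates$ids,
    scaffold = candidates$sites$scaffold,
    position = candidates$sites$position,
    chromosome = ifelse(is.na(candidates$sites$chromosome), "unplaced",
                        candidates$sites$chromosome),
    ref = candidates$sites$ref, alt = candidates$sites$alt,
    pass_coverage = as.vector(cov_ok), pass_flank_variants = var_ok,
    pass_mapping = as.vector(map_ok), pass_min_individuals = ind_ok,
    pass_composition = comp$hard_ok,
    n_called = n_called, bonus = comp$soft_bonus,
    score = n_called + comp$soft_bonus,
    stringsAsFactors = FALSE)
}

#' Select the autosomal SNP panel
#'
#' Only candidates passing every hard criterion are eligible. Each
#' candidate's score is its called-sample count plus the composition bonus.
#' At most one SNP is kept per scaffold (the scaffold's highest-scoring
#' candidate; ties broken by position). Chromosomes are then filled
#' round-robin — cycling through chromosomes in label order, taking each
#' chromosome's next-best remaining candidate — until `target_n` SNPs are
#' selected or candidates are exhausted (a warning reports a short panel).
#'
#' @param candidates a `PanelCandidates` with chromosome annotation.
#' @param target_n autosomal panel size (default 125).
#' @param min_combined,window,max_variants,per_flank,mapping_stats,min_called
#'   criterion parameters, see the `check_*` functions.
#' @return a `PanelDefinition` with the autosomal part filled.
#' @export
select_autosomal_panel <- function(candidates, target_n = 125L,
                                   min_combined = 20L, window = 50L,
                                   max_variants = 1L, per_flank = FALSE,
                                   mapping_stats = NULL, min_called = 8L) {
  ev <- .evaluate_candidates(candidates, min_combined, window, max_variants,
                             per_flank, mapping_stats, min_called)
  elig <- ev[ev$pass_coverage & ev$pass_flank_variants & ev$pass_mapping &
               ev$pass_min_individuals & ev$pass_composition, , drop = FALSE]
  if (nrow(elig) == 0L) stop("no candidates pass the hard criteria")

  # one SNP per scaffold: keep the scaffold's best (score desc, position asc)
  elig <- elig[order(elig$scaffold, -elig$score, elig$position), , drop = FALSE]
  elig <- elig[!duplicated(elig$scaffold), , drop = FALSE]

  # round-robin across chromosomes ("unplaced" cycles last)
  chroms <- sort(unique(elig$chromosome))
  chroms <- c(setdiff(chroms, "unplaced"),
              intersect("unplaced", chroms))
  per_chrom <- lapply(chroms, function(ch) {
    sub <- elig[elig$chromosome == ch, , drop = FALSE]
    sub[order(-sub$score, sub$position, sub$scaffold), , drop = FALSE]
  })
  names(per_chrom) <- chroms
  taken <- integer(length(per_chrom))
  selected <- list()
  while (length(selected) < target_n && any(taken < vapply(per_chrom, nrow, 0L))) {
    for (k in seq_along(per_chrom)) {
      if (length(selected) >= target_n) break
      if (taken[k] < nrow(per_chrom[[k]])) {
        taken[k] <- taken[k] + 1L
        selected[[length(selected) + 1L]] <- per_chrom[[k]][taken[k], , drop = FALSE]
      }
    }
  }
  aut <- do.call(rbind, selected)
  rownames(aut) <- NULL
  if (nrow(aut) < target_n)
    warning("only ", nrow(aut), " eligible SNPs available (target ",
            target_n, ")")
  panel_definition(
    autosomal = aut, mtdna = NULL,
    params = list(target_autosomal = target_n, min_combined = min_combined,
                  window = window, max_variants = max_variants,
                  per_flank = per_flank, min_called = min_called))
}

#' Screen a mitochondrial assay flank against numt decoys
#'
#' Local alignment (Smith-Waterman via Biostrings) of the 101-nt flank
#' against each numt sequence. The candidate is a numt risk if any alignment
#' covers the focal position with identity at least `min_identity` over at
#' least `min_length` aligned columns.
#'
#' @param flank 101-nt flank with the focal SNP at position `focal_pos`.
#' @param numts named character vector of numt sequences.
#' @param min_identity identity threshold (default 0.8).
#' @param min_length minimum aligned columns (default 40).
#' @param focal_pos focal position within the flank (default 51).
#' @return `TRUE` when the flank is at numt risk (attribute `unscreened`
#'   when no numts were supplied).
#' @export
screen_numts <- function(flank, numts, min_identity = 0.8, min_length = 40L,
                         focal_pos = 51L) {
  if (length(numts) == 0L)
    return(structure(FALSE, unscreened = TRUE))
  p <- Biostrings::DNAString(flank)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (nm in seq_along(numts)) {
    aln <- Biostrings::pairwiseAlignment(
      p, Biostrings::DNAString(numts[[nm]]), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    cols <- length(pat)
    if (cols < min_length) next
    identity <- sum(pat == sub & pat != "-") / cols
    covers <- Biostrings::start(Biostrings::pattern(aln)) <= focal_pos &&
      Biostrings::end(Biostrings::pattern(aln)) >= focal_pos
    if (covers && identity >= min_identity) return(TRUE)
  }
  FALSE
}

#' Select the mitochondrial diagnostic SNP panel
#'
#' Picks haplogroup-diagnostic sites from the model's candidate key so that
#' every one of the six haplogroups is distinguished by at least one
#' selected SNP, exactly two selected SNPs are subspecies-diagnostic
#' (northern vs southern), and every selected SNP passes numt screening.
#' The remaining slots are filled round-robin across haplogroup branches.
#'
#' @param model an `MtDNAModel` (supplies candidate sites and their flanks).
#' @param numts named character vector of numt sequences (empty vector =
#'   screening skipped, flagged).
#' @param target_n mtDNA panel size (default 14).
#' @param min_identity,min_length numt screening thresholds.
#' @return a `PanelDefinition` with the mtDNA part filled (the selected-key
#'   matrix is attached as the `key` element).
#' @export
select_mtdna_panel <- function(model, numts, target_n = 14L,
                               min_identity = 0.8, min_length = 40L) {
  n_branch <- length(model$haplogroups)
  if (target_n < n_branch + 2L)
    stop("target_n = ", target_n, " is infeasible: need at least one SNP per ",
         "haplogroup branch plus two subspecies-diagnostic SNPs")
  sites <- model$sites
  glen <- nchar(model$genome)
  flank_of <- function(pos) substr(model$genome, pos - 50L, pos + 50L)
  risk <- vapply(sites$position, function(pos) {
    if (pos - 50L < 1L || pos + 50L > glen) return(TRUE)
    as.logical(screen_numts(flank_of(pos), numts, min_identity, min_length))
  }, TRUE)
  clean <- sites[!risk, , drop = FALSE]

  missing_branch <- setdiff(model$haplogroups,
                            unique(clean$branch[clean$branch != "subspecies"]))
  if (length(missing_branch) > 0L)
    stop("no numt-clean diagnostic candidate for haplogroup branch(es): ",
         paste(missing_branch, collapse = ", "))
  n_sub <- sum(clean$branch == "subspecies")
  if (n_sub < 2L)
    stop("fewer than two numt-clean subspecies-diagnostic candidates")

  sub_sel <- clean[clean$branch == "subspecies", , drop = FALSE][1:2, ]
  pools <- lapply(model$haplogroups, function(h)
    clean[clean$branch == h, , drop = FALSE])
  names(pools) <- model$haplogroups
  taken <- integer(n_branch)
  picked <- list()
  needed <- target_n - 2L
  while (length(picked) < needed && any(taken < vapply(pools, nrow, 0L))) {
    for (k in seq_len(n_branch)) {
      if (length(picked) >= needed) break
      if (taken[k] < nrow(pools[[k]])) {
        taken[k] <- taken[k] + 1L
        picked[[length(picked) + 1L]] <- pools[[k]][taken[k], , drop = FALSE]
      }
    }
  }
  if (length(picked) < needed)
    stop("not enough numt-clean branch candidates for a ", target_n,
         "-SNP mtDNA panel")
  sel <- rbind(do.call(rbind, picked), sub_sel)
  sel <- sel[order(sel$position), , drop = FALSE]
  rownames(sel) <- NULL

  key <- haplogroup_key(model, sel$id)
  for (i in seq_len(nrow(key) - 1L)) for (j in seq.int(i + 1L, nrow(key)))
    if (all(key[i, ] == key[j, ]))
      stop("selected mtDNA panel fails to separate haplogroups ",
           rownames(key)[i], " and ", rownames(key)[j])

  mt <- data.frame(id = sel$id, position = sel$position, branch = sel$branch,
                   ref = sel$ancestral, alt = sel$derived,
                   stringsAsFactors = FALSE)
  panel_definition(autosomal = NULL, mtdna = mt,
                   params = list(target_mtdna = target_n,
                                 min_identity = min_identity,
                                 min_length = min_length),
                   key = key)
}

#' Panel definition container
#'
#' @param autosomal data.frame of selected autosomal SNPs (or `NULL`).
#' @param mtdna data.frame of selected mtDNA SNPs (or `NULL`).
#' @param params list of design parameters (provenance snapshot).
#' @param key optional haplogroup key over the selected mtDNA SNPs.
#' @return an object of class `PanelDefinition`.
#' @export
panel_definition <- function(autosomal = NULL, mtdna = NULL,
                             params = list(), key = NULL) {
  if (!is.null(autosomal) && anyDuplicated(autosomal$scaffold))
    stop("autosomal panel must contain at most one SNP per scaffold")
  if (!is.null(autosomal) && !is.null(mtdna) &&
      length(intersect(autosomal$id, mtdna$id)) > 0L)
    stop("autosomal and mtDNA panels must be disjoint")
  structure(list(autosomal = autosomal, mtdna = mtdna, params = params,
                 key = key),
            class = "PanelDefinition")
}

#' Merge autosomal and mtDNA panel parts
#' @param autosomal_panel,mtdna_panel `PanelDefinition`s holding the
#'   respective parts.
#' @return a combined `PanelDefinition`.
#' @export
combine_panels <- function(autosomal_panel, mtdna_panel) {
  panel_definition(autosomal = autosomal_panel$autosomal,
                   mtdna = mtdna_panel$mtdna,
                   params = c(autosomal_panel$params, mtdna_panel$params),
                   key = mtdna_panel$key)
}

#' @export
print.PanelDefinition <- function(x, ...) {
  cat("PanelDefinition:",
      if (is.null(x$autosomal)) 0L else nrow(x$autosomal), "autosomal +",
      if (is.null(x$mtdna)) 0L else nrow(x$mtdna), "mtDNA SNPs\n")
  if (!is.null(x$autosomal)) {
    tab <- table(x$autosomal$chromosome)
    cat("  per-chromosome counts:",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Write / read a panel definition as CSV
#'
#' One row per panel SNP: id, type, scaffold, position, chromosome, ref,
#' alt, branch (mtDNA), score and provenance columns.
#'
#' @param panel a `PanelDefinition`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `PanelDefinition` (reader; the
#'   haplogroup key is not round-tripped).
#' @export
write_panel <- function(panel, path) {
  aut <- panel$autosomal; mt <- panel$mtdna
  rows <- list()
  if (!is.null(aut))
    rows$aut <- data.frame(id = aut$id, type = "autosomal",
                           scaffold = aut$scaffold, position = aut$position,
                           chromosome = aut$chromosome, ref = aut$ref,
                           alt = aut$alt, branch = NA_character_,
                           n_called = aut$n_called, score = aut$score)
  if (!is.null(mt))
    rows$mt <- data.frame(id = mt$id, type = "mitochondrial",
                          scaffold = "mitogenome", position = mt$position,
                          chromosome = "MT", ref = mt$ref, alt = mt$alt,
                          branch = mt$branch, n_called = NA_real_,
                          score = NA_real_)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  aut <- df[df$type == "autosomal", , drop = FALSE]
  mt <- df[df$type == "mitochondrial", , drop = FALSE]
  panel_definition(
    autosomal = if (nrow(aut)) aut[, c("id", "scaffold", "position",
                                       "chromosome", "ref", "alt",
                                       "n_called", "score")],
    mtdna = if (nrow(mt)) mt[, c("id", "position", "branch", "ref", "alt")])
}

#' Apply a panel to genotype data
#'
#' Extracts panel-SNP calls for every sample of a dataset (autosomal part)
#' and converts mtDNA haplotype calls to haploid panel codes, producing the
#' `PanelCalls` table a genotyping assay would deliver.
#'
#' @param panel a combined `PanelDefinition`.
#' @param dataset a `VariantDataset` containing the autosomal panel sites.
#' @param mt_calls optional character matrix of per-sample mtDNA alleles
#'   (columns = candidate site ids, as from [simulate_mtdna()]).
#' @return a `PanelCalls`.
#' @export
apply_panel <- function(panel, dataset, mt_calls = NULL) {
  stopifnot(inherits(panel, "PanelDefinition"), !is.null(panel$autosomal))
  aut <- panel$autosomal
  m <- match(aut$id, site_ids(dataset))
  if (anyNA(m)) stop("dataset lacks ", sum(is.na(m)), " panel site(s)")
  calls <- t(dataset$geno[m, , drop = FALSE])
  snps <- data.frame(id = aut$id, type = "autosomal", ref = aut$ref,
                     alt = aut$alt, stringsAsFactors = FALSE)
  if (!is.null(panel$mtdna) && !is.null(mt_calls)) {
    mt <- panel$mtdna
    if (!all(mt$id %in% colnames(mt_calls)))
      stop("mt_calls lacks some mtDNA panel sites")
    alle <- mt_calls[dataset$samples, mt$id, drop = FALSE]
    code <- matrix(NA_integer_, nrow(alle), ncol(alle))
    code[alle == rep(mt$ref, each = nrow(alle))] <- 0L
    code[alle == rep(mt$alt, each = nrow(alle))] <- 2L
    calls <- cbind(calls, code)
    snps <- rbind(snps, data.frame(id = mt$id, type = "mitochondrial",
                                   ref = mt$ref, alt = mt$alt))
  }
  panel_calls(dataset$samples, snps, calls)
}
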