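# Hierarchical Balding-Nichols simulator for structured lion-like cohorts:
# an ancestral allele frequency drifts into two subspecies (northern /
# southern), each subspecies into two clades, giving the four autosomal
# clusters (West & Central Africa and India in the north; East Africa and
# Southern Africa in the south). Individuals are binomial draws from
# admixture-weighted clade frequencies; sequencing is emulated by Poisson
# depth with allelic dropout. Mitochondrial haplotypes follow a six-
# haplogroup diagnostic key, with numt decoy sequences for assay screening.

CLADE_LEVELS <- c("West & Central Africa", "India", "East Africa",
                  "Southern Africa")
NORTHERN_CLADES <- c("West & Central Africa", "India")

HAPLOGROUPS <- c("West Africa", "Central Africa", "North East Africa",
                 "East/Southern Africa", "South West Africa", "India")
NORTHERN_HAPLOGROUPS <- c("West Africa", "Central Africa",
                          "North East Africa", "India")

# clade -> plausible mitochondrial haplogroups (used when a cohort sample
# sheet does not pin the haplogroup explicitly)
CLADE_HAPLOGROUP_MAP <- list(
  "West & Central Africa" = c("West Africa", "Central Africa"),
  "India" = "India",
  "East Africa" = c("North East Africa", "East/Southern Africa"),
  "Southern Africa" = c("East/Southern Africa", "South West Africa"))

# felid karyotype: 18 autosomes
FELID_CHROMOSOMES <- c("A1", "A2", "A3", "B1", "B2", "B3", "B4", "C1", "C2",
                       "D1", "D2", "D3", "D4", "E1", "E2", "E3", "F1", "F2")

#' Demography configuration for the synthetic cohort generator
#'
#' Defines the hierarchical drift model (ancestral -> subspecies -> clade),
#' the sample roster with admixture proportions and mean sequencing depths,
#' and nuisance parameters for flank simulation.
#'
#' @param samples data.frame with columns `id`, `region` (one of the four
#'   clade labels, or `"Outgroup"`), `lambda` (mean read depth, > 0) and
#'   optionally `population` and `haplogroup`.
#' @param n_sites number of autosomal SNP sites to simulate.
#' @param q admixture matrix (`n_samples x 4`, columns in clade-label
#'   order, rows summing to 1). Defaults to one-hot vectors from `region`;
#'   outgroup rows are ignored.
#' @param ancestral_maf_range interval within (0, 0.5]; ancestral minor
#'   allele frequencies are uniform on it, with random allele orientation.
#' @param F_subspecies drift coefficient of the basal northern/southern
#'   split, in \[0, 1).
#' @param F_clade named numeric of per-clade drift coefficients; the India
#'   clade defaults to a high value emulating its bottleneck.
#' @param F_outgroup drift of the outgroup lineage from the ancestral
#'   frequency (tiger analogue).
#' @param n_scaffolds number of scaffolds sites are spread over (scaffolds
#'   map round-robin onto the 18 felid autosomes).
#' @param flank_variant_rate Poisson mean of extra variable positions per
#'   50-bp flank.
#' @param seed integer seed making every generator call reproducible.
#' @return a `DemographyConfig` list.
#' @export
demography_config <- function(samples, n_sites = 5000L, q = NULL,
                              ancestral_maf_range = c(0.1, 0.5),
                              F_subspecies = 0.15,
                              F_clade = c("West & Central Africa" = 0.05,
                                          "India" = 0.30,
                                          "East Africa" = 0.05,
                                          "Southern Africa" = 0.05),
                              F_outgroup = 0.5,
                              n_scaffolds = 400L,
                              flank_variant_rate = 0.5,
                              seed = 1L) {
  stopifnot(is.data.frame(samples), all(c("id", "region", "lambda") %in% names(samples)))
  if (anyDuplicated(samples$id)) stop("duplicate sample ids")
  ok_region <- c(CLADE_LEVELS, "Outgroup")
  if (!all(samples$region %in% ok_region))
    stop("sample regions must be in: ", paste(ok_region, collapse = ", "))
  if (any(samples$lambda <= 0)) stop("mean depths lambda must be > 0")
  if (!"population" %in% names(samples)) samples$population <- samples$id
  if (!"haplogroup" %in% names(samples)) samples$haplogroup <- NA_character_

  if (length(F_clade) != 4L) stop("F_clade must have 4 values")
  if (is.null(names(F_clade))) names(F_clade) <- CLADE_LEVELS
  F_clade <- F_clade[CLADE_LEVELS]
  all_F <- c(F_subspecies, F_clade, F_outgroup)
  if (any(all_F < 0) || any(all_F >= 1))
    stop("drift coefficients must lie in [0, 1)")
  if (length(ancestral_maf_range) != 2L ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      diff(ancestral_maf_range) < 0)
    stop("ancestral_maf_range must be an interval within (0, 0.5]")

  n <- nrow(samples)
  if (is.null(q)) {
    q <- matrix(0, n, 4L, dimnames = list(samples$id, CLADE_LEVELS))
    lion <- samples$region != "Outgroup"
    q[cbind(which(lion), match(samples$region[lion], CLADE_LEVELS))] <- 1
  } else {
    q <- as.matrix(q)
    if (!all(dim(q) == c(n, 4L))) stop("q must be n_samples x 4")
    colnames(q) <- CLADE_LEVELS; rownames(q) <- samples$id
  }
  lion <- samples$region != "Outgroup"
  if (any(abs(rowSums(q[lion, , drop = FALSE]) - 1) > 1e-9))
    stop("admixture proportions must sum to 1 for every lion sample")

  structure(list(samples = samples, q = q, n_sites = as.integer(n_sites),
                 ancestral_maf_range = ancestral_maf_range,
                 F_subspecies = F_subspecies, F_clade = F_clade,
                 F_outgroup = F_outgroup, n_scaffolds = as.integer(n_scaffolds),
                 flank_variant_rate = flank_variant_rate,
                 seed = as.integer(seed)),
            class = "DemographyConfig")
}

#' Default 10-sample discovery preset
#'
#' Ten low-coverage diploid genomes spanning the four clades (three
#' West & Central Africa, one India, two East Africa, four Southern Africa),
#' mean depth 3.8x, with one very-low-coverage individual (Benin analogue,
#' 0.5x) and the inbred low-diversity India clade. Optionally appends a
#' deeply diverged outgroup pseudo-sample (tiger analogue) for ABBA-BABA
#' work.
#'
#' @param n_sites,n_scaffolds,seed see [demography_config()].
#' @param include_outgroup append the outgroup sample?
#' @return a `DemographyConfig`.
#' @export
discovery_config <- function(n_sites = 5000L, n_scaffolds = 400L, seed = 1L,
                             include_outgroup = TRUE) {
  samples <- data.frame(
    id = c("Benin", "Cameroon", "DRC", "India", "Somalia", "Kenya",
           "Zambia1", "Zambia2", "RSA", "Namibia"),
    region = c(rep("West & Central Africa", 3L), "India",
               rep("East Africa", 2L), rep("Southern Africa", 4L)),
    lambda = c(0.5, 4.2, 3.0, 4.5, 3.6, 7.4, 4.0, 3.2, 2.6, 5.0),
    haplogroup = c("West Africa", "Central Africa", "Central Africa", "India",
                   "North East Africa", "East/Southern Africa",
                   "East/Southern Africa", "East/Southern Africa",
                   "South West Africa", "South West Africa"),
    stringsAsFactors = FALSE)
  if (include_outgroup)
    samples <- rbind(samples, data.frame(id = "Tiger", region = "Outgroup",
                                         lambda = 8.0, haplogroup = NA))
  samples$population <- samples$id
  demography_config(samples, n_sites = n_sites, n_scaffolds = n_scaffolds,
                    seed = seed)
}

.set_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

# Balding-Nichols draw around p with drift F; F = 0 is the no-drift limit.
.rbn <- function(p, F) {
  if (F < 0 || F >= 1) stop("drift coefficient F must lie in [0, 1)")
  if (F == 0) return(p)
  k <- (1 - F) / F
  pmin(pmax(stats::rbeta(length(p), p * k, (1 - p) * k), 1e-9), 1 - 1e-9)
}

#' Simulate hierarchical allele frequencies
#'
#' Ancestral frequencies are uniform on the configured minor-allele range
#' (random orientation); subspecies frequencies are Balding-Nichols draws
#' around the ancestral value with drift `F_subspecies`, and clade
#' frequencies are drawn the same way around their subspecies frequency with
#' the per-clade drift.
#'
#' @param config a `DemographyConfig`.
#' @param seed seed (default: the config's); `NULL` leaves the RNG state
#'   untouched so callers can compose draws.
#' @return list with `ancestral` (vector), `subspecies` (matrix, columns
#'   `northern`/`southern`), `clade` (matrix, one column per clade) and
#'   `outgroup` (vector).
#' @export
simulate_allele_frequencies <- function(config, seed = config$seed) {
  .set_seed(seed)
  n <- config$n_sites
  maf <- stats::runif(n, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  flip <- stats::runif(n) < 0.5
  ancestral <- ifelse(flip, 1 - maf, maf)
  subspecies <- cbind(northern = .rbn(ancestral, config$F_subspecies),
                      southern = .rbn(ancestral, config$F_subspecies))
  clade <- sapply(CLADE_LEVELS, function(cl) {
    ss <- if (cl %in% NORTHERN_CLADES) "northern" else "southern"
    .rbn(subspecies[, ss], config$F_clade[[cl]])
  })
  outgroup <- .rbn(ancestral, config$F_outgroup)
  list(ancestral = ancestral, subspecies = subspecies, clade = clade,
       outgroup = outgroup)
}

# random site table spread over scaffolds; <=1 site per position
.simulate_sites <- function(config) {
  n <- config$n_sites
  scaffolds <- sprintf("scaffold_%03d", seq_len(config$n_scaffolds))
  scaf <- sort(sample(rep_len(seq_len(config$n_scaffolds), n)))
  counts <- tabulate(scaf, nbins = config$n_scaffolds)
  pos <- unlist(lapply(counts[counts > 0L], function(k)
    sort(sample.int(1e6L, k))), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, n, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
  data.frame(scaffold = scaffolds[scaf], position = pos, ref = bases[ref_i],
             alt = bases[alt_i], stringsAsFactors = FALSE)
}

#' Scaffold-to-chromosome map of a configuration
#'
#' Scaffolds map round-robin onto the 18 felid autosomes, mimicking
#' attribution of scaffolds to chromosomes via a related reference
#' karyotype.
#'
#' @param config a `DemographyConfig`.
#' @return data.frame with columns `scaffold`, `chromosome`.
#' @export
scaffold_chromosome_map <- function(config) {
  scaffolds <- sprintf("scaffold_%03d", seq_len(config$n_scaffolds))
  data.frame(scaffold = scaffolds,
             chromosome = rep_len(FELID_CHROMOSOMES, length(scaffolds)),
             stringsAsFactors = FALSE)
}

#' Simulate truth genotypes
#'
#' Each individual's alt dose at a site is Binomial(2, f) with
#' f = sum_c q_c p_c, the admixture-weighted clade frequency (the outgroup
#' uses its own lineage frequency).
#'
#' @param freqs output of [simulate_allele_frequencies()].
#' @param config a `DemographyConfig`.
#' @param seed seed; `NULL` to compose with an outer seed.
#' @param sites optional site table (defaults to a fresh random layout).
#' @return a `VariantDataset` of truth genotypes (uniform nominal depth).
#' @export
simulate_genotypes <- function(freqs, config, seed = NULL, sites = NULL) {
  .set_seed(seed)
  if (is.null(sites)) sites <- .simulate_sites(config)
  n <- config$n_sites
  f <- freqs$clade %*% t(config$q)   # n_sites x n_samples
  out <- config$samples$region == "Outgroup"
  if (any(out)) f[, out] <- freqs$outgroup
  geno <- matrix(stats::rbinom(length(f), 2L, f), n, ncol(f))
  storage.mode(geno) <- "integer"
  .variant_dataset_fast(sites, config$samples$id, geno,
                        depth = matrix(100L, n, ncol(f)))
}

#' Overlay Poisson coverage and allelic dropout on truth genotypes
#'
#' Per-cell depth is Poisson with the sample's mean depth. Depth 0 yields a
#' missing call. A heterozygous truth genotype with depth d is observed
#' heterozygous only if both alleles appear among d uniformly drawn reads
#' (probability `1 - 2^(1-d)`); otherwise it is called homozygous for the
#' sampled allele. Homozygous truth is observed as-is whenever d >= 1.
#'
#' @param truth truth `VariantDataset` from [simulate_genotypes()].
#' @param config a `DemographyConfig`.
#' @param seed seed; `NULL` to compose.
#' @return an observed `VariantDataset` carrying the simulated depths.
#' @export
simulate_coverage_and_calls <- function(truth, config, seed = NULL) {
  .set_seed(seed)
  lambda <- config$samples$lambda[match(truth$samples, config$samples$id)]
  n <- n_sites(truth); m <- n_samples(truth)
  depth <- matrix(stats::rpois(n * m, rep(lambda, each = n)), n, m)
  geno <- truth$geno
  obs <- geno
  obs[depth == 0L] <- NA_integer_
  het <- which(!is.na(geno) & geno == 1L & depth >= 1L)
  if (length(het)) {
    d <- depth[het]
    keep <- stats::runif(length(het)) < (1 - 2^(1 - d))
    calls <- 2L * (stats::runif(length(het)) < 0.5)
    calls[keep] <- 1L
    obs[het] <- calls
  }
  .variant_dataset_fast(truth$sites, truth$samples, obs, depth)
}

#' Simulate flanking sequences and flank variants
#'
#' Each site receives a random 101-nt flank with the focal SNP's reference
#' base at position 51 (50 bp upstream + focal + 50 bp downstream). Extra
#' variable positions are injected per 50-bp flank as Poisson draws with the
#' configured rate; their positions are recorded as truth.
#'
#' @param dataset a `VariantDataset` (its sites get flanks).
#' @param config a `DemographyConfig`.
#' @param rate Poisson mean of variable positions per flank.
#' @param seed seed; `NULL` to compose.
#' @return list with `flanks` (named character, 101 nt each) and `variants`
#'   (data.frame `site_id`, `flank_pos` in 1..101, focal position excluded).
#' @export
simulate_flanks <- function(dataset, config, rate = config$flank_variant_rate,
                            seed = NULL) {
  .set_seed(seed)
  n <- n_sites(dataset)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(sample(bases, n * 101L, replace = TRUE), n, 101L)
  mat[, 51L] <- dataset$sites$ref
  flanks <- apply(mat, 1L, paste, collapse = "")
  names(flanks) <- site_ids(dataset)

  k_up <- stats::rpois(n, rate)
  k_dn <- stats::rpois(n, rate)
  pick <- function(k, range) if (k == 0L) integer() else sample(range, min(k, length(range)))
  pos_list <- lapply(seq_len(n), function(i)
    c(pick(k_up[i], 1:50), pick(k_dn[i], 52:101)))
  variants <- data.frame(
    site_id = rep(site_ids(dataset), lengths(pos_list)),
    flank_pos = unlist(pos_list),
    stringsAsFactors = FALSE)
  list(flanks = flanks, variants = variants)
}

#' Simulate combined-depth profiles over the 101-nt windows
#'
#' Position 51 carries the realized summed depth across lion samples from
#' the observed dataset; the other 100 window positions are Poisson draws at
#' the summed lion mean depth.
#'
#' @param dataset observed `VariantDataset` (with depths).
#' @param config a `DemographyConfig`.
#' @param seed seed; `NULL` to compose.
#' @return integer matrix `n_sites x 101`, rownames = site ids.
#' @export
simulate_window_depth <- function(dataset, config, seed = NULL) {
  .set_seed(seed)
  lions <- config$samples$id[config$samples$region != "Outgroup"]
  lions <- intersect(dataset$samples, lions)
  lambda_tot <- sum(config$samples$lambda[match(lions, config$samples$id)])
  n <- n_sites(dataset)
  prof <- matrix(stats::rpois(n * 101L, lambda_tot), n, 101L)
  prof[, 51L] <- as.integer(rowSums(dataset$depth[, lions, drop = FALSE]))
  rownames(prof) <- site_ids(dataset)
  prof
}

#' Mitochondrial haplogroup model
#'
#' A synthetic mitogenome with candidate diagnostic sites: for each of the
#' six haplogroups a set of private sites (derived allele carried by that
#' haplogroup only) plus subspecies-diagnostic candidates whose derived
#' allele separates the northern haplogroups (West Africa, Central Africa,
#' North East Africa, India) from the southern ones (East/Southern Africa,
#' South West Africa). Numt specs control the decoy sequences emitted by
#' [simulate_mtdna()].
#'
#' @param seed seed for the model's own randomness.
#' @param genome_length mitogenome length in bp.
#' @param n_private candidate private sites per haplogroup.
#' @param n_subspecies candidate subspecies-diagnostic sites.
#' @param numt_count,numt_length,numt_divergence numt specs: number of
#'   nuclear copies, segment length, per-base divergence from the
#'   mitochondrial source segment.
#' @return an `MtDNAModel` list.
#' @export
mtdna_model <- function(seed = 1L, genome_length = 16756L, n_private = 3L,
                        n_subspecies = 4L, numt_count = 3L,
                        numt_length = 1000L, numt_divergence = 0.08) {
  .set_seed(seed)
  bases <- c("A", "C", "G", "T")
  genome <- paste(sample(bases, genome_length, replace = TRUE), collapse = "")
  n_cand <- 6L * n_private + n_subspecies
  # keep candidates away from the genome edges so 101-nt flanks exist
  pos <- sort(sample(60:(genome_length - 60L), n_cand))
  anc <- strsplit(genome, "")[[1]][pos]
  der <- vapply(anc, function(b) sample(setdiff(bases, b), 1L), "")
  branch <- sample(c(rep(HAPLOGROUPS, each = n_private),
                     rep("subspecies", n_subspecies)))
  sites <- data.frame(id = paste0("mt_", pos), position = pos, branch = branch,
                      ancestral = anc, derived = der, stringsAsFactors = FALSE)
  structure(list(genome = genome, sites = sites, haplogroups = HAPLOGROUPS,
                 northern = NORTHERN_HAPLOGROUPS,
                 numt = list(count = as.integer(numt_count),
                             length = as.integer(numt_length),
                             divergence = numt_divergence)),
            class = "MtDNAModel")
}

#' Haplogroup key implied by an mtDNA model
#'
#' @param model an `MtDNAModel`.
#' @param site_ids candidate site ids to include (default: all).
#' @return character matrix, rows = haplogroups, columns = sites; entries
#'   are the expected allele of that haplogroup at that site.
#' @export
haplogroup_key <- function(model, site_ids = model$sites$id) {
  sites <- model$sites[match(site_ids, model$sites$id), , drop = FALSE]
  if (anyNA(sites$id)) stop("unknown mtDNA site id(s)")
  key <- matrix(rep(sites$ancestral, each = 6L), 6L, nrow(sites),
                dimnames = list(model$haplogroups, sites$id))
  for (j in seq_len(nrow(sites))) {
    carriers <- if (sites$branch[j] == "subspecies") model$northern else sites$branch[j]
    key[carriers, j] <- sites$derived[j]
  }
  key
}

#' Simulate per-sample mtDNA haplotypes and numt decoys
#'
#' Haplotype calls follow the haplogroup key exactly (before missingness).
#' Numts are segments of the model mitogenome mutated at the configured
#' divergence, emitted as decoy records.
#'
#' @param model an `MtDNAModel`.
#' @param samples data.frame with `id` and `haplogroup` columns (every
#'   non-outgroup sample must have a haplogroup).
#' @param failure_rate per-call probability of a missing call.
#' @param seed seed; `NULL` to compose.
#' @return list with `calls` (character matrix samples x sites, NA =
#'   missing), `numts` (named character vector) and `numt_source`
#'   (data.frame of segment coordinates).
#' @export
simulate_mtdna <- function(model, samples, failure_rate = 0, seed = NULL) {
  .set_seed(seed)
  stopifnot(all(c("id", "haplogroup") %in% names(samples)))
  lion <- if ("region" %in% names(samples)) samples$region != "Outgroup"
          else rep(TRUE, nrow(samples))
  hap <- samples$haplogroup
  if (any(lion & (is.na(hap) | !(hap %in% model$haplogroups))))
    stop("clade->haplogroup map incomplete: every lion sample needs a ",
         "haplogroup from: ", paste(model$haplogroups, collapse = ", "))
  key <- haplogroup_key(model)
  calls <- matrix(NA_character_, nrow(samples), ncol(key),
                  dimnames = list(samples$id, colnames(key)))
  calls[lion, ] <- key[hap[lion], , drop = FALSE]
  if (failure_rate > 0) {
    drop <- matrix(stats::runif(length(calls)) < failure_rate,
                   nrow(calls), ncol(calls))
    calls[drop] <- NA_character_
  }

  glen <- nchar(model$genome)
  nm <- model$numt
  starts <- sample.int(glen - nm$length, nm$count)
  bases <- c("A", "C", "G", "T")
  numts <- character(nm$count)
  for (i in seq_len(nm$count)) {
    seg <- strsplit(substr(model$genome, starts[i], starts[i] + nm$length - 1L), "")[[1]]
    mut <- stats::runif(nm$length) < nm$divergence
    seg[mut] <- vapply(seg[mut], function(b) sample(setdiff(bases, b), 1L), "")
    numts[i] <- paste(seg, collapse = "")
  }
  names(numts) <- paste0("numt_", seq_len(nm$count))
  list(calls = calls, numts = numts,
       numt_source = data.frame(name = names(numts), start = starts,
                                end = starts + nm$length - 1L,
                                divergence = nm$divergence))
}

#' Inject gene flow into truth genotypes
#'
#' For a fraction of sites, the recipient samples' genotypes are redrawn
#' from a migrant-mixed frequency `(1 - m) * f_own + m * p_donor`, emulating
#' introgression from the donor clade.
#'
#' @param truth truth `VariantDataset`.
#' @param freqs frequencies used to simulate `truth`.
#' @param config the `DemographyConfig`.
#' @param donor_clade clade label supplying migrants.
#' @param recipients sample ids receiving gene flow.
#' @param migrant_fraction migrant ancestry fraction m at affected sites.
#' @param site_fraction fraction of sites affected.
#' @param seed seed; `NULL` to compose.
#' @return modified truth `VariantDataset`.
#' @export
simulate_geneflow <- function(truth, freqs, config, donor_clade,
                              recipients, migrant_fraction = 0.3,
                              site_fraction = 0.2, seed = NULL) {
  .set_seed(seed)
  stopifnot(donor_clade %in% CLADE_LEVELS, all(recipients %in% truth$samples))
  n <- n_sites(truth)
  idx <- sort(sample.int(n, floor(site_fraction * n)))
  p_donor <- freqs$clade[idx, donor_clade]
  geno <- truth$geno
  for (id in recipients) {
    f_own <- drop(freqs$clade[idx, , drop = FALSE] %*% config$q[id, ])
    f_mix <- (1 - migrant_fraction) * f_own + migrant_fraction * p_donor
    geno[idx, id] <- stats::rbinom(length(idx), 2L, f_mix)
  }
  .variant_dataset_fast(truth$sites, truth$samples, geno, truth$depth)
}

#' Generate a complete synthetic discovery bundle
#'
#' Runs the whole generator under one seed and (optionally) writes an
#' on-disk bundle consumable by every downstream stage: VCF of observed
#' calls with depths, sample sheet, scaffold map, flank FASTA, flank-variant
#' truth, window depth profiles, numt FASTA, mtDNA calls and truth tables.
#' Identical seeds give byte-identical files.
#'
#' @param config a `DemographyConfig` (e.g. [discovery_config()]).
#' @param mt_model an `MtDNAModel`.
#' @param out_dir output directory, or `NULL` for an in-memory bundle only.
#' @param force overwrite a non-empty `out_dir`?
#' @param mt_failure_rate missing-call rate for the mtDNA haplotype calls.
#' @return (invisibly, when writing) a list with all simulated components.
#' @export
generate_dataset <- function(config, mt_model = mtdna_model(seed = config$seed),
                             out_dir = NULL, force = FALSE,
                             mt_failure_rate = 0.02) {
  set.seed(config$seed)
  freqs <- simulate_allele_frequencies(config, seed = NULL)
  truth <- simulate_genotypes(freqs, config, seed = NULL)
  observed <- simulate_coverage_and_calls(truth, config, seed = NULL)
  fl <- simulate_flanks(observed, config, seed = NULL)
  wdepth <- simulate_window_depth(observed, config, seed = NULL)
  mt <- simulate_mtdna(mt_model, config$samples, failure_rate = mt_failure_rate,
                       seed = NULL)
  smap <- scaffold_chromosome_map(config)
  sheet <- data.frame(sample = config$samples$id,
                      population = config$samples$population,
                      region = config$samples$region,
                      lat = NA_real_, lon = NA_real_)
  bundle <- list(config = config, mt_model = mt_model, freqs = freqs,
                 truth = truth, observed = observed, flanks = fl$flanks,
                 flank_variants = fl$variants, window_depth = wdepth,
                 mtdna = mt, scaffold_map = smap, sheet = sheet)
  if (is.null(out_dir)) return(bundle)

  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  snapshot <- sprintf("##lionpanel_param=%s", .config_snapshot(config))
  write_vcf(observed, p("discovery.vcf"), header_extra = snapshot)
  write_sample_sheet(sheet, p("sample_sheet.csv"))
  utils::write.csv(smap, p("scaffold_map.csv"), row.names = FALSE)
  write_fasta(fl$flanks, p("flanks.fa"))
  utils::write.csv(fl$variants, p("flank_variants.csv"), row.names = FALSE)
  utils::write.csv(data.frame(site_id = rownames(wdepth), wdepth,
                              check.names = FALSE),
                   p("window_depth.csv"), row.names = FALSE)
  write_fasta(mt$numts, p("numts.fa"))
  write_fasta(c(mitogenome = mt_model$genome), p("mitogenome.fa"))
  utils::write.csv(mt_model$sites, p("mt_candidate_sites.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample = rownames(mt$calls), mt$calls,
                              check.names = FALSE),
                   p("mtdna_calls.csv"), row.names = FALSE)
  utils::write.csv(data.frame(site_id = site_ids(truth), truth$geno,
                              check.names = FALSE),
                   p("truth_genotypes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(site_id = site_ids(truth),
                              ancestral = freqs$ancestral, freqs$clade,
                              outgroup = freqs$outgroup, check.names = FALSE),
                   p("truth_frequencies.csv"), row.names = FALSE)
  invisible(bundle)
}

.config_snapshot <- function(config) {
  paste0("n_sites=", config$n_sites,
         ";F_subspecies=", config$F_subspecies,
         ";F_clade=", paste(config$F_clade, collapse = "/"),
         ";seed=", config$seed)
}

#' Cohort preset: panel-genotyped samples across the lion range
#'
#' Simulates a large cohort genotyped at a diagnostic panel (by default 125
#' autosomal SNPs plus the 14-SNP mtDNA panel of a default [mtdna_model()]):
#' 211 samples across the four clades including admixed individuals
#' (ancestry split between East Africa and West & Central Africa, the
#' Ethiopia/Kenya contact-zone analogue) and a block of poor-quality samples
#' whose assay failure rate pushes them past the 25% missingness QC cutoff.
#'
#' @param n_samples total cohort size.
#' @param n_admixed number of admixed contact-zone samples.
#' @param n_highmiss number of poor-quality samples.
#' @param n_panel_autosomal autosomal panel size.
#' @param assay_failure,assay_failure_high per-call failure rates of normal
#'   and poor-quality samples (autosomal).
#' @param assay_failure_mt,assay_failure_mt_high same for mtDNA calls.
#' @param admixed_q ancestry fraction from West & Central Africa for admixed
#'   samples (remainder East Africa).
#' @param F_subspecies,F_clade drift coefficients, see [demography_config()].
#' @param seed seed.
#' @return list with `calls` (a `PanelCalls`), `sheet` (sample sheet
#'   data.frame), `truth` (per-sample true clade, admixture flag and
#'   haplogroup, plus panel frequencies) and `panel` (SNP metadata).
#' @export
simulate_cohort <- function(n_samples = 211L, n_admixed = 10L,
                            n_highmiss = 40L, n_panel_autosomal = 125L,
                            assay_failure = 0.08, assay_failure_high = 0.35,
                            assay_failure_mt = 0.02,
                            assay_failure_mt_high = 0.30,
                            admixed_q = 0.5,
                            F_subspecies = 0.15,
                            F_clade = c("West & Central Africa" = 0.05,
                                        "India" = 0.30,
                                        "East Africa" = 0.05,
                                        "Southern Africa" = 0.05),
                            seed = 1L) {
  set.seed(as.integer(seed))
  n_pure <- n_samples - n_admixed
  clade_counts <- c(round(0.25 * n_pure), round(0.10 * n_pure),
                    round(0.27 * n_pure), 0L)
  clade_counts[4L] <- n_pure - sum(clade_counts[1:3])
  clades <- rep(CLADE_LEVELS, clade_counts)
  ids <- sprintf("L%03d", seq_len(n_samples))
  region <- c(clades, rep("East Africa", n_admixed))
  population <- region
  population[seq.int(n_pure + 1L, length.out = n_admixed)] <- "Ethiopia (contact zone)"

  q <- matrix(0, n_samples, 4L, dimnames = list(ids, CLADE_LEVELS))
  q[cbind(seq_len(n_pure), match(clades, CLADE_LEVELS))] <- 1
  if (n_admixed > 0L) {
    adm <- seq.int(n_pure + 1L, length.out = n_admixed)
    q[adm, "West & Central Africa"] <- admixed_q
    q[adm, "East Africa"] <- 1 - admixed_q
  }
  hap <- vapply(region, function(cl) {
    opts <- CLADE_HAPLOGROUP_MAP[[cl]]
    opts[sample.int(length(opts), 1L)]
  }, "")

  samples <- data.frame(id = ids, region = region, population = population,
                        lambda = 30, haplogroup = hap, stringsAsFactors = FALSE)
  config <- demography_config(samples, n_sites = as.integer(n_panel_autosomal),
                              q = q, F_subspecies = F_subspecies,
                              F_clade = F_clade,
                              n_scaffolds = as.integer(n_panel_autosomal),
                              seed = seed)
  freqs <- simulate_allele_frequencies(config, seed = NULL)
  truth <- simulate_genotypes(freqs, config, seed = NULL)

  mt_model <- mtdna_model(seed = NULL)
  mt_key_full <- haplogroup_key(mt_model)
  mt_sites <- .default_mt_panel_sites(mt_model)
  mt_key <- mt_key_full[, mt_sites$id, drop = FALSE]
  mt_alleles <- mt_key[hap, , drop = FALSE]
  mt_code <- matrix(ifelse(mt_alleles == rep(mt_sites$derived,
                                             each = n_samples), 2L, 0L),
                    n_samples, nrow(mt_sites))

  highmiss <- sample.int(n_samples, n_highmiss)
  fail_aut <- rep(assay_failure, n_samples); fail_aut[highmiss] <- assay_failure_high
  fail_mt <- rep(assay_failure_mt, n_samples); fail_mt[highmiss] <- assay_failure_mt_high

  aut_calls <- t(truth$geno)  # samples x snps
  drop_aut <- matrix(stats::runif(length(aut_calls)) <
                       rep(fail_aut, times = ncol(aut_calls)),
                     nrow(aut_calls), ncol(aut_calls))
  aut_calls[drop_aut] <- NA_integer_
  drop_mt <- matrix(stats::runif(length(mt_code)) <
                      rep(fail_mt, times = ncol(mt_code)),
                    nrow(mt_code), ncol(mt_code))
  mt_code[drop_mt] <- NA_integer_

  snps <- rbind(
    data.frame(id = site_ids(truth), type = "autosomal",
               ref = truth$sites$ref, alt = truth$sites$alt,
               stringsAsFactors = FALSE),
    data.frame(id = mt_sites$id, type = "mitochondrial",
               ref = mt_sites$ancestral, alt = mt_sites$derived,
               stringsAsFactors = FALSE))
  calls <- panel_calls(ids, snps, cbind(aut_calls, mt_code))
  sheet <- data.frame(sample = ids, population = population, region = region,
                      lat = NA_real_, lon = NA_real_)
  list(calls = calls, sheet = sheet,
       truth = list(clade = stats::setNames(region, ids),
                    admixed = stats::setNames(q[, 1] > 0 & q[, 3] > 0, ids),
                    haplogroup = stats::setNames(hap, ids),
                    q = q, freqs = freqs, highmiss = ids[highmiss]),
       panel = snps, mt_key = mt_key, config = config)
}

#' Simulate a four-taxon ABBA-BABA study
#'
#' Builds a gene-flow experiment for the D-statistic under the same drift
#' hierarchy as the discovery preset: `n_per_clade` diploid genomes from
#' each of the Southern Africa (P1), East Africa (P2) and West & Central
#' Africa (P3) clades plus one diverged outgroup genome, with Poisson
#' coverage. Under `geneflow = TRUE`, the configured migrant fraction from
#' the P3 clade is applied to every P2 sample at the configured fraction of
#' sites. Group sizes matter: single genomes per group (as in a small
#' discovery cohort) carry so much genotype-sampling noise that this effect
#' needs hundreds of thousands of sites, while a multi-genome design
#' detects it at this scale.
#'
#' The defaults (40,000 sites, 20 genomes per clade) were fixed by a power
#' analysis targeting high detection probability for the default gene-flow
#' intensity at bootstrap significance |Z| >= 3.
#'
#' @param n_sites number of unlinked sites.
#' @param n_per_clade diploid genomes per ingroup clade.
#' @param geneflow inject P3 -> P2 gene flow?
#' @param migrant_fraction,site_fraction gene-flow intensity (defaults:
#'   migrant ancestry 0.3 at 20% of sites).
#' @param lambda mean sequencing depth of every sample.
#' @param seed seed.
#' @return list with `observed` (a `VariantDataset`), `groups` (P1/P2/P3/
#'   outgroup id lists), `truth` and `freqs`.
#' @export
simulate_dstat_study <- function(n_sites = 40000L, n_per_clade = 20L,
                                 geneflow = FALSE, migrant_fraction = 0.3,
                                 site_fraction = 0.2, lambda = 3.8,
                                 seed = 1L) {
  mk <- function(prefix, region, n)
    data.frame(id = sprintf("%s%02d", prefix, seq_len(n)), region = region,
               lambda = lambda, haplogroup = NA, stringsAsFactors = FALSE)
  samples <- rbind(mk("SA", "Southern Africa", n_per_clade),
                   mk("EA", "East Africa", n_per_clade),
                   mk("WC", "West & Central Africa", n_per_clade),
                   data.frame(id = "Outgroup", region = "Outgroup",
                              lambda = 2 * lambda, haplogroup = NA))
  samples$haplogroup <- NA_character_
  config <- demography_config(samples, n_sites = as.integer(n_sites),
                              seed = seed)
  set.seed(as.integer(seed))
  freqs <- simulate_allele_frequencies(config, seed = NULL)
  truth <- simulate_genotypes(freqs, config, seed = NULL)
  if (geneflow)
    truth <- simulate_geneflow(truth, freqs, config, "West & Central Africa",
                               samples$id[samples$region == "East Africa"],
                               migrant_fraction, site_fraction)
  observed <- simulate_coverage_and_calls(truth, config, seed = NULL)
  list(observed = observed,
       groups = list(P1 = samples$id[samples$region == "Southern Africa"],
                     P2 = samples$id[samples$region == "East Africa"],
                     P3 = samples$id[samples$region == "West & Central Africa"],
                     outgroup = "Outgroup"),
       truth = truth, freqs = freqs)
}

# default 14-site mtDNA panel from a model, skipping numt screening:
# two private sites per haplogroup plus two subspecies-diagnostic sites
.default_mt_panel_sites <- function(model) {
  sites <- model$sites
  take <- unlist(lapply(model$haplogroups, function(h)
    which(sites$branch == h)[1:2]))
  take <- c(take, which(sites$branch == "subspecies")[1:2])
  sites[take, , drop = FALSE]
}
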