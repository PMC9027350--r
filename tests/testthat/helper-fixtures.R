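# Shared fixture builders. Everything is generated in code at test time.

# random VariantDataset with controllable missingness, independent of the
# package's simulator (used for IO round-trips and filter oracles)
random_dataset <- function(n_sites, n_samples, miss = 0.15, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  sites <- data.frame(
    scaffold = paste0("scf", sample.int(max(2L, n_sites %/% 3L), n_sites,
                                        replace = TRUE)),
    position = seq_len(n_sites) * 10L + sample.int(9L, n_sites, replace = TRUE),
    ref = ref, alt = alt)
  geno <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
                 n_sites, n_samples)
  geno[matrix(runif(length(geno)) < miss, n_sites, n_samples)] <- NA_integer_
  depth <- matrix(rpois(n_sites * n_samples, 5), n_sites, n_samples)
  variant_dataset(sites, sprintf("s%02d", seq_len(n_samples)), geno, depth)
}

# small literal VCF fixture: 3 biallelic records + 1 tri-allelic, 2 samples
write_vcf_fixture <- function(path, extra_record = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampleA\tsampleB",
    "scf1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/0:7\t0/1:4",
    "scf1\t250\t.\tC\tT\t.\tPASS\t.\tGT:DP\t./.:0\t1/1:9",
    "scf2\t42\t.\tG\tA\t.\tPASS\t.\tGT:DP\t0/1:3\t0/0:2",
    extra_record)
  writeLines(lines, path)
  path
}

triallelic_record <- "scf2\t90\t.\tT\tA,C\t.\tPASS\t.\tGT:DP\t0/1:5\t0/2:6"

# random PanelCalls table
random_panel_calls <- function(n_samples, n_aut, n_mt, miss = 0.1, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_snp <- n_aut + n_mt
  ref <- sample(bases, n_snp, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  snps <- data.frame(id = sprintf("p%03d", seq_len(n_snp)),
                     type = rep(c("autosomal", "mitochondrial"), c(n_aut, n_mt)),
                     ref = ref, alt = alt)
  calls <- cbind(
    matrix(sample(0:2, n_samples * n_aut, replace = TRUE), n_samples, n_aut),
    matrix(sample(c(0L, 2L), n_samples * n_mt, replace = TRUE), n_samples, n_mt))
  calls[matrix(runif(length(calls)) < miss, n_samples, n_snp)] <- NA_integer_
  panel_calls(sprintf("ind%03d", seq_len(n_samples)), snps, calls)
}

# four-sample demography mirroring the D-statistic groups of the discovery
# preset (P1 southern, P2 east, P3 west/central, diverged outgroup)
dstat_config <- function(n_sites, seed) {
  samples <- data.frame(
    id = c("Zambia1", "Somalia", "Cameroon", "Tiger"),
    region = c("Southern Africa", "East Africa", "West & Central Africa",
               "Outgroup"),
    lambda = c(4.0, 3.6, 4.2, 8.0),
    haplogroup = c("East/Southern Africa", "North East Africa",
                   "Central Africa", NA))
  demography_config(samples, n_sites = as.integer(n_sites), seed = seed)
}
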