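# Pipeline stage runners wiring the modules into the two workflows
# (discovery -> panel design; cohort genotyping -> assignment/stats), with a
# serializable run configuration whose defaults are the study thresholds,
# and machine-readable run reports. A thin command-line dispatcher over
# these functions ships in inst/scripts/lion-panel.R.

#' Default run configuration
#'
#' All pipeline thresholds with their standard defaults: masking depth 3,
#' ladder (1, 3, 5, 8, all), 50-bp flanks with combined coverage 20, at
#' most 1 flank variant, at least 8 individuals per site, panel sizes
#' 125 + 14, QC missingness cutoff 0.25, haplogroup grading bands
#' 0.40 / 0.60 / 0.85, and 1000 bootstraps for the D-statistic.
#'
#' @param seed global seed.
#' @param ... overrides for individual keys.
#' @return a named list (`RunConfig`).
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_sites = 5000L, n_scaffolds = 400L,
    min_depth = 3L, ladder = c(1L, 3L, 5L, 8L, NA),
    flank = 50L, min_combined = 20L, max_flank_variants = 1L,
    min_individuals = 8L,
    target_autosomal = 125L, target_mtdna = 14L,
    max_missing = 0.25,
    fail_hi = 0.40, qual_lo = 0.60, qual_hi = 0.85,
    n_boot = 1000L, z_threshold = 3,
    het_min_called = 5L, pseudocount = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return a `RunConfig` list (reader); `path` invisibly (writer).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_run_config, c(list(seed = cfg$seed %||% 1L),
                                cfg[setdiff(names(cfg), "seed")]))
}

#' @rdname read_run_config
#' @param config a `RunConfig` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.run_report <- function(stage, config, inputs = character(), outputs = character()) {
  list(stage = stage,
       package_version = as.character(utils::packageVersion("lionpanel")),
       seed = config$seed,
       parameters = config[setdiff(names(config), "seed")],
       input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
       outputs = outputs)
}

.write_report <- function(report, out_dir) {
  path <- file.path(out_dir, paste0("report_", report$stage, ".json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Pipeline stage: simulate a discovery bundle
#'
#' @param out_dir output directory.
#' @param config a `RunConfig` (see [default_run_config()]).
#' @param force overwrite a non-empty directory.
#' @return file path of the run report, invisibly.
#' @export
run_simulate <- function(out_dir, config = default_run_config(), force = FALSE) {
  dcfg <- discovery_config(n_sites = config$n_sites,
                           n_scaffolds = config$n_scaffolds,
                           seed = config$seed)
  generate_dataset(dcfg, out_dir = out_dir, force = force)
  rep <- .run_report("simulate", config,
                     outputs = dir(out_dir, full.names = FALSE))
  .write_report(rep, out_dir)
}

.require_files <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         " (run the upstream stage first)")
  invisible(paths)
}

#' Pipeline stage: masking and the missing-data filter ladder
#'
#' Reads the discovery VCF, masks cells below the depth cutoff, attributes
#' chromosomes, writes the filtered VCF and the ladder report CSV.
#'
#' @param in_dir directory holding `discovery.vcf` and `scaffold_map.csv`.
#' @param out_dir output directory (default: `in_dir`).
#' @param config a `RunConfig`.
#' @return the `FilterReport`, invisibly.
#' @export
run_filter <- function(in_dir, out_dir = in_dir,
                       config = default_run_config()) {
  vcf <- file.path(in_dir, "discovery.vcf")
  smap_path <- file.path(in_dir, "scaffold_map.csv")
  .require_files(vcf, smap_path)
  dataset <- read_vcf(vcf)
  sheet_path <- file.path(in_dir, "sample_sheet.csv")
  if (file.exists(sheet_path)) {
    sheet <- read_sample_sheet(sheet_path)
    lions <- sheet$sample[sheet$region != "Outgroup"]
    dataset <- dataset[, intersect(dataset$samples, lions)]
  }
  masked <- mask_low_coverage(dataset, config$min_depth)
  masked <- attribute_chromosomes(masked, utils::read.csv(smap_path))
  report <- filter_ladder(masked, levels = config$ladder, min_depth = NULL)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(masked, file.path(out_dir, "masked.vcf"),
            header_extra = sprintf("##lionpanel_min_depth=%d", config$min_depth))
  utils::write.csv(report$levels, file.path(out_dir, "filter_ladder.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample = names(report$sample_missingness),
                              missing = report$sample_missingness),
                   file.path(out_dir, "sample_missingness.csv"),
                   row.names = FALSE)
  .write_report(.run_report("filter", config, inputs = c(vcf, smap_path)),
                out_dir)
  invisible(report)
}

#' Pipeline stage: design the SNP panel
#'
#' @param in_dir bundle directory (simulate + filter outputs).
#' @param out_dir output directory.
#' @param config a `RunConfig`.
#' @param mt_model `MtDNAModel` used for the mtDNA candidates; by default
#'   the model persisted in the bundle (`mitogenome.fa` +
#'   `mt_candidate_sites.csv`) is reloaded so design stays consistent with
#'   the simulated haplotypes regardless of the seed in `config`.
#' @return the combined `PanelDefinition`, invisibly.
#' @export
run_design <- function(in_dir, out_dir = in_dir,
                       config = default_run_config(),
                       mt_model = NULL) {
  if (is.null(mt_model)) {
    gp <- file.path(in_dir, "mitogenome.fa")
    sp <- file.path(in_dir, "mt_candidate_sites.csv")
    mt_model <- if (file.exists(gp) && file.exists(sp)) {
      structure(list(genome = unname(read_fasta(gp)[["mitogenome"]]),
                     sites = utils::read.csv(sp, stringsAsFactors = FALSE),
                     haplogroups = HAPLOGROUPS,
                     northern = NORTHERN_HAPLOGROUPS,
                     numt = NULL),
                class = "MtDNAModel")
    } else mtdna_model(seed = config$seed)
  }
  paths <- file.path(in_dir, c("masked.vcf", "flanks.fa",
                               "flank_variants.csv", "window_depth.csv",
                               "numts.fa"))
  .require_files(paths)
  masked <- read_vcf(paths[1])
  flanks <- read_fasta(paths[2])
  fv <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  wd_df <- utils::read.csv(paths[4], check.names = FALSE)
  wd <- as.matrix(wd_df[, -1, drop = FALSE])
  rownames(wd) <- wd_df[[1]]
  smap <- utils::read.csv(file.path(in_dir, "scaffold_map.csv"))
  masked <- attribute_chromosomes(masked, smap)
  numts <- read_fasta(paths[5])

  cand <- panel_candidates(masked, flanks, fv, wd)
  aut <- select_autosomal_panel(cand, target_n = config$target_autosomal,
                                min_combined = config$min_combined,
                                window = config$flank,
                                max_variants = config$max_flank_variants,
                                min_called = config$min_individuals)
  mt <- select_mtdna_panel(mt_model, numts, target_n = config$target_mtdna)
  panel <- combine_panels(aut, mt)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(panel, file.path(out_dir, "panel.csv"))
  if (!is.null(panel$key))
    utils::write.csv(data.frame(haplogroup = rownames(panel$key), panel$key,
                                check.names = FALSE),
                     file.path(out_dir, "haplogroup_key.csv"),
                     row.names = FALSE)
  .write_report(.run_report("design", config, inputs = paths), out_dir)
  invisible(panel)
}

#' Pipeline stage: apply the panel to a dataset
#'
#' @param in_dir bundle directory with `discovery.vcf`, `mtdna_calls.csv`
#'   and the designed `panel.csv`.
#' @param out_dir output directory.
#' @param config a `RunConfig`.
#' @return the `PanelCalls`, invisibly.
#' @export
run_genotype <- function(in_dir, out_dir = in_dir,
                         config = default_run_config()) {
  paths <- file.path(in_dir, c("discovery.vcf", "panel.csv", "mtdna_calls.csv"))
  .require_files(paths)
  dataset <- read_vcf(paths[1])
  panel <- read_panel(paths[2])
  mt_df <- utils::read.csv(paths[3], check.names = FALSE,
                           stringsAsFactors = FALSE)
  mt_calls <- as.matrix(mt_df[, -1, drop = FALSE])
  rownames(mt_calls) <- mt_df[[1]]
  sheet_path <- file.path(in_dir, "sample_sheet.csv")
  if (file.exists(sheet_path)) {
    sheet <- read_sample_sheet(sheet_path)
    lions <- sheet$sample[sheet$region != "Outgroup"]
    dataset <- dataset[, intersect(dataset$samples, lions)]
  }
  calls <- apply_panel(panel, dataset, mt_calls)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_panel_calls(calls, file.path(out_dir, "panel_calls.csv"))
  .write_report(.run_report("genotype", config, inputs = paths), out_dir)
  invisible(calls)
}

#' Pipeline stage: assignment of panel-genotyped samples
#'
#' @param in_dir directory with `panel_calls.csv`, `sample_sheet.csv` and
#'   `haplogroup_key.csv`.
#' @param out_dir output directory.
#' @param config a `RunConfig`.
#' @return the `AssignmentResult`, invisibly.
#' @export
run_assign <- function(in_dir, out_dir = in_dir,
                       config = default_run_config()) {
  paths <- file.path(in_dir, c("panel_calls.csv", "sample_sheet.csv",
                               "haplogroup_key.csv"))
  .require_files(paths)
  calls <- read_panel_calls(paths[1])
  sheet <- read_sample_sheet(paths[2])
  key_df <- utils::read.csv(paths[3], check.names = FALSE,
                            stringsAsFactors = FALSE)
  key <- as.matrix(key_df[, -1, drop = FALSE])
  rownames(key) <- key_df[[1]]
  res <- assign_cohort(calls, sheet, key, max_missing = config$max_missing,
                       pseudocount = config$pseudocount)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$table, file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)
  tree <- distance_tree(calls, samples = res$qc$retained)
  ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  .write_report(.run_report("assign", config, inputs = paths), out_dir)
  invisible(res)
}

#' Pipeline stage: population-genetic statistics
#'
#' Computes individual observed heterozygosity on the masked discovery
#' calls and, when the four D-statistic groups are given, the ABBA-BABA
#' test with bootstrap significance.
#'
#' @param in_dir directory with `masked.vcf` (and `discovery.vcf`).
#' @param out_dir output directory.
#' @param config a `RunConfig`.
#' @param dstat_groups optional named list with elements `P1`, `P2`, `P3`,
#'   `outgroup` (sample-id vectors).
#' @return list with `het` and (optionally) `dstat`, invisibly.
#' @export
run_stats <- function(in_dir, out_dir = in_dir,
                      config = default_run_config(), dstat_groups = NULL) {
  masked_path <- file.path(in_dir, "masked.vcf")
  .require_files(masked_path)
  masked <- read_vcf(masked_path)
  het <- het_individual(masked)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(sample = names(het), het_obs = het),
                   file.path(out_dir, "heterozygosity.csv"),
                   row.names = FALSE)
  out <- list(het = het)
  if (!is.null(dstat_groups)) {
    raw <- read_vcf(file.path(in_dir, "discovery.vcf"))
    ds <- d_statistic(raw, dstat_groups$P1, dstat_groups$P2, dstat_groups$P3,
                      dstat_groups$outgroup, n_boot = config$n_boot,
                      seed = config$seed, z_threshold = config$z_threshold)
    utils::write.csv(data.frame(D = ds$D, Z = ds$Z,
                                significant = ds$significant,
                                n_sites = ds$n_sites_used,
                                n_boot = ds$n_boot),
                     file.path(out_dir, "dstat.csv"), row.names = FALSE)
    out$dstat <- ds
  }
  .write_report(.run_report("stats", config, inputs = masked_path), out_dir)
  invisible(out)
}
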