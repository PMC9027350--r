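# Readers/writers for the interchange formats: VCF (GT:DP), FASTA, the CSV
# sample sheet and the CSV panel-call table. VCF parsing goes through vcfR;
# FASTA through Biostrings. All coordinates are 1-based inclusive.

GT_MAP <- c("0/0" = 0L, "0|0" = 0L,
            "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
            "1/1" = 2L, "1|1" = 2L)
GT_MISSING <- c("./.", ".|.", ".")

REGION_LEVELS <- c("West & Central Africa", "India", "East Africa",
                   "Southern Africa", "Outgroup")

#' Read a VCF file into a `VariantDataset`
#'
#' Loads biallelic SNP records with per-sample genotypes (GT) and read depths
#' (DP). Multi-allelic records and indels are skipped with a message giving
#' the count. A missing DP field becomes depth 0 while the call is retained
#' as provided; `./.` genotypes become `NA` calls.
#'
#' @param path path to a VCF v4.x file.
#' @return a [variant_dataset()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  head_lines <- readLines(path, n = 1000L)
  if (length(head_lines) == 0L || !startsWith(head_lines[1L], "##fileformat=VCF"))
    stop("malformed VCF header at line 1: missing ##fileformat")
  chrom_line <- which(startsWith(head_lines, "#CHROM"))
  if (length(chrom_line) == 0L)
    stop("malformed VCF header: no #CHROM line within the first 1000 lines")
  n_header <- chrom_line[1L]

  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0L) {
    return(variant_dataset(
      sites = data.frame(scaffold = character(), position = integer(),
                         ref = character(), alt = character()),
      samples = colnames(v@gt)[-1L] %||% character(),
      geno = matrix(integer(), 0L, max(0L, ncol(v@gt) - 1L)),
      depth = matrix(integer(), 0L, max(0L, ncol(v@gt) - 1L))))
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0L)
    message("read_vcf: skipped ", n_skip,
            " non-biallelic-SNP record(s) (multi-allelic or indel)")

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP")
  gt <- gt[snp, , drop = FALSE]
  dp <- dp[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- !is.na(gt) & !(gt %in% GT_MISSING)
  bad <- known & !(gt %in% names(GT_MAP))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("malformed GT field '%s' at VCF line %d (sample %s)",
                 gt[bad][1L], n_header + which(snp)[idx[1L]],
                 colnames(gt)[idx[2L]]))
  }
  geno[known] <- GT_MAP[gt[known]]

  depth <- suppressWarnings(matrix(as.integer(dp), nrow(dp), ncol(dp)))
  depth[is.na(depth)] <- 0L

  variant_dataset(
    sites = data.frame(scaffold = fix[, "CHROM"],
                       position = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       stringsAsFactors = FALSE),
    samples = colnames(gt),
    geno = geno, depth = depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a `VariantDataset` to a plain-text VCF
#'
#' Serializes genotypes and depths as `GT:DP`. `read_vcf(write_vcf(d))`
#' reproduces calls and depths exactly.
#'
#' @param dataset a `VariantDataset`.
#' @param path output path.
#' @param header_extra optional character vector of extra `##` header lines
#'   (e.g. a parameter snapshot).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dataset, path, header_extra = NULL) {
  stopifnot(inherits(dataset, "VariantDataset"))
  gt_str <- c("0/0", "0/1", "1/1")
  g <- dataset$geno
  cells <- matrix("./.", nrow(g), ncol(g))
  cells[!is.na(g)] <- gt_str[g[!is.na(g)] + 1L]
  cells <- matrix(paste0(cells, ":", dataset$depth), nrow(g), ncol(g))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lionpanel",
    header_extra,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples), collapse = "\t"))
  if (n_sites(dataset) > 0L) {
    body <- paste(dataset$sites$scaffold, dataset$sites$position, ".",
                  dataset$sites$ref, dataset$sites$alt, ".", "PASS", ".",
                  "GT:DP", sep = "\t")
    body <- paste(body, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  } else body <- character()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercased sequences; names are record
#'   ids truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write the sample sheet
#'
#' CSV with header `sample,population,region,lat,lon`. Regions must come from
#' the four-clade vocabulary (West & Central Africa, India, East Africa,
#' Southern Africa), plus `Outgroup` for a non-lion outgroup entry.
#'
#' @param path CSV path.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample", "population", "region")
  if (!all(required %in% names(df)))
    stop("sample sheet needs columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(df$region), REGION_LEVELS)
  if (length(bad) > 0L)
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_sample_sheet
#' @param sheet data.frame as returned by [read_sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  for (col in c("lat", "lon"))
    if (!col %in% names(sheet)) sheet[[col]] <- NA_real_
  utils::write.csv(sheet[, c("sample", "population", "region", "lat", "lon")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a panel-call table
#'
#' Biallelic calls of many samples at the panel SNPs, with each SNP flagged
#' as autosomal or mitochondrial. Calls are integer alt doses (0/1/2, `NA`
#' missing); mitochondrial calls are haploid and restricted to 0/2.
#'
#' @param samples character vector of sample ids.
#' @param snps data.frame with columns `id`, `type` (one of `"autosomal"`,
#'   `"mitochondrial"`), `ref`, `alt`.
#' @param calls integer matrix (`n_samples x n_snps`).
#' @return an object of class `PanelCalls`.
#' @export
panel_calls <- function(samples, snps, calls) {
  stopifnot(is.data.frame(snps),
            all(c("id", "type", "ref", "alt") %in% names(snps)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(snps$id)) stop("duplicate panel SNP ids")
  if (!all(snps$type %in% c("autosomal", "mitochondrial")))
    stop("snp type must be 'autosomal' or 'mitochondrial'")
  calls <- as.matrix(calls); storage.mode(calls) <- "integer"
  if (!all(dim(calls) == c(length(samples), nrow(snps))))
    stop("calls must be n_samples x n_snps")
  if (any(calls < 0L | calls > 2L, na.rm = TRUE)) stop("call codes must be 0/1/2/NA")
  mito <- snps$type == "mitochondrial"
  if (any(calls[, mito, drop = FALSE] == 1L, na.rm = TRUE))
    stop("mitochondrial calls are haploid; heterozygous codes not allowed")
  dimnames(calls) <- list(samples, snps$id)
  rownames(snps) <- NULL
  structure(list(samples = samples, snps = snps, calls = calls),
            class = "PanelCalls")
}

#' @export
print.PanelCalls <- function(x, ...) {
  cat("PanelCalls:", length(x$samples), "samples x", nrow(x$snps), "SNPs (",
      sum(x$snps$type == "autosomal"), "autosomal,",
      sum(x$snps$type == "mitochondrial"), "mtDNA )\n")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Write / read panel calls as CSV
#'
#' One row per sample, one column per panel SNP; cells are allele pairs such
#' as `A/G` (mitochondrial calls are homozygous-style). SNP metadata (type,
#' ref, alt) is carried in `#snp` comment lines so the file round-trips
#' exactly.
#'
#' @param calls a `PanelCalls` object.
#' @param path CSV path.
#' @param missing token used for missing calls (default `"NA"`).
#' @return `path` invisibly (writer); a `PanelCalls` (reader).
#' @export
write_panel_calls <- function(calls, path, missing = "NA") {
  stopifnot(inherits(calls, "PanelCalls"))
  snps <- calls$snps
  meta <- sprintf("#snp,%s,%s,%s,%s", snps$id, snps$type, snps$ref, snps$alt)
  cells <- matrix(missing, nrow(calls$calls), ncol(calls$calls))
  for (j in seq_len(ncol(calls$calls))) {
    gt <- c(paste0(snps$ref[j], "/", snps$ref[j]),
            paste0(snps$ref[j], "/", snps$alt[j]),
            paste0(snps$alt[j], "/", snps$alt[j]))
    g <- calls$calls[, j]
    cells[!is.na(g), j] <- gt[g[!is.na(g)] + 1L]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(c("sample", snps$id), collapse = ","), con)
  writeLines(paste(calls$samples, apply(cells, 1L, paste, collapse = ","),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_panel_calls
#' @export
read_panel_calls <- function(path, missing = "NA") {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#snp,")]
  if (length(meta) == 0L) stop("panel-call CSV lacks #snp metadata lines")
  parts <- strsplit(sub("^#snp,", "", meta), ",", fixed = TRUE)
  snps <- data.frame(id = vapply(parts, `[`, "", 1L),
                     type = vapply(parts, `[`, "", 2L),
                     ref = vapply(parts, `[`, "", 3L),
                     alt = vapply(parts, `[`, "", 4L),
                     stringsAsFactors = FALSE)
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE)
  if (!identical(names(df)[-1L], snps$id))
    stop("panel-call CSV columns do not match #snp metadata")
  samples <- df$sample
  calls <- matrix(NA_integer_, nrow(df), nrow(snps))
  for (j in seq_len(nrow(snps))) {
    gt <- c(paste0(snps$ref[j], "/", snps$ref[j]),
            paste0(snps$ref[j], "/", snps$alt[j]),
            paste0(snps$alt[j], "/", snps$alt[j]),
            paste0(snps$alt[j], "/", snps$ref[j]))
    code <- c(0L, 1L, 2L, 1L)
    cell <- df[[j + 1L]]
    is_missing <- cell == missing | is.na(cell)
    m <- match(cell, gt)
    bad <- !is_missing & is.na(m)
    if (any(bad))
      stop(sprintf("unknown allele symbol '%s' in cell (sample %s, snp %s)",
                   cell[bad][1L], samples[bad][1L], snps$id[j]))
    calls[!is_missing, j] <- code[m[!is_missing]]
  }
  panel_calls(samples, snps, calls)
}
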