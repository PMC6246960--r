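## Variant-table and configuration I/O.
##
## Tumor variant tables travel either as a minimal sites-only VCF v4.2
## (CHROM POS ID REF ALT QUAL FILTER INFO, with GENE=, PCHANGE=, TMAF=,
## VTYPE= INFO keys and the variant id in the ID column) or as a mirrored
## CSV with the same 1-based positions. Internally all coordinates are
## 0-based half-open; the shift happens only here, at the format boundary.

variant_cols <- c("sample_id", "variant_id", "chrom", "pos", "ref", "alt",
                  "gene", "protein_change", "variant_type", "tumor_maf_pct")

empty_variants <- function() {
  data.frame(sample_id = character(), variant_id = character(),
             chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(),
             protein_change = character(), variant_type = character(),
             tumor_maf_pct = double(), stringsAsFactors = FALSE)
}

#' Write a tumor variant table
#'
#' @param variants variant data frame (internal 0-based `pos`).
#' @param path output path.
#' @param dialect `"vcf_minimal"` (sites-only VCF v4.2, 1-based POS) or
#'   `"csv"` (same columns, 1-based `pos`).
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path,
                                dialect = c("vcf_minimal", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    out <- variants[variant_cols]
    out$pos <- out$pos + 1L
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
           "##INFO=<ID=VTYPE,Number=1,Type=String,Description=\"Variant type\">",
           "##INFO=<ID=TMAF,Number=1,Type=Float,Description=\"Tumor MAF percent\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- if (nrow(variants)) {
    info <- sprintf("SAMPLE=%s;GENE=%s;PCHANGE=%s;VTYPE=%s;TMAF=%.6g",
                    variants$sample_id, variants$gene,
                    variants$protein_change, variants$variant_type,
                    variants$tumor_maf_pct)
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
            variants$chrom, variants$pos + 1L, variants$variant_id,
            variants$ref, variants$alt, info)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a tumor variant table
#'
#' VCF positions (1-based) are shifted to the internal 0-based convention.
#' The round trip through [write_variant_table()] is lossless.
#'
#' @param path input path.
#' @param dialect `"vcf_minimal"` or `"csv"`.
#' @return variant data frame with internal 0-based `pos`.
#' @export
read_variant_table <- function(path, dialect = c("vcf_minimal", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("no such file: ", path)
  if (dialect == "csv") {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(variant_cols, names(out))
    if (length(missing))
      stop_input("variant CSV lacks column(s): ",
                 paste(missing, collapse = ", "))
    out$pos <- as.integer(out$pos) - 1L
    return(out[variant_cols])
  }
  n_body <- sum(!startsWith(readLines(path), "#"))
  if (n_body == 0) return(empty_variants())
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_get <- function(key) {
    m <- regmatches(fix$INFO,
                    regexpr(paste0("(^|;)", key, "=[^;]*"), fix$INFO))
    has <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    val <- rep(NA_character_, nrow(fix))
    val[has] <- sub(paste0("^;?", key, "="), "", m)
    val
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (any(is.na(pos)))
    stop_input("malformed POS at record ", which(is.na(pos))[1])
  data.frame(sample_id = info_get("SAMPLE"),
             variant_id = fix$ID,
             chrom = fix$CHROM,
             pos = pos - 1L,
             ref = fix$REF, alt = fix$ALT,
             gene = info_get("GENE"),
             protein_change = info_get("PCHANGE"),
             variant_type = info_get("VTYPE"),
             tumor_maf_pct = as.numeric(info_get("TMAF")),
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline with the published
#' defaults: the caller gates ([caller_thresholds()]), the ddPCR constants
#' (0.03% MAF threshold, 0.85 nL droplets, 3.3 pg/genome), the survival
#' settings (10% minimum group fraction, automatic cut point), and the
#' simulation parameters. A single `seed` is fanned out deterministically
#' to the per-stage generators (documented offsets), so any stage can be
#' re-run reproducibly.
#'
#' @param n_patients evaluable cohort size for simulation.
#' @param seed master seed.
#' @param thresholds a [caller_thresholds()] object.
#' @param threshold_maf_pct ddPCR detection threshold (percent MAF).
#' @param droplet_volume_nl droplet volume (nL).
#' @param pg_per_genome haploid genome mass (pg).
#' @param min_group_fraction maxstat minimum group fraction.
#' @param cutpoint `"auto"` (maxstat) or a numeric copies/mL value.
#' @param true_cutpoint_cp_ml generating cut point used by the simulator to
#'   assign prognostic groups before survival is drawn.
#' @param platform_mix proportions of samples run on ddPCR only, NGS only,
#'   or both.
#' @param group_hazards per-day hazards for the three prognostic groups.
#' @param n_droplets droplets per simulated ddPCR reaction.
#' @param reaction_fraction fraction of the elution loaded per reaction.
#' @param plasma_ml plasma volume extracted (mL).
#' @param ngs_molecules cfDNA molecules per simulated NGS library.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 138L,
                            seed = 1L,
                            thresholds = caller_thresholds(),
                            threshold_maf_pct = 0.03,
                            droplet_volume_nl = 0.85,
                            pg_per_genome = 3.3,
                            min_group_fraction = 0.1,
                            cutpoint = "auto",
                            true_cutpoint_cp_ml = 210.53,
                            platform_mix = c(ddPCR = 74, NGS = 39,
                                             both = 25) / 138,
                            group_hazards = c(high = 1 / 300,
                                              low = 0.2331 / 300,
                                              not_detected = 0.1875 / 300),
                            n_droplets = 15000L,
                            reaction_fraction = 0.25,
                            plasma_ml = 1,
                            ngs_molecules = 3000L) {
  check_proportion_map(platform_mix, "platform_mix")
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed), thresholds = thresholds,
                 threshold_maf_pct = threshold_maf_pct,
                 droplet_volume_nl = droplet_volume_nl,
                 pg_per_genome = pg_per_genome,
                 min_group_fraction = min_group_fraction,
                 cutpoint = cutpoint,
                 true_cutpoint_cp_ml = true_cutpoint_cp_ml,
                 platform_mix = platform_mix,
                 group_hazards = group_hazards,
                 n_droplets = as.integer(n_droplets),
                 reaction_fraction = reaction_fraction,
                 plasma_ml = plasma_ml,
                 ngs_molecules = as.integer(ngs_molecules)),
            class = "pipeline_config")
}

#' Load / save a pipeline configuration as YAML
#'
#' Flat key-value YAML; nested maps hold the threshold and hazard sets.
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()] object.
#' @return `load_config()` returns a `pipeline_config`; `save_config()`
#'   the path, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  x$platform_mix <- as.list(x$platform_mix)
  x$group_hazards <- as.list(x$group_hazards)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  x <- yaml::read_yaml(path)
  thr <- do.call(caller_thresholds, x$thresholds %||% list())
  x$thresholds <- NULL
  args <- x
  args$platform_mix <- unlist(x$platform_mix)
  args$group_hazards <- unlist(x$group_hazards)
  do.call(pipeline_config, c(args, list(thresholds = thr)))
}
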