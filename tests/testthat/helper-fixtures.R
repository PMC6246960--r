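# Fixtures are built in code: read tables with chosen family structure and
# a 138-sample concordance-record sheet matching the published per-stratum
# counts.

# Quick read-table constructor: one row per read.
mk_reads <- function(start, end, allele, umi = NA_character_,
                     chrom = "chr1", sample_id = "S1") {
  n <- max(length(start), length(end), length(allele))
  data.frame(sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
             start = rep_len(as.integer(start), n),
             end = rep_len(as.integer(end), n),
             umi = rep_len(umi, n),
             allele = rep_len(allele, n),
             strand = rep_len("+", n), stringsAsFactors = FALSE)
}

# A family block: `size` reads at one (start, end[, umi]) key with a given
# number of alt reads (rest ref).
mk_family <- function(start, end, size, n_alt, umi = NA_character_) {
  mk_reads(start, end, c(rep("alt", n_alt), rep("ref", size - n_alt)),
           umi = umi)
}

# 138 concordance records reproducing the published contingency table:
# stage block 9/28 early and 90/110 advanced; tissue block (covering 137
# samples; one sample carries no tissue label, as the published tissue
# rows sum to 137) bladder 3/10, breast 10/27, colorectal 6/11, lung
# 73/81, ovarian 4/6, others 2/2; platform rows ddPCR 79/99 and NGS 37/64
# with 25 samples on both platforms.
table2_records <- function() {
  tiss <- list(Bladder = c(10, 3), Breast = c(27, 10), Colorectal = c(11, 6),
               Lung = c(81, 73), Ovarian = c(6, 4), Others = c(2, 2))
  tissue <- character(0); concordant <- logical(0)
  for (t in names(tiss)) {
    n <- tiss[[t]][1]; k <- tiss[[t]][2]
    tissue <- c(tissue, rep(t, n))
    concordant <- c(concordant, rep(TRUE, k), rep(FALSE, n - k))
  }
  tissue <- c(tissue, NA_character_)     # 138th sample, unlabelled tissue
  concordant <- c(concordant, TRUE)      # overall concordant = 99

  stage <- character(138)
  conc_idx <- which(concordant)          # 99
  disc_idx <- which(!concordant)         # 39
  stage[conc_idx] <- c(rep("early", 9), rep("advanced", 90))
  stage[disc_idx] <- c(rep("early", 19), rep("advanced", 20))

  platform <- character(138)
  platform[conc_idx] <- c(rep("ddPCR", 62), rep("both", 17), rep("NGS", 20))
  platform[disc_idx] <- c(rep("ddPCR", 12), rep("both", 8), rep("NGS", 19))

  data.frame(sample_id = sprintf("T2_%03d", 1:138), stage = stage,
             tissue = tissue, platform = platform,
             n_tumor_variants = 1L,
             n_detected_in_plasma = as.integer(concordant),
             concordant = concordant, stringsAsFactors = FALSE)
}

pct_of <- function(summary_df, block, stratum) {
  summary_df$pct_concordant[summary_df$block == block &
                              summary_df$stratum == stratum]
}
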