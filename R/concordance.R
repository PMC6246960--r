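## Tumor-plasma concordance tabulation.
##
## A sample is concordant when at least one of its tumor-identified somatic
## mutations is detected in the matched plasma by the applicable procedure's
## gates (ddPCR MAF >= 0.03%, or an NGS caller's detected flag). Stratified
## summaries follow the conventional contingency layout: by stage (unknown
## stage excluded), by tissue, by platform (samples run on both platforms
## count in each platform row), plus cross-platform agreement.

#' Per-sample concordance decision
#'
#' @param tumor_variants data frame of the sample's tumor variants (must be
#'   non-empty; samples without followable mutations are excluded upstream).
#' @param plasma_results list of plasma results for this sample:
#'   `plasma_call` and/or `ctdna_quant` objects, each optionally carrying a
#'   `variant_id` field linking it to a tumor variant.
#' @param sample_info optional named list/row with `stage`, `tissue`,
#'   `platform` to stamp on the record.
#' @param require_all_variants if `TRUE`, every tumor variant must be
#'   detected for concordance (default `FALSE`: at least one).
#' @return a one-row data frame (`concordance_record`): sample_id, stage,
#'   tissue, platform, n_tumor_variants, n_detected_in_plasma, concordant.
#' @export
evaluate_sample <- function(tumor_variants, plasma_results,
                            sample_info = NULL,
                            require_all_variants = FALSE) {
  if (nrow(tumor_variants) == 0)
    stop_input("evaluate_sample needs at least one tumor variant")
  sid <- unique(tumor_variants$sample_id)
  if (length(sid) != 1)
    stop_input("tumor variants span multiple samples")
  known <- tumor_variants$variant_id
  detected_ids <- character(0)
  n_unmatched_detected <- 0L
  for (r in plasma_results) {
    det <- isTRUE(r$detected)
    vid <- r$variant_id %||% NA_character_
    if (!is.na(vid) && !(vid %in% known)) {
      warning("plasma result for variant '", vid,
              "' absent from the tumor list; ignored for concordance",
              call. = FALSE)
      next
    }
    if (det) {
      if (is.na(vid)) n_unmatched_detected <- n_unmatched_detected + 1L
      else detected_ids <- union(detected_ids, vid)
    }
  }
  n_det <- length(detected_ids) + n_unmatched_detected
  concordant <- if (require_all_variants)
    length(detected_ids) == length(known)
  else n_det >= 1
  data.frame(sample_id = sid,
             stage = sample_info$stage %||% NA_character_,
             tissue = sample_info$tissue %||% NA_character_,
             platform = sample_info$platform %||% NA_character_,
             n_tumor_variants = length(known),
             n_detected_in_plasma = n_det,
             concordant = concordant,
             stringsAsFactors = FALSE)
}

summary_block <- function(labels, concordant, block) {
  labs <- unique(labels)
  rows <- lapply(labs, function(l) {
    sel <- labels == l
    n <- sum(sel)
    nc <- sum(concordant[sel])
    data.frame(block = block, stratum = l, n = n,
               n_concordant = nc,
               pct_concordant = round_half_up(100 * nc / n, 2),
               n_discordant = n - nc,
               pct_discordant = round_half_up(100 * (n - nc) / n, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratified concordance summary
#'
#' Builds the contingency summary: an overall row plus per-stage (unknown
#' excluded), per-tissue and per-platform blocks. Samples with platform
#' `"both"` are counted in the ddPCR row and in the NGS row. Percentages
#' are rounded half-up to two decimals.
#'
#' @param records data frame of concordance records ([evaluate_sample()]
#'   rows bound together).
#' @param strata which blocks to emit.
#' @return a `concordance_summary` data frame with columns block, stratum,
#'   n, n_concordant, pct_concordant, n_discordant, pct_discordant.
#' @export
summarize_concordance <- function(records,
                                  strata = c("stage", "tissue", "platform")) {
  if (nrow(records) == 0) stop_input("no concordance records")
  bad <- setdiff(strata, c("stage", "tissue", "platform"))
  if (length(bad))
    stop_input("unknown stratum key(s): ", paste(bad, collapse = ", "))
  out <- summary_block(rep("All samples", nrow(records)), records$concordant,
                       "all")
  if ("stage" %in% strata) {
    keep <- !is.na(records$stage) & records$stage != "unknown"
    if (any(keep))
      out <- rbind(out, summary_block(records$stage[keep],
                                      records$concordant[keep], "stage"))
  }
  if ("tissue" %in% strata && any(!is.na(records$tissue))) {
    keep <- !is.na(records$tissue)
    out <- rbind(out, summary_block(records$tissue[keep],
                                    records$concordant[keep], "tissue"))
  }
  if ("platform" %in% strata && any(!is.na(records$platform))) {
    keep <- !is.na(records$platform)
    r <- records[keep, , drop = FALSE]
    for (pl in c("ddPCR", "NGS")) {
      sel <- r$platform == pl | r$platform == "both"
      if (any(sel))
        out <- rbind(out, summary_block(rep(pl, sum(sel)),
                                        r$concordant[sel], "platform"))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("concordance_summary", "data.frame")
  out
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Tumor-plasma concordance\n")
  for (b in unique(x$block)) {
    sub <- x[x$block == b, , drop = FALSE]
    if (b != "all") cat(sprintf("By %s\n", b))
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-22s %4d  %3d (%.2f%%)  %3d (%.2f%%)\n",
                  sub$stratum[i], sub$n[i], sub$n_concordant[i],
                  sub$pct_concordant[i], sub$n_discordant[i],
                  sub$pct_discordant[i]))
  }
  invisible(x)
}

#' Cross-platform agreement
#'
#' For samples assayed on two platforms, the percentage whose
#' detected/not-detected status agrees.
#'
#' @param calls_a,calls_b data frames with columns `sample_id` and
#'   `detected`, one row per sample, from the two platforms.
#' @return list with `n_shared`, `n_agree`, `pct_agree` (half-up, 2 dp).
#' @export
cross_platform_agreement <- function(calls_a, calls_b) {
  shared <- intersect(calls_a$sample_id, calls_b$sample_id)
  if (length(shared) == 0) stop_input("no shared samples between platforms")
  a <- calls_a$detected[match(shared, calls_a$sample_id)]
  b <- calls_b$detected[match(shared, calls_b$sample_id)]
  n_agree <- sum(a == b)
  list(n_shared = length(shared), n_agree = n_agree,
       pct_agree = round_half_up(100 * n_agree / length(shared), 2))
}

#' Tumor mutation-profile summary
#'
#' Distribution of followable mutations per sample (bins 1, 2-3, >3) and
#' per-gene mutated-sample counts, the numeric side of a mutation-landscape
#' figure.
#'
#' @param tumor_variants data frame with `sample_id` and `gene`.
#' @return list with `n_samples`, `mutation_count_dist` (bin, n, pct) and
#'   `gene_counts` (gene, n_samples) sorted descending.
#' @export
tumor_profile_summary <- function(tumor_variants) {
  if (nrow(tumor_variants) == 0) stop_input("no tumor variants")
  per_sample <- table(tumor_variants$sample_id)
  n <- length(per_sample)
  bins <- cut(as.integer(per_sample), breaks = c(0, 1, 3, Inf),
              labels = c("1", "2-3", ">3"))
  counts <- table(bins)
  dist <- data.frame(bin = names(counts), n = as.integer(counts),
                     pct = round_half_up(100 * as.integer(counts) / n, 2),
                     stringsAsFactors = FALSE)
  gc <- tapply(tumor_variants$sample_id, tumor_variants$gene,
               function(s) length(unique(s)))
  gene_counts <- data.frame(gene = names(gc), n_samples = as.integer(gc),
                            stringsAsFactors = FALSE)
  gene_counts <- gene_counts[order(-gene_counts$n_samples, gene_counts$gene), ]
  rownames(gene_counts) <- NULL
  list(n_samples = n, mutation_count_dist = dist, gene_counts = gene_counts)
}
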