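## Plasma variant callers over read families.
##
## Four detection procedures for tumor-identified variants in plasma
## (check-known-variants mode: the caller is pointed at a locus, it never
## discovers variants de novo):
##
##   * dnaseq_positional — endogenous-UMI families keyed on (start, end);
##     a variant is bona fide if at least two families of >= 5 reads carry
##     it with strictly more than 95% within-family consistency.
##   * tagseq_ckv — exogenous-UMI families are collapsed to consensus reads;
##     detection at >= 0.4% consensus supporting reads for SNVs and
##     >= 0.2% for indels spanning multiple bases.
##   * generead — UMI families; detection needs at least two families of
##     >= 3 reads whose consensus is the variant.
##   * amplicon — no family structure; a binomial caller requiring >= 10
##     reads depth, >= 2 variant reads, a Phred-scaled binomial confidence
##     >= 50 and %SR >= 0.3 (SNV) / >= 0.2 (multi-base indel).
##
## Count gates are inclusive (>=); the 95% consistency gate is strict (>),
## following the rules' own wording.

#' Caller thresholds
#'
#' All detection gates of the four plasma calling procedures, with the
#' published defaults. `single_base_indel_as_snv` controls whether 1-bp
#' indels use the SNV supporting-read threshold instead of the multi-base
#' indel one (the published rules only address multi-base indels).
#'
#' @param dnaseq_min_family minimum reads per qualifying positional family.
#' @param dnaseq_min_families qualifying families required.
#' @param dnaseq_consistency within-family consistency, strict lower bound.
#' @param generead_min_family,generead_min_families the UMI family gate.
#' @param amplicon_min_depth,amplicon_min_var_reads,amplicon_min_confidence
#'   the binomial caller gates.
#' @param snp_sr_pct,indel_sr_pct supporting-read percent thresholds for the
#'   amplicon caller.
#' @param ckv_snp_sr_pct,ckv_indel_sr_pct relaxed check-known-variants
#'   thresholds for consensus reads.
#' @param single_base_indel_as_snv treat 1-bp indels as SNVs for %SR gates.
#' @return an object of class `caller_thresholds`.
#' @export
caller_thresholds <- function(dnaseq_min_family = 5L,
                              dnaseq_min_families = 2L,
                              dnaseq_consistency = 0.95,
                              generead_min_family = 3L,
                              generead_min_families = 2L,
                              amplicon_min_depth = 10L,
                              amplicon_min_var_reads = 2L,
                              amplicon_min_confidence = 50,
                              snp_sr_pct = 0.3,
                              indel_sr_pct = 0.2,
                              ckv_snp_sr_pct = 0.4,
                              ckv_indel_sr_pct = 0.2,
                              single_base_indel_as_snv = FALSE) {
  vals <- mget(names(formals()))
  counts <- c(dnaseq_min_family, dnaseq_min_families, generead_min_family,
              generead_min_families, amplicon_min_depth,
              amplicon_min_var_reads)
  if (any(counts < 1) || any(counts != round(counts)))
    stop_config("count thresholds must be positive integers")
  pcts <- c(snp_sr_pct, indel_sr_pct, ckv_snp_sr_pct, ckv_indel_sr_pct)
  if (any(pcts <= 0) || any(pcts >= 100))
    stop_config("%SR thresholds must lie in (0, 100)")
  if (dnaseq_consistency <= 0 || dnaseq_consistency >= 1)
    stop_config("dnaseq_consistency must lie in (0, 1)")
  structure(vals, class = "caller_thresholds")
}

## %SR threshold applicable to a variant type under a threshold set.
sr_threshold <- function(variant_type, thresholds, ckv = FALSE) {
  snv <- if (ckv) thresholds$ckv_snp_sr_pct else thresholds$snp_sr_pct
  indel <- if (ckv) thresholds$ckv_indel_sr_pct else thresholds$indel_sr_pct
  switch(variant_type,
         SNV = snv,
         multi_base_indel = indel,
         single_base_indel = if (thresholds$single_base_indel_as_snv) snv
                             else indel,
         stop_input("unknown variant_type: ", variant_type))
}

## Builds the family table from reads given key columns.
build_families <- function(reads, key_cols) {
  if (nrow(reads) == 0) {
    fam <- data.frame(chrom = character(), start = integer(),
                      end = integer(), umi = character(), size = integer(),
                      n_ref = integer(), n_alt = integer(),
                      n_other = integer(), consensus = character(),
                      consistency = double(), stringsAsFactors = FALSE)
    return(fam)
  }
  key <- factor(do.call(paste, c(reads[key_cols], sep = "\r")))
  allele <- factor(reads$allele, levels = c("ref", "alt", "other"))
  counts <- table(key, allele)
  first <- match(levels(key), key)
  size <- as.integer(rowSums(counts))
  top_idx <- max.col(counts, ties.method = "first")
  top <- counts[cbind(seq_along(size), top_idx)]
  ## strict majority: the modal allele must exceed half the family
  consensus <- ifelse(top > size / 2, colnames(counts)[top_idx],
                      NA_character_)
  fam <- data.frame(chrom = reads$chrom[first], start = reads$start[first],
                    end = reads$end[first],
                    umi = if ("umi" %in% key_cols) reads$umi[first]
                          else NA_character_,
                    size = size,
                    n_ref = as.integer(counts[, "ref"]),
                    n_alt = as.integer(counts[, "alt"]),
                    n_other = as.integer(counts[, "other"]),
                    consensus = consensus,
                    consistency = as.numeric(top) / size,
                    stringsAsFactors = FALSE, row.names = NULL)
  fam[order(fam$start, fam$end, fam$umi, method = "radix",
            na.last = TRUE), , drop = FALSE]
}

#' Group reads into positional (endogenous-UMI) families
#'
#' Reads with identical alignment start and end positions are assumed to
#' derive from the same cfDNA molecule; the (start, end) pair serves as an
#' endogenous UMI. The families partition the input reads exactly.
#'
#' @param reads read table (all on one chromosome).
#' @return a data frame of families: coordinates, `size`, allele counts,
#'   `consensus` (strict-majority allele, `NA` on ties) and `consistency`
#'   (modal-allele fraction).
#' @export
group_positional_families <- function(reads) {
  if (nrow(reads) > 0 && length(unique(reads$chrom)) != 1)
    stop_input("reads span multiple chromosomes: ",
               paste(unique(reads$chrom), collapse = ", "))
  build_families(reads, c("start", "end"))
}

#' Group reads into tagged-UMI families
#'
#' Family key is (chrom, start, end, UMI): the same UMI at different
#' coordinates is two distinct molecules.
#'
#' @param reads read table; every read must carry a UMI.
#' @return family data frame as for [group_positional_families()].
#' @export
group_umi_families <- function(reads) {
  if (nrow(reads) > 0 && length(unique(reads$chrom)) != 1)
    stop_input("reads span multiple chromosomes: ",
               paste(unique(reads$chrom), collapse = ", "))
  missing <- which(is.na(reads$umi) | reads$umi == "" | reads$umi == ".")
  if (length(missing))
    stop_input("read ", missing[1], " has no UMI tag")
  build_families(reads, c("start", "end", "umi"))
}

new_plasma_call <- function(sample_id, procedure, detected, reason,
                            depth = NA_integer_, supporting = NA_integer_,
                            supporting_families = NA_integer_,
                            confidence = NA_real_) {
  sr <- if (!is.na(depth) && depth > 0) 100 * supporting / depth else NA_real_
  structure(list(sample_id = sample_id, procedure = procedure,
                 depth = depth, supporting = supporting, sr_pct = sr,
                 supporting_families = supporting_families,
                 confidence = confidence,
                 detected = detected,
                 reason = if (detected) "" else reason),
            class = "plasma_call")
}

#' @export
print.plasma_call <- function(x, ...) {
  cat(sprintf("plasma call [%s/%s]: %s\n", x$sample_id, x$procedure,
              if (x$detected) "DETECTED" else
                paste0("not detected (", x$reason, ")")))
  cat(sprintf("  depth %s, supporting %s (%s%%), families %s, confidence %s\n",
              x$depth, x$supporting,
              if (is.na(x$sr_pct)) "NA" else formatC(x$sr_pct, digits = 4),
              x$supporting_families,
              if (is.na(x$confidence)) "NA" else
                formatC(x$confidence, digits = 4)))
  invisible(x)
}

#' Positional-family consensus caller
#'
#' The variant is called when at least `dnaseq_min_families` families of
#' size >= `dnaseq_min_family` have the variant as consensus with strictly
#' more than `dnaseq_consistency` of their reads supporting it. A family of
#' 20 reads with 19 variant reads (exactly 95%) therefore does not qualify.
#'
#' @param families output of [group_positional_families()].
#' @param thresholds a [caller_thresholds()] object.
#' @param sample_id sample identifier for the call record.
#' @return a `plasma_call`.
#' @export
call_dnaseq_positional <- function(families,
                                   thresholds = caller_thresholds(),
                                   sample_id = "S1") {
  if (nrow(families) == 0)
    return(new_plasma_call(sample_id, "dnaseq_positional", FALSE,
                           "no_families", depth = 0L, supporting = 0L,
                           supporting_families = 0L))
  qual <- !is.na(families$consensus) & families$consensus == "alt" &
    families$size >= thresholds$dnaseq_min_family &
    families$consistency > thresholds$dnaseq_consistency
  nq <- sum(qual)
  new_plasma_call(sample_id, "dnaseq_positional",
                  detected = nq >= thresholds$dnaseq_min_families,
                  reason = "insufficient_families",
                  depth = sum(families$size),
                  supporting = sum(families$n_alt),
                  supporting_families = nq)
}

#' Collapse UMI families to consensus reads
#'
#' Each family of at least `min_size` reads is replaced by one consensus
#' read carrying its strict-majority allele. Families with no strict
#' majority (ties) carry no evidence and are dropped; the dropped count is
#' returned as an attribute.
#'
#' @param families family data frame.
#' @param min_size minimum family size to emit a consensus read.
#' @return data frame of consensus reads (one per kept family) with
#'   attributes `n_dropped_tie` and `n_dropped_small`.
#' @export
collapse_consensus <- function(families, min_size = 1L) {
  big <- families$size >= min_size
  tie <- is.na(families$consensus)
  keep <- families[big & !tie, , drop = FALSE]
  out <- data.frame(chrom = keep$chrom, start = keep$start, end = keep$end,
                    umi = keep$umi, allele = keep$consensus,
                    family_size = keep$size, stringsAsFactors = FALSE)
  attr(out, "n_dropped_tie") <- sum(big & tie)
  attr(out, "n_dropped_small") <- sum(!big)
  out
}

#' Tag-seq check-known-variants caller on consensus reads
#'
#' Detection when the consensus supporting-read percentage reaches the
#' relaxed CKV thresholds: 0.4% for SNVs, 0.2% for indels spanning multiple
#' bases (both inclusive).
#'
#' @param consensus_reads output of [collapse_consensus()].
#' @param variant_type variant class of the queried variant.
#' @param thresholds a [caller_thresholds()] object.
#' @param sample_id sample identifier.
#' @return a `plasma_call`.
#' @export
call_tagseq_ckv <- function(consensus_reads,
                            variant_type = "SNV",
                            thresholds = caller_thresholds(),
                            sample_id = "S1") {
  depth <- nrow(consensus_reads)
  if (depth == 0)
    return(new_plasma_call(sample_id, "tagseq_ckv", FALSE, "no_depth",
                           depth = 0L, supporting = 0L))
  supp <- sum(consensus_reads$allele == "alt")
  thr <- sr_threshold(variant_type, thresholds, ckv = TRUE)
  new_plasma_call(sample_id, "tagseq_ckv",
                  detected = 100 * supp / depth >= thr,
                  reason = "sr_below_threshold",
                  depth = depth, supporting = supp)
}

#' UMI family-support caller
#'
#' Detection when at least `generead_min_families` UMI families of size
#' >= `generead_min_family` have the variant as their consensus allele.
#'
#' @inheritParams call_tagseq_ckv
#' @param families output of [group_umi_families()].
#' @return a `plasma_call`.
#' @export
call_generead <- function(families, thresholds = caller_thresholds(),
                          sample_id = "S1") {
  if (nrow(families) == 0)
    return(new_plasma_call(sample_id, "generead", FALSE, "no_families",
                           depth = 0L, supporting = 0L,
                           supporting_families = 0L))
  qual <- !is.na(families$consensus) & families$consensus == "alt" &
    families$size >= thresholds$generead_min_family
  nq <- sum(qual)
  new_plasma_call(sample_id, "generead",
                  detected = nq >= thresholds$generead_min_families,
                  reason = "insufficient_families",
                  depth = sum(families$size),
                  supporting = sum(families$n_alt),
                  supporting_families = nq)
}

#' Phred-scaled binomial confidence score
#'
#' \eqn{-10 \log_{10} P(X \ge k)} for \eqn{X \sim Binom(n, p_0)}: the
#' upper-tail probability of seeing at least the observed number of variant
#' reads under the null error rate, on the Phred scale. A score of 50
#' corresponds to a tail probability of 1e-5. This is a reconstruction of
#' a proprietary caller's score, not its published formula.
#'
#' @param n_var observed variant reads.
#' @param depth read depth.
#' @param error_rate_null per-read null error probability.
#' @return confidence score (Phred-scaled upper-tail p-value).
#' @export
binomial_confidence <- function(n_var, depth, error_rate_null = 0.001) {
  if (n_var == 0) return(0)
  tail <- stats::pbinom(n_var - 1, depth, error_rate_null, lower.tail = FALSE)
  -10 * log10(tail)
}

#' Amplicon binomial caller
#'
#' Detection requires, jointly: depth >= 10 reads, >= 2 variant reads,
#' %SR >= 0.3 for SNVs / >= 0.2 for multi-base indels, and confidence
#' score >= 50. Gates are evaluated in that order and the first failing
#' gate is reported as the reason.
#'
#' @param reads read table spanning the locus (amplicon chemistry).
#' @param variant_type variant class of the queried variant.
#' @param error_rate_null null per-read error rate for the confidence score.
#' @param thresholds a [caller_thresholds()] object.
#' @param sample_id sample identifier.
#' @return a `plasma_call` with the confidence score filled in.
#' @export
call_amplicon <- function(reads, variant_type = "SNV",
                          error_rate_null = 0.001,
                          thresholds = caller_thresholds(),
                          sample_id = "S1") {
  depth <- nrow(reads)
  supp <- sum(reads$allele == "alt")
  conf <- if (depth > 0) binomial_confidence(supp, depth, error_rate_null)
          else NA_real_
  thr <- sr_threshold(variant_type, thresholds, ckv = FALSE)
  reason <-
    if (depth < thresholds$amplicon_min_depth) "insufficient_depth"
    else if (supp < thresholds$amplicon_min_var_reads) "insufficient_var_reads"
    else if (100 * supp / depth < thr) "sr_below_threshold"
    else if (conf < thresholds$amplicon_min_confidence) "low_confidence"
    else ""
  new_plasma_call(sample_id, "amplicon", detected = reason == "",
                  reason = reason, depth = depth, supporting = supp,
                  confidence = conf)
}

#' Run one detection procedure end to end on a read table
#'
#' Convenience wrapper grouping reads as the procedure requires and applying
#' its caller.
#'
#' @param reads read table at the queried locus.
#' @param procedure one of `"dnaseq_positional"`, `"tagseq_ckv"`,
#'   `"generead"`, `"amplicon"`.
#' @param variant_type variant class.
#' @param thresholds a [caller_thresholds()] object.
#' @param sample_id sample identifier.
#' @param error_rate_null null error rate (amplicon only).
#' @return a `plasma_call`.
#' @export
call_variant <- function(reads,
                         procedure = c("dnaseq_positional", "tagseq_ckv",
                                       "generead", "amplicon"),
                         variant_type = "SNV",
                         thresholds = caller_thresholds(),
                         sample_id = "S1",
                         error_rate_null = 0.001) {
  procedure <- match.arg(procedure)
  switch(procedure,
    dnaseq_positional = call_dnaseq_positional(
      group_positional_families(reads), thresholds, sample_id),
    tagseq_ckv = call_tagseq_ckv(
      collapse_consensus(group_umi_families(reads), min_size = 1L),
      variant_type, thresholds, sample_id),
    generead = call_generead(group_umi_families(reads), thresholds, sample_id),
    amplicon = call_amplicon(reads, variant_type, error_rate_null,
                             thresholds, sample_id))
}
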