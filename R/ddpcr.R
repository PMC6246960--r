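## Droplet digital PCR quantification.
##
## A ddPCR reaction partitions the cfDNA template into ~10^4 droplets, each
## scored positive or negative for the mutant and wild-type probes. Under the
## Poisson partition model the mean number of target molecules per droplet is
## lambda = -ln(1 - p) where p is the fraction of positive droplets, so the
## total number of template molecules in the reaction is lambda * n_droplets
## and the concentration is lambda / droplet_volume.

#' Poisson concentration estimate from droplet counts
#'
#' Converts a positive-droplet count into a target concentration in copies
#' per microliter of reaction, using the Poisson partition correction
#' \eqn{\lambda = -\ln(1 - n_{pos}/n_{total})}.
#'
#' @param n_pos number of positive droplets.
#' @param n_total total droplet count (must be positive).
#' @param droplet_volume_nl droplet volume in nanoliters (default 0.85 nL,
#'   the QX200 convention; the value cancels out of any allele-frequency
#'   ratio, so it only matters for absolute concentrations).
#' @return copies per microliter of reaction.
#' @examples
#' poisson_copies(1000, 20000)            # ~60.3 copies/uL
#' poisson_copies(0, 10000)               # 0
#' @export
poisson_copies <- function(n_pos, n_total, droplet_volume_nl = 0.85) {
  if (length(n_total) != 1 || n_total <= 0)
    stop_input("n_total must be a positive droplet count")
  if (n_pos < 0 || n_pos > n_total)
    stop_input("n_pos must lie in [0, n_total]")
  if (droplet_volume_nl <= 0)
    stop_config("droplet_volume_nl must be strictly positive")
  if (n_pos == n_total)
    stop_input("all ", n_total, " droplets positive: reaction saturated, ",
               "concentration not estimable")
  lambda <- -log(1 - n_pos / n_total)
  lambda / (droplet_volume_nl * 1e-3)
}

#' Droplet count record for one sample/assay
#'
#' Bundles classified droplet counts with the physical scaling constants
#' needed to express copies per mL of plasma: the droplet volume, the
#' fraction of the cfDNA elution loaded into the reaction, and the plasma
#' volume extracted.
#'
#' @param sample_id sample identifier.
#' @param assay assay name.
#' @param n_total total droplets.
#' @param n_mut_pos droplets positive for the mutant probe.
#' @param n_wt_pos droplets positive for the wild-type probe.
#' @param droplet_volume_nl droplet volume (nL).
#' @param reaction_fraction_of_elution fraction of the extracted cfDNA
#'   loaded into this reaction, in (0, 1].
#' @param plasma_ml_extracted plasma volume (mL) the cfDNA came from.
#' @return an object of class `droplet_data`.
#' @export
droplet_data <- function(sample_id, assay, n_total, n_mut_pos, n_wt_pos,
                         droplet_volume_nl = 0.85,
                         reaction_fraction_of_elution = 1,
                         plasma_ml_extracted = 1) {
  if (n_total < 0 || n_mut_pos < 0 || n_wt_pos < 0 ||
      n_mut_pos > n_total || n_wt_pos > n_total)
    stop_input("droplet counts must satisfy 0 <= n_mut_pos, n_wt_pos <= n_total")
  if (droplet_volume_nl <= 0 || reaction_fraction_of_elution <= 0 ||
      plasma_ml_extracted <= 0)
    stop_config("volumes and fractions must be strictly positive")
  structure(list(sample_id = sample_id, assay = assay, n_total = n_total,
                 n_mut_pos = n_mut_pos, n_wt_pos = n_wt_pos,
                 droplet_volume_nl = droplet_volume_nl,
                 reaction_fraction_of_elution = reaction_fraction_of_elution,
                 plasma_ml_extracted = plasma_ml_extracted),
            class = "droplet_data")
}

#' Quantify ctDNA in one sample from droplet counts
#'
#' Estimates mutant and wild-type template numbers by the Poisson partition
#' correction (molecules in reaction = lambda x droplets), scales them from
#' the reaction to the full elution and then per mL of plasma, and computes
#' the mutant allele frequency from the two concentrations. Detection uses
#' the stringent MAF threshold of 0.03% (inclusive), which at the study's
#' median cfDNA yield of ~22 ng/mL corresponds to 2 mutant copies/mL plasma.
#'
#' @param d a [droplet_data()] object.
#' @param threshold_maf_pct detection threshold on MAF, percent.
#' @return an object of class `ctdna_quant`: a list with `sample_id`,
#'   `mut_copies_per_ml_plasma`, `wt_copies_per_ml_plasma`, `maf_pct`,
#'   `detected`, `representative` (set later by [representative_mutation()]).
#' @export
quantify_sample <- function(d, threshold_maf_pct = 0.03) {
  stopifnot(inherits(d, "droplet_data"))
  lam_mut <- if (d$n_mut_pos == d$n_total)
    stop_input("mutant channel saturated for sample ", d$sample_id)
  else -log(1 - d$n_mut_pos / d$n_total)
  lam_wt <- if (d$n_wt_pos == d$n_total)
    stop_input("wild-type channel saturated for sample ", d$sample_id)
  else -log(1 - d$n_wt_pos / d$n_total)
  mut_in_rxn <- lam_mut * d$n_total
  wt_in_rxn <- lam_wt * d$n_total
  scale <- 1 / (d$reaction_fraction_of_elution * d$plasma_ml_extracted)
  maf <- if (mut_in_rxn + wt_in_rxn == 0) 0 else
    100 * mut_in_rxn / (mut_in_rxn + wt_in_rxn)
  structure(list(sample_id = d$sample_id,
                 assay = d$assay,
                 mut_copies_per_ml_plasma = mut_in_rxn * scale,
                 wt_copies_per_ml_plasma = wt_in_rxn * scale,
                 maf_pct = maf,
                 detected = maf >= threshold_maf_pct,
                 representative = FALSE),
            class = "ctdna_quant")
}

#' @export
print.ctdna_quant <- function(x, ...) {
  cat(sprintf("ctDNA quant [%s] MAF %.4f%%  mutant %.2f cp/mL  %s%s\n",
              x$sample_id, x$maf_pct, x$mut_copies_per_ml_plasma,
              if (x$detected) "DETECTED" else "not detected",
              if (isTRUE(x$representative)) " (representative)" else ""))
  invisible(x)
}

#' Convert cfDNA yield and MAF to mutant copies per mL plasma
#'
#' Copies/mL = (yield_ng_per_ml x 1000 / pg_per_genome) x maf_pct / 100.
#' With the haploid genome mass fixed at 3.3 pg (~303 genome
#' equivalents/ng), a median yield of 22 ng/mL at the 0.03% detection
#' threshold corresponds to 2 mutant copies/mL plasma.
#'
#' @param yield_ng_per_ml cfDNA yield in ng per mL plasma.
#' @param maf_pct mutant allele frequency, percent.
#' @param pg_per_genome haploid genome-equivalent mass in picograms.
#' @return mutant copies per mL plasma.
#' @examples
#' copies_per_ml_from_yield(22, 0.03)   # 2 cp/mL
#' @export
copies_per_ml_from_yield <- function(yield_ng_per_ml, maf_pct,
                                     pg_per_genome = 3.3) {
  if (any(pg_per_genome <= 0))
    stop_config("pg_per_genome must be strictly positive")
  if (any(yield_ng_per_ml < 0) || any(maf_pct < 0))
    stop_input("yield and MAF must be non-negative")
  (yield_ng_per_ml * 1000 / pg_per_genome) * maf_pct / 100
}

#' Read a droplet-count table and quantify every row
#'
#' The droplet CSV carries one row per sample x assay with columns
#' sample_id, assay, n_total, n_mut_pos, n_wt_pos and optionally
#' droplet_volume_nl, reaction_fraction, plasma_ml (defaults 0.85 / 1 / 1).
#'
#' @param path droplet CSV path.
#' @return data frame of droplet counts.
#' @export
read_droplet_table <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay", "n_total", "n_mut_pos", "n_wt_pos")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop_input("droplet CSV lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(d$droplet_volume_nl)) d$droplet_volume_nl <- 0.85
  if (is.null(d$reaction_fraction)) d$reaction_fraction <- 1
  if (is.null(d$plasma_ml)) d$plasma_ml <- 1
  d
}

#' @rdname read_droplet_table
#' @param droplets droplet data frame as returned by `read_droplet_table()`.
#' @param threshold_maf_pct detection threshold on MAF, percent.
#' @return `quantify_droplet_table()` returns a data frame with one
#'   `ctdna_quant` row per input row plus a `representative` flag marking
#'   each sample's highest-MAF assay.
#' @export
quantify_droplet_table <- function(droplets, threshold_maf_pct = 0.03) {
  quants <- lapply(seq_len(nrow(droplets)), function(i) {
    d <- droplets[i, ]
    quantify_sample(droplet_data(d$sample_id, d$assay, d$n_total,
                                 d$n_mut_pos, d$n_wt_pos,
                                 d$droplet_volume_nl, d$reaction_fraction,
                                 d$plasma_ml),
                    threshold_maf_pct)
  })
  out <- data.frame(
    sample_id = vapply(quants, `[[`, "", "sample_id"),
    assay = vapply(quants, function(q) as.character(q$assay), ""),
    maf_pct = vapply(quants, `[[`, 0, "maf_pct"),
    mut_copies_per_ml_plasma = vapply(quants, `[[`, 0,
                                      "mut_copies_per_ml_plasma"),
    wt_copies_per_ml_plasma = vapply(quants, `[[`, 0,
                                     "wt_copies_per_ml_plasma"),
    detected = vapply(quants, `[[`, TRUE, "detected"),
    representative = FALSE, stringsAsFactors = FALSE)
  for (sid in unique(out$sample_id)) {
    rows <- which(out$sample_id == sid)
    rep_row <- representative_mutation(quants[rows])
    out$representative[rows[out$assay[rows] == rep_row$assay][1]] <- TRUE
  }
  out
}

#' Representative mutation for a sample
#'
#' The ctDNA level of a sample is represented by its mutation with the
#' highest mutant allele frequency. Ties are broken deterministically by
#' assay/locus order (lexicographically first label wins).
#'
#' @param quants non-empty list of `ctdna_quant` objects for one sample.
#' @return the selected `ctdna_quant`, with `representative = TRUE`.
#' @export
representative_mutation <- function(quants) {
  if (length(quants) == 0) stop_input("no quantifications supplied")
  sid <- unique(vapply(quants, `[[`, "", "sample_id"))
  if (length(sid) != 1)
    stop_input("representative_mutation expects a single sample, got: ",
               paste(sid, collapse = ", "))
  mafs <- vapply(quants, `[[`, 0, "maf_pct")
  labels <- vapply(quants, function(q) as.character(q$assay %||% ""), "")
  best <- which(mafs == max(mafs))
  pick <- best[order(labels[best])][1]
  out <- quants[[pick]]
  out$representative <- TRUE
  out
}
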