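## End-to-end pipeline driver: simulate -> call -> quantify -> concord ->
## survive. Every intermediate table is written to the output directory and
## a manifest records the seed, configuration hash and filter attrition, so
## any stage can be re-run from its written inputs.

## Deterministic seed fan-out: each stage draws from its own stream derived
## from the master seed by fixed offsets (kept well below 2^31).
stage_seed <- function(seed, stage, i = 0L) {
  offsets <- c(cohort = 100000L, droplets = 200000L, reads = 300000L,
               survival = 400000L)
  (seed + offsets[[stage]] + i) %% .Machine$integer.max
}

## Simulates one ddPCR reaction for a variant given true MAF and the
## wild-type template load implied by the cfDNA yield.
simulate_droplets <- function(sample_id, assay, true_maf_pct,
                              yield_ng_per_ml, config, seed) {
  set.seed(seed)
  total_copies_per_ml <- yield_ng_per_ml * 1000 / config$pg_per_genome
  in_reaction <- total_copies_per_ml * config$plasma_ml *
    config$reaction_fraction
  mut <- in_reaction * true_maf_pct / 100
  wt <- in_reaction - mut
  lam_mut <- mut / config$n_droplets
  lam_wt <- wt / config$n_droplets
  n_mut_pos <- stats::rbinom(1, config$n_droplets, 1 - exp(-lam_mut))
  n_wt_pos <- stats::rbinom(1, config$n_droplets, 1 - exp(-lam_wt))
  ## a fully saturated channel cannot be quantified; back off one droplet,
  ## the standard bench workaround of a diluted re-run is out of scope
  n_mut_pos <- min(n_mut_pos, config$n_droplets - 1L)
  n_wt_pos <- min(n_wt_pos, config$n_droplets - 1L)
  droplet_data(sample_id, assay, config$n_droplets, n_mut_pos, n_wt_pos,
               droplet_volume_nl = config$droplet_volume_nl,
               reaction_fraction_of_elution = config$reaction_fraction,
               plasma_ml_extracted = config$plasma_ml)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort, assays each tumor variant in plasma on its sample's
#' platform(s) (ddPCR droplet quantification and/or tagged-UMI NGS with the
#' check-known-variants caller), tabulates tumor-plasma concordance,
#' quantifies representative ctDNA copies/mL, simulates survival from the
#' generating prognostic groups, re-estimates the cut point with the
#' maximally selected log-rank statistic and emits the three-group survival
#' report.
#'
#' @param config a [pipeline_config()] object.
#' @param outdir output directory (created if missing); `NULL` to skip
#'   writing files.
#' @return an object of class `ctdna_pipeline`: list with `cohort`,
#'   `quants`, `calls`, `concordance`, `summary`, `cross_platform`,
#'   `profile`, `cutpoint`, `groups`, `survival`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(cohort_params(
    n_patients = config$n_patients,
    seed = stage_seed(config$seed, "cohort")))
  sheet <- cohort$sample_sheet
  if (nrow(sheet) == 0) stop_input("empty cohort")
  set.seed(stage_seed(config$seed, "cohort", 1L))
  sheet$platform <- draw_categories(nrow(sheet), config$platform_mix)

  truth <- cohort$true_plasma_maf
  variants <- cohort$tumor_variants
  quant_rows <- list()
  call_rows <- list()
  records <- list()
  per_sample_cp <- numeric(nrow(sheet))
  per_sample_det <- logical(nrow(sheet))
  ddpcr_status <- list()
  ngs_status <- list()

  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    sv <- variants[variants$sample_id == sid, , drop = FALSE]
    tm <- truth$maf_pct[match(sv$variant_id, truth$variant_id)]
    platform <- sheet$platform[i]
    results <- list()
    best_maf <- 0
    if (platform %in% c("ddPCR", "both")) {
      qs <- lapply(seq_len(nrow(sv)), function(j) {
        d <- simulate_droplets(sid, sv$variant_id[j], tm[j],
                               sheet$yield_ng_per_ml[i], config,
                               stage_seed(config$seed, "droplets",
                                          i * 10L + j))
        q <- quantify_sample(d, config$threshold_maf_pct)
        q$variant_id <- sv$variant_id[j]
        q
      })
      results <- c(results, qs)
      quant_rows[[length(quant_rows) + 1L]] <- data.frame(
        sample_id = sid, variant_id = sv$variant_id,
        platform = "ddPCR",
        maf_pct = vapply(qs, `[[`, 0, "maf_pct"),
        mut_copies_per_ml = vapply(qs, `[[`, 0, "mut_copies_per_ml_plasma"),
        detected = vapply(qs, `[[`, TRUE, "detected"),
        stringsAsFactors = FALSE)
      ddpcr_status[[length(ddpcr_status) + 1L]] <- data.frame(
        sample_id = sid, detected = any(vapply(qs, `[[`, TRUE, "detected")),
        stringsAsFactors = FALSE)
      best_maf <- max(best_maf,
                      vapply(qs, function(q)
                        if (q$detected) q$maf_pct else 0, 0))
    }
    if (platform %in% c("NGS", "both")) {
      cs <- lapply(seq_len(nrow(sv)), function(j) {
        rp <- read_sim_params(chrom = sv$chrom[j], pos = sv$pos[j],
                              ref = sv$ref[j], alt = sv$alt[j],
                              variant_type = sv$variant_type[j],
                              n_molecules = config$ngs_molecules,
                              maf_molecular = tm[j],
                              chemistry = "tagged_umi",
                              seed = stage_seed(config$seed, "reads",
                                                i * 10L + j))
        sim <- simulate_read_families(rp, sample_id = sid)
        cl <- call_variant(sim$reads, "tagseq_ckv",
                           variant_type = sv$variant_type[j],
                           thresholds = config$thresholds, sample_id = sid)
        cl$variant_id <- sv$variant_id[j]
        cl$measured_maf <- cl$sr_pct %||% NA_real_
        cl
      })
      results <- c(results, cs)
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        sample_id = sid, variant_id = sv$variant_id,
        procedure = "tagseq_ckv",
        depth = vapply(cs, `[[`, 0L, "depth"),
        supporting = vapply(cs, `[[`, 0L, "supporting"),
        sr_pct = vapply(cs, function(x) x$sr_pct %||% NA_real_, 0),
        detected = vapply(cs, `[[`, TRUE, "detected"),
        reason = vapply(cs, `[[`, "", "reason"),
        stringsAsFactors = FALSE)
      ngs_status[[length(ngs_status) + 1L]] <- data.frame(
        sample_id = sid, detected = any(vapply(cs, `[[`, TRUE, "detected")),
        stringsAsFactors = FALSE)
      best_maf <- max(best_maf,
                      vapply(cs, function(cl)
                        if (cl$detected) cl$sr_pct else 0, 0))
    }
    rec <- evaluate_sample(sv, results,
                           sample_info = list(stage = sheet$stage[i],
                                              tissue = sheet$tissue[i],
                                              platform = platform))
    records[[i]] <- rec
    per_sample_det[i] <- rec$concordant
    per_sample_cp[i] <- copies_per_ml_from_yield(sheet$yield_ng_per_ml[i],
                                                 best_maf,
                                                 config$pg_per_genome)
  }

  records <- do.call(rbind, records)
  conc_summary <- summarize_concordance(records)
  cross <- if (length(ddpcr_status) && length(ngs_status)) {
    a <- do.call(rbind, ddpcr_status)
    b <- do.call(rbind, ngs_status)
    if (length(intersect(a$sample_id, b$sample_id)))
      cross_platform_agreement(a, b) else NULL
  } else NULL
  profile <- tumor_profile_summary(variants)

  quants <- data.frame(sample_id = sheet$sample_id,
                       detected = per_sample_det,
                       ctdna_copies_per_ml = ifelse(per_sample_det,
                                                    per_sample_cp, 0),
                       stringsAsFactors = FALSE)

  ## survival truth: generating groups from the configured cut point
  true_groups <- stratify_ctdna(quants, config$true_cutpoint_cp_ml)
  surv <- simulate_survival(true_groups, survival_sim_params(
    group_hazards = config$group_hazards,
    seed = stage_seed(config$seed, "survival")))

  det <- quants$detected & quants$ctdna_copies_per_ml > 0
  cutpoint <- if (identical(config$cutpoint, "auto")) {
    if (sum(det) >= 10 &&
        length(unique(quants$ctdna_copies_per_ml[det])) >= 2) {
      idx <- match(quants$sample_id[det], surv$sample_id)
      maxstat_cutpoint(quants$ctdna_copies_per_ml[det],
                       surv$time_days[idx], surv$event[idx],
                       config$min_group_fraction)$cutpoint
    } else config$true_cutpoint_cp_ml
  } else as.numeric(config$cutpoint)

  groups <- stratify_ctdna(quants, cutpoint)
  surv$group <- unname(groups[surv$sample_id])
  report <- survival_report(surv, cutpoint = cutpoint)

  manifest <- list(seed = config$seed,
                   n_patients = config$n_patients,
                   n_variants = nrow(variants),
                   n_detected_samples = sum(per_sample_det),
                   cutpoint = cutpoint,
                   stage_counts = as.list(table(sheet$stage)),
                   platform_counts = as.list(table(sheet$platform)))

  out <- structure(list(cohort = cohort, sheet = sheet,
                        quants = quants,
                        calls = if (length(call_rows))
                          do.call(rbind, call_rows) else NULL,
                        ddpcr_quants = if (length(quant_rows))
                          do.call(rbind, quant_rows) else NULL,
                        concordance = records, summary = conc_summary,
                        cross_platform = cross, profile = profile,
                        cutpoint = cutpoint, groups = groups,
                        survival = surv, report = report,
                        manifest = manifest),
                   class = "ctdna_pipeline")
  if (!is.null(outdir)) write_pipeline(out, config, outdir)
  out
}

write_pipeline <- function(x, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  utils::write.csv(x$sheet, p("sample_sheet.csv"), row.names = FALSE)
  write_variant_table(x$cohort$tumor_variants, p("tumor_variants.vcf"))
  write_variant_table(x$cohort$tumor_variants, p("tumor_variants.csv"),
                      dialect = "csv")
  utils::write.csv(x$quants, p("ctdna_quants.csv"), row.names = FALSE)
  if (!is.null(x$calls))
    utils::write.csv(x$calls, p("plasma_calls.csv"), row.names = FALSE)
  if (!is.null(x$ddpcr_quants))
    utils::write.csv(x$ddpcr_quants, p("ddpcr_quants.csv"), row.names = FALSE)
  utils::write.csv(x$concordance, p("concordance_records.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(x$summary), p("concordance_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(x$survival, p("survival.csv"), row.names = FALSE)
  km <- do.call(rbind, lapply(names(x$report$curves), function(g)
    cbind(group = g, summary(x$report$curves[[g]]))))
  utils::write.csv(km, p("km_curves.csv"), row.names = FALSE)
  cfg_path <- p("config.yaml")
  save_config(config, cfg_path)
  manifest <- c(x$manifest,
                list(config_md5 = unname(tools::md5sum(cfg_path)),
                     package_version =
                       as.character(utils::packageVersion("ctdnaconcord"))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  sink(p("report.txt")); on.exit(sink())
  print(x$summary)
  if (!is.null(x$cross_platform))
    cat(sprintf("Cross-platform: %d/%d agree (%.2f%%)\n",
                x$cross_platform$n_agree, x$cross_platform$n_shared,
                x$cross_platform$pct_agree))
  print(x$report)
  invisible(outdir)
}

#' @export
print.ctdna_pipeline <- function(x, ...) {
  cat(sprintf("ctDNA concordance pipeline: %d patients (seed %d)\n",
              nrow(x$sheet), x$manifest$seed))
  print(x$summary)
  if (!is.null(x$cross_platform))
    cat(sprintf("Cross-platform: %d/%d agree (%.2f%%)\n",
                x$cross_platform$n_agree, x$cross_platform$n_shared,
                x$cross_platform$pct_agree))
  cat(sprintf("Cut point: %.2f copies/mL plasma\n", x$cutpoint))
  print(x$report)
  invisible(x)
}
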