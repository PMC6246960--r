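## Synthetic cohort generator.
##
## Emulates the statistical structure of a matched tumor-plasma liquid
## biopsy study: a mix of tissues dominated by lung, an early/advanced
## stage split, 1-3 somatic mutations followable per tumor (mostly SNVs),
## stage-dependent cfDNA yield over roughly 7-405 ng/mL plasma, a
## stage-dependent probability that the tumor mutation is present in plasma
## at all, plasma MAF spanning ~0.28%-95% when present, and survival
## follow-up with administrative censoring at the end of a 27-month study
## window. Loci are abstract coordinates; there is no attempt at sequence
## context, clonality or FFPE artifacts.

MONTH_DAYS <- 30.44  # calendar-average convention for month -> day conversion

gene_pool <- function() {
  ## TP53-dominated frequencies, a generic pan-cancer hotspot profile.
  c(TP53 = 0.35, EGFR = 0.20, KRAS = 0.15, PIK3CA = 0.12, BRAF = 0.05,
    CTNNB1 = 0.04, APC = 0.04, NRAS = 0.02, ERBB2 = 0.02, FBXW7 = 0.01)
}

#' Cohort simulation parameters
#'
#' Defaults mirror the demographics and summaries of a 180-patient
#' pan-cancer liquid-biopsy cohort: tissue counts 93 lung / 42 breast /
#' 22 colorectal / 12 bladder / 9 ovarian / 1 esophageal / 1 sarcoma,
#' stage split 36 early / 133 advanced / 11 unknown, 59.18% of tumors with
#' a single followable mutation and 35.71% with 2-3, cfDNA yields within
#' 7.13-405 ng/mL plasma, plasma MAF 0.28%-94.7% for detectable samples,
#' and per-stage plasma detection probabilities of 0.32 (early) and 0.82
#' (advanced).
#'
#' @param n_patients cohort size.
#' @param tissue_mix named tissue proportions (must sum to 1).
#' @param stage_mix named proportions over early / advanced / unknown.
#' @param mutations_per_sample_dist named probabilities over mutation counts
#'   1, 2, 3, 4 (4 standing for ">3").
#' @param yield_range_ng_per_ml list of per-stage `(min, max)` cfDNA yield
#'   ranges (ng/mL plasma); yields are drawn log-uniformly within range.
#' @param maf_log_range `(min%, max%)` plasma MAF range for detectable
#'   samples; drawn log-uniformly.
#' @param detect_prob_by_stage named per-stage probability that the tumor's
#'   mutations are present in plasma at all.
#' @param variant_type_probs probabilities over SNV / multi-base indel /
#'   single-base indel.
#' @param seed integer seed.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 180L,
                          tissue_mix = c(Lung = 93, Breast = 42,
                                         Colorectal = 22, Bladder = 12,
                                         Ovarian = 9, Esophageal = 1,
                                         Sarcoma = 1) / 180,
                          stage_mix = c(early = 36, advanced = 133,
                                        unknown = 11) / 180,
                          mutations_per_sample_dist = c(`1` = 0.5918,
                                                        `2` = 0.1786,
                                                        `3` = 0.1785,
                                                        `4` = 0.0511),
                          yield_range_ng_per_ml = list(
                            early = c(7.13, 80),
                            advanced = c(15, 405),
                            unknown = c(7.13, 405)),
                          maf_log_range = c(0.28, 94.7),
                          detect_prob_by_stage = c(early = 0.32,
                                                   advanced = 0.82,
                                                   unknown = 0.71),
                          variant_type_probs = c(SNV = 0.85,
                                                 multi_base_indel = 0.09,
                                                 single_base_indel = 0.06),
                          seed = 1L) {
  check_proportion_map(tissue_mix, "tissue_mix")
  check_proportion_map(stage_mix, "stage_mix")
  check_proportion_map(mutations_per_sample_dist, "mutations_per_sample_dist")
  check_proportion_map(variant_type_probs, "variant_type_probs")
  if (!all(names(detect_prob_by_stage) %in% names(stage_mix)) ||
      any(detect_prob_by_stage < 0) || any(detect_prob_by_stage > 1))
    stop_config("detect_prob_by_stage must map stages to probabilities")
  for (st in names(yield_range_ng_per_ml)) {
    r <- yield_range_ng_per_ml[[st]]
    if (length(r) != 2 || r[1] <= 0 || r[2] < r[1])
      stop_config("yield_range_ng_per_ml[['", st,
                  "']] must be a positive (min, max) pair")
  }
  mean_logunif <- function(r) (r[2] - r[1]) / (log(r[2]) - log(r[1]))
  if (mean_logunif(yield_range_ng_per_ml$early) >
      mean_logunif(yield_range_ng_per_ml$advanced))
    stop_config("early-stage mean yield must not exceed advanced-stage mean")
  if (length(maf_log_range) != 2 || maf_log_range[1] <= 0 ||
      maf_log_range[2] > 100 || maf_log_range[2] < maf_log_range[1])
    stop_config("maf_log_range must be a (min%, max%) pair within (0, 100]")
  structure(list(n_patients = as.integer(n_patients),
                 tissue_mix = tissue_mix, stage_mix = stage_mix,
                 mutations_per_sample_dist = mutations_per_sample_dist,
                 yield_range_ng_per_ml = yield_range_ng_per_ml,
                 maf_log_range = maf_log_range,
                 detect_prob_by_stage = detect_prob_by_stage,
                 variant_type_probs = variant_type_probs,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Simulate a synthetic tumor-plasma cohort
#'
#' Draws, per patient: tissue, stage, cfDNA yield, 1-4 somatic tumor
#' mutations (gene, abstract locus, variant type, tumor MAF), whether the
#' mutations are detectable in plasma at the patient's stage, and — for
#' detectable patients — a log-uniform plasma MAF per mutation.
#' Deterministic for a fixed seed.
#'
#' @param params a [cohort_params()] object.
#' @return an object of class `synthetic_cohort`: a list with
#'   `sample_sheet`, `tumor_variants` and `true_plasma_maf` data frames.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_patients
  sheet_proto <- data.frame(sample_id = character(), tissue = character(),
                            stage = character(),
                            yield_ng_per_ml = double(),
                            plasma_detectable = logical(),
                            n_mutations = integer(), stringsAsFactors = FALSE)
  var_proto <- data.frame(sample_id = character(), variant_id = character(),
                          chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), protein_change = character(),
                          variant_type = character(), tumor_maf_pct = double(),
                          stringsAsFactors = FALSE)
  maf_proto <- data.frame(sample_id = character(), variant_id = character(),
                          maf_pct = double(), stringsAsFactors = FALSE)
  if (n == 0) {
    return(structure(list(sample_sheet = sheet_proto,
                          tumor_variants = var_proto,
                          true_plasma_maf = maf_proto, params = params),
                     class = "synthetic_cohort"))
  }
  sample_id <- sprintf("P%04d", seq_len(n))
  tissue <- draw_categories(n, params$tissue_mix)
  stage <- draw_categories(n, params$stage_mix)
  yield <- vapply(stage, function(st) {
    r <- params$yield_range_ng_per_ml[[st]]
    rlogunif(1, r[1], r[2])
  }, 0)
  n_mut <- as.integer(draw_categories(n, params$mutations_per_sample_dist))
  detectable <- stats::runif(n) < params$detect_prob_by_stage[stage]

  genes <- gene_pool()
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n)
  mafs <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_mut[i]
    g <- sample(names(genes), k, replace = FALSE, prob = genes)
    vt <- draw_categories(k, params$variant_type_probs)
    ref <- sample(bases, k, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    vid <- sprintf("%s_v%d", sample_id[i], seq_len(k))
    rows[[i]] <- data.frame(
      sample_id = sample_id[i], variant_id = vid,
      chrom = sample(paste0("chr", 1:22), k, replace = TRUE),
      pos = sample.int(2e8L, k),
      ref = ref, alt = alt, gene = g,
      protein_change = sprintf("p.%s%d%s", ref, sample.int(500L, k), alt),
      variant_type = vt,
      tumor_maf_pct = stats::runif(k, 5, 60),
      stringsAsFactors = FALSE)
    pm <- if (detectable[i])
      rlogunif(k, params$maf_log_range[1], params$maf_log_range[2])
    else rep(0, k)
    mafs[[i]] <- data.frame(sample_id = sample_id[i], variant_id = vid,
                            maf_pct = pm, stringsAsFactors = FALSE)
  }
  structure(list(
    sample_sheet = data.frame(sample_id = sample_id, tissue = tissue,
                              stage = stage, yield_ng_per_ml = yield,
                              plasma_detectable = detectable,
                              n_mutations = n_mut, stringsAsFactors = FALSE),
    tumor_variants = do.call(rbind, rows),
    true_plasma_maf = do.call(rbind, mafs),
    params = params), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients, %d tumor variants\n",
              nrow(x$sample_sheet), nrow(x$tumor_variants)))
  if (nrow(x$sample_sheet)) {
    cat("  stages:", paste(sprintf("%s=%d", names(table(x$sample_sheet$stage)),
                                   table(x$sample_sheet$stage)),
                           collapse = ", "), "\n")
    cat(sprintf("  plasma-detectable: %d (%.1f%%)\n",
                sum(x$sample_sheet$plasma_detectable),
                100 * mean(x$sample_sheet$plasma_detectable)))
  }
  invisible(x)
}

#' Survival simulation parameters
#'
#' Event times are exponential with a group-specific hazard;
#' administrative censoring is applied at the end of a study window of 27
#' months (converted at 30.44 days/month, i.e. ~822 days). Default hazards
#' put the high-ctDNA group at a median of ~208 days with the low and
#' not-detected groups at hazard ratios 0.2331 and 0.1875 relative to it,
#' the ordering the prognostic analysis expects.
#'
#' @param group_hazards named event rates per day for
#'   high / low / not_detected.
#' @param study_days administrative censoring horizon in days.
#' @param accrual_days patients enter uniformly on `[0, accrual_days]`;
#'   censoring applies at `study_days - entry`.
#' @param seed integer seed.
#' @return an object of class `survival_sim_params`.
#' @export
survival_sim_params <- function(group_hazards = c(high = 1 / 300,
                                                  low = 0.2331 / 300,
                                                  not_detected = 0.1875 / 300),
                                study_days = round(27 * MONTH_DAYS),
                                accrual_days = 0,
                                seed = 1L) {
  if (any(group_hazards <= 0))
    stop_config("group hazards must be strictly positive")
  if (study_days < 0 || accrual_days < 0)
    stop_config("study_days and accrual_days must be non-negative")
  structure(list(group_hazards = group_hazards,
                 study_days = study_days, accrual_days = accrual_days,
                 seed = as.integer(seed)),
            class = "survival_sim_params")
}

#' Simulate survival records for grouped samples
#'
#' @param groups named character vector: sample_id -> group label; every
#'   label must have a hazard in `params$group_hazards`.
#' @param params a [survival_sim_params()] object.
#' @return data frame of survival records: `sample_id`, `group`,
#'   `time_days`, `event` (1 = death observed, 0 = administratively
#'   censored).
#' @export
simulate_survival <- function(groups, params = survival_sim_params()) {
  stopifnot(inherits(params, "survival_sim_params"))
  if (length(groups) == 0)
    return(data.frame(sample_id = character(), group = character(),
                      time_days = double(), event = integer(),
                      stringsAsFactors = FALSE))
  missing <- setdiff(unique(groups), names(params$group_hazards))
  if (length(missing))
    stop_config("no hazard configured for group(s): ",
                paste(missing, collapse = ", "))
  set.seed(params$seed)
  n <- length(groups)
  haz <- params$group_hazards[groups]
  t_event <- stats::rexp(n, rate = haz)
  entry <- if (params$accrual_days > 0)
    stats::runif(n, 0, params$accrual_days) else rep(0, n)
  horizon <- pmax(params$study_days - entry, 0)
  event <- as.integer(t_event <= horizon)
  data.frame(sample_id = names(groups) %||% sprintf("S%04d", seq_len(n)),
             group = unname(groups),
             time_days = pmin(t_event, horizon),
             event = event, row.names = NULL, stringsAsFactors = FALSE)
}
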