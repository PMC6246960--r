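## Plasma read simulator.
##
## Emits aligned cfDNA read records with the molecular family structure the
## callers rely on: each input molecule becomes one read family identified
## either by its alignment start/end coordinates (endogenous, "positional"
## UMI), by an exogenous UMI tag, or by nothing at all (amplicon chemistry,
## where every read shares the amplicon coordinates).
##
## Coordinates are 0-based, half-open throughout the package; conversion to
## 1-based happens only at VCF/SAM boundaries.

#' Parameters for the plasma read simulator
#'
#' @param chrom,pos,ref,alt the queried locus (0-based position) and alleles.
#' @param variant_type one of `"SNV"`, `"multi_base_indel"`,
#'   `"single_base_indel"`.
#' @param n_molecules number of input cfDNA molecules (= families).
#' @param maf_molecular percent of molecules carrying the alt allele.
#' @param family_size_dist named probability vector: family size ->
#'   probability. Default is a shifted geometric with mean 6, a generic
#'   PCR-duplicate profile.
#' @param error_rate per-read probability of reporting a wrong allele
#'   (capped at 0.05). Two thirds of errors flip to the opposite tracked
#'   allele, one third to an untracked "other" base.
#' @param chemistry `"positional"`, `"tagged_umi"` or `"amplicon"`.
#' @param collision_rate probability that a molecule re-uses the previous
#'   molecule's (start, end) pair under positional chemistry, probing the
#'   known failure mode of endogenous UMIs. Default 0.
#' @param seed integer seed.
#' @return an object of class `read_sim_params`.
#' @export
read_sim_params <- function(chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
                            variant_type = c("SNV", "multi_base_indel",
                                             "single_base_indel"),
                            n_molecules = 1000L, maf_molecular = 1,
                            family_size_dist = NULL,
                            error_rate = 0.001,
                            chemistry = c("positional", "tagged_umi",
                                          "amplicon"),
                            collision_rate = 0, seed = 1L) {
  variant_type <- match.arg(variant_type)
  chemistry <- match.arg(chemistry)
  if (is.null(family_size_dist)) {
    sizes <- 1:30
    p <- stats::dgeom(sizes - 1L, prob = 1 / 6)
    family_size_dist <- stats::setNames(p / sum(p), sizes)
  }
  if (maf_molecular < 0 || maf_molecular > 100)
    stop_config("maf_molecular must lie in [0, 100]")
  if (error_rate < 0 || error_rate > 0.05)
    stop_config("error_rate must lie in [0, 0.05]")
  if (abs(sum(family_size_dist) - 1) > 1e-9 || any(family_size_dist < 0))
    stop_config("family_size_dist must be a probability vector summing to 1")
  if (n_molecules == 0 && maf_molecular > 0)
    stop_config("n_molecules = 0 with maf_molecular > 0 is contradictory")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 variant_type = variant_type,
                 n_molecules = as.integer(n_molecules),
                 maf_molecular = maf_molecular,
                 family_size_dist = family_size_dist,
                 error_rate = error_rate, chemistry = chemistry,
                 collision_rate = collision_rate, seed = as.integer(seed)),
            class = "read_sim_params")
}

## Applies sequencing error to a vector of true alleles ("ref"/"alt").
inject_errors <- function(true_allele, error_rate) {
  n <- length(true_allele)
  obs <- true_allele
  err <- stats::runif(n) < error_rate
  if (any(err)) {
    to_other <- err & (stats::runif(n) < 1 / 3)
    to_flip <- err & !to_other
    obs[to_other] <- "other"
    obs[to_flip] <- ifelse(true_allele[to_flip] == "ref", "alt", "ref")
  }
  obs
}

#' Simulate read families at one locus
#'
#' Each of `n_molecules` cfDNA molecules is assigned a true allele (alt with
#' probability `maf_molecular`/100), a family identity according to the
#' chemistry, and a family size drawn from `family_size_dist`; its reads
#' report the true allele corrupted independently at `error_rate`.
#'
#' @param params a [read_sim_params()] object.
#' @param sample_id sample identifier stamped on every read.
#' @return list with `reads` (a data frame of read records: sample_id,
#'   chrom, start, end, umi, allele, strand) and `truth` (one row per
#'   molecule: family coordinates/UMI, true allele, family size).
#' @export
simulate_read_families <- function(params, sample_id = "S1") {
  stopifnot(inherits(params, "read_sim_params"))
  set.seed(params$seed)
  n <- params$n_molecules
  proto <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(), umi = character(),
                      allele = character(), strand = character(),
                      stringsAsFactors = FALSE)
  if (n == 0) {
    return(list(reads = proto,
                truth = data.frame(molecule = integer(), start = integer(),
                                   end = integer(), umi = character(),
                                   true_allele = character(), size = integer(),
                                   stringsAsFactors = FALSE)))
  }
  true_allele <- ifelse(stats::runif(n) < params$maf_molecular / 100,
                        "alt", "ref")
  sizes <- as.integer(sample(names(params$family_size_dist), n, replace = TRUE,
                             prob = params$family_size_dist))

  pos <- params$pos
  if (params$chemistry == "amplicon") {
    start <- rep.int(pos - 60L, n)
    end <- rep.int(pos + 60L, n)
    umi <- rep(NA_character_, n)
  } else {
    ## Fragmentation is random: distinct molecules get distinct (start, end)
    ## pairs except for deliberate collisions.
    start <- pos - sample.int(150L, n, replace = TRUE)
    end <- pos + sample.int(150L, n, replace = TRUE)
    key <- paste(start, end)
    while (anyDuplicated(key)) {
      dup <- duplicated(key)
      start[dup] <- pos - sample.int(150L, sum(dup), replace = TRUE)
      end[dup] <- pos + sample.int(150L, sum(dup), replace = TRUE)
      key <- paste(start, end)
    }
    if (params$chemistry == "positional" && params$collision_rate > 0 && n > 1) {
      collide <- which(stats::runif(n) < params$collision_rate)
      collide <- collide[collide > 1]
      start[collide] <- start[collide - 1L]
      end[collide] <- end[collide - 1L]
    }
    umi <- if (params$chemistry == "tagged_umi") {
      m <- matrix(sample(c("A", "C", "G", "T"), 8L * n, replace = TRUE), n)
      do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    } else rep(NA_character_, n)
  }

  idx <- rep.int(seq_len(n), sizes)
  obs <- inject_errors(true_allele[idx], params$error_rate)
  reads <- data.frame(sample_id = sample_id,
                      chrom = params$chrom,
                      start = start[idx], end = end[idx],
                      umi = umi[idx],
                      allele = obs,
                      strand = sample(c("+", "-"), length(idx), replace = TRUE),
                      stringsAsFactors = FALSE)
  truth <- data.frame(molecule = seq_len(n), start = start, end = end,
                      umi = umi, true_allele = true_allele, size = sizes,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

sam_lite_cols <- c("sample_id", "chrom", "start", "end", "umi", "allele",
                   "strand")

validate_read_table <- function(reads, where = NULL) {
  bad <- which(!(reads$start < reads$end))
  if (length(bad))
    stop_input("start >= end", if (!is.null(where))
      paste0(" on line ", where[bad[1]]) else
        paste0(" in row ", bad[1]))
  ok_allele <- reads$allele %in% c("ref", "alt", "other")
  if (!all(ok_allele)) {
    bad <- which(!ok_allele)[1]
    stop_input("invalid allele '", reads$allele[bad], "'",
               if (!is.null(where)) paste0(" on line ", where[bad]) else
                 paste0(" in row ", bad))
  }
  invisible(reads)
}

#' Write / read the SAM-lite TSV read format
#'
#' A 7-column tab-separated table (sample_id, chrom, start, end, umi,
#' allele, strand) with a header line; `start`/`end` are 0-based half-open
#' and `"."` marks an absent UMI. The round trip is lossless.
#'
#' @param reads read table as returned by [simulate_read_families()].
#' @param path file path.
#' @return `write_sam_lite()` returns `path` invisibly; `read_sam_lite()`
#'   returns the read table.
#' @export
write_sam_lite <- function(reads, path) {
  stopifnot(all(sam_lite_cols %in% names(reads)))
  validate_read_table(reads)
  out <- reads[sam_lite_cols]
  out$umi[is.na(out$umi)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sam_lite
#' @export
read_sam_lite <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  reads <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = c("character", "character",
                                            "integer", "integer", "character",
                                            "character", "character"))
  names(reads) <- sam_lite_cols
  reads$umi[reads$umi == "."] <- NA_character_
  validate_read_table(reads, where = seq_len(nrow(reads)) + 1L)
  reads
}

#' Export reads as standard SAM / import from SAM
#'
#' `write_sam()` emits a plain-text SAM file: POS is 1-based, the CIGAR is
#' a full-length match, the UMI goes into the `RX` tag and the tracked
#' allele class (ref/alt/other) into the custom `XV` tag, since these
#' records carry no base-level sequence. `read_sam()` imports such a file
#' (via Rsamtools) back into the SAM-lite table.
#'
#' @param reads read table.
#' @param path output path (`.sam`).
#' @param sample_id sample id stamped on imported reads.
#' @param umi_tag SAM tag holding the UMI (default `"RX"`).
#' @return `write_sam()` returns `path` invisibly; `read_sam()` a read table.
#' @export
write_sam <- function(reads, path) {
  validate_read_table(reads)
  chroms <- unique(reads$chrom)
  maxlen <- vapply(chroms, function(cc)
    max(reads$end[reads$chrom == cc]) + 1L, 0L)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, maxlen))
  n <- nrow(reads)
  if (n) {
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    len <- reads$end - reads$start
    body <- sprintf("r%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*\tXV:Z:%s%s",
                    seq_len(n), flag, reads$chrom, reads$start + 1L, len,
                    reads$allele,
                    ifelse(is.na(reads$umi), "",
                           paste0("\tRX:Z:", reads$umi)))
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path, sample_id = "S1", umi_tag = "RX") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop_config("standard-SAM import requires the Rsamtools package")
  if (!file.exists(path)) stop_input("no such file: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "cigar", "strand"),
    tag = c(umi_tag, "XV"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  width <- as.integer(sub("M$", "", x$cigar))
  data.frame(sample_id = sample_id,
             chrom = as.character(x$rname),
             start = x$pos - 1L,
             end = x$pos - 1L + width,
             umi = as.character(x$tag[[umi_tag]] %||% NA_character_),
             allele = as.character(x$tag[["XV"]]),
             strand = as.character(x$strand),
             stringsAsFactors = FALSE)
}
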