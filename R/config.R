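#' Default pipeline configuration
#'
#' Returns the full set of numeric thresholds used across the pipeline.
#' Every stage takes its tuning parameters from such a list, so a single
#' flat key-value file drives the command-line interface reproducibly.
#'
#' Key parameters (all distances in nucleotides):
#' \describe{
#'   \item{tss_window / pas_window}{read-to-site assignment windows for
#'     full-length read calling (50 / 150).}
#'   \item{pas_cluster_window, pas_min_support}{single-linkage clustering
#'     window (20) and minimum read support (2) for the PAS database.}
#'   \item{filter_overlap_window}{3' end filtering window against the PAS
#'     database (100).}
#'   \item{last_bin_cover_frac}{fraction of the last 3'UTR bin an isoform
#'     must cover to be corrected to the distal PAS (0.10).}
#'   \item{merge_tol_3p / merge_tol_5p / merge_tol_exon}{isoform merging
#'     tolerances (150 / 50 / 10).}
#'   \item{pileup_window, pileup_min_cpm}{5' pile-up bin size (50) and
#'     counts-per-million cutoff (30).}
#'   \item{ip_a_frac, ip_window, ip_tes_exempt}{internal-priming blacklist:
#'     A fraction (0.70, strict) in the upstream window (10 bp), with
#'     positions within 250 bp of an annotated transcript end exempt.}
#'   \item{seq3_merge, seq3_min_cov}{3'-seq cluster merge distance (15 bp)
#'     and per-sample minimum coverage (5 reads).}
#'   \item{max_tx_len, min_isoforms, min_reads_per_isoform, tpm_cutoff}{gene
#'     filters for coupling matrices (10 kb, 2, 2, 2 TPM).}
#'   \item{alpha_fly / alpha_human}{BH-adjusted p-value cutoffs (0.1 / 0.01).}
#'   \item{tss_contrib_min, pas_contrib_min}{dominance contribution cutoffs
#'     (0.20, 0.60; strict).}
#'   \item{residual_bias_cut}{absolute Pearson residual cutoff for biased
#'     feature pairs (0.7; strict).}
#'   \item{signal_window_scan / signal_window_pas}{poly(A)-signal scan
#'     windows: 20 nt for QC enrichment, 50 nt for PAS-usage analyses.}
#'   \item{proximal_frac}{3'UTR fraction defining proximal PASs (0.20).}
#'   \item{mc_reps}{Monte-Carlo replicates for the chi-squared test (2000).}
#'   \item{msa_row_occ, msa_max_ident}{MSA refinement: minimum row
#'     occupancy (0.4) and maximum pairwise identity (0.98).}
#'   \item{peak_min_height, peak_min_distance, peak_min_width}{co-evolution
#'     peak finding (0.2, 2, 2).}
#'   \item{coevo_percentile}{score percentile above which a TSS is called
#'     co-evolving (0.50).}
#'   \item{promoter_flank}{promoter region size upstream of a TSS (1000).}
#' }
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    tss_window           = 50L,
    pas_window           = 150L,
    pas_cluster_window   = 20L,
    pas_min_support      = 2L,
    filter_overlap_window = 100L,
    last_bin_cover_frac  = 0.10,
    merge_tol_3p         = 150L,
    merge_tol_5p         = 50L,
    merge_tol_exon       = 10L,
    pileup_window        = 50L,
    pileup_min_cpm       = 30,
    ip_a_frac            = 0.70,
    ip_window            = 10L,
    ip_tes_exempt        = 250L,
    seq3_merge           = 15L,
    seq3_min_cov         = 5L,
    max_tx_len           = 10000L,
    min_isoforms         = 2L,
    min_reads_per_isoform = 2L,
    alpha_fly            = 0.1,
    alpha_human          = 0.01,
    tss_contrib_min      = 0.20,
    pas_contrib_min      = 0.60,
    residual_bias_cut    = 0.7,
    signal_window_scan   = 20L,
    signal_window_pas    = 50L,
    proximal_frac        = 0.20,
    tpm_cutoff           = 2,
    mc_reps              = 2000L,
    msa_row_occ          = 0.4,
    msa_max_ident        = 0.98,
    peak_min_height      = 0.2,
    peak_min_distance    = 2L,
    peak_min_width       = 2L,
    coevo_percentile     = 0.50,
    promoter_flank       = 1000L,
    rng_seed             = 1L
  )
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' an error; missing keys take their defaults from [default_config()].
#'
#' @param path file path, or `NULL` for pure defaults.
#' @return validated config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stopf("malformed config line: '%s'", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) stopf("unknown config key: '%s'", key)
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stopf("non-numeric value for key '%s': '%s'", key, val)
      cfg[[key]] <- if (is.integer(cfg[[key]])) as.integer(num) else num
    }
  }
  validate_config(cfg)
  cfg
}

#' Write a configuration list as a flat key-value file
#' @param cfg config list.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, format, "", scientific = FALSE)), path)
  invisible(path)
}

validate_config <- function(cfg) {
  windows <- c("tss_window", "pas_window", "pas_cluster_window",
               "filter_overlap_window", "merge_tol_3p", "merge_tol_5p",
               "merge_tol_exon", "pileup_window", "ip_window",
               "ip_tes_exempt", "seq3_merge", "max_tx_len",
               "signal_window_scan", "signal_window_pas", "promoter_flank")
  counts <- c("pas_min_support", "seq3_min_cov", "min_isoforms",
              "min_reads_per_isoform", "mc_reps")
  fracs <- c("last_bin_cover_frac", "ip_a_frac", "alpha_fly", "alpha_human",
             "tss_contrib_min", "pas_contrib_min", "proximal_frac",
             "msa_row_occ", "msa_max_ident", "coevo_percentile")
  for (k in c(windows, counts))
    if (cfg[[k]] <= 0) stopf("config '%s' must be positive", k)
  for (k in fracs)
    if (cfg[[k]] < 0 || cfg[[k]] > 1) stopf("config '%s' must be in [0,1]", k)
  invisible(TRUE)
}
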