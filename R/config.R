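#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline with its default. The
#' defaults are the filtering and modeling constants of the analysis this
#' package implements; see the methods vignette for their provenance and
#' units.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `somasig_config` (a named list).
#'
#' @details Defaults:
#' * `pon_min_depth` (10): minimum normal depth for a normal to vote on a site.
#' * `pon_min_alt_fraction` (0.05): minimum quality-filtered alt fraction.
#' * `pon_min_samples` (2): normals required to blacklist a site.
#' * `min_mapq`, `min_baseq` (20, 20): read-quality cutoffs behind
#'   `alt_count_q20`.
#' * `pon_denominator` (`"all_reads"`): whether the alt-fraction denominator
#'   is total depth or quality-filtered depth (`"q20_reads"`).
#' * `cosmic_mode` (`"rescue"`): COSMIC/population-AF criteria rescue
#'   PoN-flagged calls; `"gate"` instead requires them of every call.
#' * `rescue_min_cosmic` (1, strict `>`), `rescue_max_af` (0.005).
#' * `indel_min_alt` (4), `indel_min_vaf` (0.05): tumor evidence floor.
#' * `germline_max_af` (0.05), `germline_min_cadd` (25, strict `>`).
#' * `sv_window` (500): breakpoint corroboration window in bp.
#' * `sv_pon_match` (`"window"`): SV panel matching uses the corroboration
#'   window; `"exact"` requires identical keys.
#' * `amp_focal_cn` (6), `amp_nonfocal_cn` (7), `focal_max_length` (3e6),
#'   `loss_cn` (0): gene-level copy-number thresholds.
#' * `cin_baseline` (2): copy number considered unaltered.
#' * `her2_ratio` (2): ERBB2 / chr17-ploidy ratio for CN-based HER2 status.
#' * `min_snvs_per_sample` (100): catalog inclusion gate.
#' * `n_signatures` (9), `nmf_restarts` (30), `nmf_max_iter` (5000),
#'   `nmf_tol` (1e-8): factorization settings.
#' * `cosine_label_threshold` (0.8): minimum cosine to label a factor.
#' * `n_permutations` (10000): permutation-test resamples.
#' * `alpha` (0.05): FDR level at which association directions are declared.
#' * `seed` (1): base random seed, recorded in outputs.
#' @export
run_config <- function(...) {
  cfg <- list(
    pon_min_depth = 10L,
    pon_min_alt_fraction = 0.05,
    pon_min_samples = 2L,
    min_mapq = 20L,
    min_baseq = 20L,
    pon_denominator = "all_reads",
    cosmic_mode = "rescue",
    rescue_min_cosmic = 1L,
    rescue_max_af = 0.005,
    indel_min_alt = 4L,
    indel_min_vaf = 0.05,
    germline_max_af = 0.05,
    germline_min_cadd = 25,
    sv_window = 500L,
    sv_pon_match = "window",
    amp_focal_cn = 6,
    amp_nonfocal_cn = 7,
    focal_max_length = 3e6,
    loss_cn = 0,
    cin_baseline = 2L,
    her2_ratio = 2,
    min_snvs_per_sample = 100L,
    n_signatures = 9L,
    nmf_restarts = 30L,
    nmf_max_iter = 5000L,
    nmf_tol = 1e-8,
    cosine_label_threshold = 0.8,
    n_permutations = 10000L,
    alpha = 0.05,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "somasig_config")
}

#' Read a key=value configuration file
#'
#' Plain-text `key = value` lines (`#` comments allowed) overriding
#' [run_config()] defaults. Values are parsed as numbers where possible.
#'
#' @param path file path.
#' @return a `somasig_config` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stopf("malformed config line: '%s'", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(run_config, stats::setNames(parsed, keys))
}

#' @export
print.somasig_config <- function(x, ...) {
  cat("somasig run configuration\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
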