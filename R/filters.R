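#' Two-caller SNV consensus
#'
#' For one tumor-normal pair, retains exactly the variants called with
#' `PASS` filter status by both callers; any call failing either caller's
#' PASS criteria is discarded. Per-site evidence (depths, counts,
#' annotations) is taken from one designated caller.
#'
#' @param calls_a,calls_b variant tables (see [variant_columns()]) from the
#'   two callers for the same tumor-normal pair.
#' @param evidence_from which input supplies the evidence of retained
#'   calls: `"a"` (default) or `"b"`.
#' @return variant table, a subset of the evidence caller's input.
#' @export
consensus_snvs <- function(calls_a, calls_b, evidence_from = c("a", "b")) {
  evidence_from <- match.arg(evidence_from)
  key_a <- variant_key(calls_a$chrom, calls_a$pos, calls_a$ref, calls_a$alt)
  key_b <- variant_key(calls_b$chrom, calls_b$pos, calls_b$ref, calls_b$alt)
  if (anyDuplicated(key_a)) {
    stopf("ambiguous duplicate variant key in caller A: %s", key_a[duplicated(key_a)][1])
  }
  if (anyDuplicated(key_b)) {
    stopf("ambiguous duplicate variant key in caller B: %s", key_b[duplicated(key_b)][1])
  }
  pass_a <- key_a[calls_a$filter_status == "PASS"]
  pass_b <- key_b[calls_b$filter_status == "PASS"]
  keep <- intersect(pass_a, pass_b)
  out <- if (evidence_from == "a") {
    calls_a[key_a %in% keep, , drop = FALSE]
  } else {
    calls_b[key_b %in% keep, , drop = FALSE]
  }
  log_stage("consensus_snvs", nrow(calls_a) + nrow(calls_b), nrow(out))
  rownames(out) <- NULL
  out
}

#' Build an SNV panel of normals
#'
#' A normal sample supports a site when it covers it with at least
#' `pon_min_depth` reads and at least a `pon_min_alt_fraction` fraction of
#' reads carry the alternate allele after MAPQ/base-quality filtering
#' (quality filtering applies to the numerator; by default the denominator
#' is total depth, switchable with `pon_denominator = "q20_reads"`, which
#' requires a `depth_q20` column). A site enters the blacklist when
#' supported by at least `pon_min_samples` distinct normals.
#'
#' @param normal_pileups data.frame with columns `normal_id, chrom, pos,
#'   ref, alt, depth, alt_count_q20` (optionally `depth_q20`).
#' @param config a [run_config()].
#' @return object of class `panel_of_normals` with elements `blacklist`
#'   (character keys) and `evidence` (the supporting rows).
#' @export
build_pon <- function(normal_pileups, config = run_config()) {
  p <- normal_pileups
  stopifnot(all(c("normal_id", "chrom", "pos", "ref", "alt", "depth",
                  "alt_count_q20") %in% names(p)))
  if (any(p$alt_count_q20 > p$depth)) {
    stopf("alt_count_q20 exceeds depth in pileup input")
  }
  if (any(p$depth < 0 | p$alt_count_q20 < 0)) stopf("negative pileup counts")
  denom <- if (identical(config$pon_denominator, "q20_reads")) {
    if (is.null(p$depth_q20)) stopf("pon_denominator='q20_reads' needs a depth_q20 column")
    p$depth_q20
  } else {
    p$depth
  }
  frac <- ifelse(denom > 0, p$alt_count_q20 / denom, 0)
  supports <- p$depth >= config$pon_min_depth &
    frac >= config$pon_min_alt_fraction
  ev <- p[supports, , drop = FALSE]
  key <- variant_key(ev$chrom, ev$pos, ev$ref, ev$alt)
  n_support <- tapply(ev$normal_id, key, function(x) length(unique(x)))
  blacklist <- names(n_support)[n_support >= config$pon_min_samples]
  structure(
    list(blacklist = blacklist %||% character(),
         evidence = ev,
         config = config[c("pon_min_depth", "pon_min_alt_fraction",
                           "pon_min_samples", "pon_denominator")]),
    class = "panel_of_normals"
  )
}

#' @export
print.panel_of_normals <- function(x, ...) {
  cat(sprintf("panel_of_normals: %d blacklisted site(s)\n", length(x$blacklist)))
  invisible(x)
}

new_filter_outcome <- function(variants, decision, reasons) {
  out <- variants
  out$key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  out$decision <- decision
  out$reasons <- reasons
  rownames(out) <- NULL
  out
}

#' Apply the SNV panel of normals with COSMIC rescue
#'
#' Variants at blacklisted sites are removed unless they carry positive
#' evidence of being recurrent somatic events: a COSMIC overlap count
#' strictly greater than 1 together with 1000 Genomes and ExAC allele
#' frequencies at or below 0.005. A missing COSMIC count or population
#' frequency fails the rescue conjunction (rescue demands observed
#' evidence). With `cosmic_mode = "gate"` the same conjunction is instead
#' required of every variant regardless of PoN status.
#'
#' @param snvs variant table (annotated).
#' @param pon a [build_pon()] result.
#' @param config a [run_config()]; `cosmic_mode` selects rescue vs gate.
#' @return filter-outcome data.frame: input columns plus `key`, `decision`
#'   (`retained`/`removed`) and `reasons` (semicolon-joined rule ids).
#' @export
apply_pon_with_rescue <- function(snvs, pon, config = run_config()) {
  key <- variant_key(snvs$chrom, snvs$pos, snvs$ref, snvs$alt)
  in_pon <- key %in% pon$blacklist
  cosmic_ok <- !is.na(snvs$cosmic_overlap_count) &
    snvs$cosmic_overlap_count > config$rescue_min_cosmic
  af_ok <- !is.na(snvs$af_1000g) & snvs$af_1000g <= config$rescue_max_af &
    !is.na(snvs$af_exac) & snvs$af_exac <= config$rescue_max_af
  rescue_ok <- cosmic_ok & af_ok

  if (identical(config$cosmic_mode, "gate")) {
    retained <- rescue_ok
    reasons <- ifelse(retained, "RESCUED_COSMIC", "NOT_COSMIC_SOMATIC")
  } else {
    retained <- !in_pon | rescue_ok
    reasons <- rep("", length(key))
    reasons[in_pon & rescue_ok] <- "PON;RESCUED_COSMIC"
    reasons[in_pon & !rescue_ok] <- "PON"
  }
  out <- new_filter_outcome(snvs, ifelse(retained, "retained", "removed"), reasons)
  log_stage("apply_pon_with_rescue", nrow(snvs), sum(retained))
  out
}

#' Build the indel pseudo panel of normals
#'
#' Aggregates putative indel calls that failed caller filters with status
#' `HighVafNormal` or `HighAltCountNormal`; any indel failing for one of
#' those two reasons in two or more distinct samples is blacklisted.
#' Other failure statuses are ignored.
#'
#' @param failed_calls data.frame with columns `sample_id, key` (or
#'   `chrom,pos,ref,alt`) and `filter_status`.
#' @return object of class `indel_pseudo_pon` with `blacklist` and
#'   `failure_counts`.
#' @export
build_indel_pseudo_pon <- function(failed_calls) {
  f <- failed_calls
  if (is.null(f$key)) {
    f$key <- variant_key(f$chrom, f$pos, f$ref, f$alt)
  }
  qual <- f[f$filter_status %in% c("HighVafNormal", "HighAltCountNormal"), ,
            drop = FALSE]
  counts <- if (nrow(qual)) {
    tapply(qual$sample_id, qual$key, function(x) length(unique(x)))
  } else {
    integer()
  }
  structure(
    list(
      blacklist = names(counts)[counts >= 2] %||% character(),
      failure_counts = counts
    ),
    class = "indel_pseudo_pon"
  )
}

#' Filter somatic indel calls
#'
#' Retains an indel iff it has at least 4 alternate reads in the tumor, no
#' alternate reads in the normal, tumor VAF of at least 5%, lies outside
#' repetitive regions, is not a known germline (population) variant, and is
#' not blacklisted by the pseudo panel of normals. Every failed rule is
#' recorded in `reasons`.
#'
#' @param indels variant table of indel calls.
#' @param repeat_mask a [genomic_mask()] of repetitive regions.
#' @param known_germline character vector of variant keys seen in
#'   population releases.
#' @param pseudo_pon a [build_indel_pseudo_pon()] result (or NULL).
#' @param config a [run_config()].
#' @return filter-outcome data.frame.
#' @export
filter_indels <- function(indels, repeat_mask = genomic_mask(),
                          known_germline = character(),
                          pseudo_pon = NULL, config = run_config()) {
  n <- nrow(indels)
  key <- variant_key(indels$chrom, indels$pos, indels$ref, indels$alt)
  fail <- list(
    LOW_ALT = is.na(indels$tumor_alt_count) |
      indels$tumor_alt_count < config$indel_min_alt,
    NORMAL_ALT = !is.na(indels$normal_alt_count) & indels$normal_alt_count > 0,
    LOW_VAF = is.na(indels$vaf) | indels$vaf < config$indel_min_vaf,
    REPEAT_REGION = mask_contains(repeat_mask, indels$chrom, indels$pos),
    KNOWN_GERMLINE = key %in% known_germline,
    PSEUDO_PON = if (is.null(pseudo_pon)) rep(FALSE, n) else key %in% pseudo_pon$blacklist
  )
  reason_mat <- do.call(cbind, fail)
  reasons <- apply(reason_mat, 1L, function(r) {
    paste(names(fail)[r], collapse = ";")
  })
  retained <- !apply(reason_mat, 1L, any)
  out <- new_filter_outcome(indels, ifelse(retained, "retained", "removed"), reasons)
  log_stage("filter_indels", n, sum(retained))
  out
}

#' Classify germline variants by deleteriousness
#'
#' Variants with an ExAC allele frequency of 0.05 or greater are discarded
#' as common. Remaining variants are deleterious if annotated HIGH impact,
#' or missense with a CADD score strictly greater than 25; everything else
#' is tolerated. A missing ExAC frequency is treated as rare (not
#' discarded); a missing CADD score cannot make a missense variant
#' deleterious.
#'
#' @param variants variant table with `impact`, `consequence`,
#'   `cadd_score`, `af_exac` columns.
#' @param config a [run_config()].
#' @return the input with an added `germline_status` column in
#'   `{discarded, deleterious, tolerated}`.
#' @export
classify_germline <- function(variants, config = run_config()) {
  common <- !is.na(variants$af_exac) & variants$af_exac >= config$germline_max_af
  high <- !is.na(variants$impact) & variants$impact == "HIGH"
  missense <- !is.na(variants$consequence) &
    grepl("missense", variants$consequence, ignore.case = TRUE)
  cadd_hit <- missense & !is.na(variants$cadd_score) &
    variants$cadd_score > config$germline_min_cadd
  status <- ifelse(common, "discarded",
                   ifelse(high | cadd_hit, "deleterious", "tolerated"))
  out <- variants
  out$germline_status <- status
  out
}

#' Pre/post filters for significantly-mutated-gene analysis
#'
#' Caps non-silent indels at one per gene per sample (the record with the
#' lowest coordinate is kept, a deterministic tie-break) and restricts the
#' candidate list to genes with more than two distinct individuals carrying
#' non-silent mutations after capping.
#'
#' @param mutation_table data.frame with columns `sample_id, gene, chrom,
#'   pos, variant_class, silent` (logical).
#' @param candidate_genes character vector of genes to assess.
#' @return list with `mutations` (capped table) and `eligible_genes`.
#' @export
smg_filters <- function(mutation_table, candidate_genes) {
  m <- mutation_table
  if (nrow(m) == 0L) {
    return(list(mutations = m, eligible_genes = character()))
  }
  stopifnot(is.logical(m$silent))
  m <- m[order(m$sample_id, m$gene, m$chrom, m$pos), , drop = FALSE]
  is_ns_indel <- !m$silent & m$variant_class == "indel"
  grp <- paste(m$sample_id, m$gene, sep = "\r")
  # within each (sample, gene), keep all records except extra non-silent indels
  keep <- rep(TRUE, nrow(m))
  idx <- which(is_ns_indel)
  seen <- duplicated(grp[idx])
  keep[idx[seen]] <- FALSE
  capped <- m[keep, , drop = FALSE]
  rownames(capped) <- NULL

  ns <- capped[!capped$silent, , drop = FALSE]
  carriers <- tapply(ns$sample_id, ns$gene, function(x) length(unique(x)))
  eligible <- names(carriers)[carriers > 2]
  list(
    mutations = capped,
    eligible_genes = intersect(candidate_genes, eligible)
  )
}
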