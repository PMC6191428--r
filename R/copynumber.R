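validate_segments <- function(segments) {
  stopifnot(is.data.frame(segments))
  need <- c("sample_id", "chrom", "start", "end", "total_cn")
  missing <- setdiff(need, names(segments))
  if (length(missing)) stopf("segment table lacks columns: %s", paste(missing, collapse = ", "))
  if (nrow(segments) && any(segments$end <= segments$start)) {
    stopf("segment table contains end <= start")
  }
  if (is.null(segments$minor_cn)) segments$minor_cn <- NA_integer_
  segments
}

# length-weighted median of values with weights
weighted_median <- function(x, w) {
  ok <- !is.na(x) & w > 0
  if (!any(ok)) return(NA_real_)
  x <- x[ok]; w <- w[ok]
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  lo <- x[which(cw >= 0.5)[1]]
  hi <- x[which(cw > 0.5 - 1e-12)[1]]
  (lo + hi) / 2
}

#' Gene-level copy-number calls
#'
#' For each sample and gene, the gene's copy number is the median over its
#' exons of the copy number of the segment containing each exon midpoint
#' (segments cover positions `start <= p < end`). A gene is called
#' amplified when that median is at least 6 for a focal gain (the
#' contiguous run of segments at or above the focal threshold spanning the
#' gene is shorter than 3 Mb) or at least 7 for a non-focal gain; non-focal
#' amplifications of tumor suppressor genes are excluded. Genes with a
#' median exon copy number of 0 are called lost. Genes with no covering
#' segment are indeterminate.
#'
#' @param segments segment table (`sample_id, chrom, start, end, total_cn,
#'   minor_cn`).
#' @param gene_models data.frame of exons: `gene, chrom, start, end`.
#' @param tumor_suppressors character vector of tumor suppressor genes.
#' @param config a [run_config()].
#' @return data.frame `(sample_id, gene, median_exon_cn, amplicon_length,
#'   focal, event)` with `event` in `{amplified, lost, neutral,
#'   indeterminate}`.
#' @export
call_gene_cn <- function(segments, gene_models, tumor_suppressors = character(),
                         config = run_config()) {
  segments <- validate_segments(segments)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_models)))
  samples <- unique(segments$sample_id)
  genes <- unique(gene_models$gene)
  res <- list()
  for (s in samples) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
    for (g in genes) {
      ex <- gene_models[gene_models$gene == g, , drop = FALSE]
      chrom <- ex$chrom[1]
      mids <- floor((ex$start + ex$end) / 2)
      segc <- seg[seg$chrom == chrom, , drop = FALSE]
      cn <- vapply(mids, function(p) {
        hit <- which(segc$start <= p & p < segc$end)
        if (length(hit)) segc$total_cn[hit[1]] else NA_real_
      }, numeric(1))
      if (all(is.na(cn))) {
        res[[length(res) + 1L]] <- data.frame(
          sample_id = s, gene = g, median_exon_cn = NA_real_,
          amplicon_length = NA_real_, focal = NA, event = "indeterminate",
          stringsAsFactors = FALSE
        )
        next
      }
      med <- stats::median(cn, na.rm = TRUE)
      # amplicon: maximal contiguous run of >= focal-threshold segments
      # overlapping the gene span
      amp_len <- NA_real_
      focal <- NA
      hot <- segc$total_cn >= config$amp_focal_cn
      if (any(hot)) {
        runs <- rle(hot)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        gene_lo <- min(ex$start); gene_hi <- max(ex$end)
        for (r in which(runs$values)) {
          run_rows <- starts[r]:ends[r]
          # a run must be genomically contiguous; split at coverage gaps
          piece_id <- if (length(run_rows) > 1L) {
            gap <- segc$start[run_rows[-1]] != segc$end[run_rows[-length(run_rows)]] |
              segc$chrom[run_rows[-1]] != segc$chrom[run_rows[-length(run_rows)]]
            cumsum(c(0L, as.integer(gap)))
          } else {
            0L
          }
          for (p in split(run_rows, piece_id)) {
            lo <- segc$start[p[1]]; hi <- segc$end[p[length(p)]]
            if (lo < gene_hi && hi > gene_lo) {
              amp_len <- sum(segc$end[p] - segc$start[p])
              focal <- amp_len < config$focal_max_length
            }
          }
        }
      }
      event <- "neutral"
      if (med == config$loss_cn) {
        event <- "lost"
      } else if (!is.na(focal)) {
        amplified <- (focal && med >= config$amp_focal_cn) ||
          (!focal && med >= config$amp_nonfocal_cn)
        if (amplified && !focal && g %in% tumor_suppressors) amplified <- FALSE
        if (amplified) event <- "amplified"
      }
      res[[length(res) + 1L]] <- data.frame(
        sample_id = s, gene = g, median_exon_cn = med,
        amplicon_length = amp_len, focal = focal, event = event,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Chromosomal instability (CIN) per sample
#'
#' The fraction of segment-covered genome length whose total copy number
#' differs from the baseline (diploid 2 by default; a per-sample rounded
#' ploidy can be supplied instead).
#'
#' @param segments segment table.
#' @param config a [run_config()] (`cin_baseline`).
#' @param ploidy optional named numeric vector of per-sample baselines
#'   overriding `cin_baseline`.
#' @return data.frame `(sample_id, cin)` with `cin` in `[0, 1]`.
#' @export
compute_cin <- function(segments, config = run_config(), ploidy = NULL) {
  segments <- validate_segments(segments)
  samples <- unique(segments$sample_id)
  cin <- vapply(samples, function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    base <- if (!is.null(ploidy) && s %in% names(ploidy)) ploidy[[s]] else config$cin_baseline
    len <- seg$end - seg$start
    sum(len[seg$total_cn != base]) / sum(len)
  }, numeric(1))
  data.frame(sample_id = samples, cin = unname(cin), stringsAsFactors = FALSE)
}

#' Segment counts per sample
#'
#' Counts copy-number segments after merging consecutive segments on the
#' same chromosome with identical `(total_cn, minor_cn)`, so the count is
#' invariant to re-splitting of constant-copy-number runs.
#'
#' @param segments segment table.
#' @return data.frame `(sample_id, n_segments)`.
#' @export
count_segments <- function(segments) {
  segments <- validate_segments(segments)
  samples <- unique(segments$sample_id)
  n <- vapply(samples, function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    if (nrow(seg) == 0L) return(0L)
    seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
    state <- paste(seg$chrom, seg$total_cn,
                   ifelse(is.na(seg$minor_cn), ".", seg$minor_cn))
    sum(state != c("\r", state[-length(state)]))
  }, integer(1))
  data.frame(sample_id = samples, n_segments = unname(n), stringsAsFactors = FALSE)
}

#' Copy-number-based HER2 status
#'
#' HER2 status from genomic copy number as an alternative to FISH: a
#' sample is positive when the ERBB2 locus median copy number divided by
#' the length-weighted median chromosome 17 copy number (the chr17 ploidy)
#' reaches the ratio threshold (default 2), mirroring clinical FISH-ratio
#' practice; indeterminate when chromosome 17 has no coverage.
#'
#' @param segments segment table.
#' @param erbb2_locus list/row with `chrom, start, end` of ERBB2.
#' @param chr17_segments optional segment table for the ploidy denominator;
#'   defaults to the segments on the ERBB2 chromosome.
#' @param config a [run_config()] (`her2_ratio`).
#' @return data.frame `(sample_id, erbb2_cn, chr17_ploidy, her2_cn_status)`
#'   with status in `{positive, negative, indeterminate}`.
#' @export
call_her2_cn_status <- function(segments, erbb2_locus, chr17_segments = NULL,
                                config = run_config()) {
  segments <- validate_segments(segments)
  if (is.null(chr17_segments)) {
    chr17_segments <- segments[segments$chrom == erbb2_locus$chrom, , drop = FALSE]
  } else {
    chr17_segments <- validate_segments(chr17_segments)
  }
  samples <- unique(segments$sample_id)
  rows <- lapply(samples, function(s) {
    seg <- segments[segments$sample_id == s & segments$chrom == erbb2_locus$chrom, ,
                    drop = FALSE]
    ov <- pmin(seg$end, erbb2_locus$end) - pmax(seg$start, erbb2_locus$start)
    erbb2_cn <- weighted_median(seg$total_cn, pmax(ov, 0))
    c17 <- chr17_segments[chr17_segments$sample_id == s, , drop = FALSE]
    ploidy <- weighted_median(c17$total_cn, c17$end - c17$start)
    status <- if (is.na(ploidy) || is.na(erbb2_cn) || ploidy == 0) {
      "indeterminate"
    } else if (erbb2_cn / ploidy >= config$her2_ratio) {
      "positive"
    } else {
      "negative"
    }
    data.frame(sample_id = s, erbb2_cn = erbb2_cn, chr17_ploidy = ploidy,
               her2_cn_status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
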