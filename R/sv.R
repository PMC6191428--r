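sv_columns <- function() {
  c("sample_id", "sv_type", "chrom", "start", "end", "caller",
    "filter_status", "split_read_count")
}

validate_sv_table <- function(sv, what = "SV table") {
  stopifnot(is.data.frame(sv))
  missing <- setdiff(sv_columns(), names(sv))
  if (length(missing)) stopf("%s lacks columns: %s", what, paste(missing, collapse = ", "))
  if (nrow(sv)) {
    if (any(!sv$sv_type %in% c("DEL", "DUP", "INV"))) {
      stopf("%s contains sv_type outside {DEL, DUP, INV}", what)
    }
    if (any(sv$start >= sv$end)) stopf("%s contains start >= end", what)
  }
  invisible(sv)
}

#' Build a structural-variant panel of normals
#'
#' Every SV called in at least one normal sample enters the panel,
#' regardless of its `PASS` or `LowQual` filter status. Duplicate calls
#' collapse to one entry.
#'
#' @param normal_calls SV data.frame (columns [sv_columns()]) from normal
#'   samples.
#' @return object of class `sv_panel_of_normals` holding unique
#'   `(sv_type, chrom, start, end)` entries.
#' @export
build_sv_pon <- function(normal_calls) {
  validate_sv_table(normal_calls, "normal SV calls")
  ent <- unique(normal_calls[, c("sv_type", "chrom", "start", "end"), drop = FALSE])
  rownames(ent) <- NULL
  structure(list(entries = ent), class = "sv_panel_of_normals")
}

#' @export
print.sv_panel_of_normals <- function(x, ...) {
  cat(sprintf("sv_panel_of_normals: %d entrie(s)\n", nrow(x$entries)))
  invisible(x)
}

# does anchor row match any panel entry (same type, both breakpoints within
# window; or exact keys when window is 0 / mode exact)
sv_matches_panel <- function(sv, pon, window, mode) {
  if (nrow(pon$entries) == 0L || nrow(sv) == 0L) return(rep(FALSE, nrow(sv)))
  e <- pon$entries
  vapply(seq_len(nrow(sv)), function(i) {
    cand <- e$sv_type == sv$sv_type[i] & e$chrom == sv$chrom[i]
    if (!any(cand)) return(FALSE)
    if (identical(mode, "exact")) {
      any(e$start[cand] == sv$start[i] & e$end[cand] == sv$end[i])
    } else {
      any(abs(e$start[cand] - sv$start[i]) <= window &
            abs(e$end[cand] - sv$end[i]) <= window)
    }
  }, logical(1))
}

#' Two-caller structural-variant consensus
#'
#' Anchored consensus in pipeline order: (1) anchor calls matching the SV
#' panel of normals are dropped; (2) an anchor call is corroborated when
#' at least one support call of identical type has both breakpoints within
#' the window (default 500 bp, up- or downstream); the nearest support call
#' by summed breakpoint distance is recorded (ties to the lower support
#' start); (3) corroborated pairs are dropped when any of the four
#' breakpoints falls in the repeat mask; (4) inversions require split-read
#' evidence (at least one read) from both members of the pair. The
#' asymmetry between anchor and support callers is deliberate: the result
#' is always a subset of the anchor set.
#'
#' @param anchor_calls,support_calls SV data.frames from the same sample.
#' @param pon a [build_sv_pon()] panel (or NULL to skip).
#' @param repeat_mask a [genomic_mask()].
#' @param config a [run_config()]; uses `sv_window` and `sv_pon_match`.
#' @return data.frame of retained anchor calls with matched support
#'   coordinates (`support_start`, `support_end`, `support_split_reads`).
#' @export
consensus_svs <- function(anchor_calls, support_calls, pon = NULL,
                          repeat_mask = genomic_mask(),
                          config = run_config()) {
  validate_sv_table(anchor_calls, "anchor calls")
  validate_sv_table(support_calls, "support calls")
  samples <- unique(c(anchor_calls$sample_id, support_calls$sample_id))
  if (length(samples) > 1L) {
    stopf("consensus_svs expects calls from one sample, got: %s",
          paste(samples, collapse = ", "))
  }
  window <- config$sv_window
  n0 <- nrow(anchor_calls)

  a <- anchor_calls
  if (!is.null(pon)) {
    a <- a[!sv_matches_panel(a, pon, window, config$sv_pon_match), , drop = FALSE]
  }
  if (nrow(a) == 0L || nrow(support_calls) == 0L) {
    out <- a[integer(), , drop = FALSE]
    out$support_start <- integer(); out$support_end <- integer()
    out$support_split_reads <- integer()
    log_stage("consensus_svs", n0, 0L)
    return(out)
  }
  s <- support_calls
  match_idx <- vapply(seq_len(nrow(a)), function(i) {
    cand <- which(s$sv_type == a$sv_type[i] & s$chrom == a$chrom[i] &
                    abs(s$start - a$start[i]) <= window &
                    abs(s$end - a$end[i]) <= window)
    if (!length(cand)) return(NA_integer_)
    d <- abs(s$start[cand] - a$start[i]) + abs(s$end[cand] - a$end[i])
    cand <- cand[order(d, s$start[cand])]
    cand[1]
  }, integer(1))

  keep <- !is.na(match_idx)
  a <- a[keep, , drop = FALSE]
  m <- s[match_idx[keep], , drop = FALSE]

  if (nrow(a)) {
    in_mask <- mask_contains(repeat_mask, a$chrom, a$start) |
      mask_contains(repeat_mask, a$chrom, a$end) |
      mask_contains(repeat_mask, m$chrom, m$start) |
      mask_contains(repeat_mask, m$chrom, m$end)
    a <- a[!in_mask, , drop = FALSE]
    m <- m[!in_mask, , drop = FALSE]
  }
  if (nrow(a)) {
    inv <- a$sv_type == "INV"
    bad_inv <- inv & (a$split_read_count < 1L | m$split_read_count < 1L)
    a <- a[!bad_inv, , drop = FALSE]
    m <- m[!bad_inv, , drop = FALSE]
  }
  out <- a
  out$support_start <- m$start
  out$support_end <- m$end
  out$support_split_reads <- m$split_read_count
  rownames(out) <- NULL
  log_stage("consensus_svs", n0, nrow(out))
  out
}
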