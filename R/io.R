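#' Column layout of a variant table
#'
#' Every variant record carries coordinates, alleles, class, provenance,
#' per-sample read evidence and the annotation fields used by the filter
#' cascade. Annotation fields absent from an input stay `NA` -- they are
#' never defaulted to 0.
#' @keywords internal
variant_columns <- function() {
  c(
    "chrom", "pos", "ref", "alt", "variant_class", "sample_id", "caller",
    "filter_status", "tumor_depth", "tumor_alt_count", "normal_depth",
    "normal_alt_count", "vaf", "cosmic_overlap_count", "af_1000g",
    "af_exac", "impact", "consequence", "cadd_score"
  )
}

empty_variant_table <- function() {
  df <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), variant_class = character(), sample_id = character(),
    caller = character(), filter_status = character(),
    tumor_depth = integer(), tumor_alt_count = integer(),
    normal_depth = integer(), normal_alt_count = integer(),
    vaf = numeric(), cosmic_overlap_count = numeric(),
    af_1000g = numeric(), af_exac = numeric(), impact = character(),
    consequence = character(), cadd_score = numeric(),
    stringsAsFactors = FALSE
  )
  df
}

finish_variant_table <- function(df) {
  for (col in variant_columns()) {
    if (is.null(df[[col]])) df[[col]] <- NA
  }
  df$pos <- as.integer(df$pos)
  df$tumor_depth <- as.integer(df$tumor_depth)
  df$tumor_alt_count <- as.integer(df$tumor_alt_count)
  df$variant_class <- variant_class_of(df$ref, df$alt)
  no_vaf <- is.na(df$vaf)
  if (any(no_vaf)) {
    df$vaf[no_vaf] <- ifelse(
      !is.na(df$tumor_depth[no_vaf]) & df$tumor_depth[no_vaf] > 0,
      df$tumor_alt_count[no_vaf] / df$tumor_depth[no_vaf], NA_real_
    )
  }
  rownames(df) <- NULL
  df[, variant_columns()]
}

#' Read a variant table (VCF or TSV)
#'
#' Reads SNV/indel records from a VCF (v4.x, via \pkg{vcfR}) or a
#' tab-delimited table with the variant-table columns. Multi-allelic VCF
#' records are split into one record per alternate allele. For VCF input
#' the first genotype column is taken as the tumor (its `AD` field supplies
#' ref/alt read counts) and the second, when present, as the matched
#' normal; annotation fields are read from the INFO keys `COSMIC_N`,
#' `AF_1000G`, `AF_EXAC`, `IMPACT`, `CONSEQUENCE` and `CADD`. Annotation
#' keys absent from the file are `NA`, never 0.
#'
#' @param path input file.
#' @param caller caller identifier stored in the `caller` column.
#' @param sample_id sample identifier; for TSV input an existing
#'   `sample_id` column wins.
#' @return data.frame with the [variant_columns()] layout, one row per
#'   record per alternate allele.
#' @export
read_variant_table <- function(path, caller = "unknown", sample_id = NA_character_) {
  head1 <- readLines(path, n = 1L, warn = FALSE)
  is_vcf <- grepl("^##fileformat=VCF", head1) || grepl("\\.vcf$", path)
  if (is_vcf) {
    read_variant_vcf(path, caller, sample_id)
  } else {
    read_variant_tsv(path, caller, sample_id)
  }
}

read_variant_vcf <- function(path, caller, sample_id) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("reading VCF requires the vcfR package")
  }
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variant_table())
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    stopf("malformed coordinate in %s, record %d", path, which(is.na(pos))[1])
  }
  bad_allele <- !grepl("^[ACGTNacgtn]+$", fix$REF)
  if (any(bad_allele)) {
    stopf("malformed REF allele in %s, record %d", path, which(bad_allele)[1])
  }
  gt <- vcfR::extract.gt(vcf, element = "AD")
  info_get <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else v
  }
  cosmic <- suppressWarnings(as.numeric(info_get("COSMIC_N")))
  af1k <- suppressWarnings(as.numeric(info_get("AF_1000G")))
  afex <- suppressWarnings(as.numeric(info_get("AF_EXAC")))
  impact <- info_get("IMPACT")
  csq <- info_get("CONSEQUENCE")
  cadd <- suppressWarnings(as.numeric(info_get("CADD")))

  parse_ad <- function(x) {
    if (is.na(x)) return(c(NA_integer_, NA_integer_))
    parts <- suppressWarnings(as.integer(strsplit(x, ",")[[1]]))
    c(sum(parts, na.rm = TRUE), if (length(parts) >= 2) parts[2] else NA_integer_)
  }
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    t_ad <- if (!is.null(gt) && ncol(gt) >= 1) parse_ad(gt[i, 1]) else c(NA, NA)
    n_ad <- if (!is.null(gt) && ncol(gt) >= 2) parse_ad(gt[i, 2]) else c(NA, NA)
    data.frame(
      chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i], alt = alts,
      sample_id = sample_id, caller = caller,
      filter_status = ifelse(is.na(fix$FILTER[i]), "PASS", fix$FILTER[i]),
      tumor_depth = t_ad[1], tumor_alt_count = t_ad[2],
      normal_depth = n_ad[1], normal_alt_count = n_ad[2],
      vaf = NA_real_, cosmic_overlap_count = cosmic[i], af_1000g = af1k[i],
      af_exac = afex[i], impact = impact[i], consequence = csq[i],
      cadd_score = cadd[i], stringsAsFactors = FALSE
    )
  })
  finish_variant_table(do.call(rbind, rows))
}

read_variant_tsv <- function(path, caller, sample_id) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty_variant_table())
  if (is.null(df$chrom) || is.null(df$pos) || is.null(df$ref) || is.null(df$alt)) {
    stopf("variant TSV %s must contain chrom/pos/ref/alt columns", path)
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) {
    stopf("malformed coordinate in %s, line %d", path, which(is.na(pos))[1] + 1L)
  }
  df$pos <- pos
  if (is.null(df$caller)) df$caller <- caller
  if (is.null(df$sample_id)) df$sample_id <- sample_id
  # split multi-allelic records
  multi <- grepl(",", df$alt, fixed = TRUE)
  if (any(multi)) {
    expanded <- lapply(seq_len(nrow(df)), function(i) {
      alts <- strsplit(df$alt[i], ",", fixed = TRUE)[[1]]
      out <- df[rep(i, length(alts)), , drop = FALSE]
      out$alt <- alts
      out
    })
    df <- do.call(rbind, expanded)
  }
  finish_variant_table(df)
}

#' Genomic interval mask
#'
#' A normalized (sorted, merged) set of 0-based half-open intervals backed
#' by a [GenomicRanges::GRanges]. A 1-based point `p` is contained in
#' `(start, end]` iff `start < p <= end` in BED coordinates.
#'
#' @param chrom,start,end interval vectors; `start`/`end` 0-based half-open.
#' @return object of class `genomic_mask`.
#' @export
genomic_mask <- function(chrom = character(), start = integer(), end = integer()) {
  bad <- start >= end
  if (any(bad)) {
    warnf("dropping %d mask interval(s) with start >= end", sum(bad))
    chrom <- chrom[!bad]; start <- start[!bad]; end <- end[!bad]
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
  ))
  structure(list(gr = gr), class = "genomic_mask")
}

#' Read a BED mask
#'
#' BED3+ input, 0-based half-open; intervals are sorted and merged.
#' Records with `start >= end` are rejected with a warning.
#'
#' @param path BED file.
#' @return a [genomic_mask()].
#' @export
read_bed_mask <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(genomic_mask())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stopf("malformed BED coordinates in %s", path)
  }
  genomic_mask(chrom, start, end)
}

#' Test mask membership of 1-based points
#'
#' @param mask a [genomic_mask()].
#' @param chrom,pos chromosome and 1-based position vectors.
#' @return logical vector.
#' @export
mask_contains <- function(mask, chrom, pos) {
  stopifnot(inherits(mask, "genomic_mask"))
  if (length(mask$gr) == 0L || length(pos) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  q <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L)
  )
  GenomicRanges::countOverlaps(q, mask$gr) > 0L
}

#' @export
print.genomic_mask <- function(x, ...) {
  cat(sprintf("genomic_mask with %d merged interval(s)\n", length(x$gr)))
  invisible(x)
}

#' Total masked length in bp
#' @param mask a [genomic_mask()].
#' @export
mask_width <- function(mask) sum(IRanges::width(mask$gr))

#' Write a result table deterministically
#'
#' Tab-delimited with header, rows sorted by the leading columns, doubles
#' written at full precision so that [read_table()] round-trips exactly.
#'
#' @param records data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- records
  if (nrow(df) > 1L) df <- df[do.call(order, df), , drop = FALSE]
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- sprintf("%.17g", df[[col]])
      v[is.na(df[[col]])] <- "NA"
      df[[col]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("cannot write table to '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path input path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
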