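`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical variant keys
#'
#' Builds `"chrom:pos:ref:alt"` identity keys, optionally left-normalizing
#' indel representations first (shared allele suffix then prefix trimmed,
#' keeping at least one base of each allele and shifting `pos` with the
#' prefix), so that equivalent records from different callers compare equal.
#'
#' @param chrom,pos,ref,alt vectors describing variants (recycled together).
#' @param normalize left-normalize indel alleles before keying.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt, normalize = TRUE) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  if (normalize) {
    needs <- nchar(ref) != 1L | nchar(alt) != 1L
    for (i in which(needs)) {
      r <- strsplit(ref[i], "")[[1]]
      a <- strsplit(alt[i], "")[[1]]
      # trim common suffix
      while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
        r <- r[-length(r)]
        a <- a[-length(a)]
      }
      # trim common prefix, shifting pos
      shift <- 0L
      while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
        r <- r[-1L]
        a <- a[-1L]
        shift <- shift + 1L
      }
      ref[i] <- paste(r, collapse = "")
      alt[i] <- paste(a, collapse = "")
      pos[i] <- pos[i] + shift
    }
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

# classify a ref/alt pair as SNV or indel
variant_class_of <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "indel")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# filter-stage audit logging: record counts in -> out
log_stage <- function(stage, n_in, n_out, verbose = getOption("somasig.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %d records in, %d retained", stage, n_in, n_out))
  }
  invisible(NULL)
}
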