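#' The 96 single-base-substitution classes
#'
#' Returns the conventional pyrimidine-centered 96-class vocabulary:
#' the six substitution types (C>A, C>G, C>T, T>A, T>C, T>G) crossed with
#' the sixteen 5'/3' flanking-base pairs, ordered substitution-major and
#' then lexicographically by flanks. Labels follow the `"A[C>T]G"`
#' convention used in catalog headers.
#'
#' @return character vector of length 96.
#' @export
sbs96_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(p5) paste0(p5, "[", s, "]", bases)))
  }))
}

#' The 32 pyrimidine-centered trinucleotides
#'
#' @return character vector of the 32 trinucleotides whose middle base is a
#'   pyrimidine, in the order matching [sbs96_contexts()] flank order.
#' @export
trinucleotides32 <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(c("C", "T"), function(m) {
    unlist(lapply(bases, function(p5) paste0(p5, m, bases)))
  }))
}

# map each of the 96 classes to its central trinucleotide
sbs96_to_trinucleotide <- function() {
  ctx <- sbs96_contexts()
  paste0(substr(ctx, 1, 1), substr(ctx, 3, 3), substr(ctx, 7, 7))
}

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

#' Classify SNVs into 96 substitution classes
#'
#' Assigns each SNV to one of the 96 pyrimidine-centered classes. Sites with
#' a purine reference base are reverse-complemented (both alleles and the
#' flanking context) before classification. Contexts containing `N` yield
#' `NA`.
#'
#' @param ref,alt single-base reference and alternate alleles.
#' @param context reference trinucleotide centered on the site (plus strand).
#' @return character vector of class labels (e.g. `"T[C>T]A"`), `NA` where
#'   the context is unusable.
#' @export
classify_sbs96 <- function(ref, alt, context) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  context <- toupper(context)
  n <- length(ref)
  out <- rep(NA_character_, n)
  ok <- nchar(ref) == 1L & nchar(alt) == 1L & nchar(context) == 3L &
    !grepl("N", context) & substr(context, 2, 2) == ref & ref != alt
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; cx <- context[ok]
  purine <- r %in% c("A", "G")
  if (any(purine)) {
    cx[purine] <- revcomp(cx[purine])
    r[purine] <- revcomp(r[purine])
    a[purine] <- revcomp(a[purine])
  }
  out[ok] <- paste0(
    substr(cx, 1, 1), "[", r, ">", a, "]", substr(cx, 3, 3)
  )
  out[ok][!out[ok] %in% sbs96_contexts()] <- NA_character_
  out
}

#' Bundled simulation signature profiles
#'
#' Nine fixed probability profiles over the 96 substitution classes used by
#' the synthetic cohort generator: two APOBEC-like profiles sharply peaked
#' at TCW contexts (C>T and C>G), an aging-like profile concentrated on
#' C>T at CpG sites, a flat HRD-like profile, a broad C>A profile standing
#' in for signature 8, and four sparse profiles (D-G) generated once from a
#' fixed internal seed. All rows sum to 1 and the set is mutually
#' well-separated (low pairwise cosine), so factorizations of simulated
#' catalogs have an unambiguous truth.
#'
#' @return 9 x 96 numeric matrix, rows named
#'   `APOBEC_CT, APOBEC_CG, Aging, Signature8, HRD, SignatureD..SignatureG`,
#'   columns named by [sbs96_contexts()].
#' @export
reference_signature_profiles <- function() {
  ctx <- sbs96_contexts()
  base <- function() stats::setNames(rep(0.02, 96), ctx)

  apobec_ct <- base()
  apobec_ct[c("T[C>T]A", "T[C>T]T")] <- 30
  apobec_ct[c("T[C>T]C", "T[C>T]G")] <- 3

  apobec_cg <- base()
  apobec_cg[c("T[C>G]A", "T[C>G]T")] <- 30
  apobec_cg[c("T[C>G]C", "T[C>G]G")] <- 3

  aging <- base()
  aging[paste0(c("A", "C", "G", "T"), "[C>T]G")] <- 20

  hrd <- stats::setNames(1 + 0.3 * cos(2 * pi * seq_len(96) / 96), ctx)

  sig8 <- base()
  sig8[grepl("C>A", ctx, fixed = TRUE)] <- 6

  sparse <- withr::with_seed(190224, {
    lapply(1:4, function(i) {
      v <- base()
      v[sample.int(96, 12)] <- stats::rexp(12, rate = 0.2) + 2
      v
    })
  })

  prof <- rbind(
    APOBEC_CT = apobec_ct, APOBEC_CG = apobec_cg, Aging = aging,
    Signature8 = sig8, HRD = hrd,
    SignatureD = sparse[[1]], SignatureE = sparse[[2]],
    SignatureF = sparse[[3]], SignatureG = sparse[[4]]
  )
  prof / rowSums(prof)
}

#' Trinucleotide frequencies of a sequencing territory
#'
#' Frequencies of the 32 pyrimidine-centered trinucleotides in the assayable
#' territory. The genome territory is uniform; the exome territory is a
#' fixed, deterministic non-uniform profile emulating the GC/CpG skew of
#' coding sequence. Used by [normalize_catalog()] to bring exome and genome
#' catalogs onto a common scale.
#'
#' @param territory `"genome"` or `"exome"`.
#' @return named numeric vector of 32 positive frequencies summing to 1.
#' @export
territory_context_frequencies <- function(territory = c("genome", "exome")) {
  territory <- match.arg(territory)
  tri <- trinucleotides32()
  if (territory == "genome") {
    f <- rep(1, 32)
  } else {
    i <- seq_len(32)
    f <- 0.5 + ((7L * i) %% 13L) / 13L
    f[grepl("CG$|^CG", tri)] <- f[grepl("CG$|^CG", tri)] * 1.6
  }
  stats::setNames(f / sum(f), tri)
}
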