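#' Construct a mutation catalog object
#'
#' @param counts samples x 96 non-negative matrix with column names in
#'   [sbs96_contexts()] order (reordered if needed) and sample row names.
#' @param min_snvs inclusion gate on per-sample totals (default 100).
#' @return object of class `mutation_catalog`: `counts`, `totals`,
#'   `included`, `min_snvs`.
#' @export
mutation_catalog <- function(counts, min_snvs = 100L) {
  ctx <- sbs96_contexts()
  stopifnot(is.matrix(counts), ncol(counts) == 96L)
  if (!is.null(colnames(counts))) {
    stopifnot(setequal(colnames(counts), ctx))
    counts <- counts[, ctx, drop = FALSE]
  } else {
    colnames(counts) <- ctx
  }
  if (any(counts < 0)) stopf("catalog counts must be non-negative")
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  totals <- rowSums(counts)
  structure(
    list(counts = counts, totals = totals,
         included = totals >= min_snvs, min_snvs = as.integer(min_snvs)),
    class = "mutation_catalog"
  )
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("mutation_catalog: %d samples x 96 contexts, %d included (>= %d SNVs)\n",
              nrow(x$counts), sum(x$included), x$min_snvs))
  invisible(x)
}

#' Build a 96-context catalog from SNV calls
#'
#' Assigns every SNV to one of the 96 pyrimidine-centered substitution
#' classes (purine-reference sites are reverse-complemented) and tabulates
#' counts per sample. The trinucleotide context comes from a per-variant
#' `context` column or argument, or is looked up in `reference` (a named
#' list/vector of chromosome sequences). SNVs whose context contains `N`
#' or is otherwise unusable are dropped with a warning.
#'
#' @param snvs variant table of SNVs (all rows with `variant_class ==
#'   "SNV"` are used).
#' @param context optional character vector of reference trinucleotides,
#'   one per row of `snvs`; defaults to `snvs$context`.
#' @param reference optional named character vector/list of chromosome
#'   sequences for context lookup.
#' @param config a [run_config()] (inclusion gate).
#' @return a [mutation_catalog()].
#' @export
build_catalog <- function(snvs, context = NULL, reference = NULL,
                          config = run_config()) {
  snvs <- snvs[snvs$variant_class == "SNV", , drop = FALSE]
  if (is.null(context)) context <- snvs$context
  if (is.null(context) && !is.null(reference)) {
    context <- vapply(seq_len(nrow(snvs)), function(i) {
      seqc <- reference[[snvs$chrom[i]]]
      if (is.null(seqc)) return(NA_character_)
      substr(seqc, snvs$pos[i] - 1L, snvs$pos[i] + 1L)
    }, character(1))
  }
  if (is.null(context)) {
    stopf("build_catalog needs a per-variant context column or a reference")
  }
  cls <- classify_sbs96(snvs$ref, snvs$alt, context)
  dropped <- sum(is.na(cls))
  if (dropped > 0) {
    warnf("dropping %d SNV(s) with unusable trinucleotide context", dropped)
  }
  keep <- !is.na(cls)
  ctx <- sbs96_contexts()
  samples <- unique(snvs$sample_id)
  counts <- matrix(0L, nrow = length(samples), ncol = 96L,
                   dimnames = list(samples, ctx))
  if (any(keep)) {
    tab <- table(factor(snvs$sample_id[keep], levels = samples),
                 factor(cls[keep], levels = ctx))
    counts <- matrix(as.integer(tab), nrow = length(samples),
                     dimnames = list(samples, ctx))
  }
  mutation_catalog(counts, min_snvs = config$min_snvs_per_sample)
}

#' Gate catalog samples on mutation count
#'
#' Samples with at least `min_snvs` mutations (inclusive) are flagged
#' included; excluded samples remain in the catalog but are ignored by the
#' factorization.
#'
#' @param catalog a [mutation_catalog()].
#' @param min_snvs threshold (default 100).
#' @return the catalog with refreshed `included` flags.
#' @export
gate_samples <- function(catalog, min_snvs = 100L) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  catalog$included <- catalog$totals >= min_snvs
  catalog$min_snvs <- as.integer(min_snvs)
  catalog
}

#' Normalize a catalog for factorization
#'
#' Rescales each context count by the ratio of its trinucleotide frequency
#' in the target territory to that in the sample's source territory (so
#' exome and genome samples become comparable), then divides each row by
#' its sum so rows are spectra on the simplex. With `rescale = FALSE` only
#' the per-sample row normalization is applied.
#'
#' @param catalog a [mutation_catalog()] (or samples x 96 matrix).
#' @param source_territory per-sample territory, `"exome"` or `"genome"`
#'   (scalar or named vector); default `"genome"`.
#' @param target target territory (default `"genome"`).
#' @param rescale apply the context-frequency correction.
#' @param freqs optional list of named 32-vectors overriding
#'   [territory_context_frequencies()].
#' @return numeric matrix with the same shape; non-empty rows sum to 1.
#' @export
normalize_catalog <- function(catalog, source_territory = "genome",
                              target = "genome", rescale = TRUE,
                              freqs = NULL) {
  counts <- if (inherits(catalog, "mutation_catalog")) catalog$counts else catalog
  if (is.null(colnames(counts))) colnames(counts) <- sbs96_contexts()
  counts <- counts[, sbs96_contexts(), drop = FALSE]
  n <- nrow(counts)
  get_freq <- function(t) {
    if (!is.null(freqs) && !is.null(freqs[[t]])) freqs[[t]] else territory_context_frequencies(t)
  }
  out <- counts * 1.0
  if (rescale) {
    tri <- sbs96_to_trinucleotide()
    src <- if (length(source_territory) == 1L) {
      rep(source_territory, n)
    } else {
      unname(source_territory[rownames(counts)])
    }
    tgt_f <- get_freq(target)[tri]
    for (terr in unique(src)) {
      ratio <- tgt_f / get_freq(terr)[tri]
      rows <- which(src == terr)
      out[rows, ] <- sweep(counts[rows, , drop = FALSE], 2L, ratio, `*`)
    }
  }
  rs <- rowSums(out)
  out[rs > 0, ] <- out[rs > 0, , drop = FALSE] / rs[rs > 0]
  out
}

kl_divergence <- function(V, WH, eps = 1e-12) {
  WH <- pmax(WH, eps)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

# one seeded run of multiplicative-update KL NMF, V (n x m) ~ W (n x k) H (k x m)
nmf_kl_once <- function(V, k, max_iter, tol, seed, trace = FALSE) {
  n <- nrow(V); m <- ncol(V)
  eps <- 1e-12
  withr::with_seed(seed, {
    W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
    H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  })
  d_prev <- Inf
  divergences <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    H <- H * (crossprod(W, V / pmax(WH, eps))) / pmax(colSums(W), eps)
    WH <- W %*% H
    W <- W * ((V / pmax(WH, eps)) %*% t(H)) /
      matrix(pmax(rowSums(H), eps), n, k, byrow = TRUE)
    d <- kl_divergence(V, W %*% H, eps)
    if (trace) divergences <- c(divergences, d)
    if (is.finite(d_prev) && (d_prev - d) <= tol * max(d_prev, eps)) {
      converged <- TRUE
      break
    }
    d_prev <- d
  }
  list(W = W, H = H, divergence = d, iterations = it, converged = converged,
       trace = divergences)
}

#' Extract mutational signatures by KL-NMF
#'
#' Factorizes the normalized catalog into `k` non-negative signature
#' profiles and per-sample exposures by minimizing the generalized
#' Kullback-Leibler divergence with multiplicative updates. The best of
#' `restarts` seeded initializations (by final divergence) is kept; the
#' factor scale is fixed by normalizing profiles to probability vectors
#' and absorbing the scale into the exposures. Deterministic given `seed`.
#'
#' @param normalized samples x 96 non-negative matrix (output of
#'   [normalize_catalog()]); rows that are all zero are rejected.
#' @param k number of signatures (default 9).
#' @param restarts number of random initializations (default 30).
#' @param seed base seed; restart `r` uses `seed + r - 1`.
#' @param max_iter,tol multiplicative-update iteration cap and relative
#'   divergence tolerance.
#' @return object of class `signature_set`: `profiles` (k x 96,
#'   row-stochastic), `exposures` (samples x k), `divergence`,
#'   `iterations`, `k`, `seed`.
#' @export
extract_signatures <- function(normalized, k = 9L, restarts = 30L, seed = 1L,
                               max_iter = 5000L, tol = 1e-8) {
  V <- as.matrix(normalized)
  if (nrow(V) == 0L) stopf("no included samples to factorize")
  if (k < 1L) stopf("k must be >= 1")
  if (k > nrow(V)) stopf("k (%d) exceeds the number of included samples (%d)", k, nrow(V))
  degenerate <- rowSums(V) == 0
  if (any(degenerate)) {
    stopf("degenerate all-zero rows in factorization input: %s",
          paste(utils::head(rownames(V)[degenerate]), collapse = ", "))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- nmf_kl_once(V, k, max_iter, tol, seed = seed + r - 1L)
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  if (!best$converged) {
    warnf("NMF did not reach tolerance %g within %d iterations (divergence %g)",
          tol, max_iter, best$divergence)
  }
  scale <- rowSums(best$H)
  profiles <- best$H / scale
  exposures <- sweep(best$W, 2L, scale, `*`)
  rownames(profiles) <- paste0("Factor", seq_len(k))
  colnames(profiles) <- colnames(V)
  colnames(exposures) <- rownames(profiles)
  rownames(exposures) <- rownames(V)
  structure(
    list(profiles = profiles, exposures = exposures,
         divergence = best$divergence, iterations = best$iterations,
         k = as.integer(k), seed = as.integer(seed)),
    class = "signature_set"
  )
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: k = %d over %d samples (KL divergence %.4g)\n",
              x$k, nrow(x$exposures), x$divergence))
  if (!is.null(x$labels)) {
    cat("labels:", paste(sprintf("%s=%s", x$labels$factor, x$labels$label),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match factor profiles to reference signatures
#'
#' Greedy one-to-one assignment of factors to named reference profiles in
#' descending cosine-similarity order; a factor is labeled only when its
#' cosine reaches the threshold (default 0.8), otherwise `"unmatched"`.
#'
#' @param profiles k x 96 matrix of factor profiles (rows).
#' @param reference named reference profile matrix (rows), e.g.
#'   [reference_signature_profiles()].
#' @param threshold minimum cosine for labeling.
#' @return data.frame `(factor, label, cosine)` in factor order.
#' @export
match_signatures <- function(profiles, reference = reference_signature_profiles(),
                             threshold = 0.8) {
  stopifnot(ncol(profiles) == ncol(reference))
  kf <- nrow(profiles); kr <- nrow(reference)
  cm <- matrix(0, kf, kr, dimnames = list(rownames(profiles), rownames(reference)))
  for (i in seq_len(kf)) {
    for (j in seq_len(kr)) cm[i, j] <- cosine_similarity(profiles[i, ], reference[j, ])
  }
  label <- rep("unmatched", kf)
  cosine <- rep(NA_real_, kf)
  free_f <- rep(TRUE, kf); free_r <- rep(TRUE, kr)
  repeat {
    sub <- cm
    sub[!free_f, ] <- -Inf
    sub[, !free_r] <- -Inf
    best <- which(sub == max(sub), arr.ind = TRUE)[1, , drop = TRUE]
    if (!is.finite(sub[best[1], best[2]])) break
    i <- best[1]; j <- best[2]
    cosine[i] <- cm[i, j]
    if (cm[i, j] >= threshold) label[i] <- rownames(reference)[j]
    free_f[i] <- FALSE; free_r[j] <- FALSE
    if (!any(free_f) || !any(free_r)) break
  }
  data.frame(
    factor = rownames(profiles) %||% paste0("Factor", seq_len(kf)),
    label = label, cosine = cosine, stringsAsFactors = FALSE
  )
}

#' Per-sample signature contributions by NNLS
#'
#' Refits each sample's normalized 96-context spectrum against the signature
#' profiles by non-negative least squares and renormalizes the coefficients
#' to sum to 1, giving the proportion of the sample's mutations attributed
#' to each signature. Samples below the inclusion gate (or with empty
#' spectra) get missing contributions.
#'
#' @param catalog a [mutation_catalog()], or a samples x 96 matrix of
#'   counts/spectra (then every non-empty row is attributed).
#' @param profiles k x 96 row-stochastic signature profile matrix.
#' @param source_territory per-sample sequencing territory passed to
#'   [normalize_catalog()] so exome spectra are corrected onto the
#'   profiles' (genome) scale before fitting.
#' @return samples x k matrix of contributions; included rows lie on the
#'   simplex.
#' @export
compute_contributions <- function(catalog, profiles,
                                  source_territory = "genome") {
  if (inherits(catalog, "mutation_catalog")) {
    counts <- catalog$counts
    use <- catalog$included & catalog$totals > 0
  } else {
    counts <- as.matrix(catalog)
    if (is.null(colnames(counts))) colnames(counts) <- sbs96_contexts()
    use <- rowSums(counts) > 0
  }
  spectra <- normalize_catalog(counts, source_territory = source_territory)
  spectra <- spectra[, colnames(profiles), drop = FALSE]
  k <- nrow(profiles)
  C <- t(profiles)
  out <- matrix(NA_real_, nrow(counts), k,
                dimnames = list(rownames(counts), rownames(profiles)))
  for (i in which(use)) {
    fit <- pracma::lsqnonneg(C, spectra[i, ])
    x <- fit$x
    if (sum(x) <= 0) next
    out[i, ] <- x / sum(x)
  }
  out
}

#' Combined APOBEC contribution
#'
#' Sums the APOBEC C>T and APOBEC C>G contributions per sample. Missing
#' (with a warning) when either APOBEC factor is unlabeled.
#'
#' @param contributions samples x k contribution matrix whose column names
#'   carry signature labels, or a `signature_set` with `contributions` and
#'   `labels`.
#' @param ct_label,cg_label the two APOBEC labels (defaults `APOBEC_CT`,
#'   `APOBEC_CG`).
#' @return named numeric vector per sample.
#' @export
combine_apobec <- function(contributions, ct_label = "APOBEC_CT",
                           cg_label = "APOBEC_CG") {
  if (inherits(contributions, "signature_set")) {
    m <- contributions$contributions
    if (!is.null(contributions$labels)) {
      colnames(m) <- contributions$labels$label[
        match(colnames(m), contributions$labels$factor)]
    }
  } else {
    m <- as.matrix(contributions)
  }
  if (!all(c(ct_label, cg_label) %in% colnames(m))) {
    warnf("APOBEC label(s) missing from contributions; returning NA")
    return(stats::setNames(rep(NA_real_, nrow(m)), rownames(m)))
  }
  stats::setNames(m[, ct_label, drop = TRUE] + m[, cg_label, drop = TRUE],
                  rownames(m))
}

#' Full signature analysis of a catalog
#'
#' Convenience wrapper: gate samples, normalize, factorize, match factors
#' to the bundled reference profiles, and attribute contributions to the
#' included samples. Contribution columns are renamed to their matched
#' labels (unmatched factors keep their factor name).
#'
#' @param catalog a [mutation_catalog()].
#' @param source_territory per-sample territory for normalization.
#' @param reference reference profile matrix for labeling.
#' @param config a [run_config()].
#' @return a `signature_set` with added `labels` and `contributions`.
#' @export
run_signature_analysis <- function(catalog, source_territory = "genome",
                                   reference = reference_signature_profiles(),
                                   config = run_config()) {
  catalog <- gate_samples(catalog, config$min_snvs_per_sample)
  if (!any(catalog$included)) stopf("no samples pass the %d-SNV inclusion gate",
                                    config$min_snvs_per_sample)
  V <- normalize_catalog(catalog, source_territory = source_territory)
  Vin <- V[catalog$included, , drop = FALSE]
  sigs <- extract_signatures(
    Vin, k = config$n_signatures, restarts = config$nmf_restarts,
    seed = config$seed, max_iter = config$nmf_max_iter, tol = config$nmf_tol
  )
  sigs$labels <- match_signatures(sigs$profiles, reference,
                                  threshold = config$cosine_label_threshold)
  contrib <- compute_contributions(catalog, sigs$profiles,
                                   source_territory = source_territory)
  lab <- sigs$labels$label
  lab[lab == "unmatched"] <- sigs$labels$factor[lab == "unmatched"]
  colnames(contrib) <- lab
  sigs$contributions <- contrib
  sigs
}
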