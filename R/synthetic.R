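#' Synthetic cohort generator parameters
#'
#' Collects every knob of the synthetic cohort: sample size, cohort and
#' driver-prevalence structure, the group-conditional Dirichlet over
#' signature mixtures, mutation-count distribution, caller error model,
#' artifact recurrence, SV jitter, and seed. Defaults are the study
#' conditions described in the methods vignette.
#'
#' @param ... named overrides of the defaults below.
#' @return object of class `generator_params`.
#'
#' @details Key defaults:
#' * `n_samples` (200), `cohort_probs` (A/B/C equal thirds).
#' * `driver_prevalence`: per-cohort Bernoulli rates for TP53, BRCA1/2
#'   (incl. germline), PIK3CA, CDH1, GATA3 (cohort A 62/11.6/17/0.8/17.1%,
#'   B 46/7/20/6.4/10%, C 29/4/36/16.2/9.5%).
#' * `dirichlet_concentration` (50): precision of per-sample mixtures
#'   around their balance-group mean.
#' * `effect_scale` (1): 0 collapses all group means to the grand mean
#'   (null cohort), 1 is the full planted effect (TP53/BRCA mean HRD 0.45
#'   vs CDH1/PIK3CA 0.15, reciprocal combined APOBEC).
#' * `mut_meanlog` (`log(500)`), `mut_sdlog` (0.8): log-normal mutation
#'   counts, median ~500, heavy tail; samples under 100 are kept but
#'   flagged for exclusion. `mut_count_range` (NULL): when set to
#'   `c(lo, hi)`, counts are instead drawn uniformly on that range (used
#'   by the recovery studies).
#' * `wgs_fraction` (0.2): fraction of samples assigned genome territory.
#' * `n_somatic_per_sample` (50), `sensitivity_a/_b` (0.95),
#'   `n_fp_per_caller` (5): pseudo-caller behavior for SNV call sets.
#' * `n_artifact_sites` (20), `artifact_recurrence` (3 normals),
#'   `artifact_tumor_count` (3), `rescue_fraction` (0.25), `n_normals`
#'   (30): recurrent-artifact and panel-of-normals structure.
#' * `n_indel_per_sample` (12), `n_indel_ppon_sites` (5).
#' * `sv_true_per_sample` (10), `sv_unique_per_caller` (5),
#'   `sv_pon_per_sample` (2), `sv_repeat_per_sample` (1),
#'   `sv_splitfail_per_sample` (1), `sv_jitter` (250 bp per caller, so two
#'   independently jittered breakpoints stay within the 500 bp window).
#' * `seed` (1).
#' @export
generator_params <- function(...) {
  p <- list(
    n_samples = 200L,
    cohort_probs = c(A = 1 / 3, B = 1 / 3, C = 1 / 3),
    driver_prevalence = rbind(
      A = c(tp53 = 0.62, brca = 0.116, pik3ca = 0.17, cdh1 = 0.008, gata3 = 0.171),
      B = c(tp53 = 0.46, brca = 0.070, pik3ca = 0.20, cdh1 = 0.064, gata3 = 0.100),
      C = c(tp53 = 0.29, brca = 0.040, pik3ca = 0.36, cdh1 = 0.162, gata3 = 0.095)
    ),
    subtype_probs = rbind(
      A = c("HR+/HER2-" = 0.32, "HR-/HER2-" = 0.43, "HER2+" = 0.25),
      B = c("HR+/HER2-" = 0.61, "HR-/HER2-" = 0.33, "HER2+" = 0.06),
      C = c("HR+/HER2-" = 0.85, "HR-/HER2-" = 0.13, "HER2+" = 0.02)
    ),
    dirichlet_concentration = 50,
    effect_scale = 1,
    mut_meanlog = log(500),
    mut_sdlog = 0.8,
    mut_count_range = NULL,
    wgs_fraction = 0.2,
    n_somatic_per_sample = 50L,
    sensitivity_a = 0.95,
    sensitivity_b = 0.95,
    n_fp_per_caller = 5L,
    n_artifact_sites = 20L,
    artifact_recurrence = 3L,
    artifact_tumor_count = 3L,
    rescue_fraction = 0.25,
    n_normals = 30L,
    n_indel_per_sample = 12L,
    n_indel_ppon_sites = 5L,
    sv_true_per_sample = 10L,
    sv_unique_per_caller = 5L,
    sv_pon_per_sample = 2L,
    sv_repeat_per_sample = 1L,
    sv_splitfail_per_sample = 1L,
    sv_jitter = 250L,
    sv_window = 500L,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stopf("unknown generator params: %s", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  rates <- c(p$sensitivity_a, p$sensitivity_b, p$rescue_fraction,
             p$wgs_fraction, p$effect_scale)
  if (any(rates < 0 | rates > 1)) stopf("generator rates must lie in [0, 1]")
  if (p$sv_jitter > p$sv_window) stopf("sv_jitter must not exceed sv_window")
  if (p$n_samples < 1L) stopf("n_samples must be >= 1")
  structure(p, class = "generator_params")
}

#' Balance-group mean signature mixtures
#'
#' The four group-conditional mean mixtures over the nine bundled
#' signatures. At `effect_scale = 1`: TP53/BRCA mean HRD 0.45 with
#' combined APOBEC 0.15; CDH1/PIK3CA the reverse (HRD 0.15, APOBEC 0.45);
#' Both intermediate; Neither shaped like TP53/BRCA (HRD 0.35). At
#' `effect_scale = 0` every group sits at the grand mean.
#'
#' @param effect_scale interpolation between null (0) and planted (1).
#' @return 4 x 9 matrix, rows the balance groups, columns the signature
#'   names of [reference_signature_profiles()]; rows sum to 1.
#' @export
balance_group_means <- function(effect_scale = 1) {
  sig <- rownames(reference_signature_profiles())
  other <- rep(0.15 / 4, 4)
  m <- rbind(
    "CDH1/PIK3CA" = c(0.30, 0.15, 0.15, 0.10, 0.15, other),
    "TP53/BRCA"   = c(0.10, 0.05, 0.15, 0.10, 0.45, other),
    "Both"        = c(0.20, 0.10, 0.15, 0.10, 0.30, other),
    "Neither"     = c(2 / 15, 1 / 15, 0.20, 0.10, 0.35, other)
  )
  colnames(m) <- sig
  grand <- colMeans(m)
  out <- (1 - effect_scale) * matrix(grand, 4, 9, byrow = TRUE) +
    effect_scale * m
  dimnames(out) <- dimnames(m)
  out
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate a synthetic tumor cohort
#'
#' Draws per-sample cohort labels, IHC subtypes, ages, and driver statuses
#' (per-cohort prevalence), assigns the four-way balance group, and draws
#' each sample's true signature mixture from a Dirichlet centered on its
#' group mean (concentration `dirichlet_concentration`), so the TP53/BRCA
#' group's expected HRD share exceeds the CDH1/PIK3CA group's and vice
#' versa for combined APOBEC. Mutation counts are log-normal; samples below
#' 100 mutations are retained but flagged excluded. Deterministic given
#' the seed.
#'
#' @param params a [generator_params()].
#' @return object of class `cohort_truth`: `samples` (data.frame),
#'   `mixtures` (n x 9 matrix on the simplex), `signature_names`, `params`.
#' @export
simulate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_samples
  withr::with_seed(params$seed, {
    cohort <- sample(names(params$cohort_probs), n, replace = TRUE,
                     prob = params$cohort_probs)
    subtype <- vapply(cohort, function(co) {
      sample(colnames(params$subtype_probs), 1L,
             prob = params$subtype_probs[co, ])
    }, character(1))
    age <- pmin(pmax(round(stats::rnorm(n, 55, 12)), 25), 90)
    prev <- params$driver_prevalence[cohort, , drop = FALSE]
    tp53 <- stats::runif(n) < prev[, "tp53"]
    brca <- stats::runif(n) < prev[, "brca"]
    pik3ca <- stats::runif(n) < prev[, "pik3ca"]
    cdh1 <- stats::runif(n) < prev[, "cdh1"]
    gata3 <- stats::runif(n) < prev[, "gata3"]
    group <- assign_balance_group(tp53, brca, pik3ca, cdh1)
    means <- balance_group_means(params$effect_scale)
    alpha <- means[as.character(group), , drop = FALSE] *
      params$dirichlet_concentration
    mixtures <- t(apply(alpha, 1L, rdirichlet1))
    colnames(mixtures) <- colnames(means)
    mutation_count <- if (!is.null(params$mut_count_range)) {
      r <- params$mut_count_range
      as.integer(round(stats::runif(n, r[1], r[2])))
    } else {
      pmax(1L, as.integer(round(
        stats::rlnorm(n, params$mut_meanlog, params$mut_sdlog))))
    }
    territory <- ifelse(stats::runif(n) < params$wgs_fraction, "genome", "exome")
  })
  sample_id <- sprintf("S%03d", seq_len(n))
  rownames(mixtures) <- sample_id
  samples <- data.frame(
    sample_id = sample_id, cohort = cohort, ihc_subtype = unname(subtype),
    age = age, tp53 = tp53, brca = brca, pik3ca = pik3ca, cdh1 = cdh1,
    gata3 = gata3, balance_group = group, territory = territory,
    mutation_count = mutation_count,
    included = mutation_count >= 100L,
    stringsAsFactors = FALSE
  )
  rownames(samples) <- NULL
  structure(
    list(samples = samples, mixtures = mixtures,
         signature_names = colnames(mixtures), params = params),
    class = "cohort_truth"
  )
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("cohort_truth: %d samples (%d with >= 100 mutations)\n",
              nrow(x$samples), sum(x$samples$included)))
  print(table(x$samples$balance_group))
  invisible(x)
}

#' Simulate a 96-context mutation catalog from truth mixtures
#'
#' Draws each sample's catalog row from a multinomial over the 96 classes
#' with probabilities given by the sample's mixture-weighted signature
#' profiles, at the sample's true mutation count (row sums match truth
#' exactly). Samples on genome territory use the profiles as-is; exome
#' samples have class probabilities reweighted by the exome/genome
#' trinucleotide frequency ratio, emulating territory composition.
#'
#' @param truth a [simulate_cohort()] result.
#' @param signature_profiles k x 96 row-stochastic profile matrix whose
#'   rows match `truth$signature_names`.
#' @return a [mutation_catalog()].
#' @export
simulate_mutation_catalog <- function(truth,
                                      signature_profiles = reference_signature_profiles()) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (any(abs(rowSums(signature_profiles) - 1) > 1e-9)) {
    stopf("signature profile rows must sum to 1 (tolerance 1e-9)")
  }
  P <- signature_profiles[truth$signature_names, sbs96_contexts(), drop = FALSE]
  probs <- truth$mixtures %*% P
  tri <- sbs96_to_trinucleotide()
  ratio_exome <- (territory_context_frequencies("exome") /
                    territory_context_frequencies("genome"))[tri]
  n <- nrow(probs)
  counts <- matrix(0L, n, 96L,
                   dimnames = list(truth$samples$sample_id, sbs96_contexts()))
  withr::with_seed(truth$params$seed + 1L, {
    for (i in seq_len(n)) {
      p <- probs[i, ]
      if (truth$samples$territory[i] == "exome") p <- p * ratio_exome
      p <- p / sum(p)
      m <- truth$samples$mutation_count[i]
      if (m > 0) counts[i, ] <- as.integer(stats::rmultinom(1L, m, p))
    }
  })
  mutation_catalog(counts, min_snvs = 100L)
}

random_snv_alleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1))
  list(ref = ref, alt = unname(alt))
}

snv_row <- function(chrom, pos, ref, alt, sample_id, caller, filter = "PASS",
                    depth = 80L, alt_count = NULL, normal_alt = 0L,
                    cosmic = NA_real_, af1k = NA_real_, afex = NA_real_) {
  if (is.null(alt_count)) alt_count <- pmax(1L, as.integer(round(depth * 0.3)))
  data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    variant_class = variant_class_of(ref, alt), sample_id = sample_id,
    caller = caller, filter_status = filter,
    tumor_depth = as.integer(depth), tumor_alt_count = as.integer(alt_count),
    normal_depth = 60L, normal_alt_count = as.integer(normal_alt),
    vaf = alt_count / depth, cosmic_overlap_count = cosmic,
    af_1000g = af1k, af_exac = afex, impact = NA_character_,
    consequence = NA_character_, cadd_score = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate two-caller SNV call sets with a normal panel
#'
#' Emits each sample's true somatic SNVs through two pseudo-callers with
#' the configured sensitivities, adds caller-unique false positives, and
#' plants recurrent artifact sites that appear in tumors (both callers,
#' PASS) and carry >= 5% alternate-read support at depth >= 10 in
#' `artifact_recurrence` normals, so the panel of normals blacklists them.
#' A `rescue_fraction` subset of artifact sites is tagged with a COSMIC
#' overlap count > 1 and population frequencies below 0.005, exercising
#' the rescue rule. Bookkeeping records, per emitted site and sample,
#' which cascade outcome is expected.
#'
#' @param truth a [simulate_cohort()] result.
#' @param params a [generator_params()] (defaults to the truth's).
#' @return list with `calls_a`, `calls_b` (variant tables),
#'   `normal_pileups`, and `truth` (bookkeeping data.frame with
#'   `expected_retained`).
#' @export
simulate_caller_outputs <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (params$sensitivity_a < 0 || params$sensitivity_a > 1 ||
      params$sensitivity_b < 0 || params$sensitivity_b > 1) {
    stopf("caller sensitivities must lie in [0, 1]")
  }
  ids <- truth$samples$sample_id
  n <- length(ids)
  chroms <- paste0("chr", 1:5)
  withr::with_seed(params$seed + 2L, {
    # distinct site pools: true sites per sample, artifact sites shared,
    # false-positive sites per caller, spaced so keys never collide
    n_art <- params$n_artifact_sites
    art <- data.frame(
      chrom = sample(chroms, n_art, replace = TRUE),
      pos = 5e6L + seq_len(n_art) * 10000L,
      stringsAsFactors = FALSE
    )
    aal <- random_snv_alleles(n_art)
    art$ref <- aal$ref; art$alt <- aal$alt
    n_rescue <- ceiling(params$rescue_fraction * n_art)
    art$rescue <- seq_len(n_art) <= n_rescue

    calls_a <- list(); calls_b <- list(); book <- list()
    for (i in seq_len(n)) {
      sid <- ids[i]
      m <- params$n_somatic_per_sample
      tchrom <- sample(chroms, m, replace = TRUE)
      tpos <- 20e6L + sample.int(5e6L, m) * 3L + i
      tal <- random_snv_alleles(m)
      called_a <- stats::runif(m) < params$sensitivity_a
      called_b <- stats::runif(m) < params$sensitivity_b
      depth <- 60L + sample.int(60L, m)
      altc <- pmax(3L, stats::rbinom(m, depth, stats::rbeta(m, 5, 10)))
      tv <- snv_row(tchrom, tpos, tal$ref, tal$alt, sid, "callerA",
                    depth = depth, alt_count = altc)
      tvb <- tv; tvb$caller <- "callerB"
      calls_a[[length(calls_a) + 1L]] <- tv[called_a, , drop = FALSE]
      calls_b[[length(calls_b) + 1L]] <- tvb[called_b, , drop = FALSE]
      book[[length(book) + 1L]] <- data.frame(
        sample_id = sid,
        key = variant_key(tchrom, tpos, tal$ref, tal$alt),
        kind = "true", rescue_tagged = FALSE,
        called_a = called_a, called_b = called_b,
        stringsAsFactors = FALSE
      )
      # caller-unique false positives (PASS, so only consensus removes them)
      for (side in c("a", "b")) {
        k <- params$n_fp_per_caller
        if (k < 1L) next
        fchrom <- sample(chroms, k, replace = TRUE)
        fpos <- (if (side == "a") 40e6L else 45e6L) + sample.int(2e6L, k) * 2L + i
        fal <- random_snv_alleles(k)
        fv <- snv_row(fchrom, fpos, fal$ref, fal$alt, sid,
                      paste0("caller", toupper(side)))
        if (side == "a") {
          calls_a[[length(calls_a) + 1L]] <- fv
        } else {
          calls_b[[length(calls_b) + 1L]] <- fv
        }
        book[[length(book) + 1L]] <- data.frame(
          sample_id = sid, key = variant_key(fchrom, fpos, fal$ref, fal$alt),
          kind = paste0("fp_", side), rescue_tagged = FALSE,
          called_a = side == "a", called_b = side == "b",
          stringsAsFactors = FALSE
        )
      }
    }
    # artifacts: each site appears in `artifact_tumor_count` tumors, both
    # callers, PASS
    for (j in seq_len(n_art)) {
      carriers <- sample(ids, min(params$artifact_tumor_count, n))
      for (sid in carriers) {
        av <- snv_row(art$chrom[j], art$pos[j], art$ref[j], art$alt[j], sid,
                      "callerA", depth = 70L, alt_count = 8L,
                      cosmic = if (art$rescue[j]) 5 else 0,
                      af1k = if (art$rescue[j]) 1e-4 else NA_real_,
                      afex = if (art$rescue[j]) 1e-4 else NA_real_)
        avb <- av; avb$caller <- "callerB"
        calls_a[[length(calls_a) + 1L]] <- av
        calls_b[[length(calls_b) + 1L]] <- avb
        book[[length(book) + 1L]] <- data.frame(
          sample_id = sid,
          key = variant_key(art$chrom[j], art$pos[j], art$ref[j], art$alt[j]),
          kind = "artifact", rescue_tagged = art$rescue[j],
          called_a = TRUE, called_b = TRUE, stringsAsFactors = FALSE
        )
      }
    }
    # normal pileups: recurrent support at artifact sites, sub-threshold
    # evidence elsewhere
    normal_ids <- sprintf("N%03d", seq_len(params$n_normals))
    pile <- list()
    for (j in seq_len(n_art)) {
      sup <- sample(normal_ids, params$artifact_recurrence)
      depth <- 30L + sample.int(30L, length(sup))
      pile[[length(pile) + 1L]] <- data.frame(
        normal_id = sup, chrom = art$chrom[j], pos = art$pos[j],
        ref = art$ref[j], alt = art$alt[j], depth = depth,
        alt_count_q20 = pmax(2L, as.integer(ceiling(0.08 * depth))),
        stringsAsFactors = FALSE
      )
      # sub-threshold rows: low depth, low fraction (never count as support)
      oth <- setdiff(normal_ids, sup)[1:2]
      pile[[length(pile) + 1L]] <- data.frame(
        normal_id = oth, chrom = art$chrom[j], pos = art$pos[j],
        ref = art$ref[j], alt = art$alt[j],
        depth = c(9L, 50L), alt_count_q20 = c(2L, 1L),
        stringsAsFactors = FALSE
      )
    }
  })
  calls_a <- do.call(rbind, calls_a)
  calls_b <- do.call(rbind, calls_b)
  book <- do.call(rbind, book)
  # expected cascade survivors: consensus (PASS both) minus non-rescued
  # artifact sites (the PoN blacklists every planted artifact site)
  book$expected_retained <- book$called_a & book$called_b &
    (book$kind != "artifact" | book$rescue_tagged)
  rownames(calls_a) <- rownames(calls_b) <- rownames(book) <- NULL
  list(calls_a = calls_a, calls_b = calls_b,
       normal_pileups = do.call(rbind, pile), truth = book)
}

indel_row <- function(chrom, pos, ref, alt, sid, depth, alt_count, normal_alt) {
  snv_row(chrom, pos, ref, alt, sid, "indelCaller", depth = depth,
          alt_count = alt_count, normal_alt = normal_alt)
}

#' Simulate somatic indel calls with planted filter failures
#'
#' Per sample: clean true indels that pass every rule, plus planted
#' records violating exactly one rule each (alternate count below 4,
#' alternate reads in the normal, VAF below 5%, inside the repeat mask,
#' present in the known-germline set), and shared artifact indels that
#' fail upstream with `HighVafNormal`/`HighAltCountNormal` in two or more
#' samples (populating the pseudo panel of normals) while appearing as
#' otherwise-clean calls in other samples.
#'
#' @param truth a [simulate_cohort()] result.
#' @param params a [generator_params()].
#' @return list with `calls`, `failed_calls`, `repeat_mask`,
#'   `known_germline`, and bookkeeping `truth` (with `expected_retained`).
#' @export
simulate_indel_calls <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "cohort_truth"))
  ids <- truth$samples$sample_id
  chroms <- paste0("chr", 1:5)
  # fixed repeat-region mask on the virtual genome
  mask_start <- c(8e6L, 9e6L, 10e6L)
  repeat_mask <- genomic_mask(chrom = c("chr1", "chr2", "chr3"),
                              start = mask_start, end = mask_start + 50000L)
  withr::with_seed(params$seed + 3L, {
    npp <- params$n_indel_ppon_sites
    ppon_sites <- data.frame(
      chrom = sample(chroms, npp, replace = TRUE),
      pos = 12e6L + seq_len(npp) * 5000L,
      ref = paste0("C", strrep("A", 2)), alt = "C",
      stringsAsFactors = FALSE
    )
    calls <- list(); failed <- list(); book <- list()
    add_book <- function(sid, chrom, pos, ref, alt, kind, expected) {
      book[[length(book) + 1L]] <<- data.frame(
        sample_id = sid, key = variant_key(chrom, pos, ref, alt),
        kind = kind, expected_retained = expected, stringsAsFactors = FALSE
      )
    }
    for (i in seq_along(ids)) {
      sid <- ids[i]
      m <- params$n_indel_per_sample
      # true indels live on chr1-3, planted failures on chr4/chr5 (plus the
      # chr1 repeat region), so planted keys can never collide with truth
      chrom <- sample(chroms[1:3], m, replace = TRUE)
      pos <- 30e6L + sample.int(4e6L, m) * 2L + i
      ins <- stats::runif(m) < 0.5
      ref <- ifelse(ins, "A", paste0("A", strrep("T", 1 + (seq_len(m) %% 3))))
      alt <- ifelse(ins, paste0("A", strrep("G", 1 + (seq_len(m) %% 3))), "A")
      depth <- 60L + sample.int(40L, m)
      altc <- pmax(4L, stats::rbinom(m, depth, 0.25))
      for (j in seq_len(m)) {
        calls[[length(calls) + 1L]] <-
          indel_row(chrom[j], pos[j], ref[j], alt[j], sid, depth[j], altc[j], 0L)
        add_book(sid, chrom[j], pos[j], ref[j], alt[j], "true", TRUE)
      }
      # planted single-rule failures
      plant <- function(kind, chrom, pos, ref, alt, depth, altc, nalt) {
        calls[[length(calls) + 1L]] <<-
          indel_row(chrom, pos, ref, alt, sid, depth, altc, nalt)
        add_book(sid, chrom, pos, ref, alt, kind, FALSE)
      }
      plant("low_alt", "chr4", 31e6L + i, "AT", "A", 80L, 2L, 0L)
      plant("normal_alt", "chr4", 32e6L + i, "AT", "A", 80L, 20L, 2L)
      plant("low_vaf", "chr4", 33e6L + i, "AT", "A", 120L, 4L, 0L)
      plant("repeat", "chr1", 8e6L + 100L + i, "AT", "A", 80L, 20L, 0L)
      plant("germline", "chr5", 34e6L + i, "ATT", "A", 80L, 20L, 0L)
    }
    germ <- do.call(rbind, book)
    known_germline <- unique(germ$key[germ$kind == "germline"])
    # pseudo-PoN sites: qualifying failures in 2 samples, an ignored
    # status in a third, and clean-looking calls in two more samples
    for (j in seq_len(npp)) {
      sids <- sample(ids, 5L)
      failed[[length(failed) + 1L]] <- data.frame(
        sample_id = sids[1:3],
        chrom = ppon_sites$chrom[j], pos = ppon_sites$pos[j],
        ref = ppon_sites$ref[j], alt = ppon_sites$alt[j],
        filter_status = c("HighVafNormal", "HighAltCountNormal", "LowCoverage"),
        stringsAsFactors = FALSE
      )
      for (sid in sids[4:5]) {
        calls[[length(calls) + 1L]] <- indel_row(
          ppon_sites$chrom[j], ppon_sites$pos[j], ppon_sites$ref[j],
          ppon_sites$alt[j], sid, 80L, 20L, 0L)
        add_book(sid, ppon_sites$chrom[j], ppon_sites$pos[j],
                 ppon_sites$ref[j], ppon_sites$alt[j], "ppon", FALSE)
      }
    }
  })
  calls <- do.call(rbind, calls)
  book <- do.call(rbind, book)
  rownames(calls) <- rownames(book) <- NULL
  list(calls = calls, failed_calls = do.call(rbind, failed),
       repeat_mask = repeat_mask, known_germline = known_germline,
       truth = book)
}

sv_row <- function(sid, type, chrom, start, end, caller, split_reads,
                   filter = "PASS") {
  data.frame(sample_id = sid, sv_type = type, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             caller = caller, filter_status = filter,
             split_read_count = as.integer(split_reads),
             stringsAsFactors = FALSE)
}

#' Simulate two-caller SV call sets with planted consensus failures
#'
#' Per sample: true SVs emitted by both pseudo-callers with independent
#' uniform breakpoint jitter (bounded by `sv_jitter`, at most half the
#' corroboration window, so true pairs always corroborate), caller-unique
#' calls on each side, a subset of true SVs also planted in normal samples
#' (panel-of-normals fodder, emitted `LowQual`), a subset with a
#' breakpoint inside the repeat mask, and inversions stripped of split
#' reads in one caller. Bookkeeping flags which anchors the consensus is
#' expected to retain.
#'
#' @param truth a [simulate_cohort()] result.
#' @param params a [generator_params()].
#' @return list with `anchor_calls`, `support_calls`, `normal_calls`,
#'   `repeat_mask`, and bookkeeping `truth`.
#' @export
simulate_sv_callsets <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (params$sv_jitter > params$sv_window) stopf("sv_jitter must not exceed sv_window")
  ids <- truth$samples$sample_id
  types <- c("DEL", "DUP", "INV")
  anchors <- list(); supports <- list(); normals <- list(); book <- list()
  mask_chrom <- character(); mask_start <- integer()
  withr::with_seed(params$seed + 4L, {
    for (i in seq_along(ids)) {
      sid <- ids[i]
      nt <- params$sv_true_per_sample
      n_pon <- min(params$sv_pon_per_sample, nt)
      n_rep <- min(params$sv_repeat_per_sample, max(nt - n_pon, 0L))
      n_inv <- min(params$sv_splitfail_per_sample, max(nt - n_pon - n_rep, 0L))
      kind <- c(rep("pon", n_pon), rep("repeat", n_rep),
                rep("splitfail", n_inv), rep("clean", nt - n_pon - n_rep - n_inv))
      type <- sample(types, nt, replace = TRUE)
      type[kind == "splitfail"] <- "INV"
      chrom <- sample(paste0("chr", 1:5), nt, replace = TRUE)
      start <- 1e6L + (seq_len(nt) * 100000L) + i * 7L
      len <- 5000L + sample.int(20000L, nt)
      end <- start + len
      jit <- function(v) v + sample.int(2L * params$sv_jitter + 1L,
                                        length(v), replace = TRUE) -
        params$sv_jitter - 1L
      a_start <- jit(start); a_end <- jit(end)
      s_start <- jit(start); s_end <- jit(end)
      split_a <- 1L + stats::rpois(nt, 4)
      split_s <- 1L + stats::rpois(nt, 4)
      split_s[kind == "splitfail"] <- 0L
      anchors[[length(anchors) + 1L]] <-
        sv_row(sid, type, chrom, a_start, a_end, "anchorCaller", split_a)
      supports[[length(supports) + 1L]] <-
        sv_row(sid, type, chrom, s_start, s_end, "supportCaller", split_s)
      pon_idx <- which(kind == "pon")
      if (length(pon_idx)) {
        normals[[length(normals) + 1L]] <- sv_row(
          "NORMAL", type[pon_idx], chrom[pon_idx],
          jit(start[pon_idx]), jit(end[pon_idx]),
          "anchorCaller", 1L, filter = "LowQual")
      }
      rep_idx <- which(kind == "repeat")
      if (length(rep_idx)) {
        mask_chrom <- c(mask_chrom, chrom[rep_idx])
        mask_start <- c(mask_start, a_start[rep_idx] - 10L)
      }
      book[[length(book) + 1L]] <- data.frame(
        sample_id = sid, sv_type = type, chrom = chrom,
        anchor_start = a_start, anchor_end = a_end, kind = kind,
        expected_retained = kind == "clean", stringsAsFactors = FALSE
      )
      # caller-unique calls, far from every true event
      nu <- params$sv_unique_per_caller
      if (nu > 0L) {
        u1 <- 50e6L + seq_len(nu) * 200000L + i * 11L
        anchors[[length(anchors) + 1L]] <- sv_row(
          sid, sample(types, nu, replace = TRUE),
          sample(paste0("chr", 1:5), nu, replace = TRUE),
          u1, u1 + 8000L, "anchorCaller", 2L)
        u2 <- 70e6L + seq_len(nu) * 200000L + i * 13L
        supports[[length(supports) + 1L]] <- sv_row(
          sid, sample(types, nu, replace = TRUE),
          sample(paste0("chr", 1:5), nu, replace = TRUE),
          u2, u2 + 8000L, "supportCaller", 2L)
        book[[length(book) + 1L]] <- data.frame(
          sample_id = sid, sv_type = "DEL", chrom = "chr1",
          anchor_start = u1, anchor_end = u1 + 8000L, kind = "unique_anchor",
          expected_retained = FALSE, stringsAsFactors = FALSE
        )
      }
    }
  })
  repeat_mask <- if (length(mask_start)) {
    genomic_mask(mask_chrom, mask_start, mask_start + 20L)
  } else {
    genomic_mask()
  }
  out <- list(
    anchor_calls = do.call(rbind, anchors),
    support_calls = do.call(rbind, supports),
    normal_calls = if (length(normals)) do.call(rbind, normals) else
      sv_row(character(), character(), character(), integer(), integer(),
             character(), integer())[0, ],
    repeat_mask = repeat_mask,
    truth = do.call(rbind, book)
  )
  rownames(out$anchor_calls) <- rownames(out$support_calls) <- NULL
  out
}

#' Bundled gene models for copy-number simulation
#'
#' Ten synthetic genes with five 1-kb exons each, spaced far apart on a
#' five-chromosome virtual genome, plus ERBB2 on chr17. `TSG1` and `TSG2`
#' are designated tumor suppressors.
#'
#' @return list with `exons` (data.frame `gene, chrom, start, end`),
#'   `tumor_suppressors`, `erbb2_locus`, and `chrom_lengths`.
#' @export
default_gene_models <- function() {
  genes <- c("GENE1", "GENE2", "GENE3", "GENE4", "GENE5", "GENE6",
             "TSG1", "TSG2", "GENE7", "GENE8")
  chrom <- rep(paste0("chr", 1:5), each = 2L)
  gstart <- rep(c(20e6L, 60e6L), times = 5L)
  exons <- do.call(rbind, lapply(seq_along(genes), function(i) {
    s <- gstart[i] + (0:4) * 4000L
    data.frame(gene = genes[i], chrom = chrom[i], start = s, end = s + 1000L,
               stringsAsFactors = FALSE)
  }))
  erbb2 <- data.frame(gene = "ERBB2", chrom = "chr17",
                      start = 39.7e6 + (0:4) * 4000, end = 39.7e6 + (0:4) * 4000 + 1000)
  list(
    exons = rbind(exons, erbb2),
    tumor_suppressors = c("TSG1", "TSG2"),
    erbb2_locus = list(chrom = "chr17", start = 39.7e6, end = 39.74e6),
    chrom_lengths = c(chr1 = 100e6, chr2 = 100e6, chr3 = 100e6,
                      chr4 = 100e6, chr5 = 100e6, chr17 = 81e6)
  )
}

#' Simulate allele-specific copy-number segment profiles
#'
#' Builds per-sample segment tables on the virtual genome: diploid
#' baseline with planted events per gene — focal amplifications (2 Mb
#' span, copy number >= 6), non-focal amplifications (10 Mb span, copy
#' number >= 7), non-focal copy-number-6 gains (which must NOT be called
#' amplified), homozygous deletions (copy number 0) — plus an ERBB2
#' amplification for designated HER2-positive samples. The altered genome
#' fraction is recorded exactly, so chromosomal-instability estimates have
#' an arithmetic truth.
#'
#' @param truth a [simulate_cohort()] result.
#' @param gene_models a [default_gene_models()] list.
#' @param params a [generator_params()].
#' @return list with `segments` (segment table), `gene_truth`
#'   (`sample_id, gene, expected_event`), and `cin_truth`
#'   (`sample_id, cin`).
#' @export
simulate_cn_profiles <- function(truth, gene_models = default_gene_models(),
                                 params = truth$params) {
  stopifnot(inherits(truth, "cohort_truth"))
  ids <- truth$samples$sample_id
  ex <- gene_models$exons
  genes <- unique(ex$gene)
  ts <- gene_models$tumor_suppressors
  segs <- list(); gtruth <- list(); cin <- list()
  event_types <- c("none", "focal_amp", "nonfocal_amp", "nonfocal_cn6", "loss")
  withr::with_seed(params$seed + 5L, {
    for (i in seq_along(ids)) {
      sid <- ids[i]
      ev <- sample(event_types, length(genes), replace = TRUE,
                   prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
      her2_pos <- truth$samples$ihc_subtype[i] == "HER2+"
      srows <- list()
      altered <- 0
      for (g in seq_along(genes)) {
        gene <- genes[g]
        gex <- ex[ex$gene == gene, , drop = FALSE]
        chromg <- gex$chrom[1]
        lo <- min(gex$start); hi <- max(gex$end)
        if (gene == "ERBB2") {
          ev[g] <- if (her2_pos) "focal_amp" else "none"
        }
        spec <- switch(
          ev[g],
          none = NULL,
          focal_amp = list(cn = 6L + sample.int(3L, 1L), span = 2e6),
          nonfocal_amp = list(cn = 7L + sample.int(2L, 1L), span = 10e6),
          nonfocal_cn6 = list(cn = 6L, span = 10e6),
          loss = list(cn = 0L, span = 1e6)
        )
        if (!is.null(spec)) {
          mid <- floor((lo + hi) / 2)
          es <- as.integer(mid - spec$span / 2)
          ee <- as.integer(es + spec$span)
          srows[[length(srows) + 1L]] <- data.frame(
            sample_id = sid, chrom = chromg, start = es, end = ee,
            total_cn = spec$cn, minor_cn = if (spec$cn == 0L) 0L else 1L,
            stringsAsFactors = FALSE
          )
          altered <- altered + (ee - es)
        }
        expected <- switch(
          ev[g],
          none = "neutral",
          focal_amp = "amplified",
          nonfocal_amp = if (gene %in% ts) "neutral" else "amplified",
          nonfocal_cn6 = "neutral",
          loss = "lost"
        )
        gtruth[[length(gtruth) + 1L]] <- data.frame(
          sample_id = sid, gene = gene, planted = ev[g],
          expected_event = expected, stringsAsFactors = FALSE
        )
      }
      # diploid filler covering the rest of each chromosome
      planted <- if (length(srows)) do.call(rbind, srows) else NULL
      for (chromg in names(gene_models$chrom_lengths)) {
        L <- gene_models$chrom_lengths[[chromg]]
        p <- planted[planted$chrom == chromg, , drop = FALSE]
        bounds <- c(0L, if (!is.null(p) && nrow(p)) c(rbind(p$start, p$end)), as.integer(L))
        starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
        ends <- bounds[seq(2, length(bounds), by = 2)]
        keep <- ends > starts
        if (any(keep)) {
          srows[[length(srows) + 1L]] <- data.frame(
            sample_id = sid, chrom = chromg, start = starts[keep],
            end = ends[keep], total_cn = 2L, minor_cn = 1L,
            stringsAsFactors = FALSE
          )
        }
      }
      segs[[length(segs) + 1L]] <- do.call(rbind, srows)
      cin[[length(cin) + 1L]] <- data.frame(
        sample_id = sid, cin = altered / sum(gene_models$chrom_lengths),
        stringsAsFactors = FALSE
      )
    }
  })
  segments <- do.call(rbind, segs)
  segments <- segments[order(segments$sample_id, segments$chrom, segments$start), ]
  rownames(segments) <- NULL
  list(segments = segments, gene_truth = do.call(rbind, gtruth),
       cin_truth = do.call(rbind, cin))
}
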