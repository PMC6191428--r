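test_that("SBS classification collapses purine references by reverse complement", {
  # G>A at reference context AGG is C>T at CCT on the pyrimidine strand
  expect_equal(classify_sbs96("G", "A", "AGG"), "C[C>T]T")
  expect_equal(classify_sbs96("C", "T", "TCA"), "T[C>T]A")
  expect_equal(classify_sbs96("A", "C", "TAT"), "A[T>G]A")
  expect_true(is.na(classify_sbs96("C", "T", "NCA")))
  expect_equal(length(sbs96_contexts()), 96L)
  expect_equal(anyDuplicated(sbs96_contexts()), 0L)
})

test_that("catalog construction conserves counts and drops N contexts", {
  withr::with_seed(11, {
    ctx_pool <- c("ACA", "TCT", "GCG", "ATA", "TTT")
    snvs <- do.call(rbind, lapply(1:100, function(i) {
      cx <- sample(ctx_pool, 1)
      make_variant(pos = i * 10L, ref = substr(cx, 2, 2),
                   alt = if (substr(cx, 2, 2) == "C") "T" else "G",
                   context = cx)
    }))
  })
  catalog <- build_catalog(snvs)
  expect_equal(unname(catalog$totals), 100)
  expect_equal(sum(catalog$counts), 100)

  snvs$context[1] <- "NCA"
  expect_warning(catalog2 <- build_catalog(snvs), "unusable")
  expect_equal(sum(catalog2$counts), 99)
})

test_that("the inclusion gate is at least 100, inclusive", {
  counts <- matrix(0L, 2, 96, dimnames = list(c("A", "B"), sbs96_contexts()))
  counts[1, 1] <- 100L
  counts[2, 1] <- 99L
  cat100 <- gate_samples(mutation_catalog(counts))
  expect_identical(unname(cat100$included), c(TRUE, FALSE))
  expect_error(extract_signatures(cat100$counts[0, , drop = FALSE]),
               "no included samples")
})

test_that("normalization rescales by context-frequency ratio then row-normalizes", {
  counts <- matrix(0, 1, 96, dimnames = list("S", sbs96_contexts()))
  counts[1, c("A[C>A]A", "A[C>A]C")] <- c(100, 100)
  # identical source and target: pure row normalization
  plain <- normalize_catalog(counts, source_territory = "genome")
  expect_equal(unname(plain[1, c("A[C>A]A", "A[C>A]C")]), c(0.5, 0.5))
  expect_equal(sum(plain), 1)
  # context ACA twice as frequent in source as target: its count is halved
  freqs <- list(
    src = stats::setNames(rep(1 / 32, 32), trinucleotides32()),
    tgt = stats::setNames(rep(1 / 32, 32), trinucleotides32())
  )
  freqs$src[["ACA"]] <- 2 / 32
  skewed <- normalize_catalog(counts, source_territory = "src", target = "tgt",
                              freqs = freqs)
  expect_equal(unname(skewed[1, "A[C>A]A"] / skewed[1, "A[C>A]C"]), 0.5)
  expect_equal(sum(skewed), 1)
  # disabling the rescale leaves the territories uncorrected
  expect_equal(unname(normalize_catalog(counts, source_territory = "src",
                                        target = "tgt", rescale = FALSE,
                                        freqs = freqs)[1, "A[C>A]A"]), 0.5)
})

test_that("exome and genome samples from one mixture agree after normalization", {
  params <- generator_params(n_samples = 60, seed = 23, effect_scale = 0,
                             dirichlet_concentration = 1e6,
                             mut_count_range = c(3000, 3000), wgs_fraction = 0.5)
  truth <- simulate_cohort(params)
  catalog <- simulate_mutation_catalog(truth)
  terr <- stats::setNames(truth$samples$territory, truth$samples$sample_id)
  V <- normalize_catalog(catalog, source_territory = terr)
  mean_ex <- colMeans(V[terr == "exome", , drop = FALSE])
  mean_ge <- colMeans(V[terr == "genome", , drop = FALSE])
  # cosine between mean normalized spectra of the two territories
  cosine <- sum(mean_ex * mean_ge) / sqrt(sum(mean_ex^2) * sum(mean_ge^2))
  expect_gt(cosine, 0.995)
  # without the territory correction the spectra visibly disagree
  V0 <- normalize_catalog(catalog, source_territory = terr, rescale = FALSE)
  m0e <- colMeans(V0[terr == "exome", , drop = FALSE])
  m0g <- colMeans(V0[terr == "genome", , drop = FALSE])
  cos0 <- sum(m0e * m0g) / sqrt(sum(m0e^2) * sum(m0g^2))
  expect_gt(cosine, cos0)
})

test_that("KL-NMF recovers a rank-1 catalog and is deterministic", {
  prof <- reference_signature_profiles()
  target <- prof["APOBEC_CT", ]
  V <- withr::with_seed(3, {
    t(vapply(1:12, function(i) as.numeric(stats::rmultinom(1, 5000, target)),
             numeric(96)))
  })
  Vn <- normalize_catalog(V)
  fit <- extract_signatures(Vn, k = 1, restarts = 3, seed = 2)
  cosine <- sum(fit$profiles[1, ] * target) /
    sqrt(sum(fit$profiles[1, ]^2) * sum(target^2))
  expect_gt(cosine, 1 - 1e-3)
  expect_equal(abs(sum(fit$profiles[1, ]) - 1) < 1e-9, TRUE)

  fit2 <- extract_signatures(Vn, k = 1, restarts = 3, seed = 2)
  expect_identical(fit$profiles, fit2$profiles)
  expect_error(extract_signatures(Vn, k = 20), "exceeds")
})

test_that("the KL objective is non-increasing across multiplicative updates", {
  withr::with_seed(9, {
    V <- matrix(stats::rpois(40 * 96, 4), 40, 96)
  })
  run <- somasig:::nmf_kl_once(V, k = 4, max_iter = 300, tol = 0, seed = 1,
                               trace = TRUE)
  d <- run$trace
  expect_true(all(diff(d) <= 1e-8 * pmax(d[-length(d)], 1)))
})

test_that("factor labeling is a greedy one-to-one cosine assignment", {
  prof <- reference_signature_profiles()
  # permuted copy of the reference: labels must recover the permutation
  perm <- withr::with_seed(4, sample(nrow(prof)))
  lab <- match_signatures(prof[perm, ], prof)
  expect_identical(lab$label, rownames(prof)[perm])
  expect_true(all(lab$cosine > 0.999))
  # an off-support profile stays unmatched
  ortho <- matrix(0, 1, 96, dimnames = list("weird", sbs96_contexts()))
  ortho[1, "G[T>A]G"] <- 1
  expect_identical(match_signatures(ortho, prof)$label, "unmatched")
})

test_that("NNLS attribution is exact on pure spectra and near-exact on mixtures", {
  prof <- reference_signature_profiles()
  pure <- prof["Aging", , drop = FALSE]
  contrib <- compute_contributions(pure, prof)
  expect_equal(unname(contrib[1, "Aging"]), 1, tolerance = 1e-9)
  expect_equal(unname(sum(contrib[1, ])), 1, tolerance = 1e-9)

  mix <- 0.5 * prof["APOBEC_CT", ] + 0.5 * prof["HRD", ]
  counts <- withr::with_seed(8, t(stats::rmultinom(1, 1000, mix)))
  colnames(counts) <- sbs96_contexts()
  c2 <- compute_contributions(counts, prof)
  expect_equal(unname(c2[1, "APOBEC_CT"]), 0.5, tolerance = 0.05)
  expect_equal(unname(c2[1, "HRD"]), 0.5, tolerance = 0.05)
})

test_that("NNLS agrees with the simplex grid oracle within one grid step", {
  prof <- reference_signature_profiles()
  two <- prof[c("APOBEC_CT", "Aging"), ]
  three <- prof[c("APOBEC_CT", "Aging", "Signature8"), ]
  withr::with_seed(21, {
    for (w in list(c(0.3, 0.7), c(0.85, 0.15))) {
      spec <- as.numeric(stats::rmultinom(1, 2000, as.vector(w %*% two))) / 2000
      nnls <- compute_contributions(matrix(spec, 1, 96,
                                           dimnames = list("s", sbs96_contexts())),
                                    two)
      grid <- oracle_grid_contribution(spec, two, step = 0.01)
      expect_lt(max(abs(nnls[1, ] - grid)), 0.011)
    }
    w3 <- c(0.2, 0.5, 0.3)
    spec3 <- as.numeric(stats::rmultinom(1, 3000, as.vector(w3 %*% three))) / 3000
    nnls3 <- compute_contributions(matrix(spec3, 1, 96,
                                          dimnames = list("s", sbs96_contexts())),
                                   three)
    grid3 <- oracle_grid_contribution(spec3, three, step = 0.01)
    expect_lt(max(abs(nnls3[1, ] - grid3)), 0.011)
  })
})

test_that("combined APOBEC is the sum of the two labeled contributions", {
  m <- matrix(c(0.3, 0.2, 0.5), 1, 3,
              dimnames = list("S1", c("APOBEC_CT", "APOBEC_CG", "HRD")))
  expect_equal(unname(combine_apobec(m)["S1"]), 0.5)
  # simplex: combined APOBEC can never exceed 1 - HRD
  expect_lte(combine_apobec(m)[["S1"]], 1 - m[1, "HRD"])
  m2 <- m
  colnames(m2) <- c("APOBEC_CT", "Factor2", "HRD")
  expect_warning(res <- combine_apobec(m2), "missing")
  expect_true(all(is.na(res)))
})
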