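test_that("Mann-Whitney matches hand enumeration and is symmetric", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.1)  # 2 / choose(6, 3) tail assignments
  expect_equal(res$method, "exact")

  # identical multisets: U at its mean, p = 1
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)
  expect_equal(same$p.value, 1)

  # swapping the samples reflects U and keeps p
  a <- c(1.2, 3.4, 2.2, 8); b <- c(0.5, 4.4, 9.1, 2.0, 7.7)
  f <- mann_whitney(a, b); r <- mann_whitney(b, a)
  expect_equal(f$p.value, r$p.value)
  expect_equal(f$statistic + r$statistic, length(a) * length(b))
})

test_that("exact Mann-Whitney equals full enumeration on small samples", {
  withr::with_seed(14, {
    for (rep in 1:6) {
      n1 <- sample(3:6, 1); n2 <- sample(3:8, 1)
      x <- round(stats::rnorm(n1), 6); y <- round(stats::rnorm(n2) + 0.5, 6)
      expect_equal(mann_whitney(x, y)$p.value, oracle_mwu_exact(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment equals the closed-form step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # hand-worked vector: sorted p * m / rank with cumulative minimum
  p <- c(0.005, 0.1, 0.03, 0.5)
  expect_equal(bh_adjust(p), c(0.02, 4 * 0.1 / 3, 0.06, 0.5))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("balance groups follow the four-way driver truth table", {
  combos <- expand.grid(tp53 = c(FALSE, TRUE), brca = c(FALSE, TRUE),
                        pik3ca = c(FALSE, TRUE), cdh1 = c(FALSE, TRUE))
  got <- assign_balance_group(combos$tp53, combos$brca, combos$pik3ca,
                              combos$cdh1)
  manual <- apply(combos, 1, function(r) {
    a <- r[["pik3ca"]] || r[["cdh1"]]; b <- r[["tp53"]] || r[["brca"]]
    if (a && b) "Both" else if (a) "CDH1/PIK3CA" else if (b) "TP53/BRCA" else "Neither"
  })
  expect_identical(as.character(got), manual)
  expect_identical(levels(got), c("CDH1/PIK3CA", "TP53/BRCA", "Both", "Neither"))
})

test_that("Kruskal-Wallis reduces to the uncorrected Mann-Whitney for 2 groups", {
  withr::with_seed(6, {
    x <- stats::runif(20); y <- stats::runif(25) + 0.2
  })
  kd <- kruskal_dunn(c(x, y), rep(c("a", "b"), c(20, 25)))
  mw <- mann_whitney(x, y, correct = FALSE)
  expect_equal(kd$p.value, mw$p.value, tolerance = 1e-10)
  # with two groups the single Dunn contrast carries the same p
  expect_equal(kd$pairwise$p, mw$p.value, tolerance = 1e-10)
})

test_that("Dunn z-scores use pooled tie-corrected ranks", {
  v <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("lo", "mid", "hi"), each = 3)
  kd <- kruskal_dunn(v, g)
  # hand computation: mean ranks 2, 5, 8; se = sqrt((9*10/12)*(2/3))
  se <- sqrt(9 * 10 / 12 * (2 / 3))
  row <- kd$pairwise[kd$pairwise$group1 == "hi" & kd$pairwise$group2 == "lo", ]
  expect_equal(row$z, (8 - 2) / se, tolerance = 1e-12)
  expect_equal(kd$df, 2)
})

test_that("Spearman permutation p behaves at the extremes and on hand cases", {
  mono <- spearman_permutation(1:10, (1:10)^2, n_perm = 199, seed = 5)
  expect_equal(mono$rho, 1)
  expect_equal(mono$p.value, 1 / 200)
  # hand computation: d = (-1, 1, -1, 1, 0), rho = 1 - 6*4/(5*24) = 0.8
  hand <- spearman_permutation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                               n_perm = 99, seed = 5)
  expect_equal(hand$rho, 0.8, tolerance = 1e-12)
  # determinism under the seed
  expect_equal(spearman_permutation(1:10, c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3),
                                    n_perm = 99, seed = 7)$p.value,
               spearman_permutation(1:10, c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3),
                                    n_perm = 99, seed = 7)$p.value)
})

test_that("Fisher cohort comparisons match hypergeometric enumeration", {
  counts <- data.frame(
    cohort = c("A", "B"), gene = "TP53", mutated = c(8L, 1L), total = c(10L, 10L),
    stringsAsFactors = FALSE
  )
  res <- fisher_cohort_comparison(counts)
  expect_equal(res$p, oracle_fisher_exact(8, 2, 1, 9), tolerance = 1e-9)
  expect_equal(res$p, 0.005477, tolerance = 1e-4)

  even <- data.frame(cohort = c("A", "B"), gene = "X", mutated = c(5L, 10L),
                     total = c(10L, 20L), stringsAsFactors = FALSE)
  expect_equal(fisher_cohort_comparison(even)$p, 1)

  zero <- data.frame(cohort = c("A", "B"), gene = "X", mutated = c(0L, 0L),
                     total = c(10L, 20L), stringsAsFactors = FALSE)
  expect_equal(fisher_cohort_comparison(zero)$p, 1)
})

test_that("chi-square of group composition is Pearson without correction", {
  # perfectly proportional table
  g <- rep(c("x", "y"), times = c(30, 30))
  co <- rep(c("A", "B", "C"), times = 20)
  prop <- chisq_group_by_cohort(g, co)
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_equal(prop$p.value, 1)
  # hand-computed 2x2
  g2 <- rep(c("x", "x", "y", "y"), times = c(10, 20, 20, 10))
  c2 <- rep(c("A", "B", "A", "B"), times = c(10, 20, 20, 10))
  res <- chisq_group_by_cohort(g2, c2)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(res$df, 1)
  # empty category dropped with a warning
  expect_warning(
    chisq_group_by_cohort(factor(g2, levels = c("x", "y", "z")), c2),
    "empty"
  )
})

test_that("the association grid recovers a planted effect with direction", {
  withr::with_seed(33, {
    n <- 120
    tp53 <- stats::runif(n) < 0.4
    feats <- data.frame(
      tp53 = tp53, gata3 = stats::runif(n) < 0.2,
      hrd = stats::rbeta(n, 2, 6) + ifelse(tp53, 0.25, 0),
      aging = stats::rnorm(n, 10), ihc_subtype = "HR+/HER2-",
      stringsAsFactors = FALSE
    )
  })
  grid <- associate_drivers(feats, c("tp53", "gata3"), c("hrd", "aging"))
  hit <- grid[grid$gene == "tp53" & grid$feature == "hrd", ]
  expect_lt(hit$q, 0.01)
  expect_equal(hit$direction, "increase")
  null_rows <- grid[grid$gene == "gata3", ]
  expect_true(all(null_rows$direction == "none"))
  # q >= p always, within the family
  expect_true(all(grid$q >= grid$p - 1e-15))
})

test_that("skipped pairs and subtype restriction are honored", {
  feats <- data.frame(
    tp53 = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    cdh1 = FALSE,  # zero mutated samples: pair skipped
    hrd = c(0.5, 0.2, 0.3, 0.25, 0.6, 0.22),
    ihc_subtype = c(rep("HR+/HER2-", 5), "HER2+"),
    stringsAsFactors = FALSE
  )
  grid <- associate_drivers(feats, c("tp53", "cdh1"), "hrd")
  expect_false("cdh1" %in% grid$gene)
  sub <- associate_drivers(feats, "tp53", "hrd", subtype_filter = "HR+/HER2-")
  expect_equal(sub$n_mut + sub$n_wt, 5L)
})

test_that("the multivariate HRD model recovers planted effects", {
  withr::with_seed(51, {
    n <- 400
    cohort <- sample(c("A", "B", "C"), n, replace = TRUE)
    tp53 <- stats::runif(n) < 0.4
    df <- data.frame(
      cohort = cohort, age = stats::rnorm(n, 55, 10),
      missense_burden = stats::rpois(n, 30),
      tp53 = tp53, brca = stats::runif(n) < 0.1,
      pik3ca = stats::runif(n) < 0.3, cdh1 = stats::runif(n) < 0.1,
      stringsAsFactors = FALSE
    )
    lin <- -1 + 0.8 * (cohort == "A") + 1.0 * tp53 + stats::rnorm(n, 0, 0.5)
    df$hrd <- stats::plogis(lin)
  })
  fit <- hrd_multivariate(df)
  tp53_row <- fit[fit$term == "tp53TRUE", ]
  expect_gt(tp53_row$estimate, 0)
  expect_lt(tp53_row$p, 1e-6)
  # cohort A is the reference level; B and C carry negative coefficients
  expect_lt(fit$estimate[fit$term == "cohortB"], 0)

  const <- df
  const$hrd <- 0.3
  fitc <- hrd_multivariate(const)
  expect_true(all(abs(fitc$estimate[fitc$term != "(Intercept)"]) < 1e-10))

  dup <- df
  dup$brca <- dup$tp53
  expect_error(hrd_multivariate(dup), "collinear.*brca")
})

test_that("pairwise Pearson correlations carry one BH family", {
  withr::with_seed(77, {
    n <- 500
    x <- stats::rnorm(n)
    scores <- data.frame(
      tcell = x, apobec = 0.35 * x + sqrt(1 - 0.35^2) * stats::rnorm(n),
      noise = stats::rnorm(n)
    )
  })
  res <- pairwise_pearson(scores)
  expect_equal(unname(diag(res$r)), rep(1, 3))
  expect_equal(res$pairs$r[res$pairs$feature1 == "tcell" &
                             res$pairs$feature2 == "apobec"],
               0.35, tolerance = 0.1)
  lin <- pairwise_pearson(data.frame(a = c(1, 2, 3), b = c(2, 4, 6)))
  expect_equal(lin$pairs$r, 1)
  expect_true(all(res$pairs$q >= res$pairs$p - 1e-15))
})
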