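#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The p-value is exact (by
#' enumeration of the rank-sum distribution) when the smaller sample has at
#' most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with tie correction and (by default) continuity
#' correction is used.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact_max largest min-group size for which the exact null
#'   distribution is used (default 8).
#' @param correct continuity correction for the normal approximation.
#' @return list with `statistic` (U for `x` relative to `y`), `p.value`,
#'   and `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8L, correct = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stopf("mann_whitney needs non-empty samples")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- min(length(x), length(y)) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = correct)
  )
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values:
#' `q_(i) = min_{j >= i} p_(j) * m / j` on the sorted p-values, mapped back
#' to input order and capped at 1.
#'
#' @param pvalues numeric vector of p-values.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Driver-gene vs genomic-feature association grid
#'
#' One two-sided Mann-Whitney test per (gene, feature) pair comparing
#' feature values in mutated vs wild-type samples, with BH adjustment
#' across the whole grid as a single family. Direction (`increase` /
#' `decrease` of the feature in mutants) is declared only at `q < alpha`,
#' by comparing group medians. Pairs with fewer than two samples in either
#' mutation status are skipped. Missing feature values are dropped per
#' test (listwise within the pair), with group sizes reported.
#'
#' @param features data.frame with one row per sample: logical driver
#'   status columns named by `genes`, numeric columns named by
#'   `feature_names`, optionally `ihc_subtype`.
#' @param genes driver status columns to test.
#' @param feature_names feature columns to test.
#' @param subtype_filter optional IHC subtype; restricts the grid to that
#'   subtype (e.g. `"HR+/HER2-"`).
#' @param config a [run_config()] (`alpha`).
#' @return data.frame `(gene, feature, n_mut, n_wt, statistic, p, q,
#'   direction)`.
#' @export
associate_drivers <- function(features, genes, feature_names,
                              subtype_filter = NULL, config = run_config()) {
  df <- features
  if (!is.null(subtype_filter)) {
    df <- df[!is.na(df$ihc_subtype) & df$ihc_subtype == subtype_filter, ,
             drop = FALSE]
  }
  rows <- list()
  for (g in genes) {
    status <- df[[g]]
    for (f in feature_names) {
      v <- df[[f]]
      ok <- !is.na(v) & !is.na(status)
      xm <- v[ok & status]; xw <- v[ok & !status]
      if (length(xm) < 2L || length(xw) < 2L) next
      ht <- mann_whitney(xm, xw)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, feature = f, n_mut = length(xm), n_wt = length(xw),
        statistic = ht$statistic, p = ht$p.value,
        median_mut = stats::median(xm), median_wt = stats::median(xw),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), feature = character(),
                      n_mut = integer(), n_wt = integer(),
                      statistic = numeric(), p = numeric(), q = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$direction <- ifelse(
    out$q < config$alpha,
    ifelse(out$median_mut > out$median_wt, "increase", "decrease"),
    "none"
  )
  out$median_mut <- NULL
  out$median_wt <- NULL
  rownames(out) <- NULL
  out
}

#' Four-way HRD/APOBEC balance grouping
#'
#' Partitions tumors by driver mutation status: carrying a CDH1 or PIK3CA
#' mutation; carrying a TP53 or BRCA1/2 (including germline) mutation;
#' mutations from both categories; or neither.
#'
#' @param tp53,brca,pik3ca,cdh1 logical vectors of mutation status
#'   (recycled to common length).
#' @return factor with levels `CDH1/PIK3CA`, `TP53/BRCA`, `Both`,
#'   `Neither`.
#' @export
assign_balance_group <- function(tp53, brca, pik3ca, cdh1) {
  group_a <- pik3ca | cdh1
  group_b <- tp53 | brca
  lab <- ifelse(group_a & group_b, "Both",
                ifelse(group_a, "CDH1/PIK3CA",
                       ifelse(group_b, "TP53/BRCA", "Neither")))
  factor(lab, levels = c("CDH1/PIK3CA", "TP53/BRCA", "Both", "Neither"))
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Kruskal-Wallis with tie correction, followed by Dunn's pairwise z tests
#' from the pooled ranks (tie-corrected), two-sided. Pairwise p-values are
#' unadjusted by default; `adjust = "BH"` applies Benjamini-Hochberg over
#' the pairs.
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor; empty levels dropped).
#' @param adjust `"none"` (default) or `"BH"` for the pairwise table.
#' @return list with `statistic`, `df`, `p.value`, and `pairwise`
#'   data.frame `(group1, group2, z, p)`.
#' @export
kruskal_dunn <- function(values, groups, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) < 2L) stopf("kruskal_dunn needs >= 2 non-empty groups")
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lev <- levels(groups)
  mean_rank <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z[i] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  if (adjust == "BH") p <- bh_adjust(p)
  list(
    statistic = unname(kw$statistic), df = unname(kw$parameter),
    p.value = kw$p.value,
    pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          z = z, p = p, stringsAsFactors = FALSE)
  )
}

#' Spearman correlation with permutation p-value
#'
#' Spearman's rho on tie-averaged ranks; the two-sided p-value is
#' `(1 + #{|rho_perm| >= |rho_obs|}) / (n_perm + 1)` over seeded
#' permutations of `y`.
#'
#' @param x,y numeric vectors (pairwise-complete cases used).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return list with `rho`, `p.value`, `n_perm`, `n`.
#' @export
spearman_permutation <- function(x, y, n_perm = 10000L, seed = 1L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("spearman_permutation needs >= 3 paired values")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12
    }, logical(1)))
  })
  list(rho = rho, p.value = (1 + exceed) / (n_perm + 1),
       n_perm = as.integer(n_perm), n = length(x))
}

#' Pairwise Fisher's exact cohort comparisons
#'
#' For each pair of cohorts and each gene, a two-sided Fisher's exact test
#' on the 2x2 table of mutated vs wild-type counts, with BH adjustment
#' across genes within each cohort pair (one family per comparison).
#' Degenerate (zero-margin) tables yield p = 1.
#'
#' @param counts data.frame with columns `cohort, gene, mutated, total`.
#' @return data.frame `(cohort1, cohort2, gene, odds_ratio, p, q)`.
#' @export
fisher_cohort_comparison <- function(counts) {
  stopifnot(all(c("cohort", "gene", "mutated", "total") %in% names(counts)))
  cohorts <- unique(counts$cohort)
  if (length(cohorts) < 2L) stopf("need >= 2 cohorts")
  pairs <- utils::combn(cohorts, 2L)
  out <- list()
  for (i in seq_len(ncol(pairs))) {
    c1 <- pairs[1, i]; c2 <- pairs[2, i]
    genes <- intersect(counts$gene[counts$cohort == c1],
                       counts$gene[counts$cohort == c2])
    rows <- lapply(genes, function(g) {
      a <- counts[counts$cohort == c1 & counts$gene == g, ][1, ]
      b <- counts[counts$cohort == c2 & counts$gene == g, ][1, ]
      tab <- matrix(c(a$mutated, a$total - a$mutated,
                      b$mutated, b$total - b$mutated), nrow = 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        data.frame(cohort1 = c1, cohort2 = c2, gene = g,
                   odds_ratio = NA_real_, p = 1, stringsAsFactors = FALSE)
      } else {
        ht <- stats::fisher.test(tab)
        data.frame(cohort1 = c1, cohort2 = c2, gene = g,
                   odds_ratio = unname(ht$estimate), p = ht$p.value,
                   stringsAsFactors = FALSE)
      }
    })
    fam <- do.call(rbind, rows)
    fam$q <- bh_adjust(fam$p)
    out[[length(out) + 1L]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chi-square test of group composition across cohorts
#'
#' Pearson chi-square (no continuity correction) on the groups x cohorts
#' contingency table. Empty rows/columns are dropped with a warning, as is
#' any expected count below 5.
#'
#' @param groups,cohorts label vectors of equal length.
#' @return list with `statistic`, `df`, `p.value`, `observed`, `expected`.
#' @export
chisq_group_by_cohort <- function(groups, cohorts) {
  ok <- !is.na(groups) & !is.na(cohorts)
  tab <- table(groups[ok], cohorts[ok])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warnf("dropping empty categories from contingency table")
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5)) warnf("expected count below 5 in chi-square table")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, observed = tab, expected = ht$expected)
}

#' Multivariate model of HRD contribution
#'
#' Ordinary least squares of the (logit-transformed, epsilon-clamped) HRD
#' contribution on cohort indicators, age, log1p missense burden, and the
#' four driver-status indicators, on complete cases. `link = "identity"`
#' models the raw proportion instead. Collinear covariates are rejected
#' with an error naming the degenerate term.
#'
#' @param features data.frame with columns `hrd, cohort, age,
#'   missense_burden, tp53, brca, pik3ca, cdh1`.
#' @param link `"logit"` (default) or `"identity"`.
#' @param eps clamp for the logit transform (default 1e-3).
#' @return data.frame of coefficients `(term, estimate, se, statistic, p)`.
#' @export
hrd_multivariate <- function(features, link = c("logit", "identity"),
                             eps = 1e-3) {
  link <- match.arg(link)
  need <- c("hrd", "cohort", "age", "missense_burden", "tp53", "brca",
            "pik3ca", "cdh1")
  missing <- setdiff(need, names(features))
  if (length(missing)) stopf("hrd_multivariate lacks columns: %s",
                             paste(missing, collapse = ", "))
  df <- features[stats::complete.cases(features[, need]), need, drop = FALSE]
  y <- if (link == "logit") {
    stats::qlogis(pmin(pmax(df$hrd, eps), 1 - eps))
  } else {
    df$hrd
  }
  X <- stats::model.matrix(
    ~ cohort + age + log1p(missense_burden) + tp53 + brca + pik3ca + cdh1,
    data = df
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("collinear covariate(s) in HRD model: %s", paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  dfree <- nrow(X) - ncol(X)
  sigma2 <- rss / dfree
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtX_inv) * sigma2)
  est <- fit$coefficients
  tval <- est / se
  if (sigma2 == 0) {
    tval <- ifelse(est == 0, 0, sign(est) * Inf)
  }
  data.frame(
    term = colnames(X), estimate = unname(est), se = unname(se),
    statistic = unname(tval),
    p = unname(2 * stats::pt(-abs(tval), dfree)),
    stringsAsFactors = FALSE
  )
}

#' Pairwise Pearson correlations with BH adjustment
#'
#' Pairwise-complete Pearson correlations of a set of named numeric
#' features, with t-based two-sided p-values adjusted by BH across all
#' unordered pairs as one family.
#'
#' @param scores data.frame or matrix of samples x named features.
#' @return list with `r` (correlation matrix), `p`, `q` matrices, and a
#'   long-format `pairs` data.frame `(feature1, feature2, r, n, p, q)`.
#' @export
pairwise_pearson <- function(scores) {
  m <- as.matrix(scores)
  stopifnot(is.numeric(m), ncol(m) >= 2L)
  feats <- colnames(m)
  r <- stats::cor(m, use = "pairwise.complete.obs")
  k <- ncol(m)
  pmat <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  nmat <- matrix(NA_integer_, k, k, dimnames = dimnames(r))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(m[, c(i, j)])
      n <- sum(ok)
      rij <- r[i, j]
      pv <- if (n > 2 && abs(rij) < 1) {
        tv <- rij * sqrt((n - 2) / (1 - rij^2))
        2 * stats::pt(-abs(tv), n - 2)
      } else if (n > 2) {
        0
      } else {
        NA_real_
      }
      pmat[i, j] <- pmat[j, i] <- pv
      nmat[i, j] <- nmat[j, i] <- n
      rows[[length(rows) + 1L]] <- data.frame(
        feature1 = feats[i], feature2 = feats[j], r = rij, n = n, p = pv,
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, rows)
  pairs$q <- bh_adjust(pairs$p)
  qmat <- pmat
  for (idx in seq_len(nrow(pairs))) {
    i <- match(pairs$feature1[idx], feats)
    j <- match(pairs$feature2[idx], feats)
    qmat[i, j] <- qmat[j, i] <- pairs$q[idx]
  }
  diag(r) <- 1
  list(r = r, p = pmat, q = qmat, pairs = pairs)
}
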