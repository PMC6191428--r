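# shared fixture builders; everything is generated in code

make_variant <- function(chrom = "chr1", pos = 100L, ref = "C", alt = "T",
                         sample_id = "S001", caller = "callerA",
                         filter_status = "PASS", tumor_depth = 50L,
                         tumor_alt_count = 10L, normal_depth = 40L,
                         normal_alt_count = 0L, vaf = NA_real_,
                         cosmic_overlap_count = NA_real_,
                         af_1000g = NA_real_, af_exac = NA_real_,
                         impact = NA_character_, consequence = NA_character_,
                         cadd_score = NA_real_, context = NULL) {
  df <- data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    variant_class = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "indel"),
    sample_id = sample_id, caller = caller, filter_status = filter_status,
    tumor_depth = as.integer(tumor_depth),
    tumor_alt_count = as.integer(tumor_alt_count),
    normal_depth = as.integer(normal_depth),
    normal_alt_count = as.integer(normal_alt_count),
    vaf = ifelse(is.na(vaf) & tumor_depth > 0, tumor_alt_count / tumor_depth, vaf),
    cosmic_overlap_count = cosmic_overlap_count, af_1000g = af_1000g,
    af_exac = af_exac, impact = impact, consequence = consequence,
    cadd_score = cadd_score, stringsAsFactors = FALSE
  )
  if (!is.null(context)) df$context <- context
  df
}

make_variants <- function(...) do.call(rbind, list(...))

make_sv <- function(sample_id = "S1", sv_type = "DEL", chrom = "chr1",
                    start = 1000L, end = 5000L, caller = "anchorCaller",
                    filter_status = "PASS", split_read_count = 3L) {
  data.frame(sample_id = sample_id, sv_type = sv_type, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             caller = caller, filter_status = filter_status,
             split_read_count = as.integer(split_read_count),
             stringsAsFactors = FALSE)
}

make_segments <- function(sample_id, chrom, start, end, total_cn,
                          minor_cn = NA_integer_) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             total_cn = total_cn, minor_cn = minor_cn, stringsAsFactors = FALSE)
}

# independent brute-force oracle for the SNV PoN + rescue cascade
oracle_snv_cascade <- function(calls_a, calls_b, pileups,
                               min_depth = 10, min_frac = 0.05, min_norm = 2,
                               min_cosmic = 1, max_af = 0.005) {
  key_of <- function(d) paste(d$sample_id, variant_key(d$chrom, d$pos, d$ref, d$alt))
  pass_a <- key_of(calls_a[calls_a$filter_status == "PASS", ])
  pass_b <- key_of(calls_b[calls_b$filter_status == "PASS", ])
  cons_keys <- intersect(pass_a, pass_b)
  cons <- calls_a[key_of(calls_a) %in% cons_keys, ]

  pk <- variant_key(pileups$chrom, pileups$pos, pileups$ref, pileups$alt)
  support <- pileups$depth >= min_depth &
    pileups$alt_count_q20 / pileups$depth >= min_frac
  nsup <- tapply(pileups$normal_id[support], pk[support],
                 function(x) length(unique(x)))
  blacklist <- names(nsup)[nsup >= min_norm]

  vk <- variant_key(cons$chrom, cons$pos, cons$ref, cons$alt)
  rescued <- !is.na(cons$cosmic_overlap_count) &
    cons$cosmic_overlap_count > min_cosmic &
    !is.na(cons$af_1000g) & cons$af_1000g <= max_af &
    !is.na(cons$af_exac) & cons$af_exac <= max_af
  keep <- !(vk %in% blacklist) | rescued
  key_of(cons[keep, ])
}

# independent brute-force oracle for the indel filter set
oracle_indel_filter <- function(calls, mask, germline_keys, failed_calls,
                                min_alt = 4, min_vaf = 0.05) {
  fk <- variant_key(failed_calls$chrom, failed_calls$pos, failed_calls$ref,
                    failed_calls$alt)
  qual <- failed_calls$filter_status %in% c("HighVafNormal", "HighAltCountNormal")
  nfail <- tapply(failed_calls$sample_id[qual], fk[qual],
                  function(x) length(unique(x)))
  ppon <- names(nfail)[nfail >= 2]
  vk <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  keep <- calls$tumor_alt_count >= min_alt &
    calls$normal_alt_count == 0 &
    calls$vaf >= min_vaf &
    !mask_contains(mask, calls$chrom, calls$pos) &
    !(vk %in% germline_keys) &
    !(vk %in% ppon)
  paste(calls$sample_id[keep], vk[keep])
}

# independent brute-force oracle for two-caller SV consensus
oracle_sv_consensus <- function(anchor, support, normal, mask, window = 500) {
  keep <- logical(nrow(anchor))
  partner <- integer(nrow(anchor))
  for (i in seq_len(nrow(anchor))) {
    a <- anchor[i, ]
    # panel (windowed, same type)
    if (nrow(normal)) {
      pon_hit <- any(normal$sv_type == a$sv_type & normal$chrom == a$chrom &
                       abs(normal$start - a$start) <= window &
                       abs(normal$end - a$end) <= window)
      if (pon_hit) next
    }
    cand <- which(support$sample_id == a$sample_id &
                    support$sv_type == a$sv_type & support$chrom == a$chrom &
                    abs(support$start - a$start) <= window &
                    abs(support$end - a$end) <= window)
    if (!length(cand)) next
    d <- abs(support$start[cand] - a$start) + abs(support$end[cand] - a$end)
    cand <- cand[order(d, support$start[cand])]
    j <- cand[1]
    bp <- rbind(c(a$chrom, a$start), c(a$chrom, a$end),
                c(support$chrom[j], support$start[j]),
                c(support$chrom[j], support$end[j]))
    if (any(mask_contains(mask, bp[, 1], as.integer(bp[, 2])))) next
    if (a$sv_type == "INV" &&
        (a$split_read_count < 1 || support$split_read_count[j] < 1)) next
    keep[i] <- TRUE
    partner[i] <- j
  }
  list(keep = keep, partner = partner)
}

# brute-force two-sided Mann-Whitney p by enumeration of all assignments
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pool <- c(x, y)
  u_of <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# brute-force two-sided Fisher p by hypergeometric enumeration
oracle_fisher_exact <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n, k), numeric(1))
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# dense grid search on the simplex for NNLS attribution toys
oracle_grid_contribution <- function(spectrum, profiles, step = 0.01) {
  k <- nrow(profiles)
  stopifnot(k %in% c(2L, 3L))
  grid <- seq(0, 1, by = step)
  best <- NULL; best_err <- Inf
  if (k == 2L) {
    for (w1 in grid) {
      w <- c(w1, 1 - w1)
      err <- sum((spectrum - as.vector(w %*% profiles))^2)
      if (err < best_err) { best_err <- err; best <- w }
    }
  } else {
    for (w1 in grid) for (w2 in grid[grid <= 1 - w1 + 1e-12]) {
      w <- c(w1, w2, 1 - w1 - w2)
      err <- sum((spectrum - as.vector(w %*% profiles))^2)
      if (err < best_err) { best_err <- err; best <- w }
    }
  }
  best
}
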