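# MWU spectrum-offset and MK-like polymorphism/divergence tests, the site and
# fixed-difference cleaning filters, masking scans, and small auxiliary tests.

#' Filter raw segregating-site records to analysis-ready sites
#'
#' Applies the study's site-level cleaning rules to a table of raw records:
#' sites genotyped in fewer than 8 chromosomes are dropped; sites with more
#' than two distinct alleles among the reference, ancestral, and sample
#' alleles are dropped; sites whose ancestral allele is undetermined
#' (`NA`, `"."`, or `"N"`) are dropped.  A lowercase ancestral allele flags an
#' uncertain call but is retained (`anc_uncertain` column).  Retained sites
#' get `derived`, `k`, and `klass` assigned by polarizing against the
#' ancestral allele.
#'
#' @param raw Data frame with columns `pos`, `ref`, `ancestral`, `alleles`
#'   (comma-separated distinct sample alleles), `counts` (comma-separated
#'   allele counts, parallel to `alleles`), `n` (chromosomes genotyped), and
#'   optionally `region_id`, `chrom`.
#' @param min_n Minimum chromosomes genotyped (default 8).
#' @return Data frame of retained sites with columns `pos`, `ancestral`,
#'   `derived`, `k`, `n`, `klass`, `anc_uncertain` (plus any carried-through
#'   `region_id`/`chrom`).
#' @export
filter_segregating_sites <- function(raw, min_n = 8L) {
  keep_rows <- list()
  for (i in seq_len(NROW(raw))) {
    n <- as.integer(raw$n[i])
    if (is.na(n) || n < min_n) next
    anc_raw <- raw$ancestral[i]
    if (is.na(anc_raw) || anc_raw %in% c(".", "N", "n", "")) next
    anc <- toupper(anc_raw)
    alleles <- toupper(strsplit(as.character(raw$alleles[i]), ",")[[1]])
    counts <- as.integer(strsplit(as.character(raw$counts[i]), ",")[[1]])
    if (length(alleles) != 2L) next               # must actually segregate
    pool <- unique(c(toupper(raw$ref[i]), anc, alleles))
    if (length(pool) > 2L) next                   # > 2 alleles in play
    if (!(anc %in% alleles)) next
    derived <- alleles[alleles != anc]
    k <- counts[alleles == derived]
    if (k < 1L || k > n - 1L) next
    row <- data.frame(pos = raw$pos[i], ancestral = anc, derived = derived,
                      k = k, n = n,
                      klass = classify_mutation(anc, derived),
                      anc_uncertain = anc_raw != toupper(anc_raw))
    for (col in c("region_id", "chrom")) {
      if (col %in% names(raw)) row[[col]] <- raw[[col]][i]
    }
    keep_rows[[length(keep_rows) + 1L]] <- row
  }
  if (!length(keep_rows)) {
    return(data.frame(pos = numeric(), ancestral = character(),
                      derived = character(), k = integer(), n = integer(),
                      klass = character(), anc_uncertain = logical()))
  }
  out <- do.call(rbind, keep_rows)
  rownames(out) <- NULL
  out
}

#' Clean candidate fixed differences against exclusion sets
#'
#' Retains candidates only when the position is callable, the ancestral
#' allele is determined and equals one of the two observed species alleles,
#' and the position appears in neither the segregating-site set nor the SNP
#' catalog.  Returns the cleaned table together with per-class counts and the
#' removed fraction.
#'
#' @param candidates Data frame with columns `pos`, `human`, `chimp`,
#'   `ancestral` (possibly `NA`/`"."`).
#' @param segregating_pos Positions segregating in the sample (excluded).
#' @param snp_catalog_pos Positions in an external SNP catalog (excluded).
#' @param callable Either a numeric vector of callable positions, a
#'   two-column matrix of covered intervals, or `NULL` (everything callable).
#' @return Object of class `fixed_diff_set`: list with `table` (cleaned
#'   annotated data frame), `counts` (named W2S/S2W/OTHER totals),
#'   `n_input`, `n_kept`, `removed_fraction`.
#' @export
clean_fixed_differences <- function(candidates, segregating_pos = numeric(),
                                    snp_catalog_pos = numeric(),
                                    callable = NULL) {
  n_input <- NROW(candidates)
  anc_raw <- candidates$ancestral
  determined <- !is.na(anc_raw) & !(anc_raw %in% c(".", "N", "n", ""))
  anc <- toupper(anc_raw)
  polarizable <- determined &
    (anc == toupper(candidates$human) | anc == toupper(candidates$chimp))
  callable_ok <- if (is.null(callable)) {
    rep(TRUE, n_input)
  } else if (is.matrix(callable) || is.data.frame(callable)) {
    iv <- as.matrix(callable[, 1:2, drop = FALSE])
    Reduce(`|`, lapply(seq_len(nrow(iv)), function(r) {
      candidates$pos >= iv[r, 1] & candidates$pos < iv[r, 2]
    }), rep(FALSE, n_input))
  } else {
    candidates$pos %in% callable
  }
  keep <- polarizable & callable_ok &
    !(candidates$pos %in% segregating_pos) &
    !(candidates$pos %in% snp_catalog_pos)
  tab <- annotate_fixed(candidates[keep, , drop = FALSE])
  rownames(tab) <- NULL
  counts <- c(W2S = sum(tab$klass == "W2S"),
              S2W = sum(tab$klass == "S2W"),
              OTHER = sum(tab$klass == "OTHER"))
  structure(list(table = tab, counts = counts, n_input = n_input,
                 n_kept = nrow(tab),
                 removed_fraction = if (n_input > 0) 1 - nrow(tab) / n_input else 0),
            class = "fixed_diff_set")
}

#' @export
print.fixed_diff_set <- function(x, ...) {
  cat(sprintf("fixed differences: %d kept of %d (%.1f%% removed)\n",
              x$n_kept, x$n_input, 100 * x$removed_fraction))
  print(x$counts)
  invisible(x)
}

# Extract a numeric vector of derived-allele frequencies from sites or numbers
daf_of <- function(x) {
  if (is.data.frame(x)) as.numeric(x$k) / as.numeric(x$n) else as.numeric(x)
}

#' Mann-Whitney U test for a W2S vs S2W frequency offset
#'
#' Two-sided rank-sum test comparing the derived-allele frequencies of the
#' W2S segregating sites against the S2W sites, with a Hodges-Lehmann shift
#' estimate (median of all pairwise frequency differences) normalized to 22
#' chromosomal samples.  A positive offset means W2S mutations segregate at
#' higher derived-allele frequencies.
#'
#' By default the p-value follows `stats::wilcox.test`: the exact rank
#' distribution when the combined sample is smaller than `exact_max` and
#' tie-free, otherwise the continuity-corrected normal approximation with
#' midranks.  `exact = "enumerate"` instead enumerates all rank assignments
#' (midranks under ties) and doubles the smaller tail; feasible for combined
#' sizes up to ~16.
#'
#' @param w2s_sites,s2w_sites Site data frames (columns `k`, `n`) or numeric
#'   frequency vectors.
#' @param exact `NULL` (wilcox.test behavior) or `"enumerate"`.
#' @param exact_max Combined-size threshold for the exact switch (default 50,
#'   mirroring the reference implementation).
#' @param norm_n Sample size the offset is normalized to (default 22).
#' @return Object of class `mwu_result`: list with `p`, `offset22`, `n_w2s`,
#'   `n_s2w`, `method`.  When either class is empty the result is "absent":
#'   `p` and `offset22` are `NA` and only the counts are informative.
#' @export
mwu_test <- function(w2s_sites, s2w_sites, exact = NULL, exact_max = 50L,
                     norm_n = 22L) {
  x <- daf_of(w2s_sites)
  y <- daf_of(s2w_sites)
  if (length(x) == 0L || length(y) == 0L) {
    return(structure(list(p = NA_real_, offset22 = NA_real_,
                          n_w2s = length(x), n_s2w = length(y),
                          method = "absent"),
                     class = "mwu_result"))
  }
  if (identical(exact, "enumerate")) {
    p <- mwu_enumerate_p(x, y)
    method <- "exact midrank enumeration"
  } else {
    use_exact <- (length(x) + length(y)) < exact_max
    wt <- suppressWarnings(
      wilcox.test(x, y, paired = FALSE, alternative = "two.sided",
                  exact = use_exact, correct = TRUE)
    )
    p <- wt$p.value
    method <- wt$method
  }
  hl <- median(outer(x, y, "-"))
  structure(list(p = p, offset22 = hl * norm_n,
                 n_w2s = length(x), n_s2w = length(y), method = method),
            class = "mwu_result")
}

# Exact two-sided MWU p by enumerating all C(m+n, m) assignments of the
# (mid)ranks to the first sample; two-sided p doubles the smaller tail.
mwu_enumerate_p <- function(x, y) {
  m <- length(x)
  N <- m + length(y)
  if (choose(N, m) > 5e5) stop("samples too large for exact enumeration")
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  cmb <- utils::combn(N, m)
  u_all <- colSums(matrix(r[cmb], nrow = m)) - m * (m + 1) / 2
  eps <- 1e-9
  lo <- mean(u_all <= u_obs + eps)
  hi <- mean(u_all >= u_obs - eps)
  min(1, 2 * min(lo, hi))
}

#' @export
print.mwu_result <- function(x, ...) {
  if (is.na(x$p)) {
    cat(sprintf("MWU: absent (n_w2s = %d, n_s2w = %d)\n", x$n_w2s, x$n_s2w))
  } else {
    cat(sprintf("MWU: p = %.5g, offset22 = %+.3f (n_w2s = %d, n_s2w = %d; %s)\n",
                x$p, x$offset22, x$n_w2s, x$n_s2w, x$method))
  }
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p by summation of hypergeometric point probabilities no larger
#' than that of the observed table (the `stats::fisher.test` convention).
#'
#' @param a,b,c,d Nonnegative integer cell counts, rows `(a, b)` / `(c, d)`.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) stop("counts must be nonnegative")
  if (all(rowSums(matrix(cells, 2, byrow = TRUE)) == 0) ||
      all(colSums(matrix(cells, 2, byrow = TRUE)) == 0)) {
    stop("at least one margin must be nonzero")
  }
  fisher.test(matrix(cells, nrow = 2, byrow = TRUE),
              alternative = "two.sided")$p.value
}

# Class counts from a fixed_diff_set, a site data frame (klass column), or a
# named vector c(W2S=, S2W=).
class_counts <- function(x) {
  if (inherits(x, "fixed_diff_set")) {
    return(x$counts[c("W2S", "S2W")])
  }
  if (is.data.frame(x)) {
    return(c(W2S = sum(x$klass == "W2S"), S2W = sum(x$klass == "S2W")))
  }
  v <- x[c("W2S", "S2W")]
  if (any(is.na(v))) stop("cannot extract W2S/S2W counts")
  v
}

#' McDonald-Kreitman-like test of fixed vs segregating mutation classes
#'
#' Builds the 2x2 table with rows (fixed, segregating) and columns
#' (W2S, S2W) - OTHER-class changes are excluded - and applies the two-sided
#' Fisher's exact test.  `direction` is `"W2S"` when the W2S:S2W odds among
#' fixed differences exceed those among segregating sites (historical
#' weak-to-strong fixation bias), `"S2W"` for the reverse, `NA` for equality.
#'
#' @param fixed A `fixed_diff_set`, a data frame with a `klass` column, or a
#'   named count vector `c(W2S =, S2W =)`.
#' @param segregating Same forms accepted as `fixed`.
#' @return Object of class `mk_result`: list with `p`, `direction`, `table`.
#'   Absent (p = NA) when either stratum has no W2S+S2W mutations.
#' @export
mk_test <- function(fixed, segregating) {
  f <- class_counts(fixed)
  s <- class_counts(segregating)
  tab <- rbind(fixed = f, segregating = s)
  if (sum(f) == 0 || sum(s) == 0) {
    return(structure(list(p = NA_real_, direction = NA_character_, table = tab),
                     class = "mk_result"))
  }
  p <- fisher_exact_2x2(f["W2S"], f["S2W"], s["W2S"], s["S2W"])
  # compare odds via cross-products to dodge division by zero
  cross <- f["W2S"] * s["S2W"] - f["S2W"] * s["W2S"]
  direction <- if (cross > 0) "W2S" else if (cross < 0) "S2W" else NA_character_
  structure(list(p = p, direction = direction, table = tab),
            class = "mk_result")
}

#' @export
print.mk_result <- function(x, ...) {
  if (is.na(x$p)) {
    cat("MK: absent (empty stratum)\n")
  } else {
    cat(sprintf("MK: p = %.5g, direction = %s\n", x$p,
                ifelse(is.na(x$direction), "none", x$direction)))
  }
  print(x$table)
  invisible(x)
}

#' Pooled MWU and MK tests across regions
#'
#' Concatenates the per-region segregating sites (and fixed differences) and
#' delegates to [mwu_test] and [mk_test].
#'
#' @param region_data List of per-region lists, each with elements `sites`
#'   (site data frame with `klass`) and optionally `fixed` (a
#'   `fixed_diff_set` or klass-annotated data frame).
#' @param ... Passed through to [mwu_test].
#' @return List with elements `mwu` ([mwu_test] result) and, when fixed
#'   differences are present, `mk` ([mk_test] result).
#' @export
pooled_tests <- function(region_data, ...) {
  sites <- do.call(rbind, lapply(region_data, function(r) {
    r$sites[, c("k", "n", "klass"), drop = FALSE]
  }))
  mwu <- mwu_test(sites[sites$klass == "W2S", , drop = FALSE],
                  sites[sites$klass == "S2W", , drop = FALSE], ...)
  out <- list(mwu = mwu)
  have_fixed <- vapply(region_data, function(r) !is.null(r$fixed), logical(1))
  if (any(have_fixed)) {
    f <- Reduce(`+`, lapply(region_data[have_fixed],
                            function(r) class_counts(r$fixed)))
    out$mk <- mk_test(f, sites)
  }
  out
}

#' Masking scan of a bias test across a region
#'
#' Reruns a bias test after removing all segregating sites (and fixed
#' differences, for the MK test) under a mask.  Central masks of width `w`
#' remove everything within `w/2` of the region center; the sliding scan uses
#' 5 kb windows centered every 2.5 kb from the region start (15 windows in a
#' 40 kb region), and `sliding_max` ("5kbHi") is the largest - least
#' significant - p over the non-missing windows.  A mask that empties a
#' required stratum yields `NA` for that mask.
#'
#' @param reg A [region].
#' @param sites Site data frame with `pos` and `klass`.
#' @param fixed Optional fixed differences (`fixed_diff_set` or annotated
#'   data frame with `pos`); required for `test = "MK"`.
#' @param test `"MWU"` or `"MK"`.
#' @param central_widths Central mask widths in bp.
#' @param sliding_width,sliding_spacing Sliding-window geometry in bp.
#' @param ... Passed to [mwu_test].
#' @return Object of class `mask_scan_result`: list with `unmasked` p,
#'   `central` (named p vector), `sliding` (data frame center/p),
#'   `sliding_max`.
#' @export
mask_scan <- function(reg, sites, fixed = NULL, test = c("MWU", "MK"),
                      central_widths = c(500, 1000, 5000, 10000),
                      sliding_width = 5000, sliding_spacing = 2500, ...) {
  test <- match.arg(test)
  stopifnot(inherits(reg, "region"))
  fixed_tab <- if (inherits(fixed, "fixed_diff_set")) fixed$table else fixed
  if (test == "MK" && is.null(fixed_tab)) {
    stop("MK mask scan needs fixed differences")
  }
  run <- function(keep_sites, keep_fixed) {
    s <- sites[keep_sites, , drop = FALSE]
    if (test == "MWU") {
      mwu_test(s[s$klass == "W2S", , drop = FALSE],
               s[s$klass == "S2W", , drop = FALSE], ...)$p
    } else {
      f <- fixed_tab[keep_fixed, , drop = FALSE]
      mk_test(f, s)$p
    }
  }
  all_sites <- rep(TRUE, NROW(sites))
  all_fixed <- rep(TRUE, NROW(fixed_tab))
  unmasked <- run(all_sites, all_fixed)
  ctr <- region_center(reg)
  central <- vapply(central_widths, function(w) {
    run(abs(sites$pos - ctr) >= w / 2,
        if (is.null(fixed_tab)) all_fixed else abs(fixed_tab$pos - ctr) >= w / 2)
  }, numeric(1))
  names(central) <- as.character(central_widths)
  centers <- seq(reg$start + sliding_spacing, reg$end - sliding_spacing,
                 by = sliding_spacing)
  sliding_p <- vapply(centers, function(cc) {
    run(abs(sites$pos - cc) >= sliding_width / 2,
        if (is.null(fixed_tab)) all_fixed else abs(fixed_tab$pos - cc) >= sliding_width / 2)
  }, numeric(1))
  sliding <- data.frame(center = centers, p = sliding_p)
  sliding_max <- if (all(is.na(sliding_p))) NA_real_ else max(sliding_p, na.rm = TRUE)
  structure(list(test = test, unmasked = unmasked, central = central,
                 sliding = sliding, sliding_max = sliding_max),
            class = "mask_scan_result")
}

#' @export
print.mask_scan_result <- function(x, ...) {
  cat(sprintf("%s mask scan: unmasked p = %.4g; 5kbHi = %.4g\n",
              x$test, x$unmasked, x$sliding_max))
  print(x$central)
  invisible(x)
}

#' Association statistics between per-region MWU and MK significance calls
#'
#' Cross-tabulates the two boolean flag vectors and reports the two-sided
#' Fisher's exact p.  If a reference rate is supplied, also reports the
#' upper-tail exact binomial p for the observed number of MWU-significant
#' (and MK-significant) units at that rate, and the matching Poisson
#' upper-tail p at mean `n * rate`.
#'
#' @param mwu_flags,mk_flags Equal-length logical vectors (`NA` treated as
#'   not significant).
#' @param ref_rate_mwu,ref_rate_mk Optional reference significance rates
#'   (e.g. from neutral or BGC simulations).
#' @return List with `table` (2x2), `fisher_p`, and optional `binomial_p_*`
#'   and `poisson_p_*` entries.
#' @export
association_tests <- function(mwu_flags, mk_flags,
                              ref_rate_mwu = NULL, ref_rate_mk = NULL) {
  if (length(mwu_flags) != length(mk_flags)) {
    stop("flag vectors must have equal length")
  }
  mwu <- !is.na(mwu_flags) & mwu_flags
  mk <- !is.na(mk_flags) & mk_flags
  tab <- matrix(c(sum(mwu & mk), sum(mwu & !mk),
                  sum(!mwu & mk), sum(!mwu & !mk)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("MWU", "notMWU"), c("MK", "notMK")))
  out <- list(table = tab,
              fisher_p = fisher.test(tab, alternative = "two.sided")$p.value)
  n <- length(mwu)
  tail_pair <- function(obs, rate) {
    list(binomial = pbinom(obs - 1, n, rate, lower.tail = FALSE),
         poisson = ppois(obs - 1, n * rate, lower.tail = FALSE))
  }
  if (!is.null(ref_rate_mwu)) {
    tp <- tail_pair(sum(mwu), ref_rate_mwu)
    out$binomial_p_mwu <- tp$binomial
    out$poisson_p_mwu <- tp$poisson
  }
  if (!is.null(ref_rate_mk)) {
    tp <- tail_pair(sum(mk), ref_rate_mk)
    out$binomial_p_mk <- tp$binomial
    out$poisson_p_mk <- tp$poisson
  }
  out
}

#' Exact conditional Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (nonnegative, at least 1 individual).
#' @return Exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("genotype counts must be nonnegative with at least one individual")
  }
  n <- sum(counts)                  # individuals
  nA <- 2 * n_AA + n_Aa             # A alleles
  na <- 2 * n_aa + n_Aa
  het <- seq(nA %% 2, min(nA, na), by = 2)
  # P(n_Aa = h | allele counts) via log factorials
  logp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((na - het) / 2) + het * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[het == n_Aa]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Poisson test of substitution-rate acceleration
#'
#' Upper-tail probability that a Poisson count with the neutral expectation
#' reaches the observed substitution count: `P(X >= observed)`.
#'
#' @param observed_subs Observed substitutions (nonnegative integer).
#' @param expected_neutral Neutral expectation (positive).
#' @return Upper-tail p-value.
#' @export
poisson_acceleration_test <- function(observed_subs, expected_neutral) {
  if (expected_neutral <= 0) stop("expected_neutral must be positive")
  if (observed_subs < 0) stop("observed count must be nonnegative")
  ppois(observed_subs - 1, expected_neutral, lower.tail = FALSE)
}

#' Expected number of sweeps detectable in a recent time window
#'
#' Upper-bounds the number of adaptive human-lineage substitutions by the
#' human count minus the chimp count (the chimp count estimating the
#' non-adaptive baseline), assumes those events occurred uniformly over the
#' species divergence time, and returns the expected number falling inside
#' the detectable window.
#'
#' @param human_subs,chimp_subs Lineage-specific substitution counts,
#'   `human_subs >= chimp_subs >= 0`.
#' @param divergence Species divergence time (years).
#' @param window Detectable time window (years), `0 < window <= divergence`.
#' @return List with `detectable` (expected detectable sweeps) and
#'   `adaptive_bound` (upper bound on adaptive substitutions).
#' @export
estimate_detectable_sweeps <- function(human_subs, chimp_subs, divergence,
                                       window) {
  if (chimp_subs < 0 || human_subs < chimp_subs) {
    stop("need human_subs >= chimp_subs >= 0")
  }
  if (window <= 0 || window > divergence) {
    stop("window must lie in (0, divergence]")
  }
  bound <- human_subs - chimp_subs
  list(detectable = bound * window / divergence, adaptive_bound = bound)
}
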