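#' Classify a mutation as weak-to-strong, strong-to-weak, or other
#'
#' Weak alleles are A/T (two hydrogen bonds), strong alleles are G/C.  A
#' mutation whose ancestral allele is weak and derived allele is strong is
#' `"W2S"`; the reverse is `"S2W"`; weak-to-weak and strong-to-strong changes
#' are `"OTHER"`.  Biased gene conversion favors W2S fixation, so the W2S/S2W
#' partition is the axis every downstream test works along.
#'
#' @param ancestral,derived Character vectors of single bases in
#'   `A`, `C`, `G`, `T` (case-insensitive).  Recycled to a common length.
#' @return Character vector in `c("W2S", "S2W", "OTHER")`.
#' @examples
#' classify_mutation("A", "G")  # "W2S"
#' classify_mutation("C", "T")  # "S2W"
#' classify_mutation("A", "T")  # "OTHER"
#' @export
classify_mutation <- function(ancestral, derived) {
  anc <- toupper(as.character(ancestral))
  der <- toupper(as.character(derived))
  n <- max(length(anc), length(der))
  anc <- rep_len(anc, n)
  der <- rep_len(der, n)
  bases <- c("A", "C", "G", "T")
  if (!all(anc %in% bases) || !all(der %in% bases)) {
    stop("alleles must be single bases in A, C, G, T")
  }
  if (any(anc == der)) {
    stop("ancestral and derived alleles must differ")
  }
  weak <- c("A", "T")
  out <- rep("OTHER", n)
  out[anc %in% weak & !(der %in% weak)] <- "W2S"
  out[!(anc %in% weak) & der %in% weak] <- "S2W"
  out
}

#' Derived allele frequency spectrum
#'
#' Container for counts of segregating sites by derived-allele count
#' `1 .. n-1` at sample size `n`.  Counts are real-valued because
#' hypergeometric projection produces fractional weights.
#'
#' @param counts Nonnegative numeric vector.  For an unfolded spectrum it has
#'   length `n - 1` (index i = derived count i); for a folded spectrum,
#'   length `floor(n / 2)` (index i = minor-allele count i).
#' @param n Integer sample size (chromosomes), `n >= 2`.
#' @param folded Logical; is this a folded (minor-allele) spectrum?
#' @return An object of class `daf_spectrum`.
#' @export
daf_spectrum <- function(counts, n, folded = FALSE) {
  n <- as.integer(n)
  if (n < 2L) stop("sample size n must be >= 2")
  counts <- as.numeric(counts)
  want <- if (folded) n %/% 2L else n - 1L
  if (length(counts) != want) {
    stop("counts has length ", length(counts), ", expected ", want)
  }
  if (any(counts < 0)) stop("spectrum counts must be nonnegative")
  structure(list(counts = counts, n = n, folded = folded),
            class = "daf_spectrum")
}

#' @export
print.daf_spectrum <- function(x, ...) {
  cat(sprintf("%s derived allele frequency spectrum, n = %d, total = %g\n",
              if (x$folded) "Folded" else "Unfolded", x$n, sum(x$counts)))
  print(setNames(x$counts, seq_along(x$counts)))
  invisible(x)
}

#' Total mass of a spectrum
#' @param spec A `daf_spectrum`.
#' @return Sum of all class counts.
#' @export
spectrum_total <- function(spec) {
  stopifnot(inherits(spec, "daf_spectrum"))
  sum(spec$counts)
}

#' Hypergeometric projection of a spectrum to a smaller sample size
#'
#' Each input class `i` (of `n`) contributes to output class `j` (of `m`)
#' with weight `choose(i, j) * choose(n - i, m - j) / choose(n, m)`: the
#' probability that a without-replacement subsample of `m` chromosomes
#' contains exactly `j` derived alleles.  Mass landing on the monomorphic
#' classes `j = 0` and `j = m` is discarded (a subsampled site that no longer
#' segregates is unobservable); with `normalize = TRUE` the result is divided
#' by its own total so it sums to 1.
#'
#' @param spec Unfolded `daf_spectrum` at sample size `n`.
#' @param m Target sample size, `2 <= m <= n`.
#' @param normalize Divide the projected spectrum by its total?
#' @return A `daf_spectrum` at sample size `m`.
#' @export
project_spectrum <- function(spec, m, normalize = FALSE) {
  stopifnot(inherits(spec, "daf_spectrum"))
  if (spec$folded) stop("cannot project a folded spectrum")
  m <- as.integer(m)
  n <- spec$n
  if (m < 2L || m > n) stop("target size m must satisfy 2 <= m <= n")
  W <- projection_weights(n, m)            # (n-1) x (m-1)
  out <- as.numeric(crossprod(W, spec$counts))
  if (normalize) {
    tot <- sum(out)
    if (tot <= 0) stop("projected spectrum has zero mass; cannot normalize")
    out <- out / tot
  }
  daf_spectrum(out, m)
}

# Weight matrix: rows input class i = 1..n-1, cols output class j = 1..m-1.
# Monomorphic output classes (j = 0, m) are simply not represented.
projection_weights <- function(n, m) {
  i <- seq_len(n - 1L)
  j <- seq_len(m - 1L)
  W <- outer(i, j, function(ii, jj) {
    exp(lchoose(ii, jj) + lchoose(n - ii, m - jj) - lchoose(n, m))
  })
  W[is.na(W)] <- 0
  W
}

#' Aggregate segregating sites into a spectrum at a common sample size
#'
#' Sites already at `n_target` contribute a unit count at their derived
#' count `k`; sites genotyped in more chromosomes are projected down
#' hypergeometrically, with each site's projected weights renormalized over
#' the segregating outcomes so every input site contributes total mass 1.
#'
#' @param sites Data frame with integer columns `k` (derived count) and `n`
#'   (chromosomes genotyped), one row per segregating site.  May be empty.
#' @param n_target Common sample size; must not exceed any site's `n`.
#' @return Unfolded `daf_spectrum` at `n_target` with total equal to
#'   `nrow(sites)`.
#' @export
build_spectrum <- function(sites, n_target) {
  n_target <- as.integer(n_target)
  if (n_target < 2L) stop("n_target must be >= 2")
  counts <- numeric(n_target - 1L)
  if (NROW(sites) == 0L) return(daf_spectrum(counts, n_target))
  k <- as.integer(sites$k)
  n <- as.integer(sites$n)
  if (any(k < 1L) || any(k > n - 1L)) stop("sites must satisfy 1 <= k <= n-1")
  if (any(n < n_target)) {
    stop("n_target exceeds the sample size of at least one site")
  }
  direct <- n == n_target
  if (any(direct)) {
    tab <- tabulate(k[direct], nbins = n_target - 1L)
    counts <- counts + tab
  }
  for (idx in which(!direct)) {
    w <- projection_weights(n[idx], n_target)[k[idx], ]
    s <- sum(w)
    if (s > 0) counts <- counts + w / s
  }
  daf_spectrum(counts, n_target)
}

#' Fold a spectrum onto minor-allele frequency classes
#'
#' `folded[i] = counts[i] + counts[n - i]` for `i < n/2`, and
#' `folded[n/2] = counts[n/2]` when `n` is even.  Folding discards the
#' ancestral/derived polarization and conserves total mass.
#'
#' @param spec Unfolded `daf_spectrum`.
#' @return Folded `daf_spectrum`.
#' @export
fold_spectrum <- function(spec) {
  stopifnot(inherits(spec, "daf_spectrum"))
  if (spec$folded) return(spec)
  n <- spec$n
  half <- n %/% 2L
  out <- numeric(half)
  for (i in seq_len(half)) {
    out[i] <- if (i == n - i) spec$counts[i] else spec$counts[i] + spec$counts[n - i]
  }
  daf_spectrum(out, n, folded = TRUE)
}

#' Classical site-frequency summary statistics
#'
#' Computes the segregating-site count S, Watterson's theta, nucleotide
#' diversity pi, Tajima's D and Fay & Wu's H from per-site derived-allele
#' counts at a common sample size.  All sites are assumed genotyped in the
#' same `n` chromosomes (project or filter first if not).  With `S = 0`,
#' D and H are undefined and reported as `NA` rather than 0.
#'
#' Per-region estimators:
#' \deqn{\theta_W = S / a_1, \quad a_1 = \sum_{i=1}^{n-1} 1/i}
#' \deqn{\pi = \sum_{sites} 2 k (n-k) / (n (n-1))}
#' \deqn{\theta_H = \sum_{sites} 2 k^2 / (n (n-1))}
#' D is \eqn{(\pi - \theta_W)} over the square root of Tajima's (1989)
#' variance estimate; H is \eqn{\pi - \theta_H}.
#'
#' @param sites Data frame with column `k`, or an integer vector of derived
#'   counts.  May be empty.
#' @param n Sample size (chromosomes), `n >= 2`.
#' @param L Optional callable-base count; when given, per-site versions of
#'   theta and pi are included.
#' @return Object of class `summary_stats`: a list with elements `S`,
#'   `theta_w`, `pi`, `theta_h`, `tajima_d`, `fay_wu_h`, `n`, and (if `L`
#'   given) `L`, `theta_w_site`, `pi_site`.
#' @export
summary_stats <- function(sites, n, L = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("sample size n must be >= 2")
  k <- if (is.data.frame(sites)) as.integer(sites$k) else as.integer(sites)
  if (any(k < 1L | k > n - 1L)) stop("derived counts must satisfy 1 <= k <= n-1")
  S <- length(k)
  a1 <- sum(1 / seq_len(n - 1L))
  theta_w <- S / a1
  pi <- sum(2 * k * (n - k)) / (n * (n - 1))
  theta_h <- sum(2 * k^2) / (n * (n - 1))
  if (S == 0L) {
    d <- NA_real_
    h <- NA_real_
  } else {
    a2 <- sum(1 / seq_len(n - 1L)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    vd <- e1 * S + e2 * S * (S - 1)
    d <- if (vd > 0) (pi - theta_w) / sqrt(vd) else 0
    h <- pi - theta_h
  }
  out <- list(S = S, theta_w = theta_w, pi = pi, theta_h = theta_h,
              tajima_d = d, fay_wu_h = h, n = n)
  if (!is.null(L)) {
    out$L <- L
    out$theta_w_site <- theta_w / L
    out$pi_site <- pi / L
  }
  structure(out, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("S = %d, theta_W = %.4g, pi = %.4g, Tajima's D = %s, Fay & Wu's H = %s\n",
              x$S, x$theta_w, x$pi,
              ifelse(is.na(x$tajima_d), "NA", sprintf("%.4g", x$tajima_d)),
              ifelse(is.na(x$fay_wu_h), "NA", sprintf("%.4g", x$fay_wu_h))))
  invisible(x)
}
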