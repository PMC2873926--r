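# Composite-likelihood-ratio scan for completed selective sweeps against an
# arbitrary background derived-allele-frequency spectrum, with
# simulation-based p-values conditional on S, the coverage mask, and rho.

#' Background derived-allele-frequency spectrum
#'
#' Normalized probabilities over derived-allele counts `1..n-1`.
#'
#' @param probs Nonnegative weights over classes `1..n-1`; normalized
#'   internally.
#' @param n Sample size.
#' @return Object of class `background_sfs`.
#' @export
background_sfs <- function(probs, n) {
  n <- as.integer(n)
  probs <- as.numeric(probs)
  if (length(probs) != n - 1L) stop("need n-1 class probabilities")
  if (any(probs < 0) || sum(probs) <= 0) stop("probabilities must be nonnegative with positive sum")
  structure(list(probs = probs / sum(probs), n = n), class = "background_sfs")
}

#' Estimate a background spectrum from pooled segregating sites
#'
#' Aggregates the derived-allele frequencies of sites from many regions into
#' a normalized spectrum at a common sample size: sites at `n_target` count
#' directly, sites at larger `n` are projected down hypergeometrically
#' (monomorphic subsample mass discarded), the aggregate is normalized once,
#' and sites at smaller `n` are excluded with a warning.  The single final
#' normalization (rather than per-site renormalization) makes estimation
#' commute with projection.
#'
#' @param sites Site data frame with columns `k`, `n`.
#' @param n_target Common sample size of the background.
#' @return A [background_sfs] at `n_target`.
#' @export
estimate_background <- function(sites, n_target) {
  if (NROW(sites) == 0L) stop("need at least one site")
  drop <- sites$n < n_target
  if (any(drop)) {
    warning(sum(drop), " site(s) with n < n_target excluded from the background")
    sites <- sites[!drop, , drop = FALSE]
  }
  counts <- numeric(n_target - 1L)
  for (nn in unique(sites$n)) {
    sub <- sites[sites$n == nn, , drop = FALSE]
    spec <- daf_spectrum(tabulate(sub$k, nbins = nn - 1L), nn)
    counts <- counts + if (nn == n_target) spec$counts else
      project_spectrum(spec, n_target)$counts
  }
  background_sfs(counts, n_target)
}

# Post-sweep class-probability kernel.  Row e+1 (escapees e = 0..n), column
# j+1 (observed derived count j = 0..n): probability of observing j derived
# alleles given that e of the n lineages escaped the sweep.  Non-escaped
# lineages coalesce through the sweep into a single ancestral lineage (star
# approximation), so the e + 1 ancestral lineages are a hypergeometric
# subsample of the background; the swept lineage's allele is copied to the
# n - e non-escaped samples.
sweep_kernel <- function(bg) {
  n <- bg$n
  probs <- bg$probs
  K <- matrix(0, n + 1L, n + 1L)
  for (e in 0:n) {
    if (e == n) {
      # everyone escapes: the sample is an unperturbed background draw
      K[n + 1L, 2:n] <- probs
      next
    }
    a <- e + 1L  # ancestral lineages sampled from the background
    # d-distribution: derived count among the a ancestral lineages
    pd <- numeric(a + 1L)
    for (i in seq_len(n - 1L)) {
      if (probs[i] == 0) next
      d <- 0:a
      pd <- pd + probs[i] * exp(lchoose(i, d) + lchoose(n - i, a - d) - lchoose(n, a))
    }
    for (d in 0:a) {
      if (pd[d + 1L] == 0) next
      p_swept_derived <- d / a
      j_hot <- (d - 1L) + (n - e)     # swept lineage derived
      j_cold <- d                      # swept lineage ancestral
      K[e + 1L, j_hot + 1L] <- K[e + 1L, j_hot + 1L] + pd[d + 1L] * p_swept_derived
      K[e + 1L, j_cold + 1L] <- K[e + 1L, j_cold + 1L] + pd[d + 1L] * (1 - p_swept_derived)
    }
  }
  K
}

# Per-site log-likelihood under the sweep model at escape probabilities pe
# (vector over sites), given kernel K and observed counts k.  Probabilities
# are renormalized over the polymorphic outcomes 1..n-1.
sweep_site_loglik <- function(pe, k, n, K) {
  W <- outer(pe, 0:n, function(p, e) dbinom(e, n, p))   # sites x (n+1)
  M <- W %*% K                                          # sites x (n+1)
  poly <- rowSums(M[, 2:n, drop = FALSE])
  li <- M[cbind(seq_along(k), k + 1L)] / poly
  li[poly <= 0 | li <= 0] <- NA
  if (anyNA(li)) return(-Inf)
  sum(log(li))
}

#' Composite-likelihood-ratio sweep scan across a region
#'
#' For each position on a grid across the region, fits the sweep-intensity
#' parameter `alpha` of a complete-sweep model in which each of the `n`
#' sampled lineages at a site at distance `d` escapes the sweep independently
#' with probability `p_e = 1 - exp(-alpha * d)` (alpha absorbs the
#' recombination rate), the non-escaped lineages coalesce through the sweep,
#' and the pre-sweep frequencies follow the background spectrum.  The CLR at
#' a grid point is `2 * (max_alpha log CL_sweep - log CL_background)`,
#' floored at 0 (the background is the `alpha -> Inf` limit of the model).
#' `alpha` is maximized on a log-spaced grid refined by bounded scalar
#' optimization; ties in the argmax break toward the leftmost grid point.
#'
#' @param sites Site data frame with columns `pos`, `k` (and constant `n`
#'   matching the background, or projectable via the background's `n`).
#' @param reg A [region]; sites must lie in its covered intervals.
#' @param bg A [background_sfs] whose `n` equals the sites' sample size.
#' @param grid_size Number of grid points, inclusive of region endpoints
#'   (default 1000).
#' @param alpha_grid Log-spaced candidate alphas per bp (default
#'   `10^seq(-7, -1, length.out = 13)`).
#' @param refine Refine the best grid alpha by bounded scalar optimization
#'   (default TRUE; FALSE restricts the fit to `alpha_grid`).
#' @return Object of class `clr_scan`: list with `grid`, `clr`, `alpha_hat`,
#'   `max_clr`, `argmax`, `loglik0`.
#' @export
clr_scan <- function(sites, reg, bg, grid_size = 1000L,
                     alpha_grid = 10^seq(-7, -1, length.out = 13),
                     refine = TRUE) {
  stopifnot(inherits(bg, "background_sfs"))
  if (NROW(sites) < 1L) stop("need at least one segregating site")
  n <- bg$n
  if (any(sites$n != n)) {
    stop("site sample sizes must match the background (project first)")
  }
  k <- as.integer(sites$k)
  if (any(k < 1L | k > n - 1L)) stop("derived counts must be polymorphic")
  pos <- as.numeric(sites$pos)
  if (inherits(reg, "region") && !all(in_covered(reg, pos))) {
    stop("sites outside the covered intervals of the region")
  }
  K <- sweep_kernel(bg)
  loglik0 <- sum(log(bg$probs[k]))
  grid <- seq(reg$start, reg$end, length.out = grid_size)
  clr <- numeric(grid_size)
  alpha_hat <- numeric(grid_size)
  la <- log(alpha_grid)
  for (g in seq_len(grid_size)) {
    d <- abs(pos - grid[g])
    ll_of <- function(loga) {
      sweep_site_loglik(-expm1(-exp(loga) * d), k, n, K)
    }
    ll <- vapply(la, ll_of, numeric(1))
    best <- which.max(ll)
    lo <- la[max(1L, best - 1L)]
    hi <- la[min(length(la), best + 1L)]
    opt <- if (refine && hi > lo && is.finite(ll[best])) {
      optimize(ll_of, c(lo, hi), maximum = TRUE, tol = 1e-4)
    } else {
      list(maximum = la[best], objective = ll[best])
    }
    ll_best <- max(opt$objective, ll[best])
    a_best <- if (opt$objective >= ll[best]) exp(opt$maximum) else exp(la[best])
    clr[g] <- max(0, 2 * (ll_best - loglik0))
    alpha_hat[g] <- a_best
  }
  argmax <- which.max(clr)  # which.max already breaks ties leftmost
  structure(list(grid = grid, clr = clr, alpha_hat = alpha_hat,
                 max_clr = clr[argmax], argmax = grid[argmax],
                 loglik0 = loglik0, n = n, p = NULL),
            class = "clr_scan")
}

#' @export
print.clr_scan <- function(x, ...) {
  cat(sprintf("CLR scan: %d grid points, max CLR = %.4g at %.0f%s\n",
              length(x$grid), x$max_clr, x$argmax,
              if (is.null(x$p)) "" else sprintf(", p = %.4g", x$p)))
  invisible(x)
}

#' Simulation p-value for an observed maximum CLR
#'
#' Simulates neutral replicates of the region conditional on the observed
#' number of segregating sites, the coverage mask, and the recombination
#' rate; scans each with the same background; and reports the fraction of
#' replicates whose maximum CLR reaches the observed maximum.
#'
#' @param scan A [clr_scan] result for the observed data.
#' @param reg The scanned [region].
#' @param observed_S Number of segregating sites conditioned on.
#' @param bg The same [background_sfs] used for the observed scan.
#' @param rho Region-scaled recombination rate for the null replicates.
#' @param n_reps Number of null replicates (default 1000).
#' @param grid_size Grid size for the replicate scans (default 200; the
#'   null maximum is insensitive to grid density beyond this).
#' @return The scan with `p` filled in, plus attribute `null_max` holding
#'   the replicate maxima.
#' @export
sweep_pvalue <- function(scan, reg, observed_S, bg, rho = 0, n_reps = 1000L,
                         grid_size = 200L) {
  stopifnot(inherits(scan, "clr_scan"), inherits(bg, "background_sfs"))
  null_max <- numeric(n_reps)
  mask0 <- cbind(reg$covered[, 1] - reg$start, reg$covered[, 2] - reg$start)
  for (r in seq_len(n_reps)) {
    sim <- simulate_neutral_region(n = bg$n, S = observed_S, rho = rho,
                                   L = region_length(reg), mask = mask0)
    sim$pos <- sim$pos + reg$start
    rs <- clr_scan(sim, reg, bg, grid_size = grid_size)
    null_max[r] <- rs$max_clr
  }
  scan$p <- mean(null_max >= scan$max_clr)
  attr(scan, "null_max") <- null_max
  scan
}
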