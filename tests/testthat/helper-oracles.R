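# Independent oracle implementations used to check the package's results.
# These deliberately use different algorithms (exhaustive enumeration,
# textbook formulas written from scratch) from the code paths they verify.

# --- spectrum projection by exhaustive subsample enumeration ----------------
# For every class i of an n-spectrum, enumerate all choose(n, m) subsamples
# of a configuration with i derived alleles and tally the derived counts.
oracle_project <- function(counts, n, m, normalize = FALSE) {
  out <- numeric(m - 1)
  subs <- utils::combn(n, m)
  for (i in seq_len(n - 1)) {
    if (counts[i] == 0) next
    derived <- seq_len(i)  # exchangeable: put derived alleles in slots 1..i
    tall <- apply(subs, 2, function(ss) sum(ss %in% derived))
    for (j in seq_len(m - 1)) {
      out[j] <- out[j] + counts[i] * mean(tall == j)
    }
  }
  if (normalize) out <- out / sum(out)
  out
}

# --- Tajima's D and Fay & Wu's H from scratch -------------------------------
oracle_tajima_d <- function(k, n) {
  S <- length(k)
  pi <- 0
  for (kk in k) pi <- pi + (2 * kk * (n - kk)) / (n * (n - 1))
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  (pi - S / a1) / sqrt(v)
}

oracle_fay_wu_h <- function(k, n) {
  pi <- sum(vapply(k, function(kk) 2 * kk * (n - kk), numeric(1))) / (n * (n - 1))
  th <- sum(vapply(k, function(kk) 2 * kk^2, numeric(1))) / (n * (n - 1))
  pi - th
}

# --- exact two-sided MWU p by full rank-assignment enumeration --------------
oracle_mwu_p <- function(x, y) {
  m <- length(x)
  N <- m + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  u_all <- apply(utils::combn(N, m), 2, function(ix) {
    sum(r[ix]) - m * (m + 1) / 2
  })
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# --- two-sided Fisher p by enumeration of all tables with fixed margins -----
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  obs <- probs[(lo:hi) == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# --- Poisson upper tail by term-by-term series summation --------------------
oracle_poisson_upper <- function(obs, mean, terms = 500) {
  xs <- 0:(obs - 1)
  1 - sum(exp(-mean + xs * log(mean) - lfactorial(xs)))
}

# --- sweep-model class probabilities by brute-force enumeration (n <= 6) ----
# Enumerates every escape pattern (2^n), every placement of the derived
# alleles (choose(n, i) configurations), and every ordered choice of the
# escaped lineages' ancestors plus the swept group's single ancestor among
# the n background slots.
oracle_sweep_probs <- function(bg_probs, n, pe) {
  pj <- numeric(n + 1)  # j = 0..n
  for (i in seq_len(n - 1)) {
    if (bg_probs[i] == 0) next
    dsets <- utils::combn(n, i)
    for (dc in seq_len(ncol(dsets))) {
      derived <- dsets[, dc]
      w_conf <- bg_probs[i] / ncol(dsets)
      for (e in 0:n) {
        w_e <- choose(n, e) * pe^e * (1 - pe)^(n - e)
        if (w_e == 0) next
        if (e == n) {
          # everyone escapes: ancestors are the whole configuration
          pj[i + 1] <- pj[i + 1] + w_conf * w_e
          next
        }
        # e escaped ancestors (subset A) plus one swept-group ancestor
        # (slot s not in A), all equally likely distinct slots
        asets <- utils::combn(n, e)  # n >= 1 columns even for e = 0
        n_pairs <- ncol(asets) * (n - e)
        for (ac in seq_len(ncol(asets))) {
          A <- if (e == 0) integer() else asets[, ac]
          for (s in setdiff(seq_len(n), A)) {
            j <- sum(A %in% derived) + (n - e) * (s %in% derived)
            pj[j + 1] <- pj[j + 1] + w_conf * w_e / n_pairs
          }
        }
      }
    }
  }
  pj
}

# Oracle CLR at fixed grid points / alpha grid: direct summation likelihood.
oracle_clr <- function(sites, bg_probs, n, grid_pos, alphas) {
  loglik0 <- sum(log(bg_probs[sites$k]))
  vapply(grid_pos, function(x) {
    best <- -Inf
    for (a in alphas) {
      ll <- 0
      for (s in seq_len(nrow(sites))) {
        pe <- 1 - exp(-a * abs(sites$pos[s] - x))
        pj <- oracle_sweep_probs(bg_probs, n, pe)
        poly <- sum(pj[2:n])
        li <- pj[sites$k[s] + 1] / poly
        ll <- ll + log(li)
      }
      if (ll > best) best <- ll
    }
    max(0, 2 * (best - loglik0))
  }, numeric(1))
}

# --- misc -------------------------------------------------------------------
# 99% binomial envelope for an empirical fraction at nominal rate a
binom_envelope <- function(a, n_reps) {
  a + c(-1, 1) * 2.576 * sqrt(a * (1 - a) / n_reps)
}

make_region_40kb <- function(id = "r1", start = 0) {
  region(id, "chr1", start, start + 40000)
}
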