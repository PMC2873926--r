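# Neutral calibration machinery: a Kingman-coalescent segregating-site
# simulator (fixed-S conditioning, coverage masks, independent-block
# recombination approximation) and an HKY phylogenetic substitution simulator
# for fixed differences.

# Simulate one Kingman genealogy for n samples.  Returns a data frame of
# branches with columns `length` (in units of 4N generations, the ms
# convention: coalescence rate k(k-1)/2 for k lineages) and `ndesc` (sample
# leaves below the branch).
coalescent_branches <- function(n) {
  if (n < 2L) stop("need n >= 2 samples")
  ndesc <- rep(1L, n)           # live lineages' descendant counts
  t_created <- rep(0, n)        # time each live lineage appeared
  lens <- numeric(2 * n - 2)
  descs <- integer(2 * n - 2)
  b <- 0L
  t_now <- 0
  k <- n
  while (k > 1L) {
    t_now <- t_now + rexp(1, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    for (i in pair) {
      b <- b + 1L
      lens[b] <- t_now - t_created[i]
      descs[b] <- ndesc[i]
    }
    merged <- sum(ndesc[pair])
    ndesc <- c(ndesc[-pair], merged)
    t_created <- c(t_created[-pair], t_now)
    k <- k - 1L
  }
  data.frame(length = lens, ndesc = descs)
}

# Draw derived-allele counts for `S` mutations on one genealogy: each
# mutation lands on a branch with probability proportional to its length and
# is carried by the branch's descendants.
mutation_counts_on_tree <- function(branches, S) {
  if (S == 0L) return(integer())
  idx <- sample.int(nrow(branches), S, replace = TRUE, prob = branches$length)
  branches$ndesc[idx]
}

#' Simulate segregating sites for a region under the standard neutral model
#'
#' Generates a standard-coalescent sample and returns `(pos, k, n)` records.
#' With `S` given, exactly `S` mutations are placed on the genealogy in
#' proportion to branch length (fixed-S conditioning, the `-s` behavior of
#' the classic simulators); with `theta` given, the mutation count is Poisson
#' with mean `theta * Ltree / 2` (`theta` = 4Nu for the whole region).
#' Positions are uniform over the covered intervals of the mask.
#'
#' Recombination is approximated by independent blocks: `rho/2` expected
#' uniformly-placed breakpoints partition the region and each block receives
#' an independent genealogy; sites falling in the same block share a
#' genealogy.  With `rho = 0` (default) all sites share one genealogy.
#'
#' @param n Sampled chromosomes (>= 2).
#' @param S Conditioned segregating-site count (exclusive with `theta`).
#' @param theta Region-scaled mutation rate 4Nu (exclusive with `S`).
#' @param rho Region-scaled recombination rate 4Nr (default 0).
#' @param L Region length in bp (default 40000).
#' @param mask Optional [region] or two-column matrix of covered intervals;
#'   site positions are restricted to it.
#' @return Data frame with columns `pos`, `k`, `n`, sorted by position.
#' @export
simulate_neutral_region <- function(n, S = NULL, theta = NULL, rho = 0,
                                    L = 40000, mask = NULL) {
  n <- as.integer(n)
  if (is.null(S) == is.null(theta)) {
    stop("give exactly one of S (fixed-S conditioning) or theta")
  }
  intervals <- if (is.null(mask)) {
    cbind(0, L)
  } else if (inherits(mask, "region")) {
    mask$covered
  } else {
    as.matrix(mask[, 1:2, drop = FALSE])
  }
  widths <- intervals[, 2] - intervals[, 1]
  if (!is.null(S) && S > 0 && sum(widths) <= 0) {
    stop("empty coverage mask with S > 0")
  }
  draw_pos <- function(m) {
    iv <- sample.int(nrow(intervals), m, replace = TRUE, prob = widths)
    floor(intervals[iv, 1] + runif(m) * widths[iv])
  }
  # block boundaries from the recombination approximation
  n_bp <- if (rho > 0) rpois(1, rho / 2) else 0L
  bounds <- sort(c(0, if (n_bp > 0) runif(n_bp, 0, L), L))
  n_blocks <- length(bounds) - 1L
  trees <- lapply(seq_len(n_blocks), function(i) coalescent_branches(n))
  if (!is.null(S)) {
    S <- as.integer(S)
    pos <- if (S > 0) sort(draw_pos(S)) else numeric()
    block <- findInterval(pos, bounds, rightmost.closed = TRUE)
    k <- integer(S)
    for (bl in unique(block)) {
      sel <- block == bl
      k[sel] <- mutation_counts_on_tree(trees[[bl]], sum(sel))
    }
  } else {
    # theta-mode: mutations per block proportional to block share of the
    # region times the block tree length
    k <- integer()
    pos <- numeric()
    for (bl in seq_len(n_blocks)) {
      ltree <- sum(trees[[bl]]$length)
      frac <- (bounds[bl + 1] - bounds[bl]) / L
      s_bl <- rpois(1, theta * frac * ltree / 2)
      if (s_bl > 0) {
        k <- c(k, mutation_counts_on_tree(trees[[bl]], s_bl))
        p <- draw_pos(s_bl)
        pos <- c(pos, p)
      }
    }
    ord <- order(pos)
    pos <- pos[ord]
    k <- k[ord]
  }
  data.frame(pos = pos, k = as.integer(k), n = rep(n, length(k)))
}

#' Assign W2S/S2W mutation classes by Bernoulli trials
#'
#' Labels each site `W2S` with probability `w2s_fraction` (default the
#' study-wide W2S:S2W ratio 2057:2114) and `S2W` otherwise, and draws
#' ancestral/derived bases consistent with the class (uniform within the
#' weak/strong pairs).
#'
#' @param sites Site data frame.
#' @param w2s_fraction Probability a site is W2S.
#' @return `sites` with `klass`, `ancestral`, `derived` columns.
#' @export
label_mutation_classes <- function(sites, w2s_fraction = 2057 / (2057 + 2114)) {
  if (w2s_fraction < 0 || w2s_fraction > 1) stop("w2s_fraction must be in [0, 1]")
  m <- NROW(sites)
  is_w2s <- runif(m) < w2s_fraction
  weak <- c("A", "T")
  strong <- c("G", "C")
  anc <- ifelse(is_w2s, sample(weak, m, replace = TRUE),
                sample(strong, m, replace = TRUE))
  der <- ifelse(is_w2s, sample(strong, m, replace = TRUE),
                sample(weak, m, replace = TRUE))
  sites$klass <- ifelse(is_w2s, "W2S", "S2W")
  sites$ancestral <- anc
  sites$derived <- der
  sites
}

# HKY85 rate matrix with equilibrium GC content and ts/tv ratio kappa,
# scaled to one expected substitution per unit branch length.
hky_rate_matrix <- function(eq_gc = 0.41, kappa = 2) {
  if (eq_gc <= 0 || eq_gc >= 1) stop("eq_gc must be in (0, 1)")
  bases <- c("A", "C", "G", "T")
  pi <- c(A = (1 - eq_gc) / 2, C = eq_gc / 2, G = eq_gc / 2, T = (1 - eq_gc) / 2)
  transition <- function(i, j) {
    (bases[i] == "A" & bases[j] == "G") | (bases[i] == "G" & bases[j] == "A") |
      (bases[i] == "C" & bases[j] == "T") | (bases[i] == "T" & bases[j] == "C")
  }
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in 1:4) for (j in 1:4) {
    if (i != j) Q[i, j] <- pi[j] * if (transition(i, j)) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate <= 0) stop("degenerate rate matrix")
  list(Q = Q / rate, pi = pi)
}

# Transition probability matrix P(t) = expm(Q t) via eigendecomposition.
hky_transition <- function(Q, t) {
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
  }

#' Simulate human-chimp fixed differences under a neutral substitution model
#'
#' Evolves alignment columns on a three-taxon tree (human and chimp from
#' their common ancestor, an outgroup attached by a longer branch) under an
#' HKY model, and collects columns where human and chimp differ and the
#' outgroup allele matches exactly one of them (so the ancestral allele is
#' unambiguous).  Columns are simulated in batches until `n_fixed_sites`
#' usable sites have accumulated.
#'
#' @param n_fixed_sites Target number of fixed differences (default 335).
#' @param eq_gc Equilibrium GC content of the model (default 0.41, the
#'   genome-wide average).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param branch_human,branch_chimp Terminal branch lengths in expected
#'   substitutions per site (defaults 0.006 each).
#' @param branch_outgroup Ancestor-to-outgroup path length (default 0.024,
#'   4x the terminal branches).
#' @param max_batches Safety cap on simulation batches.
#' @return A `fixed_diff_set` whose table has columns `human`, `chimp`,
#'   `ancestral`, `lineage`, `klass`.
#' @export
simulate_fixed_differences <- function(n_fixed_sites = 335, eq_gc = 0.41,
                                       kappa = 2,
                                       branch_human = 0.006,
                                       branch_chimp = 0.006,
                                       branch_outgroup = 0.024,
                                       max_batches = 200L) {
  if (branch_human <= 0 && branch_chimp <= 0) {
    stop("human and chimp branch lengths are both zero: no differences can arise")
  }
  mod <- hky_rate_matrix(eq_gc, kappa)
  Ph <- hky_transition(mod$Q, branch_human)
  Pc <- hky_transition(mod$Q, branch_chimp)
  Po <- hky_transition(mod$Q, branch_outgroup)
  bases <- c("A", "C", "G", "T")
  p_diff <- max(1e-4, 1 - sum(vapply(1:4, function(a) {
    mod$pi[a] * sum(Ph[a, ] * Pc[a, ])
  }, numeric(1))))
  batch <- max(1000L, ceiling(2 * n_fixed_sites / p_diff))
  got <- list()
  n_got <- 0L
  for (it in seq_len(max_batches)) {
    anc <- sample.int(4, batch, replace = TRUE, prob = mod$pi)
    evolve <- function(P) {
      u <- runif(batch)
      cp <- t(apply(P, 1, cumsum))
      out <- integer(batch)
      for (a in 1:4) {
        sel <- anc == a
        out[sel] <- findInterval(u[sel], c(0, cp[a, ]), rightmost.closed = TRUE)
      }
      pmin(out, 4L)
    }
    h <- evolve(Ph)
    c_ <- evolve(Pc)
    o <- evolve(Po)
    usable <- h != c_ & (o == h | o == c_)
    if (any(usable)) {
      df <- data.frame(human = bases[h[usable]], chimp = bases[c_[usable]],
                       ancestral = bases[o[usable]])
      got[[length(got) + 1L]] <- df
      n_got <- n_got + nrow(df)
    }
    if (n_got >= n_fixed_sites) break
  }
  if (n_got < n_fixed_sites) {
    stop("failed to collect ", n_fixed_sites, " fixed differences (branches too short?)")
  }
  tab <- head(do.call(rbind, got), n_fixed_sites)
  tab$pos <- seq_len(nrow(tab))
  tab <- annotate_fixed(tab)
  counts <- c(W2S = sum(tab$klass == "W2S"), S2W = sum(tab$klass == "S2W"),
              OTHER = sum(tab$klass == "OTHER"))
  structure(list(table = tab, counts = counts, n_input = nrow(tab),
                 n_kept = nrow(tab), removed_fraction = 0),
            class = "fixed_diff_set")
}

#' Neutral calibration of the MWU or MK test
#'
#' Repeats the study-shaped neutral experiment and reports, for each
#' significance level in `alpha_grid`, the fraction of replicates with
#' p below it and the subset of that fraction whose direction favors W2S.
#'
#' MWU mode: each replicate simulates a fixed-S coalescent sample
#' (default S = 85 sites, n = 22 chromosomes) and Bernoulli-labels the sites
#' W2S/S2W at the study-wide ratio.  MK mode: each replicate simulates
#' `n_fixed` phylogenetic fixed differences and `n_seg` Bernoulli-labeled
#' segregating sites whose class probabilities are the pooled fixed-difference
#' class ratios across all replicates.
#'
#' @param test `"MWU"` or `"MK"`.
#' @param n_reps Number of neutral replicates.
#' @param alpha_grid Significance levels to evaluate.
#' @param n_chrom,S MWU-mode sample size and conditioned site count.
#' @param n_fixed,n_seg MK-mode fixed-difference and segregating-site counts.
#' @param w2s_fraction MWU-mode labeling probability.
#' @param ... Passed to [simulate_fixed_differences] in MK mode.
#' @return List with `table` (data frame alpha / frac_below / frac_below_w2s),
#'   `p` (replicate p-values), `w2s_direction` (logical per replicate).
#' @export
calibrate_test <- function(test = c("MWU", "MK"), n_reps = 2000,
                           alpha_grid = c(0.01, 0.05, 0.10),
                           n_chrom = 22L, S = 85L,
                           n_fixed = 335L, n_seg = 101L,
                           w2s_fraction = 2057 / (2057 + 2114), ...) {
  test <- match.arg(test)
  p <- numeric(n_reps)
  w2s_dir <- logical(n_reps)
  if (test == "MWU") {
    for (r in seq_len(n_reps)) {
      sites <- simulate_neutral_region(n = n_chrom, S = S)
      sites <- label_mutation_classes(sites, w2s_fraction)
      res <- mwu_test(sites[sites$klass == "W2S", , drop = FALSE],
                      sites[sites$klass == "S2W", , drop = FALSE])
      p[r] <- res$p
      w2s_dir[r] <- !is.na(res$offset22) && res$offset22 > 0
    }
  } else {
    fixed_counts <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      fixed_counts[[r]] <- simulate_fixed_differences(n_fixed, ...)$counts
    }
    pooled <- Reduce(`+`, fixed_counts)
    class_prob <- pooled / sum(pooled)
    for (r in seq_len(n_reps)) {
      kl <- sample(names(class_prob), n_seg, replace = TRUE, prob = class_prob)
      seg <- c(W2S = sum(kl == "W2S"), S2W = sum(kl == "S2W"))
      res <- mk_test(fixed_counts[[r]][c("W2S", "S2W")], seg)
      p[r] <- res$p
      w2s_dir[r] <- !is.na(res$direction) && res$direction == "W2S"
    }
  }
  tab <- data.frame(
    alpha = alpha_grid,
    frac_below = vapply(alpha_grid, function(a) mean(!is.na(p) & p < a), numeric(1)),
    frac_below_w2s = vapply(alpha_grid, function(a) {
      mean(!is.na(p) & p < a & w2s_dir)
    }, numeric(1))
  )
  list(table = tab, p = p, w2s_direction = w2s_dir)
}
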