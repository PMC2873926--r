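# R surface of the forward Wright-Fisher simulator of biased gene conversion.

#' Configuration for the forward BGC simulator
#'
#' The simulator models biased gene conversion as genic selection: every new
#' weak-to-strong mutation multiplies its haplotype's fitness by
#' `1 + |e|` and every strong-to-weak mutation by `1 - |e|`, with `e` a
#' normal deviate scaled so the mean population-scaled effect `4N E|e|`
#' equals `scaled_bgc`.  The population evolves `burnin * N` generations to
#' stationarity, splits instantaneously into two populations (the
#' human/chimp vicariance), and each evolves a further `split_time * 4N`
#' generations before sampling.
#'
#' The per-locus scaled mutation rate `theta_locus = 4Nu` defaults to 21,
#' sized so the mean segregating-site count in a 50-chromosome human sample
#' (`theta * a_49` with `a_49 = sum(1/1:49) = 4.48`) matches study-scale
#' per-region averages of roughly 85-101 sites, and the expected human-chimp
#' fixed-difference count over `2 * split_time` units of 4N generations
#' (about `13 * theta` under neutrality) is comparable to the study-scale
#' average of ~335.  Supplying `bgc_mut_ratio` instead derives
#' `theta_locus = scaled_bgc / bgc_mut_ratio`.
#'
#' @param N Diploid population size (default 10000; use 500-1000 for
#'   scaled-down experiments - the scaled parameters are preserved).
#' @param scaled_bgc Population-scaled conversion strength 4NB (default 1.3).
#' @param theta_locus Population-scaled per-locus mutation rate 4Nu
#'   (default 21; see above).
#' @param bgc_mut_ratio Optional ratio 4NB : 4Nu; when given it overrides
#'   `theta_locus`.
#' @param L Mutable sites per haplotype (default 2000).
#' @param burnin Burn-in length as a multiple of N generations (default 40).
#' @param split_time Post-split duration in units of 4N generations
#'   (default 6.5).
#' @param n_human,n_chimp Sampled chromosomes per lineage (defaults 50, 1).
#' @param fitness_sd Per-mutation fitness-effect standard deviation; `NULL`
#'   derives it from `scaled_bgc` as above.
#' @param seed RNG seed applied at the start of every replicate run.
#' @return A list of class `bgc_sim_config`.
#' @export
bgc_sim_config <- function(N = 10000L, scaled_bgc = 1.3, theta_locus = 21,
                           bgc_mut_ratio = NULL,
                           L = 2000L, burnin = 40, split_time = 6.5,
                           n_human = 50L, n_chimp = 1L, fitness_sd = NULL,
                           seed = NULL) {
  if (N < 2L) stop("N must be >= 2")
  if (scaled_bgc < 0) stop("scaled_bgc must be nonnegative")
  if (split_time <= 0) stop("split_time must be positive")
  if (!is.null(bgc_mut_ratio)) theta_locus <- scaled_bgc / bgc_mut_ratio
  if (theta_locus < 0) stop("theta_locus must be nonnegative")
  structure(list(N = as.integer(N), scaled_bgc = scaled_bgc,
                 bgc_mut_ratio = bgc_mut_ratio,
                 theta_locus = theta_locus,
                 L = as.integer(L), burnin = burnin, split_time = split_time,
                 n_human = as.integer(n_human), n_chimp = as.integer(n_chimp),
                 fitness_sd = fitness_sd, seed = seed),
            class = "bgc_sim_config")
}

#' Run one forward BGC replicate and its downstream tests
#'
#' Runs the forward simulation, extracts segregating sites among the human
#' sample and sample-level fixed differences between the human sample and the
#' single chimp chromosome, classifies both as W2S/S2W, and applies the MWU
#' and MK tests.
#'
#' Polarization: segregating sites are polarized by the chimp sample's allele
#' (always one of the two alleles at a biallelic site); fixed differences are
#' polarized by the population-majority state recorded at the split.
#'
#' @param cfg A [bgc_sim_config].  If `cfg$theta_locus` is 0 the replicate
#'   is degenerate.
#' @return Object of class `bgc_replicate`: list with `mwu` ([mwu_test]),
#'   `mk` ([mk_test]), `segregating` (site data frame with `klass`),
#'   `fixed_counts`, `seg_counts`, `gc_content`.
#' @export
run_bgc_replicate <- function(cfg) {
  stopifnot(inherits(cfg, "bgc_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sim <- .bgc_forward_cpp(cfg$N, cfg$theta_locus, cfg$scaled_bgc, cfg$L,
                          cfg$burnin, cfg$split_time, cfg$n_human,
                          cfg$n_chimp, ifelse(is.null(cfg$fitness_sd), -1,
                                              cfg$fitness_sd))
  nh <- sim$n_human
  hs <- sim$human_strong
  cs <- sim$chimp_strong  # 0..n_chimp
  chimp_allele <- as.integer(cs > sim$n_chimp / 2)  # n_chimp = 1 in practice
  poly <- hs > 0L & hs < nh
  # --- segregating sites: ancestral = chimp allele, derived = other state
  seg_derived_strong <- 1L - chimp_allele[poly]
  seg_k <- ifelse(seg_derived_strong == 1L, hs[poly], nh - hs[poly])
  seg <- data.frame(pos = sim$site[poly],
                    k = as.integer(seg_k), n = nh,
                    klass = ifelse(seg_derived_strong == 1L, "W2S", "S2W"))
  seg <- seg[seg$k >= 1 & seg$k <= nh - 1, , drop = FALSE]
  # --- fixed differences: human sample monomorphic and != chimp allele
  mono <- !poly
  human_allele <- as.integer(hs[mono] == nh)
  fixed_sel <- human_allele != chimp_allele[mono]
  anc <- sim$split_state[mono][fixed_sel]
  hum <- human_allele[fixed_sel]
  chi <- chimp_allele[mono][fixed_sel]
  changed <- ifelse(hum != anc, hum, chi)
  fixed_klass <- ifelse(anc == 0L & changed == 1L, "W2S",
                        ifelse(anc == 1L & changed == 0L, "S2W", "OTHER"))
  fixed_counts <- c(W2S = sum(fixed_klass == "W2S"),
                    S2W = sum(fixed_klass == "S2W"))
  seg_counts <- c(W2S = sum(seg$klass == "W2S"),
                  S2W = sum(seg$klass == "S2W"))
  mwu <- mwu_test(seg[seg$klass == "W2S", , drop = FALSE],
                  seg[seg$klass == "S2W", , drop = FALSE],
                  norm_n = nh)
  mk <- mk_test(fixed_counts, seg_counts)
  structure(list(mwu = mwu, mk = mk, segregating = seg,
                 fixed_counts = fixed_counts, seg_counts = seg_counts,
                 gc_content = sim$gc_content),
            class = "bgc_replicate")
}

#' Run a batch of forward BGC replicates and summarize test outcomes
#'
#' Tallies per-replicate MWU/MK significance and direction, the union and
#' intersection of W2S-significant replicates, and the Fisher association
#' between the two tests' significance flags.
#'
#' @param cfg A [bgc_sim_config]; its `seed` seeds the whole batch.
#' @param n_reps Number of replicates.
#' @param alpha Significance threshold (default 0.05).
#' @return Object of class `bgc_experiment`: list with `n_reps`, counts
#'   (`mwu_sig_w2s`, `mwu_sig_s2w`, `mk_sig_w2s`, `mk_sig_s2w`, `union_w2s`,
#'   `intersection_w2s`), `association` ([association_tests] output), and
#'   the per-replicate `flags` data frame.
#' @export
run_bgc_experiment <- function(cfg, n_reps, alpha = 0.05) {
  stopifnot(inherits(cfg, "bgc_sim_config"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_rep <- cfg
  cfg_rep$seed <- NULL  # one RNG stream across the batch
  flags <- data.frame(mwu_p = numeric(n_reps), mwu_dir = character(n_reps),
                      mk_p = numeric(n_reps), mk_dir = character(n_reps))
  for (r in seq_len(n_reps)) {
    rep <- run_bgc_replicate(cfg_rep)
    flags$mwu_p[r] <- rep$mwu$p
    flags$mwu_dir[r] <- if (is.na(rep$mwu$offset22)) NA_character_ else
      if (rep$mwu$offset22 > 0) "W2S" else if (rep$mwu$offset22 < 0) "S2W" else NA_character_
    flags$mk_p[r] <- rep$mk$p
    flags$mk_dir[r] <- rep$mk$direction
  }
  sig <- function(p) !is.na(p) & p <= alpha
  mwu_w2s <- sig(flags$mwu_p) & !is.na(flags$mwu_dir) & flags$mwu_dir == "W2S"
  mwu_s2w <- sig(flags$mwu_p) & !is.na(flags$mwu_dir) & flags$mwu_dir == "S2W"
  mk_w2s <- sig(flags$mk_p) & !is.na(flags$mk_dir) & flags$mk_dir == "W2S"
  mk_s2w <- sig(flags$mk_p) & !is.na(flags$mk_dir) & flags$mk_dir == "S2W"
  structure(list(n_reps = n_reps, alpha = alpha,
                 mwu_sig_w2s = sum(mwu_w2s), mwu_sig_s2w = sum(mwu_s2w),
                 mk_sig_w2s = sum(mk_w2s), mk_sig_s2w = sum(mk_s2w),
                 union_w2s = sum(mwu_w2s | mk_w2s),
                 intersection_w2s = sum(mwu_w2s & mk_w2s),
                 association = association_tests(mwu_w2s, mk_w2s),
                 flags = flags),
            class = "bgc_experiment")
}

#' @export
print.bgc_experiment <- function(x, ...) {
  cat(sprintf(paste0("BGC experiment, %d replicates (alpha = %g):\n",
                     "  MWU significant: %d W2S, %d S2W\n",
                     "  MK  significant: %d W2S, %d S2W\n",
                     "  union (W2S) = %d, intersection (W2S) = %d, Fisher p = %.3g\n"),
              x$n_reps, x$alpha, x$mwu_sig_w2s, x$mwu_sig_s2w,
              x$mk_sig_w2s, x$mk_sig_s2w, x$union_w2s, x$intersection_w2s,
              x$association$fisher_p))
  invisible(x)
}

#' Single-mutant fixation trials under genic selection
#'
#' Repeated single-site Wright-Fisher trajectories starting from one mutant
#' copy with haplotype fitness `1 + s`, counting fixations.  The diffusion
#' prediction is `(1 - exp(-2s)) / (1 - exp(-4Ns))`.
#'
#' @param N Diploid population size.
#' @param s Haplotype selection coefficient of the mutant.
#' @param n_trials Number of trials.
#' @return List with `fixed`, `n_trials`, `p_fix`, `diffusion` (the
#'   predicted probability).
#' @export
wf_fixation_probability <- function(N, s, n_trials) {
  fixed <- .wf_fixation_cpp(as.integer(N), s, as.integer(n_trials))
  diffusion <- if (s == 0) 1 / (2 * N) else (1 - exp(-2 * s)) / (1 - exp(-4 * N * s))
  list(fixed = fixed, n_trials = n_trials, p_fix = fixed / n_trials,
       diffusion = diffusion)
}
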