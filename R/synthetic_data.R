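# Synthetic study generator: region sets, probe-coverage masks, site and
# fixed-difference tables, and background spectra with the statistical shape
# of a targeted-resequencing study of accelerated-region neighborhoods.
# All emitted data are synthetic; nothing is derived from real samples.

#' Template describing the shape of a synthetic resequencing study
#'
#' Defaults emulate the scale of a targeted study of 49 accelerated-region
#' neighborhoods and 13 control regions: 40 kb regions, 22 sampled
#' chromosomes, about 101 segregating sites and 335 fixed differences per
#' region, a W2S:S2W segregating ratio of 2057:2114, and probe coverage
#' fractions between 0.65 and 0.98 with median about 0.88.
#'
#' @param n_target_regions,n_control_regions Region counts (defaults 49, 13).
#' @param region_length Region length in bp (default 40000).
#' @param n_chromosomes Sampled chromosomes (default 22).
#' @param mean_segregating,mean_fixed Per-region Poisson means
#'   (defaults 101, 335).
#' @param w2s_seg_ratio Probability a segregating site is W2S
#'   (default 2057 / (2057 + 2114)).
#' @param coverage_range Range of per-region covered fractions
#'   (default c(0.65, 0.98)).
#' @param bias_w2s_shift Per-target-region frequency shift injected into W2S
#'   sites (scalar recycled; 0 = unbiased).
#' @param bias_fixed_enrichment Multiplier on the odds that a fixed
#'   difference is W2S in target regions (1 = unbiased).
#' @param seed Seed fixed at the start of generation.
#' @return A list of class `study_template`.
#' @export
study_template <- function(n_target_regions = 49L, n_control_regions = 13L,
                           region_length = 40000L, n_chromosomes = 22L,
                           mean_segregating = 101, mean_fixed = 335,
                           w2s_seg_ratio = 2057 / (2057 + 2114),
                           coverage_range = c(0.65, 0.98),
                           bias_w2s_shift = 0, bias_fixed_enrichment = 1,
                           seed = 1L) {
  stopifnot(n_target_regions >= 1, region_length > 0, n_chromosomes >= 2,
            mean_segregating > 0, mean_fixed > 0,
            all(coverage_range > 0), all(coverage_range <= 1))
  structure(as.list(environment()), class = "study_template")
}

# Alternating covered/uncovered runs with geometric lengths tuned to hit a
# target covered fraction; covered runs average `mean_run` bp.
draw_coverage_mask <- function(L, fraction, mean_run = 2000) {
  if (fraction >= 1) return(cbind(0, L))
  mean_gap <- mean_run * (1 - fraction) / fraction
  pos <- 0
  covered <- runif(1) < fraction
  runs <- list()
  while (pos < L) {
    len <- ceiling(rexp(1, 1 / if (covered) mean_run else mean_gap))
    end <- min(L, pos + len)
    if (covered) runs[[length(runs) + 1L]] <- c(pos, end)
    pos <- end
    covered <- !covered
  }
  if (!length(runs)) return(cbind(0, L))
  do.call(rbind, runs)
}

#' Shift W2S site frequencies upward (positive control injection)
#'
#' Resamples the derived-allele counts of W2S sites from a distribution
#' stochastically larger by roughly `shift` in frequency (a Poisson
#' increment of mean `shift * n`, capped at `n - 1`), leaving S2W and OTHER
#' sites untouched.
#'
#' @param sites Site data frame with `k`, `n`, `klass`.
#' @param shift Target frequency offset in `[0, 1)`.
#' @return `sites` with updated `k` for the W2S class.
#' @export
inject_w2s_shift <- function(sites, shift) {
  if (shift < 0 || shift >= 1) stop("shift must be in [0, 1)")
  if (shift == 0) return(sites)
  sel <- sites$klass == "W2S"
  if (!any(sel)) return(sites)
  k <- sites$k[sel]
  n <- sites$n[sel]
  inc <- rpois(length(k), shift * n)
  sites$k[sel] <- pmin(n - 1L, k + inc)
  sites
}

#' Generate a full synthetic study
#'
#' Produces regions with probe-coverage masks, filtered segregating-site
#' tables, fixed-difference tables, and a pooled background spectrum, all
#' with the statistical shape described by the template.  Segregating sites
#' come from the neutral coalescent simulator (with the template's W2S
#' frequency shift injected in target regions when requested); fixed
#' differences come from the phylogenetic substitution simulator, with the
#' template's per-region class enrichment applied by reweighted resampling.
#'
#' @param template A [study_template].
#' @param out_dir Optional directory; when given, all files are written in
#'   the package's standard dialects (regions.bed, covered.bed, sites.tsv,
#'   fixed.tsv, background_sfs.txt).
#' @return List of class `synthetic_study` with `regions` (named list),
#'   `sites`, `fixed` (data frames with region_id), `background`
#'   ([background_sfs]), and `template`.
#' @export
generate_study <- function(template = study_template(), out_dir = NULL) {
  stopifnot(inherits(template, "study_template"))
  set.seed(template$seed)
  t <- template
  ids <- c(sprintf("target%02d", seq_len(t$n_target_regions)),
           sprintf("control%02d", seq_len(t$n_control_regions)))
  is_target <- c(rep(TRUE, t$n_target_regions), rep(FALSE, t$n_control_regions))
  shift <- rep_len(t$bias_w2s_shift, t$n_target_regions)
  regions <- list()
  sites_all <- list()
  fixed_all <- list()
  for (i in seq_along(ids)) {
    start <- (i - 1) * (t$region_length + 10000)
    frac <- runif(1, t$coverage_range[1], t$coverage_range[2])
    mask <- draw_coverage_mask(t$region_length, frac)
    reg <- region(ids[i], "chrS", start, start + t$region_length,
                  covered = mask + start)
    regions[[ids[i]]] <- reg
    S <- rpois(1, t$mean_segregating)
    sites <- simulate_neutral_region(n = t$n_chromosomes, S = S,
                                     L = t$region_length, mask = mask)
    sites$pos <- sites$pos + start
    sites <- label_mutation_classes(sites, t$w2s_seg_ratio)
    if (is_target[i] && shift[min(i, length(shift))] > 0) {
      sites <- inject_w2s_shift(sites, shift[min(i, length(shift))])
    }
    sites$region_id <- ids[i]
    sites$chrom <- "chrS"
    sites_all[[i]] <- sites
    nf <- rpois(1, t$mean_fixed)
    fx <- simulate_fixed_differences(nf)$table
    if (is_target[i] && t$bias_fixed_enrichment != 1) {
      fx <- enrich_fixed_classes(fx, t$bias_fixed_enrichment)
    }
    # place fixed differences uniformly in the covered mask
    widths <- mask[, 2] - mask[, 1]
    iv <- sample.int(nrow(mask), nrow(fx), replace = TRUE, prob = widths)
    fx$pos <- floor(mask[iv, 1] + runif(nrow(fx)) * widths[iv]) + start
    fx$region_id <- ids[i]
    fx$chrom <- "chrS"
    fixed_all[[i]] <- fx
  }
  sites <- do.call(rbind, sites_all)
  fixed <- do.call(rbind, fixed_all)
  rownames(sites) <- rownames(fixed) <- NULL
  background <- estimate_background(sites, t$n_chromosomes)
  out <- structure(list(regions = regions, sites = sites, fixed = fixed,
                        background = background, template = template),
                   class = "synthetic_study")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

# Reweighted resampling of fixed-difference classes: multiplies the W2S odds
# by `enrichment`, preserving the total count.
enrich_fixed_classes <- function(fx, enrichment) {
  counts <- table(factor(fx$klass, levels = c("W2S", "S2W", "OTHER")))
  w <- counts
  w["W2S"] <- w["W2S"] * enrichment
  if (sum(w) == 0) return(fx)
  new_klass <- sample(names(w), nrow(fx), replace = TRUE, prob = as.numeric(w))
  pool <- split(seq_len(nrow(fx)), fx$klass)
  rows <- vapply(new_klass, function(kl) {
    cand <- pool[[kl]]
    if (is.null(cand) || !length(cand)) NA_integer_ else sample(cand, 1L)
  }, integer(1))
  rows[is.na(rows)] <- seq_len(nrow(fx))[is.na(rows)]
  out <- fx[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a synthetic study to disk in the standard dialects
#' @param study A `synthetic_study`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(regions = file.path(out_dir, "regions.bed"),
             covered = file.path(out_dir, "covered.bed"),
             sites = file.path(out_dir, "sites.tsv"),
             fixed = file.path(out_dir, "fixed.tsv"),
             background = file.path(out_dir, "background_sfs.txt"))
  write_regions_bed(study$regions, paths["regions"], paths["covered"])
  write_sites(study$sites, paths["sites"])
  write_fixed(study$fixed, paths["fixed"])
  write_spectrum(daf_spectrum(study$background$probs, study$background$n),
                 paths["background"])
  invisible(paths)
}

#' Read a synthetic study back from disk
#' @param dir Directory written by [write_study].
#' @return List with `regions`, `sites`, `fixed`, `background`.
#' @export
read_study <- function(dir) {
  spec <- read_spectrum(file.path(dir, "background_sfs.txt"))
  list(regions = read_regions_bed(file.path(dir, "regions.bed"),
                                  file.path(dir, "covered.bed")),
       sites = read_sites(file.path(dir, "sites.tsv")),
       fixed = read_fixed(file.path(dir, "fixed.tsv")),
       background = background_sfs(spec$counts, spec$n))
}
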