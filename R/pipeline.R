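# End-to-end orchestration: filters -> per-region tests -> mask scans ->
# pooled tests -> CLR scans with p-values -> association statistics ->
# detectable-sweeps estimate.  The pipeline adds no computation of its own;
# every number in the report bundle comes from the module functions.

#' Configuration for a full analysis run
#'
#' @param regions_bed,covered_bed,sites_tsv,fixed_tsv,background_sfs Input
#'   paths in the package dialects ([read_regions_bed], [read_sites],
#'   [read_fixed], [read_spectrum]).  `covered_bed`, `fixed_tsv`, and
#'   `background_sfs` may be `NULL`; dependent stages are then skipped with
#'   a logged warning.
#' @param alpha Significance threshold (default 0.05).
#' @param mask_scans,pooled,sweep_scan Stage toggles.
#' @param bonferroni Also report Bonferroni-adjusted p columns?
#' @param sweep_reps Null replicates per region for sweep p-values.
#' @param sweep_grid Grid size for the observed CLR scans.
#' @param rho Region-scaled recombination rate for the null replicates.
#' @param detectable_sweeps Optional list(human_subs, chimp_subs, divergence,
#'   window) echoed through [estimate_detectable_sweeps].
#' @param annotations Optional TSV with a region_id column; its columns are
#'   echoed into the reports (never computed).
#' @param seed Seed fixed at the start of the run.
#' @param out_dir Report directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(regions_bed, sites_tsv, covered_bed = NULL,
                       fixed_tsv = NULL, background_sfs = NULL,
                       alpha = 0.05, mask_scans = TRUE, pooled = TRUE,
                       sweep_scan = TRUE, bonferroni = FALSE,
                       sweep_reps = 200L, sweep_grid = 200L, rho = 0,
                       detectable_sweeps = NULL, annotations = NULL,
                       seed = 1L, out_dir = "bgcscan-report") {
  for (p in c(regions_bed, sites_tsv, covered_bed, fixed_tsv, background_sfs,
              annotations)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(as.list(environment())[setdiff(ls(), "p")], class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  # hash the analysis parameters, not where the report lands
  keep <- sort(setdiff(names(cfg), "out_dir"))
  dput(cfg[keep], file = f)
  unname(tools::md5sum(f))
}

provenance_header <- function(cfg) {
  sprintf("# bgcscan %s seed=%d config=%s",
          as.character(utils::packageVersion("bgcscan")), cfg$seed,
          config_hash(cfg))
}

write_report <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(cfg), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the full bias-test and sweep-scan analysis
#'
#' Executes the whole analysis flow on the configured inputs and writes a
#' TSV report bundle to `cfg$out_dir`: `mwu_report.tsv` and `mk_report.tsv`
#' (per-region tests with central-mask and sliding-mask p-values),
#' `sweep_report.tsv` (per-region max CLR, argmax, p), `pooled_report.tsv`,
#' `association_report.tsv`, and `run.log`.  Every table begins with a
#' provenance header line (version, seed, config hash).
#'
#' @param cfg A [run_config].
#' @return Invisibly, a list with the report data frames and paths.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_msg <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  regions <- read_regions_bed(cfg$regions_bed, cfg$covered_bed)
  sites <- read_sites(cfg$sites_tsv)
  log_msg("loaded %d regions, %d segregating sites", length(regions),
          nrow(sites))
  fixed <- NULL
  if (!is.null(cfg$fixed_tsv)) {
    fixed <- read_fixed(cfg$fixed_tsv)
    log_msg("loaded %d fixed differences", nrow(fixed))
  } else {
    log_msg("WARNING: no fixed-difference table; MK stages skipped")
  }
  ann <- NULL
  if (!is.null(cfg$annotations)) {
    ann <- read.table(cfg$annotations, sep = "\t", header = TRUE,
                      colClasses = list(region_id = "character"))
  }
  adj <- function(p, n) if (cfg$bonferroni) pmin(1, p * n) else NULL

  mask_cols <- function(ms) {
    out <- as.list(ms$central)
    names(out) <- paste0("mask", names(ms$central))
    out$mask5kbHi <- ms$sliding_max
    out
  }

  mwu_rows <- list()
  mk_rows <- list()
  for (id in names(regions)) {
    reg <- regions[[id]]
    s <- sites[sites$region_id == id, , drop = FALSE]
    mwu <- mwu_test(s[s$klass == "W2S", , drop = FALSE],
                    s[s$klass == "S2W", , drop = FALSE])
    row <- data.frame(region = id, n_w2s = mwu$n_w2s, n_s2w = mwu$n_s2w,
                      offset = mwu$offset22, p = mwu$p)
    if (cfg$mask_scans && !is.na(mwu$p)) {
      row <- cbind(row, mask_cols(mask_scan(reg, s, test = "MWU")))
    }
    mwu_rows[[id]] <- row
    if (!is.null(fixed)) {
      f <- fixed[fixed$region_id == id, , drop = FALSE]
      mk <- mk_test(f, s)
      frow <- data.frame(region = id,
                         fixed_w2s = mk$table["fixed", "W2S"],
                         fixed_s2w = mk$table["fixed", "S2W"],
                         seg_w2s = mk$table["segregating", "W2S"],
                         seg_s2w = mk$table["segregating", "S2W"],
                         direction = ifelse(is.na(mk$direction), NA,
                                            mk$direction),
                         p = mk$p)
      if (cfg$mask_scans && !is.na(mk$p)) {
        frow <- cbind(frow, mask_cols(mask_scan(reg, s, fixed = f, test = "MK")))
      }
      mk_rows[[id]] <- frow
    }
  }
  bind_ragged <- function(rows) {
    cols <- unique(unlist(lapply(rows, names)))
    do.call(rbind, lapply(rows, function(r) {
      for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
      r[, cols, drop = FALSE]
    }))
  }
  mwu_report <- bind_ragged(mwu_rows)
  if (cfg$bonferroni) mwu_report$p_bonferroni <- adj(mwu_report$p, nrow(mwu_report))
  if (!is.null(ann)) mwu_report <- merge(mwu_report, ann, by.x = "region",
                                         by.y = "region_id", all.x = TRUE,
                                         sort = FALSE)
  reports <- list(mwu = mwu_report)
  mk_report <- NULL
  if (length(mk_rows)) {
    mk_report <- bind_ragged(mk_rows)
    if (cfg$bonferroni) mk_report$p_bonferroni <- adj(mk_report$p, nrow(mk_report))
    reports$mk <- mk_report
  }

  if (cfg$pooled) {
    per_region <- lapply(names(regions), function(id) {
      list(sites = sites[sites$region_id == id, , drop = FALSE],
           fixed = if (is.null(fixed)) NULL else
             fixed[fixed$region_id == id, , drop = FALSE])
    })
    pl <- pooled_tests(per_region)
    pooled_report <- data.frame(
      test = c("MWU", if (!is.null(pl$mk)) "MK"),
      p = c(pl$mwu$p, if (!is.null(pl$mk)) pl$mk$p),
      offset_or_direction = c(format(pl$mwu$offset22),
                              if (!is.null(pl$mk)) pl$mk$direction))
    reports$pooled <- pooled_report
    log_msg("pooled MWU p = %.4g%s", pl$mwu$p,
            if (!is.null(pl$mk)) sprintf(", pooled MK p = %.4g", pl$mk$p) else "")
  }

  if (cfg$sweep_scan && !is.null(cfg$background_sfs)) {
    bgspec <- read_spectrum(cfg$background_sfs)
    sweep_rows <- list()
    for (id in names(regions)) {
      reg <- regions[[id]]
      s <- sites[sites$region_id == id, , drop = FALSE]
      s <- s[in_covered(reg, s$pos), , drop = FALSE]
      if (nrow(s) < 1) {
        log_msg("WARNING: region %s has no usable sites; sweep scan skipped", id)
        next
      }
      n_common <- min(s$n)
      bg <- background_sfs(project_spectrum(bgspec, n_common,
                                            normalize = TRUE)$counts, n_common)
      if (any(s$n > n_common)) {
        log_msg("region %s: %d site(s) above common n projected out", id,
                sum(s$n > n_common))
        s <- s[s$n == n_common, , drop = FALSE]
      }
      sc <- clr_scan(s, reg, bg, grid_size = cfg$sweep_grid)
      sc <- sweep_pvalue(sc, reg, observed_S = nrow(s), bg = bg,
                         rho = cfg$rho, n_reps = cfg$sweep_reps,
                         grid_size = cfg$sweep_grid)
      sweep_rows[[id]] <- data.frame(region = id, n_sites = nrow(s),
                                     max_clr = sc$max_clr, argmax = sc$argmax,
                                     p = sc$p)
    }
    if (length(sweep_rows)) {
      sweep_report <- do.call(rbind, sweep_rows)
      if (cfg$bonferroni) {
        sweep_report$p_bonferroni <- adj(sweep_report$p, nrow(sweep_report))
      }
      reports$sweep <- sweep_report
    }
  } else if (cfg$sweep_scan) {
    log_msg("WARNING: no background spectrum; sweep scan skipped")
  }

  if (!is.null(mk_report)) {
    assoc <- association_tests(
      !is.na(mwu_report$p) & mwu_report$p <= cfg$alpha,
      !is.na(mk_report$p[match(mwu_report$region, mk_report$region)]) &
        mk_report$p[match(mwu_report$region, mk_report$region)] <= cfg$alpha)
    reports$association <- data.frame(
      both = assoc$table[1, 1], mwu_only = assoc$table[1, 2],
      mk_only = assoc$table[2, 1], neither = assoc$table[2, 2],
      fisher_p = assoc$fisher_p)
    log_msg("MWUxMK association Fisher p = %.4g", assoc$fisher_p)
  }

  if (!is.null(cfg$detectable_sweeps)) {
    ds <- do.call(estimate_detectable_sweeps, cfg$detectable_sweeps)
    reports$detectable <- data.frame(adaptive_bound = ds$adaptive_bound,
                                     detectable = ds$detectable)
    log_msg("detectable sweeps estimate: %.3g (bound %d)", ds$detectable,
            ds$adaptive_bound)
  }

  paths <- character()
  for (nm in names(reports)) {
    p <- file.path(cfg$out_dir, paste0(nm, "_report.tsv"))
    write_report(reports[[nm]], p, cfg)
    paths[nm] <- p
  }
  writeLines(c(provenance_header(cfg), log_lines),
             file.path(cfg$out_dir, "run.log"))
  invisible(list(reports = reports, paths = paths))
}
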