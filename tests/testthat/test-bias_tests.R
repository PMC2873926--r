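# Site/fixed-difference cleaning filters, the MWU and MK fixation-bias
# tests, masking scans, association statistics, and the small auxiliary
# tests.

test_that("segregating-site filter applies the cleaning rules", {
  raw <- data.frame(
    pos = 1:6,
    ref = c("A", "A", "A", "A", "A", "A"),
    ancestral = c("A", "A", "A", NA, "a", "A"),
    alleles = c("A,G", "A,G", "G,T", "A,G", "A,G", "A,G"),
    counts = c("10,12", "3,4", "5,5", "10,12", "10,12", "21,1"),
    n = c(22, 7, 10, 22, 22, 22)
  )
  out <- filter_segregating_sites(raw)
  # kept: row 1 (clean), row 5 (lowercase ancestral retained), row 6
  expect_equal(out$pos, c(1, 5, 6))
  expect_equal(out$klass, c("W2S", "W2S", "W2S"))
  expect_true(out$anc_uncertain[out$pos == 5])
  expect_false(out$anc_uncertain[out$pos == 1])
  # row 2 dropped for n < 8; row 3 for >2 alleles; row 4 undetermined
  expect_false(any(out$pos %in% c(2, 3, 4)))
  expect_equal(out$k[out$pos == 6], 1L)  # derived = G with count 1
})

test_that("fixed-difference cleaning removes segregating, cataloged, and uncallable sites", {
  cand <- data.frame(pos = 1:6,
                     human = c("G", "G", "G", "G", "G", "C"),
                     chimp = c("A", "A", "A", "A", "A", "T"),
                     ancestral = c("A", "A", "A", NA, "A", "T"))
  fds <- clean_fixed_differences(cand, segregating_pos = 2,
                                 snp_catalog_pos = 3,
                                 callable = cbind(0, 6))  # pos 6 uncallable
  expect_equal(fds$table$pos, c(1, 5))
  expect_equal(unname(fds$counts["W2S"]), 2L)
  expect_equal(fds$removed_fraction, 4 / 6)
  # empty exclusion sets, all callable: counts preserved
  fds2 <- clean_fixed_differences(cand[c(1, 2, 6), ])
  expect_equal(fds2$n_kept, 3L)
  expect_equal(unname(fds2$counts["W2S"]), 3L)  # A->G twice, T->C once
  expect_equal(fds2$table$lineage[3], "human")  # C vs ancestral T
})

test_that("MWU test: identity, symmetry, extreme case, and absence", {
  same <- mwu_test(c(.1, .3, .5), c(.1, .3, .5))
  expect_equal(same$offset22, 0)
  expect_equal(same$p, 1)

  x <- rep(21 / 22, 5); y <- rep(1 / 22, 5)
  ex <- mwu_test(x, y, exact = "enumerate")
  expect_equal(ex$p, 2 / 252)  # doubled tail of the single extreme assignment
  expect_equal(ex$offset22, 20)

  a <- c(.1, .4, .6); b <- c(.2, .3, .9)
  fwd <- mwu_test(a, b); rev <- mwu_test(b, a)
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$offset22, -rev$offset22)

  absent <- mwu_test(numeric(), c(.1, .2))
  expect_true(is.na(absent$p))
  expect_equal(absent$n_w2s, 0L)
  expect_equal(absent$n_s2w, 2L)
})

test_that("MWU exact p agrees with full rank enumeration on tie-free data", {
  set.seed(21)
  for (m in c(3, 5)) for (nn in c(4, 6)) {
    x <- runif(m); y <- runif(nn)
    expect_equal(mwu_test(x, y)$p, oracle_mwu_p(x, y), tolerance = 1e-12)
  }
})

test_that("Fisher exact p matches published values and the enumeration oracle", {
  expect_equal(round(fisher_exact_2x2(1, 10, 10, 28), 2), 0.42)
  expect_equal(round(fisher_exact_2x2(12, 39, 118, 330), 2), 0.74)
  expect_equal(fisher_exact_2x2(2, 4, 3, 6), 1)  # proportional rows
  expect_error(fisher_exact_2x2(-1, 2, 3, 4))
  set.seed(31)
  for (rep in 1:20) {
    cells <- as.vector(rmultinom(1, sample(5:40, 1), runif(4, .1, 1)))
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
                 oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-7)
  }
})

test_that("MK test: direction, symmetry, and absence", {
  none <- mk_test(c(W2S = 10, S2W = 10), c(W2S = 10, S2W = 10))
  expect_equal(none$p, 1)
  expect_true(is.na(none$direction))

  biased <- mk_test(c(W2S = 30, S2W = 10), c(W2S = 10, S2W = 30))
  expect_equal(biased$p, oracle_fisher_p(30, 10, 10, 30), tolerance = 1e-10)
  expect_equal(biased$direction, "W2S")

  flipped <- mk_test(c(W2S = 10, S2W = 30), c(W2S = 30, S2W = 10))
  expect_equal(flipped$direction, "S2W")
  expect_equal(flipped$p, biased$p)

  absent <- mk_test(c(W2S = 0, S2W = 0), c(W2S = 5, S2W = 5))
  expect_true(is.na(absent$p))
})

test_that("pooling one region reproduces the per-region result and doubles counts", {
  set.seed(12)
  sites <- data.frame(k = sample(1:21, 40, TRUE), n = 22,
                      klass = sample(c("W2S", "S2W"), 40, TRUE))
  fixed <- c(W2S = 30, S2W = 20)
  one <- pooled_tests(list(list(sites = sites, fixed = fixed)))
  direct <- mwu_test(sites[sites$klass == "W2S", ],
                     sites[sites$klass == "S2W", ])
  expect_equal(one$mwu$p, direct$p)
  expect_equal(one$mwu$offset22, direct$offset22)
  two <- pooled_tests(list(list(sites = sites, fixed = fixed),
                           list(sites = sites, fixed = fixed)))
  expect_equal(two$mk$table["fixed", ], 2 * one$mk$table["fixed", ])
  # doubling preserves the MK odds ratio (same direction)
  expect_equal(two$mk$direction, one$mk$direction)
})

test_that("mask scans: zero-width identity, emptied stratum, fifteen windows", {
  reg <- make_region_40kb()
  set.seed(14)
  sites <- data.frame(pos = sample(0:39999, 60), k = sample(1:21, 60, TRUE),
                      n = 22, klass = sample(c("W2S", "S2W"), 60, TRUE))
  fixed <- data.frame(pos = sample(0:39999, 80),
                      human = "G", chimp = "A",
                      ancestral = sample(c("A", "G"), 80, TRUE))
  fixed <- fixed[fixed$human != fixed$chimp, ]
  fixed <- bgcscan:::annotate_fixed(fixed)
  ms <- mask_scan(reg, sites, fixed, test = "MWU",
                  central_widths = c(0, 1000, 5000))
  unmasked <- mwu_test(sites[sites$klass == "W2S", ],
                       sites[sites$klass == "S2W", ])$p
  expect_equal(unname(ms$central["0"]), unmasked)
  expect_equal(ms$unmasked, unmasked)
  expect_equal(nrow(ms$sliding), 15L)

  msk <- mask_scan(reg, sites, fixed, test = "MK")
  expect_equal(nrow(msk$sliding), 15L)
  expect_true(all(is.na(msk$central) | msk$central >= 0))

  # all W2S sites inside the central 1 kb -> masking 1 kb empties the class
  ctr <- region_center(reg)
  toy <- data.frame(pos = c(ctr - 100, ctr + 100, 100, 39900),
                    k = c(5, 6, 7, 8), n = 22,
                    klass = c("W2S", "W2S", "S2W", "S2W"))
  mt <- mask_scan(reg, toy, test = "MWU", central_widths = 1000)
  expect_true(is.na(mt$central["1000"]))
})

test_that("association tests reproduce the published cross-tabulation p and edge cases", {
  mwu <- c(rep(TRUE, 11), rep(FALSE, 38))
  mk <- c(TRUE, rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 28))
  out <- association_tests(mwu, mk)
  expect_equal(out$table[1, 1], 1)
  expect_equal(round(out$fisher_p, 2), 0.42)

  allf <- association_tests(rep(FALSE, 20), rep(FALSE, 20))
  expect_equal(allf$fisher_p, 1)

  rates <- association_tests(rep(FALSE, 10), rep(FALSE, 10),
                             ref_rate_mwu = 0.3)
  expect_equal(rates$binomial_p_mwu, 1)  # 0 observed successes
  expect_error(association_tests(c(TRUE), c(TRUE, FALSE)))
})

test_that("HWE exact test matches enumeration of conditional heterozygote counts", {
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_equal(hwe_exact_test(5, 0, 0), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # larger case against direct enumeration
  nAA <- 3; nAa <- 2; naa <- 5
  nA <- 2 * nAA + nAa; na <- 2 * naa + nAa; n <- nAA + nAa + naa
  het <- seq(nA %% 2, min(nA, na), 2)
  pr <- vapply(het, function(h) {
    exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((na - h) / 2) + h * log(2) +
          lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  expected <- sum(pr[pr <= pr[het == nAa] * (1 + 1e-12)])
  expect_equal(hwe_exact_test(nAA, nAa, naa), expected, tolerance = 1e-12)
})

test_that("Poisson acceleration test matches closed forms and series summation", {
  expect_equal(poisson_acceleration_test(0, 2), 1)
  expect_equal(poisson_acceleration_test(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poisson_acceleration_test(10, 2), oracle_poisson_upper(10, 2),
               tolerance = 1e-12)
  expect_error(poisson_acceleration_test(3, 0))
})

test_that("detectable-sweeps estimate reproduces the published arithmetic", {
  ds <- estimate_detectable_sweeps(206, 16, 5e6, 2e5)
  expect_equal(ds$detectable, 7.6)
  expect_equal(ds$adaptive_bound, 190)
  expect_equal(estimate_detectable_sweeps(50, 50, 5e6, 2e5)$detectable, 0)
  expect_equal(estimate_detectable_sweeps(100, 40, 5e6, 5e6)$detectable, 60)
  expect_error(estimate_detectable_sweeps(10, 20, 5e6, 2e5))
  expect_error(estimate_detectable_sweeps(100, 10, 5e6, 6e6))
})
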