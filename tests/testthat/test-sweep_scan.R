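# Composite-likelihood-ratio sweep scan.

toy_background <- function(n) {
  w <- 1 / seq_len(n - 1)
  background_sfs(w / sum(w), n)
}

test_that("background estimation reduces larger-n sites via projection", {
  set.seed(41)
  sites22 <- data.frame(k = sample(1:21, 200, TRUE), n = 22)
  bg <- estimate_background(sites22, 22)
  expect_equal(sum(bg$probs), 1)
  emp <- tabulate(sites22$k, 21) / 200
  expect_equal(bg$probs, emp, tolerance = 1e-12)

  # n=47 spectrum reduced to n=21 equals the project_spectrum output
  sites47 <- data.frame(k = sample(1:46, 300, TRUE), n = 47)
  bg21 <- estimate_background(sites47, 21)
  spec47 <- daf_spectrum(tabulate(sites47$k, 46), 47)
  direct <- project_spectrum(spec47, 21, normalize = TRUE)
  expect_equal(bg21$probs, direct$counts, tolerance = 1e-10)

  expect_warning(estimate_background(rbind(sites22,
                                           data.frame(k = 3, n = 10)), 22))
})

test_that("estimate-then-project equals project-then-estimate", {
  set.seed(42)
  sites <- data.frame(k = sample(1:11, 150, TRUE), n = 12)
  route1 <- estimate_background(sites, 8)   # per-site projection
  spec <- build_spectrum(sites, 12)
  route2 <- background_sfs(project_spectrum(spec, 8, normalize = TRUE)$counts, 8)
  expect_equal(route1$probs, route2$probs, tolerance = 1e-10)
})

test_that("scan values match the brute-force escape-enumeration oracle", {
  set.seed(43)
  n <- 5
  bg <- toy_background(n)
  reg <- region("toy", "chr1", 0, 10000)
  sites <- data.frame(pos = c(500, 2600, 5100, 7600, 9500),
                      k = c(1, 4, 2, 1, 3), n = n)
  alphas <- 10^seq(-5, -2, length.out = 8)
  grid3 <- seq(0, 10000, length.out = 3)
  got <- clr_scan(sites, reg, bg, grid_size = 3, alpha_grid = alphas,
                  refine = FALSE)
  want <- oracle_clr(sites, bg$probs, n, grid3, alphas)
  expect_equal(got$clr, want, tolerance = 1e-8)
})

test_that("sweep kernel distributions are proper and hit the model limits", {
  n <- 6
  bg <- toy_background(n)
  K <- bgcscan:::sweep_kernel(bg)
  expect_true(all(abs(rowSums(K) - 1) < 1e-12))
  for (pe in c(0.05, 0.3, 0.9)) {
    want <- oracle_sweep_probs(bg$probs, n, pe)
    got <- as.numeric(dbinom(0:n, n, pe) %*% K)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # alpha -> Inf (pe = 1): model equals the background
  expect_equal(K[n + 1, 2:n], bg$probs, tolerance = 1e-12)
})

test_that("background-distributed data give CLR near zero and translation invariance", {
  set.seed(44)
  n <- 22
  bg <- toy_background(n)
  reg <- make_region_40kb()
  sites <- data.frame(pos = sort(sample(0:39999, 60)),
                      k = sample(1:21, 60, TRUE, prob = bg$probs), n = n)
  sc <- clr_scan(sites, reg, bg, grid_size = 21)
  expect_true(all(sc$clr >= 0))
  # translation invariance
  reg2 <- region("r2", "chr1", 1e6, 1e6 + 40000)
  sites2 <- transform(sites, pos = pos + 1e6)
  sc2 <- clr_scan(sites2, reg2, bg, grid_size = 21)
  expect_equal(sc$clr, sc2$clr, tolerance = 1e-9)
  expect_equal(sc$max_clr, sc2$max_clr, tolerance = 1e-9)
})

test_that("argmax concentrates near a simulated sweep and p is small", {
  set.seed(46)
  n <- 22
  bg <- toy_background(n)
  reg <- make_region_40kb()
  hits <- 0
  ps <- numeric(6)
  for (r in 1:6) {
    # crude complete sweep at the center: sites nearby are mostly
    # high-frequency derived or low-frequency (post-sweep recovery),
    # distant sites follow the background
    pos <- sort(sample(0:39999, 80))
    d <- abs(pos - 20000)
    near <- d < 6000
    k <- ifelse(near,
                ifelse(runif(80) < 0.5, n - 1, 1),
                sample(1:21, 80, TRUE, prob = bg$probs))
    sites <- data.frame(pos = pos, k = as.integer(k), n = n)
    sc <- clr_scan(sites, reg, bg, grid_size = 81)
    if (abs(sc$argmax - 20000) < 8000) hits <- hits + 1
    sc <- sweep_pvalue(sc, reg, observed_S = 80, bg = bg, n_reps = 39,
                       grid_size = 41)
    ps[r] <- sc$p
  }
  expect_gte(hits, 4)
  expect_true(mean(ps <= 0.05) > 0.5)
})

test_that("sweep p-values are deterministic under a fixed seed and 1 at max CLR 0", {
  set.seed(47)
  n <- 8
  bg <- toy_background(n)
  reg <- region("r", "chr1", 0, 5000)
  sites <- data.frame(pos = c(100, 2500, 4900), k = c(1, 2, 1), n = n)
  sc <- clr_scan(sites, reg, bg, grid_size = 11)
  set.seed(123)
  p1 <- sweep_pvalue(sc, reg, 3, bg, n_reps = 25, grid_size = 11)$p
  set.seed(123)
  p2 <- sweep_pvalue(sc, reg, 3, bg, n_reps = 25, grid_size = 11)$p
  expect_identical(p1, p2)
  sc0 <- sc
  sc0$max_clr <- 0
  set.seed(5)
  expect_equal(sweep_pvalue(sc0, reg, 3, bg, n_reps = 10, grid_size = 11)$p, 1)
})

test_that("scans reject mismatched sample sizes and uncovered sites", {
  bg <- toy_background(10)
  reg <- region("r", "chr1", 0, 1000, covered = cbind(0, 500))
  expect_error(clr_scan(data.frame(pos = 700, k = 2, n = 10), reg, bg,
                        grid_size = 5), "covered")
  expect_error(clr_scan(data.frame(pos = 100, k = 2, n = 12), reg, bg,
                        grid_size = 5), "match")
})
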