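# Core spectrum machinery: mutation classification, hypergeometric
# projection, folding, and classical summary statistics.

test_that("mutation classification follows the weak/strong partition", {
  expect_equal(classify_mutation("A", "G"), "W2S")
  expect_equal(classify_mutation("C", "T"), "S2W")
  expect_equal(classify_mutation("A", "T"), "OTHER")
  expect_equal(classify_mutation("G", "C"), "OTHER")
  expect_equal(classify_mutation(c("a", "t"), c("c", "g")),
               c("W2S", "W2S"))
  expect_error(classify_mutation("A", "A"))
  expect_error(classify_mutation("A", "N"))
})

test_that("classification is its own mirror under argument swap", {
  bases <- c("A", "C", "G", "T")
  for (anc in bases) for (der in setdiff(bases, anc)) {
    fwd <- classify_mutation(anc, der)
    rev <- classify_mutation(der, anc)
    expected <- switch(fwd, W2S = "S2W", S2W = "W2S", OTHER = "OTHER")
    expect_equal(rev, expected)
  }
})

test_that("projection matches exhaustive subsample enumeration", {
  # single-site identity and the k=1, n=4 -> m=2 worked case
  b <- build_spectrum(data.frame(k = 3, n = 22), 22)
  expect_equal(b$counts[3], 1)
  expect_equal(sum(b$counts), 1)
  expect_equal(sum(build_spectrum(data.frame(k = integer(), n = integer()),
                                  10)$counts), 0)
  b2 <- build_spectrum(data.frame(k = 1, n = 4), 2)
  # enumeration of C(4,2) draws: 3/6 contain the derived allele once,
  # renormalized over segregating draws -> weight 1
  expect_equal(b2$counts[1], 1)

  set.seed(101)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    m <- sample(2:(n - 1), 1)
    counts <- runif(n - 1, 0, 5)
    got <- project_spectrum(daf_spectrum(counts, n), m)
    expect_equal(got$counts, oracle_project(counts, n, m), tolerance = 1e-12)
    norm <- project_spectrum(daf_spectrum(counts, n), m, normalize = TRUE)
    expect_equal(sum(norm$counts), 1, tolerance = 1e-12)
  }
})

test_that("projection to the same size is the identity", {
  counts <- c(4, 2, 1, 0.5)
  expect_equal(project_spectrum(daf_spectrum(counts, 5), 5)$counts, counts)
})

test_that("projection errors outside 2 <= m <= n", {
  s <- daf_spectrum(rep(1, 9), 10)
  expect_error(project_spectrum(s, 1))
  expect_error(project_spectrum(s, 11))
  expect_error(build_spectrum(data.frame(k = 2, n = 6), 8))
})

test_that("projection composes and commutes with folding", {
  set.seed(77)
  for (rep in 1:4) {
    n <- 12
    counts <- runif(n - 1, 0, 3)
    s <- daf_spectrum(counts, n)
    # composition up to renormalization of discarded monomorphic mass
    p1 <- project_spectrum(project_spectrum(s, 9, normalize = TRUE), 5,
                           normalize = TRUE)
    p2 <- project_spectrum(s, 5, normalize = TRUE)
    expect_equal(p1$counts, p2$counts, tolerance = 1e-10)
    # fold(project) = project(fold) is only meaningful on the unfolded
    # side, so compare fold of two projection routes
    f1 <- fold_spectrum(project_spectrum(s, 6))
    f2 <- fold_spectrum(project_spectrum(project_spectrum(s, 9), 6))
    expect_equal(sum(f1$counts), sum(project_spectrum(s, 6)$counts))
    expect_equal(length(f1$counts), 3L)
    expect_equal(length(f2$counts), 3L)
  }
})

test_that("folding matches its definition and conserves mass", {
  f <- fold_spectrum(daf_spectrum(c(2, 5, 1), 4))
  expect_equal(f$counts, c(3, 5))
  expect_true(f$folded)
  set.seed(3)
  counts <- runif(10)
  f2 <- fold_spectrum(daf_spectrum(counts, 11))
  expect_equal(sum(f2$counts), sum(counts))
  # symmetric spectrum folds to double its lower half
  sym <- c(1, 2, 3, 2, 1)
  fs <- fold_spectrum(daf_spectrum(sym, 6))
  expect_equal(fs$counts, c(2, 4, 3))
})

test_that("summary statistics: closed form at n=2, absence at S=0, oracle at n=10", {
  s2 <- summary_stats(c(1, 1, 1), 2)
  expect_equal(s2$tajima_d, 0)
  expect_equal(s2$fay_wu_h, 0)
  expect_equal(s2$pi, s2$theta_w)

  s0 <- summary_stats(integer(), 10)
  expect_true(is.na(s0$tajima_d))
  expect_true(is.na(s0$fay_wu_h))
  expect_equal(s0$S, 0L)

  set.seed(9)
  k <- sample(1:9, 20, replace = TRUE)
  st <- summary_stats(k, 10, L = 1000)
  expect_equal(st$tajima_d, oracle_tajima_d(k, 10), tolerance = 1e-10)
  expect_equal(st$fay_wu_h, oracle_fay_wu_h(k, 10), tolerance = 1e-10)
  expect_equal(st$theta_w_site, st$theta_w / 1000)
  expect_error(summary_stats(k, 1))
})

test_that("spectrum containers validate their invariants", {
  expect_error(daf_spectrum(c(-1, 2), 3))
  expect_error(daf_spectrum(c(1, 2), 4))  # wrong length
  expect_error(build_spectrum(data.frame(k = 5, n = 5), 5))  # k = n
  expect_equal(spectrum_total(daf_spectrum(c(1, 2, 3), 4)), 6)
})
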