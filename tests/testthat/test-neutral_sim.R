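# Coalescent and phylogenetic neutral simulators.

test_that("fixed-S conditioning yields exactly S polymorphic sites", {
  set.seed(1)
  sim <- simulate_neutral_region(n = 22, S = 85)
  expect_equal(nrow(sim), 85L)
  expect_true(all(sim$k >= 1 & sim$k <= 21))
  expect_true(all(sim$n == 22))
  expect_equal(nrow(simulate_neutral_region(n = 10, S = 0)), 0L)
  expect_error(simulate_neutral_region(n = 10, S = 5, theta = 1))
  expect_error(simulate_neutral_region(n = 10))
})

test_that("n = 2 forces singletons and masks confine positions", {
  set.seed(2)
  sim <- simulate_neutral_region(n = 2, S = 30)
  expect_true(all(sim$k == 1))
  mask <- rbind(c(1000, 2000), c(30000, 31000))
  sm <- simulate_neutral_region(n = 22, S = 50, mask = mask)
  expect_true(all((sm$pos >= 1000 & sm$pos < 2000) |
                    (sm$pos >= 30000 & sm$pos < 31000)))
  expect_error(simulate_neutral_region(n = 5, S = 3,
                                       mask = cbind(numeric(), numeric())))
})

test_that("mean unfolded spectrum is proportional to 1/i", {
  set.seed(3)
  n <- 10; reps <- 3000
  tot <- numeric(n - 1)
  for (r in seq_len(reps)) {
    sim <- simulate_neutral_region(n = n, theta = 5, L = 1000)
    if (nrow(sim)) tot <- tot + tabulate(sim$k, n - 1)
  }
  expected <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  observed <- tot / sum(tot)
  se <- sqrt(expected * (1 - expected) / sum(tot))
  expect_true(all(abs(observed - expected) < 3.5 * se + 0.005))
  # theta-mode mean S near theta * a1
  a1 <- sum(1 / seq_len(n - 1))
  expect_equal(sum(tot) / reps, 5 * a1, tolerance = 0.1)
})

test_that("class labeling hits the requested W2S fraction", {
  set.seed(4)
  sites <- data.frame(pos = 1:10000, k = 1, n = 22)
  all_w <- label_mutation_classes(sites, 1)
  expect_true(all(all_w$klass == "W2S"))
  expect_true(all(classify_mutation(all_w$ancestral, all_w$derived) == "W2S"))
  all_s <- label_mutation_classes(sites, 0)
  expect_true(all(all_s$klass == "S2W"))
  frac <- 2057 / 4171
  lab <- label_mutation_classes(sites, frac)
  se <- sqrt(frac * (1 - frac) / 10000)
  expect_lt(abs(mean(lab$klass == "W2S") - frac), 3 * se)
})

test_that("phylogenetic simulator collects the requested fixed differences", {
  set.seed(5)
  fd <- simulate_fixed_differences(335)
  expect_equal(sum(fd$counts), 335L)
  expect_true(all(fd$table$human != fd$table$chimp))
  expect_true(all(fd$table$ancestral == fd$table$human |
                    fd$table$ancestral == fd$table$chimp))
  expect_error(simulate_fixed_differences(10, branch_human = 0,
                                          branch_chimp = 0))
})

test_that("symmetric model yields balanced W2S and S2W fixed differences", {
  set.seed(6)
  tot <- c(W2S = 0, S2W = 0)
  for (r in 1:20) {
    fd <- simulate_fixed_differences(200, eq_gc = 0.5)
    tot <- tot + fd$counts[c("W2S", "S2W")]
  }
  n <- sum(tot)
  se <- sqrt(0.25 / n)
  expect_lt(abs(tot["W2S"] / n - 0.5), 3 * se + 0.01)
})

test_that("calibration output is monotone and reproducible under a seed", {
  set.seed(7)
  cal <- calibrate_test("MWU", n_reps = 50)
  expect_true(all(diff(cal$table$frac_below) >= 0))
  expect_true(all(cal$table$frac_below_w2s <= cal$table$frac_below))
  set.seed(8)
  a <- calibrate_test("MK", n_reps = 10, n_fixed = 100, n_seg = 50)
  set.seed(8)
  b <- calibrate_test("MK", n_reps = 10, n_fixed = 100, n_seg = 50)
  expect_identical(a$p, b$p)
})

test_that("simulator output is bit-reproducible under a fixed seed", {
  set.seed(99)
  a <- simulate_neutral_region(n = 22, S = 40, rho = 3)
  set.seed(99)
  b <- simulate_neutral_region(n = 22, S = 40, rho = 3)
  expect_identical(a, b)
})
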