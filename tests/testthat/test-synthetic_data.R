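# Synthetic study generator.

small_template <- function(seed = 1, ...) {
  study_template(n_target_regions = 4L, n_control_regions = 2L,
                 mean_segregating = 40, mean_fixed = 60, seed = seed, ...)
}

test_that("generated studies have the templated shape", {
  st <- generate_study(small_template())
  expect_length(st$regions, 6L)
  expect_true(all(vapply(st$regions, region_length, integer(1)) == 40000L))
  expect_true(all(st$sites$n == 22L))
  expect_true(all(st$sites$k >= 1 & st$sites$k <= 21))
  fr <- vapply(st$regions, covered_fraction, numeric(1))
  expect_true(all(fr >= 0.5 & fr <= 1))
  per_region <- table(st$sites$region_id)
  expect_gt(mean(per_region), 20)
  expect_lt(mean(per_region), 60)
  # all sites fall inside their region's coverage mask
  for (id in names(st$regions)) {
    s <- st$sites[st$sites$region_id == id, ]
    expect_true(all(in_covered(st$regions[[id]], s$pos)))
  }
  expect_s3_class(st$background, "background_sfs")
  expect_equal(sum(st$background$probs), 1, tolerance = 1e-12)
})

test_that("same seed produces byte-identical files", {
  d1 <- file.path(tempdir(), "synth1")
  d2 <- file.path(tempdir(), "synth2")
  generate_study(small_template(seed = 5), out_dir = d1)
  generate_study(small_template(seed = 5), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("emitted files round-trip through the readers", {
  d <- file.path(tempdir(), "synth-rt")
  st <- generate_study(small_template(seed = 9), out_dir = d)
  back <- read_study(d)
  expect_equal(names(back$regions), names(st$regions))
  expect_equal(back$sites$k, st$sites$k)
  expect_equal(back$sites$klass, st$sites$klass)
  expect_equal(nrow(back$fixed), nrow(st$fixed))
  expect_equal(back$background$probs, st$background$probs, tolerance = 1e-12)
})

test_that("injected W2S shift raises the MWU offset; relabeling destroys it", {
  set.seed(55)
  pos <- numeric(0)
  wins <- 0
  for (r in 1:40) {
    sites <- label_mutation_classes(
      simulate_neutral_region(n = 22, S = 120), 0.5)
    shifted <- inject_w2s_shift(sites, 0.1)
    res <- mwu_test(shifted[shifted$klass == "W2S", ],
                    shifted[shifted$klass == "S2W", ])
    if (!is.na(res$offset22) && res$offset22 > 0) wins <- wins + 1
  }
  expect_gte(wins / 40, 0.95)

  # relabeling uniformly destroys the association
  set.seed(56)
  offs <- vapply(1:30, function(r) {
    sites <- label_mutation_classes(
      simulate_neutral_region(n = 22, S = 120), 0.5)
    shifted <- inject_w2s_shift(sites, 0.1)
    shifted$klass <- sample(shifted$klass)
    mwu_test(shifted[shifted$klass == "W2S", ],
             shifted[shifted$klass == "S2W", ])$offset22
  }, numeric(1))
  expect_lt(abs(mean(offs)), 1)

  # zero shift is a no-op
  sites <- data.frame(k = c(1, 5), n = 22, klass = c("W2S", "S2W"))
  expect_identical(inject_w2s_shift(sites, 0), sites)
  expect_error(inject_w2s_shift(sites, 1))
})

test_that("biased templates produce detectably biased regions", {
  st <- generate_study(small_template(seed = 31, bias_w2s_shift = 0.25,
                                      bias_fixed_enrichment = 4))
  target_ids <- grep("^target", names(st$regions), value = TRUE)
  offs <- vapply(target_ids, function(id) {
    s <- st$sites[st$sites$region_id == id, ]
    mwu_test(s[s$klass == "W2S", ], s[s$klass == "S2W", ])$offset22
  }, numeric(1))
  expect_gt(mean(offs > 0), 0.7)
})
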