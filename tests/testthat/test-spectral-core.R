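test_that("containers enforce the grid and pairing invariants", {
  expect_error(leaf_spectrum(c(400, 402, 403), c(1, 2, 3) / 10),
               "non-constant")
  expect_error(leaf_spectrum(c(403, 402), c(0.1, 0.2)), "increasing")
  expect_error(spectral_dataset(400:402, matrix(0.1, 2, 3), lac = c(1, -1)),
               ">= 0")
  expect_error(spectral_dataset(400:402, matrix(0.1, 2, 3), lac = 1:3),
               "number of samples")
})

test_that("replicate averaging is the pointwise mean", {
  s <- leaf_spectrum(400:405, runif(6, 0.2, 0.4))
  expect_equal(average_replicates(list(s))$values, s$values)

  a <- leaf_spectrum(400:405, rep(0.2, 6))
  b <- leaf_spectrum(400:405, rep(0.4, 6))
  expect_equal(average_replicates(list(a, b))$values, rep(0.3, 6))

  withr::with_seed(7, {
    reps <- replicate(10, leaf_spectrum(400:409, runif(10, 0.05, 0.9)),
                      simplify = FALSE)
  })
  # brute-force per-band sum / 10
  manual <- sapply(seq_len(10), function(j) {
    s <- 0
    for (r in reps) s <- s + r$values[j]
    s / 10
  })
  expect_equal(average_replicates(reps)$values, manual)

  c_shift <- leaf_spectrum(401:406, rep(0.4, 6))
  expect_error(average_replicates(list(a, c_shift)), "grids")
})

test_that("range restriction keeps the closed interval and errors when empty", {
  d <- spectral_dataset(350:2500, matrix(0.3, 2, 2151), lac = c(1, 2))
  r <- restrict_range(d)  # defaults 400-1400
  expect_equal(n_bands(r), 1001)
  expect_equal(range(r$wavelengths), c(400, 1400))
  full <- restrict_range(d, 350, 2500)
  expect_equal(full$values, d$values)
  expect_error(restrict_range(d, 3000, 3100), "intersect")
})

test_that("base transforms match direct elementwise evaluation", {
  d <- spectral_dataset(500:504, matrix(0.1, 1, 5), lac = 1)
  expect_equal(apply_transform(d, "1/P")$values[1, 1], 10)
  expect_equal(apply_transform(d, "lgP")$values[1, 1], -1)
  expect_equal(apply_transform(d, "1/lgP")$values[1, 1], -1)

  d5 <- spectral_dataset(500:504, matrix(0.5, 1, 5), lac = 1)
  expect_equal(apply_transform(d5, "1/lgP")$values[1, 1],
               -3.321928094887362, tolerance = 1e-12)

  rd <- random_reflectance_dataset(n = 8, seed = 3)
  for (base in c("P", "1/P", "lgP", "1/lgP")) {
    expect_equal(apply_transform(rd, base)$values,
                 oracle_base_transform(rd$values, base),
                 ignore_attr = TRUE, tolerance = 1e-14)
  }
})

test_that("singular reflectance errors in strict mode and masks otherwise", {
  m <- matrix(c(0.5, 1, 0.5, 0.5), 1, 4)
  d <- spectral_dataset(500:503, m, lac = 1)
  expect_error(apply_transform(d, "lgP"), "singular")
  masked <- apply_transform(d, "lgP", on_singular = "mask")
  expect_true(is.na(masked$values[1, 2]))
  expect_false(anyNA(masked$values[1, -2]))
})

test_that("printed differential is half the backward difference on lambda_i", {
  s <- leaf_spectrum(400:410, rep(0.3, 11))
  expect_equal(first_derivative(s)$values, rep(0, 10))

  ramp <- leaf_spectrum(400:410, as.numeric(400:410))
  dr <- first_derivative(ramp)
  expect_equal(dr$values, rep(0.5, 10))
  expect_equal(dr$wavelengths, as.numeric(401:410))

  withr::with_seed(5, v <- runif(20, 0.1, 0.9))
  s2 <- leaf_spectrum(601:620, v)
  expect_equal(first_derivative(s2)$values, oracle_printed_derivative(v, 1))

  # linearity: d(a v1 + b v2) = a d(v1) + b d(v2)
  withr::with_seed(6, {
    v1 <- runif(15); v2 <- runif(15)
  })
  lin <- first_derivative(leaf_spectrum(1:15, 2 * v1 + 3 * v2))$values
  expect_equal(lin,
               2 * first_derivative(leaf_spectrum(1:15, v1))$values +
                 3 * first_derivative(leaf_spectrum(1:15, v2))$values)

  expect_error(first_derivative(leaf_spectrum(500, 0.5)), "at least 2")
  expect_error(first_derivative(s2, delta_lambda = 2), "grid step")
})

test_that("central mode drops both ends and uses the symmetric stencil", {
  ramp <- leaf_spectrum(400:410, as.numeric(400:410))
  dc <- first_derivative(ramp, mode = "central")
  expect_equal(dc$values, rep(1, 9))
  expect_equal(dc$wavelengths, as.numeric(401:409))
})

test_that("log transform round-trips and sign contracts hold", {
  for (seed in 1:5) {
    rd <- random_reflectance_dataset(n = 6, seed = seed, lo = 1e-4,
                                     hi = 1 - 1e-4)
    lg <- apply_transform(rd, "lgP")$values
    expect_equal(10^lg, rd$values, tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(lg < 0))
    expect_true(all(apply_transform(rd, "1/lgP")$values < 0))
    expect_true(all(apply_transform(rd, "1/P")$values > 1))
  }
})

test_that("transform and range restriction commute (derivatives at boundary)", {
  rd <- random_reflectance_dataset(n = 5, bands = 400:450, seed = 9)
  for (k in c("1/P", "lgP", "1/lgP")) {
    a <- restrict_range(apply_transform(rd, k), 410, 440)
    b <- apply_transform(restrict_range(rd, 410, 440), k)
    expect_equal(a$values, b$values, ignore_attr = TRUE)
  }
  # derivative kinds agree except at the first retained band
  a <- restrict_range(apply_transform(rd, "P'"), 410, 440)
  b <- apply_transform(restrict_range(rd, 410, 440), "P'")
  expect_equal(a$wavelengths[1], 410)
  expect_equal(b$wavelengths[1], 411)
  shared <- intersect(a$wavelengths, b$wavelengths)
  expect_equal(a$values[, match(shared, a$wavelengths)],
               b$values[, match(shared, b$wavelengths)],
               ignore_attr = TRUE)
})

test_that("spectral tables round-trip through the wide CSV dialect", {
  rd <- random_reflectance_dataset(n = 2, bands = 500:504, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectral_table(rd, path)
  back <- read_spectral_table(path)
  expect_equal(back$values, rd$values)
  expect_equal(back$lac, rd$lac)
  expect_equal(back$sample_id, rd$sample_id)

  # re-written file is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_spectral_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("the reader validates grids, LAC and reflectance bounds", {
  p <- tiny_csv(c("sample_id,lac_mg_per_g,w400,w402,w403",
                  "A,1,0.1,0.2,0.3"))
  expect_error(read_spectral_table(p), "non-constant")

  p2 <- tiny_csv(c("sample_id,w400,w401", "A,0.1,0.2"))
  expect_error(read_spectral_table(p2), "lac_mg_per_g")

  p3 <- tiny_csv(c("sample_id,lac_mg_per_g,w400,w401",
                   "A,1,0.1,0.2", "B,2,1.2,0.3"))
  expect_error(read_spectral_table(p3, on_invalid = "error"), "B")
  expect_warning(kept <- read_spectral_table(p3, on_invalid = "reject"),
                 "B")
  expect_equal(kept$sample_id, "A")
  expect_warning(clipped <- read_spectral_table(p3, on_invalid = "clip"),
                 "clipped")
  expect_equal(clipped$values[2, 1], 1 - 1e-6)
})

test_that("long-dialect tables load to the same dataset", {
  rd <- random_reflectance_dataset(n = 2, bands = 500:502, seed = 4)
  long <- data.frame(sample_id = rep(rd$sample_id, each = 3),
                     lac_mg_per_g = rep(rd$lac, each = 3),
                     wavelength_nm = rep(500:502, 2),
                     reflectance = as.vector(t(rd$values)))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, path, row.names = FALSE)
  back <- read_spectral_table(path, dialect = "long")
  expect_equal(back$values, rd$values, tolerance = 1e-12)
  expect_equal(back$lac, rd$lac)
})
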