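exact_cases <- list(
  linear = list(x = seq(0.5, 5, by = 0.5),
                truth = c(a = 2, b = 1),
                f = function(x) 2 * x + 1),
  poly2 = list(x = seq(-2, 2, by = 0.25),
               truth = c(a = 1.5, b = -2, c = 0.5),
               f = function(x) 1.5 * x^2 - 2 * x + 0.5),
  power = list(x = seq(0.5, 2, by = 0.1),
               truth = c(a = 2, b = 3),
               f = function(x) 2 * x^3),
  exponential = list(x = seq(0, 2, by = 0.1),
                     truth = c(a = 3, b = 0.5),
                     f = function(x) 3 * exp(0.5 * x)),
  logarithmic = list(x = seq(0.5, 3, by = 0.1),
                     truth = c(a = 2.5, b = 1),
                     f = function(x) 2.5 * log(x) + 1)
)

test_that("every family recovers exact generating coefficients with R2 = 1", {
  for (fam in names(exact_cases)) {
    cs <- exact_cases[[fam]]
    fit <- fit_model(cs$x, cs$f(cs$x), fam)
    expect_equal(coef(fit), cs$truth, tolerance = 1e-6)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
    expect_equal(fit$status, "ok")
    # predictions reproduce the data
    expect_equal(predict(fit, cs$x), cs$f(cs$x), tolerance = 1e-6)
  }
})

test_that("power and exponential fits agree with log-linearisation oracles", {
  # y = 2 x^3: log y = log 2 + 3 log x
  cs <- exact_cases$power
  o <- coef(lm(log(cs$f(cs$x)) ~ log(cs$x)))
  fit <- fit_model(cs$x, cs$f(cs$x), "power")
  expect_equal(unname(coef(fit)["a"]), exp(unname(o[1])), tolerance = 1e-8)
  expect_equal(unname(coef(fit)["b"]), unname(o[2]), tolerance = 1e-8)
  expect_equal(fit$r2_log, 1, tolerance = 1e-12)

  cs <- exact_cases$exponential
  o <- coef(lm(log(cs$f(cs$x)) ~ cs$x))
  fit <- fit_model(cs$x, cs$f(cs$x), "exponential")
  expect_equal(unname(coef(fit)["a"]), exp(unname(o[1])), tolerance = 1e-8)
  expect_equal(unname(coef(fit)["b"]), unname(o[2]), tolerance = 1e-8)
})

test_that("linear R2 equals squared Pearson correlation; poly2 nests linear", {
  withr::with_seed(31, {
    x <- runif(40, 0.1, 2)
    y <- 3 * x + rnorm(40, 0, 0.5)
  })
  fl <- fit_model(x, y, "linear")
  expect_equal(fl$r2, cor(x, y)^2, tolerance = 1e-10)
  fq <- fit_model(x, y, "poly2")
  expect_gte(fq$r2 + 1e-12, fl$r2)
})

test_that("nonlinear refinement never ends worse than its start", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      x <- runif(60, 0.2, 3)
      y <- 1.7 * x^1.3 * exp(rnorm(60, 0, 0.3))
    })
    fit <- fit_model(x, y, "power")
    init <- coef(lm(log(y) ~ log(x)))
    ss_init <- sum((y - exp(init[1]) * x^init[2])^2)
    ss_fit <- sum((y - predict(fit, x))^2)
    expect_lte(ss_fit, ss_init + 1e-8)
    # original-scale refinement should strictly help under log-normal noise
    expect_lte(ss_fit, ss_init)
  }
})

test_that("domain-violating points are excluded or the family is skipped", {
  x <- c(-1, seq(0.5, 3, length.out = 20))  # ~5% non-positive
  y <- 2 * x + 1
  fit <- fit_model(x, y, "logarithmic")
  expect_equal(fit$status, "ok")
  expect_equal(fit$n_excluded, 1L)
  expect_equal(fit$n_fit, 20L)

  x_bad <- c(seq(-2, -0.1, length.out = 10), seq(0.5, 2, length.out = 10))
  fit2 <- fit_model(x_bad, 2 * x_bad + 5, "power")
  expect_equal(fit2$status, "skipped")
  expect_match(fit2$reason, "outside domain")

  # too few samples: poly2 needs n >= 4
  fit3 <- fit_model(c(1, 2, 3), c(1, 2, 3), "poly2")
  expect_equal(fit3$status, "skipped")
  fit4 <- fit_model(c(1, 2, 3), c(1.2, 1.9, 3.4), "linear")
  expect_equal(fit4$status, "ok")
})

test_that("predict evaluates the symbolic forms and guards domains", {
  lin <- fit_model(1:5, (1:5) * 1, "linear")
  expect_equal(predict(lin, 7), 7, tolerance = 1e-12)
  sq <- fit_model(seq(-2, 2, 0.5), seq(-2, 2, 0.5)^2, "poly2")
  expect_equal(predict(sq, 3), 9, tolerance = 1e-8)

  # printed calibration coefficients: a = 3e9, b = 4.5896 at x = 1e-3
  pw <- structure(list(family = "power",
                       coefficients = c(a = 3e9, b = 4.5896),
                       status = "ok", band = NA_real_,
                       transform = NA_character_),
                  class = "calibration_fit")
  direct <- exp(log(3e9) + 4.5896 * log(1e-3))
  expect_equal(predict(pw, 1e-3), direct, tolerance = 1e-6)
  expect_equal(predict(pw, 1e-3), 5.11e-5, tolerance = 1e-2)
  expect_error(predict(pw, -1), "undefined")
  expect_equal(predict(pw, c(-1, 1e-3), on_domain = "na"),
               c(NA, direct), tolerance = 1e-6)
})

test_that("coefficient error shrinks with sample size for every family", {
  sim_rmse <- function(fam, n, reps = 12) {
    cs <- exact_cases[[fam]]
    errs <- sapply(seq_len(reps), function(r) {
      withr::with_seed(1000 + r, {
        x <- runif(n, min(cs$x), max(cs$x))
        y <- cs$f(x) + rnorm(n, 0, 0.2)
      })
      fit <- fit_model(x, y, fam)
      if (fit$status != "ok") return(NA_real_)
      sqrt(mean((coef(fit) - cs$truth)^2))
    })
    sqrt(mean(errs^2, na.rm = TRUE))
  }
  for (fam in names(exact_cases)) {
    expect_lt(sim_rmse(fam, 5000), sim_rmse(fam, 50))
  }
})

test_that("candidate grids respect structure and the n_fit rule", {
  d <- restrict_range(
    generate_dataset(simulation_config(n_samples = 30, seed = 13)))
  sc <- screen_all_transforms(d)
  cands <- fit_all_candidates(d, sc)
  grid <- candidate_grid(cands)
  expect_lte(nrow(grid), 8 * 5)
  expect_true(all(grid$r2_original_scale[grid$status == "ok"] <= 1 + 1e-12))
  expect_setequal(unique(grid$transform), transform_kinds()$kind)

  # 4-sample dataset: poly2 (3 coefficients) still fits at n = 4,
  # and is skipped at n = 3
  expect_equal(fit_model(1:4, c(1, 3, 2, 5), "poly2")$status, "ok")
  expect_equal(fit_model(1:3, c(1, 3, 2), "poly2")$status, "skipped")
})

test_that("a generative power law between (lgP)' and LAC wins the fit", {
  # build LAC as a pure power law of the (lgP)' feature-band value
  cfg <- simulation_config(n_samples = 80, seed = 17,
                           noise_additive_sd = 0, noise_multiplicative_sd = 0,
                           chl_mean = 0, chl_sd = 0, moisture_sd = 0)
  d <- restrict_range(generate_dataset(cfg))
  td <- apply_transform(d, "(lgP)'")
  j <- match(656, td$wavelengths)  # rising flank of the 650 nm feature
  x <- td$values[, j]
  expect_true(all(x > 0))
  d2 <- spectral_dataset(d$wavelengths, d$values, 5e4 * x^1.7, d$sample_id)
  td2 <- apply_transform(d2, "(lgP)'")
  fits <- lapply(model_families(), function(f)
    fit_model(td2$values[, j], d2$lac, f))
  names(fits) <- model_families()
  ok <- Filter(function(f) f$status == "ok", fits)
  r2 <- vapply(ok, `[[`, numeric(1), "r2")
  expect_equal(names(which.max(r2)), "power")
  expect_equal(unname(coef(fits$power)["b"]), 1.7, tolerance = 1e-4)
})

test_that("best-model selection maximises R2 with simplicity tie-breaks", {
  mk <- function(fam, r2, band = 650) {
    structure(list(family = fam, coefficients = c(a = 1, b = 1),
                   r2 = r2, status = "ok", band = band,
                   transform = "P", n_fit = 10),
              class = "calibration_fit")
  }
  picks <- select_best_model(list(mk("linear", 0.3), mk("power", 0.9),
                                  mk("exponential", 0.5)))
  expect_equal(picks$r2, 0.9)

  tie <- select_best_model(list(mk("poly2", 0.8), mk("linear", 0.8)))
  expect_equal(tie$family, "linear")

  solo <- select_best_model(list(mk("exponential", 0.4)))
  expect_equal(solo$family, "exponential")

  skipped <- structure(list(family = "power", status = "skipped",
                            r2 = NA_real_), class = "calibration_fit")
  expect_error(select_best_model(list(skipped)), "skipped")
})

test_that("equation strings use 4 significant digits and flag skips", {
  fit <- fit_model(1:10, 2 * (1:10) + 1, "linear")
  fit$band <- 667
  expect_equal(equation_string(fit), "y = 2*W667 + 1")
  fit$coefficients <- c(a = -0.00091234, b = 0.037711)
  expect_equal(equation_string(fit), "y = -0.0009123*W667 + 0.03771")
  sk <- fit_model(c(-1, -2, -3, -4), 1:4, "power")
  expect_match(equation_string(sk), "skipped")
})
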