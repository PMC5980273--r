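# Small fixtures built in code, reproducibly.

random_reflectance_dataset <- function(n = 10, bands = 500:519, seed = 1,
                                       lo = 0.05, hi = 0.95) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * length(bands), lo, hi), n, length(bands))
    spectral_dataset(bands, m, lac = runif(n, 0.1, 40))
  })
}

# independent elementwise oracle for the four base transforms
oracle_base_transform <- function(p, base) {
  switch(base,
         "P" = p,
         "1/P" = 1 / p,
         "lgP" = log(p, base = 10),
         "1/lgP" = 1 / log(p, base = 10))
}

# independent loop oracle for the printed differential at the i-th output
oracle_printed_derivative <- function(v, step) {
  out <- numeric(length(v) - 1L)
  for (i in 2:length(v)) out[i - 1L] <- (v[i] - v[i - 1L]) / (2 * step)
  out
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

tiny_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
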