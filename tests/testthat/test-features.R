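test_that("msi worked examples hold exactly", {
  expect_identical(compute_msi(rep(2.5, 30)), 0)
  expect_identical(compute_msi(c(rep(1, 20), rep(3, 10))), 20)
  expect_identical(compute_msi(as.numeric(0:29)), 0)
})

test_that("msi equals the brute-force median-subtraction oracle", {
  set.seed(99)
  for (i in 1:1000) {
    v <- rnorm(30, runif(1, 0, 5), runif(1, 0.01, 2))
    expect_equal(compute_msi(v), oracle_msi(v), tolerance = 1e-12)
  }
})

test_that("msi is offset-invariant, scale-linear, and signs convexity", {
  set.seed(7)
  for (i in 1:20) {
    v <- rnorm(30)
    expect_equal(compute_msi(v + 11.3), compute_msi(v), tolerance = 1e-10)
    expect_equal(compute_msi(3.7 * v), 3.7 * compute_msi(v),
                 tolerance = 1e-10)
  }
  convex <- exp(seq(0, 2, length.out = 30))   # convex increasing
  expect_gt(compute_msi(convex), 0)
})

test_that("noiseless biexponential parameters are recovered", {
  x <- seq(0, 1, length.out = 60)
  for (abc in list(c(0.5, 2, 1), c(1, 0, 1), c(2, -1, 3))) {
    yn <- abc[1] * exp(abc[2] * x^2 + abc[3] * x)
    f <- fit_biexponential(yn, normalize = FALSE)
    expect_true(f$converged)
    expect_equal(c(f$A, f$B, f$C), abc, tolerance = 1e-3)
  }
})

test_that("window normalization is applied before fitting by default", {
  x <- seq(0, 1, length.out = 60)
  yn <- 0.8 * exp(0.5 * x^2 + x) - 0.8      # normalized signal, min 0 at x=0
  f_raw <- fit_biexponential(yn + 3.1)      # arbitrary baseline offset
  f_norm <- fit_biexponential(yn, normalize = FALSE)
  expect_true(f_raw$converged)
  expect_equal(c(f_raw$A, f_raw$B, f_raw$C),
               c(f_norm$A, f_norm$B, f_norm$C), tolerance = 1e-6)
})

test_that("flat windows yield a non-converged fit with zero fallbacks", {
  f <- fit_biexponential(rep(4.2, 60))
  expect_false(f$converged)
  feats <- curvefit_features(f)
  expect_equal(as.numeric(feats), rep(0, 6))
  expect_true(attr(feats, "degenerate"))
})

test_that("curvefit features match closed-form derivatives of exp(x)", {
  # A=1, B=0, C=1: y = e^x, monotone on [0, 1]
  f <- list(A = 1, B = 0, C = 1, converged = TRUE, n = 60)
  class(f) <- "biexp_fit"
  v <- curvefit_features(f)
  e <- exp(1)
  expect_equal(as.numeric(v), c(1, e, 1, e, 1, e^2), tolerance = 1e-4)
  # A=1, B=1, C=0: y = exp(x^2)
  f2 <- list(A = 1, B = 1, C = 0, converged = TRUE, n = 60)
  class(f2) <- "biexp_fit"
  v2 <- curvefit_features(f2)
  expect_equal(as.numeric(v2), c(0, 2 * e, 2, 6 * e, 0, 12 * e^2),
               tolerance = 1e-4)
})

test_that("grid extrema agree with a dense finite-difference oracle", {
  set.seed(2024)
  for (i in 1:100) {
    A <- runif(1, 0.1, 5); B <- runif(1, -3, 3); C <- runif(1, -3, 3)
    f <- list(A = A, B = B, C = C, converged = TRUE, n = 60)
    class(f) <- "biexp_fit"
    got <- curvefit_features(f, grid_n = 10001)
    fd <- oracle_curvefit_fd(A, B, C, 10001)
    want <- c(min(fd$d1), max(fd$d1), min(fd$d2), max(fd$d2),
              min(fd$d12), max(fd$d12))
    # an extremum can legitimately be near zero (y' vanishing at a boundary);
    # compare such cases relative to the derivative's overall scale
    scale <- rep(c(max(abs(fd$d1)), max(abs(fd$d2)), max(abs(fd$d12))),
                 each = 2)
    # 1e-6 relative, beyond the oracle's own roundoff floor
    err <- pmax(abs(got - want) - fd$floors, 0)
    expect_lt(max(err / pmax(abs(want), 1e-3 * scale)), 1e-6)
  }
})

test_that("fits degrade gracefully under additive noise", {
  set.seed(11)
  x <- seq(0, 1, length.out = 60)
  ok <- 0L
  for (i in 1:200) {
    # magnitudes bounded away from zero so a 10%-relative band is meaningful
    B <- sample(c(-1, 1), 1) * runif(1, 0.5, 1.5)
    C <- sample(c(-1, 1), 1) * runif(1, 0.5, 1.5)
    y <- exp(B * x^2 + C * x)
    y <- y / max(y)                       # unit amplitude
    A_true <- 1 / max(exp(B * x^2 + C * x))
    f <- fit_biexponential(y + rnorm(60, 0, 0.01), normalize = FALSE)
    if (f$converged &&
        all(abs(c(f$A - A_true, f$B - B, f$C - C)) <=
            0.1 * pmax(abs(c(A_true, B, C)), 0.1))) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 180L)
})

test_that("feature series cover the window grid and propagate gaps", {
  tr <- mk_trace(rep(1, 100))
  expect_equal(nrow(extract_feature_series(tr, "msi")), 15L)
  expect_equal(nrow(extract_feature_series(tr, "d2max")), 9L)
  s <- extract_feature_series(tr, "msi")
  expect_true(all(s$value == 0))

  cut <- apply_exclusions(mk_trace(rep(1, 300)), exclusion_mask(100, 120))
  s2 <- extract_feature_series(cut, "msi")
  full <- extract_feature_series(mk_trace(rep(1, 300)), "msi")
  expect_lt(nrow(s2), nrow(full))
})

test_that("one fit feeds all six curvefit features per window", {
  set.seed(5)
  tr <- mk_trace(2 + cumsum(rnorm(130, 0.02, 0.05)))
  ft <- compute_features(generate_windows(tr, 60, 5),
                         c("d1min", "d1max", "d2min", "d2max",
                           "d1d2min", "d1d2max"))
  expect_true(all(ft$d1max >= ft$d1min))
  expect_true(all(ft$d2max >= ft$d2min))
  expect_true(all(ft$d1d2max >= ft$d1d2min))
})
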