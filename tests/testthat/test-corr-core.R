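# Correlation estimation and the triadic association measures.

test_that("pearson correlation matches the explicit sample formula on a small integer table", {
  x <- matrix(c(
    1, 4, 2, 7,
    3, 1, 5, 2,
    2, 6, 1, 9,
    5, 2, 4, 3,
    4, 5, 3, 8,
    6, 3, 6, 4
  ), nrow = 6, byrow = TRUE)
  expected <- matrix(NA_real_, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      xi <- x[, i] - mean(x[, i])
      xj <- x[, j] - mean(x[, j])
      expected[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  got <- pearson_correlation(x)
  expect_equal(unname(got), expected, tolerance = 1e-12)
  expect_identical(diag(got), rep(1, 4))
  expect_identical(got, t(got))
  expect_true(all(abs(got) <= 1))
})

test_that("perfectly (anti)correlated columns give +/- 1 and constant columns error", {
  x <- matrix(rnorm(40), 10, 4)
  x[, 2] <- x[, 1]
  x[, 3] <- -x[, 1]
  rho <- pearson_correlation(x)
  expect_equal(rho[1, 2], 1)
  expect_equal(rho[1, 3], -1)

  x[, 4] <- 2
  colnames(x) <- c("a", "b", "c", "flat")
  expect_error(pearson_correlation(x), "flat.*zero variance|zero variance")
  expect_error(pearson_correlation(x[1:3, 1:3, drop = FALSE]), "at least 4")
})

test_that("full partial correlation: independence, N = 3 reduction, regression oracle", {
  expect_equal(full_partial_correlation(diag(4)), diag(4))

  set.seed(42)
  r3 <- random_corr(3, 40)
  p3 <- full_partial_correlation(r3)
  expect_equal(p3[1, 2], partial_correlation3(r3[1, 2], r3[3, 1], r3[3, 2]),
               tolerance = 1e-12)
  expect_equal(p3[1, 3], partial_correlation3(r3[1, 3], r3[2, 1], r3[2, 3]),
               tolerance = 1e-12)

  # residual-regression oracle: partial corr(i, j | rest) is the correlation
  # of the residuals after regressing each on all remaining variables
  for (n in 5:8) {
    x <- matrix(rnorm(60 * n), 60, n)
    rho <- cor(x)
    got <- full_partial_correlation(rho)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        others <- x[, -c(i, j), drop = FALSE]
        ri <- residuals(lm(x[, i] ~ others))
        rj <- residuals(lm(x[, j] ~ others))
        expect_equal(got[i, j], cor(ri, rj), tolerance = 1e-8)
      }
    }
  }
})

test_that("full partial correlation refuses singular input", {
  m <- matrix(0.5, 4, 4)
  diag(m) <- 1
  m[1, 2] <- m[2, 1] <- 1  # rank-deficient: node 2 duplicates node 1
  expect_error(full_partial_correlation(m), "singular|ill-conditioned")
})

test_that("three-way partial correlation: trivial cases, frozen value, symmetry", {
  expect_equal(partial_correlation3(0.7, 0, 0), 0.7)
  # rho_jl exactly equals the indirect-path product => 0
  expect_equal(partial_correlation3(0.25, 0.5, 0.5), 0)
  expect_equal(partial_correlation3(0.5, 0.6, 0.4), 0.354604071633,
               tolerance = 1e-10)

  set.seed(7)
  for (rep in 1:200) {
    r <- random_corr(3, 30)
    expect_equal(partial_correlation3(r[2, 3], r[1, 2], r[1, 3]),
                 partial_correlation3(r[2, 3], r[1, 3], r[1, 2]),
                 tolerance = 1e-14)
    p <- partial_correlation3(r[2, 3], r[1, 2], r[1, 3])
    expect_true(abs(p) <= 1 + 1e-12)
  }

  expect_error(partial_correlation3(0.2, 1, 0.3), "degenerate")
  expect_error(partial_correlation3(0.2, 0.3, 1 - 1e-15), "degenerate")
})

test_that("gaussian partial MI: collapse cases, nonnegativity, closed-form identity", {
  expect_equal(gaussian_partial_mi(0, 0, 0), 0)
  for (r in c(-0.8, -0.3, 0.2, 0.9)) {
    expect_equal(gaussian_partial_mi(r, 0, 0), -0.5 * log(1 - r^2),
                 tolerance = 1e-14)
  }

  # identity with the partial correlation: I = -log(1 - p^2) / 2
  set.seed(11)
  for (rep in 1:1000) {
    r <- random_corr(3, 25)
    p <- partial_correlation3(r[2, 3], r[1, 2], r[1, 3])
    mi <- gaussian_partial_mi(r[2, 3], r[1, 2], r[1, 3])
    expect_lt(abs(mi - (-0.5 * log(1 - p^2))), 1e-10)
    expect_gte(mi, -1e-12)  # zero up to round-off when p == 0
  }

  expect_error(gaussian_partial_mi(0.99, 0.9, -0.9), "degenerate")
})

test_that("gaussian partial MI matches a Monte-Carlo conditional-MI estimate", {
  # Sampling oracle: draw from the trivariate normal with the given triple and
  # average the log conditional density ratio log f(xj, xl | xi) -
  # log f(xj | xi) - log f(xl | xi), whose expectation is I(Xj; Xl | Xi).
  r_ij <- 0.6; r_il <- 0.4; r_jl <- 0.5  # ordering (i, j, l)
  sigma <- matrix(c(1, r_ij, r_il,
                    r_ij, 1, r_jl,
                    r_il, r_jl, 1), 3, 3)
  set.seed(99)
  z <- matrix(rnorm(3 * 5e5), ncol = 3) %*% chol(sigma)
  xi <- z[, 1]; xj <- z[, 2]; xl <- z[, 3]
  ldnorm <- function(x, mu, v) -0.5 * log(2 * pi * v) - (x - mu)^2 / (2 * v)
  # conditionals on xi from standard normal theory
  lj <- ldnorm(xj, r_ij * xi, 1 - r_ij^2)
  ll <- ldnorm(xl, r_il * xi, 1 - r_il^2)
  s11 <- 1 - r_ij^2; s22 <- 1 - r_il^2; s12 <- r_jl - r_ij * r_il
  det2 <- s11 * s22 - s12^2
  uj <- xj - r_ij * xi; ul <- xl - r_il * xi
  q <- (s22 * uj^2 - 2 * s12 * uj * ul + s11 * ul^2) / det2
  ljl <- -log(2 * pi) - 0.5 * log(det2) - 0.5 * q
  samples <- ljl - lj - ll
  est <- mean(samples)
  se <- sd(samples) / sqrt(length(samples))
  expect_equal(est, gaussian_partial_mi(r_jl, r_ij, r_il),
               tolerance = max(4 * se / abs(est), 0.01))
})

test_that("mean absolute three-way partial correlation averages all triples", {
  set.seed(3)
  rho <- random_corr(6, 40)
  total <- 0; count <- 0
  for (i in 1:6) {
    for (j in 1:6) {
      for (l in 1:6) {
        if (j >= l || j == i || l == i) next
        total <- total + abs(oracle_partial3(rho[j, l], rho[i, j], rho[i, l]))
        count <- count + 1
      }
    }
  }
  expect_equal(mean_abs_partial3(rho), total / count, tolerance = 1e-12)
})
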