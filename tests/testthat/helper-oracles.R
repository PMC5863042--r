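# Independent brute-force oracles: literal triple loops over the defining
# formulas, sharing no code with the package internals. Deliberately slow and
# explicit.

random_corr <- function(n, t = n + 20) {
  stats::cor(matrix(stats::rnorm(t * n), t, n))
}

oracle_partial3 <- function(r_jl, r_ij, r_il) {
  (r_jl - r_ij * r_il) / (sqrt(1 - r_ij^2) * sqrt(1 - r_il^2))
}

oracle_gauss_mi <- function(r_jl, r_ij, r_il) {
  det3 <- 1 - r_ij^2 - r_il^2 - r_jl^2 + 2 * r_ij * r_il * r_jl
  0.5 * (log(1 - r_ij^2) + log(1 - r_il^2) - log(det3))
}

.oracle_triple_ok <- function(rho, i, j, l, filter) {
  if (filter == "all") return(TRUE)
  if (filter == "positive") {
    return(rho[i, j] > 0 && rho[i, l] > 0 && rho[j, l] > 0)
  }
  rho[i, j] < 0 && rho[i, l] < 0 && rho[j, l] < 0
}

# Returns per-node numerator/denominator sums as well as the coefficient so
# that sum-partition properties can be checked directly.
oracle_corr_A <- function(rho, filter = "all") {
  n <- nrow(rho)
  num <- den <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        if (j >= l || j == i || l == i) next
        if (!.oracle_triple_ok(rho, i, j, l, filter)) next
        w <- abs(rho[i, j] * rho[i, l])
        num[i] <- num[i] + w * abs(oracle_partial3(rho[j, l], rho[i, j], rho[i, l]))
        den[i] <- den[i] + w
      }
    }
  }
  list(values = ifelse(den > 0, num / den, NA_real_), defined = den > 0,
       num = num, den = den)
}

oracle_corr_M <- function(rho, filter = "all") {
  n <- nrow(rho)
  num <- den <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        if (j >= l || j == i || l == i) next
        if (!.oracle_triple_ok(rho, i, j, l, filter)) next
        w <- abs(rho[i, j] * rho[i, l])
        num[i] <- num[i] + w * oracle_gauss_mi(rho[j, l], rho[i, j], rho[i, l])
        den[i] <- den[i] + w
      }
    }
  }
  vals <- ifelse(den > 0, num / (den * (1 + log(2 * pi)) / 2), NA_real_)
  list(values = vals, defined = den > 0, num = num, den = den)
}

oracle_unweighted <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    tri <- 0
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        if (j >= l || j == i || l == i) next
        tri <- tri + a[i, j] * a[i, l] * a[j, l]
      }
    }
    vals[i] <- tri / (k[i] * (k[i] - 1) / 2)
  }
  list(values = vals, defined = k >= 2)
}

oracle_barrat <- function(w) {
  n <- nrow(w)
  a <- (w > 0) + 0
  k <- rowSums(a)
  s <- rowSums(w)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (k[i] < 2 || s[i] <= 0) next
    total <- 0
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        if (j == l || j == i || l == i) next
        total <- total + (w[i, j] + w[i, l]) / 2 * a[i, j] * a[i, l] * a[j, l]
      }
    }
    vals[i] <- total / (s[i] * (k[i] - 1))
  }
  list(values = vals, defined = k >= 2 & s > 0)
}

oracle_onnela <- function(w) {
  n <- nrow(w)
  wmax <- max(w)
  k <- rowSums(w > 0)
  vals <- rep(NA_real_, n)
  if (wmax == 0) return(list(values = vals, defined = rep(FALSE, n)))
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    total <- 0
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        if (j == l || j == i || l == i) next
        total <- total + (w[i, j] * w[i, l] * w[j, l] / wmax^3)^(1 / 3)
      }
    }
    vals[i] <- total / (k[i] * (k[i] - 1))
  }
  list(values = vals, defined = k >= 2)
}

oracle_zhang <- function(w) {
  n <- nrow(w)
  wmax <- max(w)
  vals <- rep(NA_real_, n)
  if (wmax == 0) return(list(values = vals, defined = rep(FALSE, n)))
  defined <- rep(FALSE, n)
  for (i in seq_len(n)) {
    num <- den <- 0
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        if (j == l || j == i || l == i) next
        num <- num + w[i, j] * w[i, l] * w[j, l] / wmax^3
        den <- den + w[i, j] * w[i, l] / wmax^2
      }
    }
    if (den > 0) {
      vals[i] <- num / den
      defined[i] <- TRUE
    }
  }
  list(values = vals, defined = defined)
}

# Constructors for the network containers (internal to the package).
unweighted_network_for_test <- function(a) corrclust:::unweighted_network(a)
weighted_network_for_test <- function(w) corrclust:::weighted_network(w)
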