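test_that("normalization factors absorb depth and keep geometric mean one", {
  withr::local_seed(83)
  m <- matrix(rpois(400, 100), 100, 4,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("l%d", 1:4)))
  ident <- cbind(m[, 1], m[, 1], m[, 1])
  colnames(ident) <- sprintf("l%d", 1:3)
  expect_equal(unname(norm_factors(ident)), rep(1, 3), tolerance = 1e-12)

  # exact doubling: factor ratio 2
  two <- cbind(A = m[, 1], B = 2L * m[, 1])
  f <- norm_factors(two)
  expect_equal(unname(f["B"] / f["A"]), 2, tolerance = 1e-9)

  f4 <- norm_factors(m)
  expect_equal(exp(mean(log(f4))), 1, tolerance = 1e-12)
  zero <- m; zero[, 2] <- 0L
  expect_error(norm_factors(zero), "all-zero")
  expect_error(norm_factors(m[, 1, drop = FALSE]), "two libraries")
})

test_that("the moment dispersion estimator recovers known dispersions", {
  design <- build_design(stages = "s1", groups = c("A", "B"),
                         replicates_per_cell = 3)
  withr::local_seed(89)
  mk <- function(gen) {
    m <- t(vapply(seq_len(500), function(i) {
      mu <- exp(runif(1, log(20), log(500)))
      as.integer(gen(6, mu))
    }, integer(6)))
    dimnames(m) <- list(sprintf("g%03d", 1:500), design$library_id)
    m
  }
  pois <- mk(function(n, mu) rpois(n, mu))
  expect_lt(estimate_dispersion(pois, design), 0.05)
  nb <- mk(function(n, mu) rnbinom(n, mu = mu, size = 1 / 0.2))
  phi_hat <- estimate_dispersion(nb, design)
  expect_gte(phi_hat, 0.1)
  expect_lte(phi_hat, 0.3)
  const <- matrix(7L, 10, 6,
                  dimnames = list(sprintf("c%d", 1:10), design$library_id))
  expect_equal(estimate_dispersion(const, design), 0)
})

test_that("the exact NB test is symmetric and degenerates correctly", {
  a <- c(30L, 40L, 35L)
  r0 <- exact_nb_test(a, a, phi = 0.1)
  expect_equal(r0$log2FC, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(exact_nb_test(c(0L, 0L), c(0L, 0L), 0.2),
               list(log2FC = 0, p_value = 1))
  b <- c(10L, 14L, 12L)
  fwd <- exact_nb_test(a, b, 0.1)
  rev <- exact_nb_test(b, a, 0.1)
  expect_equal(fwd$log2FC, -rev$log2FC)
  expect_equal(fwd$p_value, rev$p_value)
  expect_error(exact_nb_test(a, b, phi = -0.1), "phi")
})

test_that("at phi = 0 the test equals the exact conditional binomial on 100 random cases", {
  withr::local_seed(97)
  for (k in 1:100) {
    n_a <- sample(2:4, 1); n_b <- sample(2:4, 1)
    mu <- exp(runif(1, log(1), log(80)))
    a <- rpois(n_a, mu)
    b <- rpois(n_b, mu * sample(c(0.5, 1, 2), 1))
    got <- exact_nb_test(a, b, phi = 0)
    want <- oracle_binom_p(sum(a), sum(b), n_a, n_b)
    expect_equal(got$p_value, want, tolerance = 1e-9)
  }
})

test_that("at phi > 0 the p-value matches a conditional Monte-Carlo oracle", {
  withr::local_seed(103)
  cases <- list(c(8, 3, 0.2), c(15, 6, 0.1), c(4, 12, 0.4))
  for (cs in cases) {
    a_counts <- rpois(3, cs[1]); b_counts <- rpois(3, cs[2])
    phi <- cs[3]
    got <- exact_nb_test(a_counts, b_counts, phi)$p_value
    a <- sum(a_counts); b <- sum(b_counts); tt <- a + b
    mu <- tt / 6
    lp <- function(x) dnbinom(x, mu = 3 * mu, size = 3 / phi, log = TRUE) +
      dnbinom(tt - x, mu = 3 * mu, size = 3 / phi, log = TRUE)
    draws_a <- rnbinom(1e5, mu = 3 * mu, size = 3 / phi)
    draws_b <- rnbinom(1e5, mu = 3 * mu, size = 3 / phi)
    keep <- draws_a + draws_b == tt
    expect_gte(sum(keep), 200)  # enough conditional draws to compare
    mc <- mean(lp(draws_a[keep]) <= lp(a) + 1e-9)
    se <- sqrt(mc * (1 - mc) / sum(keep))
    expect_lt(abs(got - mc), 3 * se + 1e-9)
  }
})

test_that("BH adjustment reproduces the worked step-up example and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, -0.1)), "\\[0, 1\\]")
  withr::local_seed(107)
  p <- runif(50)
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))       # monotone in sorted order
  expect_true(all(q >= p - 1e-12))             # never below p
  expect_true(all(q <= 1))
})

test_that("significance calls apply the inclusive fold-change and strict FDR thresholds", {
  res <- data.frame(log2FC = c(2.0, 5, -3, 1.99, 2.5),
                    q_value = c(0.049, 0.2, 0.001, 0.0001, 0.05))
  out <- call_de(res)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("up", "ns", "down", "ns", "ns"))
})

test_that("detection of a fixed planted fold change degrades as dispersion grows", {
  withr::local_seed(109)
  recall <- vapply(c(0.05, 0.4, 1.5), function(phi) {
    hits <- 0L
    for (r in 1:20) {
      p <- vapply(1:40, function(i) {
        mu <- exp(runif(1, log(3), log(12)))
        a <- rnbinom(3, mu = mu, size = 1 / phi)
        b <- rnbinom(3, mu = mu * 16, size = 1 / phi)
        exact_nb_test(a, b, phi)$p_value
      }, 0)
      hits <- hits + sum(p < 0.05)
    }
    hits / (20 * 40)
  }, 0)
  expect_true(all(diff(recall) < 0))
})

test_that("stage-wise DE runs every contrast and flags planted effects", {
  s <- small_study()
  de <- run_de(s$counts, s$design, pipeline_params())
  expect_setequal(unique(de$contrast),
                  c("UF_vs_FED6h", "FED6h_vs_FED12h", "FED12h_vs_FED24h",
                    "FED24h_vs_FED5d", "UF_vs_FED5d"))
  expect_setequal(unique(de$stage), unique(s$design$stage))
  expect_true(all(de$q_value >= de$p_value - 1e-12))
  expect_true(all(de$direction %in% c("up", "down", "ns")))
})
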