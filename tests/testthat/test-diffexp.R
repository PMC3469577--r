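test_that("tpm scales counts per million and sums to one million over a library", {
  expect_identical(tpm(0, 1e6), 0)
  expect_identical(tpm(1, 1e6), 1)
  expect_error(tpm(1, 0), "N")
  expect_error(tpm(-1, 10), "count")
  set.seed(41)
  counts <- rpois(100, 50)
  N <- sum(counts)
  expect_equal(sum(tpm(counts, N)), 1e6)
  # ratio identity: TPM(x,N)/TPM(y,N) = x/y
  expect_equal(tpm(12, N) / tpm(5, N), 12 / 5)
})

test_that("the Audic-Claverie kernel is normalized and symmetric at equal counts", {
  # kernel sums to 1 over all y for fixed x (truncated far past the mode)
  lp <- mirseed:::.ac_log_kernel(0:3000, 7, 1e6, 1e6)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-12)
  expect_identical(audic_claverie_p(50, 50, 1e6, 1e6), 1)
  # exact swap identity of the kernel: the lower tails of the two
  # orientations are complementary, P(Y<=y|x) + P(X<=x|y, swapped) = 1
  set.seed(42)
  for (i in 1:30) {
    x <- rpois(1, 50); y <- rpois(1, 120)
    N1 <- sample(1e5:2e6, 1); N2 <- sample(1e5:2e6, 1)
    expect_equal(audic_claverie_p(x, y, N1, N2, alternative = "less") +
                   audic_claverie_p(y, x, N2, N1, alternative = "less"),
                 1, tolerance = 1e-10)
    # the two-sided values agree up to the boundary point mass (the
    # inclusive-tail convention counts the observed point in both
    # orientations, so exact equality holds only up to that mass)
    pt <- max(exp(mirseed:::.ac_log_kernel(y, x, N1, N2)),
              exp(mirseed:::.ac_log_kernel(x, y, N2, N1)))
    expect_lte(abs(audic_claverie_p(x, y, N1, N2) -
                     audic_claverie_p(y, x, N2, N1)), 2 * pt + 1e-12)
  }
})

test_that("p-values match the negative-binomial oracle to 1e-9 relative error", {
  set.seed(43)
  for (i in 1:80) {
    x <- sample(0:500, 1)
    N1 <- sample(1e5:2e6, 1); N2 <- sample(1e5:2e6, 1)
    y <- rpois(1, max(0.5, x * N2 / N1 * runif(1, 0.5, 2)))
    p <- audic_claverie_p(x, y, N1, N2)
    o <- oracle_ac_p(x, y, N1, N2)
    expect_lt(abs(p - o) / o, 1e-9)
  }
  # spec-style worked case
  expect_lt(abs(audic_claverie_p(20, 80, 1e6, 1e6) -
                  oracle_ac_p(20, 80, 1e6, 1e6)) /
              oracle_ac_p(20, 80, 1e6, 1e6), 1e-9)
})

test_that("signed fold change follows the reciprocal-negative convention with sentinels", {
  expect_equal(signed_fold_change(5, 5), 1)
  expect_equal(mirseed:::round_half_up(signed_fold_change(95.07, 38.57)),
               2.46)
  expect_equal(mirseed:::round_half_up(signed_fold_change(45.43, 95.28)),
               -2.10)
  expect_identical(signed_fold_change(3, 0), Inf)
  expect_identical(signed_fold_change(0, 3), -Inf)
  expect_true(is.na(signed_fold_change(0, 0)))
  # antisymmetry whenever the change is non-trivial
  set.seed(44)
  for (i in 1:50) {
    a <- runif(1, 0.1, 1000); b <- runif(1, 0.1, 1000)
    fc <- signed_fold_change(a, b)
    if (abs(fc) > 1)
      expect_equal(fc, -signed_fold_change(b, a), tolerance = 1e-12)
  }
})

test_that("differential calls require |FC| strictly above the cutoff and p below alpha", {
  rec <- data.frame(name = c("a", "b", "c"),
                    count_treated = c(400L, 200L, 0L),
                    count_control = c(100L, 100L, 50L),
                    stringsAsFactors = FALSE)
  de <- call_differential(rec, 1e6, 1e6)
  expect_true(de$significant[de$name == "a"])
  expect_identical(de$fc[de$name == "a"], 4)
  # |FC| exactly 2.00 is not significant (strict inequality)
  expect_identical(de$fc[de$name == "b"], 2)
  expect_false(de$significant[de$name == "b"])
  # zero-count sentinel is excluded from calling by default
  expect_identical(de$fc[de$name == "c"], -Inf)
  expect_false(de$significant[de$name == "c"])
  # with a pseudo-TPM floor the zero record becomes callable
  de2 <- call_differential(rec, 1e6, 1e6, pseudo_tpm = 1)
  expect_true(is.finite(de2$fc[de2$name == "c"]))
})

test_that("null simulations call at about the nominal rate and planted changes are recovered", {
  truth <- make_reference(20, 0, seed = 19, n_de = 0)
  depth <- 1e5
  sig <- 0; tot <- 0
  for (r in 1:60) {
    x <- simulate_counts(truth, "HT", "drought", depth, seed = 5000 + 2 * r)
    y <- simulate_counts(truth, "HT", "irrigated", depth,
                         seed = 5001 + 2 * r)
    p <- audic_claverie_p(x, y, depth, depth)
    sig <- sig + sum(p < 0.05); tot <- tot + length(p)
  }
  expect_gt(sig / tot, 0.02)
  expect_lt(sig / tot, 0.08)
  # power: fc = 4 at 200 TPM baseline and 2e5 depth flags with the
  # correct sign in at least 95% of seeds
  ok <- 0
  for (s in 1:100) {
    set.seed(6000 + s)
    x <- rpois(1, 2e5 * 800 / 1e6)  # treated: 200 TPM x 4
    y <- rpois(1, 2e5 * 200 / 1e6)  # control baseline
    de <- call_differential(
      data.frame(name = "m", count_treated = x, count_control = y),
      2e5, 2e5)
    ok <- ok + (de$significant && de$fc > 0)
  }
  expect_gte(ok, 95)
})
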