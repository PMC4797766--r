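test_that("comparative delta-Ct matches hand-enumerated pair SDs", {
  m <- cbind(A = c(20, 21, 20.5), B = c(25, 26, 25.5), C = c(30, 31, 30.4))
  rownames(m) <- paste0("s", 1:3)
  res <- delta_ct_stability(m)
  # A-B constant -> SD 0; A-C and B-C both have SD sd1(c(0,0,0.1))
  s_ac <- sd1(m[, "A"] - m[, "C"])
  expect_equal(unname(res$values),
               c(mean(c(0, s_ac)), mean(c(0, s_ac)), s_ac),
               tolerance = 1e-12)
  expect_equal(round(unname(res$values), 4), c(0.0289, 0.0289, 0.0577))
  expect_equal(unname(res$ranks), c(1L, 1L, 3L))
})

test_that("delta-Ct agrees with the brute-force oracle on random matrices", {
  for (seed in 1:5) {
    m <- random_cq(n = 8, G = 6, seed = seed)
    expect_equal(delta_ct_stability(m)$values, oracle_delta_ct(m),
                 tolerance = 1e-12)
  }
})

test_that("constant-offset gene pairs end as geNorm's final pair with V = 0", {
  set.seed(21)
  m <- random_cq(10, 3, seed = 21)
  m <- cbind(m, g04 = m[, "g01"] + 2.5)  # exact constant offset to g01
  res <- genorm(m)
  final_pair <- names(res$ranks)[res$ranks == 1L]
  expect_setequal(final_pair, c("g01", "g04"))
  expect_equal(unname(res$values[final_pair]), c(0, 0), tolerance = 1e-12)
})

test_that("geNorm initial M equals the delta-Ct score at base 2", {
  m <- cbind(A = c(20, 21, 20.5), B = c(25, 26, 25.5), C = c(30, 31, 30.4))
  res <- genorm(m)
  expect_equal(round(unname(res$initial_m), 4), c(0.0289, 0.0289, 0.0577))
  expect_equal(res$initial_m, delta_ct_stability(m)$values, tolerance = 1e-12)
})

test_that("geNorm reports exclusion-step M, shared rank 1 and a V series", {
  m <- random_cq(20, 6, seed = 8)
  res <- genorm(m)
  expect_equal(sort(unname(res$ranks)), c(1L, 1L, 3L, 4L, 5L, 6L))
  expect_equal(length(res$trace), 4)  # G - 2 exclusions
  expect_equal(res$v_series$n, 2:5)
  expect_true(all(res$v_series$v >= 0))
  # the excluded gene at each step had the worst remaining M
  expect_equal(res$trace[[1L]], names(which.max(res$initial_m)))
  expect_error(genorm(m[, 1:2]), "at least 3 genes")
})

test_that("NormFinder is exact on noise-free additive data and recovers sigma", {
  # pure gene + sample structure, zero epsilon -> all stability values 0
  set.seed(5)
  alpha <- c(22, 25, 27, 30)
  beta <- rnorm(15)
  m0 <- outer(beta, rep(1, 4)) + outer(rep(1, 15), alpha)
  colnames(m0) <- paste0("g", 1:4)
  expect_equal(unname(normfinder_stability(m0)$values), rep(0, 4),
               tolerance = 1e-10)

  # one noisy gene among quiet ones: sigma-hat near truth, worst rank
  sigma <- c(0.5, rep(0.1, 7))
  set.seed(33)
  n <- 1000
  eps <- matrix(rnorm(n * 8), n, 8) %*% diag(sigma)
  m <- 26 + outer(rnorm(n, 0, 0.7), rep(1, 8)) + eps
  colnames(m) <- paste0("g", 1:8)
  res <- normfinder_stability(m)
  expect_equal(unname(res$values[1]), 0.5, tolerance = 0.05)  # within 10%
  expect_equal(unname(res$ranks[1]), 8L)
  expect_error(normfinder_stability(m[, 1:2]), "at least 3 genes")
})

test_that("NormFinder with condition groups pools within-group variances", {
  set.seed(44)
  m <- random_cq(24, 5, seed = 44)
  groups <- rep(c("healthy", "inflamed"), each = 12)
  res <- normfinder_stability(m, groups = groups)
  expect_equal(length(res$values), 5)
  expect_true(all(res$values >= 0))
  expect_error(normfinder_stability(m, groups = c("a", rep("b", 23))),
               "at least 2 samples")
})

test_that("BestKeeper dispersion, MAD option and index correlations", {
  m <- cbind(gA = c(20, 21, 22), gB = c(20, 20, 20), gC = c(25, 26, 25))
  res <- bestkeeper(m)
  expect_equal(unname(res$values["gA"]), 1.000, tolerance = 1e-12)
  expect_equal(unname(res$values["gB"]), 0)
  expect_equal(unname(res$ranks["gB"]), 1L)
  mad <- bestkeeper(m, dispersion = "mad")
  expect_equal(unname(mad$values["gA"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(res$index), exp(rowMeans(log(m))), tolerance = 1e-12)
  expect_true(is.na(res$index_correlation[["gB"]]))  # zero-variance gene
  expect_equal(unname(res$index_correlation["gA"]),
               cor(m[, "gA"], exp(rowMeans(log(m)))))
})

test_that("sample-wise Cq shifts are invisible to relative-quantity methods only", {
  m <- random_cq(15, 6, seed = 12)
  shifted <- m
  shifted[4, ] <- shifted[4, ] + 1.8  # one sample loaded more RNA
  expect_equal(delta_ct_stability(shifted)$values, delta_ct_stability(m)$values,
               tolerance = 1e-12)
  expect_equal(genorm(shifted)$values, genorm(m)$values, tolerance = 1e-12)
  expect_equal(normfinder_stability(shifted)$values,
               normfinder_stability(m)$values, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(bestkeeper(shifted)$values,
                                bestkeeper(m)$values)))
})

test_that("stability values are invariant to gene and sample permutations", {
  m <- random_cq(12, 5, seed = 19)
  set.seed(19)
  pg <- sample(ncol(m))
  ps <- sample(nrow(m))
  perm <- m[ps, pg]
  for (fn in list(delta_ct_stability, genorm, normfinder_stability, bestkeeper)) {
    a <- fn(m)$values
    b <- fn(perm)$values
    expect_equal(b[names(a)], a, tolerance = 1e-10)
  }
})

test_that("all four algorithms worsen monotonically with iid noise", {
  sigmas <- c(0.1, 0.4, 1.0)
  mean_value <- function(sigma, fn, seed) {
    set.seed(seed)
    m <- 26 + matrix(rnorm(40 * 6, sd = sigma), 40, 6)
    colnames(m) <- paste0("g", 1:6)
    mean(fn(m)$values)
  }
  for (fn in list(delta_ct_stability, genorm, normfinder_stability, bestkeeper)) {
    vals <- vapply(sigmas, mean_value, numeric(1), fn = fn, seed = 77)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("missing cells are refused with advice to drop incomplete samples", {
  m <- random_cq(6, 4, seed = 2)
  m[3, 2] <- NA
  expect_error(delta_ct_stability(m), "drop incomplete samples")
  expect_error(genorm(m), "drop incomplete samples")
  expect_error(normfinder_stability(m), "drop incomplete samples")
  expect_error(bestkeeper(m), "drop incomplete samples")
})
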