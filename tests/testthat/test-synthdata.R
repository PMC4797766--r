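test_that("generation is byte-identical for a repeated seed", {
  truth <- synthetic_truth(seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cq_dataset(truth, n_samples = 20, write_dir = d1)
  generate_cq_dataset(truth, n_samples = 20, write_dir = d2)
  for (f in c("cq_wide.csv", "cq_long.csv", "curves.csv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("the generative model separates gene noise from sample shifts", {
  # sigma = 0: only the shared shift remains; relative-quantity methods see
  # nothing, BestKeeper sees tau
  truth <- synthetic_truth(sigma = rep(0, 13), tau = 0.5, seed = 10)
  sim <- generate_cq_dataset(truth, n_samples = 200)
  m <- sim$matrix
  expect_lt(max(genorm(m)$values), 1e-10)
  expect_lt(max(delta_ct_stability(m)$values), 1e-10)
  expect_lt(max(normfinder_stability(m)$values), 1e-6)
  bk <- bestkeeper(m)$values
  expect_equal(unname(mean(bk)), 0.5, tolerance = 0.15)
})

test_that("sample metadata follows the study design proportions", {
  sim <- generate_cq_dataset(synthetic_truth(seed = 3), n_samples = 60)
  meta <- sample_meta(sim$matrix)
  tab <- table(meta$condition)
  expect_equal(unname(tab[c("healthy", "inflammation", "skin_lesion",
                            "internal_disease")]),
               c(30L, 6L, 9L, 15L), ignore_attr = TRUE)
  expect_equal(length(unique(meta$animal_id)), 4)
  expect_equal(nrow(sim$replicates), 60 * 13 * 3)
})

test_that("generate -> collapse -> correct -> rank runs clean at outlier rate 0", {
  truth <- synthetic_truth(seed = 9, replicate_sd = 0.1)
  dir <- withr::local_tempdir()
  sim <- generate_cq_dataset(truth, n_samples = 30, write_dir = dir)
  reps <- read_cq_table(file.path(dir, "cq_long.csv"))
  collapsed <- collapse_replicates(reps)
  expect_equal(nrow(attr(collapsed, "flagged")), 0)
  expect_false(anyNA(as.matrix(collapsed)))
  eff <- data.frame(gene = truth$genes,
                    efficiency_percent = unname(truth$efficiency))
  corrected <- correct_cq(collapsed, eff)
  expect_no_warning(fit <- ref_stability(corrected))
  expect_equal(nrow(fit$ranking), 13)
})

test_that("outlier replicates inflate the triplicate SD and get flagged", {
  truth <- synthetic_truth(seed = 8, replicate_sd = 0.05, outlier_rate = 0.1)
  sim <- generate_cq_dataset(truth, n_samples = 40)
  collapsed <- collapse_replicates(sim$replicates)
  expect_gt(nrow(attr(collapsed, "flagged")), 0)
})

test_that("noisier genes earn worse stability values in all four algorithms", {
  base <- synthetic_truth(seed = 15)
  noisy_sigma <- base$sigma
  noisy_sigma["GAPDH"] <- 2.0  # was mid-pack; make it the worst
  noisy <- synthetic_truth(sigma = noisy_sigma, seed = 15)
  m_base <- generate_cq_dataset(base, n_samples = 500)$matrix
  m_noisy <- generate_cq_dataset(noisy, n_samples = 500)$matrix
  for (fn in list(delta_ct_stability, genorm, normfinder_stability, bestkeeper))
    expect_gt(fn(m_noisy)$values[["GAPDH"]], fn(m_base)$values[["GAPDH"]])
})

test_that("condition-regulated pseudo-housekeepers sink in the ranking", {
  G <- 13
  effects <- matrix(0, 4, G,
                    dimnames = list(c("healthy", "inflammation", "skin_lesion",
                                      "internal_disease"), NULL))
  effects[c("inflammation", "internal_disease"), 3] <- 2  # GAPDH regulated
  truth <- synthetic_truth(sigma = rep(0.2, G), condition_effects = effects,
                           seed = 23)
  sim <- generate_cq_dataset(truth, n_samples = 200)
  fit <- ref_stability(sim$matrix)
  reg_rank <- fit$ranking$final_rank[fit$ranking$gene == "GAPDH"]
  expect_gt(reg_rank, G / 2)
})

test_that("dilution series round-trip through the standard-curve fit", {
  ideal <- generate_dilution_series("x", true_efficiency = 100)
  fit <- fit_standard_curve(ideal)
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(fit$efficiency_percent, 100, tolerance = 1e-6)

  pgk1 <- generate_dilution_series("PGK1", true_efficiency = 95.47)
  expect_equal(fit_standard_curve(pgk1)$efficiency_percent, 95.47,
               tolerance = 1e-4)

  recovered <- vapply(1:100, function(s) {
    pts <- generate_dilution_series("x", 95, noise_sd = 0.05, seed = s)
    fit_standard_curve(pts)$efficiency_percent
  }, numeric(1))
  expect_equal(mean(recovered), 95, tolerance = 95 * 0.01)
})

test_that("invalid generator parameters are rejected", {
  expect_error(synthetic_truth(tau = -1), "non-negative")
  expect_error(synthetic_truth(outlier_rate = 1.5), "outlier_rate")
  expect_error(synthetic_truth(efficiency = rep(-120, 13)), "-100")
  expect_error(synthetic_truth(sigma = rep(0.1, 3)), "length")
  expect_error(generate_dilution_series("x", 100, levels = 2), "3 dilution")
  expect_error(generate_dilution_series("x", 100, step = 1), "step")
})
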