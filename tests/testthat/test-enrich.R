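# shared small calibration fixture: four exact input levels, outputs drawn
# from the generalized Poisson null (mean = input, lambda = 0.25)
null_fixture <- withr::with_seed(2024, {
  input <- rep(c(20L, 40L, 80L, 160L), each = 750)
  output <- rgenpois(length(input), theta = input * 0.75, lam = 0.25)
  list(input = input, output = output)
})

test_that("normalize_reads caps, passes through, and excludes per the rules", {
  counts <- withr::with_seed(1, as.integer(rmultinom(1, 2000000, rep(1, 2000))))
  nr <- normalize_reads(counts, seed = 7)
  expect_false(nr$excluded)
  expect_identical(sum(nr$counts), 1250000L)
  expect_true(all(nr$counts <= counts))
  # deterministic per seed
  nr2 <- normalize_reads(counts, seed = 7)
  expect_identical(nr$counts, nr2$counts)
  expect_false(identical(normalize_reads(counts, seed = 8)$counts, nr$counts))
  mid <- normalize_reads(rep(450L, 2000))      # total 900,000
  expect_false(mid$excluded)
  expect_identical(mid$counts, rep(450L, 2000))
  low <- normalize_reads(rep(350L, 2000))      # total 700,000
  expect_true(low$excluded)
  expect_error(normalize_reads(c(-1L, 5L)), "non-negative")
})

test_that("null model fit recovers the generating parameters per bin", {
  m <- fit_null_model(null_fixture$input, null_fixture$output,
                      min_bin_obs = 200, refit = FALSE)
  pars <- null_params_at(m, c(20L, 40L, 80L, 160L))
  expect_equal(pars$theta, c(20, 40, 80, 160) * 0.75, tolerance = 0.06)
  expect_true(all(abs(pars$lam - 0.25) < 0.06))
  # interpolated theta non-decreasing in input
  grid <- null_params_at(m, 10:300)
  expect_true(all(diff(grid$theta) >= 0))
})

test_that("score_peptides equals the brute-force tail sum and is monotone", {
  m <- fit_null_model(null_fixture$input, null_fixture$output,
                      min_bin_obs = 200, refit = FALSE)
  idx <- withr::with_seed(5, sample(length(null_fixture$input), 100))
  # subsampling can leave inputs outside the fitted bin range: the clamp
  # warning is the documented behaviour
  p <- suppressWarnings(
    score_peptides(null_fixture$input[idx], null_fixture$output[idx], m))
  pars <- null_params_at(m, null_fixture$input[idx])
  brute <- vapply(seq_along(idx), function(i) {
    k <- null_fixture$output[idx[i]]
    if (k == 0) return(1)
    1 - sum(oracle_gp_pmf(0:(k - 1), pars$theta[i], pars$lam[i]))
  }, numeric(1))
  expect_equal(p, brute, tolerance = 1e-12)
  expect_true(all(p > 0 & p <= 1))
  # p = 1 at output 0; tiny p far above the null mean
  expect_identical(score_peptides(80L, 0L, m), 1)
  expect_lt(score_peptides(80L, 80L * 50L, m), 1e-6)
  # monotone non-increasing in output at fixed input
  ps <- score_peptides(rep(80L, 61), seq(40L, 160L, by = 2L), m)
  expect_true(all(diff(ps) <= 0))
})

test_that("Bonferroni seropositivity follows the adjusted-p rule", {
  cl <- call_seropositive(c(1e-9, 0.04, 0.5), m = 344000)
  expect_identical(cl$seropositive, c(TRUE, FALSE, FALSE))
  expect_equal(cl$p_adj[1], 1e-9 * 344000)
  expect_identical(call_seropositive(rep(1, 5), m = 10)$seropositive,
                   rep(FALSE, 5))
  empty <- call_seropositive(numeric(0), m = 0)
  expect_identical(nrow(empty), 0L)
  expect_error(call_seropositive(0.5, m = 2, alpha = 1.5), "alpha")
  expect_error(call_seropositive(c(0.1, 0.2), m = 1), "m must")
})

test_that("fold change applies the seropositivity and 25-input-read gates", {
  expect_equal(compute_fold_change(50, 500, TRUE), 10)
  expect_equal(compute_fold_change(24, 500, TRUE), 0)
  expect_equal(compute_fold_change(1000, 9000, FALSE), 0)
})

test_that("sample QC excludes below 200 enriched peptides, strict inequality", {
  calls <- data.frame(
    sample_id = rep(c("a", "b", "c"), each = 250),
    seropositive = c(rep(TRUE, 199), rep(FALSE, 51),    # a: 199
                     rep(TRUE, 200), rep(FALSE, 50),    # b: 200
                     rep(TRUE, 250)))                   # c: 250
  kept <- qc_samples(calls, min_enriched = 200)
  expect_identical(sort(as.character(kept)), c("b", "c"))
  expect_identical(attr(kept, "excluded"), "a")
  empty <- qc_samples(calls[0, ])
  expect_length(empty, 0)
})

test_that("type-I error is controlled on a null matrix", {
  # 12 null samples x 1,500 peptides: no cell should clear Bonferroni often
  sim <- withr::with_seed(31, {
    input <- matrix(rep(as.integer(rmultinom(1, 80000, rlnorm(1500))), 12),
                    1500, 12, dimnames = list(sprintf("p%04d", 1:1500),
                                              sprintf("s%02d", 1:12)))
    output <- matrix(rgenpois(length(input), theta = input * 0.75, lam = 0.25),
                     1500, 12, dimnames = dimnames(input))
    list(input = input, output = output)
  })
  calls <- enrichment_calls(sim$input, sim$output, min_bin_obs = 150)
  # expected false-positive cells per sample is bounded by alpha under
  # Bonferroni, so 12 samples should yield ~0.6 FP cells; 4 is the 99.9%
  # Poisson bound (the full 200-sample family-wise criterion is in
  # test-acceptance.R)
  expect_lte(sum(calls$seropositive), 4)
})
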