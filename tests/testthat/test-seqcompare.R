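test_that("alignment identity matches hand-checked examples", {
  a <- align("ACDEFG", "ACDEFG", mode = "global")
  expect_equal(a$identity_pct, 100)
  expect_identical(a$identities, 6L)
  b <- align("ACDEFG", "ACDQFG", mode = "global")
  expect_identical(b$identities, 5L)
  expect_identical(b$aligned_length, 6L)
  expect_equal(b$identity_pct, 100 * 5 / 6, tolerance = 1e-10)
  expect_error(align("ACDX1", "ACD"), "non-standard")
  expect_error(align("", "ACD"), "non-empty")
})

test_that("alignment score/identity are symmetric; self-identity is 100", {
  seqs <- withr::with_seed(8, replicate(15, random_peptide(sample(5:40, 1))))
  for (i in 1:7) {
    q <- seqs[2 * i - 1]; t <- seqs[2 * i]
    expect_equal(align(q, t)$score, align(t, q)$score, tolerance = 1e-10)
    expect_equal(identity_pct(q, t), identity_pct(t, q), tolerance = 1e-10)
    expect_equal(identity_pct(q, q), 100)
  }
})

test_that("DP alignment score equals the exhaustive enumeration oracle", {
  withr::with_seed(17, {
    for (i in 1:30) {
      q <- random_peptide(sample(2:7, 1))
      t <- random_peptide(sample(2:7, 1))
      expect_equal(align(q, t, mode = "global")$score,
                   oracle_align_score(q, t, "global"),
                   tolerance = 1e-9, label = paste(q, t, "global"))
      loc <- align(q, t, mode = "local")$score
      expect_equal(max(loc, 0), max(oracle_align_score(q, t, "local"), 0),
                   tolerance = 1e-9, label = paste(q, t, "local"))
    }
  })
})

tmpl <- flagellin_template()

test_that("annotate_domains recovers constructed domain footprints", {
  withr::with_seed(23, {
    nref <- substr(tmpl$n_domain_seq, 1, 130)
    cref <- tmpl$c_domain_seq
    prot <- paste0(nref, random_peptide(200), cref)
    ann <- annotate_domains(prot, c(n = nref), c(c = cref))
    expect_true(abs(ann$n_domain[1] - 1) <= 2 && abs(ann$n_domain[2] - 130) <= 2)
    expect_true(abs(ann$c_domain[1] - 331) <= 2 && abs(ann$c_domain[2] - 415) <= 2)
    expect_identical(ann$n_source_ref, "n")
    # random protein at high min_score: both absent (absence is legal)
    r <- annotate_domains(random_peptide(300), c(n = nref), c(c = cref),
                          min_score = 1e5)
    expect_null(r$n_domain); expect_null(r$c_domain)
    # protein consisting of the C reference alone
    co <- annotate_domains(cref, c(n = nref), c(c = cref))
    expect_null(co$n_domain)
    expect_identical(co$c_domain, c(1L, nchar(cref)))
    expect_error(annotate_domains(prot, character(0), c(c = cref)),
                 "non-empty")
  })
})

test_that("relative_start follows the protein-length convention", {
  expect_equal(relative_start(1, 500), 0.002)
  expect_equal(relative_start(500, 500), 1)
  expect_equal(relative_start(351, 415), 351 / 415, tolerance = 1e-12)
  expect_error(relative_start(0, 10), "within")
  expect_error(relative_start(11, 10), "within")
})

test_that("domain_position_summary partitions boundaries into fractions", {
  mk <- function(len, n_span) {
    structure(list(protein_id = "x", protein_length = len,
                   n_domain = n_span, c_domain = NULL,
                   rel_n_start = n_span[1] / len, rel_n_end = n_span[2] / len,
                   rel_c_start = NULL, rel_c_end = NULL),
              class = "domain_annotation")
  }
  all_first <- list(mk(400, c(1L, 130L)), mk(500, c(1L, 140L)))
  s <- domain_position_summary(all_first, "n_start",
                               bins = list(c(0, 0.05)))
  expect_equal(s$fraction, 1)
  mixed <- list(mk(400, c(1L, 130L)), mk(400, c(100L, 230L)))
  s2 <- domain_position_summary(mixed, "n_start",
                                bins = list(c(0, 0.05), c(0.05, 1)))
  expect_equal(s2$fraction, c(0.5, 0.5))
  expect_equal(sum(s2$fraction), 1)
  expect_error(domain_position_summary(list(), "n_start"), "no annotation")
})

test_that("prevalence ratios apply the half-subject continuity correction", {
  sero <- matrix(FALSE, 3, 200,
                 dimnames = list(c("p1", "p2", "p3"),
                                 sprintf("s%03d", 1:200)))
  groups <- setNames(rep(c("case", "control"), each = 100), colnames(sero))
  sero["p1", 1:10] <- TRUE; sero["p1", 101:102] <- TRUE  # 10/100 vs 2/100
  sero["p2", 1:20] <- TRUE                               # 20/100 vs 0/100
  sero["p3", c(1:5, 101:105)] <- TRUE                    # identical groups
  pr <- prevalence_ratio(sero, groups)
  expect_equal(pr$prevalence_ratio[pr$peptide_id == "p1"], 5)
  expect_equal(pr$prevalence_ratio[pr$peptide_id == "p2"], 40)
  expect_equal(pr$prevalence_ratio[pr$peptide_id == "p3"], 1)
  flt <- prevalence_ratio(sero, groups, min_prevalence = 0.05, min_ratio = 2.5)
  expect_identical(flt$peptide_id, c("p1", "p2"))
  expect_error(prevalence_ratio(sero, setNames(rep("x", 200), colnames(sero))),
               "case or control")
})
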