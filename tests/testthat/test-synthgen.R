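tmpl <- flagellin_template()

zero_rates <- list(stimulator = c(background = 0, motif = 0, allosteric = 0),
                   silent = c(background = 0, motif = 0, allosteric = 0),
                   evader = c(background = 0, motif = 0.5, allosteric = 0))

test_that("zero-mutation stimulators reproduce the template domains", {
  pan <- generate_reference_panel(tmpl, 2, mutation_rates = zero_rates,
                                  seed = 5)
  st <- pan[pan$true_class == "stimulator", ][1, ]
  expect_identical(substr(st$sequence, st$n_start, st$n_end),
                   tmpl$n_domain_seq)
  expect_identical(substr(st$sequence, st$c_start, st$c_end),
                   tmpl$c_domain_seq)
  # domain truth reconstructs the sequence: N + HV + C
  expect_identical(st$n_start, 1L)
  expect_identical(st$c_end, nchar(st$sequence))
  expect_lt(st$n_end, st$c_start)
})

test_that("evader TLR5 motifs diverge more than any stimulator motif", {
  pan <- generate_reference_panel(tmpl, 10, mutation_rates = zero_rates,
                                  seed = 6)
  mspan <- tmpl$tlr5_motif_span
  motif_of <- function(row) substr(row$sequence,
                                   row$n_start + mspan[1] - 1L,
                                   row$n_start + mspan[2] - 1L)
  tmpl_motif <- substr(tmpl$n_domain_seq, mspan[1], mspan[2])
  d_stim <- vapply(which(pan$true_class == "stimulator"), function(i)
    hamming_str(motif_of(pan[i, ]), tmpl_motif), numeric(1))
  d_eva <- vapply(which(pan$true_class == "evader"), function(i)
    hamming_str(motif_of(pan[i, ]), tmpl_motif), numeric(1))
  expect_true(all(d_eva > max(d_stim)))
})

test_that("class separability holds at default mutation rates", {
  pan <- generate_reference_panel(tmpl, 20, seed = 7)
  mspan <- tmpl$tlr5_motif_span
  tmpl_motif <- substr(tmpl$n_domain_seq, mspan[1], mspan[2])
  ident <- vapply(seq_len(nrow(pan)), function(i) {
    m <- substr(pan$sequence[i], mspan[1], mspan[2])
    1 - hamming_str(m, tmpl_motif) / nchar(tmpl_motif)
  }, numeric(1))
  by_class <- tapply(ident, pan$true_class, mean)
  expect_gte(by_class["stimulator"], by_class["silent"])
  expect_gt(by_class["silent"], by_class["evader"])
})

test_that("panel generation is deterministic per seed and validates rates", {
  p1 <- generate_reference_panel(tmpl, 5, seed = 42)
  p2 <- generate_reference_panel(tmpl, 5, seed = 42)
  expect_identical(p1, p2)
  expect_false(identical(p1$sequence,
                         generate_reference_panel(tmpl, 5, seed = 43)$sequence))
  bad <- default_mutation_rates(); bad$evader["motif"] <- 1.5
  expect_error(generate_reference_panel(tmpl, 2, mutation_rates = bad),
               "\\[0,1\\]")
  expect_error(generate_reference_panel(tmpl, 0), "n_per_class")
})

test_that("library annotation carries flagellin flags and domain overlaps", {
  pan <- generate_reference_panel(tmpl, 3, seed = 8)
  lib <- generate_library(pan, n_nonflagellin = 10, seed = 9)
  ann <- lib$annotation
  expect_true(all(ann$parent_class[ann$flagellin] %in%
                    c("stimulator", "silent", "evader")))
  expect_true(all(ann$parent_class[!ann$flagellin] == "none"))
  # first tile of each flagellin lies fully inside the true N domain
  first <- ann[ann$flagellin & ann$start == 1L & ann$end == 64L, ]
  expect_true(all(first$n_overlap_frac == 1))
  # no decoys: all tiles flagellin
  lib0 <- generate_library(pan, n_nonflagellin = 0, seed = 9)
  expect_true(all(lib0$annotation$flagellin))
  expect_error(generate_library(pan[0, ], 5), "non-empty")
  # determinism
  expect_identical(lib$annotation,
                   generate_library(pan, n_nonflagellin = 10, seed = 9)$annotation)
})

small_lib <- local({
  pan <- generate_reference_panel(tmpl, 4, seed = 10)
  generate_library(pan, n_nonflagellin = 10, seed = 10)
})

test_that("simulate_counts respects the planted-truth contract", {
  # zero planted sets -> truth all false
  d0 <- cohort_design(n_cases = 5, n_controls = 5, seed = 3)
  s0 <- simulate_counts(small_lib, d0, total_reads_per_sample = 20000)
  expect_false(any(s0$truth_bound))
  expect_identical(colSums(s0$input_counts), rep(20000, 10),
                   ignore_attr = TRUE)
  # determinism
  s0b <- simulate_counts(small_lib, d0, total_reads_per_sample = 20000)
  expect_identical(s0$output_counts, s0b$output_counts)
  expect_identical(s0$metadata, s0b$metadata)
  # truth_bound only within planted sets
  set <- small_lib$annotation$peptide_id[1:10]
  d1 <- cohort_design(20, 20, planted_peptide_sets = list(sig = set),
                      case_binding_prevalence = c(sig = 0.5),
                      control_binding_prevalence = c(sig = 0), seed = 4)
  s1 <- simulate_counts(small_lib, d1, total_reads_per_sample = 20000)
  bound_peps <- rownames(s1$truth_bound)[rowSums(s1$truth_bound) > 0]
  expect_true(all(bound_peps %in% set))
  ctrl <- s1$metadata$sample_id[s1$metadata$group == "control"]
  expect_false(any(s1$truth_bound[, ctrl]))
  # parameter validation
  expect_error(simulate_counts(small_lib, d0, gp_dispersion = 1),
               "not normalizable")
  expect_error(simulate_counts(small_lib, d0, total_reads_per_sample = 0),
               "> 0")
  expect_error(cohort_design(5, 5, planted_peptide_sets = list(s = set),
                             case_binding_prevalence = c(s = 1.2),
                             control_binding_prevalence = c(s = 0)),
               "\\[0,1\\]")
  expect_error(cohort_design(5, 5, enrichment_factor_range = c(0.5, 2)),
               "> 1")
})

test_that("a fixed enrichment factor multiplies the mean output accordingly", {
  # enrichment factor 50 at input 100: bound-cell sample mean ~ 50x unbound
  lam <- 0.25
  draws_unbound <- withr::with_seed(61,
    rgenpois(1000, theta = 100 * (1 - lam), lam = lam))
  draws_bound <- withr::with_seed(62,
    rgenpois(1000, theta = 100 * 50 * (1 - lam), lam = lam))
  expect_equal(mean(draws_bound) / mean(draws_unbound), 50, tolerance = 0.05)
})

test_that("generated cohorts are age/sex balanced in >= 90% of seeds", {
  passes <- vapply(1:30, function(s) {
    d <- cohort_design(n_cases = 40, n_controls = 40, seed = s)
    sim <- simulate_counts(small_lib, d, total_reads_per_sample = 1000)
    cohort_balance_check(sim$metadata)$balanced
  }, logical(1))
  expect_gte(mean(passes), 0.9)
})

test_that("write_simulation emits the documented text formats", {
  dir <- withr::local_tempdir()
  d0 <- cohort_design(3, 3, seed = 3)
  s0 <- simulate_counts(small_lib, d0, total_reads_per_sample = 5000)
  write_simulation(s0, small_lib, dir)
  expect_true(all(file.exists(file.path(dir,
    c("peptides.fasta", "input.tsv", "output.tsv", "metadata.tsv",
      "truth.tsv", "annotation.tsv", "manifest.yaml", "manifest.json")))))
  inp <- read_count_matrix(file.path(dir, "input.tsv"))
  expect_identical(inp, s0$input_counts)
  fa <- Biostrings::readAAStringSet(file.path(dir, "peptides.fasta"))
  expect_identical(length(fa), nrow(small_lib$annotation))
  expect_match(names(fa)[1], "\\|1\\|64\\|flagellin=1$")
})
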