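# End-to-end orchestration: simulate (optional) -> normalize/score/call/QC ->
# burden and cohort tests -> prevalence ratios and relative positions ->
# domain annotation -> class-similarity profiling -> statistics -> report.

#' Pipeline configuration
#'
#' Defaults encode the desk-scale synthetic world: 60 flagellins (20/class),
#' 200 decoy proteins (~3,000 peptides), 40 cases + 40 controls at 200,000
#' reads/sample. \code{min_enriched} defaults to 0 here because the published
#' threshold (200, for a 344,000-peptide library) would exclude every sample
#' from a 3,000-peptide library.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param mimic planted signature set: \code{"cd"} or \code{"mecfs"}.
#' @param n_per_class,n_nonflagellin,n_cases,n_controls,total_reads_per_sample,gp_dispersion
#'   generator geometry.
#' @param alpha,min_input,min_enriched,min_bin_obs enrichment-calling knobs.
#' @param min_prevalence,min_ratio overrepresentation filters for bound
#'   peptides (prevalence > 5\% in either group, ratio > 2.5).
#' @param n_reference_per_class size of the classification reference panel.
#' @param out_dir optional output directory (TSV/JSON written when set).
#' @param write_plots write position/identity PNGs into \code{out_dir}.
#' @return config list.
#' @export
pipeline_config <- function(seed = 1L, mimic = c("cd", "mecfs"),
                            n_per_class = 20, n_nonflagellin = 200,
                            n_cases = 40, n_controls = 40,
                            total_reads_per_sample = 200000,
                            gp_dispersion = 0.25,
                            alpha = 0.05, min_input = 25, min_enriched = 0,
                            min_bin_obs = 200,
                            min_prevalence = 0.05, min_ratio = 2.5,
                            n_reference_per_class = 5,
                            out_dir = NULL, write_plots = FALSE) {
  list(seed = as.integer(seed), mimic = match.arg(mimic),
       n_per_class = n_per_class, n_nonflagellin = n_nonflagellin,
       n_cases = n_cases, n_controls = n_controls,
       total_reads_per_sample = total_reads_per_sample,
       gp_dispersion = gp_dispersion, alpha = alpha, min_input = min_input,
       min_enriched = min_enriched, min_bin_obs = min_bin_obs,
       min_prevalence = min_prevalence, min_ratio = min_ratio,
       n_reference_per_class = n_reference_per_class,
       out_dir = out_dir, write_plots = write_plots)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic analysis pipeline
#'
#' Generates panel + library + cohort (per config), calls enrichment under the
#' generalized Poisson null, applies QC, computes per-sample anti-flagellin
#' burden and cohort balance, prevalence ratios and relative start positions
#' of overrepresented bound peptides, annotates N-/C-terminal domains of
#' antibody-bound flagellins, profiles class similarity (full-length, N, C
#' scopes; bound and unbound sets), and runs the class-contrast statistics.
#' Fully seeded; identical config implies an identical report.
#'
#' A pre-built \code{library} (and matching \code{design}) can be supplied to
#' share one peptide library across several cohort runs.
#'
#' @param config a \code{\link{pipeline_config}} list.
#' @param library optional pre-built \code{\link{generate_library}} object.
#' @param design optional pre-built \code{\link{cohort_design}}.
#' @return report list of class \code{phip_report}.
#' @export
run_pipeline <- function(config = pipeline_config(), library = NULL,
                         design = NULL) {
  cfg <- config
  template <- flagellin_template()

  if (is.null(library)) library <- pipeline_stage("synthesis", {
    panel <- generate_reference_panel(template, n_per_class = cfg$n_per_class,
                                      seed = child_seed(cfg$seed, 1))
    generate_library(panel, n_nonflagellin = cfg$n_nonflagellin,
                     seed = child_seed(cfg$seed, 2))
  })
  ann <- library$annotation

  if (is.null(design)) design <- pipeline_stage("design", {
    ctor <- if (cfg$mimic == "cd") cohort_design_cd else cohort_design_mecfs
    ctor(library, n_cases = cfg$n_cases, n_controls = cfg$n_controls,
         seed = child_seed(cfg$seed, 3))
  })

  sim <- pipeline_stage("simulate",
    simulate_counts(library, design,
                    total_reads_per_sample = cfg$total_reads_per_sample,
                    gp_dispersion = cfg$gp_dispersion))

  calls <- pipeline_stage("enrichment",
    enrichment_calls(sim$input_counts, sim$output_counts, alpha = cfg$alpha,
                     min_input = cfg$min_input,
                     min_bin_obs = cfg$min_bin_obs))

  retained <- pipeline_stage("qc", qc_samples(calls, cfg$min_enriched))
  calls <- calls[calls$sample_id %in% retained, , drop = FALSE]
  meta <- sim$metadata[sim$metadata$sample_id %in% retained, , drop = FALSE]
  groups <- setNames(meta$group, meta$sample_id)

  stats <- pipeline_stage("cohort-stats", {
    flags <- setNames(ann$flagellin, ann$peptide_id)
    burden <- suppressWarnings(flagellin_burden(calls, flags, groups))
    list(burden = burden,
         burden_test = wilcoxon_rank_sum(
           burden$flagellin_ratio[burden$group == "case"],
           burden$flagellin_ratio[burden$group == "control"]),
         balance = cohort_balance_check(meta))
  })

  sero <- seropositivity_matrix(calls)

  prevalence <- pipeline_stage("prevalence", {
    all_prev <- prevalence_ratio(sero, groups)
    over <- prevalence_ratio(sero, groups,
                             min_prevalence = cfg$min_prevalence,
                             min_ratio = cfg$min_ratio)
    over <- merge(over, ann[, c("peptide_id", "parent_id", "start", "end",
                                "flagellin", "parent_class",
                                "parent_length")], by = "peptide_id")
    over$rel_start <- relative_start(over$start, over$parent_length)
    list(all = all_prev, overrepresented = over)
  })

  bound_parents <- unique(
    prevalence$overrepresented$parent_id[prevalence$overrepresented$flagellin])
  sero_parent <- tapply(
    rowSums(sero)[ann$peptide_id[ann$flagellin]] > 0,
    ann$parent_id[ann$flagellin], any)
  unbound_parents <- names(sero_parent)[!sero_parent]

  domains <- pipeline_stage("domains", {
    c_silent <- paste0(
      substr(template$c_domain_seq, 1, template$c_allosteric_span[1] - 1),
      template$silent_allosteric_seq,
      substr(template$c_domain_seq, template$c_allosteric_span[2] + 1,
             nchar(template$c_domain_seq)))
    n_refs <- c(stim_n = template$n_domain_seq)
    c_refs <- c(stim_c = template$c_domain_seq, silent_c = c_silent)
    anns <- lapply(bound_parents, function(pid)
      annotate_domains(library$proteins[[pid]], n_refs, c_refs,
                       protein_id = pid))
    setNames(anns, bound_parents)
  })

  references <- pipeline_stage("references",
    generate_reference_panel(template,
                             n_per_class = cfg$n_reference_per_class,
                             seed = child_seed(cfg$seed, 4)))

  similarity <- pipeline_stage("similarity", {
    bound_seqs <- library$proteins[bound_parents]
    unbound_seqs <- library$proteins[unbound_parents]
    scopes <- c("full_length", "n_domain", "c_domain")
    profiles <- lapply(setNames(scopes, scopes), function(sc)
      suppressWarnings(profile_similarity_set(bound_seqs, references, sc,
                                              domains = domains)))
    tests <- lapply(profiles, function(pr) {
      if (is.null(pr) || length(unique(pr$query_id)) < 3L) return(NULL)
      list(paired = compare_class_similarity(pr, paired = TRUE),
           unpaired = compare_class_similarity(pr, paired = FALSE))
    })
    unbound_profiles <- if (length(unbound_seqs) >= 3)
      profile_similarity_set(unbound_seqs, references, "full_length")
    else NULL
    bound_unbound <- if (!is.null(unbound_profiles) &&
                         !is.null(profiles$full_length))
      bound_vs_unbound_contrast(profiles$full_length, unbound_profiles,
                                paired = FALSE)
    else NULL
    list(profiles = profiles, tests = tests,
         unbound_profiles = unbound_profiles, bound_unbound = bound_unbound)
  })

  report <- structure(list(
    config = cfg, library = library, design = design, simulation = sim,
    calls = calls, retained_samples = retained, stats = stats,
    prevalence = prevalence, bound_flagellins = bound_parents,
    unbound_flagellins = unbound_parents, domains = domains,
    references = references, similarity = similarity),
    class = "phip_report")

  if (!is.null(cfg$out_dir))
    pipeline_stage("write", write_report(report, cfg$out_dir))
  report
}

#' @export
print.phip_report <- function(x, ...) {
  cat(sprintf("PhIP-Seq pipeline report (%s mimic, seed %d)\n",
              x$config$mimic, x$config$seed))
  cat(sprintf("  samples retained: %d; seropositive calls: %d\n",
              length(x$retained_samples), sum(x$calls$seropositive)))
  cat(sprintf("  overrepresented peptides: %d (bound flagellins: %d)\n",
              nrow(x$prevalence$overrepresented),
              length(x$bound_flagellins)))
  cat(sprintf("  case vs control flagellin-burden Wilcoxon p = %.3g\n",
              x$stats$burden_test$p))
  invisible(x)
}

#' Case-group per-peptide seropositivity prevalence from a report
#'
#' @param report a \code{\link{run_pipeline}} report.
#' @param flagellin_only restrict to flagellin peptides.
#' @return named numeric vector (peptide id -> case prevalence).
#' @export
case_prevalence <- function(report, flagellin_only = TRUE) {
  prev <- report$prevalence$all
  if (flagellin_only) {
    ann <- report$library$annotation
    prev <- prev[prev$peptide_id %in% ann$peptide_id[ann$flagellin], ]
  }
  setNames(prev$prevalence_case, prev$peptide_id)
}

#' Write a pipeline report to disk
#'
#' TSV tables, a JSON summary, and (optionally) position/identity plots.
#'
#' @param report a \code{phip_report}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$calls, file.path(dir, "calls.tsv"))
  write_tsv(report$stats$burden, file.path(dir, "qc.tsv"))
  write_tsv(report$prevalence$all, file.path(dir, "prevalence.tsv"))
  write_tsv(report$prevalence$overrepresented, file.path(dir, "relpos.tsv"))
  dom <- do.call(rbind, lapply(report$domains, function(d)
    data.frame(protein_id = d$protein_id,
               n_start = d$n_domain[1] %||% NA,
               n_end = d$n_domain[2] %||% NA,
               c_start = d$c_domain[1] %||% NA,
               c_end = d$c_domain[2] %||% NA)))
  if (!is.null(dom)) write_tsv(dom, file.path(dir, "domains.tsv"))
  for (sc in names(report$similarity$profiles)) {
    pr <- report$similarity$profiles[[sc]]
    if (!is.null(pr))
      write_tsv(pr, file.path(dir, sprintf("similarity_%s.tsv", sc)))
  }
  summarise_test <- function(t)
    if (is.null(t)) NULL else list(statistic = t$statistic, p = t$p)
  tests_json <- lapply(report$similarity$tests, function(tt) {
    if (is.null(tt)) return(NULL)
    list(friedman = summarise_test(tt$paired$omnibus),
         kruskal = summarise_test(tt$unpaired$omnibus),
         dunn = tt$unpaired$pairwise)
  })
  summary <- list(
    mimic = report$config$mimic, seed = report$config$seed,
    n_retained = length(report$retained_samples),
    burden_wilcoxon_p = report$stats$burden_test$p,
    balance_age_p = report$stats$balance$age$p,
    balance_sex_p = report$stats$balance$sex$p,
    n_overrepresented = nrow(report$prevalence$overrepresented),
    bound_flagellins = report$bound_flagellins,
    class_tests = tests_json)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- report$config
  write_manifest_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                      file.path(dir, "config.yaml"))
  if (isTRUE(report$config$write_plots)) {
    over <- report$prevalence$overrepresented
    if (nrow(over)) {
      grDevices::png(file.path(dir, "relative_positions.png"), 700, 500)
      graphics::hist(over$rel_start[over$flagellin], breaks = seq(0, 1, 0.05),
                     main = "Relative start positions of bound flagellin peptides",
                     xlab = "start / protein length", col = "grey70")
      grDevices::dev.off()
    }
    pr <- report$similarity$profiles$full_length
    if (!is.null(pr)) {
      grDevices::png(file.path(dir, "class_identity.png"), 700, 500)
      graphics::boxplot(identity_pct ~ class, data = pr,
                        main = "Identity of bound flagellins to reference classes",
                        ylab = "identity (%)")
      grDevices::dev.off()
    }
  }
  invisible(dir)
}
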