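# Synthetic-data generator: reference flagellin panels, peptide libraries,
# matched case/control cohorts, and PhIP-Seq count matrices with planted
# disease-like anti-flagellin binding.
#
# The generator's stated world (documented in the methods vignette):
#  - 60 flagellins (20 per class), ~200 non-flagellin proteins, ~3,000
#    peptides, 40 cases + 40 controls, 200,000 reads per sample;
#  - stimulators are near-template copies; silents conserve the TLR5 motif
#    but carry a coherent divergent lineage at the C-terminal allosteric
#    span; evaders heavily mutate the TLR5 motif and are globally more
#    divergent;
#  - bound peptide-by-sample cells multiply the generalized Poisson rate by
#    an enrichment factor drawn uniformly from [20, 100].

#' The synthetic flagellin template
#'
#' Loads the packaged hard-coded template (or a drop-in replacement FASTA in
#' the same three-record schema: N_DOMAIN, C_DOMAIN, C_ALLOSTERIC_SILENT).
#' Spans are 1-based inclusive within their domain sequences.
#'
#' @param path optional FASTA path.
#' @param tlr5_motif_span,hinge_span intervals within the N-domain sequence.
#' @param c_allosteric_span interval within the C-domain sequence.
#' @param hv_length_range integer pair: hypervariable-region length range.
#' @return object of class \code{flagellin_template}.
#' @export
flagellin_template <- function(path = NULL,
                               tlr5_motif_span = c(89L, 110L),
                               hinge_span = c(31L, 52L),
                               c_allosteric_span = c(30L, 64L),
                               hv_length_range = c(100L, 180L)) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_flagellin_template.fasta",
                        package = "phipflag")
  seqs <- read_fasta(path)
  names(seqs) <- sub(" .*", "", names(seqs))
  n_seq <- seqs[["N_DOMAIN"]]; c_seq <- seqs[["C_DOMAIN"]]
  silent_alt <- seqs[["C_ALLOSTERIC_SILENT"]]
  n_evader <- seqs[["N_EVADER_LINEAGE"]]
  c_evader <- seqs[["C_EVADER_LINEAGE"]]
  stopifnot(tlr5_motif_span[2] <= nchar(n_seq),
            hinge_span[2] <= nchar(n_seq),
            c_allosteric_span[2] <= nchar(c_seq),
            nchar(silent_alt) ==
              c_allosteric_span[2] - c_allosteric_span[1] + 1L,
            nchar(n_evader) == nchar(n_seq),
            nchar(c_evader) == nchar(c_seq),
            hv_length_range[1] <= hv_length_range[2])
  structure(list(n_domain_seq = n_seq, c_domain_seq = c_seq,
                 n_evader_seq = n_evader, c_evader_seq = c_evader,
                 tlr5_motif_span = as.integer(tlr5_motif_span),
                 hinge_span = as.integer(hinge_span),
                 c_allosteric_span = as.integer(c_allosteric_span),
                 hv_length_range = as.integer(hv_length_range),
                 silent_allosteric_seq = silent_alt,
                 id = "template"),
            class = "flagellin_template")
}

#' Default per-class, per-region substitution probabilities
#'
#' Background applies to every residue outside the motif/allosteric spans of
#' its domain; motif to the TLR5 motif span; allosteric to the C-terminal
#' allosteric span. Rates are divergences from the class's own ancestral
#' sequence: stimulators and silents descend from the template (silents with
#' the shared silent-lineage segment spliced into the allosteric span before
#' noise); evaders descend from the fixed evader-lineage domains, which are
#' themselves heavily diverged from the template at the TLR5 motif (~55%)
#' and moderately elsewhere (~25%), the way pathogen flagellins form their
#' own coherent clade.
#'
#' @return nested list \code{class -> c(background, motif, allosteric)}.
#' @export
default_mutation_rates <- function() {
  # motif conservation is strictly strongest in stimulators (0.01 < 0.03):
  # silents conserve the motif too but, like their background (0.05 vs
  # 0.02), drift slightly more, so the class ordering of motif identity is
  # structural rather than a sampling accident
  list(stimulator = c(background = 0.02, motif = 0.01, allosteric = 0.02),
       silent     = c(background = 0.05, motif = 0.03, allosteric = 0.05),
       evader     = c(background = 0.05, motif = 0.05, allosteric = 0.05))
}

mutate_span <- function(chars, span, rate) {
  idx <- span[1]:span[2]
  seg <- mutate_aa(paste(chars[idx], collapse = ""), rate)
  chars[idx] <- strsplit(seg, "")[[1]]
  chars
}

synth_one_flagellin <- function(template, class, rates) {
  n_ancestor <- if (class == "evader") template$n_evader_seq
                else template$n_domain_seq
  c_ancestor <- if (class == "evader") template$c_evader_seq
                else template$c_domain_seq
  n_chars <- strsplit(n_ancestor, "")[[1]]
  c_chars <- strsplit(c_ancestor, "")[[1]]
  mspan <- template$tlr5_motif_span
  aspan <- template$c_allosteric_span
  # N domain: background everywhere except motif; motif at its own rate
  bg_idx <- setdiff(seq_along(n_chars), mspan[1]:mspan[2])
  hit <- runif(length(bg_idx)) < rates["background"]
  n_chars[bg_idx[hit]] <- vapply(n_chars[bg_idx[hit]], function(a)
    sample(setdiff(AA_ALPHABET, a), 1L), character(1))
  n_chars <- mutate_span(n_chars, mspan, rates["motif"])
  # C domain
  if (class == "silent")
    c_chars[aspan[1]:aspan[2]] <-
      strsplit(template$silent_allosteric_seq, "")[[1]]
  bg_idx <- setdiff(seq_along(c_chars), aspan[1]:aspan[2])
  hit <- runif(length(bg_idx)) < rates["background"]
  c_chars[bg_idx[hit]] <- vapply(c_chars[bg_idx[hit]], function(a)
    sample(setdiff(AA_ALPHABET, a), 1L), character(1))
  c_chars <- mutate_span(c_chars, aspan, rates["allosteric"])
  hv_len <- sample(template$hv_length_range[1]:template$hv_length_range[2], 1L)
  n_seq <- paste(n_chars, collapse = "")
  c_seq <- paste(c_chars, collapse = "")
  seq <- paste0(n_seq, random_aa(hv_len), c_seq)
  list(sequence = seq,
       n_domain = c(1L, nchar(n_seq)),
       c_domain = c(nchar(seq) - nchar(c_seq) + 1L, nchar(seq)))
}

# TLR5 readouts consistent with class, relative to the PIM reference (= 1, 1)
class_readouts <- function(class) {
  switch(class,
         stimulator = c(binding = runif(1, 1.5, 4), activation = runif(1, 1.5, 4)),
         silent     = c(binding = runif(1, 1.5, 4), activation = runif(1, 0.05, 0.7)),
         evader     = c(binding = runif(1, 0.05, 0.7), activation = runif(1, 0.05, 0.7)))
}

#' Generate a synthetic reference flagellin panel
#'
#' Per class: stimulators are near-template copies; silents conserve the TLR5
#' motif and carry the shared silent lineage at the allosteric span; evaders
#' heavily mutate the TLR5 motif (and are globally more divergent). The
#' hypervariable region is drawn independently per flagellin. Every record
#' carries its true class, true domain coordinates, and TLR5
#' binding/activation readouts consistent with the class.
#'
#' @param template a \code{\link{flagellin_template}}.
#' @param n_per_class flagellins per class (default 20).
#' @param mutation_rates see \code{\link{default_mutation_rates}}.
#' @param seed integer seed.
#' @return data frame of class \code{flagellin_panel}: id, true_class,
#'   sequence, n_start, n_end, c_start, c_end, binding, activation.
#' @export
generate_reference_panel <- function(template = flagellin_template(),
                                     n_per_class = 20,
                                     mutation_rates = default_mutation_rates(),
                                     seed = 1L) {
  if (n_per_class < 1) stop_param("n_per_class must be >= 1")
  rates_ok <- vapply(mutation_rates, function(r)
    all(r >= 0) && all(r <= 1), logical(1))
  if (!all(rates_ok)) stop_param("mutation rates must be in [0,1]")
  prefix <- c(stimulator = "STIM", silent = "SIL", evader = "EVA")
  with_seed(seed, {
    rows <- lapply(names(mutation_rates), function(cl) {
      do.call(rbind, lapply(seq_len(n_per_class), function(i) {
        f <- synth_one_flagellin(template, cl, mutation_rates[[cl]])
        ro <- class_readouts(cl)
        data.frame(id = sprintf("%s%02d", prefix[[cl]], i),
                   true_class = cl, sequence = f$sequence,
                   n_start = f$n_domain[1], n_end = f$n_domain[2],
                   c_start = f$c_domain[1], c_end = f$c_domain[2],
                   binding = ro["binding"], activation = ro["activation"],
                   stringsAsFactors = FALSE, row.names = NULL)
      }))
    })
    out <- do.call(rbind, rows)
    class(out) <- c("flagellin_panel", "data.frame")
    out
  })
}

#' Generate a synthetic peptide library
#'
#' Tiles every panel flagellin and \code{n_nonflagellin} random proteins via
#' \code{\link{tile_protein}}, annotating each tile with its parent class,
#' flagellin status, overlap fractions against the true N/C domains, and a
#' per-peptide immunogenicity weight (probability that a signature-carrying
#' sample binds the peptide) shared by all cohorts simulated from this
#' library.
#'
#' @param panel a \code{\link{generate_reference_panel}} data frame.
#' @param n_nonflagellin number of non-flagellin decoy proteins (default 200).
#' @param tiling a \code{\link{tiling_params}} object.
#' @param seed integer seed.
#' @param nonflagellin_length_range length range for decoy proteins.
#' @param immunogenicity_range per-peptide binding probability range for
#'   planted peptides (uniform; default \code{c(0.6, 1)}).
#' @return object of class \code{phip_library}: \code{annotation} data frame,
#'   \code{proteins} named sequences, \code{panel}.
#' @export
generate_library <- function(panel, n_nonflagellin = 200,
                             tiling = tiling_params(), seed = 1L,
                             nonflagellin_length_range = c(100, 600),
                             immunogenicity_range = c(0.6, 1)) {
  if (!nrow(panel)) stop_param("panel must be non-empty")
  with_seed(seed, {
    decoys <- if (n_nonflagellin > 0) setNames(
      vapply(seq_len(n_nonflagellin), function(i)
        random_aa(sample(nonflagellin_length_range[1]:
                           nonflagellin_length_range[2], 1L)),
        character(1)),
      sprintf("NF%03d", seq_len(n_nonflagellin))) else character(0)
    proteins <- c(setNames(panel$sequence, panel$id), decoys)
    tiles <- do.call(rbind, lapply(names(proteins), function(pid)
      tile_protein(proteins[[pid]], tiling, parent_id = pid)))
    pi <- match(tiles$parent_id, panel$id)
    tile_len <- tiles$end - tiles$start + 1L
    n_ov <- ifelse(is.na(pi), 0L, interval_overlap(
      tiles$start, tiles$end, panel$n_start[pi], panel$n_end[pi]))
    c_ov <- ifelse(is.na(pi), 0L, interval_overlap(
      tiles$start, tiles$end, panel$c_start[pi], panel$c_end[pi]))
    ann <- data.frame(
      tiles,
      flagellin = !is.na(pi),
      parent_class = ifelse(is.na(pi), "none", panel$true_class[pi]),
      parent_length = nchar(proteins)[match(tiles$parent_id, names(proteins))],
      n_overlap_frac = n_ov / tile_len,
      c_overlap_frac = c_ov / tile_len,
      immunogenicity = runif(nrow(tiles), immunogenicity_range[1],
                             immunogenicity_range[2]),
      stringsAsFactors = FALSE)
    structure(list(annotation = ann, proteins = proteins, panel = panel),
              class = "phip_library")
  })
}

#' @export
print.phip_library <- function(x, ...) {
  cat(sprintf("synthetic PhIP-Seq library: %d peptides from %d proteins (%d flagellin peptides)\n",
              nrow(x$annotation), length(x$proteins),
              sum(x$annotation$flagellin)))
  invisible(x)
}

#' Cohort design
#'
#' @param n_cases,n_controls sample counts (> 0).
#' @param planted_peptide_sets named list of peptide-id vectors.
#' @param case_binding_prevalence,control_binding_prevalence named numeric
#'   vectors (one probability per signature) in \code{[0, 1]}.
#' @param enrichment_factor_range uniform range for the multiplicative
#'   enrichment of bound cells; both ends must be > 1.
#' @param age_group_distribution named weights over 5-year age bins.
#' @param sex_distribution female fraction.
#' @param seed integer seed used by \code{\link{simulate_counts}}.
#' @return object of class \code{cohort_design}.
#' @export
cohort_design <- function(n_cases = 40, n_controls = 40,
                          planted_peptide_sets = list(),
                          case_binding_prevalence = numeric(0),
                          control_binding_prevalence = numeric(0),
                          enrichment_factor_range = c(20, 100),
                          age_group_distribution = setNames(
                            rep(1 / 6, 6),
                            c("20-24", "25-29", "30-34", "35-39", "40-44", "45-49")),
                          sex_distribution = 0.6, seed = 1L) {
  if (n_cases <= 0 || n_controls <= 0) stop_param("cohort counts must be > 0")
  prev <- c(case_binding_prevalence, control_binding_prevalence)
  if (length(prev) && (any(prev < 0) || any(prev > 1)))
    stop_param("prevalences must be in [0,1]")
  if (any(enrichment_factor_range <= 1))
    stop_param("enrichment factors must be > 1")
  stopifnot(identical(sort(names(planted_peptide_sets)),
                      sort(names(case_binding_prevalence))),
            identical(sort(names(planted_peptide_sets)),
                      sort(names(control_binding_prevalence))))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 planted_peptide_sets = planted_peptide_sets,
                 case_binding_prevalence = case_binding_prevalence,
                 control_binding_prevalence = control_binding_prevalence,
                 enrichment_factor_range = enrichment_factor_range,
                 age_group_distribution = age_group_distribution,
                 sex_distribution = sex_distribution,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

planted_set <- function(ann, parents, region = c("n", "c"), min_frac = 0.5) {
  region <- match.arg(region)
  frac <- if (region == "n") ann$n_overlap_frac else ann$c_overlap_frac
  ann$peptide_id[ann$parent_id %in% parents & frac >= min_frac]
}

#' Disease-mimicking cohort designs
#'
#' \code{cohort_design_cd} plants the CD-like signature: N-terminal tiles of a
#' stimulator subset plus silents (shared with the ME/CFS mimic), C-terminal
#' tiles of all stimulators, and the small evader tile set at low prevalence.
#' \code{cohort_design_mecfs} plants N-terminal tiles only, plus the evader
#' tile set at higher prevalence than in the CD mimic.
#'
#' @param library a \code{\link{generate_library}} object.
#' @param n_cases,n_controls cohort sizes.
#' @param seed simulation seed.
#' @return a \code{\link{cohort_design}}.
#' @export
cohort_design_cd <- function(library, n_cases = 40, n_controls = 40,
                             seed = 1L) {
  ann <- library$annotation
  pan <- library$panel
  stim <- pan$id[pan$true_class == "stimulator"]
  sil <- pan$id[pan$true_class == "silent"]
  eva <- pan$id[pan$true_class == "evader"]
  sets <- list(
    nterm_shared = planted_set(ann, c(head(stim, 8), head(sil, 14)), "n"),
    cterm_cd = planted_set(ann, stim, "c"),
    evader_set = planted_set(ann, head(eva, 6), "n"))
  cohort_design(n_cases, n_controls, planted_peptide_sets = sets,
                case_binding_prevalence = c(nterm_shared = 0.2,
                                            cterm_cd = 0.2,
                                            evader_set = 0.08),
                control_binding_prevalence = c(nterm_shared = 0.02,
                                               cterm_cd = 0.02,
                                               evader_set = 0.02),
                seed = seed)
}

#' @rdname cohort_design_cd
#' @export
cohort_design_mecfs <- function(library, n_cases = 40, n_controls = 40,
                                seed = 1L) {
  ann <- library$annotation
  pan <- library$panel
  stim <- pan$id[pan$true_class == "stimulator"]
  sil <- pan$id[pan$true_class == "silent"]
  eva <- pan$id[pan$true_class == "evader"]
  sets <- list(
    nterm_shared = planted_set(ann, c(head(stim, 8), head(sil, 14)), "n"),
    evader_set = planted_set(ann, head(eva, 6), "n"))
  cohort_design(n_cases, n_controls, planted_peptide_sets = sets,
                case_binding_prevalence = c(nterm_shared = 0.2,
                                            evader_set = 0.2),
                control_binding_prevalence = c(nterm_shared = 0.02,
                                               evader_set = 0.02),
                seed = seed)
}

#' Simulate PhIP-Seq count matrices for a cohort
#'
#' Input counts per sample are multinomial over lognormal library abundances.
#' Output counts are generalized Poisson with mean equal to the input count
#' for unbound cells; for bound cells the mean is multiplied by an enrichment
#' factor drawn uniformly from the design's range (dispersion unchanged).
#' A sample carries a signature with the group's binding prevalence; a carrier
#' binds each peptide of the signature's set with that peptide's
#' immunogenicity weight.
#'
#' @param library a \code{\link{generate_library}} object.
#' @param design a \code{\link{cohort_design}}.
#' @param total_reads_per_sample reads per sample (default 200,000).
#' @param gp_dispersion generalized Poisson lambda in \code{[0, 1)}.
#' @return object of class \code{phip_simulation}: input_counts,
#'   output_counts, truth_bound (peptide x sample), metadata data frame.
#' @export
simulate_counts <- function(library, design,
                            total_reads_per_sample = 200000,
                            gp_dispersion = 0.25) {
  stopifnot(inherits(library, "phip_library"),
            inherits(design, "cohort_design"))
  if (gp_dispersion < 0 || gp_dispersion >= 1)
    stop_param("gp_dispersion must be in [0, 1): pmf not normalizable")
  if (total_reads_per_sample <= 0)
    stop_param("total_reads_per_sample must be > 0")
  ann <- library$annotation
  n_pep <- nrow(ann)
  n_samp <- design$n_cases + design$n_controls
  sample_ids <- sprintf("S%03d", seq_len(n_samp))
  groups <- rep(c("case", "control"), c(design$n_cases, design$n_controls))
  with_seed(design$seed, {
    abund <- rlnorm(n_pep, meanlog = 0, sdlog = 1)
    input <- rmultinom(n_samp, total_reads_per_sample, prob = abund)
    dimnames(input) <- list(ann$peptide_id, sample_ids)
    metadata <- data.frame(
      sample_id = sample_ids, group = groups,
      age_bin = sample(names(design$age_group_distribution), n_samp,
                       replace = TRUE, prob = design$age_group_distribution),
      sex = ifelse(runif(n_samp) < design$sex_distribution, "F", "M"),
      stringsAsFactors = FALSE)
    truth <- matrix(FALSE, n_pep, n_samp,
                    dimnames = dimnames(input))
    sig_names <- names(design$planted_peptide_sets)
    for (s in seq_len(n_samp)) {
      prev <- if (groups[s] == "case") design$case_binding_prevalence
              else design$control_binding_prevalence
      for (sig in sig_names) {
        if (runif(1) < prev[[sig]]) {
          peps <- design$planted_peptide_sets[[sig]]
          idx <- match(peps, ann$peptide_id)
          bind <- runif(length(idx)) < ann$immunogenicity[idx]
          truth[idx[bind], s] <- TRUE
        }
      }
    }
    lam <- gp_dispersion
    mean_mat <- input * 1.0
    n_bound <- sum(truth)
    if (n_bound > 0)
      mean_mat[truth] <- mean_mat[truth] *
        runif(n_bound, design$enrichment_factor_range[1],
              design$enrichment_factor_range[2])
    output <- matrix(rgenpois(length(mean_mat), theta = mean_mat * (1 - lam),
                              lam = lam),
                     n_pep, n_samp, dimnames = dimnames(input))
    structure(list(input_counts = input, output_counts = output,
                   truth_bound = truth, metadata = metadata,
                   gp_dispersion = gp_dispersion,
                   total_reads_per_sample = total_reads_per_sample,
                   design = design),
              class = "phip_simulation")
  })
}

#' @export
print.phip_simulation <- function(x, ...) {
  cat(sprintf("PhIP-Seq simulation: %d peptides x %d samples (%d bound cells, lambda %.2f)\n",
              nrow(x$input_counts), ncol(x$input_counts),
              sum(x$truth_bound), x$gp_dispersion))
  invisible(x)
}

#' Write a simulation and its library to disk
#'
#' Writes the peptide library as FASTA (headers
#' \code{peptideID|parentID|start|end|flagellin=\{0,1\}}), counts as
#' \code{input.tsv}/\code{output.tsv}, sample metadata and truth table as TSV,
#' and the generation parameters to a YAML (plus JSON) run manifest.
#'
#' @param sim a \code{\link{simulate_counts}} object.
#' @param library the \code{\link{generate_library}} object it was built from.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- library$annotation
  headers <- sprintf("%s|%s|%d|%d|flagellin=%d", ann$peptide_id,
                     ann$parent_id, ann$start, ann$end,
                     as.integer(ann$flagellin))
  write_fasta(setNames(ann$sequence, headers),
              file.path(dir, "peptides.fasta"))
  write_count_matrix(sim$input_counts, file.path(dir, "input.tsv"))
  write_count_matrix(sim$output_counts, file.path(dir, "output.tsv"))
  write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  truth_df <- data.frame(peptide_id = rownames(sim$truth_bound),
                         sim$truth_bound * 1L, check.names = FALSE)
  write_tsv(truth_df, file.path(dir, "truth.tsv"))
  write_tsv(ann, file.path(dir, "annotation.tsv"))
  manifest <- list(
    n_peptides = nrow(ann), n_samples = ncol(sim$input_counts),
    n_cases = sim$design$n_cases, n_controls = sim$design$n_controls,
    total_reads_per_sample = sim$total_reads_per_sample,
    gp_dispersion = sim$gp_dispersion,
    enrichment_factor_min = sim$design$enrichment_factor_range[1],
    enrichment_factor_max = sim$design$enrichment_factor_range[2],
    signatures = names(sim$design$planted_peptide_sets),
    seed = sim$design$seed)
  write_manifest_yaml(manifest, file.path(dir, "manifest.yaml"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
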