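# Pairwise protein alignment, percent identity, flagellin N-/C-terminal
# domain annotation against reference domains, and relative epitope-position
# profiling.
#
# Scoring follows the de facto protein default: BLOSUM62 with affine gaps
# (open 11, extend 1; a gap of length L costs 11 + L). Identity is computed
# over aligned columns (gap columns count against identity; gap-gap columns
# cannot occur in a pairwise alignment).

default_scoring <- function() {
  list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Pairwise protein alignment
#'
#' Optimal global (Needleman-Wunsch) or local (Smith-Waterman) alignment under
#' BLOSUM62 with affine gap penalties, with percent identity over aligned
#' columns.
#'
#' @param query,target amino-acid strings (standard residues only).
#' @param mode \code{"global"} or \code{"local"}.
#' @param query_id,target_id identifiers carried into the result.
#' @param scoring list with \code{gap_open} and \code{gap_extend} (BLOSUM62 is
#'   the only shipped matrix).
#' @return object of class \code{alignment_result}: score, aligned_length,
#'   identities, identity_pct, query_span, target_span.
#' @export
align <- function(query, target, mode = c("global", "local"),
                  query_id = "query", target_id = "target",
                  scoring = default_scoring()) {
  mode <- match.arg(mode)
  assert_aa(query, "query"); assert_aa(target, "target")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = mode, substitutionMatrix = blosum62(),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  alen <- nchar(pat)
  ident <- if (alen > 0)
    sum(strsplit(pat, "")[[1]] == strsplit(sub, "")[[1]]) else 0L
  qs <- if (alen > 0) c(Biostrings::start(Biostrings::pattern(aln)),
                        Biostrings::end(Biostrings::pattern(aln))) else c(NA, NA)
  ts <- if (alen > 0) c(Biostrings::start(Biostrings::subject(aln)),
                        Biostrings::end(Biostrings::subject(aln))) else c(NA, NA)
  structure(list(
    query_id = query_id, target_id = target_id, mode = mode,
    score = Biostrings::score(aln),
    aligned_length = alen, identities = as.integer(ident),
    identity_pct = if (alen > 0) 100 * ident / alen else 0,
    query_span = as.integer(qs), target_span = as.integer(ts)),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment %s vs %s: score %.1f, identity %.1f%% (%d/%d)\n",
              x$mode, x$query_id, x$target_id, x$score, x$identity_pct,
              x$identities, x$aligned_length))
  invisible(x)
}

#' Percent identity of the optimal alignment
#'
#' The alignment score is symmetric in its arguments, but when several
#' alignments tie for the optimal score their identities can differ, so the
#' backend's tie-broken identity need not be orientation-symmetric. This
#' convenience wrapper therefore evaluates the pair in a canonical
#' (lexicographic) order, making reported identity symmetric by
#' construction; use \code{\link{align}} directly when query/target roles
#' matter.
#'
#' @inheritParams align
#' @return identity percentage in \code{[0, 100]}.
#' @export
identity_pct <- function(query, target, mode = "global") {
  if (query > target) { tmp <- query; query <- target; target <- tmp }
  align(query, target, mode = mode)$identity_pct
}

#' Annotate flagellin N-/C-terminal domains by reference mapping
#'
#' The N-terminal domain is the footprint on the protein of the best-scoring
#' local alignment against any N-domain reference, constrained to start in the
#' first half of the protein; the C-terminal domain the best footprint against
#' any C-domain reference, constrained to end in the last quarter. Footprints
#' scoring below \code{min_score} are reported absent. References are tried in
#' list order, so a stimulator-derived reference first and a silent-derived
#' fallback second reproduces the two-stage annotation strategy.
#'
#' @param protein amino-acid string.
#' @param n_refs,c_refs named character vectors of reference domain sequences.
#' @param min_score minimum local alignment score for a footprint (default 50).
#' @param protein_id identifier.
#' @return object of class \code{domain_annotation}: intervals (or NULL),
#'   source reference ids, and relative boundary coordinates.
#' @export
annotate_domains <- function(protein, n_refs, c_refs, min_score = 50,
                             protein_id = "protein") {
  assert_aa(protein)
  if (!length(n_refs) || !length(c_refs))
    stop_param("reference lists must be non-empty")
  L <- nchar(protein)
  best_fp <- function(refs, constraint) {
    best <- NULL
    for (rid in names(refs)) {
      a <- align(protein, refs[[rid]], mode = "local",
                 query_id = protein_id, target_id = rid)
      if (a$aligned_length == 0 || a$score < min_score) next
      span <- a$query_span
      if (!constraint(span)) next
      if (is.null(best) || a$score > best$score)
        best <- list(span = span, ref = rid, score = a$score)
    }
    best
  }
  nb <- best_fp(n_refs, function(s) s[1] <= ceiling(L / 2))
  cb <- best_fp(c_refs, function(s) s[2] >= ceiling(0.75 * L))
  # domains must not overlap and N must precede C; drop the weaker on conflict
  if (!is.null(nb) && !is.null(cb) && nb$span[2] >= cb$span[1]) {
    if (nb$score >= cb$score) cb <- NULL else nb <- NULL
  }
  structure(list(
    protein_id = protein_id, protein_length = L,
    n_domain = nb$span, c_domain = cb$span,
    n_source_ref = nb$ref, c_source_ref = cb$ref,
    rel_n_start = if (!is.null(nb)) nb$span[1] / L,
    rel_n_end = if (!is.null(nb)) nb$span[2] / L,
    rel_c_start = if (!is.null(cb)) cb$span[1] / L,
    rel_c_end = if (!is.null(cb)) cb$span[2] / L),
    class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  fmt <- function(iv) if (is.null(iv)) "absent" else
    sprintf("%d-%d", iv[1], iv[2])
  cat(sprintf("%s (%d aa): N domain %s, C domain %s\n", x$protein_id,
              x$protein_length, fmt(x$n_domain), fmt(x$c_domain)))
  invisible(x)
}

#' Relative start position of a peptide on its parent protein
#'
#' The 1-based start position of the peptide's first residue divided by the
#' full length of the parent protein.
#'
#' @param start 1-based start coordinate.
#' @param parent_length parent protein length in residues.
#' @return real in \code{(0, 1]}.
#' @export
relative_start <- function(start, parent_length) {
  if (any(start < 1) || any(start > parent_length))
    stop_param("start must be within [1, parent_length]")
  start / parent_length
}

#' Fractions of domain boundaries per relative-position interval
#'
#' @param annotations list of \code{\link{annotate_domains}} results.
#' @param boundary which boundary to summarise: one of \code{"n_start"},
#'   \code{"n_end"}, \code{"c_start"}, \code{"c_end"}.
#' @param bins list of closed intervals \code{c(lo, hi)} on \code{[0, 1]}.
#' @return data frame with interval bounds and the fraction of present domains
#'   whose boundary falls inside each interval.
#' @export
domain_position_summary <- function(annotations,
                                    boundary = c("n_start", "n_end",
                                                 "c_start", "c_end"),
                                    bins = list(c(0, 0.05), c(0.05, 1))) {
  boundary <- match.arg(boundary)
  field <- paste0("rel_", boundary)
  vals <- unlist(lapply(annotations, function(a) a[[field]]))
  if (!length(vals)) stop_param("no annotation has the queried domain")
  do.call(rbind, lapply(bins, function(b) {
    data.frame(lo = b[1], hi = b[2],
               fraction = mean(vals >= b[1] & vals <= b[2]),
               n = length(vals))
  }))
}

#' Per-peptide seropositivity prevalence ratios between groups
#'
#' Prevalence is the seropositive fraction per group; the ratio is
#' case/control with a half-subject continuity correction applied to a group
#' whose seropositive count is zero.
#'
#' @param sero logical peptide-by-sample matrix (e.g.
#'   \code{\link{seropositivity_matrix}}).
#' @param groups named character vector mapping sample id to \code{"case"} or
#'   \code{"control"}.
#' @param min_prevalence if non-NULL, retain peptides with prevalence
#'   strictly above this value in either group (the published analyses use
#'   0.05); NULL (default) keeps every peptide.
#' @param min_ratio if non-NULL, retain peptides with ratio strictly above
#'   this value (published thresholds: 2.5, 15, 20, 25).
#' @return data frame: peptide_id, prevalence_case, prevalence_control,
#'   prevalence_ratio.
#' @export
prevalence_ratio <- function(sero, groups, min_prevalence = NULL,
                             min_ratio = NULL) {
  groups <- groups[colnames(sero)]
  if (any(is.na(groups)) || !all(groups %in% c("case", "control")))
    stop_param("groups must label every sample as case or control")
  if (!any(groups == "case") || !any(groups == "control"))
    stop_param("both groups must be non-empty")
  n_case <- sum(groups == "case"); n_ctrl <- sum(groups == "control")
  k_case <- rowSums(sero[, groups == "case", drop = FALSE])
  k_ctrl <- rowSums(sero[, groups == "control", drop = FALSE])
  cc_case <- ifelse(k_case == 0, 0.5, k_case)
  cc_ctrl <- ifelse(k_ctrl == 0, 0.5, k_ctrl)
  ratio <- (cc_case / n_case) / (cc_ctrl / n_ctrl)
  out <- data.frame(peptide_id = rownames(sero),
                    prevalence_case = k_case / n_case,
                    prevalence_control = k_ctrl / n_ctrl,
                    prevalence_ratio = ratio, row.names = NULL)
  keep <- rep(TRUE, nrow(out))
  if (!is.null(min_prevalence))
    keep <- keep & (out$prevalence_case > min_prevalence |
                      out$prevalence_control > min_prevalence)
  if (!is.null(min_ratio)) keep <- keep & out$prevalence_ratio > min_ratio
  out[keep, , drop = FALSE]
}
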