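# Stimulator / silent / evader flagellin classification and class-similarity
# profiling of antibody-bound flagellins.
#
# Classes are defined by TLR5 binding and activation readouts relative to the
# FliC-PIM reference: both stronger -> stimulator; both weaker -> evader;
# binding stronger but activation weaker -> silent. The remaining quadrant
# (binding weaker, activation stronger) is undefined and raises an error, as
# is exact equality with the reference.

#' Classify a flagellin from TLR5 readouts
#'
#' @param binding,activation TLR5 readouts of the flagellin.
#' @param pim_binding,pim_activation readouts of the FliC-PIM reference.
#' @return one of \code{"stimulator"}, \code{"silent"}, \code{"evader"}.
#' @export
classify_reference <- function(binding, activation, pim_binding = 1,
                               pim_activation = 1) {
  vals <- c(binding, activation, pim_binding, pim_activation)
  if (!all(is.finite(vals))) stop_param("all readouts must be finite")
  if (binding == pim_binding || activation == pim_activation)
    stop("unclassifiable: readout equals the PIM reference", call. = FALSE)
  if (binding > pim_binding && activation > pim_activation) return("stimulator")
  if (binding < pim_binding && activation < pim_activation) return("evader")
  if (binding > pim_binding && activation < pim_activation) return("silent")
  stop("unclassifiable: binding weaker but activation stronger than PIM is undefined",
       call. = FALSE)
}

# normalize a reference table: panel data frames use `true_class`, user
# sidecar tables `class`
reference_table <- function(references) {
  if (!nrow(references)) stop_param("reference list must be non-empty")
  cls_col <- intersect(c("class", "class_label", "true_class"),
                       names(references))[1]
  if (is.na(cls_col)) stop_param("references need a class column")
  need <- c("id", "sequence", "n_start", "n_end", "c_start", "c_end")
  if (!all(need %in% names(references)))
    stop_param("references need columns: ", paste(need, collapse = ", "))
  data.frame(id = references$id, class = references[[cls_col]],
             sequence = references$sequence,
             n_start = references$n_start, n_end = references$n_end,
             c_start = references$c_start, c_end = references$c_end,
             stringsAsFactors = FALSE)
}

#' Read a reference FASTA with its class/domain sidecar TSV
#'
#' Sidecar schema:
#' \code{id<TAB>class<TAB>binding<TAB>activation<TAB>n_start<TAB>n_end<TAB>c_start<TAB>c_end}.
#'
#' @param fasta_path reference sequences.
#' @param sidecar_path TSV path.
#' @return reference data frame suitable for \code{\link{profile_similarity}}.
#' @export
read_references <- function(fasta_path, sidecar_path) {
  seqs <- read_fasta(fasta_path)
  names(seqs) <- sub(" .*", "", names(seqs))
  side <- read_tsv(sidecar_path)
  side$sequence <- unname(seqs[side$id])
  if (anyNA(side$sequence)) stop_param("sidecar ids missing from FASTA")
  side
}

#' Class-similarity profile of a query against reference flagellins
#'
#' For each reference of each class, the percent identity of the
#' scope-restricted alignment: \code{full_length} aligns the whole query
#' globally against the whole reference; \code{peptide} aligns the (short)
#' query locally against the full reference; \code{n_domain}/\code{c_domain}
#' align the query's annotated domain globally against the reference's domain.
#' Queries lacking the required domain annotation are skipped with a warning.
#'
#' @param query_seq amino-acid string (full protein or peptide).
#' @param references reference data frame (panel or \code{\link{read_references}}).
#' @param scope one of \code{"full_length"}, \code{"peptide"},
#'   \code{"n_domain"}, \code{"c_domain"}.
#' @param query_id identifier.
#' @param query_domains for domain scopes: list with \code{n_domain} /
#'   \code{c_domain} intervals (e.g. a \code{\link{annotate_domains}} result).
#' @return long data frame of class \code{class_similarity_profile}:
#'   query_id, scope, class, reference, identity_pct; or \code{NULL} if the
#'   query was skipped.
#' @export
profile_similarity <- function(query_seq, references,
                               scope = c("full_length", "peptide",
                                         "n_domain", "c_domain"),
                               query_id = "query", query_domains = NULL) {
  scope <- match.arg(scope)
  refs <- reference_table(references)
  qseq <- query_seq
  if (scope %in% c("n_domain", "c_domain")) {
    dom <- query_domains[[scope]]
    if (is.null(dom)) {
      warning(sprintf("query %s lacks %s annotation; skipped",
                      query_id, scope))
      return(NULL)
    }
    qseq <- substr(query_seq, dom[1], dom[2])
  }
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    rseq <- switch(scope,
      full_length = refs$sequence[i],
      peptide = refs$sequence[i],
      n_domain = substr(refs$sequence[i], refs$n_start[i], refs$n_end[i]),
      c_domain = substr(refs$sequence[i], refs$c_start[i], refs$c_end[i]))
    mode <- if (scope == "peptide") "local" else "global"
    data.frame(query_id = query_id, scope = scope, class = refs$class[i],
               reference = refs$id[i],
               identity_pct = align(qseq, rseq, mode = mode,
                                    query_id = query_id,
                                    target_id = refs$id[i])$identity_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("class_similarity_profile", "data.frame")
  out
}

#' Profile a set of queries
#'
#' @param queries named character vector of query sequences.
#' @param references reference data frame.
#' @param scope alignment scope (see \code{\link{profile_similarity}}).
#' @param domains optional named list of domain annotations per query id.
#' @return combined long data frame over all (non-skipped) queries.
#' @export
profile_similarity_set <- function(queries, references, scope = "full_length",
                                   domains = NULL) {
  rows <- lapply(names(queries), function(qid)
    profile_similarity(queries[[qid]], references, scope, query_id = qid,
                       query_domains = domains[[qid]]))
  out <- do.call(rbind, rows)
  if (!is.null(out)) class(out) <- c("class_similarity_profile", "data.frame")
  out
}

# per-query class summary: mean identity over references within a class
class_summary_matrix <- function(profiles) {
  agg <- tapply(profiles$identity_pct,
                list(profiles$query_id, profiles$class), mean)
  agg[, intersect(c("stimulator", "silent", "evader"), colnames(agg)),
      drop = FALSE]
}

#' Compare class similarity across stimulator / silent / evader references
#'
#' Summarises each query as its mean identity per reference class, then
#' compares the three class columns: paired (Friedman across queries as
#' blocks, Wilcoxon signed-rank post hocs) or unpaired (Kruskal-Wallis with
#' Dunn's post hoc), Bonferroni-adjusted over the three pairwise contrasts.
#'
#' @param profiles long profile data frame (\code{\link{profile_similarity_set}}).
#' @param paired use the paired battery (default TRUE: the three class
#'   summaries of one query are repeated measures).
#' @return list: \code{summary} (query-by-class matrix), \code{omnibus}
#'   (a \code{\link{test_result}}), \code{pairwise} data frame with raw and
#'   Bonferroni-adjusted p per class contrast.
#' @export
compare_class_similarity <- function(profiles, paired = TRUE) {
  m <- class_summary_matrix(profiles)
  if (nrow(m) < 3L)
    stop("insufficient data: need >= 3 queries", call. = FALSE)
  if (ncol(m) < 3L || anyNA(m))
    stop("need all three class groups for every query", call. = FALSE)
  classes <- colnames(m)
  pairs <- combn(classes, 2, simplify = FALSE)
  if (paired) {
    omnibus <- friedman(m)
    pw <- do.call(rbind, lapply(pairs, function(pr) {
      d <- m[, pr[1]] - m[, pr[2]]
      p <- if (all(d == 0)) 1 else
        suppressWarnings(wilcox.test(m[, pr[1]], m[, pr[2]],
                                     paired = TRUE, exact = FALSE)$p.value)
      data.frame(contrast = paste(pr, collapse = " vs "),
                 median_diff = median(d), p = p,
                 stringsAsFactors = FALSE)
    }))
    pw$p_adjusted <- pmin(1, pw$p * nrow(pw))
  } else {
    kd <- kruskal_dunn(setNames(lapply(classes, function(cl) m[, cl]),
                                classes))
    omnibus <- kd$omnibus
    pw <- kd$pairwise
    med <- apply(m, 2, median)
    dd <- strsplit(pw$contrast, " vs ")
    pw$median_diff <- vapply(dd, function(pr) med[pr[1]] - med[pr[2]],
                             numeric(1))
  }
  list(summary = m, omnibus = omnibus, pairwise = pw, paired = paired)
}

#' Contrast bound against unbound flagellins
#'
#' Runs the same class-contrast battery on profiles of antibody-bound
#' flagellins and of library flagellins never called seropositive, reporting
#' the two side by side. Query ids must be disjoint.
#'
#' @param bound_profiles,unbound_profiles long profile data frames.
#' @param paired battery choice, as in \code{\link{compare_class_similarity}}.
#' @return list with elements \code{bound} and \code{unbound}.
#' @export
bound_vs_unbound_contrast <- function(bound_profiles, unbound_profiles,
                                      paired = TRUE) {
  if (is.null(bound_profiles) || is.null(unbound_profiles) ||
      !nrow(bound_profiles) || !nrow(unbound_profiles))
    stop_param("both profile sets must be non-empty")
  overlap <- intersect(unique(bound_profiles$query_id),
                       unique(unbound_profiles$query_id))
  if (length(overlap))
    stop_param("bound and unbound query ids overlap: ",
               paste(head(overlap, 3), collapse = ","))
  list(bound = compare_class_similarity(bound_profiles, paired),
       unbound = compare_class_similarity(unbound_profiles, paired))
}
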