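# PhIP-Seq pre-processing and enrichment calling.
#
# Post-IP counts for a peptide are compared against a generalized Poisson null
# whose parameters depend on the peptide's input (pre-IP) read level: peptides
# are grouped into logarithmic input-level bins, (theta, lambda) is fitted per
# bin by maximum likelihood, and both parameters are interpolated piecewise
# linearly on log input so that any input level maps to null parameters.
# Seropositivity is Bonferroni-adjusted p <= alpha; fold change is reported
# only for seropositive peptides with >= 25 input reads.

#' Normalize a sample's reads to the identifiable-read cap
#'
#' Samples above \code{cap} total reads are subsampled without replacement
#' (multivariate hypergeometric, deterministic per seed) down to exactly
#' \code{cap}; samples between \code{floor} and \code{cap} are kept unchanged;
#' samples below \code{floor} are marked excluded.
#'
#' @param sample_counts named non-negative integer vector (peptide counts).
#' @param cap per-sample read cap (default 1,250,000).
#' @param floor minimum acceptable reads (default 750,000).
#' @param seed integer seed for the subsampling.
#' @return list with \code{counts} (normalized vector), \code{excluded}
#'   (logical) and \code{total} (post-normalization total).
#' @export
normalize_reads <- function(sample_counts, cap = 1250000, floor = 750000,
                            seed = 1L) {
  if (any(sample_counts < 0) || any(sample_counts != base::floor(sample_counts)))
    stop_param("counts must be non-negative integers")
  total <- sum(sample_counts)
  if (total < floor)
    return(list(counts = sample_counts, excluded = TRUE, total = total))
  if (total <= cap)
    return(list(counts = sample_counts, excluded = FALSE, total = total))
  out <- with_seed(seed, {
    remaining_total <- total
    remaining_draw <- cap
    res <- sample_counts
    for (i in seq_along(sample_counts)) {
      ci <- sample_counts[i]
      if (remaining_draw == 0L) { res[i] <- 0L; next }
      x <- stats::rhyper(1, m = ci, n = remaining_total - ci,
                         k = remaining_draw)
      res[i] <- x
      remaining_total <- remaining_total - ci
      remaining_draw <- remaining_draw - x
    }
    res
  })
  list(counts = out, excluded = FALSE, total = sum(out))
}

# per-bin maximum likelihood with the input level as an offset:
# output_i ~ GP(theta_i = r * input_i * (1 - lambda), lambda), so the fitted
# rate tracks each peptide's exact input level inside the bin (the paper fits
# per exact input read level; at desk scale levels are pooled into bins and
# the offset keeps the mean structure exact).
fit_gp_offset_bin <- function(x, y) {
  r0 <- max(mean(y) / mean(x), 1e-6)
  nll <- function(par) {
    theta <- par[1] * x * (1 - par[2])
    -sum(gp_log_pmf(y, theta, par[2]))
  }
  fit <- optim(c(r0, 0.3), nll, method = "L-BFGS-B",
               lower = c(1e-8, 0), upper = c(Inf, 0.98))
  c(r = unname(fit$par[1]), lam = unname(fit$par[2]))
}

fit_null_model_once <- function(input_counts, output_counts, min_bin_obs) {
  use <- input_counts > 0
  x_raw <- input_counts[use]
  x <- log1p(x_raw)
  y <- output_counts[use]
  n <- length(y)
  if (n < min_bin_obs) stop("too few observations to fit null model",
                            call. = FALSE)
  n_bins <- max(1L, min(25L, n %/% min_bin_obs))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(x, breaks = br, include.lowest = TRUE)
  fits <- lapply(levels(bin), function(b) {
    idx <- bin == b
    if (sum(idx) < 5L || stats::var(y[idx]) == 0) return(NULL)
    f <- tryCatch(fit_gp_offset_bin(x_raw[idx], y[idx]),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(x = mean(x[idx]), r = f["r"], lam = f["lam"],
               theta = f["r"] * mean(x_raw[idx]) * (1 - f["lam"]),
               n_obs = sum(idx), row.names = NULL)
  })
  bins <- do.call(rbind, fits)
  if (is.null(bins) || nrow(bins) == 0L)
    stop("null model fit failed in every input-level bin", call. = FALSE)
  bins <- bins[order(bins$x), , drop = FALSE]
  structure(list(bins = bins, range = range(expm1(bins$x))),
            class = "phip_null_model")
}

#' Fit the per-sample generalized Poisson null model
#'
#' Peptides are binned by input read level (logarithmic, quantile-spaced bins
#' holding at least \code{min_bin_obs} peptides each). Per bin, a generalized
#' Poisson with rate proportional to the peptide's input level
#' (theta = r * input * (1 - lambda)) is fitted by maximum likelihood; the
#' rate ratio r and dispersion lambda are then interpolated piecewise linearly
#' on log(input + 1) across bin centres, yielding null parameters for any
#' input level. Truly antibody-bound peptides would otherwise contaminate the
#' null, so the fit is re-run once after excluding cells whose
#' Bonferroni-adjusted upper-tail p under the first-pass model is below
#' \code{exclude_alpha} (set \code{refit = FALSE} to disable). Zero-input
#' peptides carry no calibration information and are excluded.
#'
#' @param input_counts,output_counts equal-length non-negative integer vectors.
#' @param min_bin_obs minimum peptides per input-level bin (default 200).
#' @param refit robust second pass excluding enriched cells (default TRUE).
#' @param exclude_alpha family-wise exclusion level for the refit.
#' @return object of class \code{phip_null_model} with a \code{bins} data
#'   frame (bin centre, rate ratio r, lambda, theta at the bin-mean input,
#'   n_obs) and the fitted input range.
#' @export
fit_null_model <- function(input_counts, output_counts, min_bin_obs = 200,
                           refit = TRUE, exclude_alpha = 0.05) {
  if (length(input_counts) != length(output_counts))
    stop_param("input and output vectors must have equal length")
  model <- fit_null_model_once(input_counts, output_counts, min_bin_obs)
  if (refit) {
    # iterate exclusion to a fixed point: heavily reactive samples need
    # several passes before all bound cells leave the null fit
    excluded <- rep(FALSE, length(input_counts))
    for (it in seq_len(5L)) {
      p <- suppressWarnings(score_peptides(input_counts, output_counts,
                                           model))
      drop <- p * length(p) < exclude_alpha
      if (!any(drop & !excluded) || sum(!drop) < min_bin_obs) break
      excluded <- excluded | drop
      model <- fit_null_model_once(input_counts[!excluded],
                                   output_counts[!excluded], min_bin_obs)
    }
    model$n_excluded <- sum(excluded)
  }
  model
}

#' @export
print.phip_null_model <- function(x, ...) {
  cat(sprintf("PhIP-Seq generalized Poisson null: %d input-level bins, input range [%.0f, %.0f]\n",
              nrow(x$bins), x$range[1], x$range[2]))
  invisible(x)
}

#' Interpolate null parameters at given input levels
#'
#' The rate ratio r and dispersion lambda are interpolated piecewise linearly
#' on log(input + 1) (clamped to the fitted range outside it), and
#' theta = r * input * (1 - lambda). Zero-input levels are assigned the
#' half-read pseudo-level 0.5. The returned theta is projected onto the
#' non-decreasing-in-input cone (cumulative maximum along increasing input).
#'
#' @param model a \code{phip_null_model}.
#' @param input_counts integer vector of input read levels.
#' @return data frame with columns \code{theta} and \code{lam}.
#' @export
null_params_at <- function(model, input_counts) {
  stopifnot(inherits(model, "phip_null_model"))
  inp <- pmax(input_counts, 0.5)
  x <- log1p(inp)
  b <- model$bins
  if (nrow(b) == 1L) {
    r <- rep(b$r, length(x)); lam <- rep(b$lam, length(x))
  } else {
    r <- approx(b$x, b$r, xout = x, rule = 2)$y
    lam <- approx(b$x, b$lam, xout = x, rule = 2)$y
  }
  theta <- r * inp * (1 - lam)
  o <- order(inp)
  theta[o] <- cummax(theta[o])
  data.frame(theta = theta, lam = lam)
}

#' Score peptides against the null model
#'
#' Upper-tail p-value P(X >= observed output) under the generalized Poisson
#' with parameters interpolated at the peptide's input level. Input levels
#' outside the fitted range are clamped to the nearest bin (with a warning).
#'
#' @param input_counts,output_counts equal-length count vectors.
#' @param model a \code{phip_null_model}.
#' @return numeric p-value vector in (0, 1].
#' @export
score_peptides <- function(input_counts, output_counts, model) {
  stopifnot(inherits(model, "phip_null_model"))
  if (length(input_counts) != length(output_counts))
    stop_param("input and output vectors must have equal length")
  pos <- input_counts[input_counts > 0]
  if (length(pos) && (min(pos) < model$range[1] ||
                      max(input_counts) > model$range[2]))
    warning("input levels outside fitted range clamped to nearest bin")
  p <- rep(1, length(output_counts))
  par <- null_params_at(model, input_counts)
  # group peptides by (rounded) parameter pair for vectorised tail sums
  key <- paste(signif(par$theta, 6), signif(par$lam, 6))
  for (k in unique(key)) {
    idx <- which(key == k)
    kk <- output_counts[idx]
    kmax <- max(kk)
    if (kmax == 0L) next
    lp <- gp_log_pmf(0:(kmax - 1L), par$theta[idx[1]], par$lam[idx[1]])
    cdf <- cumsum(exp(lp))        # cdf[j] = P(X <= j-1)
    pj <- ifelse(kk == 0L, 1, pmax(1 - cdf[pmax(kk, 1L)],
                                   .Machine$double.xmin))
    p[idx] <- pj
  }
  p
}

#' Bonferroni seropositivity calls
#'
#' @param p p-value vector.
#' @param m total number of peptides scored library-wide (Bonferroni m);
#'   must be >= \code{length(p)}.
#' @param alpha significance level (default 0.05).
#' @return data frame with \code{p_adj} and logical \code{seropositive}.
#' @export
call_seropositive <- function(p, m, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_param("alpha must be in (0,1)")
  if (m < length(p)) stop_param("m must be >= length(p)")
  if (length(p) == 0L)
    return(data.frame(p_adj = numeric(0), seropositive = logical(0)))
  p_adj <- pmin(1, p * m)
  data.frame(p_adj = p_adj, seropositive = p_adj <= alpha)
}

#' Fold change for seropositive peptides
#'
#' output/input, reported only for seropositive peptides with at least
#' \code{min_input} input reads; all other peptides are set to zero.
#'
#' @param input_counts,output_counts count vectors.
#' @param seropositive logical vector.
#' @param min_input minimum input reads (default 25).
#' @return numeric fold-change vector.
#' @export
compute_fold_change <- function(input_counts, output_counts, seropositive,
                                min_input = 25) {
  ifelse(seropositive & input_counts >= min_input,
         output_counts / input_counts, 0)
}

#' Sample quality control on enriched-peptide counts
#'
#' Samples with fewer than \code{min_enriched} seropositive peptides are
#' excluded (strict inequality: exactly \code{min_enriched} is retained).
#'
#' @param calls data frame with columns \code{sample_id} and
#'   \code{seropositive} (e.g. from \code{\link{enrichment_calls}}).
#' @param min_enriched exclusion threshold (default 200, the full-library
#'   value; scale down for small synthetic libraries).
#' @return character vector of retained sample ids; excluded ids are attached
#'   as attribute \code{"excluded"}.
#' @export
qc_samples <- function(calls, min_enriched = 200) {
  if (nrow(calls) == 0L)
    return(structure(character(0), excluded = character(0)))
  n_pos <- tapply(calls$seropositive, calls$sample_id, sum)
  keep <- names(n_pos)[n_pos >= min_enriched]
  structure(keep, excluded = setdiff(names(n_pos), keep))
}

#' Full enrichment-calling pass over count matrices
#'
#' For each sample column: fit the generalized Poisson null on its
#' (input, output) pairs, score all peptides, apply Bonferroni seropositivity
#' and the fold-change rule.
#'
#' @param input_mat,output_mat peptide-by-sample integer matrices with
#'   identical dimnames (an input matrix with a single column is recycled
#'   across samples).
#' @param alpha Bonferroni-adjusted significance level.
#' @param min_input minimum input reads for fold change.
#' @param m Bonferroni m; defaults to the number of peptides.
#' @param min_bin_obs per-bin minimum for the null fit.
#' @return long data frame: peptide_id, sample_id, input, output, p, p_adj,
#'   seropositive, fold_change.
#' @export
enrichment_calls <- function(input_mat, output_mat, alpha = 0.05,
                             min_input = 25, m = nrow(output_mat),
                             min_bin_obs = 200) {
  if (!identical(rownames(input_mat), rownames(output_mat)))
    stop_param("input and output matrices must share peptide rownames")
  samples <- colnames(output_mat)
  if (!length(samples))
    return(data.frame(peptide_id = character(0), sample_id = character(0),
                      input = integer(0), output = integer(0),
                      p = numeric(0), p_adj = numeric(0),
                      seropositive = logical(0), fold_change = numeric(0)))
  res <- lapply(samples, function(s) {
    inp <- if (ncol(input_mat) == 1L) input_mat[, 1L] else input_mat[, s]
    out <- output_mat[, s]
    model <- fit_null_model(inp, out, min_bin_obs = min_bin_obs)
    p <- suppressWarnings(score_peptides(inp, out, model))
    cl <- call_seropositive(p, m = m, alpha = alpha)
    fc <- compute_fold_change(inp, out, cl$seropositive, min_input = min_input)
    data.frame(peptide_id = rownames(output_mat), sample_id = s,
               input = as.integer(inp), output = as.integer(out),
               p = p, p_adj = cl$p_adj, seropositive = cl$seropositive,
               fold_change = fc, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Seropositivity matrix from a calls table
#'
#' @param calls output of \code{\link{enrichment_calls}}.
#' @return logical peptide-by-sample matrix.
#' @export
seropositivity_matrix <- function(calls) {
  peps <- unique(calls$peptide_id)
  samp <- unique(calls$sample_id)
  m <- matrix(FALSE, length(peps), length(samp), dimnames = list(peps, samp))
  m[cbind(match(calls$peptide_id, peps), match(calls$sample_id, samp))] <-
    calls$seropositive
  m
}
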