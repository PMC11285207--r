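# Independent oracles used to freeze expected values. These deliberately share
# no code with the package implementation paths they check.

.blosum62 <- local({
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive optimal-alignment score by enumeration over all monotone column
# mappings (aligned residue pairs); affine gap of length L costs open + L*ext.
# Feasible for sequences up to ~8 residues (C(16,8) = 12,870 mappings).
oracle_align_score <- function(q, t, mode = c("global", "local"),
                               open = 11, ext = 1) {
  mode <- match.arg(mode)
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  gap <- function(L) if (L > 0) open + ext * L else 0
  best <- if (mode == "global") -(gap(n) + gap(m)) else 0
  rec <- function(pi, pj, acc, started) {
    if (mode == "global") {
      cand <- acc - gap(n - pi) - gap(m - pj)
      if (cand > best) best <<- cand
    } else if (started && acc > best) best <<- acc
    if (pi >= n || pj >= m) return(invisible())
    for (i in (pi + 1L):n) for (j in (pj + 1L):m) {
      internal <- if (mode == "local" && !started) 0 else
        gap(i - pi - 1L) + gap(j - pj - 1L)
      rec(i, j, acc - internal + .blosum62[qc[i], tc[j]], TRUE)
    }
  }
  rec(0L, 0L, 0, FALSE)
  best
}

# Generalized Poisson pmf recomputed from the definition, independent of
# gp_pmf (log factorial via explicit summation, not lgamma)
oracle_gp_pmf <- function(k, theta, lam) {
  vapply(k, function(ki) {
    lf <- if (ki == 0) 0 else sum(log(seq_len(ki)))
    exp(log(theta) + (ki - 1) * log(theta + ki * lam) -
          theta - ki * lam - lf)
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x)
  u_stat <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  idxs <- utils::combn(length(pooled), n1, simplify = FALSE)
  us <- vapply(idxs, u_stat, numeric(1))
  u_obs <- u_stat(seq_len(n1))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Friedman chi-square (tie-corrected), recomputed from first principles
oracle_friedman_stat <- function(m) {
  r <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  stat <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
  tie <- sum(apply(m, 1, function(row) {
    tt <- table(rank(row)); sum(tt^3 - tt)
  }))
  C <- 1 - tie / (n * (k^3 - k))
  if (C <= 0) 0 else stat / C
}

# Monte-Carlo Friedman p by within-block permutation of the observed values
oracle_friedman_perm_p <- function(m, n_perm = 5000, seed = 1) {
  obs <- oracle_friedman_stat(m)
  withr::with_seed(seed, {
    perm <- replicate(n_perm, {
      mp <- t(apply(m, 1, sample))
      oracle_friedman_stat(mp)
    })
    (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  })
}

random_peptide <- function(n) {
  paste(sample(phipflag:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

hamming_str <- function(a, b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
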