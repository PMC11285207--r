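# Antigen-library encoding: peptide tiling, reverse translation under E. coli
# codon usage with restriction-site avoidance, and Hamming error-correcting
# barcode construction / nearest-codeword decoding.

#' Restriction enzyme recognition sites used during cloning
#' @export
RESTRICTION_SITES <- c(EcoRI = "GAATTC", HindIII = "AAGCTT", SwaI = "ATTTAAAT")

#' Tiling parameters
#'
#' @param max_len maximum peptide length in residues (64 for the large
#'   library, 54 for the small one).
#' @param overlap overlap between adjacent tiles in residues (default 20).
#' @return object of class \code{tiling_params}.
#' @export
tiling_params <- function(max_len = 64, overlap = 20) {
  if (!(overlap > 0 && overlap < max_len))
    stop_param("need 0 < overlap < max_len")
  structure(list(max_len = as.integer(max_len),
                 overlap = as.integer(overlap)), class = "tiling_params")
}

#' Tile a protein into overlapping library peptides
#'
#' Tile starts advance by \code{max_len - overlap}; the final tile is anchored
#' to end at the last residue, so full C-terminal coverage is guaranteed (its
#' overlap with the previous tile may exceed \code{overlap}). Proteins shorter
#' than \code{max_len} yield a single full-length tile.
#'
#' @param sequence amino-acid string.
#' @param params a \code{\link{tiling_params}} object.
#' @param parent_id identifier recorded for each tile.
#' @return data frame: peptide_id, parent_id, start, end, sequence
#'   (1-based inclusive coordinates).
#' @export
tile_protein <- function(sequence, params = tiling_params(),
                         parent_id = "protein") {
  assert_aa(sequence)
  stopifnot(inherits(params, "tiling_params"))
  L <- nchar(sequence)
  step <- params$max_len - params$overlap
  if (L <= params$max_len) {
    starts <- 1L
  } else {
    starts <- seq.int(1L, L, by = step)
    starts <- starts[starts + params$max_len - 1L < L]
    starts <- c(starts, L - params$max_len + 1L)
  }
  ends <- pmin(starts + params$max_len - 1L, L)
  data.frame(
    peptide_id = sprintf("%s_t%02d", parent_id, seq_along(starts)),
    parent_id = parent_id,
    start = as.integer(starts), end = as.integer(ends),
    sequence = substring(sequence, starts, ends),
    stringsAsFactors = FALSE)
}

#' Load a codon usage table
#'
#' The packaged default is an E. coli high-expression usage table; any TSV in
#' the same schema (\code{residue<TAB>codon<TAB>weight}) may be substituted.
#'
#' @param path TSV path; \code{NULL} loads the packaged table.
#' @return object of class \code{codon_table}: per-residue codon lists ranked
#'   by usage weight.
#' @export
load_codon_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ecoli_codon_usage.tsv",
                        package = "phipflag")
  df <- read_tsv(path)
  stopifnot(all(c("residue", "codon", "weight") %in% names(df)))
  df <- df[order(df$residue, -df$weight), ]
  tab <- split(df[, c("codon", "weight")], df$residue)
  missing <- setdiff(AA_ALPHABET, names(tab))
  if (length(missing))
    stop_param("codon table lacks residues: ", paste(missing, collapse = ","))
  structure(tab, class = "codon_table")
}

GENETIC_CODE_MAP <- NULL  # populated lazily from Biostrings

#' Translate a DNA coding sequence
#'
#' @param dna nucleotide string, length a multiple of 3.
#' @return amino-acid string (stop codons as \code{*}).
#' @export
translate_dna <- function(dna) {
  if (nchar(dna) %% 3 != 0) stop_param("length must be a multiple of 3")
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  paste(unname(gc[codons]), collapse = "")
}

stop_encoding <- function(pos, msg) {
  stop(structure(class = c("phipflag_encoding_error", "error", "condition"),
                 list(message = sprintf("%s (peptide position %d)", msg, pos),
                      call = NULL)))
}

#' Reverse translate a peptide avoiding forbidden motifs
#'
#' Codons are chosen by usage rank; \code{variant_index > 0} deterministically
#' selects alternate codons (mixed-radix over positions with synonymous
#' choices), yielding a distinct DNA encoding of the same peptide so identical
#' peptides stay distinguishable by sequence. Any occurrence of a forbidden
#' motif is removed by switching one overlapping codon to its next-ranked
#' synonym (greedy left-to-right rescan); if no codon substitution can remove
#' a motif, an encoding error names the offending peptide position.
#'
#' @param peptide amino-acid string (standard residues).
#' @param table a \code{\link{load_codon_table}} object.
#' @param forbidden nucleotide motifs to exclude (default EcoRI + HindIII).
#' @param variant_index non-negative integer selecting an alternate encoding.
#' @return DNA string whose translation reproduces \code{peptide}.
#' @export
reverse_translate <- function(peptide, table = load_codon_table(),
                              forbidden = unname(RESTRICTION_SITES[c("EcoRI", "HindIII")]),
                              variant_index = 0L) {
  assert_aa(peptide, "peptide")
  if (any(!nzchar(forbidden))) stop_param("forbidden motifs must be non-empty")
  res <- strsplit(peptide, "")[[1]]
  n_codons <- vapply(res, function(a) nrow(table[[a]]), integer(1))
  choice <- integer(length(res))          # 0-based rank per position
  v <- as.integer(variant_index)
  for (i in rev(seq_along(res))) {        # mixed-radix expansion of the index
    if (v == 0L) break
    if (n_codons[i] > 1L) {
      choice[i] <- v %% n_codons[i]
      v <- v %/% n_codons[i]
    }
  }
  build <- function(choice)
    paste(vapply(seq_along(res),
                 function(i) table[[res[i]]]$codon[choice[i] + 1L],
                 character(1)), collapse = "")
  dna <- build(choice)
  for (pass in seq_len(10L * length(res) + 10L)) {
    motif_at <- integer(0); motif_len <- integer(0)
    for (m in forbidden) {
      g <- gregexpr(m, dna, fixed = TRUE)[[1]]
      if (g[1] != -1L) {
        motif_at <- c(motif_at, as.integer(g))
        motif_len <- c(motif_len, rep(nchar(m), length(g)))
      }
    }
    if (!length(motif_at)) return(dna)
    o <- order(motif_at)
    s <- motif_at[o[1]]; e <- s + motif_len[o[1]] - 1L
    cod_first <- (s - 1L) %/% 3L + 1L
    cod_last <- (e - 1L) %/% 3L + 1L
    fixed <- FALSE
    for (ci in cod_first:cod_last) {
      if (n_codons[ci] <= 1L) next
      for (alt in setdiff(seq_len(n_codons[ci]) - 1L, choice[ci])) {
        trial <- choice; trial[ci] <- alt
        cand <- build(trial)
        # accept if this occurrence is gone and no new occurrence precedes it
        still <- any(vapply(forbidden, function(m) {
          g <- gregexpr(m, cand, fixed = TRUE)[[1]]
          g[1] != -1L && any(g <= s)
        }, logical(1)))
        if (!still) { choice <- trial; dna <- cand; fixed <- TRUE; break }
      }
      if (fixed) break
    }
    if (!fixed) stop_encoding(cod_first,
      "no codon substitution removes forbidden motif")
  }
  stop_encoding(1L, "motif avoidance did not converge")
}

#' Encode a peptide as a fixed-length library oligo
#'
#' Coding sequence (restriction-site-free reverse translation) plus a stop
#' codon; peptides shorter than the design length are padded after the stop
#' codon with a SwaI site and deterministic filler to reach
#' \code{oligo_length}.
#'
#' @inheritParams reverse_translate
#' @param oligo_length total oligo length in nt (230 or 200).
#' @return list with \code{dna}, \code{coding_nt} and
#'   \code{forbidden_sites_absent}.
#' @export
encode_oligo <- function(peptide, table = load_codon_table(),
                         oligo_length = 230, variant_index = 0L) {
  coding <- reverse_translate(peptide, table, variant_index = variant_index)
  dna <- paste0(coding, "TAA")
  if (nchar(dna) < oligo_length) {
    pad_len <- oligo_length - nchar(dna) - nchar(RESTRICTION_SITES["SwaI"])
    filler <- if (pad_len > 0)
      paste(rep(c("G", "C", "A", "T"), length.out = pad_len), collapse = "")
    else ""
    dna <- substr(paste0(dna, RESTRICTION_SITES["SwaI"], filler),
                  1, oligo_length)
  }
  list(dna = dna, coding_nt = nchar(coding),
       forbidden_sites_absent =
         !any(vapply(RESTRICTION_SITES[c("EcoRI", "HindIII")],
                     grepl, logical(1), x = coding, fixed = TRUE)))
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

stop_capacity <- function(...) {
  stop(structure(class = c("phipflag_capacity_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Build an error-correcting barcode code by greedy rejection sampling
#'
#' Random nucleotide codewords are accepted only when at minimum Hamming
#' distance \code{min_distance} from every accepted codeword. A code of
#' minimum distance d corrects floor((d-1)/2) substitution errors under
#' nearest-codeword decoding (d = 3: one error at 44 nt; d = 5: two errors at
#' 75 nt).
#'
#' @param length codeword length in nt (44 or 75 in the published designs).
#' @param min_distance minimum pairwise Hamming distance (3 or 5).
#' @param n_codewords number of codewords required.
#' @param seed integer seed (construction is deterministic per seed).
#' @param max_attempts rejection-sampling budget.
#' @return object of class \code{barcode_code}.
#' @export
build_barcode_code <- function(length, min_distance, n_codewords, seed = 1L,
                               max_attempts = 200L * n_codewords) {
  if (min_distance < 1 || n_codewords < 1)
    stop_param("min_distance and n_codewords must be >= 1")
  if (min_distance > length)
    stop_capacity("min_distance ", min_distance,
                  " exceeds codeword length ", length)
  nt <- c("A", "C", "G", "T")
  with_seed(seed, {
    words <- matrix(NA_character_, nrow = 0, ncol = length)
    attempts <- 0L
    while (nrow(words) < n_codewords) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop_capacity("could not place ", n_codewords, " codewords of length ",
                      length, " at distance ", min_distance,
                      " within attempt budget")
      cand <- sample(nt, length, replace = TRUE)
      if (nrow(words) == 0L ||
          all(rowSums(words != matrix(cand, nrow(words), length,
                                      byrow = TRUE)) >= min_distance))
        words <- rbind(words, cand)
    }
    rownames(words) <- NULL
    structure(list(codeword_length = as.integer(length),
                   min_distance = as.integer(min_distance),
                   codewords = unname(apply(words, 1, paste, collapse = "")),
                   matrix = words),
              class = "barcode_code")
  })
}

#' @export
print.barcode_code <- function(x, ...) {
  cat(sprintf("barcode code: %d codewords, length %d nt, min Hamming distance %d (corrects %d errors)\n",
              length(x$codewords), x$codeword_length, x$min_distance,
              (x$min_distance - 1L) %/% 2L))
  invisible(x)
}

#' Nearest-codeword barcode decoding
#'
#' Returns the unique codeword within Hamming distance
#' floor((min_distance - 1)/2) of the read, or \code{NULL} (rejection) when no
#' codeword is that close. An ambiguous match (impossible for a true code, but
#' checked) is also rejected.
#'
#' @param read nucleotide string of exactly \code{code$codeword_length} nt.
#' @param code a \code{\link{build_barcode_code}} object.
#' @return the decoded codeword string, or \code{NULL}.
#' @export
decode_barcode <- function(read, code) {
  stopifnot(inherits(code, "barcode_code"))
  if (nchar(read) != code$codeword_length)
    stop_param("read length ", nchar(read), " != codeword length ",
               code$codeword_length)
  r <- strsplit(read, "")[[1]]
  d <- rowSums(code$matrix != matrix(r, nrow(code$matrix),
                                     code$codeword_length, byrow = TRUE))
  t_max <- (code$min_distance - 1L) %/% 2L
  hits <- which(d <= t_max)
  if (length(hits) != 1L) return(NULL)
  code$codewords[hits]
}
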