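# internal helpers: validation, FASTA/TSV io, seeds

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(structure(class = c("phipflag_parameter_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_aa <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) < 1L)
    stop_param(what, " must be a non-empty amino-acid string")
  bad <- setdiff(strsplit(x, "")[[1]], AA_ALPHABET)
  if (length(bad))
    stop_param(what, " contains non-standard residues: ",
               paste(unique(bad), collapse = ","))
  invisible(x)
}

# deterministic child seeds below 2^31, derived from a user seed
child_seed <- function(seed, k) {
  (as.integer(seed) + 9973L * as.integer(k)) %% 2147483587L
}

with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

random_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                               collapse = "")

# substitute each position independently with probability `rate`
# (always to a *different* residue)
mutate_aa <- function(seq, rate) {
  if (rate < 0 || rate > 1) stop_param("mutation rate must be in [0,1]")
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA_ALPHABET, a), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Read / write peptide-by-sample count matrices
#'
#' Tab-separated with a header row; the first column \code{peptide_id} holds
#' row names, remaining columns are samples (the \code{input.tsv} /
#' \code{output.tsv} interchange format).
#'
#' @param mat integer matrix with peptide rownames and sample colnames.
#' @param path TSV path.
#' @return \code{read_count_matrix}: an integer matrix;
#'   \code{write_count_matrix}: \code{path}, invisibly.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(peptide_id = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

# minimal flat YAML emitter (scalars and atomic vectors only) for run manifests
write_manifest_yaml <- function(x, path) {
  fmt <- function(v) {
    if (is.character(v)) v else format(v, scientific = FALSE, trim = TRUE)
  }
  lines <- unlist(lapply(names(x), function(nm) {
    v <- x[[nm]]
    if (length(v) == 1L && !is.list(v)) paste0(nm, ": ", fmt(v))
    else c(paste0(nm, ":"), paste0("  - ", fmt(unlist(v))))
  }))
  writeLines(lines, path)
  invisible(path)
}

interval_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start) + 1L)
}

jaccard_interval <- function(a, b) {
  if (is.null(a) || is.null(b)) return(0)
  inter <- interval_overlap(a[1], a[2], b[1], b[2])
  uni <- (a[2] - a[1] + 1L) + (b[2] - b[1] + 1L) - inter
  inter / uni
}
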