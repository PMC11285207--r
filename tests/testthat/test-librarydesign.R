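test_that("tile_protein handles the documented geometries", {
  p64 <- tile_protein(strrep("A", 64), tiling_params(64, 20))
  expect_identical(nrow(p64), 1L)
  expect_identical(c(p64$start, p64$end), c(1L, 64L))
  p108 <- tile_protein(strrep("A", 108), tiling_params(64, 20))
  expect_identical(p108$start, c(1L, 45L))
  expect_identical(p108$end, c(64L, 108L))
  # short proteins are legal single tiles
  p30 <- tile_protein(strrep("M", 30), tiling_params(64, 20))
  expect_identical(nrow(p30), 1L)
  expect_identical(nchar(p30$sequence), 30L)
  expect_error(tile_protein("", tiling_params()), "non-empty")
  expect_error(tiling_params(64, 64), "overlap")
})

test_that("tiling covers every residue with the promised overlap", {
  lens <- withr::with_seed(4, sample(1:2000, 40))
  for (L in lens) {
    seq <- strrep("K", L)
    for (pars in list(tiling_params(64, 20), tiling_params(54, 20))) {
      tl <- tile_protein(seq, pars)
      covered <- logical(L)
      for (i in seq_len(nrow(tl))) covered[tl$start[i]:tl$end[i]] <- TRUE
      expect_true(all(covered))
      expect_true(all(tl$end - tl$start + 1L <= pars$max_len))
      if (nrow(tl) > 1) {
        ov <- tl$end[-nrow(tl)] - tl$start[-1] + 1L
        expect_true(all(ov >= pars$overlap))
      }
    }
  }
})

codon_tab <- load_codon_table()

test_that("reverse translation round-trips and ranks codons by usage", {
  expect_identical(reverse_translate("M", codon_tab), "ATG")
  peps <- withr::with_seed(11, replicate(1000, random_peptide(sample(1:40, 1))))
  for (p in peps) {
    dna <- reverse_translate(p, codon_tab)
    expect_identical(translate_dna(dna), p)
    expect_false(grepl("GAATTC", dna, fixed = TRUE))
    expect_false(grepl("AAGCTT", dna, fixed = TRUE))
  }
})

test_that("forbidden motifs are avoided via alternate codons", {
  # EcoRI-style case: E+F top-ranked codons (GAA+TTT) spell GAATTT, so ban
  # exactly that motif to force an alternate codon
  dna <- reverse_translate("EF", codon_tab, forbidden = "GAATTT")
  expect_identical(translate_dna(dna), "EF")
  expect_false(grepl("GAATTT", dna, fixed = TRUE))
  # and the literal EcoRI site is avoided whichever ranking produces it
  dna2 <- reverse_translate("EF", codon_tab, forbidden = "GAATTC")
  expect_identical(translate_dna(dna2), "EF")
  expect_false(grepl("GAATTC", dna2, fixed = TRUE))
  # motif avoidance across many random peptides with a permissive motif
  peps <- withr::with_seed(12, replicate(50, random_peptide(30)))
  for (p in peps) {
    dna <- reverse_translate(p, codon_tab, forbidden = c("GAATTC", "AAGCTT",
                                                         "ATTTAAAT"))
    expect_identical(translate_dna(dna), p)
    expect_false(grepl("GAATTC|AAGCTT|ATTTAAAT", dna))
  }
  # unachievable avoidance: every lysine codon contains AA
  expect_error(reverse_translate("K", codon_tab, forbidden = "AA"),
               "position 1", class = "phipflag_encoding_error")
})

test_that("variant_index produces distinct encodings of the same peptide", {
  p <- "MEKLF"
  encs <- vapply(0:4, function(v)
    reverse_translate(p, codon_tab, variant_index = v), character(1))
  expect_identical(length(unique(encs)), 5L)
  for (e in encs) expect_identical(translate_dna(e), p)
})

test_that("encode_oligo pads short peptides to fixed length after the stop", {
  o <- encode_oligo("MKV", codon_tab, oligo_length = 60)
  expect_identical(nchar(o$dna), 60L)
  expect_identical(translate_dna(substr(o$dna, 1, o$coding_nt)), "MKV")
  expect_true(grepl("ATTTAAAT", o$dna, fixed = TRUE))   # SwaI failsafe
  expect_true(o$forbidden_sites_absent)
})

test_that("barcode codes respect the pairwise Hamming distance bound", {
  expect_error(build_barcode_code(4, 5, 10),
               class = "phipflag_capacity_error")
  code <- build_barcode_code(44, 3, 100, seed = 3)
  d <- utils::combn(code$codewords, 2,
                    function(pr) hamming_str(pr[1], pr[2]))
  expect_true(all(d >= 3))
  expect_identical(length(code$codewords), 100L)
  # distance 1: any distinct strings
  c1 <- build_barcode_code(6, 1, 50, seed = 4)
  expect_identical(length(unique(c1$codewords)), 50L)
  # determinism
  expect_identical(build_barcode_code(44, 3, 20, seed = 9)$codewords,
                   build_barcode_code(44, 3, 20, seed = 9)$codewords)
})

test_that("decoding corrects up to floor((d-1)/2) errors on a toy code", {
  nt <- c("A", "C", "G", "T")
  code3 <- build_barcode_code(10, 3, 10, seed = 21)
  # exact reads and all weight-1 errors decode to the original
  for (cw in code3$codewords) {
    expect_identical(decode_barcode(cw, code3), cw)
    chars <- strsplit(cw, "")[[1]]
    for (pos in 1:10) for (sub in setdiff(nt, chars[pos])) {
      r <- chars; r[pos] <- sub
      expect_identical(decode_barcode(paste(r, collapse = ""), code3), cw)
    }
  }
  # weight-2 reads never decode to the original (rejected or, at worst,
  # nearer another codeword - never silently accepted as the original)
  cw <- code3$codewords[1]
  chars <- strsplit(cw, "")[[1]]
  rejected <- 0L
  for (pr in utils::combn(10, 2, simplify = FALSE)) {
    r <- chars
    r[pr] <- vapply(chars[pr], function(a) setdiff(nt, a)[1], character(1))
    dec <- decode_barcode(paste(r, collapse = ""), code3)
    expect_false(identical(dec, cw))
    if (is.null(dec)) rejected <- rejected + 1L
  }
  expect_gt(rejected, 0L)
  expect_error(decode_barcode("ACGT", code3), "length")
})
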