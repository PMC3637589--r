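# Translation, frame selection and window arithmetic.

test_that("translation follows the standard code and handles ambiguity", {
  expect_equal(translate_dna("TTC"), "F")
  expect_equal(translate_dna("AGC"), "S")
  expect_equal(translate_dna("TCC"), "S")
  expect_equal(translate_dna("TGC"), "C")
  expect_equal(translate_dna("TCN"), "S")   # all disambiguations agree
  expect_equal(translate_dna("ATN"), "X")   # ATA (I) vs ATG (M) disagree
  expect_equal(translate_dna("TAA"), "*")
  expect_equal(translate_dna("TTCAGC"), "FS")
  expect_equal(translate_dna("ATTCAGC", frame = 1), "FS")
  expect_equal(translate_dna(reverse_complement("TTCAGC"), reverse = TRUE), "FS")
  expect_error(translate_dna("AT"), "shorter than one codon")
  expect_error(translate_dna("TTZ"), "invalid DNA")
})

test_that("translation inverts codon encoding for every residue and codon", {
  gc_tab <- Biostrings::GENETIC_CODE
  for (codon in names(gc_tab)) {
    expect_equal(translate_dna(codon), unname(gc_tab[codon]), info = codon)
  }
  # multi-residue round trip over random synonymous encodings
  for (seed in 1:5) {
    aa <- "FISCIFSVFTV"
    expect_equal(translate_dna(encode_aa(aa, seed)), aa)
  }
})

test_that("frame and strand are recovered for planted encodings", {
  aa <- "FISCIFSVFTV"   # survey consensus window, sites 84-94
  for (seed in 1:10) {
    dna <- encode_aa(aa, seed)
    set.seed(seed * 100)
    pad5 <- paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = "")
    for (frame in 0:2) {
      frag <- paste0(substr(pad5, 1, frame), dna)
      sf <- select_frame(frag)
      expect_equal(sf$frame, frame)
      expect_false(sf$reverse)
      expect_equal(residue_at(sf$window, 86), "S")
      expect_equal(residue_at(sf$window, 90), "S")
      # reverse strand
      sr <- select_frame(reverse_complement(frag))
      expect_true(sr$reverse)
      expect_equal(sr$window$residues, sf$window$residues)
      expect_equal(sr$window$start_site, sf$window$start_site)
    }
  }
})

test_that("anchoring fails informatively on garbage and low identity", {
  expect_error(select_frame("GGGGGGGGGGGGGGGGGGGGG"), "no-anchor")
  # a stop codon inside the anchored region invalidates the frame
  aa_stop <- "FISCI*SVFTV"
  dna <- paste(vapply(strsplit(aa_stop, "")[[1]],
                      function(a) codons_for(a)[1], character(1)),
               collapse = "")
  expect_error(select_frame(dna), "no-anchor")
})

test_that("window hamming distance matches the survey arithmetic", {
  ptarmigan <- aa_window("FISCILSVFVV", 84)
  sandpiper <- aa_window("FIACIFSVFTV", 84)
  d <- window_hamming(ptarmigan, sandpiper)
  expect_equal(as.integer(d), 3L)
  expect_equal(attr(d, "compared"), 11L)
  expect_equal(as.integer(window_hamming(ptarmigan, ptarmigan)), 0L)
})

test_that("hamming is symmetric, reflexive and triangular; X is excluded", {
  wx <- aa_window("FVSCXFSVFIV", 84)
  wy <- aa_window("FISCIFSVFIV", 84)
  d <- window_hamming(wx, wy)
  expect_equal(as.integer(d), 1L)      # V85 vs I85; X site excluded
  expect_equal(attr(d, "compared"), 10L)
  expect_equal(attr(d, "excluded"), 1L)
  # X counts as mismatch under the alternative policy
  expect_equal(as.integer(window_hamming(wx, wy, x_policy = "mismatch")), 2L)

  set.seed(42)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    r <- function() aa_window(paste(sample(alphabet, 8, TRUE), collapse = ""), 84)
    a <- r(); b <- r(); cc <- r()
    expect_equal(as.integer(window_hamming(a, b)),
                 as.integer(window_hamming(b, a)))
    expect_equal(as.integer(window_hamming(a, a)), 0L)
    expect_lte(as.integer(window_hamming(a, cc)),
               as.integer(window_hamming(a, b)) +
                 as.integer(window_hamming(b, cc)))
  }
  expect_error(window_hamming(aa_window("FIS", 84), aa_window("FISC", 84)),
               "alignment mismatch")
  expect_error(window_hamming(aa_window("FIS", 84), aa_window("FIS", 85)),
               "alignment mismatch")
})

test_that("FASTA I/O round-trips sequences and ids", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(frag_a = "TTCATCTCCTGTATCTTCAGCGTCTTCACCGTC",
            frag_b = "AGCTGCAGGTTTTTCCCC")
  write_fasta(seqs, tmp, type = "dna")
  back <- read_fasta_dna(tmp)
  expect_equal(back, seqs)
  expect_error(read_fasta_dna(withr::local_tempfile()), "no such file")
})
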