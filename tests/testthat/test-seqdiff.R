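# Parental sequence comparison: ORF handling, translation, fixed-difference
# discovery, peptide regions and marker validation.

test_that("validate_orf flags start, frame, terminal and internal stops", {
  ok <- validate_orf("ATGGGTTAA")
  expect_true(ok$valid)
  expect_true(ok$starts_with_start_codon)
  expect_true(ok$terminal_stop)
  expect_length(ok$internal_stop_codons, 0)

  planted <- validate_orf("ATGTAAGGTTAA")
  expect_equal(planted$internal_stop_codons, 2L)
  expect_false(planted$valid)

  frame <- validate_orf("ATGGG")
  expect_false(frame$length_multiple_of_three)
  expect_false(frame$terminal_stop)

  expect_error(validate_orf("ATGXGT"), "non-nucleotide")
})

test_that("translate_orf follows the standard code and drops the stop", {
  expect_equal(translate_orf("ATGGGTTAA"), "MG")
  expect_error(translate_orf("ATGTAAGGTTAA"), "codon index 2")
  expect_error(translate_orf("ATGGGTGGT"), "terminal stop")
  expect_equal(translate_orf("ATGGGTGGT", require_terminal_stop = FALSE),
               "MGG")
})

test_that("a 324-nt ORF encodes 107 residues and conversely", {
  cfg <- sim_config(seq_length = 324, seed = 42)
  seqs <- simulate_parental_sequences(cfg)
  prot <- translate_orf(seqs$maternal)
  expect_equal(nchar(prot), 107L)
  expect_equal(3L * (nchar(prot) + 1L), 324L)
})

test_that("translation matches an independent codon-table oracle", {
  set.seed(11)
  for (i in 1:50) {
    cfg <- sim_config(seq_length = 90, n_snps = 0, seed = i)
    s <- simulate_parental_sequences(cfg)$maternal
    via_oracle <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1, nchar(s) - 3))))
    expect_equal(translate_orf(s), via_oracle)
  }
})

test_that("find_fixed_differences reports 1-based positions and labels", {
  expect_equal(nrow(find_fixed_differences("ACGTACGT", "ACGTACGT")), 0L)
  d <- find_fixed_differences("ATGA", "ACGA")
  expect_equal(d$position, 2L)
  expect_equal(d$label, "T/C")
  expect_error(find_fixed_differences("ATG", "ATGA"), "length")
  expect_error(find_fixed_differences("ATY", "ATG"), "non-nucleotide")
})

test_that("fixed-difference count equals the Hamming distance and swapping
           parents swaps the alleles", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  for (i in 1:25) {
    a <- paste(sample(bases, 60, replace = TRUE), collapse = "")
    b <- paste(sample(bases, 60, replace = TRUE), collapse = "")
    hamming <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    fwd <- find_fixed_differences(a, b)
    rev <- find_fixed_differences(b, a)
    expect_equal(nrow(fwd), hamming)
    expect_equal(fwd$position, rev$position)
    expect_equal(fwd$maternal_allele, rev$paternal_allele)
    expect_equal(fwd$paternal_allele, rev$maternal_allele)
  }
})

test_that("diff_peptides reports residue differences 1-based", {
  d <- diff_peptides("MKTD", "MKTE")
  expect_equal(d$position, 4L)
  expect_equal(d$residue_a, "D")
  expect_equal(d$residue_b, "E")
  expect_equal(nrow(diff_peptides("MKTD", "MKTD")), 0L)
  expect_error(diff_peptides("MK", "MKT"), "length")
})

test_that("extract_regions slices signal and mature peptides verbatim", {
  signal <- "MLLKRNTCLLAFLLCSLTLWCKSTSA"  # 26 residues
  mature <- "GSSFLSPSOKPONKVKSSRI"        # 20 residues, non-standard O kept
  protein <- paste0(signal, mature, "AEXAMPLETAILAEXAMPLETAIL")
  out <- extract_regions(protein, signal = c(1, 26), mature = c(27, 46))
  expect_equal(out$signal, signal)
  expect_equal(out$mature, mature)
  empty <- extract_regions(protein, signal = c(1, 26), mature = c(30, 29))
  expect_equal(empty$mature, "")
  expect_error(extract_regions(protein, c(1, 26), c(20, 400)),
               "out of bounds")
  expect_error(extract_regions(protein, c(1, 26), c(10, 30)), "overlap")
})

test_that("marker validation demands homozygous parents and heterozygous
           hybrids", {
  site <- list(maternal_allele = "T", paternal_allele = "C")
  calls <- data.frame(
    sample_id = c("N1", "N2", "B1", "B2", "NB1", "NB2"),
    role = c("maternal_parent", "maternal_parent", "paternal_parent",
             "paternal_parent", "hybrid", "hybrid"),
    alleles = c("T", "T", "C", "C", "TC", "Y")  # Y decodes to C/T
  )
  ok <- validate_marker(site, calls)
  expect_true(ok$usable)
  expect_equal(ok$reason, "")

  bad_hybrid <- calls
  bad_hybrid$alleles[5] <- "T"
  res <- validate_marker(site, bad_hybrid)
  expect_false(res$usable)
  expect_match(res$reason, "NB1")

  het_parent <- calls
  het_parent$alleles[1] <- "TC"
  res2 <- validate_marker(site, het_parent)
  expect_false(res2$usable)
  expect_match(res2$reason, "N1")

  expect_error(validate_marker(site, calls[calls$role != "hybrid", ]),
               "hybrid")
})

test_that("IUPAC genotype letters decode to allele sets", {
  expect_equal(decode_iupac(c("Y", "S", "TC", "G")),
               list(c("C", "T"), c("C", "G"), c("C", "T"), "G"))
  expect_error(decode_iupac("Z"), "unknown")
})
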