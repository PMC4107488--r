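test_that("degenerate codon expansion follows the IUPAC product rule", {
  expect_equal(expand_degenerate_codon("CAT"),
               list(codons = "CAT", residues = "H"))
  ywt <- expand_degenerate_codon("YWT")
  expect_setequal(ywt$codons, c("CAT", "CTT", "TAT", "TTT"))
  expect_setequal(ywt$residues, c("H", "L", "Y", "F"))
  expect_setequal(expand_degenerate_codon("SAW")$residues,
                  c("E", "D", "Q", "H"))
  expect_setequal(expand_degenerate_codon("MWT")$residues,
                  c("N", "I", "H", "L"))
  expect_error(expand_degenerate_codon("XAT"), "X")
  # expansion size is the product of per-symbol multiplicities
  set.seed(1)
  syms <- names(Biostrings::IUPAC_CODE_MAP)
  for (i in 1:25) {
    cod <- paste(sample(syms, 3, replace = TRUE), collapse = "")
    mult <- prod(nchar(Biostrings::IUPAC_CODE_MAP[strsplit(cod, "")[[1]]]))
    expect_length(expand_degenerate_codon(cod)$codons, mult)
  }
})

test_that("mixed-codon design covers wild type and His without stops", {
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVY", "")[[1]], character(0))
  for (aa in aas) {
    cod <- design_mixed_codon(aa)
    res <- expand_degenerate_codon(cod)$residues
    expect_true(aa %in% res, label = sprintf("%s in expansion of %s", aa, cod))
    expect_true("H" %in% res)
    expect_false("*" %in% res)
  }
  # tryptophan cannot be covered without a stop: any degenerate codon
  # containing TGG and CAT/CAC necessarily expands to TAG
  expect_error(design_mixed_codon("W"), "stop-free")
  expect_equal(design_mixed_codon("H"), "CAY")
  expect_error(design_mixed_codon("B"), "standard amino acid")
})

test_that("the default design reproduces the published mixed codons", {
  expect_equal(design_mixed_codon("Q"), "CAW")
  expect_equal(design_mixed_codon("D"), "SAT")
  expect_equal(design_mixed_codon("Y"), "YAT")
  expect_equal(design_mixed_codon("N"), "MAY")
  expect_equal(design_mixed_codon("F"), "YWT")
  expect_equal(design_mixed_codon("E"), "SAW")
  expect_equal(design_mixed_codon("L"), "CWK")
  expect_equal(design_mixed_codon("R"), "CRY")
  expect_equal(design_mixed_codon("K"), "MAW")
  expect_equal(design_mixed_codon("I"), "MWT")
  # explicit wild-type codon overrides the default gene codon
  expect_equal(design_mixed_codon("N", wt_codon = "AAT"), "MAT")
})

test_that("library diversity is an exact product, invariant to reordering", {
  d1 <- his_scan_design(1, "Q", "CAW")
  expect_equal(library_diversity(d1)$aa_diversity, 2)
  expect_equal(library_diversity(d1)$codon_diversity, 2)
  d2 <- his_scan_design(c(1, 2), c("Q", "E"), c("CAW", "SAW"))
  expect_equal(library_diversity(d2)$aa_diversity, 8)
  expect_equal(library_diversity(d2)$codon_diversity, 8)
  d <- pab_library_design()
  perm <- d[sample(nrow(d)), ]
  expect_equal(library_diversity(perm)$aa_diversity,
               library_diversity(d)$aa_diversity)
  expect_true(library_diversity(d)$aa_diversity <=
                library_diversity(d)$codon_diversity)
  expect_error(library_diversity(d[0, ]), "empty")
})

test_that("design invariants are enforced", {
  expect_error(his_scan_design(1, "Q", "TAR"), "stop")
  expect_error(his_scan_design(1, "Q", "CAY"), "wild type")
  expect_error(his_scan_design(1, "Q", "CAR"), "histidine")
  d <- his_scan_design(1, "Q", "CAW")
  expect_equal(d$substituted, "H")
  expect_setequal(encoded_residues(d)[[1]], c("Q", "H"))
})

test_that("oligo emission splices codons and round-trips", {
  d <- his_scan_design(1, "Q", "CAW")
  expect_equal(emit_library_oligos(d, "CAA"), "CAW")
  expect_equal(emit_library_oligos(d[0, ], "CAAGGT"), "CAAGGT")
  d2 <- his_scan_design(c(1, 3), c("Q", "D"), c("CAW", "SAT"))
  oligo <- emit_library_oligos(d2, "CAAGGTGAT")
  expect_equal(oligo, "CAWGGTSAT")
  expect_setequal(expand_degenerate_codon(substr(oligo, 7, 9))$residues,
                  c("D", "H"))
  expect_error(emit_library_oligos(d2, "CAAG"), "divisible")
  expect_error(emit_library_oligos(his_scan_design(4, "Q", "CAW"),
                                   "CAAGGTGAT"), "outside")
})

test_that("design tables round-trip through TSV", {
  d <- pab_library_design()
  path <- tempfile(fileext = ".tsv")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(d2$codon, d$codon)
  expect_equal(d2$encoded, d$encoded)
})
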