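# Tuning-site genotype extraction, UVS/VS classification, lambda-max
# estimation and the conservativeness rule.

test_that("genotypes are read at absolute sites 86/90/93", {
  expect_equal(unlist(extract_genotype(aa_window("FIFCVFCVFMV", 84))[1:3],
                      use.names = FALSE), c("F", "C", "M"))  # ostrich-type
  expect_equal(unlist(extract_genotype(aa_window("FLACIFCIFTV", 84))[1:3],
                      use.names = FALSE), c("A", "C", "T"))  # cockatoo-type
  expect_equal(unlist(extract_genotype(aa_window("FISCILSVFVV", 84))[1:3],
                      use.names = FALSE), c("S", "S", "V"))  # ptarmigan-type
  expect_error(extract_genotype(aa_window("FISCIF", 84)), "site")
  # attached codons must translate to their residues
  g <- extract_genotype(aa_window("FIFCVFCVFMV", 84),
                        codons = c(`86` = "TTC", `90` = "TGC", `93` = "ATG"))
  expect_equal(g$codon90, "TGC")
  expect_error(extract_genotype(aa_window("FIFCVFCVFMV", 84),
                                codons = c(`86` = "AGC", `90` = "TGC",
                                           `93` = "ATG")),
               "translates to")
})

test_that("classification follows the C90/F86 dichotomy with overrides", {
  # palaeognath genotype: UVS genotype, VS phenotype via MSP override
  call <- classify_genotype(tuning_genotype("F", "C", "M"),
                            taxon_labels = c("Struthio camelus",
                                             "Palaeognathae"))
  expect_equal(call$genotype_class, "UVS")
  expect_equal(call$phenotype_class, "VS")
  expect_true(any(grepl("override", call$evidence)))
  expect_true(any(grepl("Schiff-base", call$evidence)))  # M93 with C90

  expect_equal(classify_genotype(tuning_genotype("F", "S", "T"))$phenotype_class,
               "UVS")  # trogon-type, F86 route
  expect_equal(classify_genotype(tuning_genotype("S", "S", "T"))$phenotype_class,
               "VS")
  expect_equal(classify_genotype(tuning_genotype("S", "C", "T"))$genotype_class,
               "UVS")
  expect_equal(classify_genotype(tuning_genotype("X", "S", "T"))$genotype_class,
               "INDETERMINATE")
  expect_equal(classify_genotype(tuning_genotype("W", "S", "T"))$genotype_class,
               "INDETERMINATE")  # residue never seen with S90: no guess
})

test_that("classification is total and consistent with the rule table", {
  residues <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  rules <- default_lambda_rules()
  classes <- c("UVS", "VS", "INDETERMINATE")
  for (r86 in residues) {
    for (r90 in residues) {
      g <- tuning_genotype(r86, r90, "T")
      call <- classify_genotype(g, rules = rules)
      expect_true(call$genotype_class %in% classes)
      # repeated calls are deterministic
      expect_identical(call$genotype_class,
                       classify_genotype(g, rules = rules)$genotype_class)
      # the rule table agrees with the classifier on the class
      expect_identical(estimate_lambda_max(g, rules)$class, call$genotype_class,
                       label = paste(r86, r90))
    }
  }
})

test_that("lambda estimates sit inside their class intervals", {
  rules <- default_lambda_rules()
  residues <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  for (r86 in residues) {
    for (r90 in residues) {
      lm <- estimate_lambda_max(tuning_genotype(r86, r90, "T"), rules)
      if (lm$class == "UVS") {
        expect_gte(lm$lambda_max_nm, 355); expect_lte(lm$lambda_max_nm, 380)
      } else if (lm$class == "VS") {
        expect_gte(lm$lambda_max_nm, 402); expect_lte(lm$lambda_max_nm, 426)
      } else {
        expect_true(is.na(lm$lambda_max_nm))
      }
    }
  }
  # the single-substitution UV shift magnitude is within the reported band
  vs <- estimate_lambda_max(tuning_genotype("S", "S", "T"), rules)$lambda_max_nm
  uv90 <- estimate_lambda_max(tuning_genotype("S", "C", "T"), rules)$lambda_max_nm
  uv86 <- estimate_lambda_max(tuning_genotype("F", "S", "T"), rules)$lambda_max_nm
  expect_gte(abs(vs - uv90), 31); expect_lte(abs(vs - uv90), 47)
  expect_gte(abs(vs - uv86), 31); expect_lte(abs(vs - uv86), 47)
})

test_that("every tuning-site substitution seen at 86/90 is non-conservative", {
  pairs <- list(c("S", "C"), c("S", "F"), c("S", "A"), c("A", "T"),
                c("T", "I"), c("C", "M"))
  for (p in pairs) {
    expect_true(is_nonconservative(p[1], p[2]),
                label = paste(p, collapse = "->"))
    expect_true(is_nonconservative(p[2], p[1]),
                label = paste(rev(p), collapse = "->"))
  }
  expect_false(is_nonconservative("I", "L"))
  expect_false(is_nonconservative("D", "E"))  # both acidic, both polar
  expect_true(is_nonconservative("D", "K"))   # charge change
  expect_error(is_nonconservative("X", "S"), "indeterminate")
})

test_that("substitution labels use from-site-to notation", {
  expect_equal(substitution_label(90, "S", "C"), "S90C")
  expect_equal(substitution_label(86, "S", "F"), "S86F")
  expect_equal(substitution_label(93, "P", "T"), "P93T")
  expect_error(substitution_label(90, "S", "S"), "no substitution")
})
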