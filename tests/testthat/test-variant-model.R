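test_that("cohort table round-trips through write and read unchanged", {
  fx <- table2_variants()
  expect_equal(nrow(fx), 31)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(fx, tmp)
  back <- read_variant_table(tmp)
  expect_equal(as.data.frame(back)[names(fx)], as.data.frame(fx),
               tolerance = 1e-12)
  # second round trip is byte-identical (deterministic column order)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("table reader enforces the column contract", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  # header-only file -> empty table
  writeLines(paste(c("variant_id", "family_id", "gene_symbol",
                     "consequence_terms"), collapse = "\t"), tmp)
  expect_equal(nrow(read_variant_table(tmp)), 0)
  # missing mandatory column -> format error
  writeLines(c("variant_id\tfamily_id", "v1\tF1"), tmp)
  expect_error(read_variant_table(tmp), "mandatory")
  # NA score cell -> absent, never zero
  writeLines(c("variant_id\tfamily_id\tgene_symbol\tconsequence_terms\tmutpred2_score",
               "v1\tF1\tG1\tstop_gained\tNA"), tmp)
  expect_true(is.na(read_variant_table(tmp)$mutpred2_score))
  # non-numeric score cell -> parse error naming row and column
  writeLines(c("variant_id\tfamily_id\tgene_symbol\tconsequence_terms\tcadd_phred",
               "v1\tF1\tG1\tmissense_variant\thigh"),
             tmp)
  expect_error(read_variant_table(tmp), "cadd_phred")
  # duplicate variant ids rejected
  writeLines(c("variant_id\tfamily_id\tgene_symbol\tconsequence_terms",
               "v1\tF1\tG1\tmissense_variant",
               "v1\tF2\tG2\tmissense_variant"), tmp)
  expect_error(read_variant_table(tmp), "duplicate")
})

test_that("invariant violations are rejected by the validator", {
  expect_error(variant_table(toy_variant(af_global = 1.5)), "af_global")
  expect_error(variant_table(toy_variant(phastcons = -0.1)), "phastcons")
  expect_error(variant_table(toy_variant(exon_index = 9, exon_total = 5)),
               "exon_index")
  expect_error(variant_table(toy_variant(pos = 0)), "pos")
})

test_that("classification follows the precedence order and is term-order stable", {
  got <- classify_variants(c("stop_gained", "splice_donor_variant",
                             "frameshift_variant", "missense_variant",
                             "synonymous_variant"))
  expect_equal(as.character(got$variant_class),
               c("STOP_GAIN", "CANONICAL_SPLICE", "FRAMESHIFT", "MISSENSE",
                 "OTHER"))
  # splice term dominates regardless of term order
  expect_equal(
    as.character(classify_variants("stop_gained&splice_acceptor_variant")$variant_class),
    as.character(classify_variants("splice_acceptor_variant&stop_gained")$variant_class))
  # protein HGVS fallback when no terms are present
  fallback <- classify_variants(c(NA, NA, NA),
                                hgvs_p = c("Gln147Ter", "Gln196ProfsTer8",
                                           "p.Ile157Thr"))
  expect_equal(as.character(fallback$variant_class),
               c("STOP_GAIN", "FRAMESHIFT", "MISSENSE"))
  expect_false(any(fallback$class_warning))
  # no usable evidence -> OTHER with a warning flag
  none <- classify_variants(NA_character_)
  expect_equal(as.character(none$variant_class), "OTHER")
  expect_true(none$class_warning)
})

test_that("MutPred2 mechanism strings parse with significance flags", {
  m <- parse_mutpred2_mechanisms(
    "Iron binding (p=7.1352e-05); Catalytic site (p=0.0006); Weak site (p=0.2)")
  expect_equal(m$mechanism, c("Iron binding", "Catalytic site", "Weak site"))
  expect_equal(m$p, c(7.1352e-05, 6e-4, 0.2))
  expect_equal(m$significant, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(parse_mutpred2_mechanisms(NA_character_)), 0)
})

test_that("VEP-annotated VCF reading keeps only canonical transcripts", {
  skip_if_not_installed("vcfR")
  tmp <- withr::local_tempfile(fileext = ".vcf")
  csq_fmt <- "Allele|Consequence|SYMBOL|Feature|CANONICAL|HGVSc|HGVSp|EXON|INTRON|gnomAD_exomes_AF|gnomAD_exomes_NFE_AF|gnomAD_exomes_POPMAX_AF|CADD_PHRED"
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="VEP. Format: ',
           csq_fmt, '">'),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    # two transcript blocks, one canonical -> one record
    paste0("22\t28725099\t.\tT\tC\t.\t.\tCSQ=",
           "C|missense_variant|CHEK2|ENST00000404276|YES|c.470T>C|p.Ile157Thr|4/15||0.0005||0.0008|23.5,",
           "C|missense_variant|CHEK2|ENST00000999999||c.1T>C|p.Ile1Thr|1/2|||||10"),
    # empty AF sub-fields stay absent
    paste0("1\t1000\t.\tG\tA\t.\t.\tCSQ=",
           "A|stop_gained|GENE2|ENST00000000002|YES|c.1G>A|p.Glu1Ter|2/9|||||35")
  ), tmp)
  got <- read_vep_vcf(tmp, family_id = "F1")
  expect_equal(nrow(got), 2)
  chek2 <- got[got$gene_symbol == "CHEK2", ]
  expect_equal(chek2$variant_id, "22_28725099_T_C")
  expect_equal(chek2$cadd_phred, 23.5)
  expect_equal(chek2$exon_index, 4L)
  expect_equal(chek2$exon_total, 15L)
  expect_equal(chek2$af_global, 5e-4)
  expect_true(is.na(chek2$af_nfe))     # empty sub-field, not zero
  g2 <- got[got$gene_symbol == "GENE2", ]
  expect_true(all(is.na(c(g2$af_global, g2$af_nfe, g2$af_popmax))))
  # a block with too many sub-fields names the offending record
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="VEP. Format: ',
           "Allele|Consequence", '">'),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t5\t.\tA\tT\t.\t.\tCSQ=T|missense_variant|extra|fields"
  ), tmp)
  expect_error(read_vep_vcf(tmp), "mismatch")
})

test_that("multi-allelic records split one alternate allele per row", {
  skip_if_not_installed("vcfR")
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=CSQ,Number=.,Type=String,Description="VEP. Format: Allele|Consequence|SYMBOL|Feature|CANONICAL">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("2\t500\t.\tG\tA,C\t.\t.\tCSQ=",
           "A|missense_variant|GENEX|ENST1|YES,",
           "C|stop_gained|GENEX|ENST1|YES")
  ), tmp)
  got <- read_vep_vcf(tmp)
  expect_equal(sort(got$variant_id), c("2_500_G_A", "2_500_G_C"))
  expect_equal(got$consequence_terms[got$alt == "C"], "stop_gained")
})
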