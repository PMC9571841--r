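# Candidate filtering, EMS-spectrum classification, effect annotation and
# CAPS feasibility.

region_fixture <- function() {
  data.frame(chrom = "chrA", start_bp = 1e5, end_bp = 9e5)
}

test_that("filter_candidates keeps homozygous novel variants inside the region", {
  sites <- rbind(
    count_row("chrA", 2e5, 1, 19, 10, 10, ref = "G", alt = "A",
              origin = "INDUCED"),   # AF 0.95: retained
    count_row("chrA", 3e5, 10, 10, 10, 10, origin = "INDUCED"),  # AF 0.5: dropped
    count_row("chrA", 4e5, 0, 5, 5, 5, origin = "INDUCED"),      # depth < 10: dropped
    count_row("chrA", 5e5, 0, 30, 10, 10, ref = "C", alt = "T",
              origin = "INDUCED"),   # in panel: dropped
    count_row("chrA", 95e4, 0, 30, 10, 10, origin = "INDUCED"))  # outside region
  panel <- data.frame(chrom = "chrA", pos = 5e5, ref = "C", alt = "T")
  kept <- filter_candidates(sites, region_fixture(), panel, hom_af = 0.9,
                            min_depth = 10)
  expect_equal(kept$pos, 2e5)
  expect_equal(kept$mut_af, 0.95)
  # same site with different alleles is not masked by the panel entry
  panel_other <- data.frame(chrom = "chrA", pos = 5e5, ref = "C", alt = "G")
  kept2 <- filter_candidates(sites, region_fixture(), panel_other)
  expect_true(5e5 %in% kept2$pos)
})

test_that("filter_candidates warns (not errors) on a region with no sites", {
  sites <- count_row("chrA", 2e5, 0, 30, 10, 10)
  region <- data.frame(chrom = "chrZ", start_bp = 1, end_bp = 1e6)
  expect_warning(out <- filter_candidates(sites, region), "absent")
  expect_equal(nrow(out), 0)
})

test_that("substitution classes agree with the hand-enumerated SNV table", {
  for (i in seq_len(nrow(ORACLE_SNV_CLASS))) {
    expect_equal(
      classify_substitution(ORACLE_SNV_CLASS$ref[i], ORACLE_SNV_CLASS$alt[i]),
      ORACLE_SNV_CLASS$class[i],
      info = paste(ORACLE_SNV_CLASS$ref[i], ">", ORACLE_SNV_CLASS$alt[i]))
  }
  expect_equal(classify_substitution("CA", "C"), "single_base_deletion")
  expect_equal(classify_substitution("C", "CA"), "single_base_insertion")
  expect_equal(classify_substitution("CAT", "C"), "other_indel")
  expect_error(classify_substitution("A", "A"), "identical")
  expect_error(classify_substitution("A", "X"), "A/C/G/T")
})

# 4-codon toy gene on the plus strand: ATG TGG AAA TAA at chrA:101-112.
toy_plus_gene <- function() {
  gene_model("toy", "chrA", "+", data.frame(start = 101, end = 112),
             seq = "ATGTGGAAATAA", seq_start = 101)
}

test_that("SNV annotation distinguishes nonsense, missense and synonymous", {
  g <- toy_plus_gene()
  # TGG -> TGA: stop gained in codon 2, one amino acid retained
  eff <- annotate_variant("chrA", 106, "G", "A", list(g))
  expect_equal(eff$category, "nonsense")
  expect_equal(eff$protein_change, "W2*")
  expect_equal(eff$truncated_protein_length_aa, 1L)
  # TGG -> TCG: missense
  expect_equal(annotate_variant("chrA", 105, "G", "C", list(g))$category,
               "missense")
  # AAA -> GAA (first codon base): missense
  expect_equal(annotate_variant("chrA", 107, "A", "G", list(g))$category,
               "missense")
  # AAA -> AAG (third codon base): synonymous, both lysine
  expect_equal(annotate_variant("chrA", 109, "A", "G", list(g))$category,
               "synonymous")
})

test_that("minus-strand genes are annotated through the reverse complement", {
  # transcript ATG TGG AAA TAA; genomic span is its reverse complement
  tx <- "ATGTGGAAATAA"
  genomic <- oracle_revcomp(tx)
  g <- gene_model("toyminus", "chrA", "-", data.frame(start = 201, end = 212),
                  seq = genomic, seq_start = 201)
  expect_equal(spliced_cds(g), tx)
  # transcript position 6 (G of TGG) sits at genomic 201 + (12 - 6) = 207;
  # transcript G>A is genomic C>T
  eff <- annotate_variant("chrA", 207, "C", "T", list(g))
  expect_equal(eff$category, "nonsense")
  expect_equal(eff$truncated_protein_length_aa, 1L)
})

test_that("positions outside genes and inside introns are labelled accordingly", {
  g <- make_random_gene()
  far <- g$gene_end + 1e4
  expect_equal(annotate_variant("chrA", far, "A", "T", list(g))$category,
               "intergenic")
  intron_pos <- g$cds$end[1] + 5
  expect_equal(annotate_variant("chrA", intron_pos, "A", "T",
                                list(g))$category, "intronic")
})

test_that("boundary-straddling variants are reported as other, not guessed", {
  g <- toy_plus_gene()
  eff <- annotate_variant("chrA", 111, "AAA", "A", list(g))
  expect_equal(eff$category, "other")
  expect_match(eff$note, "boundary")
})

test_that("a single-base CDS deletion is a frameshift with oracle-checked truncation", {
  set.seed(7)
  # 60-codon single-exon gene, deletion in codon 20
  sense <- setdiff(names(ORACLE_CODON), c("TAA", "TAG", "TGA"))
  cds_seq <- paste0("ATG", paste(sample(sense, 58, replace = TRUE),
                                 collapse = ""), "TAA")
  g <- gene_model("g60", "chrA", "+", data.frame(start = 501, end = 680),
                  seq = cds_seq, seq_start = 501)
  pos <- 501 + 3 * 19  # first base of codon 20
  ref <- substr(cds_seq, pos - 500, pos - 499)
  alt <- substr(ref, 1, 1)
  eff <- annotate_variant("chrA", pos, ref, alt, list(g))
  expect_equal(eff$category, "frameshift")
  expect_equal(eff$truncated_protein_length_aa,
               oracle_effect(g, pos, ref, alt)$trunc)
})

test_that("annotation agrees with the naive mutate-and-translate oracle", {
  set.seed(11)
  for (rep in 1:200) {
    g <- make_random_gene()
    seg <- g$cds[sample(1:2, 1), ]
    if (runif(1) < 0.5) {
      # SNV strictly inside a CDS segment
      pos <- sample(seg$start:seg$end, 1)
      ref <- substr(g$seq, pos - g$seq_start + 1, pos - g$seq_start + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else {
      # anchored 1-2 bp deletion fully inside the segment
      width <- sample(1:2, 1)
      pos <- sample(seg$start:(seg$end - width), 1)
      ref <- substr(g$seq, pos - g$seq_start + 1, pos - g$seq_start + width)
      alt <- substr(ref, 1, 1)
    }
    eff <- annotate_variant(g$chrom, pos, ref, alt, list(g))
    orc <- oracle_effect(g, pos, ref, alt)
    expect_equal(eff$category, orc$category,
                 info = sprintf("strand %s pos %d %s>%s", g$strand, pos, ref, alt))
    if (orc$category %in% c("frameshift", "nonsense"))
      expect_equal(eff$truncated_protein_length_aa, orc$trunc)
  }
})

test_that("CAPS feasibility counts cut sites on both strands", {
  # EcoRI site created by the mutant allele only
  wt <- "ACGTACGGAATACCGGTTACGT"
  mut <- "ACGTACGGAATTCCGGTTACGT"
  rep <- caps_feasibility(wt, mut, "GAATTC")
  expect_equal(rep$cuts_wt, 0)
  expect_equal(rep$cuts_mut, 1)
  expect_true(rep$distinguishable)
  expect_false(caps_feasibility(wt, wt, "GAATTC")$distinguishable)
  # non-palindromic site present on the reverse strand only
  amp <- paste0("AAAAAA", oracle_revcomp("GGTCTC"), "AAAAAA")
  expect_equal(caps_feasibility("AAAAAAAAAAAAAAAAAA", amp, "GGTCTC")$cuts_mut, 1)
  expect_error(caps_feasibility(wt, mut, ""), "empty")
})
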