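# Independent oracles used by the tests. These are deliberately coded from
# scratch (hand-written codon table, naive loops) so they share no code with
# the package implementation they check.

ORACLE_CODON <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# Full translation (includes "*" characters), codon by codon.
oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3
  if (n == 0) return("")
  paste(vapply(seq_len(n), function(i)
    ORACLE_CODON[[substr(dna, 3 * i - 2, 3 * i)]], character(1)),
    collapse = "")
}

# Amino acids before the first stop character of a translated protein.
oracle_aa_before_stop <- function(aa) {
  hit <- as.integer(regexpr("*", aa, fixed = TRUE))
  if (hit < 0) nchar(aa) else hit - 1L
}

# Amino acids emitted before the first stop, translating from position 1.
oracle_trunc_len <- function(dna) {
  oracle_aa_before_stop(oracle_translate(dna))
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Naive full-sequence mutate-and-translate oracle: applies the edit to the
# genomic span sequence, shifts CDS coordinates across the indel, re-extracts
# and translates the mutated transcript.
oracle_effect <- function(model, pos, ref, alt) {
  span <- model$seq
  i <- pos - model$seq_start + 1
  stopifnot(substr(span, i, i + nchar(ref) - 1) == ref)
  mut_span <- paste0(substr(span, 1, i - 1), alt,
                     substr(span, i + nchar(ref), nchar(span)))
  delta <- nchar(alt) - nchar(ref)
  cds <- model$cds
  new_cds <- cds
  for (k in seq_len(nrow(cds))) {
    if (cds$start[k] > pos) {
      new_cds$start[k] <- cds$start[k] + delta
      new_cds$end[k] <- cds$end[k] + delta
    } else if (cds$end[k] >= pos) {
      new_cds$end[k] <- cds$end[k] + delta
    }
  }
  extract <- function(seq, segs) {
    paste(vapply(seq_len(nrow(segs)), function(k)
      substr(seq, segs$start[k] - model$seq_start + 1,
             segs$end[k] - model$seq_start + 1), character(1)),
      collapse = "")
  }
  wt_tx <- extract(span, cds)
  mut_tx <- extract(mut_span, new_cds)
  if (model$strand == "-") {
    wt_tx <- oracle_revcomp(wt_tx)
    mut_tx <- oracle_revcomp(mut_tx)
  }
  if (delta != 0) {
    if (abs(delta) %% 3 == 0)
      return(list(category = "other", trunc = NA_integer_))
    return(list(category = "frameshift",
                trunc = oracle_trunc_len(mut_tx)))
  }
  wt_aa <- oracle_translate(wt_tx)
  mut_aa <- oracle_translate(mut_tx)
  d <- which(strsplit(wt_aa, "")[[1]] != strsplit(mut_aa, "")[[1]])
  if (length(d) == 0) return(list(category = "synonymous", trunc = NA_integer_))
  if (substr(mut_aa, d[1], d[1]) == "*")
    return(list(category = "nonsense", trunc = oracle_aa_before_stop(mut_aa)))
  list(category = "missense", trunc = NA_integer_)
}

# Hand enumeration of the 12 ordered SNV pairs (transition/transversion
# chemistry written out explicitly).
ORACLE_SNV_CLASS <- data.frame(
  ref = c("G", "C", "A", "T", "A", "A", "G", "G", "C", "C", "T", "T"),
  alt = c("A", "T", "G", "C", "C", "T", "C", "T", "A", "G", "A", "G"),
  class = c("GC_to_AT_transition", "GC_to_AT_transition",
            "AT_to_GC_transition", "AT_to_GC_transition",
            rep("transversion", 8)))

# Random toy gene for the annotation property test: two CDS exons on a
# random strand, placed on a small chromosome.
make_random_gene <- function(gene_id = "g1", chrom = "chrA") {
  sense <- setdiff(names(ORACLE_CODON), c("TAA", "TAG", "TGA"))
  n1 <- 3 * sample(8:20, 1)  # exon lengths, multiples of 3 for clean toys
  n2 <- 3 * sample(8:20, 1)
  cds_seq <- paste0("ATG",
                    paste(sample(sense, (n1 + n2) / 3 - 2, replace = TRUE),
                          collapse = ""), "TAA")
  span_start <- 1001
  exon1 <- c(span_start + 50, span_start + 50 + n1 - 1)
  intron_len <- sample(30:80, 1)
  exon2 <- c(exon1[2] + intron_len + 1, exon1[2] + intron_len + n2)
  span_len <- exon2[2] - span_start + 1 + 60
  bases <- c("A", "C", "G", "T")
  seq <- paste(sample(bases, span_len, replace = TRUE), collapse = "")
  strand <- sample(c("+", "-"), 1)
  genomic_cds <- if (strand == "-") oracle_revcomp(cds_seq) else cds_seq
  put <- function(seq, at, what) {
    paste0(substr(seq, 1, at - 1), what,
           substr(seq, at + nchar(what), nchar(seq)))
  }
  seq <- put(seq, exon1[1] - span_start + 1, substr(genomic_cds, 1, n1))
  seq <- put(seq, exon2[1] - span_start + 1,
             substr(genomic_cds, n1 + 1, n1 + n2))
  gene_model(gene_id, chrom, strand,
             data.frame(start = c(exon1[1], exon2[1]),
                        end = c(exon1[2], exon2[2])),
             seq, seq_start = span_start, gene_start = span_start,
             gene_end = span_start + span_len - 1)
}
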