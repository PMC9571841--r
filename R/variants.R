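# Candidate-variant triage inside a detected region: homozygous + novel
# filtering, EMS-spectrum classification, and functional-impact annotation
# against single-transcript gene models. Coordinates are 1-based inclusive
# and indels use VCF-style anchored alleles (first base shared).

#' Filter for homozygous, novel candidate mutations
#'
#' Keeps sites inside the region whose mutant-pool allele frequency is at
#' least `hom_af` (homozygous state) at depth >= `min_depth`, and whose
#' `(chrom, pos, ref, alt)` key is absent from the known-variants panel — the
#' "unique mutations in homozygous state" triage step.
#'
#' @param sites Count table.
#' @param region One region: a single-row data.frame (or list) with `chrom`,
#'   `start_bp`, `end_bp`, as returned by [detect_candidate_region()].
#' @param panel Known-variants panel: data.frame with `chrom`, `pos`, `ref`,
#'   `alt` (or `NULL` for no panel).
#' @param hom_af Homozygosity threshold in `(0.5, 1]` (default 0.9).
#' @param min_depth Minimum mutant-pool depth (default 10).
#' @return Filtered rows sorted by position, with `mut_af` and `mut_depth`
#'   columns appended.
#' @export
filter_candidates <- function(sites, region, panel = NULL, hom_af = 0.9,
                              min_depth = 10) {
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1)
    region <- as.list(region)
  }
  if (!(hom_af > 0.5 && hom_af <= 1)) stop("hom_af must be in (0.5, 1]")
  if (!region$chrom %in% sites$chrom) {
    warning("region chromosome ", region$chrom, " absent from sites")
    out <- sites[0, , drop = FALSE]
    out$mut_af <- numeric(0)
    out$mut_depth <- numeric(0)
    return(out)
  }
  s <- sites[sites$chrom == region$chrom &
               sites$pos >= region$start_bp & sites$pos <= region$end_bp, ,
             drop = FALSE]
  s$mut_depth <- s$mut_ref + s$mut_alt
  s$mut_af <- compute_af(s$mut_ref, s$mut_alt)
  keep <- !is.na(s$mut_af) & s$mut_af >= hom_af & s$mut_depth >= min_depth
  if (!is.null(panel) && nrow(panel) > 0) {
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    keep <- keep & !(key(s) %in% key(panel))
  }
  out <- s[keep, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a substitution or indel against the EMS spectrum
#'
#' EMS alkylates guanine, so G:C -> A:T transitions (`G>A`, `C>T`) dominate
#' the induced spectrum; the remaining single-nucleotide changes are the
#' `A>G`/`T>C` transition pair or transversions, and length changes are
#' classified by size.
#'
#' @param ref,alt Allele strings over A/C/G/T, `ref != alt`.
#' @return One of `"GC_to_AT_transition"`, `"AT_to_GC_transition"`,
#'   `"transversion"`, `"single_base_deletion"`, `"single_base_insertion"`,
#'   `"other_indel"`.
#' @examples
#' classify_substitution("G", "A")  # GC_to_AT_transition
#' classify_substitution("CA", "C") # single_base_deletion
#' @export
classify_substitution <- function(ref, alt) {
  if (length(ref) != 1 || length(alt) != 1) stop("one variant at a time")
  if (identical(ref, alt)) stop("ref and alt are identical")
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
    stop("alleles must be non-empty A/C/G/T strings")
  dl <- nchar(alt) - nchar(ref)
  if (dl == 0 && nchar(ref) == 1) {
    if ((ref == "G" && alt == "A") || (ref == "C" && alt == "T"))
      return("GC_to_AT_transition")
    if ((ref == "A" && alt == "G") || (ref == "T" && alt == "C"))
      return("AT_to_GC_transition")
    return("transversion")
  }
  if (dl == -1 && nchar(alt) >= 1) return("single_base_deletion")
  if (dl == 1) return("single_base_insertion")
  "other_indel"
}

#' Construct a single-transcript gene model
#'
#' @param gene_id Identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds data.frame with 1-based inclusive `start`, `end`; segments must
#'   be sorted by genome coordinate and non-overlapping.
#' @param seq Genomic sequence covering at least `[gene_start, gene_end]`.
#' @param seq_start Genomic position of `substr(seq, 1, 1)` (default
#'   `gene_start`).
#' @param gene_start,gene_end Gene span (defaults: CDS extent). Positions
#'   inside the span but outside every CDS segment are annotated intronic.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds, seq,
                       seq_start = NULL, gene_start = NULL, gene_end = NULL) {
  strand <- match.arg(strand, c("+", "-"))
  stopifnot(is.data.frame(cds), all(c("start", "end") %in% names(cds)),
            nrow(cds) >= 1)
  cds <- cds[order(cds$start), , drop = FALSE]
  if (any(cds$end < cds$start)) stop("CDS segment with end < start")
  if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)]))
    stop("overlapping CDS segments")
  gene_start <- gene_start %||% min(cds$start)
  gene_end <- gene_end %||% max(cds$end)
  seq_start <- seq_start %||% gene_start
  if (!grepl("^[ACGTN]*$", seq)) stop("sequence must be A/C/G/T/N")
  if (seq_start > gene_start || seq_start + nchar(seq) - 1 < gene_end)
    stop("sequence does not cover the gene span")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds = cds, seq = seq, seq_start = seq_start,
                 gene_start = gene_start, gene_end = gene_end),
            class = "gene_model")
}

# Spliced CDS in genome orientation (no strand flip).
cds_genomic_seq <- function(model) {
  paste(vapply(seq_len(nrow(model$cds)), function(i) {
    substr(model$seq, model$cds$start[i] - model$seq_start + 1,
           model$cds$end[i] - model$seq_start + 1)
  }, character(1)), collapse = "")
}

#' Spliced coding sequence of a gene model (strand-aware)
#' @param model A [gene_model()].
#' @return Character: the mRNA-orientation CDS (reverse-complemented for
#'   minus-strand genes).
#' @export
spliced_cds <- function(model) {
  g <- cds_genomic_seq(model)
  if (model$strand == "-") revcomp_chr(g) else g
}

translate_chr <- function(dna) {
  n <- 3 * (nchar(dna) %/% 3)
  if (n == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(dna, 1, n)),
                                     no.init.codon = TRUE))
}

# Amino acids emitted before the first stop when translating `dna` from
# position 1 (whole protein length if no stop is reached).
translated_length_aa <- function(dna) {
  aa <- translate_chr(dna)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at < 0) nchar(aa) else stop_at - 1L
}

variant_effect <- function(category, gene_id = NA_character_,
                           protein_change = NA_character_,
                           truncated_protein_length_aa = NA_integer_,
                           note = NA_character_) {
  list(category = category, gene_id = gene_id,
       protein_change = protein_change,
       truncated_protein_length_aa = truncated_protein_length_aa,
       note = note)
}

#' Annotate the functional impact of a variant
#'
#' Positions outside all gene spans are intergenic; inside a gene but outside
#' its CDS, intronic. Within the CDS: an indel whose length change is not a
#' multiple of three is a frameshift; an SNV is translated through the
#' standard genetic code (strand-aware) and called synonymous, nonsense
#' (stop gained) or missense. For frameshift and nonsense variants the
#' truncated protein length is the number of amino acids emitted before the
#' first stop when translating the mutated spliced CDS. Variants straddling a
#' CDS/intron or gene boundary (and in-frame indels) are reported as
#' `"other"` with a diagnostic note rather than guessed.
#'
#' @param chrom,pos,ref,alt The variant (1-based, VCF-anchored alleles).
#' @param models List of [gene_model()] objects.
#' @return A variant-effect list: `category`, `gene_id`, `protein_change`,
#'   `truncated_protein_length_aa` (frameshift/nonsense only), `note`.
#' @export
annotate_variant <- function(chrom, pos, ref, alt, models) {
  span_end <- pos + nchar(ref) - 1
  hit <- NULL
  for (m in models) {
    if (m$chrom == chrom && span_end >= m$gene_start && pos <= m$gene_end) {
      hit <- m
      break
    }
  }
  if (is.null(hit)) return(variant_effect("intergenic"))
  if (pos < hit$gene_start || span_end > hit$gene_end)
    return(variant_effect("other", hit$gene_id,
                          note = "variant straddles the gene boundary"))
  seg <- which(hit$cds$start <= span_end & hit$cds$end >= pos)
  if (length(seg) == 0)
    return(variant_effect("intronic", hit$gene_id))
  if (length(seg) > 1 || pos < hit$cds$start[seg] || span_end > hit$cds$end[seg])
    return(variant_effect("other", hit$gene_id,
                          note = "variant overlaps a CDS/intron boundary"))
  cds_len <- sum(hit$cds$end - hit$cds$start + 1)
  # offset of pos within the genome-orientation spliced CDS
  prior <- if (seg > 1) sum(hit$cds$end[1:(seg - 1)] - hit$cds$start[1:(seg - 1)] + 1) else 0
  g_off <- prior + (pos - hit$cds$start[seg]) + 1
  g_cds <- cds_genomic_seq(hit)
  observed_ref <- substr(g_cds, g_off, g_off + nchar(ref) - 1)
  note <- NA_character_
  if (!identical(observed_ref, ref))
    note <- sprintf("ref allele %s does not match model sequence %s", ref,
                    observed_ref)
  mut_g_cds <- paste0(substr(g_cds, 1, g_off - 1), alt,
                      substr(g_cds, g_off + nchar(ref), cds_len))
  wt_cds <- if (hit$strand == "-") revcomp_chr(g_cds) else g_cds
  mut_cds <- if (hit$strand == "-") revcomp_chr(mut_g_cds) else mut_g_cds
  if (nchar(ref) != nchar(alt)) {
    shift <- abs(nchar(ref) - nchar(alt))
    if (shift %% 3 == 0)
      return(variant_effect("other", hit$gene_id,
                            note = "in-frame indel (no frameshift)"))
    # first transcript position at which the mutated CDS diverges
    minlen <- min(nchar(wt_cds), nchar(mut_cds))
    diff_at <- which(utf8ToInt(substr(wt_cds, 1, minlen)) !=
                       utf8ToInt(substr(mut_cds, 1, minlen)))
    first_diff <- if (length(diff_at)) diff_at[1] else minlen + 1L
    codon <- ceiling(first_diff / 3)
    trunc <- translated_length_aa(mut_cds)
    return(variant_effect("frameshift", hit$gene_id,
                          protein_change = sprintf("fs@codon%d", codon),
                          truncated_protein_length_aa = as.integer(trunc),
                          note = note))
  }
  # SNV
  t_pos <- if (hit$strand == "-") cds_len - g_off + 1 else g_off
  codon_idx <- ceiling(t_pos / 3)
  codon_from <- function(s) substr(s, 3 * codon_idx - 2, 3 * codon_idx)
  wt_aa <- translate_chr(codon_from(wt_cds))
  mut_aa <- translate_chr(codon_from(mut_cds))
  if (identical(wt_aa, mut_aa))
    return(variant_effect("synonymous", hit$gene_id,
                          protein_change = sprintf("%s%d=", wt_aa, codon_idx),
                          note = note))
  if (identical(mut_aa, "*"))
    return(variant_effect("nonsense", hit$gene_id,
                          protein_change = sprintf("%s%d*", wt_aa, codon_idx),
                          truncated_protein_length_aa =
                            as.integer(translated_length_aa(mut_cds)),
                          note = note))
  variant_effect("missense", hit$gene_id,
                 protein_change = sprintf("%s%d%s", wt_aa, codon_idx, mut_aa),
                 note = note)
}

#' Annotate every row of a variant table
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param models List of [gene_model()]s.
#' @return `sites` with `effect`, `gene_id`, `protein_change`,
#'   `truncated_protein_length_aa` columns appended.
#' @export
annotate_variants <- function(sites, models) {
  eff <- lapply(seq_len(nrow(sites)), function(i)
    annotate_variant(sites$chrom[i], sites$pos[i], sites$ref[i], sites$alt[i],
                     models))
  sites$effect <- vapply(eff, `[[`, character(1), "category")
  sites$gene_id <- vapply(eff, `[[`, character(1), "gene_id")
  sites$protein_change <- vapply(eff, `[[`, character(1), "protein_change")
  sites$truncated_protein_length_aa <-
    vapply(eff, `[[`, integer(1), "truncated_protein_length_aa")
  sites
}

# Unique genomic positions at which `site` matches `amplicon` on either
# strand.
count_recognition_sites <- function(amplicon, site) {
  a <- Biostrings::DNAString(amplicon)
  fwd <- Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(site), a))
  rev <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(site)), a))
  length(union(fwd, rev))
}

#' CAPS marker feasibility
#'
#' Checks whether a restriction enzyme distinguishes the wild-type and mutant
#' alleles of a PCR amplicon: counts exact occurrences of the recognition
#' site on both strands of each amplicon (unique cut positions); the digest
#' patterns are distinguishable iff the counts differ — e.g. a site created
#' by the mutant allele digests the mutant amplicon into two fragments while
#' leaving the WT amplicon intact.
#'
#' @param wt_amplicon,mut_amplicon A/C/G/T amplicon sequences.
#' @param recognition_site Non-empty A/C/G/T recognition sequence.
#' @return list with `cuts_wt`, `cuts_mut`, `distinguishable`.
#' @export
caps_feasibility <- function(wt_amplicon, mut_amplicon, recognition_site) {
  if (!nzchar(recognition_site)) stop("empty recognition site")
  for (s in c(wt_amplicon, mut_amplicon, recognition_site))
    if (!grepl("^[ACGT]+$", s)) stop("sequences must be A/C/G/T strings")
  cuts_wt <- count_recognition_sites(wt_amplicon, recognition_site)
  cuts_mut <- count_recognition_sites(mut_amplicon, recognition_site)
  list(cuts_wt = cuts_wt, cuts_mut = cuts_mut,
       distinguishable = cuts_wt != cuts_mut)
}
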