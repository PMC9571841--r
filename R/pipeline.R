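# End-to-end wiring: default study configuration, full-experiment simulation
# with ground truth, and the analysis pipeline (profile -> detect -> filter
# -> annotate -> report).

#' Default study configuration
#'
#' Desk-scale analog of an interspecific tomato bulk-segregant design:
#' 2 chromosomes x 50 Mb (60 cM each), interspecific markers every 100 kb,
#' a recessive causal single-base deletion near the end of chr2, 300
#' EMS-spectrum background mutations (0.90 / 0.05 / 0.05), pools of 15 + 15
#' F2 plants sequenced at mean depth 50 with per-read error 0.002, and the
#' window/threshold defaults of the detector and variant filter. Every value
#' can be overridden; unknown keys are rejected.
#'
#' @param ... Overrides, e.g. `default_config(depth_mean = 30)`.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
    chrom_cM = c(chr1 = 60, chr2 = 60),
    marker_spacing_bp = 1e5,
    causal_chrom = "chr2",
    causal_pos = 4.5e7,
    n_f2 = 200,
    pool_size_mut = 15,
    pool_size_wt = 15,
    depth_mean = 50,
    error_rate = 0.002,
    n_background_mutations = 300,
    spectrum = c(GC_to_AT_transition = 0.90, other_substitution = 0.05,
                 single_base_deletion = 0.05),
    n_decoy_genes = 4,
    window_bp = 1e6,
    step_bp = 2.5e5,
    min_sites = 3,
    min_depth = 10,
    tau_mut = 0.05,
    wt_band = c(0.45, 0.85),
    min_run = 3,
    pad_bp = 1.75e6,
    hom_af = 0.9,
    filter_min_depth = 10)
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

# Random codon sequence of `n_codons` with a start codon, no internal stop,
# and a terminal stop.
random_cds_seq <- function(n_codons) {
  codons <- apply(expand.grid(DNA_BASES_CHR, DNA_BASES_CHR, DNA_BASES_CHR),
                  1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG",
         paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
         "TAA")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES_CHR, n, replace = TRUE), collapse = "")
}

# Toy gene models: a two-exon gene whose second exon contains the causal
# position, plus single-exon decoys elsewhere.
simulate_gene_models <- function(map, causal_chrom, causal_pos,
                                 n_decoys = 4, seed = NULL) {
  with_seed(seed, {
    models <- list()
    span_start <- causal_pos - 1500
    exon1 <- c(span_start + 300, span_start + 899)    # 600 bp
    exon2 <- c(causal_pos - 300, causal_pos + 299)    # 600 bp, causal inside
    cds_len <- 1200
    cds_seq <- random_cds_seq(cds_len / 3)
    seq <- random_dna(3300)
    put <- function(seq, from_genomic, what, span_start) {
      i <- from_genomic - span_start + 1
      paste0(substr(seq, 1, i - 1), what, substr(seq, i + nchar(what), nchar(seq)))
    }
    seq <- put(seq, exon1[1], substr(cds_seq, 1, 600), span_start)
    seq <- put(seq, exon2[1], substr(cds_seq, 601, 1200), span_start)
    models[["gene_causal"]] <- gene_model(
      "gene_causal", causal_chrom, "+",
      data.frame(start = c(exon1[1], exon2[1]), end = c(exon1[2], exon2[2])),
      seq, seq_start = span_start, gene_start = span_start,
      gene_end = span_start + 3299)
    chrs <- map$chromosomes
    for (k in seq_len(n_decoys)) {
      j <- ((k - 1) %% nrow(chrs)) + 1
      center <- floor(chrs$length_bp[j] * (0.15 + 0.15 * k))
      if (chrs$name[j] == causal_chrom && abs(center - causal_pos) < 1e6)
        center <- center - 2e6
      g_start <- center - 500
      cds <- random_cds_seq(100)  # 300 bp
      seq <- random_dna(1000)
      seq <- put(seq, center - 150, cds, g_start)
      gid <- sprintf("gene_decoy%d", k)
      models[[gid]] <- gene_model(gid, chrs$name[j], sample(c("+", "-"), 1),
                                  data.frame(start = center - 150,
                                             end = center + 149),
                                  seq, seq_start = g_start,
                                  gene_start = g_start, gene_end = g_start + 999)
    }
    models
  })
}

# Make induced-variant alleles inside gene spans consistent with the gene
# sequence (so annotation sees matching reference bases).
harmonize_alleles <- function(sites, models) {
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  for (i in seq_len(nrow(sites))) {
    if (sites$origin[i] != "INDUCED") next
    for (m in models) {
      if (m$chrom != sites$chrom[i] || sites$pos[i] < m$gene_start ||
          sites$pos[i] > m$gene_end) next
      at <- sites$pos[i] - m$seq_start + 1
      actual <- substr(m$seq, at, at + nchar(sites$ref[i]) - 1)
      if (identical(actual, sites$ref[i])) break
      if (nchar(sites$ref[i]) == nchar(sites$alt[i])) {
        base <- substr(actual, 1, 1)
        sites$ref[i] <- base
        sites$alt[i] <- transition[[base]]
      } else {
        sites$ref[i] <- actual
        sites$alt[i] <- substr(actual, 1, 1)
      }
      sites$category[i] <- classify_substitution(sites$ref[i], sites$alt[i])
      break
    }
  }
  sites
}

#' Simulate a complete bulk-segregant experiment
#'
#' Generates every input of the analysis: the genetic map, toy gene models
#' (the causal gene plus decoys), the F2 population, phenotype-stratified
#' pools, interspecific markers, EMS-spectrum background mutations, the
#' causal single-base CDS deletion, and pooled sequencing counts; ground
#' truth is recorded alongside.
#'
#' @param config Configuration from [default_config()].
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return Object of class `bsa_simulation`: list with `map`, `models`,
#'   `population`, `pools`, `counts`, `markers`, `truth`.
#' @export
simulate_bsa_experiment <- function(config = default_config(), seed = 1) {
  chrs <- data.frame(name = names(config$chrom_lengths),
                     length_bp = as.numeric(config$chrom_lengths),
                     length_cM = as.numeric(config$chrom_cM[names(config$chrom_lengths)]))
  map <- genetic_map(chrs, causal_locus = list(chrom = config$causal_chrom,
                                               pos = config$causal_pos))
  models <- simulate_gene_models(map, config$causal_chrom, config$causal_pos,
                                 n_decoys = config$n_decoy_genes,
                                 seed = derive_seed(seed, 1))
  causal_gene <- models[["gene_causal"]]
  at <- config$causal_pos - causal_gene$seq_start + 1
  causal <- list(chrom = config$causal_chrom, pos = config$causal_pos,
                 ref = substr(causal_gene$seq, at, at + 1),
                 alt = substr(causal_gene$seq, at, at))
  markers <- place_markers(map, config$marker_spacing_bp)
  induced <- spike_ems_mutations(map, config$n_background_mutations,
                                 spectrum = config$spectrum,
                                 seed = derive_seed(seed, 2), causal = causal)
  induced <- harmonize_alleles(induced, models)
  # induced sites take precedence over a marker at the same position
  markers <- markers[!(paste(markers$chrom, markers$pos) %in%
                         paste(induced$chrom, induced$pos)), , drop = FALSE]
  sites <- rbind(markers, induced)
  pop <- simulate_f2_population(map, config$n_f2, seed = derive_seed(seed, 3))
  pools <- build_pools(pop, config$pool_size_mut, config$pool_size_wt,
                       seed = derive_seed(seed, 4))
  counts <- simulate_pool_counts(sites, pools, depth_mean = config$depth_mean,
                                 error_rate = config$error_rate,
                                 seed = derive_seed(seed, 5))
  truth <- list(seed = seed,
                pool_size_mut = config$pool_size_mut,
                pool_size_wt = config$pool_size_wt,
                depth_mean = config$depth_mean,
                error_rate = config$error_rate,
                spectrum = as.list(config$spectrum),
                causal = causal,
                n_background = sum(induced$origin == "INDUCED") - 1L,
                config_hash = fingerprint(config))
  structure(list(map = map, models = models, population = pop, pools = pools,
                 counts = counts, markers = markers, truth = truth,
                 config = config),
            class = "bsa_simulation")
}

severity_rank <- c(frameshift = 1, nonsense = 2, missense = 3, synonymous = 4,
                   intronic = 5, intergenic = 6, other = 7)

#' Run the full mapping-by-sequencing analysis on a simulated experiment
#'
#' Simulates the experiment, builds both pool profiles, detects the candidate
#' region, filters for homozygous novel variants inside the top region (the
#' interspecific marker panel plays the known-variants panel), annotates the
#' survivors, and reports the top candidate ranked by impact severity
#' (frameshift > nonsense > missense > ...), ties broken by mutant-pool
#' allele frequency then position.
#'
#' @param config Configuration from [default_config()].
#' @param seed Master seed.
#' @param out_dir Optional output directory; when given, counts (VCF + TSV),
#'   window table, regions, candidates, gene models (GFF3 + FASTA), truth and
#'   report JSON, and the effective config are written there.
#' @return List with `sim`, `profiles`, `regions`, `candidates`, `report`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1, out_dir = NULL) {
  sim <- simulate_bsa_experiment(config, seed)
  lens <- chrom_lengths(sim$map)
  prof_mut <- build_profile(sim$counts, "MUT", lens, config$window_bp,
                            config$step_bp, config$min_sites, config$min_depth)
  prof_wt <- build_profile(sim$counts, "WT", lens, config$window_bp,
                           config$step_bp, config$min_sites, config$min_depth)
  regions <- detect_candidate_region(prof_mut, prof_wt, config$tau_mut,
                                     config$wt_band, config$min_run,
                                     config$pad_bp)
  candidates <- NULL
  top <- NULL
  if (nrow(regions) > 0) {
    candidates <- filter_candidates(sim$counts, regions[1, ],
                                    panel = sim$markers,
                                    hom_af = config$hom_af,
                                    min_depth = config$filter_min_depth)
    if (nrow(candidates) > 0) {
      candidates <- annotate_variants(candidates, sim$models)
      ord <- order(severity_rank[candidates$effect], -candidates$mut_af,
                   candidates$pos)
      candidates <- candidates[ord, , drop = FALSE]
      rownames(candidates) <- NULL
      top <- as.list(candidates[1, c("chrom", "pos", "ref", "alt", "effect",
                                     "gene_id", "protein_change",
                                     "truncated_protein_length_aa",
                                     "mut_af")])
    }
  }
  report <- list(version = as.character(utils::packageVersion("emsmap")),
                 seed = seed, config_hash = sim$truth$config_hash,
                 n_regions = nrow(regions),
                 top_region = if (nrow(regions) > 0) as.list(regions[1, ]) else NULL,
                 n_candidates = if (is.null(candidates)) 0L else nrow(candidates),
                 top_candidate = top)
  result <- list(sim = sim, profiles = list(MUT = prof_mut, WT = prof_wt),
                 regions = regions, candidates = candidates, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- list(seed = seed, config_hash = sim$truth$config_hash,
                 version = report$version)
    write_vcf_counts(sim$counts, file.path(out_dir, "pool_counts.vcf"), lens,
                     provenance = prov)
    write_tsv(sim$counts, file.path(out_dir, "pool_counts.tsv"), prov)
    write_tsv(af_table(prof_mut, prof_wt), file.path(out_dir, "af_windows.tsv"),
              prov)
    write_tsv(regions, file.path(out_dir, "regions.tsv"), prov)
    if (!is.null(candidates))
      write_tsv(candidates, file.path(out_dir, "candidates.tsv"), prov)
    write_gff3_models(sim$models, file.path(out_dir, "genes.gff3"),
                      file.path(out_dir, "genes.fasta"))
    write_json_doc(sim$truth, file.path(out_dir, "truth.json"))
    write_json_doc(report, file.path(out_dir, "report.json"))
    cfg <- sim$config
    cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
    cfg$chrom_cM <- as.list(cfg$chrom_cM)
    cfg$spectrum <- as.list(cfg$spectrum)
    write_json_doc(cfg, file.path(out_dir, "config.json"))
  }
  result
}
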