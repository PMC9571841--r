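# Readers and writers for the interchange formats: VCF 4.2 with per-sample
# allelic depths (canonical), TSV mirrors with provenance headers, GFF3 gene
# models, FASTA, and JSON truth/report documents. Writers are deterministic:
# fixed column order, "."-style missing markers, LF line endings.

na_dot <- function(x) ifelse(is.na(x), ".", as.character(x))

#' Write a pooled count table as VCF 4.2
#'
#' Two samples (`MUT`, `WT`) carry `AD` (ref,alt allelic depths) and `DP` per
#' sample; the site origin (interspecific marker vs induced mutation) is kept
#' in the `ORIGIN` INFO key. Output is byte-deterministic.
#'
#' @param sites Count table (chrom, pos, ref, alt, origin, mut_ref, mut_alt,
#'   wt_ref, wt_alt).
#' @param path Output path.
#' @param chrom_lengths Optional named lengths for `##contig` headers.
#' @param provenance Optional named list echoed as `##emsmap_<key>=` headers
#'   (e.g. seed, config hash).
#' @return `path`, invisibly.
#' @export
write_vcf_counts <- function(sites, path, chrom_lengths = NULL,
                             provenance = NULL) {
  chrom_order <- unique(sites$chrom[natural_order(sites$chrom)])
  sites <- sites[order(match(sites$chrom, chrom_order), sites$pos), , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=emsmap ", as.character(utils::packageVersion("emsmap"))))
  for (key in names(provenance))
    hdr <- c(hdr, sprintf("##emsmap_%s=%s", key, provenance[[key]]))
  for (cn in names(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", cn,
                          as.integer(chrom_lengths[[cn]])))
  hdr <- c(hdr,
           "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Site origin: MARKER or INDUCED\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", "MUT", "WT", sep = "\t"))
  fmt_sample <- function(ref, alt) {
    ifelse(is.na(ref) | is.na(alt), ".,.:.",
           sprintf("%d,%d:%d", as.integer(ref), as.integer(alt),
                   as.integer(ref + alt)))
  }
  body <- paste(sites$chrom, as.integer(sites$pos), ".", sites$ref, sites$alt,
                ".", "PASS", paste0("ORIGIN=", sites$origin), "AD:DP",
                fmt_sample(sites$mut_ref, sites$mut_alt),
                fmt_sample(sites$wt_ref, sites$wt_alt), sep = "\t")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

parse_ad <- function(ad) {
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1)))
  alt <- suppressWarnings(as.numeric(vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1))))
  list(ref = ref, alt = alt)
}

#' Read a pooled count table from VCF
#'
#' Parses biallelic SNV/indel records of a VCF 4.x file whose `MUT` and `WT`
#' samples carry `AD` allelic depths; multi-allelic records are skipped with
#' a warning. `AD` values of `.,.` yield missing counts with the row
#' retained.
#'
#' @param path VCF path (plain or gzipped).
#' @return Count table data.frame (chrom, pos, ref, alt, origin, mut_ref,
#'   mut_alt, wt_ref, wt_alt).
#' @export
read_vcf_counts <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("no records in ", path)
  gt <- v@gt
  for (sample in c("MUT", "WT"))
    if (!sample %in% colnames(gt))
      stop("sample ", sample, " absent from ", path)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) skipped")
  fmt <- gt[, "FORMAT"]
  if (any(!grepl("(^|:)AD(:|$)", fmt))) {
    bad <- which(!grepl("(^|:)AD(:|$)", fmt))[1]
    stop(sprintf("AD field missing at record %d (samples MUT/WT)", bad))
  }
  ad_mut <- parse_ad(vcfR::extract.gt(v, element = "AD")[, "MUT"])
  ad_wt <- parse_ad(vcfR::extract.gt(v, element = "AD")[, "WT"])
  info <- vcfR::getINFO(v)
  origin <- sub(".*ORIGIN=([^;]+).*", "\\1", info)
  origin[!grepl("ORIGIN=", info)] <- NA_character_
  keep <- !multi
  data.frame(chrom = fix[keep, "CHROM"], pos = as.numeric(fix[keep, "POS"]),
             ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
             origin = origin[keep],
             mut_ref = ad_mut$ref[keep], mut_alt = ad_mut$alt[keep],
             wt_ref = ad_wt$ref[keep], wt_alt = ad_wt$alt[keep],
             stringsAsFactors = FALSE)
}

#' Write / read a data.frame as deterministic TSV
#'
#' Fixed column order as given, `NA` written as `.`, LF line endings, and an
#' optional provenance header of `# key: value` lines.
#'
#' @param x data.frame.
#' @param path Output path.
#' @param provenance Optional named list written as comment headers.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (key in names(provenance))
    writeLines(sprintf("# %s: %s", key, provenance[[key]]), con, sep = "\n")
  writeLines(paste(names(x), collapse = "\t"), con, sep = "\n")
  if (nrow(x) > 0) {
    cols <- lapply(x, function(col) {
      if (is.numeric(col)) {
        out <- format(col, trim = TRUE, digits = 15, scientific = FALSE)
        out[is.na(col)] <- "."
        out
      } else {
        na_dot(col)
      }
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = ".",
                    stringsAsFactors = FALSE)
}

#' Read gene models from GFF3 (+ FASTA)
#'
#' Assembles single-transcript [gene_model()]s from `gene` and `CDS` features
#' (CDS grouped by `Parent`). Sequences are attached from the FASTA: records
#' named after chromosomes provide genomic context directly; records named
#' after gene IDs are taken as the gene-span sequence.
#'
#' @param gff_path GFF3 file.
#' @param fasta_path FASTA file.
#' @return List of `gene_model` objects.
#' @export
read_gff3_models <- function(gff_path, fasta_path) {
  gff <- ape::read.gff(gff_path)
  seqs <- read_fasta(fasta_path)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]+"), attrs))
    ifelse(lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "=[^;]+"), attrs))) > 0,
           sub(paste0(".*", key, "="), "", m), NA_character_)
  }
  genes <- gff[gff$type == "gene", , drop = FALSE]
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) stop("no CDS features in ", gff_path)
  cds_parent <- vapply(as.character(cds$attributes), function(a) {
    m <- regmatches(a, regexpr("Parent=[^;]+", a))
    if (length(m) == 0) stop("CDS feature without Parent attribute")
    sub("Parent=", "", m)
  }, character(1), USE.NAMES = FALSE)
  gene_ids <- vapply(as.character(genes$attributes), function(a) {
    m <- regmatches(a, regexpr("ID=[^;]+", a))
    if (length(m) == 0) stop("gene feature without ID attribute")
    sub("ID=", "", m)
  }, character(1), USE.NAMES = FALSE)
  lapply(seq_len(nrow(genes)), function(i) {
    gid <- gene_ids[i]
    gcds <- cds[cds_parent == gid, , drop = FALSE]
    if (nrow(gcds) == 0) stop("gene ", gid, " has no CDS children")
    chrom <- as.character(genes$seqid[i])
    g_start <- genes$start[i]
    g_end <- genes$end[i]
    if (gid %in% names(seqs)) {
      seq <- seqs[[gid]]
      seq_start <- g_start
    } else if (chrom %in% names(seqs)) {
      seq <- substr(seqs[[chrom]], g_start, g_end)
      seq_start <- g_start
    } else {
      stop("no sequence for gene ", gid, " (neither gene nor chromosome record)")
    }
    if (nchar(seq) < g_end - g_start + 1)
      stop("sequence shorter than the span of gene ", gid)
    gene_model(gid, chrom, as.character(genes$strand[i]),
               data.frame(start = gcds$start, end = gcds$end), seq,
               seq_start = seq_start, gene_start = g_start, gene_end = g_end)
  })
}

#' Write gene models as GFF3 plus a gene-span FASTA
#'
#' @param models List of [gene_model()]s.
#' @param gff_path,fasta_path Output paths.
#' @return `gff_path`, invisibly.
#' @export
write_gff3_models <- function(models, gff_path, fasta_path = NULL) {
  lines <- "##gff-version 3"
  for (m in models) {
    lines <- c(lines,
               paste(m$chrom, "emsmap", "gene", m$gene_start, m$gene_end, ".",
                     m$strand, ".", paste0("ID=", m$gene_id), sep = "\t"))
    for (i in seq_len(nrow(m$cds)))
      lines <- c(lines,
                 paste(m$chrom, "emsmap", "CDS", m$cds$start[i], m$cds$end[i],
                       ".", m$strand, "0", paste0("ID=", m$gene_id, ".cds", i,
                                                  ";Parent=", m$gene_id),
                       sep = "\t"))
  }
  con <- file(gff_path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  if (!is.null(fasta_path)) {
    spans <- lapply(models, function(m)
      substr(m$seq, m$gene_start - m$seq_start + 1,
             m$gene_end - m$seq_start + 1))
    names(spans) <- vapply(models, `[[`, character(1), "gene_id")
    write_fasta(unlist(spans), fasta_path)
  }
  invisible(gff_path)
}

#' Read / write FASTA as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (empty file: empty vector).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write an R list as pretty JSON (UTF-8, LF)
#'
#' Used for simulation-truth and pipeline-report documents.
#'
#' @param x List.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_doc <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_json_doc
#' @export
read_json_doc <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
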