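#' Define a genetic map for the F2 simulator
#'
#' A genetic map holds the physical and genetic length of each chromosome plus
#' (optionally) the position of the recessive causal lesion. It is the frame
#' of reference for recombination simulation, marker placement and mutation
#' spiking.
#'
#' @param chromosomes data.frame with columns `name`, `length_bp` (>= 1) and
#'   `length_cM` (> 0, genetic length used by the Haldane/Poisson crossover
#'   model).
#' @param causal_locus `NULL`, or `list(chrom =, pos =)` giving the position of
#'   the recessive causal mutation on the cultivated haplotype.
#' @return An object of class `genetic_map`.
#' @examples
#' gmap <- genetic_map(
#'   data.frame(name = c("chr1", "chr2"),
#'              length_bp = c(5e7, 5e7), length_cM = c(60, 60)),
#'   causal_locus = list(chrom = "chr2", pos = 4.5e7))
#' @export
genetic_map <- function(chromosomes, causal_locus = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp", "length_cM") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names in map")
  if (any(chromosomes$length_bp < 1) || any(chromosomes$length_cM <= 0))
    stop("chromosome lengths must satisfy length_bp >= 1 bp and length_cM > 0")
  chromosomes <- chromosomes[natural_order(chromosomes$name), , drop = FALSE]
  rownames(chromosomes) <- NULL
  if (!is.null(causal_locus)) {
    stopifnot(is.list(causal_locus), !is.null(causal_locus$chrom),
              !is.null(causal_locus$pos))
    i <- match(causal_locus$chrom, chromosomes$name)
    if (is.na(i)) stop("causal locus chromosome not in map")
    if (causal_locus$pos < 1 || causal_locus$pos > chromosomes$length_bp[i])
      stop("causal locus position outside its chromosome")
  }
  structure(list(chromosomes = chromosomes, causal_locus = causal_locus),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", nrow(x$chromosomes), "chromosome(s),",
      sum(x$chromosomes$length_bp), "bp,",
      sum(x$chromosomes$length_cM), "cM total\n")
  if (!is.null(x$causal_locus))
    cat("  causal locus:", x$causal_locus$chrom, "@", x$causal_locus$pos, "bp\n")
  invisible(x)
}

chrom_lengths <- function(map) {
  stats::setNames(map$chromosomes$length_bp, map$chromosomes$name)
}
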