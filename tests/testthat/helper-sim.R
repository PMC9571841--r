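# Small fixture builders shared by the simulator and mapping tests.

toy_map <- function(lengths = c(chrA = 1e6), cM = 50, causal = NULL) {
  genetic_map(data.frame(name = names(lengths),
                         length_bp = as.numeric(lengths),
                         length_cM = rep_len(cM, length(lengths))),
              causal_locus = causal)
}

# A hand-built f2_pools object from explicit individuals (bypasses
# phenotyping), for count-model tests that need exact pool compositions.
manual_pools <- function(mut, wt, map) {
  structure(list(mut = mut, wt = wt, idx_mut = seq_along(mut),
                 idx_wt = seq_along(wt), map = map), class = "f2_pools")
}

# An individual with zero crossovers everywhere; origin 0 = cultivated,
# 1 = wild, per haplotype and chromosome.
constant_individual <- function(map, origins = c(0L, 0L), phenotype = "MUT") {
  haplos <- lapply(seq_len(nrow(map$chromosomes)), function(j)
    list(list(start = origins[1], xo = numeric(0)),
         list(start = origins[2], xo = numeric(0))))
  names(haplos) <- map$chromosomes$name
  list(haplotypes = haplos, phenotype = phenotype)
}

# Count-table row builder.
count_row <- function(chrom, pos, mut_ref, mut_alt, wt_ref, wt_alt,
                      ref = "A", alt = "G", origin = "MARKER") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, origin = origin,
             category = NA_character_, mut_ref = mut_ref, mut_alt = mut_alt,
             wt_ref = wt_ref, wt_alt = wt_alt)
}
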