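# Synthetic bulk-segregant experiment generator.
#
# The generator emulates an interspecific F2 mapping design: a mutagenized
# cultivated line (carrying a recessive causal lesion plus EMS-spectrum
# background mutations, all on the cultivated haplotype) crossed to a wild
# relative, F2 phenotyping, and pooled sequencing of mutant and wild-type
# bulks at interspecific SNP markers. Haplotype origin is coded 0 = CULTIVATED
# (reference genome background), 1 = WILD.

ORIGIN_CULT <- 0L
ORIGIN_WILD <- 1L

# One gamete on one chromosome: crossover positions (sorted, bp) plus the
# parental origin of the first segment. Origin at any bp follows by parity.
simulate_gamete <- function(length_bp, length_cM) {
  k <- stats::rpois(1L, length_cM / 100)
  list(start = sample(c(ORIGIN_CULT, ORIGIN_WILD), 1L),
       xo = sort(stats::runif(k, min = 1, max = length_bp)))
}

# Parental origin of one haplotype at a vector of positions.
haplotype_origin_at <- function(hap, pos) {
  (hap$start + findInterval(pos, hap$xo)) %% 2L
}

#' Convert a haplotype to its parental-segment representation
#'
#' @param hap A haplotype as stored in an [simulate_f2_population()]
#'   individual (`start` origin + crossover positions).
#' @param length_bp Chromosome length.
#' @return data.frame with columns `start_bp`, `end_bp`, `parent`
#'   (`"CULTIVATED"`/`"WILD"`); first segment starts at 1, last ends at
#'   `length_bp`.
#' @export
haplotype_segments <- function(hap, length_bp) {
  bounds <- c(1, floor(hap$xo) + 1, length_bp + 1)
  n <- length(bounds) - 1L
  parent <- (hap$start + seq_len(n) - 1L) %% 2L
  data.frame(start_bp = bounds[-length(bounds)],
             end_bp = bounds[-1] - 1,
             parent = ifelse(parent == ORIGIN_CULT, "CULTIVATED", "WILD"))
}

#' Simulate an F2 mapping population
#'
#' Each F2 individual is formed from two independent gametes of a fully
#' heterozygous F1 (cultivated x wild). Crossover counts per chromosome are
#' Poisson with mean `length_cM / 100` (Haldane model, no interference) and
#' crossover positions are uniform in bp. If the map carries a causal locus,
#' the phenotype is assigned by the fully penetrant recessive rule: `"MUT"`
#' iff both haplotypes are CULTIVATED at the locus, else `"WT"`.
#'
#' @param map A [genetic_map()].
#' @param n Number of individuals (>= 1).
#' @param seed Optional integer seed (local to this call).
#' @return An object of class `f2_population`: list with `map` and
#'   `individuals` (each with per-chromosome haplotype pairs and `phenotype`).
#' @export
simulate_f2_population <- function(map, n, seed = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  stop_if_not_scalar_count(n, "n")
  if (n < 1) stop("n must be >= 1")
  chrs <- map$chromosomes
  with_seed(seed, {
    individuals <- vector("list", n)
    for (i in seq_len(n)) {
      haplos <- vector("list", nrow(chrs))
      names(haplos) <- chrs$name
      for (j in seq_len(nrow(chrs))) {
        haplos[[j]] <- list(simulate_gamete(chrs$length_bp[j], chrs$length_cM[j]),
                            simulate_gamete(chrs$length_bp[j], chrs$length_cM[j]))
      }
      phenotype <- NA_character_
      if (!is.null(map$causal_locus)) {
        h <- haplos[[map$causal_locus$chrom]]
        o1 <- haplotype_origin_at(h[[1]], map$causal_locus$pos)
        o2 <- haplotype_origin_at(h[[2]], map$causal_locus$pos)
        phenotype <- if (o1 == ORIGIN_CULT && o2 == ORIGIN_CULT) "MUT" else "WT"
      }
      individuals[[i]] <- list(haplotypes = haplos, phenotype = phenotype)
    }
    structure(list(map = map, individuals = individuals), class = "f2_population")
  })
}

#' @export
print.f2_population <- function(x, ...) {
  ph <- phenotypes(x)
  cat("f2_population:", length(x$individuals), "individuals;",
      sum(ph == "MUT", na.rm = TRUE), "MUT /", sum(ph == "WT", na.rm = TRUE),
      "WT\n")
  invisible(x)
}

#' Phenotype labels of an F2 population
#' @param pop An `f2_population`.
#' @return Character vector (`"MUT"`/`"WT"`, `NA` if no causal locus).
#' @export
phenotypes <- function(pop) {
  vapply(pop$individuals, function(ind) ind$phenotype, character(1))
}

#' Randomize phenotype labels (null experiment)
#'
#' Replaces phenotype labels with independent Bernoulli draws, severing any
#' link between genotype and phenotype. Used for null calibration of the
#' region detector.
#'
#' @param pop An `f2_population`.
#' @param prob Probability of the `"MUT"` label (default 0.25, the recessive
#'   F2 expectation).
#' @param seed Optional seed.
#' @return The population with shuffled labels.
#' @export
randomize_phenotypes <- function(pop, prob = 0.25, seed = NULL) {
  with_seed(seed, {
    lab <- ifelse(stats::runif(length(pop$individuals)) < prob, "MUT", "WT")
    for (i in seq_along(pop$individuals)) pop$individuals[[i]]$phenotype <- lab[i]
    pop
  })
}

#' Genotype of every individual at one position
#'
#' @param pop An `f2_population`.
#' @param chrom Chromosome name.
#' @param pos Position (bp).
#' @return Integer vector: number of WILD alleles (0, 1 or 2) per individual,
#'   so 0 = homozygous cultivated, 1 = heterozygous, 2 = homozygous wild.
#' @export
genotype_at <- function(pop, chrom, pos) {
  if (!chrom %in% names(pop$individuals[[1]]$haplotypes))
    stop("unknown chromosome: ", chrom)
  vapply(pop$individuals, function(ind) {
    h <- ind$haplotypes[[chrom]]
    as.integer(haplotype_origin_at(h[[1]], pos) + haplotype_origin_at(h[[2]], pos))
  }, integer(1))
}

#' Draw phenotype-stratified sequencing pools
#'
#' Random disjoint subsets of the requested sizes, stratified by phenotype
#' label, mirroring the bulked-segregant design (default 15 mutant + 15
#' wild-type plants).
#'
#' @param pop An `f2_population` with assigned phenotypes.
#' @param n_mut,n_wt Pool sizes (defaults 15 and 15).
#' @param seed Optional seed.
#' @return Object of class `f2_pools`: list with `mut` and `wt` (lists of
#'   individuals), their indices, and the map.
#' @export
build_pools <- function(pop, n_mut = 15, n_wt = 15, seed = NULL) {
  stop_if_not_scalar_count(n_mut, "n_mut")
  stop_if_not_scalar_count(n_wt, "n_wt")
  ph <- phenotypes(pop)
  if (anyNA(ph)) stop("population has no phenotype labels (no causal locus)")
  mut_idx <- which(ph == "MUT")
  wt_idx <- which(ph == "WT")
  if (length(mut_idx) < n_mut)
    stop(sprintf("requested %d MUT individuals but only %d available",
                 n_mut, length(mut_idx)))
  if (length(wt_idx) < n_wt)
    stop(sprintf("requested %d WT individuals but only %d available",
                 n_wt, length(wt_idx)))
  with_seed(seed, {
    take_mut <- sort(sample(mut_idx, n_mut))
    take_wt <- sort(sample(wt_idx, n_wt))
    structure(list(mut = pop$individuals[take_mut],
                   wt = pop$individuals[take_wt],
                   idx_mut = take_mut, idx_wt = take_wt,
                   map = pop$map),
              class = "f2_pools")
  })
}

#' Place interspecific SNP markers on a regular grid
#'
#' Markers sit at `spacing_bp, 2 * spacing_bp, ...` on every chromosome. The
#' non-reference (ALT) allele of a marker is by convention the WILD-species
#' allele: the reference genome is the cultivated background, so the mutant
#' pool's marker allele frequency collapses to zero at loci linked to the
#' causal mutation.
#'
#' @param map A [genetic_map()].
#' @param spacing_bp Marker spacing (>= 1).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `origin = "MARKER"`, `category = NA` (counts not yet simulated).
#' @export
place_markers <- function(map, spacing_bp = 1e5) {
  stop_if_not_scalar_count(spacing_bp, "spacing_bp")
  if (spacing_bp < 1) stop("spacing_bp must be >= 1")
  chrs <- map$chromosomes
  out <- lapply(seq_len(nrow(chrs)), function(j) {
    n <- floor(chrs$length_bp[j] / spacing_bp)
    if (n == 0) return(NULL)
    data.frame(chrom = chrs$name[j], pos = spacing_bp * seq_len(n),
               ref = "A", alt = "G", origin = "MARKER",
               category = NA_character_)
  })
  out <- do.call(rbind, out) %||%
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               alt = character(), origin = character(), category = character())
  rownames(out) <- NULL
  out
}

# Ordered SNV pairs that are NOT G>A / C>T, used for the
# "other_substitution" spectrum category.
other_snv_pairs <- local({
  p <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                   stringsAsFactors = FALSE)
  p <- p[p$ref != p$alt, ]
  p[!(p$ref == "G" & p$alt == "A") & !(p$ref == "C" & p$alt == "T"), ]
})

#' Spike EMS-spectrum induced mutations
#'
#' Draws `n_mutations` background mutations at uniform random positions, with
#' mutation category drawn from the EMS spectrum (dominated by G:C -> A:T
#' transitions). All induced mutations reside on the CULTIVATED haplotype:
#' they arose in the mutagenized cultivar, so in the mutant pool near the
#' causal locus they are homozygous.
#'
#' @param map A [genetic_map()].
#' @param n_mutations Number of background mutations.
#' @param spectrum Named fractions over
#'   `c(GC_to_AT_transition, other_substitution, single_base_deletion)`,
#'   summing to 1 (tolerance 1e-9).
#' @param seed Optional seed.
#' @param causal Optional `list(chrom, pos, ref, alt)` appended exactly once
#'   as the causal lesion (`category = "causal"` recorded separately by the
#'   caller's truth object).
#' @return data.frame like [place_markers()] but `origin = "INDUCED"` and
#'   `category` filled.
#' @export
spike_ems_mutations <- function(map, n_mutations,
                                spectrum = c(GC_to_AT_transition = 0.90,
                                             other_substitution = 0.05,
                                             single_base_deletion = 0.05),
                                seed = NULL, causal = NULL) {
  stop_if_not_scalar_count(n_mutations, "n_mutations")
  want <- c("GC_to_AT_transition", "other_substitution", "single_base_deletion")
  if (!setequal(names(spectrum), want))
    stop("spectrum must be named over: ", paste(want, collapse = ", "))
  spectrum <- spectrum[want]
  if (abs(sum(spectrum) - 1) > 1e-9) stop("spectrum fractions must sum to 1")
  chrs <- map$chromosomes
  empty <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                      alt = character(), origin = character(),
                      category = character())
  with_seed(seed, {
    out <- empty
    if (n_mutations > 0) {
      tries <- 0
      while (nrow(out) < n_mutations && tries < 100) {
        need <- n_mutations - nrow(out)
        ci <- sample.int(nrow(chrs), need, replace = TRUE,
                         prob = chrs$length_bp)
        pos <- floor(stats::runif(need, min = 1, max = chrs$length_bp[ci] + 1))
        cat_i <- sample(want, need, replace = TRUE, prob = spectrum)
        ref <- alt <- character(need)
        is_gc <- cat_i == "GC_to_AT_transition"
        ref[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
        alt[is_gc] <- ifelse(ref[is_gc] == "G", "A", "T")
        is_other <- cat_i == "other_substitution"
        if (any(is_other)) {
          k <- sample.int(nrow(other_snv_pairs), sum(is_other), replace = TRUE)
          ref[is_other] <- other_snv_pairs$ref[k]
          alt[is_other] <- other_snv_pairs$alt[k]
        }
        is_del <- cat_i == "single_base_deletion"
        if (any(is_del)) {
          anchor <- sample(DNA_BASES_CHR, sum(is_del), replace = TRUE)
          gone <- sample(DNA_BASES_CHR, sum(is_del), replace = TRUE)
          ref[is_del] <- paste0(anchor, gone)
          alt[is_del] <- anchor
        }
        out <- rbind(out, data.frame(chrom = chrs$name[ci], pos = pos,
                                     ref = ref, alt = alt, origin = "INDUCED",
                                     category = cat_i))
        out <- out[!duplicated(out[c("chrom", "pos")]), , drop = FALSE]
        tries <- tries + 1
      }
    }
    if (!is.null(causal)) {
      out <- out[!(out$chrom == causal$chrom & out$pos == causal$pos), ,
                 drop = FALSE]
      out <- rbind(out, data.frame(chrom = causal$chrom, pos = causal$pos,
                                   ref = causal$ref, alt = causal$alt,
                                   origin = "INDUCED",
                                   category = classify_substitution(causal$ref,
                                                                    causal$alt)))
    }
    out <- out[order(match(out$chrom, chrs$name), out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# Non-reference allele frequency of a pool at given positions of one
# chromosome. origin MARKER -> wild allele; origin INDUCED -> cultivated
# haplotype carries the induced allele.
pool_nonref_freq <- function(pool_individuals, chrom, pos, origin) {
  n_hap <- 2L * length(pool_individuals)
  if (n_hap == 0) return(rep(NA_real_, length(pos)))
  wild <- numeric(length(pos))
  for (ind in pool_individuals) {
    h <- ind$haplotypes[[chrom]]
    wild <- wild + haplotype_origin_at(h[[1]], pos) +
      haplotype_origin_at(h[[2]], pos)
  }
  q_wild <- wild / n_hap
  ifelse(origin == "MARKER", q_wild, 1 - q_wild)
}

#' Simulate pooled sequencing counts
#'
#' Per site and pool: depth ~ Poisson(`depth_mean`); with true pool
#' non-reference allele frequency `q` (fraction of carrier haplotypes among
#' `2 * pool_size`), observed non-reference reads ~ Binomial(depth,
#' `q (1 - eps) + (1 - q) eps`), the symmetric per-read error model; reference
#' count is the remainder.
#'
#' @param sites data.frame from [place_markers()] / [spike_ems_mutations()].
#' @param pools An `f2_pools` object.
#' @param depth_mean Mean sequencing depth (> 0).
#' @param error_rate Per-read miscall rate `eps` in `[0, 0.5)`.
#' @param seed Optional seed.
#' @return `sites` with columns `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt`
#'   appended, sorted by (chrom, pos); an empty pool yields `NA` counts.
#' @export
simulate_pool_counts <- function(sites, pools, depth_mean = 50,
                                 error_rate = 0.002, seed = NULL) {
  stopifnot(inherits(pools, "f2_pools"))
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  chrs <- pools$map$chromosomes$name
  sites <- sites[do.call(order, list(match(sites$chrom, chrs), sites$pos)), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  n <- nrow(sites)
  res <- list(MUT = list(ref = rep(NA_real_, n), alt = rep(NA_real_, n)),
              WT = list(ref = rep(NA_real_, n), alt = rep(NA_real_, n)))
  with_seed(seed, {
    for (pool_name in c("MUT", "WT")) {
      members <- if (pool_name == "MUT") pools$mut else pools$wt
      if (length(members) == 0) next
      for (chrom in unique(sites$chrom)) {
        i <- which(sites$chrom == chrom)
        q <- pool_nonref_freq(members, chrom, sites$pos[i], sites$origin[i])
        depth <- stats::rpois(length(i), depth_mean)
        p <- q * (1 - error_rate) + (1 - q) * error_rate
        alt <- stats::rbinom(length(i), depth, p)
        res[[pool_name]]$ref[i] <- depth - alt
        res[[pool_name]]$alt[i] <- alt
      }
    }
  })
  sites$mut_ref <- res$MUT$ref
  sites$mut_alt <- res$MUT$alt
  sites$wt_ref <- res$WT$ref
  sites$wt_alt <- res$WT$alt
  sites
}

#' Simulate phenotype counts for one segregating family
#'
#' @param n Family size (>= 1).
#' @param ratio Hypothesized class ratio (length >= 2, non-negative, sum > 0),
#'   e.g. `c(3, 1)` for a recessive F2 expectation.
#' @param seed Optional seed.
#' @return Integer vector of class counts (multinomial draw).
#' @export
simulate_segregation_family <- function(n, ratio, seed = NULL) {
  stop_if_not_scalar_count(n, "n")
  if (n < 1) stop("n must be >= 1")
  if (length(ratio) < 2) stop("ratio needs at least 2 classes")
  if (any(ratio < 0) || sum(ratio) <= 0) stop("ratio must be non-negative with positive sum")
  with_seed(seed, as.integer(stats::rmultinom(1, n, ratio / sum(ratio))))
}

#' Simulate a germination / fertility dose-response experiment
#'
#' Germination and overall fertility decline with mutagen dose along logistic
#' curves: `g(d) = g0 * plogis(g_slope (g_mid - d)) / plogis(g_slope g_mid)`
#' (so `g(0) = g0` exactly) and `f(d) = plogis(f_slope (f_mid - d))`, the
#' seed-level fertile fraction, which crosses 50% exactly at `f_mid`.
#' Per dose and replicate, `germinated ~ Binomial(seeds, g(dose))` and
#' `fertile ~ Binomial(germinated, min(1, f/g))`.
#'
#' @param doses Mutagen doses in percent (non-negative).
#' @param replicates Replicates per dose (default 5).
#' @param seeds_per_replicate Seeds per replicate (default 100).
#' @param params List with `g0`, `g_mid`, `g_slope`, `f_mid`, `f_slope`.
#' @param seed Optional seed.
#' @return data.frame with columns `dose`, `replicate`, `seeds`, `germinated`,
#'   `fertile`.
#' @export
simulate_dose_response <- function(doses = c(0.5, 0.7, 1.0), replicates = 5,
                                   seeds_per_replicate = 100,
                                   params = list(g0 = 0.95, g_mid = 1.05,
                                                 g_slope = 6, f_mid = 0.7,
                                                 f_slope = 8),
                                   seed = NULL) {
  if (any(doses < 0)) stop("doses must be non-negative")
  stop_if_not_scalar_count(replicates, "replicates")
  if (replicates < 1) stop("replicates must be >= 1")
  g <- params$g0 * stats::plogis(params$g_slope * (params$g_mid - doses)) /
    stats::plogis(params$g_slope * params$g_mid)
  f <- stats::plogis(params$f_slope * (params$f_mid - doses))
  if (any(g < 0 | g > 1) || any(f < 0 | f > 1))
    stop("dose-response probabilities outside [0, 1]")
  p_f <- ifelse(g > 0, pmin(1, f / g), 0)
  with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(replicates), dose = doses)
    rows <- rows[order(rows$dose, rows$replicate), c("dose", "replicate")]
    rows$seeds <- seeds_per_replicate
    gi <- match(rows$dose, doses)
    rows$germinated <- stats::rbinom(nrow(rows), rows$seeds, g[gi])
    rows$fertile <- stats::rbinom(nrow(rows), rows$germinated, p_f[gi])
    rownames(rows) <- NULL
    rows
  })
}
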