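# F2 population simulator, pooling, marker/mutation placement and the
# pooled-count generative model.

test_that("zero genetic length gives zero crossovers and single-parent haplotypes", {
  map <- toy_map(c(chrA = 1e6), cM = 1e-9)
  pop <- simulate_f2_population(map, 50, seed = 1)
  for (ind in pop$individuals) {
    for (h in ind$haplotypes$chrA) {
      expect_length(h$xo, 0)
      segs <- haplotype_segments(h, 1e6)
      expect_equal(nrow(segs), 1)
      expect_equal(segs$start_bp, 1)
      expect_equal(segs$end_bp, 1e6)
    }
  }
})

test_that("phenotype follows the fully penetrant recessive rule at the causal locus", {
  map <- toy_map(c(chrA = 5e6), cM = 80,
                 causal = list(chrom = "chrA", pos = 2.5e6))
  pop <- simulate_f2_population(map, 400, seed = 2)
  g <- genotype_at(pop, "chrA", 2.5e6)
  expect_identical(phenotypes(pop) == "MUT", g == 0L)
  # mutant fraction near the 1/4 recessive expectation (4 sigma)
  p_hat <- mean(g == 0L)
  expect_lt(abs(p_hat - 0.25), 4 * sqrt(0.25 * 0.75 / 400))
})

test_that("population without a causal locus carries no phenotype labels", {
  pop <- simulate_f2_population(toy_map(), 5, seed = 3)
  expect_true(all(is.na(phenotypes(pop))))
  expect_error(build_pools(pop, 2, 2), "phenotype")
})

test_that("build_pools returns disjoint stratified pools of the requested sizes", {
  map <- toy_map(c(chrA = 1e6), causal = list(chrom = "chrA", pos = 5e5))
  pop <- simulate_f2_population(map, 120, seed = 4)
  ph <- phenotypes(pop)
  pools <- build_pools(pop, seed = 5)
  expect_length(pools$mut, 15)
  expect_length(pools$wt, 15)
  expect_length(intersect(pools$idx_mut, pools$idx_wt), 0)
  expect_true(all(ph[pools$idx_mut] == "MUT"))
  expect_true(all(ph[pools$idx_wt] == "WT"))
})

test_that("build_pools accepts empty requests and rejects infeasible ones", {
  map <- toy_map(c(chrA = 1e6), causal = list(chrom = "chrA", pos = 5e5))
  pop <- simulate_f2_population(map, 30, seed = 6)
  ph <- phenotypes(pop)
  pools <- build_pools(pop, n_mut = 0, n_wt = 2, seed = 1)
  expect_length(pools$mut, 0)
  too_many <- sum(ph == "MUT") + 1
  expect_error(build_pools(pop, n_mut = too_many, n_wt = 1), "available")
})

test_that("place_markers uses floor division per chromosome", {
  expect_equal(nrow(place_markers(toy_map(c(chrA = 1e6)), 1e5)), 10)
  expect_equal(nrow(place_markers(toy_map(c(chrA = 4e4)), 1e5)), 0)
  two <- place_markers(toy_map(c(chrA = 5e6, chrB = 5e6)), 5e4)
  expect_equal(nrow(two), 200)
  expect_true(all(two$pos %% 5e4 == 0))
})

test_that("EMS spectrum category counts match the multinomial expectation", {
  map <- toy_map(c(chrA = 2e7, chrB = 2e7))
  spectrum <- c(GC_to_AT_transition = 0.9, other_substitution = 0.05,
                single_base_deletion = 0.05)
  mut <- spike_ems_mutations(map, 10000, spectrum, seed = 7)
  expect_equal(nrow(mut), 10000)
  expect_false(any(duplicated(paste(mut$chrom, mut$pos))))
  for (cat in names(spectrum)) {
    n_cat <- sum(mut$category == cat)
    sigma <- sqrt(10000 * spectrum[[cat]] * (1 - spectrum[[cat]]))
    expect_lt(abs(n_cat - 10000 * spectrum[[cat]]), 4 * sigma)
  }
  # deletions are anchored: two-base ref, one-base alt sharing the first base
  dels <- mut[mut$category == "single_base_deletion", ]
  expect_true(all(nchar(dels$ref) == 2 & nchar(dels$alt) == 1))
  expect_true(all(substr(dels$ref, 1, 1) == dels$alt))
  expect_error(spike_ems_mutations(map, 10, spectrum * 1.01), "sum to 1")
  expect_equal(nrow(spike_ems_mutations(map, 0, spectrum, seed = 1)), 0)
})

test_that("a configured causal deletion appears exactly once with its coordinates", {
  map <- toy_map(c(chrA = 1e6))
  causal <- list(chrom = "chrA", pos = 1234, ref = "CA", alt = "C")
  mut <- spike_ems_mutations(map, 50, seed = 8, causal = causal)
  hit <- mut[mut$pos == 1234 & mut$chrom == "chrA", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$ref, "CA")
  expect_equal(hit$alt, "C")
  expect_equal(hit$category, "single_base_deletion")
})

test_that("pool counts are exact in the error-free homozygous limits", {
  map <- toy_map(c(chrA = 1e6))
  hom_cult <- lapply(1:5, function(i) constant_individual(map, c(0L, 0L)))
  hom_wild <- lapply(1:5, function(i) constant_individual(map, c(1L, 1L), "WT"))
  pools <- manual_pools(hom_cult, hom_wild, map)
  sites <- place_markers(map, 1e5)
  counts <- simulate_pool_counts(sites, pools, depth_mean = 40,
                                 error_rate = 0, seed = 9)
  # all-homozygous-reference pool: zero non-reference reads at any depth
  expect_true(all(counts$mut_alt == 0))
  # all-homozygous-wild pool: every read is non-reference
  expect_true(all(counts$wt_ref == 0))
  expect_true(all(counts$wt_alt >= 0))
})

test_that("heterozygous pools give unbiased allele frequencies at q = 0.5", {
  map <- toy_map(c(chrA = 1e7))
  het <- lapply(1:10, function(i) constant_individual(map, c(0L, 1L), "WT"))
  pools <- manual_pools(het, het, map)
  sites <- place_markers(map, 1e4)  # 1000 sites
  counts <- simulate_pool_counts(sites, pools, depth_mean = 100,
                                 error_rate = 0, seed = 10)
  af <- compute_af(counts$mut_ref, counts$mut_alt)
  se <- stats::sd(af) / sqrt(length(af))
  expect_lt(abs(mean(af) - 0.5), 4 * se)
})

test_that("an empty pool yields missing counts, not an error", {
  map <- toy_map(c(chrA = 1e6))
  pools <- manual_pools(list(), lapply(1:2, function(i)
    constant_individual(map, c(0L, 1L), "WT")), map)
  counts <- simulate_pool_counts(place_markers(map, 2e5), pools, seed = 11)
  expect_true(all(is.na(counts$mut_ref)))
  expect_true(all(!is.na(counts$wt_ref)))
})

test_that("segregation family draws conserve n and respect degenerate ratios", {
  counts <- simulate_segregation_family(120, c(3, 1), seed = 12)
  expect_equal(sum(counts), 120)
  expect_equal(simulate_segregation_family(77, c(1, 0), seed = 13), c(77L, 0L))
  expect_error(simulate_segregation_family(10, c(0, 0)), "ratio")
})

test_that("dose-response table has the expected shape and exact dose-0 limit", {
  tab <- simulate_dose_response(c(0.5, 0.7, 1.0), replicates = 5,
                                seeds_per_replicate = 100, seed = 14)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$fertile <= tab$germinated & tab$germinated <= tab$seeds))
  zero <- simulate_dose_response(0, replicates = 5,
                                 params = list(g0 = 1, g_mid = 1.05,
                                               g_slope = 6, f_mid = 0.7,
                                               f_slope = 8), seed = 15)
  expect_true(all(zero$germinated == zero$seeds))
})

test_that("mean germination is non-increasing in dose for the logistic decline", {
  doses <- c(0.2, 0.5, 0.8, 1.1)
  tab <- simulate_dose_response(doses, replicates = 1000, seed = 16)
  means <- tapply(tab$germinated, tab$dose, mean)
  expect_true(all(diff(means[as.character(doses)]) < 0))
})

test_that("identical seeds give bit-identical simulations, different seeds differ", {
  cfg <- default_config(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                        chrom_cM = c(chr1 = 30, chr2 = 30),
                        causal_pos = 4e6, n_f2 = 120,
                        n_background_mutations = 40)
  a <- simulate_bsa_experiment(cfg, seed = 17)
  b <- simulate_bsa_experiment(cfg, seed = 17)
  c <- simulate_bsa_experiment(cfg, seed = 18)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$counts, c$counts))
})
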