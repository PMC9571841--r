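# Pooled non-reference allele-frequency profiles and candidate-region
# detection. The mapping signal is the paper-style signature: the mutant
# pool's marker allele frequency falls to (near) zero around the causal
# locus, while the wild-type pool stays intermediate (expected 2/3 under the
# recessive 1 hom-wild : 2 het composition of phenotypically WT plants).

#' Non-reference allele frequency
#'
#' `nonref / (ref + nonref)`, the pooled allele-frequency ratio computed from
#' allele counts; missing (`NA`) when total depth is zero or counts are
#' absent. Vectorized.
#'
#' @param ref_count,nonref_count Non-negative allele counts.
#' @return Numeric vector of frequencies in `[0, 1]` (or `NA`).
#' @examples
#' compute_af(30, 0)   # 0: fully linked site in the mutant pool
#' compute_af(15, 15)  # 0.5
#' @export
compute_af <- function(ref_count, nonref_count) {
  if (any(ref_count < 0, na.rm = TRUE) || any(nonref_count < 0, na.rm = TRUE))
    stop("negative allele counts")
  total <- ref_count + nonref_count
  ifelse(is.na(total) | total == 0, NA_real_, nonref_count / total)
}

pool_count_cols <- function(pool) {
  pool <- match.arg(pool, c("MUT", "WT"))
  if (pool == "MUT") c("mut_ref", "mut_alt") else c("wt_ref", "wt_alt")
}

#' Build a windowed allele-frequency profile for one pool
#'
#' Per-site non-reference allele frequencies plus sliding-window summaries.
#' Only MARKER-origin sites with depth >= `min_depth` enter window statistics
#' (induced mutations are not informative interspecific markers); windows
#' tile `[1, chrom_length]` with the given step and carry missing summaries
#' when fewer than `min_sites` usable sites fall inside.
#'
#' @param sites Count table (as from [simulate_pool_counts()] or
#'   [read_vcf_counts()]).
#' @param pool `"MUT"` or `"WT"`.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window_bp,step_bp Window and step size; `window_bp >= step_bp >= 1`.
#' @param min_sites Minimum usable sites per window (default 3).
#' @param min_depth Minimum site depth (default 10).
#' @return Object of class `af_profile_set`: named list of per-chromosome
#'   profiles, each with `sites` (pos, af, depth, origin, usable) and
#'   `windows` (start_bp, end_bp, n_sites, mean_af, median_af).
#' @export
build_profile <- function(sites, pool, chrom_lengths, window_bp = 1e6,
                          step_bp = 2.5e5, min_sites = 3, min_depth = 10) {
  if (!(window_bp >= step_bp && step_bp >= 1))
    stop("need window_bp >= step_bp >= 1")
  pool <- match.arg(pool, c("MUT", "WT"))
  cols <- pool_count_cols(pool)
  chrom_lengths <- chrom_lengths[natural_order(names(chrom_lengths))]
  profiles <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    if (anyDuplicated(s$pos))
      stop("duplicate positions on ", chrom)
    depth <- s[[cols[1]]] + s[[cols[2]]]
    af <- compute_af(s[[cols[1]]], s[[cols[2]]])
    usable <- !is.na(af) & depth >= min_depth & s$origin == "MARKER"
    upos <- s$pos[usable]
    uaf <- af[usable]
    starts <- seq(1, len, by = step_bp)
    ends <- pmin(starts + window_bp - 1, len)
    lo <- findInterval(starts - 1, upos) + 1L
    hi <- findInterval(ends, upos)
    n_sites <- pmax(0L, hi - lo + 1L)
    mean_af <- median_af <- rep(NA_real_, length(starts))
    ok <- n_sites >= min_sites
    for (w in which(ok)) {
      vals <- uaf[lo[w]:hi[w]]
      mean_af[w] <- mean(vals)
      median_af[w] <- stats::median(vals)
    }
    list(chrom = chrom, pool = pool, length_bp = len,
         sites = data.frame(pos = s$pos, af = af, depth = depth,
                            origin = s$origin),
         windows = data.frame(start_bp = starts, end_bp = ends,
                              n_sites = n_sites, mean_af = mean_af,
                              median_af = median_af),
         window_bp = window_bp, step_bp = step_bp,
         min_sites = min_sites, min_depth = min_depth)
  })
  names(profiles) <- names(chrom_lengths)
  structure(profiles, class = "af_profile_set", pool = pool)
}

check_same_grid <- function(mut, wt) {
  if (!identical(names(mut), names(wt)))
    stop("profiles cover different chromosomes")
  for (chrom in names(mut)) {
    if (!identical(mut[[chrom]]$windows$start_bp, wt[[chrom]]$windows$start_bp) ||
        !identical(mut[[chrom]]$windows$end_bp, wt[[chrom]]$windows$end_bp))
      stop("window grids differ on ", chrom)
  }
  invisible(TRUE)
}

empty_regions <- function() {
  data.frame(chrom = character(), start_bp = numeric(), end_bp = numeric(),
             n_windows = integer(), mean_mut_af = numeric(),
             mean_wt_af = numeric(), expansion_bp = numeric())
}

#' Detect the candidate region from paired pool profiles
#'
#' A window is a hit when the mutant pool's window mean allele frequency is at
#' most `tau_mut` (the "reaches zero" signature) while the wild-type pool's
#' mean lies inside `wt_band` (centered on the recessive expectation of 2/3).
#' Maximal runs of at least `min_run` consecutive hit windows become regions;
#' missing windows never count as hits and break runs. Each region is padded
#' by `pad_bp` on both sides (the default padding brings the shortest
#' reportable run to a 5 Mb inspection interval) and regions are ranked by
#' run length, ties broken by lower mutant mean, then leftmost start.
#'
#' @param mut,wt `af_profile_set`s on the same window grid.
#' @param tau_mut Mutant-pool detection threshold (default 0.05).
#' @param wt_band Allowed wild-type band, `c(lo, hi)` (default
#'   `c(0.45, 0.85)`).
#' @param min_run Minimum run of hit windows (default 3).
#' @param pad_bp Padding per side (default 1.75e6).
#' @return data.frame of regions (possibly empty): `chrom`, `start_bp`,
#'   `end_bp`, `n_windows`, `mean_mut_af`, `mean_wt_af`, `expansion_bp`.
#' @export
detect_candidate_region <- function(mut, wt, tau_mut = 0.05,
                                    wt_band = c(0.45, 0.85), min_run = 3,
                                    pad_bp = 1.75e6) {
  stopifnot(inherits(mut, "af_profile_set"), inherits(wt, "af_profile_set"))
  check_same_grid(mut, wt)
  out <- empty_regions()
  for (chrom in names(mut)) {
    wm <- mut[[chrom]]$windows
    ww <- wt[[chrom]]$windows
    hit <- !is.na(wm$mean_af) & !is.na(ww$mean_af) &
      wm$mean_af <= tau_mut &
      ww$mean_af >= wt_band[1] & ww$mean_af <= wt_band[2]
    if (!any(hit)) next
    r <- rle(hit)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_run)
    for (k in keep) {
      i <- starts[k]:stops[k]
      out <- rbind(out, data.frame(
        chrom = chrom,
        start_bp = max(1, wm$start_bp[i[1]] - pad_bp),
        end_bp = min(mut[[chrom]]$length_bp, wm$end_bp[i[length(i)]] + pad_bp),
        n_windows = length(i),
        mean_mut_af = mean(wm$mean_af[i]),
        mean_wt_af = mean(ww$mean_af[i]),
        expansion_bp = pad_bp))
    }
  }
  out <- out[order(-out$n_windows, out$mean_mut_af, match(out$chrom, names(mut)),
                   out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Long-format window table for one or more profiles
#'
#' @param ... `af_profile_set` objects (any number >= 1).
#' @return data.frame with columns `chrom`, `window_start`, `window_end`,
#'   `pool`, `n_sites`, `mean_af`, `median_af`; windows with missing summaries
#'   are emitted, not dropped; order is deterministic (pool, chromosome,
#'   window start).
#' @export
af_table <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "af_profile_set"))
    sets <- sets[[1]]
  if (length(sets) < 1) stop("need at least one profile set")
  rows <- lapply(sets, function(set) {
    do.call(rbind, lapply(set, function(p) {
      data.frame(chrom = p$chrom, window_start = p$windows$start_bp,
                 window_end = p$windows$end_bp, pool = p$pool,
                 n_sites = p$windows$n_sites, mean_af = p$windows$mean_af,
                 median_af = p$windows$median_af)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pool, match(out$chrom, unique(out$chrom)),
                   out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
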