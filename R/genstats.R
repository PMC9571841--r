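# Segregation and screening statistics: goodness-of-fit chi-square for
# Mendelian ratios, inheritance-mode classification, phenotypic-class
# tabulation, screening rates, and LD50 interpolation from dose-response
# tables.

#' Chi-square goodness of fit to a hypothesized segregation ratio
#'
#' Pearson's statistic `sum((obs - exp)^2 / exp)` with no continuity
#' correction, `df = k - 1`, and the p-value from the upper tail of the
#' chi-square distribution. For a recessive monogenic trait the classic
#' checks are phenotypes against 3:1 and genotype classes against 1:2:1.
#'
#' @param observed Non-negative integer counts (length >= 2).
#' @param ratio Hypothesized ratio, same length (default: uniform).
#' @return Object of class `chisq_gof`: `statistic`, `df`, `p_value`,
#'   `expected`, `observed`.
#' @examples
#' chi_square_gof(c(87, 33), c(3, 1))      # statistic 0.4
#' chi_square_gof(c(26, 61, 33), c(1, 2, 1)) # statistic 0.85
#' @export
chi_square_gof <- function(observed, ratio = rep(1, length(observed))) {
  if (length(observed) < 2) stop("need at least 2 classes")
  if (length(ratio) != length(observed)) stop("ratio and observed differ in length")
  if (any(observed < 0)) stop("negative observed counts")
  if (sum(observed) < 1) stop("no observations")
  expected <- sum(observed) * ratio / sum(ratio)
  if (any(expected <= 0)) stop("zero expected count in a class")
  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 expected = expected, observed = observed),
            class = "chisq_gof")
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat(sprintf("chi-square goodness of fit: X2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Classify the inheritance mode of a mutant line
#'
#' A line whose M1 plant already showed the phenotype and whose M2 family
#' fits the dominant 1:3 (WT:mutant) expectation is called dominant; a line
#' fitting the recessive 3:1 (WT:mutant) expectation is recessive; a line
#' failing both Mendelian fits has complex inheritance.
#'
#' @param m1_phenotype_mutant Did the M1 plant show the phenotype?
#' @param observed M2 counts as `c(WT, mutant)`.
#' @param alpha Significance level for the chi-square fits (default 0.05).
#' @return `"dominant"`, `"recessive"` or `"complex"`.
#' @examples
#' classify_inheritance(FALSE, c(87, 33))  # "recessive"
#' @export
classify_inheritance <- function(m1_phenotype_mutant, observed, alpha = 0.05) {
  stopifnot(length(observed) == 2)
  if (isTRUE(m1_phenotype_mutant)) {
    p_dom <- chi_square_gof(observed, c(1, 3))$p_value
    if (p_dom > alpha) return("dominant")
  }
  p_rec <- chi_square_gof(observed, c(3, 1))$p_value
  if (p_rec > alpha) return("recessive")
  "complex"
}

#' Tabulate phenotypic classes by inheritance mode
#'
#' Summarizes one screened line per row into the per-class table used to
#' report a mutant collection: dominant/recessive/complex counts, row total,
#' and the class frequency as percent of the grand total (2 decimals), plus
#' a TOTAL row.
#'
#' @param lines data.frame with columns `phenotypic_class` and
#'   `inheritance_mode` (values `dominant`/`recessive`/`complex`).
#' @return data.frame with columns `phenotypic_class`, `dominant`,
#'   `recessive`, `complex`, `total`, `frequency_pct`; empty input yields a
#'   single TOTAL row of zeros with missing frequency.
#' @export
tabulate_classes <- function(lines) {
  modes <- c("dominant", "recessive", "complex")
  if (nrow(lines) == 0) {
    return(data.frame(phenotypic_class = "TOTAL", dominant = 0L,
                      recessive = 0L, complex = 0L, total = 0L,
                      frequency_pct = NA_real_))
  }
  bad <- setdiff(unique(lines$inheritance_mode), modes)
  if (length(bad))
    stop("unknown inheritance mode(s): ", paste(bad, collapse = ", "))
  cls <- unique(lines$phenotypic_class)
  tab <- table(factor(lines$phenotypic_class, levels = cls),
               factor(lines$inheritance_mode, levels = modes))
  out <- data.frame(phenotypic_class = cls,
                    dominant = as.integer(tab[, "dominant"]),
                    recessive = as.integer(tab[, "recessive"]),
                    complex = as.integer(tab[, "complex"]))
  out$total <- out$dominant + out$recessive + out$complex
  grand <- sum(out$total)
  out$frequency_pct <- round(100 * out$total / grand, 2)
  total_row <- data.frame(phenotypic_class = "TOTAL",
                          dominant = sum(out$dominant),
                          recessive = sum(out$recessive),
                          complex = sum(out$complex), total = grand,
                          frequency_pct = round(sum(100 * out$total / grand), 2))
  rbind(out, total_row)
}

#' Expand a per-class count table into one-line-per-mutant form
#'
#' Convenience inverse of [tabulate_classes()]: turns a table of
#' dominant/recessive/complex counts per phenotypic class into the long
#' per-line data.frame that `tabulate_classes` consumes.
#'
#' @param counts data.frame with `phenotypic_class`, `dominant`, `recessive`,
#'   `complex`.
#' @return data.frame with `phenotypic_class`, `inheritance_mode`.
#' @export
expand_class_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    data.frame(phenotypic_class = counts$phenotypic_class[i],
               inheritance_mode = rep(c("dominant", "recessive", "complex"),
                                      times = c(counts$dominant[i],
                                                counts$recessive[i],
                                                counts$complex[i])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Example phenotypic-class counts from a tomato EMS screen
#'
#' Per-class dominant/recessive/complex mutant counts of a large greenhouse
#' screen of an EMS-mutagenized tomato collection (fourteen phenotypic
#' categories, 2800 mutant lines), shipped as a plain-text table.
#'
#' @return data.frame with `phenotypic_class`, `category`, `dominant`,
#'   `recessive`, `complex`.
#' @export
ems_screen_classes <- function() {
  path <- system.file("extdata", "ems_screen_classes.tsv", package = "emsmap",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Screening-program rates
#'
#' Percentages (2 decimals) summarizing a mutagenesis program: germination
#' (plants obtained / treated seeds), fertility (M2-producing plants over the
#' configured denominator), sterility (its complement) and mutant detection
#' (mutants found / families screened). Any `NULL` count skips its row.
#'
#' @param treated_seeds,germinated,m2_producing,families_screened,mutants_found
#'   Program counts; each numerator must not exceed its denominator.
#' @param fertility_denominator `"germinated"` (default) or `"treated_seeds"`.
#' @return data.frame with `rate`, `numerator`, `denominator`, `percent`.
#' @examples
#' compute_rates(germinated = 12560, m2_producing = 7379)  # fertility 58.75
#' @export
compute_rates <- function(treated_seeds = NULL, germinated = NULL,
                          m2_producing = NULL, families_screened = NULL,
                          mutants_found = NULL,
                          fertility_denominator = c("germinated",
                                                    "treated_seeds")) {
  fertility_denominator <- match.arg(fertility_denominator)
  rows <- list()
  add <- function(rate, num, den) {
    if (is.null(num) || is.null(den)) return()
    if (den == 0) stop("zero denominator for rate ", rate)
    if (num > den) stop("numerator exceeds denominator for rate ", rate)
    rows[[length(rows) + 1]] <<- data.frame(rate = rate, numerator = num,
                                            denominator = den,
                                            percent = round(100 * num / den, 2))
  }
  add("germination", germinated, treated_seeds)
  fert_den <- if (fertility_denominator == "germinated") germinated else treated_seeds
  add("fertility", m2_producing, fert_den)
  if (!is.null(m2_producing) && !is.null(fert_den))
    add("sterility", fert_den - m2_producing, fert_den)
  add("mutant_detection", mutants_found, families_screened)
  if (length(rows) == 0) stop("no computable rates from the given counts")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interpolate the 50% crossing of a dose-response curve
#'
#' Linear interpolation between the two doses bracketing 50%; a dose sitting
#' exactly at 50% is returned as is. If the pooled rates are not monotone the
#' first crossing (in dose order) is used, with a warning.
#'
#' @param doses Distinct doses (percent), any order.
#' @param rates_percent Endpoint rates (percent of treated seeds) per dose.
#' @return The interpolated LD50 dose (percent).
#' @examples
#' interpolate_ld50(c(0.5, 0.7), c(79.2, 48.8))  # ~0.692
#' @export
interpolate_ld50 <- function(doses, rates_percent) {
  stopifnot(length(doses) == length(rates_percent), length(doses) >= 2)
  o <- order(doses)
  doses <- doses[o]
  rates <- rates_percent[o]
  exact <- which(rates == 50)
  if (length(exact)) return(doses[exact[1]])
  if (all(rates > 50) || all(rates < 50))
    stop("no dose pair brackets the 50% rate")
  cross <- which(diff(sign(rates - 50)) != 0)
  if (!all(diff(rates) < 0))
    warning("rates not monotone decreasing in dose; using the first crossing")
  i <- cross[1]
  doses[i] + (doses[i + 1] - doses[i]) * (rates[i] - 50) / (rates[i] - rates[i + 1])
}

#' Estimate the LD50 from a dose-response table
#'
#' Pools replicates per dose into a single endpoint rate (germinated or
#' fertile counts over the chosen denominator) and interpolates the dose at
#' which the rate crosses 50%.
#'
#' @param table data.frame as from [simulate_dose_response()]: `dose`,
#'   `seeds`, `germinated`, `fertile`.
#' @param endpoint `"fertility"` (default) or `"germination"`.
#' @param denominator `"seeds"` (treated-seed rates, default) or
#'   `"germinated"` (per-germinated-plant fertility).
#' @return Interpolated LD50 dose (percent).
#' @export
estimate_ld50 <- function(table, endpoint = c("fertility", "germination"),
                          denominator = c("seeds", "germinated")) {
  endpoint <- match.arg(endpoint)
  denominator <- match.arg(denominator)
  num_col <- if (endpoint == "fertility") "fertile" else "germinated"
  den_col <- if (endpoint == "germination") "seeds" else denominator
  doses <- sort(unique(table$dose))
  if (length(doses) < 2) stop("need at least 2 distinct doses")
  rates <- vapply(doses, function(d) {
    rows <- table[table$dose == d, ]
    100 * sum(rows[[num_col]]) / sum(rows[[den_col]])
  }, numeric(1))
  interpolate_ld50(doses, rates)
}
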