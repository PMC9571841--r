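# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Natural ordering of chromosome names
#'
#' Orders names so that numeric suffixes sort numerically (`chr2` before
#' `chr11`), the convention used by all writers in the package.
#'
#' @param x Character vector of names.
#' @return Integer permutation ordering `x`.
#' @export
natural_order <- function(x) {
  prefix <- gsub("[0-9]+", "", x)
  num <- suppressWarnings(as.numeric(gsub("[^0-9]+", "", x)))
  num[is.na(num)] <- -Inf
  order(prefix, num, x)
}

# Run code with a temporary RNG state seeded at `seed`; the caller's RNG
# stream is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic stage seed derived from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  ((as.numeric(seed) %% 1e6) * 1009 + offset * 9973 + 17) %% 2147483629
}

# Cheap stable fingerprint of an R object (for provenance headers).
fingerprint <- function(obj) {
  s <- paste(deparse(obj, control = "all"), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_if_not_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name), call. = FALSE)
}

DNA_BASES_CHR <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
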