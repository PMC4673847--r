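# Shared internal helpers.

#' Round half away from zero
#'
#' Percentages in published variant tables are conventionally rounded half-up
#' (e.g. 4.472 -> 4.5), whereas [base::round()] rounds half to even.  All
#' displayed rates in this package go through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# percentage of `part` in `total`, half-up rounded; 0 total reports 0.0
pct_of <- function(part, total, digits = 1) {
  if (total == 0) return(rep(0, length(part)))
  round_half_up(100 * part / total, digits)
}

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

revcomp <- function(x) {
  vapply(strsplit(comp_base(x), ""),
         function(b) paste(rev(b), collapse = ""), character(1))
}

# Deterministic per-stream child seed from a root seed; stays < 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 1e6 * 1009 + stream * 99991) %% 2147483629L)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

is_upper_acgt <- function(x) grepl("^[ACGT]+$", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
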