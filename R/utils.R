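`%||%` <- function(a, b) if (is.null(a)) b else a

# Separator used inside haplotype/genotype hash keys. Allele codes are opaque
# strings, so a non-printing unit separator avoids collisions with user codes.
KEY_SEP <- "\x1f"

hap_keys <- function(m) {
  stopifnot(is.matrix(m))
  do.call(paste, c(lapply(seq_len(ncol(m)), function(j) m[, j]), list(sep = KEY_SEP)))
}

# Genotype keys from canonical (elementwise sorted) allele-pair matrices.
geno_keys <- function(a1, a2) {
  cols <- vector("list", 2L * ncol(a1))
  for (j in seq_len(ncol(a1))) {
    cols[[2L * j - 1L]] <- a1[, j]
    cols[[2L * j]] <- a2[, j]
  }
  do.call(paste, c(cols, list(sep = KEY_SEP)))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic steps in a multi-stage run (pool generation, genotype
#' sampling, EM restarts, Monte Carlo integration) draw their own seed from
#' one master seed through this fixed affine scheme, so that any stage can be
#' re-run in isolation and whole pipelines are reproducible across platforms.
#'
#' @param seed master seed (integer-valued).
#' @param k non-negative integer index of the substream.
#' @return An integer seed in `[0, 2^31)`.
#' @export
sub_seed <- function(seed, k) {
  stopifnot(length(seed) == 1L, length(k) == 1L, is.finite(seed), is.finite(k))
  as.integer((abs(as.double(seed)) * 48271 + 104729 * (as.double(k) + 1)) %% 2147483587)
}

# Internal alias so functions may take an argument literally named
# `stringency` and still reach the parser.
as_match_stringency <- function(x, loci = hla_loci()) stringency(x, loci = loci)

pkg_version_string <- function() {
  as.character(utils::packageVersion("hlamatchr"))
}
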