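#' Hardy-Weinberg probability of an unphased genotype
#'
#' Under Hardy-Weinberg equilibrium an individual's two haplotypes are
#' independent draws from the population haplotype distribution, so
#' `P(g) = sum over unordered compatible pairs (h1, h2) of
#' (2 - [h1 == h2]) * f(h1) * f(h2)`. If the table carries more loci than
#' are considered, it is summed over the extra loci first (equivalently, the
#' genotype keys are restricted), so four-locus tables answer three-locus
#' questions consistently.
#'
#' @param table a `hap_freq_table` whose loci include `considered_loci`.
#' @param g an `unphased_genotype` covering `considered_loci`.
#' @param considered_loci loci to restrict to (default: the table's loci).
#' @return A probability; 0 when the genotype is unsupported.
#' @export
hwe_genotype_prob <- function(table, g, considered_loci = NULL) {
  stopifnot(inherits(table, "hap_freq_table"), inherits(g, "unphased_genotype"))
  considered_loci <- considered_loci %||% table$loci
  if (!all(considered_loci %in% table$loci)) stop("table does not cover the considered loci", call. = FALSE)
  if (!all(considered_loci %in% g$loci)) stop("genotype does not cover the considered loci", call. = FALSE)
  gr <- unphased_genotype(g$pairs[, considered_loci, drop = FALSE])
  hm <- table$haplotypes[, considered_loci, drop = FALSE]
  key <- hap_keys(hm)
  agg <- rowsum(table$freq, key)          # marginal frequencies over considered loci
  lookup <- function(h) {
    i <- match(paste(h[considered_loci], collapse = KEY_SEP), rownames(agg))
    if (is.na(i)) 0 else unname(agg[i, 1L])
  }
  dec <- enumerate_phase_decompositions(gr)
  s <- 0
  for (d in dec) {
    mult <- if (identical(unname(d$h1), unname(d$h2))) 1 else 2
    s <- s + mult * lookup(d$h1) * lookup(d$h2)
  }
  s
}

#' Exhaustive Hardy-Weinberg genotype probability map
#'
#' Enumerates every unordered pair of haplotypes in the table, forms the
#' corresponding unphased genotype restricted to the considered loci, and
#' accumulates its HWE probability. The result supports O(1) zero-mismatch
#' lookups and exact mismatch-tolerant queries. Restricting the genotype
#' keys (rather than pre-summing the table) makes results from a full table
#' and from its marginalized counterpart agree by construction.
#'
#' @param table a `hap_freq_table`.
#' @param considered_loci subset of the table's loci (default all).
#' @param cap maximum number of haplotype pairs to enumerate (default
#'   `2e6`); larger supports must use the registry model's Monte Carlo mode.
#' @return An object of class `genotype_prob_map` with fields `loci`, `a1`,
#'   `a2` (canonical pair matrices, one row per distinct genotype), `key`,
#'   `prob` (summing to 1 within 1e-9).
#' @export
build_genotype_probability_map <- function(table, considered_loci = NULL, cap = 2e6) {
  stopifnot(inherits(table, "hap_freq_table"))
  considered_loci <- considered_loci %||% table$loci
  if (inherits(considered_loci, "match_stringency")) considered_loci <- considered_loci$considered_loci
  if (!all(considered_loci %in% table$loci)) stop("table does not cover the considered loci", call. = FALSE)
  H <- nrow(table$haplotypes)
  npairs <- H * (H + 1) / 2
  if (npairs > cap) {
    stop(sprintf(
      "genotype support too large for exact enumeration (%d haplotype pairs > cap %g); use method = \"monte_carlo\"",
      npairs, cap), call. = FALSE)
  }
  i <- sequence(seq_len(H))                 # pairs (i, j) with i <= j
  j <- rep.int(seq_len(H), seq_len(H))
  f <- table$freq
  p <- f[i] * f[j] * (2 - (i == j))
  hm <- table$haplotypes[, considered_loci, drop = FALSE]
  L <- length(considered_loci)
  A1 <- matrix("", length(i), L, dimnames = list(NULL, considered_loci))
  A2 <- A1
  for (l in seq_len(L)) {
    x <- hm[i, l]
    y <- hm[j, l]
    A1[, l] <- pmin(x, y)
    A2[, l] <- pmax(x, y)
  }
  key <- geno_keys(A1, A2)
  tot <- rowsum(p, key)
  u <- !duplicated(key)
  prob <- unname(tot[match(key[u], rownames(tot)), 1L])
  structure(
    list(loci = considered_loci,
         a1 = A1[u, , drop = FALSE], a2 = A2[u, , drop = FALSE],
         key = key[u], prob = prob),
    class = "genotype_prob_map"
  )
}

#' @export
print.genotype_prob_map <- function(x, ...) {
  cat(sprintf("HWE genotype probability map: %d genotypes over loci %s (total %.9f)\n",
              length(x$prob), paste(x$loci, collapse = "/"), sum(x$prob)))
  invisible(x)
}

# Internal: allele-mismatch count matrix between np patient genotypes
# (canonical pair matrices pa1/pa2) and the ng genotypes of a map.
mismatch_matrix <- function(map, pa1, pa2) {
  np <- nrow(pa1)
  ng <- length(map$prob)
  mm <- matrix(0L, np, ng)
  for (l in seq_along(map$loci)) {
    p1 <- pa1[, l]; p2 <- pa2[, l]
    d1 <- map$a1[, l]; d2 <- map$a2[, l]
    isec <- pmax(outer(p1, d1, "==") + outer(p2, d2, "=="),
                 outer(p1, d2, "==") + outer(p2, d1, "=="))
    mm <- mm + (2L - isec)
  }
  mm
}

# Internal: probability that a random population donor (described by `map`)
# is within `budget` allele mismatches of each of the np patient genotypes.
# budget 0: direct key lookup. budget 1: key lookup plus exact enumeration of
# all single-allele-substitution neighbors (substituted allele drawn from the
# donor map's allele universe; anything else has probability 0). budget >= 2:
# chunked scan of the full map.
match_prob_vector <- function(map, pa1, pa2, budget) {
  np <- nrow(pa1)
  q <- map$prob[match(geno_keys(pa1, pa2), map$key)]
  q[is.na(q)] <- 0
  if (budget == 0L) return(q)

  if (budget == 1L) {
    L <- length(map$loci)
    comps <- lapply(seq_len(L), function(l) paste(pa1[, l], pa2[, l], sep = KEY_SEP))
    lookup <- function(cols) {
      add <- map$prob[match(do.call(paste, c(cols, list(sep = KEY_SEP))), map$key)]
      add[is.na(add)] <- 0
      add
    }
    for (l in seq_len(L)) {
      uni <- unique(c(map$a1[, l], map$a2[, l]))
      x <- pa1[, l]; y <- pa2[, l]
      hom <- x == y
      for (z in uni) {
        # replace the first allele of the pair by z
        cols <- comps
        cols[[l]] <- paste(pmin(z, y), pmax(z, y), sep = KEY_SEP)
        q <- q + ifelse(z != x, lookup(cols), 0)
        # replace the second allele (heterozygous pairs only, to avoid
        # counting the same neighbor genotype twice for homozygotes)
        cols[[l]] <- paste(pmin(x, z), pmax(x, z), sep = KEY_SEP)
        q <- q + ifelse(z != y & !hom, lookup(cols), 0)
      }
    }
    return(pmin(q, 1))
  }

  ng <- length(map$prob)
  chunk <- max(1L, as.integer(floor(2e6 / ng)))
  out <- numeric(np)
  s <- 1L
  while (s <= np) {
    e <- min(np, s + chunk - 1L)
    mm <- mismatch_matrix(map, pa1[s:e, , drop = FALSE], pa2[s:e, , drop = FALSE])
    out[s:e] <- as.vector((mm <= budget) %*% map$prob)
    s <- e + 1L
  }
  pmin(out, 1)
}

#' Probability that a random donor matches a patient at a given stringency
#'
#' For a patient genotype `g` and a donor population with haplotype table
#' `table`, returns `q = sum over donor genotypes g' with
#' mismatch_count(g, g') <= budget of P(g')` under Hardy-Weinberg
#' equilibrium on the stringency's considered loci. With a zero budget this
#' is simply the HWE probability of the patient's own (restricted) genotype.
#'
#' @param table the donor population's `hap_freq_table`.
#' @param patient_g the patient's `unphased_genotype` (must cover the
#'   considered loci).
#' @param stringency a [match_stringency] or preset string such as `"7/8"`.
#' @param map optional precomputed [build_genotype_probability_map()] for
#'   `table` on the stringency's loci (saves rebuilding in tight loops).
#' @param cap passed to the map builder.
#' @return A probability in `[0, 1]`.
#' @export
donor_match_prob <- function(table, patient_g, stringency, map = NULL, cap = 2e6) {
  st <- as_match_stringency(stringency, loci = table$loci)
  if (!all(st$considered_loci %in% patient_g$loci)) {
    stop("patient genotype does not cover the stringency's considered loci", call. = FALSE)
  }
  map <- map %||% build_genotype_probability_map(table, st$considered_loci, cap = cap)
  stopifnot(identical(map$loci, st$considered_loci))
  pa1 <- patient_g$pairs[1L, st$considered_loci, drop = FALSE]
  pa2 <- patient_g$pairs[2L, st$considered_loci, drop = FALSE]
  match_prob_vector(map, pa1, pa2, st$allowed_mismatches)
}
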