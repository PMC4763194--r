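#' Generate multi-population haplotype frequency tables with known truth
#'
#' Emulates the structure a registry matching analysis assumes: several
#' populations, each with its own haplotype frequency spectrum; strong
#' linkage disequilibrium induced by drawing each population's support as a
#' sparse subset of the allele-combination space (frequencies live at the
#' haplotype level, never as allele-frequency products); partial sharing of
#' haplotypes between populations controlled by an overlap fraction; and
#' skewed frequency spectra from a symmetric Dirichlet draw.
#'
#' Each population receives `round(overlap * n_haplotypes)` haplotypes from
#' a common pool shared across populations plus population-private
#' haplotypes drawn disjointly from the remaining combination space, so
#' `overlap = 1` gives identical supports and `overlap = 0` pairwise
#' disjoint ones. A population with low overlap is a "minority" population
#' in the registry sense: most of its haplotypes are absent from the other
#' populations' pools.
#'
#' @param n_populations number of populations.
#' @param loci locus names (default [hla_loci()]).
#' @param alleles_per_locus scalar or per-locus vector of allele counts.
#' @param n_haplotypes scalar or per-population vector of support sizes.
#' @param overlap scalar or per-population vector in `[0, 1]`.
#' @param concentration symmetric Dirichlet concentration of the frequency
#'   draw; the default 0.5 yields the skewed spectra characteristic of HLA
#'   haplotype tables.
#' @param seed integer seed; identical arguments and seed reproduce the
#'   output exactly.
#' @param labels population labels (default `pop1`, `pop2`, ...).
#' @return An object of class `synthetic_truth`: `tables` (named list of
#'   `hap_freq_table`), `params`, `seed`.
#' @export
generate_population_tables <- function(n_populations = 2L, loci = hla_loci(),
                                       alleles_per_locus = 8L,
                                       n_haplotypes = 30L, overlap = 0.5,
                                       concentration = 0.5, seed = 1L,
                                       labels = NULL) {
  assert_loci(loci)
  L <- length(loci)
  nallele <- rep_len(as.integer(alleles_per_locus), L)
  n_hap <- rep_len(as.integer(n_haplotypes), n_populations)
  ov <- rep_len(as.numeric(overlap), n_populations)
  if (any(ov < 0 | ov > 1)) stop("overlap must be in [0, 1]", call. = FALSE)
  if (any(n_hap < 1L)) stop("each population needs at least one haplotype", call. = FALSE)
  if (concentration <= 0) stop("concentration must be positive", call. = FALSE)
  labels <- labels %||% paste0("pop", seq_len(n_populations))
  stopifnot(length(labels) == n_populations)

  space <- prod(as.numeric(nallele))
  n_shared <- as.integer(round(ov * n_hap))
  n_common <- max(n_shared, 0L)
  n_private <- n_hap - n_shared
  total <- n_common + sum(n_private)
  if (any(n_hap > space) || total > space) {
    stop(sprintf("requested support (%d haplotypes) exceeds the %g allele combinations available",
                 total, space), call. = FALSE)
  }

  out <- withr::with_seed(as.integer(seed), {
    idx0 <- sample.int(space, total) - 1
    # decode mixed-radix indices into allele tuples
    am <- matrix("", total, L, dimnames = list(NULL, loci))
    rem <- idx0
    for (l in seq_len(L)) {
      a <- rem %% nallele[l]
      rem <- rem %/% nallele[l]
      am[, l] <- sprintf("%s*%02d", loci[l], a + 1)
    }
    common <- am[seq_len(n_common), , drop = FALSE]
    offset <- n_common
    tables <- vector("list", n_populations)
    for (k in seq_len(n_populations)) {
      priv <- am[offset + seq_len(n_private[k]), , drop = FALSE]
      offset <- offset + n_private[k]
      supp <- rbind(common[seq_len(n_shared[k]), , drop = FALSE], priv)
      f <- stats::rgamma(n_hap[k], shape = concentration)
      f[f <= 0] <- .Machine$double.xmin
      tables[[k]] <- hap_freq_table(supp, f / sum(f), population = labels[k],
                                    normalize = TRUE)
    }
    names(tables) <- labels
    tables
  })

  structure(
    list(tables = out,
         params = list(n_populations = n_populations, loci = loci,
                       alleles_per_locus = nallele, n_haplotypes = n_hap,
                       overlap = ov, concentration = concentration,
                       labels = labels),
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d population(s), loci %s, seed %d\n",
              length(x$tables), paste(x$params$loci, collapse = "/"), x$seed))
  for (t in x$tables) {
    cat(sprintf("  %-12s %d haplotypes, max freq %.4f\n",
                t$population, n_haplotypes(t), max(t$freq)))
  }
  invisible(x)
}

#' Sample unphased genotypes under Hardy-Weinberg equilibrium
#'
#' Each genotype is formed from two i.i.d. haplotype draws from the table,
#' then unphased into per-locus unordered allele pairs — exactly the
#' population model the matching computations assume.
#'
#' @param table a `hap_freq_table`.
#' @param n number of genotypes (>= 1).
#' @param seed integer seed.
#' @param id_prefix prefix for generated ids (default `"S"`).
#' @return A `genotype_set` labelled with the table's population.
#' @export
sample_genotypes <- function(table, n, seed, id_prefix = "S") {
  stopifnot(inherits(table, "hap_freq_table"), n >= 1L)
  H <- n_haplotypes(table)
  idx <- withr::with_seed(as.integer(seed), {
    cbind(sample.int(H, n, replace = TRUE, prob = table$freq),
          sample.int(H, n, replace = TRUE, prob = table$freq))
  })
  a1 <- table$haplotypes[idx[, 1L], , drop = FALSE]
  a2 <- table$haplotypes[idx[, 2L], , drop = FALSE]
  new_genotype_set(a1, a2, table$loci,
                   rep.int(table$population, n),
                   sprintf("%s%06d", id_prefix, seq_len(n)))
}

#' Brute-force per-donor match probability (oracle)
#'
#' Independent reference implementation for [donor_match_prob()]: enumerates
#' every ordered pair of haplotypes in the table, forms the donor genotype,
#' counts allele mismatches locus by locus, and sums `f(h1) * f(h2)` over
#' pairs within the budget. Exact but quadratic in the support, hence capped
#' at 200 haplotypes; intended for validation, not production.
#'
#' @param table donor `hap_freq_table` (support at most 200 haplotypes).
#' @param patient_g patient `unphased_genotype`.
#' @param stringency a [match_stringency] or preset string.
#' @return A probability.
#' @export
brute_force_match_prob <- function(table, patient_g, stringency) {
  stopifnot(inherits(table, "hap_freq_table"))
  H <- n_haplotypes(table)
  if (H > 200L) stop("support too large for the brute-force oracle (> 200 haplotypes)", call. = FALSE)
  st <- as_match_stringency(stringency, loci = table$loci)
  loci <- st$considered_loci
  if (!all(loci %in% patient_g$loci)) {
    stop("patient genotype does not cover the stringency's considered loci", call. = FALSE)
  }
  hm <- table$haplotypes[, loci, drop = FALSE]
  p1 <- patient_g$pairs[1L, loci]
  p2 <- patient_g$pairs[2L, loci]
  total <- 0
  for (i in seq_len(H)) {
    for (j in seq_len(H)) {
      mism <- 0L
      for (l in seq_along(loci)) {
        d1 <- hm[i, l]
        d2 <- hm[j, l]
        isec <- max((p1[l] == d1) + (p2[l] == d2), (p1[l] == d2) + (p2[l] == d1))
        mism <- mism + (2L - isec)
      }
      if (mism <= st$allowed_mismatches) total <- total + table$freq[i] * table$freq[j]
    }
  }
  total
}

#' Simulate registry searches donor by donor (oracle)
#'
#' Independent stochastic reference for [registry_match_likelihood()]: in
#' each replicate a patient genotype and every registry donor's genotype are
#' drawn from their populations' Hardy-Weinberg distributions, and the
#' replicate scores a success if at least one donor falls within the
#' stringency's mismatch budget. Requires integer effective donor counts
#' with at most 50 donors in total, so that full enumeration stays cheap.
#'
#' @param registry an `hla_registry` whose effective counts
#'   (`donors * availability`) are whole numbers summing to at most 50.
#' @param patient_population patient population label.
#' @param stringency a [match_stringency] or preset string.
#' @param n_replicates number of simulated registries (>= 1000).
#' @param seed integer seed.
#' @return List with `match_freq` (empirical frequency), `standard_error`
#'   (binomial), `n_replicates`, `seed`.
#' @export
simulate_registry_search <- function(registry, patient_population, stringency,
                                     n_replicates = 10000L, seed = 1L) {
  stopifnot(inherits(registry, "hla_registry"))
  if (n_replicates < 1000L) stop("n_replicates must be at least 1000", call. = FALSE)
  Ns <- effective_donors(registry)
  if (any(abs(Ns - round(Ns)) > 1e-9)) {
    stop("simulation oracle requires integer effective donor counts", call. = FALSE)
  }
  Ns <- as.integer(round(Ns))
  if (sum(Ns) > 50L) stop("simulation oracle supports at most 50 donors in total", call. = FALSE)
  st <- as_match_stringency(stringency, loci = registry$loci)
  loci <- st$considered_loci
  budget <- st$allowed_mismatches
  pt <- registry$populations[[patient_population]]$table
  R <- as.integer(n_replicates)

  matched <- withr::with_seed(as.integer(seed), {
    Hp <- n_haplotypes(pt)
    pi1 <- sample.int(Hp, R, replace = TRUE, prob = pt$freq)
    pi2 <- sample.int(Hp, R, replace = TRUE, prob = pt$freq)
    phm <- pt$haplotypes[, loci, drop = FALSE]
    hit <- rep.int(FALSE, R)
    for (k in seq_along(registry$populations)) {
      Nk <- Ns[k]
      if (Nk == 0L) next
      tab <- registry$populations[[k]]$table
      Hk <- n_haplotypes(tab)
      hm <- tab$haplotypes[, loci, drop = FALSE]
      di1 <- matrix(sample.int(Hk, R * Nk, replace = TRUE, prob = tab$freq), R, Nk)
      di2 <- matrix(sample.int(Hk, R * Nk, replace = TRUE, prob = tab$freq), R, Nk)
      mism <- matrix(0L, R, Nk)
      for (l in seq_along(loci)) {
        p1 <- phm[pi1, l]                    # length R, recycles down columns
        p2 <- phm[pi2, l]
        d1 <- matrix(hm[di1, l], R, Nk)
        d2 <- matrix(hm[di2, l], R, Nk)
        isec <- pmax((d1 == p1) + (d2 == p2), (d1 == p2) + (d2 == p1))
        mism <- mism + (2L - isec)
      }
      hit <- hit | (rowSums(mism <= budget) > 0L)
    }
    hit
  })
  p_hat <- mean(matched)
  list(match_freq = p_hat,
       standard_error = sqrt(p_hat * (1 - p_hat) / R),
       n_replicates = R, seed = as.integer(seed))
}
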