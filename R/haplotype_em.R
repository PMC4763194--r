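#' Enumerate phase decompositions of an unphased genotype
#'
#' An unphased genotype heterozygous at `H` loci is compatible with
#' `2^(H-1)` unordered haplotype pairs (one when fully homozygous): at the
#' first heterozygous locus one allele is arbitrarily assigned to the first
#' haplotype, and the remaining heterozygous loci are phased freely. This
#' enumeration is the combinatorial core of both the EM algorithm and the
#' Hardy-Weinberg genotype probabilities.
#'
#' @param g an `unphased_genotype`.
#' @return A list of `list(h1 = , h2 = )` pairs, each haplotype a named
#'   character vector (names = loci); pairs are unordered and distinct.
#' @export
enumerate_phase_decompositions <- function(g) {
  stopifnot(inherits(g, "unphased_genotype"))
  a1 <- g$pairs[1L, ]
  a2 <- g$pairs[2L, ]
  het <- which(a1 != a2)
  H <- length(het)
  if (H == 0L) return(list(list(h1 = a1, h2 = a1)))
  free <- het[-1L]
  n <- 2L^(H - 1L)
  out <- vector("list", n)
  for (b in seq_len(n) - 1L) {
    h1 <- a1
    h2 <- a2
    if (length(free)) {
      bits <- bitwAnd(b %/% 2L^(seq_along(free) - 1L), 1L) == 1L
      sw <- free[bits]
      h1[sw] <- a2[sw]
      h2[sw] <- a1[sw]
    }
    out[[b + 1L]] <- list(h1 = h1, h2 = h2)
  }
  out
}

# Internal: collapse a genotype_set to unique phase patterns and index all
# decomposition pairs against the support of compatible haplotypes.
# Returns list(support (matrix), pa, pb, mult, gi, cnt, G, ids_by_pattern).
build_em_structures <- function(gs) {
  n <- length(gs)
  gkey <- geno_keys(gs$a1, gs$a2)
  first <- !duplicated(gkey)
  ukey <- gkey[first]
  pat_of <- match(gkey, ukey)
  cnt <- tabulate(pat_of, nbins = length(ukey))
  uidx <- which(first)

  hapA <- list(); hapB <- list(); gi_l <- list()
  for (u in seq_along(uidx)) {
    dec <- enumerate_phase_decompositions(gs[[uidx[u]]])
    hapA[[u]] <- do.call(rbind, lapply(dec, `[[`, "h1"))
    hapB[[u]] <- do.call(rbind, lapply(dec, `[[`, "h2"))
    gi_l[[u]] <- rep.int(u, length(dec))
  }
  HA <- do.call(rbind, hapA)
  HB <- do.call(rbind, hapB)
  gi <- unlist(gi_l)
  kA <- hap_keys(HA)
  kB <- hap_keys(HB)
  all_keys <- c(kA, kB)
  support_first <- !duplicated(all_keys)
  support <- rbind(HA, HB)[support_first, , drop = FALSE]
  colnames(support) <- gs$loci
  skey <- all_keys[support_first]
  pa <- match(kA, skey)
  pb <- match(kB, skey)
  mult <- ifelse(pa == pb, 1, 2)
  list(support = support, skey = skey, pa = pa, pb = pb, mult = mult,
       gi = gi, cnt = cnt, G = length(ukey), n = n, pat_of = pat_of)
}

#' Estimate haplotype frequencies by expectation-maximization
#'
#' Maximum-likelihood haplotype frequency estimation from unphased
#' multi-locus genotypes. The E-step distributes each genotype over its
#' phase decompositions with posterior weight proportional to
#' `f(h1) * f(h2) * (2 - [h1 == h2])`; the M-step sets each haplotype
#' frequency to its expected gamete count divided by `2n`. Iteration stops
#' when the observed-data log-likelihood changes by less than `tol` or after
#' `max_iter` iterations. The support is restricted to haplotypes compatible
#' with at least one observed genotype, so no observation can have zero
#' probability during the run.
#'
#' The observed-data log-likelihood is non-decreasing along the iteration
#' (standard EM ascent property); the full trace is returned for inspection.
#' When phase is unambiguous (at most one heterozygous locus per genotype)
#' a single M-step equals the closed-form gamete-counting estimator. Note
#' the likelihood can have flat ridges (e.g. data consisting only of double
#' heterozygotes), on which the uniform start is a stationary point; random
#' restarts via `init = "random"` expose such multimodality.
#'
#' @param genotypes a `genotype_set` (or coercible) of at least one genotype.
#' @param tol convergence tolerance on the log-likelihood change (default
#'   `1e-8`).
#' @param max_iter iteration cap (default 1000).
#' @param init `"uniform"` (uniform over the compatible support; default) or
#'   `"random"` (symmetric Dirichlet(1) draw, requires `seed`).
#' @param seed integer seed; mandatory for `init = "random"`, ignored otherwise.
#' @param prune_tol haplotypes with final frequency below this are removed
#'   and the table renormalized (default `1e-12`, far below any
#'   interpretable frequency).
#' @return An object of class `em_result`: fields `table`
#'   (`hap_freq_table`), `log_likelihood`, `n_iterations`, `converged`,
#'   `ll_trace`, `init`, `seed`, `n`.
#' @export
em_estimate <- function(genotypes, tol = 1e-8, max_iter = 1000L,
                        init = c("uniform", "random"), seed = NULL,
                        prune_tol = 1e-12) {
  gs <- as_genotype_set(genotypes)
  if (length(gs) == 0L) stop("at least one genotype is required", call. = FALSE)
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  init <- match.arg(init)
  st <- build_em_structures(gs)
  H <- nrow(st$support)
  n <- st$n

  if (init == "uniform") {
    f <- rep.int(1 / H, H)
  } else {
    if (is.null(seed)) stop("init = \"random\" requires a seed", call. = FALSE)
    f <- withr::with_seed(as.integer(seed), stats::rexp(H))
    f <- f / sum(f)
  }

  pop <- unique(gs$population)
  pop <- if (length(pop) == 1L) pop else NA_character_

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    w <- f[st$pa] * f[st$pb] * st$mult
    Pg <- as.vector(rowsum(w, st$gi))          # groups 1..G, all present
    ll <- sum(st$cnt * log(Pg))
    ll_trace <- c(ll_trace, ll)
    if (iter > 0L && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    post <- w / Pg[st$gi] * st$cnt[st$gi]
    cc <- numeric(H)
    t1 <- rowsum(post, st$pa)
    cc[as.integer(rownames(t1))] <- t1[, 1L]
    t2 <- rowsum(post, st$pb)
    i2 <- as.integer(rownames(t2))
    cc[i2] <- cc[i2] + t2[, 1L]
    f <- cc / (2 * n)
    iter <- iter + 1L
  }

  keep <- f >= prune_tol
  table <- hap_freq_table(st$support[keep, , drop = FALSE], f[keep],
                          population = pop, normalize = TRUE)
  structure(
    list(table = table, log_likelihood = ll, n_iterations = iter,
         converged = converged, ll_trace = ll_trace, init = init,
         seed = if (init == "random") as.integer(seed) else NA_integer_,
         n = n),
    class = "em_result"
  )
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf(
    "EM haplotype frequency fit: n = %d genotypes, %d haplotypes retained\n",
    x$n, n_haplotypes(x$table)))
  cat(sprintf("  log-likelihood %.6f after %d iteration(s); converged: %s; init: %s\n",
              x$log_likelihood, x$n_iterations, x$converged, x$init))
  invisible(x)
}

#' Observed-data log-likelihood of a frequency table
#'
#' `sum_g log P(g)` where `P(g)` sums `(2 - [h1 == h2]) * f(h1) * f(h2)`
#' over the phase decompositions of `g`. Haplotypes absent from the table
#' have frequency zero; if any genotype then has zero probability the
#' function returns `-Inf` with attribute `"zero_ids"` listing the offending
#' genotype ids.
#'
#' @param table a `hap_freq_table`.
#' @param genotypes a `genotype_set` (or coercible) over the table's loci.
#' @return Log-likelihood (possibly `-Inf` with attribute `zero_ids`).
#' @export
log_likelihood <- function(table, genotypes) {
  gs <- as_genotype_set(genotypes)
  stopifnot(inherits(table, "hap_freq_table"))
  if (!identical(gs$loci, table$loci)) {
    stop("genotype loci do not match the frequency table's loci", call. = FALSE)
  }
  st <- build_em_structures(gs)
  f <- table$freq[match(st$skey, hap_keys(table$haplotypes))]
  f[is.na(f)] <- 0
  w <- f[st$pa] * f[st$pb] * st$mult
  Pg <- as.vector(rowsum(w, st$gi))
  if (any(Pg == 0)) {
    bad_patterns <- which(Pg == 0)
    ids <- gs$id[st$pat_of %in% bad_patterns]
    return(structure(-Inf, zero_ids = ids))
  }
  sum(st$cnt * log(Pg))
}
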