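# Shared builders and independent oracles for the test suite.

# Quick genotype builder: ug(A = c("a1","a2"), B = c("b1","b1"), ...)
ug <- function(..., population = NA_character_, id = NA_character_) {
  unphased_genotype(list(...), population = population, id = id)
}

# A 2-locus table over haplotypes written as "a|b" strings.
tab2 <- function(freqs, population = "toy", loci = c("A", "B")) {
  hm <- do.call(rbind, strsplit(names(freqs), "|", fixed = TRUE))
  colnames(hm) <- loci
  hap_freq_table(hm, unname(freqs), population = population)
}

# Random haplotype frequency table on a small allele space.
rand_table <- function(loci = c("A", "B", "C"), alleles = 3L, n_hap = 6L,
                       seed = 1L, population = "rnd") {
  generate_population_tables(
    n_populations = 1L, loci = loci, alleles_per_locus = alleles,
    n_haplotypes = n_hap, overlap = 0, concentration = 0.7,
    seed = seed, labels = population)$tables[[1L]]
}

# Random unphased genotype: usually drawn from the table under HWE, sometimes
# carrying an allele foreign to the table (exercises the zero-support paths).
rand_patient <- function(table, seed, foreign = FALSE) {
  g <- sample_genotypes(table, 1L, seed = seed)[[1L]]
  if (foreign) {
    pairs <- g$pairs
    pairs[1L, 1L] <- "ZZ*99"
    g <- unphased_genotype(pairs)
  }
  g
}

# ---- independent 2-locus / 2-allele likelihood oracle -----------------------
# Haplotypes in fixed order: (A1,B1), (A1,B2), (A2,B1), (A2,B2) with
# frequencies h (length 4). Genotype probability by explicit enumeration of
# all 16 ordered haplotype pairs; written without any package internals.
oracle_alleles_2x2 <- list(A = c("A1", "A2"), B = c("B1", "B2"))
oracle_haps_2x2 <- expand.grid(B = oracle_alleles_2x2$B, A = oracle_alleles_2x2$A,
                               stringsAsFactors = FALSE)[, c("A", "B")]
oracle_haps_2x2 <- as.matrix(oracle_haps_2x2)

# Precompute, for each distinct observed genotype, which ordered haplotype
# pairs (i, j) reproduce it, plus the observation count. Done once per data
# set so that likelihood evaluations inside the grid/optimizer are cheap.
oracle_structure_2x2 <- function(gs) {
  keys <- vapply(seq_len(length(gs)), function(r) {
    g <- gs[[r]]
    paste(c(g$pairs[, "A"], g$pairs[, "B"]), collapse = "/")
  }, character(1))
  ukeys <- unique(keys)
  cnt <- as.vector(table(factor(keys, levels = ukeys)))
  pairs <- lapply(ukeys, function(k) {
    g <- gs[[match(k, keys)]]
    hits <- NULL
    for (i in 1:4) {
      for (j in 1:4) {
        gA <- unname(sort(c(oracle_haps_2x2[i, "A"], oracle_haps_2x2[j, "A"])))
        gB <- unname(sort(c(oracle_haps_2x2[i, "B"], oracle_haps_2x2[j, "B"])))
        if (identical(gA, unname(g$pairs[, "A"])) &&
            identical(gB, unname(g$pairs[, "B"]))) {
          hits <- rbind(hits, c(i, j))
        }
      }
    }
    hits
  })
  list(pairs = pairs, cnt = cnt)
}

oracle_loglik_2x2 <- function(h, struct) {
  ll <- 0
  for (u in seq_along(struct$cnt)) {
    pr <- struct$pairs[[u]]
    ll <- ll + struct$cnt[u] * log(sum(h[pr[, 1]] * h[pr[, 2]]))
  }
  ll
}

# Maximum log-likelihood over the 3-simplex of 4 haplotype frequencies:
# coarse grid scan followed by Nelder-Mead refinement on a softmax
# parameterization. Independent of the EM implementation.
oracle_max_loglik_2x2 <- function(gs, grid_step = 0.05) {
  struct <- oracle_structure_2x2(gs)
  grid <- expand.grid(a = seq(0, 1, grid_step), b = seq(0, 1, grid_step),
                      c = seq(0, 1, grid_step))
  grid <- grid[grid$a + grid$b + grid$c <= 1 + 1e-12, ]
  best <- -Inf
  best_h <- rep(0.25, 4)
  for (r in seq_len(nrow(grid))) {
    h <- c(grid$a[r], grid$b[r], grid$c[r], 1 - grid$a[r] - grid$b[r] - grid$c[r])
    h <- pmax(h, 1e-12)
    h <- h / sum(h)
    ll <- oracle_loglik_2x2(h, struct)
    if (ll > best) {
      best <- ll
      best_h <- h
    }
  }
  soft <- function(theta) {
    e <- exp(c(theta, 0))
    e / sum(e)
  }
  opt <- stats::optim(log(best_h[1:3] / best_h[4]),
                      function(theta) -oracle_loglik_2x2(soft(theta), struct),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 20000))
  max(best, -opt$value)
}

# Closed-form gamete counting for phase-unambiguous genotype sets (at most
# one heterozygous locus per genotype): each genotype contributes its two
# haplotypes directly.
counting_estimator <- function(gs) {
  counts <- list()
  for (i in seq_len(length(gs))) {
    g <- gs[[i]]
    het <- which(g$pairs[1L, ] != g$pairs[2L, ])
    stopifnot(length(het) <= 1L)
    h1 <- g$pairs[1L, ]
    h2 <- g$pairs[2L, ]
    for (h in list(h1, h2)) {
      k <- paste(h, collapse = "~")
      counts[[k]] <- (counts[[k]] %||% 0) + 1
    }
  }
  unlist(counts) / (2 * length(gs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
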