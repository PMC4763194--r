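test_that("phase decomposition enumerates 2^(H-1) distinct unordered pairs", {
  hom <- ug(A = c("a", "a"), B = c("b", "b"))
  dec <- enumerate_phase_decompositions(hom)
  expect_length(dec, 1L)
  expect_identical(dec[[1]]$h1, dec[[1]]$h2)

  dbl <- ug(A = c("a1", "a2"), B = c("b1", "b2"))
  dec2 <- enumerate_phase_decompositions(dbl)
  expect_length(dec2, 2L)
  got <- sort(vapply(dec2, function(d)
    paste(sort(c(paste(d$h1, collapse = "~"), paste(d$h2, collapse = "~"))),
          collapse = " + "), character(1)))
  expect_identical(got, sort(c("a1~b1 + a2~b2", "a1~b2 + a2~b1")))

  tri <- ug(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2"))
  dec3 <- enumerate_phase_decompositions(tri)
  expect_length(dec3, 4L)
  # pairs are distinct as unordered pairs and reproduce the genotype
  keys <- vapply(dec3, function(d)
    paste(sort(c(paste(d$h1, collapse = "~"), paste(d$h2, collapse = "~"))),
          collapse = "+"), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (d in dec3) {
    for (l in c("A", "B", "C")) {
      expect_identical(sort(c(d$h1[[l]], d$h2[[l]])), sort(tri$pairs[, l]))
    }
  }
})

test_that("EM equals the gamete-counting estimator on phase-unambiguous data", {
  # 50 + 50 homozygotes: closed-form 0.5/0.5 after one sweep
  gs <- as_genotype_set(c(
    replicate(50, ug(A = c("a1", "a1"), B = c("b1", "b1")), simplify = FALSE),
    replicate(50, ug(A = c("a2", "a2"), B = c("b2", "b2")), simplify = FALSE)))
  fit <- em_estimate(gs)
  expect_true(fit$converged)
  expect_equal(sort(fit$table$freq), c(0.5, 0.5))

  # random dataset with at most one heterozygous locus per genotype
  set.seed(31)
  mk <- function() {
    a <- sample(c("a1", "a2", "a3"), 1)
    b <- sample(c("b1", "b2"), 2, replace = TRUE)  # may be het at B only
    ug(A = c(a, a), B = b)
  }
  gs2 <- as_genotype_set(replicate(80, mk(), simplify = FALSE))
  fit2 <- em_estimate(gs2)
  expected <- counting_estimator(gs2)
  got <- fit2$table$freq
  names(got) <- apply(fit2$table$haplotypes, 1, paste, collapse = "~")
  expect_equal(sort(names(got)), sort(names(expected)))
  expect_equal(got[names(expected)], expected, tolerance = 1e-12)
})

test_that("uniform frequencies are a stationary point on the double-heterozygote ridge", {
  gs <- as_genotype_set(replicate(40, ug(A = c("a1", "a2"), B = c("b1", "b2")),
                                  simplify = FALSE))
  fit <- em_estimate(gs)
  expect_true(fit$converged)
  expect_equal(n_haplotypes(fit$table), 4L)
  expect_equal(fit$table$freq, rep(0.25, 4), tolerance = 1e-12)
  # and the attained log-likelihood matches the hand-computed P(g) = 0.25
  expect_equal(fit$log_likelihood, 40 * log(0.25), tolerance = 1e-9)
})

test_that("log_likelihood matches hand-computed values and flags zero support", {
  one <- tab2(c("a|b" = 1))
  hom <- ug(A = c("a", "a"), B = c("b", "b"), id = "g1")
  expect_equal(log_likelihood(one, hom), 0)

  # double heterozygote under uniform 0.25: both phase pairs contribute 2 * 0.0625
  uni <- tab2(c("a1|b1" = 0.25, "a1|b2" = 0.25, "a2|b1" = 0.25, "a2|b2" = 0.25))
  dbl <- ug(A = c("a1", "a2"), B = c("b1", "b2"), id = "g2")
  expect_equal(log_likelihood(uni, dbl), log(0.25))

  alien <- ug(A = c("zz", "zz"), B = c("b1", "b1"), id = "g3")
  ll <- log_likelihood(uni, alien)
  expect_identical(as.numeric(ll), -Inf)
  expect_identical(attr(ll, "zero_ids"), "g3")
})

test_that("EM attains the grid/simplex-oracle maximum on 2-locus biallelic data", {
  for (s in c(2, 7, 19)) {
    truth_h <- withr::with_seed(s, {
      h <- rexp(4)
      h / sum(h)
    })
    n <- 120
    gs <- withr::with_seed(s + 100, {
      i <- sample(4, n, TRUE, prob = truth_h)
      j <- sample(4, n, TRUE, prob = truth_h)
      lapply(seq_len(n), function(r) {
        ug(A = sort(c(oracle_haps_2x2[i[r], "A"], oracle_haps_2x2[j[r], "A"])),
           B = sort(c(oracle_haps_2x2[i[r], "B"], oracle_haps_2x2[j[r], "B"])))
      })
    })
    gs <- as_genotype_set(gs)
    fit <- em_estimate(gs, tol = 1e-12, max_iter = 10000)
    oracle <- oracle_max_loglik_2x2(gs)
    expect_lt(abs(fit$log_likelihood - oracle), 1e-6)
  }
})

test_that("EM ascent: the log-likelihood never decreases and frequencies stay normalized", {
  for (s in 1:20) {
    tab <- rand_table(loci = c("A", "B", "C"), alleles = 3, n_hap = 5, seed = s)
    gs <- sample_genotypes(tab, 40, seed = s + 500)
    fit <- em_estimate(gs)
    expect_true(all(diff(fit$ll_trace) >= -1e-8))
    expect_lt(abs(sum(fit$table$freq) - 1), 1e-9)
    expect_true(all(fit$table$freq >= 0))
  }
})

test_that("random initialization is seeded and reproducible; misuse errors", {
  tab <- rand_table(seed = 8)
  gs <- sample_genotypes(tab, 60, seed = 9)
  f1 <- em_estimate(gs, init = "random", seed = 42)
  f2 <- em_estimate(gs, init = "random", seed = 42)
  expect_identical(f1$table$freq, f2$table$freq)
  expect_error(em_estimate(gs, init = "random"), "seed")
  expect_error(em_estimate(list()), "genotype")
  expect_error(em_estimate(gs, tol = 0), "tol")
})
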