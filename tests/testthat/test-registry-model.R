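# A degenerate one-haplotype world: every donor matches every patient.
degenerate_registry <- function(n = 5, avail = 1) {
  hm <- matrix(c("a", "b", "c", "d"), 1, 4, dimnames = list(NULL, hla_loci()))
  tab <- hap_freq_table(hm, 1, population = "only")
  hla_registry(list(list(label = "only", table = tab, donors = n, availability = avail)))
}

# Patient population with a fixed genotype (degenerate table, zero donors)
# searching a donor population built to give a constant per-donor match
# probability; verifies the closed form 1 - (1 - q)^N.
constant_q_registry <- function(N) {
  loci <- hla_loci()
  hshared <- c("a", "b", "c", "d")
  hother <- c("x", "y", "z", "w")
  pt <- hap_freq_table(matrix(hshared, 1, 4, dimnames = list(NULL, loci)), 1,
                       population = "patient")
  dm <- hap_freq_table(matrix(c(hshared, hother), 2, 4, byrow = TRUE,
                              dimnames = list(NULL, loci)),
                       c(0.5, 0.5), population = "donorpool")
  hla_registry(list(
    list(label = "patient", table = pt, donors = 0, availability = 1),
    list(label = "donorpool", table = dm, donors = N, availability = 1)))
}

test_that("effective donor counts are availability-scaled and real-valued", {
  reg <- hla_registry(list(
    list(label = "a", table = rand_table(seed = 1, population = "a"),
         donors = 100, availability = 0.6),
    list(label = "b", table = rand_table(seed = 2, population = "b"),
         donors = 250, availability = 0),
    list(label = "c", table = rand_table(seed = 3, population = "c"),
         donors = 77, availability = 1)))
  expect_equal(effective_donors(reg), c(a = 60, b = 0, c = 77))
})

test_that("likelihood is 1 in a degenerate single-haplotype world and 0 with no donors", {
  reg <- degenerate_registry(n = 5)
  for (s in c("8/8", "7/8", "6/6:A", "5/6:DRB1")) {
    expect_equal(registry_match_likelihood(reg, "only", s)$likelihood, 1)
  }
  empty <- degenerate_registry(n = 0)
  expect_equal(registry_match_likelihood(empty, "only", "8/8")$likelihood, 0)
  none <- degenerate_registry(n = 100, avail = 0)
  expect_equal(registry_match_likelihood(none, "only", "8/8")$likelihood, 0)
})

test_that("constant-q constructions reproduce the closed form 1 - (1 - q)^N", {
  # 8/8: the patient's genotype occurs in the donor pool with P = 0.25
  reg2 <- constant_q_registry(2)
  expect_equal(registry_match_likelihood(reg2, "patient", "8/8")$likelihood,
               1 - (1 - 0.25)^2, tolerance = 1e-12)
  # budget 4 additionally admits the mixed genotype (P = 0.5): q = 0.75
  st4 <- match_stringency(hla_loci(), 4L)
  expect_equal(registry_match_likelihood(reg2, "patient", st4)$likelihood,
               1 - (1 - 0.75)^2, tolerance = 1e-12)
  # non-integer effective counts enter the exponent as-is
  reg75 <- constant_q_registry(15)
  reg75$populations$donorpool$availability <- 0.5   # N = 7.5
  expect_equal(registry_match_likelihood(reg75, "patient", "8/8")$likelihood,
               1 - (1 - 0.25)^7.5, tolerance = 1e-12)
})

test_that("exact and Monte Carlo modes agree within reported error", {
  truth <- generate_population_tables(2, alleles_per_locus = 4,
                                      n_haplotypes = c(8, 10), overlap = 0.4,
                                      seed = 17, labels = c("p1", "p2"))
  reg <- hla_registry(list(
    list(label = "p1", table = truth$tables$p1, donors = 800, availability = 0.5),
    list(label = "p2", table = truth$tables$p2, donors = 150, availability = 0.4)))
  for (s in c("8/8", "5/6:B")) {
    ex <- registry_match_likelihood(reg, "p2", s)
    mc <- registry_match_likelihood(reg, "p2", s, method = "monte_carlo",
                                    n_samples = 50000, seed = 99)
    expect_lt(abs(ex$likelihood - mc$likelihood), 3 * mc$standard_error + 1e-12)
    expect_false(is.null(mc$seed))
  }
  expect_error(registry_match_likelihood(reg, "p2", "8/8", method = "monte_carlo",
                                         n_samples = 50, seed = 1), "n_samples")
  expect_error(registry_match_likelihood(reg, "p2", "8/8", method = "monte_carlo"),
               "seed")
  expect_error(registry_match_likelihood(reg, "nope", "8/8"), "not present")
})

test_that("likelihood is monotone in every effective population size", {
  truth <- generate_population_tables(2, alleles_per_locus = 3,
                                      n_haplotypes = 6, overlap = 0.5,
                                      seed = 23, labels = c("p1", "p2"))
  base <- list(
    list(label = "p1", table = truth$tables$p1, donors = 300, availability = 0.6),
    list(label = "p2", table = truth$tables$p2, donors = 50, availability = 0.3))
  lik <- function(pops, s) registry_match_likelihood(hla_registry(pops), "p2", s)$likelihood
  for (s in c("8/8", "7/8")) {
    l0 <- lik(base, s)
    for (k in 1:2) {
      up <- base
      up[[k]]$donors <- up[[k]]$donors * 3
      expect_gte(lik(up, s), l0 - 1e-12)
    }
  }
})

test_that("registry search simulation agrees with the analytic model", {
  # single-haplotype world: every replicate finds a match
  reg1 <- degenerate_registry(n = 10)
  sim1 <- simulate_registry_search(reg1, "only", "8/8", n_replicates = 1000, seed = 1)
  expect_equal(sim1$match_freq, 1)

  # zero donors: no replicate can find one
  reg0 <- degenerate_registry(n = 0)
  sim0 <- simulate_registry_search(reg0, "only", "8/8", n_replicates = 1000, seed = 1)
  expect_equal(sim0$match_freq, 0)

  # constant q = 0.25, N = 2: analytic 0.4375
  regq <- constant_q_registry(2)
  simq <- simulate_registry_search(regq, "patient", "8/8",
                                   n_replicates = 10000, seed = 5)
  expect_lt(abs(simq$match_freq - 0.4375), 3 * max(simq$standard_error, 1e-6))

  expect_error(simulate_registry_search(regq, "patient", "8/8",
                                        n_replicates = 100, seed = 1), "1000")
  big <- degenerate_registry(n = 100)
  expect_error(simulate_registry_search(big, "only", "8/8", seed = 1), "50")
})

test_that("locus-drop reports have the documented shape and degenerate values", {
  reg <- degenerate_registry(n = 5)
  rep1 <- locus_drop_report(reg)
  expect_equal(nrow(rep1), 1L)
  lik_cols <- grep("^p_", names(rep1), value = TRUE)
  gain_cols <- grep("^gain_", names(rep1), value = TRUE)
  expect_length(lik_cols, 2L + 2L * 4L)
  expect_length(gain_cols, 2L * 4L)
  expect_true(all(as.numeric(rep1[lik_cols]) == 1))
  expect_true(all(as.numeric(rep1[gain_cols]) == 0))
  expect_false(is.null(attr(rep1, "metadata")))
})

test_that("registry configurations round-trip through disk", {
  truth <- generate_population_tables(2, alleles_per_locus = 3, n_haplotypes = 5,
                                      overlap = 0.5, seed = 29,
                                      labels = c("p1", "p2"))
  reg <- hla_registry(list(
    list(label = "p1", table = truth$tables$p1, donors = 120, availability = 0.55),
    list(label = "p2", table = truth$tables$p2, donors = 40, availability = 0.25)))
  dir <- file.path(tempdir(), "regcfg")
  cfg <- write_registry_config(reg, dir)
  back <- read_registry_config(cfg)
  expect_equal(effective_donors(back), effective_donors(reg))
  expect_equal(registry_match_likelihood(back, "p2", "7/8")$likelihood,
               registry_match_likelihood(reg, "p2", "7/8")$likelihood)
})
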