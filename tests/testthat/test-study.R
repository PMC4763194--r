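# A reduced scenario for fast end-to-end runs: same structure as the
# packaged minority scenario, smaller pools and registry.
small_scenario <- function(seed) {
  minority_scenario(seed = seed, donors = c(majority = 2000, minority = 300),
                    availability = c(majority = 0.6, minority = 0.3),
                    alleles_per_locus = 4L, n_haplotypes = c(12L, 16L),
                    overlap = c(0.9, 0.1))
}

test_that("per-population frequency estimation writes tables and diagnostics", {
  truth <- generate_population_tables(2, alleles_per_locus = 4, n_haplotypes = 8,
                                      overlap = 0.5, seed = 19,
                                      labels = c("p1", "p2"))
  gs <- as_genotype_set(c(
    lapply(1:150, function(i) sample_genotypes(truth$tables$p1, 1, seed = i)[[1]]),
    lapply(1:150, function(i) sample_genotypes(truth$tables$p2, 1, seed = 1000 + i)[[1]])
  ))
  # fix ids/populations after the single-draw trick
  csv <- tempfile(fileext = ".csv")
  df <- as.data.frame(gs)
  df$id <- sprintf("D%04d", seq_len(nrow(df)))
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)

  out <- file.path(tempdir(), "est1")
  res <- run_frequency_estimation(csv, out_dir = out)
  expect_setequal(names(res$tables), c("p1", "p2"))
  expect_true(file.exists(file.path(out, "p1_freqs.csv")))
  expect_true(file.exists(file.path(out, "p2_freqs.csv")))
  expect_true(file.exists(file.path(out, "em_diagnostics.json")))
  expect_true(all(res$diagnostics$converged))

  # reruns are byte-identical
  out2 <- file.path(tempdir(), "est2")
  run_frequency_estimation(csv, out_dir = out2)
  expect_identical(readLines(file.path(out, "p1_freqs.csv")),
                   readLines(file.path(out2, "p1_freqs.csv")))
})

test_that("the locus-elimination study holds its directional properties end to end", {
  res <- run_locus_elimination_study(seed = 7, scenario = small_scenario(101),
                                     n_donors_typed = 600)
  rep <- res$report
  expect_equal(sort(rep$population), c("majority", "minority"))
  p88 <- rep$p_8of8
  expect_lt(p88[rep$population == "minority"], p88[rep$population == "majority"])
  for (l in hla_loci()) {
    expect_true(all(rep[[sprintf("gain_6of6_drop%s", l)]] > 0))
    expect_true(all(rep[[sprintf("p_5of6_drop%s", l)]] >=
                    rep[[sprintf("p_6of6_drop%s", l)]] - 1e-9))
    expect_true(all(rep[[sprintf("p_5of6_drop%s", l)]] >= rep$p_7of8 - 1e-9))
  }
  expect_true(all(res$em_diagnostics$converged))
})

test_that("study runs are reproducible byte for byte", {
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  run_locus_elimination_study(seed = 11, scenario = small_scenario(102),
                              n_donors_typed = 400, out_dir = d1)
  run_locus_elimination_study(seed = 11, scenario = small_scenario(102),
                              n_donors_typed = 400, out_dir = d2)
  expect_identical(readLines(file.path(d1, "locus_drop_estimated.tsv")),
                   readLines(file.path(d2, "locus_drop_estimated.tsv")))
  expect_identical(readLines(file.path(d1, "locus_drop_truth.tsv")),
                   readLines(file.path(d2, "locus_drop_truth.tsv")))
})

test_that("likelihoods from EM-estimated tables track the ground-truth tables", {
  res <- run_locus_elimination_study(
    seed = 101,
    scenario = minority_scenario(seed = 101,
                                 donors = c(majority = 6000, minority = 600),
                                 availability = c(majority = 0.6, minority = 0.3),
                                 alleles_per_locus = 5L,
                                 n_haplotypes = c(15L, 20L),
                                 overlap = c(0.9, 0.1)),
    n_donors_typed = 4000)
  expect_lt(res$max_abs_error, 0.02)
})

test_that("a violated scenario property is reported as an error", {
  # swapping the population labels breaks the minority-below-majority check
  sc <- small_scenario(103)
  names(sc$truth$tables) <- rev(names(sc$truth$tables))
  for (k in seq_along(sc$truth$tables)) {
    sc$truth$tables[[k]]$population <- names(sc$truth$tables)[k]
  }
  sc$registry <- hla_registry(list(
    list(label = "majority", table = sc$truth$tables$majority,
         donors = 300, availability = 0.3),
    list(label = "minority", table = sc$truth$tables$minority,
         donors = 2000, availability = 0.6)))
  expect_error(run_locus_elimination_study(seed = 5, scenario = sc,
                                           n_donors_typed = 400),
               "minority")
})
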