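#' Construct a multi-population donor registry
#'
#' A registry is a list of populations, each carrying its haplotype
#' frequency table, the number of registered donors, and the fraction of
#' those donors actually available when called (availability rates differ
#' markedly between population groups and discount the nominal registry
#' size). All tables must share one locus set.
#'
#' @param populations list of `list(label =, table =, donors =,
#'   availability =)` entries; `table` a `hap_freq_table`, `donors` a
#'   non-negative count, `availability` in `[0, 1]`.
#' @return An object of class `hla_registry`; populations are addressable by
#'   label.
#' @export
hla_registry <- function(populations) {
  stopifnot(is.list(populations), length(populations) > 0L)
  labels <- vapply(populations, function(p) as.character(p$label), character(1))
  if (anyDuplicated(labels)) stop("population labels must be unique", call. = FALSE)
  loci <- populations[[1L]]$table$loci
  pops <- lapply(populations, function(p) {
    stopifnot(inherits(p$table, "hap_freq_table"))
    if (!identical(p$table$loci, loci)) stop("all tables must share one locus set", call. = FALSE)
    donors <- as.numeric(p$donors)
    avail <- as.numeric(p$availability)
    if (is.na(donors) || donors < 0) stop("donor count must be non-negative", call. = FALSE)
    if (is.na(avail) || avail < 0 || avail > 1) stop("availability must be in [0, 1]", call. = FALSE)
    list(label = as.character(p$label), table = p$table,
         donors = donors, availability = avail)
  })
  names(pops) <- labels
  structure(list(populations = pops, loci = loci), class = "hla_registry")
}

#' @export
print.hla_registry <- function(x, ...) {
  cat(sprintf("HLA donor registry: %d population(s), loci %s\n",
              length(x$populations), paste(x$loci, collapse = "/")))
  for (p in x$populations) {
    cat(sprintf("  %-12s %9.0f donors x availability %.2f = %10.1f effective; %d haplotypes\n",
                p$label, p$donors, p$availability,
                p$donors * p$availability, n_haplotypes(p$table)))
  }
  invisible(x)
}

#' Effective donor counts
#'
#' The effective number of donors per population is the registered count
#' multiplied by that population's availability rate. The product is kept
#' real-valued: the matching model treats registry size as a population-level
#' expectation, not a roster of individuals.
#'
#' @param registry an `hla_registry`.
#' @return Named numeric vector of effective counts.
#' @export
effective_donors <- function(registry) {
  stopifnot(inherits(registry, "hla_registry"))
  vapply(registry$populations, function(p) p$donors * p$availability, numeric(1))
}

#' Registry-wide likelihood of finding at least one matched donor
#'
#' Averages, over the patient population's Hardy-Weinberg genotype
#' distribution, the probability that a registry with effective population
#' sizes `N_k` contains at least one donor within the stringency's mismatch
#' budget:
#' \deqn{P = \sum_g P(g) \left[1 - \prod_k (1 - q_k(g))^{N_k}\right]}
#' where `q_k(g)` is the per-donor match probability in population `k`.
#' Donors of every population count toward every patient's search. The
#' survival factor is evaluated as `exp(N_k * log1p(-q))` for numerical
#' stability at tiny `q` and large `N_k`.
#'
#' Exact mode enumerates the patient genotype map (feasible while the
#' haplotype-pair count stays within `cap`); Monte Carlo mode samples
#' patient genotypes (two i.i.d. haplotypes from the patient table) and
#' averages the bracketed term, reporting the standard error of the mean.
#'
#' @param registry an `hla_registry`.
#' @param patient_population label of the patient's population (must be in
#'   the registry).
#' @param stringency a [match_stringency] or preset string.
#' @param method `"exact"` (default) or `"monte_carlo"`.
#' @param n_samples Monte Carlo sample count (default `1e5`, minimum 100).
#' @param seed integer seed; mandatory for Monte Carlo.
#' @param cap cap on exact genotype enumeration (haplotype pairs).
#' @return An object of class `match_likelihood_result` with fields
#'   `patient_population`, `stringency`, `likelihood`, `method`, and for
#'   Monte Carlo runs `n_samples`, `seed`, `standard_error`.
#' @export
registry_match_likelihood <- function(registry, patient_population, stringency,
                                      method = c("exact", "monte_carlo"),
                                      n_samples = 1e5, seed = NULL, cap = 2e6) {
  stopifnot(inherits(registry, "hla_registry"))
  method <- match.arg(method)
  if (!patient_population %in% names(registry$populations)) {
    stop(sprintf("patient population '%s' not present in registry", patient_population), call. = FALSE)
  }
  st <- as_match_stringency(stringency, loci = registry$loci)
  budget <- st$allowed_mismatches
  pt <- registry$populations[[patient_population]]$table

  if (method == "exact") {
    pm <- build_genotype_probability_map(pt, st$considered_loci, cap = cap)
    pa1 <- pm$a1; pa2 <- pm$a2
    weights <- pm$prob
  } else {
    if (n_samples < 100) stop("monte_carlo requires n_samples >= 100", call. = FALSE)
    if (is.null(seed)) stop("monte_carlo requires a seed", call. = FALSE)
    H <- n_haplotypes(pt)
    idx <- withr::with_seed(as.integer(seed), {
      cbind(sample.int(H, n_samples, replace = TRUE, prob = pt$freq),
            sample.int(H, n_samples, replace = TRUE, prob = pt$freq))
    })
    hm <- pt$haplotypes[, st$considered_loci, drop = FALSE]
    s1 <- hm[idx[, 1L], , drop = FALSE]
    s2 <- hm[idx[, 2L], , drop = FALSE]
    a1 <- pmin(s1, s2)
    a2 <- pmax(s1, s2)
    key <- geno_keys(a1, a2)
    u <- !duplicated(key)
    cnt <- tabulate(match(key, key[u]), nbins = sum(u))
    pa1 <- a1[u, , drop = FALSE]
    pa2 <- a2[u, , drop = FALSE]
    weights <- cnt / n_samples
  }

  log_surv <- numeric(nrow(pa1))
  for (p in registry$populations) {
    Nk <- p$donors * p$availability
    if (Nk == 0) next
    dm <- build_genotype_probability_map(p$table, st$considered_loci, cap = cap)
    q <- match_prob_vector(dm, pa1, pa2, budget)
    contrib <- ifelse(q >= 1, -Inf, Nk * log1p(-q))
    log_surv <- log_surv + contrib
  }
  bracket <- -expm1(log_surv)               # 1 - prod_k (1 - q_k)^{N_k}
  lik <- sum(weights * bracket)

  res <- list(patient_population = patient_population,
              stringency = st$label,
              likelihood = min(max(lik, 0), 1),
              method = method)
  if (method == "monte_carlo") {
    n <- n_samples
    v <- sum(weights * (bracket - lik)^2) * n / max(n - 1, 1)
    res$n_samples <- as.integer(n)
    res$seed <- as.integer(seed)
    res$standard_error <- sqrt(v / n)
  }
  structure(res, class = "match_likelihood_result")
}

#' @export
print.match_likelihood_result <- function(x, ...) {
  cat(sprintf("Match likelihood [%s, %s]: %.6f (%s%s)\n",
              x$patient_population, x$stringency, x$likelihood, x$method,
              if (x$method == "monte_carlo")
                sprintf(", n = %d, se = %.2g, seed = %d",
                        x$n_samples, x$standard_error, x$seed) else ""))
  invisible(x)
}

#' Locus-elimination match-likelihood report
#'
#' For each requested patient population, computes the baseline 8/8 and 7/8
#' match likelihoods over the full locus set, then — removing one locus at a
#' time from mathematical consideration — the analogous 6/6 and 5/6
#' likelihoods, together with the absolute gains over the corresponding
#' baselines. Any donor matching at a stricter criterion also matches at the
#' looser one, so every 6/6 value is at least the 8/8 value and every 5/6
#' value at least both its 6/6 and the 7/8 value.
#'
#' Column names are generated from the allele denominators, e.g.
#' `p_8of8`, `p_7of8`, `p_6of6_dropA`, `gain_6of6_dropA`, `p_5of6_dropA`,
#' `gain_5of6_dropA` for the four-locus set.
#'
#' @param registry an `hla_registry`.
#' @param patient_populations labels to report on (default: all).
#' @param method,n_samples,seed,cap passed to
#'   [registry_match_likelihood()].
#' @return A data frame with one row per patient population, with a
#'   `metadata` attribute recording method, seed, and package version.
#' @export
locus_drop_report <- function(registry, patient_populations = NULL,
                              method = "exact", n_samples = 1e5,
                              seed = NULL, cap = 2e6) {
  stopifnot(inherits(registry, "hla_registry"))
  patient_populations <- patient_populations %||% names(registry$populations)
  loci <- registry$loci
  M <- 2L * length(loci)
  K <- 2L * (length(loci) - 1L)
  lik <- function(pop, strg) {
    registry_match_likelihood(registry, pop, strg, method = method,
                              n_samples = n_samples, seed = seed, cap = cap)$likelihood
  }
  rows <- lapply(patient_populations, function(pop) {
    row <- list(population = pop)
    base_full <- lik(pop, sprintf("%d/%d", M, M))
    base_one <- lik(pop, sprintf("%d/%d", M - 1L, M))
    row[[sprintf("p_%dof%d", M, M)]] <- base_full
    row[[sprintf("p_%dof%d", M - 1L, M)]] <- base_one
    for (l in loci) {
      p66 <- lik(pop, sprintf("%d/%d:%s", K, K, l))
      p56 <- lik(pop, sprintf("%d/%d:%s", K - 1L, K, l))
      row[[sprintf("p_%dof%d_drop%s", K, K, l)]] <- p66
      row[[sprintf("gain_%dof%d_drop%s", K, K, l)]] <- p66 - base_full
      row[[sprintf("p_%dof%d_drop%s", K - 1L, K, l)]] <- p56
      row[[sprintf("gain_%dof%d_drop%s", K - 1L, K, l)]] <- p56 - base_one
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "metadata") <- list(
    version = pkg_version_string(),
    loci = loci, method = method,
    n_samples = if (method == "monte_carlo") n_samples else NA,
    seed = seed %||% NA,
    effective_donors = as.list(effective_donors(registry))
  )
  out
}

#' Write a locus-elimination report as TSV with embedded metadata
#'
#' Likelihood and gain columns are printed with six decimal places; the
#' run's configuration (package version, method, seed, effective donor
#' counts) is embedded as `#`-prefixed header lines.
#'
#' @param report output of [locus_drop_report()].
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_locus_drop_report <- function(report, path) {
  meta <- attr(report, "metadata")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) paste(format(unlist(v)), collapse = ","), character(1))),
               con)
  }
  fmt <- report
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) sprintf("%.6f", v))
  utils::write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write registry configuration files
#'
#' A registry configuration is a JSON or YAML document with a `populations`
#' list whose entries carry `label`, `frequency_table` (path to a
#' [write_freq_table()] file, resolved relative to the configuration file),
#' `donors` and `availability`.
#'
#' @param path configuration file (`.json`, `.yaml`/`.yml`).
#' @return An `hla_registry`.
#' @export
read_registry_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(cfg$populations)) stop("registry config must have a 'populations' list", call. = FALSE)
  base <- dirname(path)
  pops <- lapply(cfg$populations, function(p) {
    tp <- p$frequency_table
    if (!file.exists(tp)) tp <- file.path(base, tp)
    tab <- read_freq_table(tp)
    if (!inherits(tab, "hap_freq_table")) tab <- tab[[p$label]]
    list(label = p$label, table = tab, donors = p$donors, availability = p$availability)
  })
  hla_registry(pops)
}

#' @rdname read_registry_config
#' @param registry an `hla_registry` to serialize.
#' @param dir output directory; receives `registry.json` and one
#'   `<label>_freqs.csv` per population.
#' @return Path to the written configuration file, invisibly.
#' @export
write_registry_config <- function(registry, dir) {
  stopifnot(inherits(registry, "hla_registry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pops <- lapply(registry$populations, function(p) {
    fn <- sprintf("%s_freqs.csv", gsub("[^A-Za-z0-9_.-]", "_", p$label))
    write_freq_table(p$table, file.path(dir, fn))
    list(label = p$label, frequency_table = fn,
         donors = p$donors, availability = p$availability)
  })
  cfg_path <- file.path(dir, "registry.json")
  jsonlite::write_json(list(version = pkg_version_string(),
                            populations = unname(pops)),
                       cfg_path, digits = NA, auto_unbox = TRUE)
  invisible(cfg_path)
}
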