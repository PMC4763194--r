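#' Construct a haplotype frequency table
#'
#' A haplotype frequency table is the central object of the registry matching
#' model: for one population it assigns a frequency to each multi-locus
#' haplotype (one allele per locus on one chromosome). Linkage disequilibrium
#' is implicit — frequencies live at the haplotype level and are not products
#' of per-locus allele frequencies.
#'
#' @param haplotypes character matrix (or data frame) with one row per
#'   haplotype and one named column per locus.
#' @param freq numeric vector of frequencies, one per row; non-negative and
#'   summing to 1 within `tol` (unless `normalize = TRUE`).
#' @param population population label.
#' @param normalize if `TRUE`, rescale `freq` to sum to exactly 1.
#' @param tol tolerance on the frequency total (default `1e-9`).
#' @return An object of class `hap_freq_table` with fields `haplotypes`,
#'   `freq`, `loci`, `population`.
#' @export
hap_freq_table <- function(haplotypes, freq, population = NA_character_,
                           normalize = FALSE, tol = 1e-9) {
  if (is.data.frame(haplotypes)) haplotypes <- as.matrix(haplotypes)
  if (!is.matrix(haplotypes) || !is.character(haplotypes)) {
    stop("'haplotypes' must be a character matrix with one column per locus", call. = FALSE)
  }
  loci <- colnames(haplotypes)
  assert_loci(loci)
  if (nrow(haplotypes) == 0L) stop("frequency table must contain at least one haplotype", call. = FALSE)
  if (length(freq) != nrow(haplotypes)) stop("'freq' length must match haplotype count", call. = FALSE)
  if (anyNA(freq) || any(freq < 0)) stop("frequencies must be non-negative and non-missing", call. = FALSE)
  if (anyDuplicated(hap_keys(haplotypes))) stop("duplicate haplotypes in frequency table", call. = FALSE)
  s <- sum(freq)
  if (normalize) {
    if (s <= 0) stop("cannot normalize: total frequency is zero", call. = FALSE)
    freq <- freq / s
  } else if (abs(s - 1) > tol) {
    stop(sprintf("frequencies sum to %.12g, not 1 (tolerance %g)", s, tol), call. = FALSE)
  }
  structure(
    list(haplotypes = haplotypes, freq = as.numeric(freq),
         loci = loci, population = as.character(population)),
    class = "hap_freq_table"
  )
}

#' @export
print.hap_freq_table <- function(x, n = 5L, ...) {
  cat(sprintf("Haplotype frequency table [%s]: %d haplotypes over loci %s\n",
              x$population, nrow(x$haplotypes), paste(x$loci, collapse = "/")))
  ord <- order(x$freq, decreasing = TRUE)
  show <- head(ord, n)
  for (i in show) {
    cat(sprintf("  %-40s %.6f\n",
                paste(x$haplotypes[i, ], collapse = "~"), x$freq[i]))
  }
  if (length(ord) > n) cat(sprintf("  ... and %d more\n", length(ord) - n))
  invisible(x)
}

#' Number of haplotypes in a frequency table
#' @param table a `hap_freq_table`.
#' @return Integer count.
#' @export
n_haplotypes <- function(table) nrow(table$haplotypes)

#' Marginalize a haplotype frequency table over one locus
#'
#' Removing a locus from matching consideration corresponds to summing the
#' haplotype distribution over that locus's alleles: every group of
#' haplotypes identical at the remaining loci is merged and its frequencies
#' added, preserving total mass. Three-locus B/C/DRB1 frequencies, for
#' example, arise from the four-locus table by summing over HLA-A.
#'
#' @param table a `hap_freq_table`.
#' @param drop_locus name of the locus to remove (must leave at least one).
#' @return A `hap_freq_table` over the remaining loci.
#' @export
marginalize <- function(table, drop_locus) {
  stopifnot(inherits(table, "hap_freq_table"))
  if (length(drop_locus) != 1L || !drop_locus %in% table$loci) {
    stop(sprintf("unknown locus '%s'", paste(drop_locus, collapse = ",")), call. = FALSE)
  }
  keep <- setdiff(table$loci, drop_locus)
  if (length(keep) == 0L) stop("cannot marginalize away the last locus", call. = FALSE)
  hm <- table$haplotypes[, keep, drop = FALSE]
  key <- hap_keys(hm)
  agg <- rowsum(table$freq, key)
  first <- !duplicated(key)
  reps <- hm[first, , drop = FALSE]
  f <- agg[match(key[first], rownames(agg)), 1L]
  hap_freq_table(reps, f, population = table$population, tol = 1e-6)
}

#' Drop negligible haplotypes and renormalize
#'
#' Frequencies far below `1 / (2 n)` for a typed sample of size `n` are
#' sampling noise rather than signal; truncating them keeps downstream
#' genotype enumeration tractable. The remaining frequencies are rescaled to
#' sum to 1.
#'
#' @param table a `hap_freq_table`.
#' @param min_freq threshold; haplotypes with frequency strictly below it are
#'   removed.
#' @return A `hap_freq_table`.
#' @export
prune_freq_table <- function(table, min_freq) {
  stopifnot(inherits(table, "hap_freq_table"), min_freq >= 0)
  keep <- table$freq >= min_freq
  if (!any(keep)) stop("pruning threshold removes every haplotype", call. = FALSE)
  hap_freq_table(table$haplotypes[keep, , drop = FALSE], table$freq[keep],
                 population = table$population, normalize = TRUE)
}

#' Write haplotype frequency tables to CSV or JSON
#'
#' The CSV layout has columns `population`, one column per locus, and
#' `frequency`; several populations may share one file. Frequencies are
#' written with 17 significant digits so that read/write round trips are
#' lossless for double precision. A `.json` extension selects an equivalent
#' JSON layout.
#'
#' @param x a `hap_freq_table` or a list of them (sharing one locus set).
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(x, path) {
  tabs <- if (inherits(x, "hap_freq_table")) list(x) else x
  stopifnot(length(tabs) > 0L, all(vapply(tabs, inherits, logical(1), "hap_freq_table")))
  loci <- tabs[[1L]]$loci
  for (t in tabs) stopifnot(identical(t$loci, loci))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    payload <- list(
      loci = loci,
      populations = lapply(unname(tabs), function(t) {
        list(population = t$population,
             haplotypes = unname(t$haplotypes),
             frequency = t$freq)
      })
    )
    jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  } else {
    rows <- lapply(tabs, function(t) {
      df <- data.frame(population = t$population, stringsAsFactors = FALSE)
      df <- cbind(df, as.data.frame(t$haplotypes, stringsAsFactors = FALSE))
      df$frequency <- sprintf("%.17g", t$freq)
      df
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read haplotype frequency tables written by [write_freq_table()]
#'
#' @param path `.csv` or `.json` file.
#' @return A single `hap_freq_table` if the file holds one population,
#'   otherwise a named list of tables.
#' @export
read_freq_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    loci <- payload$loci
    pops <- payload$populations
    tabs <- lapply(seq_len(nrow(pops)), function(i) {
      hm <- pops$haplotypes[[i]]
      if (!is.matrix(hm)) hm <- matrix(hm, nrow = 1L)
      colnames(hm) <- loci
      hap_freq_table(hm, pops$frequency[[i]], population = pops$population[[i]])
    })
    names(tabs) <- pops$population
  } else {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    need <- c("population", "frequency")
    if (!all(need %in% names(df))) {
      stop(sprintf("frequency table '%s' must have 'population' and 'frequency' columns", path),
           call. = FALSE)
    }
    loci <- setdiff(names(df), need)
    assert_loci(loci)
    freq <- as.numeric(df$frequency)
    tabs <- lapply(split(seq_len(nrow(df)), df$population), function(idx) {
      hm <- as.matrix(df[idx, loci, drop = FALSE])
      dimnames(hm) <- list(NULL, loci)
      hap_freq_table(hm, freq[idx], population = df$population[idx[1L]])
    })
  }
  if (length(tabs) == 1L) tabs[[1L]] else tabs
}

#' Total variation distance between two frequency tables
#'
#' Half the L1 distance between the two distributions over the union of
#' their haplotype supports; 0 for identical tables, 1 for disjoint ones.
#' Used to score how well EM estimates recover a known truth.
#'
#' @param a,b `hap_freq_table` objects over the same loci.
#' @return A number in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  stopifnot(inherits(a, "hap_freq_table"), inherits(b, "hap_freq_table"),
            identical(a$loci, b$loci))
  ka <- hap_keys(a$haplotypes)
  kb <- hap_keys(b$haplotypes)
  keys <- union(ka, kb)
  fa <- a$freq[match(keys, ka)]
  fb <- b$freq[match(keys, kb)]
  fa[is.na(fa)] <- 0
  fb[is.na(fb)] <- 0
  sum(abs(fa - fb)) / 2
}
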