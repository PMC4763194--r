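#' Canonical HLA locus set for adult unrelated-donor matching
#'
#' Adult unrelated-donor searches assess allele-level matching at the class I
#' loci HLA-A, -B, -C and the class II locus HLA-DRB1; two alleles at each of
#' the four loci give the "8/8" match denominator. The order returned here is
#' the canonical column order used by every haplotype and genotype container
#' in the package.
#'
#' @return Character vector `c("A", "B", "C", "DRB1")`.
#' @export
hla_loci <- function() c("A", "B", "C", "DRB1")

assert_loci <- function(loci) {
  if (!is.character(loci) || length(loci) == 0L || anyNA(loci)) {
    stop("locus set must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(loci)) {
    stop("locus names must be unique", call. = FALSE)
  }
  invisible(loci)
}

#' Construct an unphased multi-locus genotype
#'
#' An unphased genotype records, for each locus, the unordered pair of allele
#' codes an individual carries, with no information about which alleles share
#' a chromosome. Homozygotes carry the same code twice. Pairs are stored in
#' canonical (sorted) order so genotypes that differ only in allele listing
#' order compare equal. Allele codes are opaque strings; no HLA nomenclature
#' parsing is attempted, and missing/untyped alleles are rejected.
#'
#' @param pairs either a 2-row character matrix with one named column per
#'   locus, or a named list of length-2 character vectors.
#' @param population optional population label.
#' @param id optional identifier.
#' @return An object of class `unphased_genotype` with fields `pairs`
#'   (canonical 2 x L character matrix), `loci`, `population`, `id`.
#' @examples
#' g <- unphased_genotype(list(A = c("A*02", "A*01"), B = c("B*07", "B*07")))
#' g$pairs
#' @export
unphased_genotype <- function(pairs, population = NA_character_, id = NA_character_) {
  if (is.list(pairs)) {
    nm <- names(pairs)
    pairs <- vapply(pairs, function(p) as.character(p), character(2L))
    colnames(pairs) <- nm
  }
  if (!is.matrix(pairs) || nrow(pairs) != 2L) {
    stop("'pairs' must be a 2-row matrix or a list of length-2 allele vectors", call. = FALSE)
  }
  loci <- colnames(pairs)
  assert_loci(loci)
  if (anyNA(pairs) || any(pairs == "")) {
    stop("genotype has a missing allele code; untyped loci are not supported", call. = FALSE)
  }
  pairs <- apply(pairs, 2L, sort)
  structure(
    list(pairs = pairs, loci = loci, population = population, id = id),
    class = "unphased_genotype"
  )
}

#' @export
print.unphased_genotype <- function(x, ...) {
  cat("Unphased genotype", if (!is.na(x$id)) paste0("'", x$id, "'") else "",
      if (!is.na(x$population)) paste0("[", x$population, "]") else "", "\n")
  cat(paste(sprintf("%s: %s/%s", x$loci, x$pairs[1L, ], x$pairs[2L, ]),
            collapse = "  "), "\n")
  invisible(x)
}

# Compact column-parallel container for many genotypes: a1/a2 are n x L
# character matrices holding the canonical (sorted) allele pair per locus.
new_genotype_set <- function(a1, a2, loci, population, id) {
  stopifnot(is.matrix(a1), is.matrix(a2), all(dim(a1) == dim(a2)))
  colnames(a1) <- loci
  colnames(a2) <- loci
  sw <- a1 > a2
  if (any(sw)) {
    tmp <- a1[sw]
    a1[sw] <- a2[sw]
    a2[sw] <- tmp
  }
  structure(
    list(a1 = a1, a2 = a2, loci = loci,
         population = as.character(population), id = as.character(id)),
    class = "genotype_set"
  )
}

#' Coerce to a genotype set
#'
#' @param x a `genotype_set`, a single `unphased_genotype`, or a list of
#'   `unphased_genotype` objects sharing one locus set.
#' @return A `genotype_set`.
#' @export
as_genotype_set <- function(x) {
  if (inherits(x, "genotype_set")) return(x)
  if (inherits(x, "unphased_genotype")) x <- list(x)
  if (!is.list(x) || length(x) == 0L ||
      !all(vapply(x, inherits, logical(1), "unphased_genotype"))) {
    stop("cannot coerce to genotype_set: need unphased_genotype objects", call. = FALSE)
  }
  loci <- x[[1L]]$loci
  for (g in x) {
    if (!identical(g$loci, loci)) stop("genotypes have differing locus sets", call. = FALSE)
  }
  a1 <- do.call(rbind, lapply(x, function(g) g$pairs[1L, ]))
  a2 <- do.call(rbind, lapply(x, function(g) g$pairs[2L, ]))
  new_genotype_set(a1, a2, loci,
                   vapply(x, function(g) g$population, character(1)),
                   vapply(x, function(g) g$id, character(1)))
}

#' @export
length.genotype_set <- function(x) nrow(x$a1)

#' @export
`[.genotype_set` <- function(x, i, ...) {
  new_genotype_set(x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                   x$loci, x$population[i], x$id[i])
}

#' @export
`[[.genotype_set` <- function(x, i) {
  pairs <- rbind(x$a1[i, ], x$a2[i, ])
  colnames(pairs) <- x$loci
  unphased_genotype(pairs, population = x$population[i], id = x$id[i])
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("Genotype set: %d genotypes, loci %s\n",
              length(x), paste(x$loci, collapse = "/")))
  pops <- table(x$population, useNA = "ifany")
  cat("  populations:", paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.genotype_set <- function(x, ...) {
  df <- data.frame(id = x$id, population = x$population, stringsAsFactors = FALSE)
  for (l in x$loci) {
    df[[paste0(l, "_1")]] <- x$a1[, l]
    df[[paste0(l, "_2")]] <- x$a2[, l]
  }
  df
}

#' Read a genotype table from CSV
#'
#' The expected format is one data row per typed individual with mandatory
#' header columns `id`, `population`, then `<locus>_1`, `<locus>_2` for each
#' locus. Allele pairs are canonicalized on input (pair order in the file is
#' irrelevant). Missing typings are not supported: an empty allele cell is an
#' error naming the offending row, as is a duplicated id or a missing column.
#'
#' @param path path to a UTF-8 comma-separated file with header.
#' @param loci locus set the table must cover (default [hla_loci()]).
#' @return A `genotype_set` preserving row order.
#' @export
parse_genotype_table <- function(path, loci = hla_loci()) {
  assert_loci(loci)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("id", "population", paste0(rep(loci, each = 2L), c("_1", "_2")))
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop(sprintf("genotype table '%s' is missing required column(s): %s",
                 path, paste(absent, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop(sprintf("genotype table '%s' contains no data rows", path), call. = FALSE)
  }
  allele_cols <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  am <- as.matrix(df[allele_cols])
  bad <- which(is.na(am) | am == "", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    r <- bad[1L, 1L]
    stop(sprintf("row id '%s': empty allele cell in column '%s' (missing typing not supported)",
                 df$id[r], allele_cols[bad[1L, 2L]]), call. = FALSE)
  }
  dup <- duplicated(df$id)
  if (any(dup)) {
    stop(sprintf("duplicate genotype id '%s'", df$id[which(dup)[1L]]), call. = FALSE)
  }
  a1 <- as.matrix(df[paste0(loci, "_1")])
  a2 <- as.matrix(df[paste0(loci, "_2")])
  new_genotype_set(a1, a2, loci, df$population, df$id)
}

#' Write a genotype table to CSV
#'
#' Inverse of [parse_genotype_table()].
#'
#' @param genotypes a `genotype_set` (or coercible).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  gs <- as_genotype_set(genotypes)
  utils::write.csv(as.data.frame(gs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Multiset intersection size of two unordered allele pairs. Equivalent to the
# maximum bipartite matching between {p1,p2} and {d1,d2}; works whether or not
# the pairs are canonically sorted. Vectorized over all arguments.
pair_intersection <- function(p1, p2, d1, d2) {
  pmax((p1 == d1) + (p2 == d2), (p1 == d2) + (p2 == d1))
}

#' Count allele mismatches between two genotypes
#'
#' The per-locus mismatch is `2 - |multiset intersection|` of the two allele
#' pairs, so a homozygote `x/x` against a heterozygote `x/y` counts one
#' mismatch, and the total over the four classical loci ranges 0..8. This is
#' the quantity thresholded by the match stringencies: one total allele
#' mismatch at any considered locus is a 7/8 (or 5/6) match.
#'
#' @param g1,g2 `unphased_genotype` objects.
#' @param loci loci to consider: a character vector or a
#'   [match_stringency] (whose considered loci are used). Default: all loci
#'   of `g1`.
#' @return Non-negative integer mismatch count; symmetric in `g1`, `g2`.
#' @export
mismatch_count <- function(g1, g2, loci = NULL) {
  if (inherits(loci, "match_stringency")) loci <- loci$considered_loci
  loci <- loci %||% g1$loci
  missing1 <- setdiff(loci, g1$loci)
  missing2 <- setdiff(loci, g2$loci)
  if (length(missing1) || length(missing2)) {
    stop(sprintf("locus '%s' absent from a genotype",
                 c(missing1, missing2)[1L]), call. = FALSE)
  }
  p <- g1$pairs[, loci, drop = FALSE]
  d <- g2$pairs[, loci, drop = FALSE]
  isec <- pair_intersection(p[1L, ], p[2L, ], d[1L, ], d[2L, ])
  as.integer(sum(2L - isec))
}

#' Construct a match stringency
#'
#' A stringency is the set of loci a donor search considers together with the
#' total allele-mismatch budget tolerated across them. The clinical presets
#' are 8/8 (all four loci, zero mismatches), 7/8 (one allele mismatch at any
#' of the four loci), and — once one locus is removed from consideration —
#' the analogous 6/6 and 5/6 criteria over the remaining three loci.
#'
#' @param considered_loci non-empty character vector of loci.
#' @param allowed_mismatches non-negative integer, at most `2 * length(considered_loci)`.
#' @param label optional display label.
#' @return An object of class `match_stringency`.
#' @seealso [stringency()] for the `"8/8"`, `"7/8"`, `"6/6:A"`, `"5/6:A"`
#'   string shorthand.
#' @export
match_stringency <- function(considered_loci, allowed_mismatches, label = NULL) {
  assert_loci(considered_loci)
  allowed_mismatches <- as.integer(allowed_mismatches)
  if (is.na(allowed_mismatches) || allowed_mismatches < 0L ||
      allowed_mismatches > 2L * length(considered_loci)) {
    stop("allowed_mismatches must be in [0, 2 * number of considered loci]", call. = FALSE)
  }
  label <- label %||% sprintf("%d/%d over %s",
                              2L * length(considered_loci) - allowed_mismatches,
                              2L * length(considered_loci),
                              paste(considered_loci, collapse = "/"))
  structure(
    list(considered_loci = considered_loci,
         allowed_mismatches = allowed_mismatches,
         label = label),
    class = "match_stringency"
  )
}

#' Parse a stringency preset string
#'
#' Accepts `"k/m"` (all loci considered, `m = 2 * length(loci)` alleles,
#' `m - k` mismatches allowed) and `"k/m:L"` (locus `L` removed from
#' consideration, `m = 2 * (length(loci) - 1)`). With the default four-locus
#' set this yields the presets `"8/8"`, `"7/8"`, `"6/6:A"`, `"5/6:DRB1"`, etc.
#'
#' @param x preset string, or an existing `match_stringency` (returned as is).
#' @param loci full locus set the preset refers to.
#' @return A `match_stringency`.
#' @examples
#' stringency("7/8")
#' stringency("5/6:A")
#' @export
stringency <- function(x, loci = hla_loci()) {
  if (inherits(x, "match_stringency")) return(x)
  assert_loci(loci)
  if (!is.character(x) || length(x) != 1L) {
    stop("stringency must be a single string such as \"8/8\" or \"6/6:A\"", call. = FALSE)
  }
  m <- regmatches(x, regexec("^([0-9]+)/([0-9]+)(?::(.+))?$", x, perl = TRUE))[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("cannot parse stringency '%s'", x), call. = FALSE)
  }
  k <- as.integer(m[2L])
  denom <- as.integer(m[3L])
  drop <- if (m[4L] == "") NULL else m[4L]
  considered <- loci
  if (!is.null(drop)) {
    if (!drop %in% loci) {
      stop(sprintf("stringency '%s' drops unknown locus '%s'", x, drop), call. = FALSE)
    }
    considered <- setdiff(loci, drop)
  }
  if (denom != 2L * length(considered)) {
    stop(sprintf("stringency '%s': denominator %d does not fit %d considered loci",
                 x, denom, length(considered)), call. = FALSE)
  }
  if (k > denom || k < 0L) {
    stop(sprintf("stringency '%s': numerator out of range", x), call. = FALSE)
  }
  match_stringency(considered, denom - k, label = x)
}

#' @export
print.match_stringency <- function(x, ...) {
  cat(sprintf("Match stringency '%s': loci %s, <= %d allele mismatch(es)\n",
              x$label, paste(x$considered_loci, collapse = "/"),
              x$allowed_mismatches))
  invisible(x)
}
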