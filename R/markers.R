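#' Detect parental characteristic bands
#'
#' Partitions the band loci of each primer pair into three disjoint sets
#' based on the parents' calls: `paternal_only` (band present in the father,
#' absent in the mother — the male characteristic bands, MF1),
#' `maternal_only` (the female characteristic bands, FF1) and `shared` (band
#' present in both). Loci absent in both parents carry no information about
#' parentage and are excluded, as are loci where either parent's call is
#' missing (reported via a message).
#'
#' @param m a [band_matrix()].
#' @return An object of class `characteristic_bands`: a data frame with one
#'   row per primer and list-columns `paternal_only`, `maternal_only`,
#'   `shared`, plus integer columns `MF1` (= number of paternal-only loci)
#'   and `FF1` (= number of maternal-only loci). Attribute `excluded` lists
#'   loci dropped because a parent call was missing.
#' @examples
#' calls <- rbind(M = c(1, 0, 1), P = c(1, 1, 0), o1 = c(1, 1, 0))
#' colnames(calls) <- c("a", "b", "c")
#' m <- band_matrix(calls, c(a = "p1", b = "p1", c = "p1"), "M", "P")
#' detect_characteristic_bands(m)
#' @export
detect_characteristic_bands <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  mo <- m$calls[m$mother_id, ]
  fa <- m$calls[m$father_id, ]
  classifiable <- !is.na(mo) & !is.na(fa)
  excluded <- colnames(m$calls)[!classifiable]
  if (length(excluded))
    message("excluding ", length(excluded),
            " locus/loci with missing parent call: ",
            paste(excluded, collapse = ", "))
  loci <- colnames(m$calls)
  primers <- unique(m$primer_map)
  rows <- lapply(primers, function(p) {
    in_p <- classifiable & m$primer_map == p
    pat <- loci[in_p & fa == 1L & mo == 0L]
    mat <- loci[in_p & mo == 1L & fa == 0L]
    sha <- loci[in_p & mo == 1L & fa == 1L]
    data.frame(primer_id = p, MF1 = length(pat), FF1 = length(mat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$paternal_only <- lapply(primers, function(p) {
    in_p <- classifiable & m$primer_map == p
    loci[in_p & fa == 1L & mo == 0L]
  })
  out$maternal_only <- lapply(primers, function(p) {
    in_p <- classifiable & m$primer_map == p
    loci[in_p & mo == 1L & fa == 0L]
  })
  out$shared <- lapply(primers, function(p) {
    in_p <- classifiable & m$primer_map == p
    loci[in_p & mo == 1L & fa == 1L]
  })
  attr(out, "excluded") <- excluded
  class(out) <- c("characteristic_bands", "data.frame")
  out
}

#' @export
print.characteristic_bands <- function(x, ...) {
  cat("characteristic_bands:\n")
  print(data.frame(primer_id = x$primer_id, MF1 = x$MF1, FF1 = x$FF1,
                   shared = vapply(x$shared, length, 0L)), row.names = FALSE)
  invisible(x)
}

#' Classify offspring and compute hybrid purity
#'
#' Applies the standard dominant-marker rule: an offspring carrying at least
#' `min_paternal_bands` paternal characteristic bands (bands present in the
#' male but not the female parent) is a true hybrid; an offspring whose
#' paternal characteristic loci are all scored and all absent shows the
#' female marker type and is called a maternal (self) type; an offspring
#' whose evidence is incomplete (missing calls and too few presences) is
#' unresolved and excluded from the purity denominator.
#'
#' Hybrid purity (\%) = (tested plants - plants with female marker type) /
#' tested plants x 100, where "tested" counts the non-unresolved offspring.
#'
#' @param m a [band_matrix()].
#' @param bands result of [detect_characteristic_bands()] on the same matrix
#'   (computed if omitted).
#' @param min_paternal_bands minimum number of paternal characteristic bands
#'   required to call a true hybrid (default 1).
#' @return An object of class `hybrid_calls`: a list with `calls` (data frame
#'   `individual_id`, `call`, `n_paternal_bands_carried`), `purity`
#'   (percentage), `n_tested`, `false_hybrid_ids`.
#' @export
classify_offspring <- function(m, bands = detect_characteristic_bands(m),
                               min_paternal_bands = 1L) {
  stopifnot(inherits(m, "band_matrix"))
  min_paternal_bands <- check_count(min_paternal_bands, "min_paternal_bands")
  pat_loci <- unlist(bands$paternal_only)
  if (length(pat_loci) == 0L)
    gh_stop("no paternal characteristic bands; classification impossible")
  off <- offspring_ids(m)
  sub <- m$calls[off, pat_loci, drop = FALSE]
  n_carried <- rowSums(sub == 1L, na.rm = TRUE)
  n_scored <- rowSums(!is.na(sub))
  call <- ifelse(n_carried >= min_paternal_bands, "true_hybrid",
                 ifelse(n_scored == length(pat_loci), "maternal_type",
                        "unresolved"))
  tested <- call != "unresolved"
  n_maternal <- sum(call == "maternal_type")
  purity <- 100 * (sum(tested) - n_maternal) / sum(tested)
  structure(
    list(calls = data.frame(individual_id = off, call = call,
                            n_paternal_bands_carried = as.integer(n_carried),
                            stringsAsFactors = FALSE, row.names = NULL),
         purity = purity,
         n_tested = sum(tested),
         false_hybrid_ids = off[call == "maternal_type"]),
    class = "hybrid_calls")
}

#' @export
print.hybrid_calls <- function(x, ...) {
  tab <- table(factor(x$calls$call,
                      levels = c("true_hybrid", "maternal_type", "unresolved")))
  cat(sprintf("hybrid_calls: %d offspring (%s)\n", nrow(x$calls),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  cat(sprintf("  hybrid purity: %.2f%% of %d tested\n", x$purity, x$n_tested))
  invisible(x)
}

#' Per-locus allele frequencies from dominant calls
#'
#' For a dominant biallelic locus, only the band phenotype frequency is
#' observable. Two estimators of the band-allele frequency `p` are offered:
#' `phenotypic` takes `p` as the observed band frequency (treating the
#' phenotype itself as the allele, the convention of band-based diversity
#' summaries), and `hwe_dominant` assumes Hardy-Weinberg proportions and
#' recovers the null-allele frequency as `q = sqrt(freq(absent))`.
#'
#' @param m a [band_matrix()].
#' @param estimator `"phenotypic"` or `"hwe_dominant"`.
#' @param include_parents count the parent rows in the frequencies
#'   (default TRUE).
#' @return Data frame with `locus_id`, `primer_id`, `n` (non-missing calls),
#'   `p`, `q`.
#' @export
allele_frequencies <- function(m, estimator = c("phenotypic", "hwe_dominant"),
                               include_parents = TRUE) {
  stopifnot(inherits(m, "band_matrix"))
  estimator <- match.arg(estimator)
  calls <- m$calls
  if (!include_parents)
    calls <- calls[offspring_ids(m), , drop = FALSE]
  n <- colSums(!is.na(calls))
  if (any(n == 0L))
    gh_stop(sprintf("locus with no non-missing call among the selected individuals: %s",
                    paste(colnames(calls)[n == 0L], collapse = ", ")))
  band_freq <- colSums(calls == 1L, na.rm = TRUE) / n
  if (estimator == "phenotypic") {
    p <- band_freq
  } else {
    q <- sqrt(1 - band_freq)
    p <- 1 - q
  }
  p <- pmin(pmax(p, 0), 1)
  data.frame(locus_id = colnames(calls),
             primer_id = unname(m$primer_map[colnames(calls)]),
             n = as.integer(n), p = unname(p), q = unname(1 - p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dominant-marker diversity statistics
#'
#' Per-locus statistics from the allele frequencies `(p, q)`: observed allele
#' number `na` (2 if the locus is polymorphic, else 1), effective allele
#' number `ne = 1/(p^2 + q^2)`, Nei gene diversity `h = 1 - p^2 - q^2`, and
#' Shannon information index `I = -p ln p - q ln q` (zero-frequency terms
#' contribute 0). Per primer, the statistics are arithmetic means over that
#' primer's loci, `T` is the locus count and `PPB` the percentage of
#' polymorphic loci; the panel-level `Mean` row averages the per-primer
#' means (not pooled loci).
#'
#' For biallelic presence/absence loci `na_mean = 1 + PPB/100` holds exactly,
#' and per locus `h = 1 - 1/ne`.
#'
#' @inheritParams allele_frequencies
#' @return An object of class `diversity_stats`: data frame with one row per
#'   primer plus a final `Mean` row; columns `primer_id`, `na_mean`,
#'   `ne_mean`, `h_mean`, `i_mean`, `T`, `ppb`. The per-locus table is kept
#'   in attribute `per_locus`.
#' @export
diversity_stats <- function(m, estimator = c("phenotypic", "hwe_dominant"),
                            include_parents = TRUE) {
  freq <- allele_frequencies(m, estimator, include_parents)
  p <- freq$p
  q <- freq$q
  poly <- p > 0 & p < 1
  plogp <- function(x) ifelse(x > 0, -x * log(x), 0)
  per_locus <- data.frame(
    locus_id = freq$locus_id, primer_id = freq$primer_id,
    p = p, polymorphic = poly,
    na = ifelse(poly, 2, 1),
    ne = 1 / (p^2 + q^2),
    h = 1 - p^2 - q^2,
    i = plogp(p) + plogp(q),
    stringsAsFactors = FALSE)
  agg <- function(d) data.frame(
    na_mean = mean(d$na), ne_mean = mean(d$ne), h_mean = mean(d$h),
    i_mean = mean(d$i), T = nrow(d), ppb = 100 * mean(d$polymorphic))
  by_primer <- do.call(rbind, lapply(split(per_locus, per_locus$primer_id)
                                     [unique(per_locus$primer_id)], agg))
  out <- cbind(primer_id = unique(per_locus$primer_id), by_primer)
  mean_row <- data.frame(primer_id = "Mean",
                         na_mean = mean(out$na_mean), ne_mean = mean(out$ne_mean),
                         h_mean = mean(out$h_mean), i_mean = mean(out$i_mean),
                         T = mean(out$T), ppb = mean(out$ppb))
  out <- rbind(out, mean_row)
  rownames(out) <- NULL
  attr(out, "per_locus") <- per_locus
  attr(out, "estimator") <- match.arg(estimator)
  class(out) <- c("diversity_stats", "data.frame")
  out
}

#' Genetic similarity matrix from dominant band profiles
#'
#' Pairwise similarity over loci non-missing in both individuals, from the
#' 2x2 band contingency counts `a` (1/1), `b` and `c` (mismatches) and `d`
#' (0/0): simple matching `(a+d)/(a+b+c+d)`, Dice `2a/(2a+b+c)`, Jaccard
#' `a/(a+b+c)`.
#'
#' @param m a [band_matrix()].
#' @param coefficient similarity coefficient; simple matching is the default
#'   (the usual qualitative-data choice in NTSYS-style analyses).
#' @return An object of class `similarity_matrix`: symmetric numeric matrix
#'   with unit diagonal and the coefficient name in attribute `coefficient`.
#' @export
similarity_matrix <- function(m, coefficient = c("simple_matching", "dice", "jaccard")) {
  stopifnot(inherits(m, "band_matrix"))
  coefficient <- match.arg(coefficient)
  x <- m$calls
  pres <- (x == 1L) * 1
  pres[is.na(x)] <- 0
  abs_ <- (x == 0L) * 1
  abs_[is.na(x)] <- 0
  a <- pres %*% t(pres)
  d <- abs_ %*% t(abs_)
  bc <- pres %*% t(abs_) + abs_ %*% t(pres)
  shared <- a + d + bc
  if (any(shared == 0)) {
    idx <- which(shared == 0, arr.ind = TRUE)[1, ]
    gh_stop(sprintf("no shared non-missing locus for pair (%s, %s)",
                    rownames(x)[idx[1]], rownames(x)[idx[2]]))
  }
  s <- switch(coefficient,
              simple_matching = (a + d) / shared,
              dice = ifelse(2 * a + bc > 0, 2 * a / (2 * a + bc), 1),
              jaccard = ifelse(a + bc > 0, a / (a + bc), 1))
  diag(s) <- 1
  dimnames(s) <- list(rownames(x), rownames(x))
  structure(s, coefficient = coefficient,
            mother_id = m$mother_id, father_id = m$father_id,
            class = c("similarity_matrix", "matrix", "array"))
}

#' Summarize a similarity matrix against the parents
#'
#' Reports the progeny-father and progeny-mother similarity ranges (over
#' offspring rows only), the parent-parent similarity, and the overall
#' extreme offspring pairs with their ids.
#'
#' @param s a [similarity_matrix()].
#' @param mother_id,father_id parent ids (defaults taken from `s`).
#' @return A list with elements `progeny_father` and `progeny_mother` (each
#'   min/max with the offspring id attaining it), `parent_parent`, and
#'   `overall` (min/max offspring-offspring pair, when >= 2 offspring).
#' @export
similarity_summary <- function(s, mother_id = attr(s, "mother_id"),
                               father_id = attr(s, "father_id")) {
  ids <- rownames(s)
  if (!all(c(mother_id, father_id) %in% ids))
    gh_stop("parents not present in similarity matrix", class = "gh_input_error")
  off <- setdiff(ids, c(mother_id, father_id))
  rng <- function(v) {
    list(min = unname(min(v)), min_id = names(v)[which.min(v)],
         max = unname(max(v)), max_id = names(v)[which.max(v)])
  }
  out <- list(
    progeny_father = rng(s[off, father_id]),
    progeny_mother = rng(s[off, mother_id]),
    parent_parent = unname(s[mother_id, father_id]))
  if (length(off) >= 2L) {
    sub <- s[off, off, drop = FALSE]
    vals <- sub
    vals[!upper.tri(vals)] <- NA  # keep each unordered pair once, drop diagonal
    low <- which(vals == min(vals, na.rm = TRUE), arr.ind = TRUE)[1, ]
    hig <- which(vals == max(vals, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out$overall <- list(
      min = min(vals, na.rm = TRUE),
      min_pair = sort(c(off[low[1]], off[low[2]])),
      max = max(vals, na.rm = TRUE),
      max_pair = sort(c(off[hig[1]], off[hig[2]])))
  }
  out
}
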