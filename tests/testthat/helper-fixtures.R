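# build a band_matrix from an explicit call matrix; one primer unless mapped
bm <- function(calls, mother_id = "M", father_id = "P", primer_map = NULL) {
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("L%02d", seq_len(ncol(calls)))
  if (is.null(primer_map))
    primer_map <- stats::setNames(rep("p1", ncol(calls)), colnames(calls))
  band_matrix(calls, primer_map, mother_id, father_id)
}

# random 0/1/NA call matrix with parents in rows 1-2
random_bm <- function(n_ind, n_loci, miss = 0, seed = 1) {
  withr::with_seed(seed, {
    calls <- matrix(rbinom(n_ind * n_loci, 1, 0.5), n_ind, n_loci)
    if (miss > 0) calls[runif(n_ind * n_loci) < miss] <- NA
  })
  rownames(calls) <- c("M", "P", sprintf("o%02d", seq_len(n_ind - 2)))
  # guard the validator: no all-missing locus
  for (j in seq_len(n_loci)) if (all(is.na(calls[, j]))) calls[1, j] <- 0L
  bm(calls)
}

# brute-force similarity between two call vectors (independent oracle)
oracle_similarity <- function(x, y, coefficient) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1)
  d <- sum(x == 0 & y == 0)
  switch(coefficient,
         simple_matching = (a + d) / (a + b + c_ + d),
         dice = if (2 * a + b + c_ == 0) 1 else 2 * a / (2 * a + b + c_),
         jaccard = if (a + b + c_ == 0) 1 else a / (a + b + c_))
}

# brute-force characteristic-band sets by per-locus set comprehension
oracle_bands <- function(m) {
  mo <- m$calls[m$mother_id, ]
  fa <- m$calls[m$father_id, ]
  loci <- colnames(m$calls)
  keep <- !is.na(mo) & !is.na(fa)
  list(paternal = sort(loci[keep & fa == 1 & mo == 0]),
       maternal = sort(loci[keep & mo == 1 & fa == 0]),
       shared = sort(loci[keep & mo == 1 & fa == 1]))
}

# a small trait table with exact column means (mean(base) == target)
exact_mean_traits <- function(targets, n = 5) {
  stopifnot(n >= 3)
  cols <- lapply(targets, function(m) m + seq(-1, 1, length.out = n) * 0.1 * max(abs(m), 1))
  df <- data.frame(individual_id = sprintf("pl%02d", seq_len(n)), cols)
  names(df)[-1] <- names(targets)
  df
}

# reference contribution-rate weights used throughout the scoring tests
printed_pca_weights <- function() {
  list(contribution_rates = c(0.3678, 0.1446, 0.1127, 0.0930, 0.0763, 0.0697),
       n_retained = 6L)
}

# 16-row published-style component-score table (plant id, Y1..Y6)
printed_score_table <- function() {
  tab <- rbind(
    c(3.98, 1.93, 2.28, 0.93, -1.84, -0.14),
    c(6.26, -2.07, -2.57, 2.16, -0.71, 0.39),
    c(6.58, -2.14, -5.09, 0.24, 1.14, 1.51),
    c(2.31, 0.93, 1.61, 1.86, 0.36, 1.82),
    c(4.51, -1.09, 0.43, 0.65, -0.61, -1.21),
    c(2.02, 5.17, -2.74, 3.29, -0.56, -1.03),
    c(2.36, 2.89, -1.32, -0.26, -0.34, 3.54),
    c(3.64, -1.38, 1.20, 0.74, -0.68, 0.21),
    c(2.17, 0.55, 1.92, 1.74, -0.03, -1.23),
    c(2.03, 0.99, 0.17, 0.16, 1.74, 0.07),
    c(3.48, -0.80, -1.60, 0.06, 1.42, -0.53),
    c(4.06, 0.75, -1.86, -0.51, -2.03, -2.37),
    c(2.69, -0.63, 1.07, -1.00, -0.19, 1.57),
    c(2.03, 0.39, 1.60, -0.46, 0.30, -0.21),
    c(2.93, -1.71, 0.87, 0.72, -1.32, 0.19),
    c(2.82, -3.05, 1.05, -0.48, -1.14, 1.74))
  dimnames(tab) <- list(c("2", "3", "110", "73", "7", "4", "91", "9", "15",
                          "67", "111", "1", "123", "81", "16", "38"),
                        paste0("Y", 1:6))
  tab
}
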