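#' Standardize a trait matrix
#'
#' Centers each trait to mean 0 and scales to unit sample SD (n-1), the
#' prerequisite for correlation-matrix PCA. Rows with any missing value are
#' dropped (they cannot receive component scores) and recorded in the
#' `dropped` attribute.
#'
#' @param traits trait table as in [normality_report()] (an `individual_id`
#'   column is used for row names if present), or a numeric matrix.
#' @return Numeric matrix with attribute `dropped` (ids of excluded rows),
#'   `center` and `scale`.
#' @export
standardize <- function(traits) {
  df <- as.data.frame(traits)
  ids <- if ("individual_id" %in% names(df)) df$individual_id else rownames(df)
  x <- as.matrix(trait_values(df))
  rownames(x) <- ids
  complete <- stats::complete.cases(x)
  dropped <- ids[!complete]
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 2L)
    gh_stop("standardize needs at least 2 complete rows", class = "gh_input_error")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sample_sd)
  if (any(scl == 0))
    gh_stop(sprintf("constant trait(s) cannot be standardized: %s",
                    paste(colnames(x)[scl == 0], collapse = ", ")))
  out <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  attr(out, "dropped") <- dropped
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Principal component analysis of standardized traits
#'
#' Eigen-decomposition of the sample correlation matrix. The contribution
#' rate of component `i` is `eigenvalue_i / n_traits` (eigenvalues of a
#' correlation matrix sum to the trait count), and components are retained
#' until the cumulative contribution reaches `cumulative_threshold`, or
#' exactly `n_components` when given. Each eigenvector is oriented so its
#' largest-magnitude loading is positive — a convention that makes the
#' result independent of the sign returned by the eigen solver.
#'
#' @param z standardized matrix from [standardize()].
#' @param cumulative_threshold retain the smallest k with cumulative
#'   contribution >= this proportion (default 0.85).
#' @param n_components retain exactly this many components (overrides the
#'   threshold).
#' @return An object of class `pca_result`: list with `eigenvalues`,
#'   `contribution_rates`, `cumulative_rates`, `loadings` (traits x
#'   components, unit-norm columns), `n_retained`, `n_traits`.
#' @export
run_pca <- function(z, cumulative_threshold = 0.85, n_components = NULL) {
  if (nrow(z) < 2L || ncol(z) < 2L)
    gh_stop("run_pca needs at least 2 rows and 2 columns", class = "gh_input_error")
  if (is.null(n_components) &&
      (cumulative_threshold <= 0 || cumulative_threshold > 1))
    gh_stop("cumulative_threshold must be in (0, 1]", class = "gh_input_error")
  r <- stats::cor(z)
  ev <- eigen(r, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  k <- ncol(z)
  contrib <- vals / k
  cum <- cumsum(contrib)
  vecs <- ev$vectors
  for (i in seq_len(k)) {  # orient: largest |loading| positive
    piv <- which.max(abs(vecs[, i]))
    if (vecs[piv, i] < 0) vecs[, i] <- -vecs[, i]
  }
  dimnames(vecs) <- list(colnames(z), paste0("Y", seq_len(k)))
  n_ret <- if (!is.null(n_components)) check_count(n_components, "n_components")
           else which(cum >= cumulative_threshold - 1e-12)[1]
  if (is.na(n_ret) || n_ret > k)
    gh_stop("cannot retain more components than traits", class = "gh_input_error")
  structure(
    list(eigenvalues = vals, contribution_rates = contrib,
         cumulative_rates = cum, loadings = vecs,
         n_retained = n_ret, n_traits = k),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d traits, %d retained components (cumulative %.2f%%)\n",
              x$n_traits, x$n_retained, 100 * x$cumulative_rates[x$n_retained]))
  print(round(rbind(eigenvalue = x$eigenvalues,
                    `contribution (%)` = 100 * x$contribution_rates,
                    `cumulative (%)` = 100 * x$cumulative_rates), 2))
  invisible(x)
}

#' Per-plant principal component scores
#'
#' `Y_i` for each plant is the inner product of its standardized trait row
#' with the i-th unit-norm loading vector, for the retained components.
#'
#' @param z standardized matrix from [standardize()].
#' @param pca a [run_pca()] result fitted on data with the same columns.
#' @return Numeric matrix (plants x retained components) with columns
#'   `Y1..Yk`.
#' @export
component_scores <- function(z, pca) {
  stopifnot(inherits(pca, "pca_result"))
  if (ncol(z) != pca$n_traits ||
      !identical(colnames(z), rownames(pca$loadings)))
    gh_stop("columns of `z` do not match the PCA loadings", class = "gh_input_error")
  z %*% pca$loadings[, seq_len(pca$n_retained), drop = FALSE]
}

#' Contribution-weighted synthesis score
#'
#' The comprehensive score `Z = sum_i(contribution_rate_i * Y_i) /
#' cumulative_rate_k` over the k retained components: a weighted mean of the
#' component scores with the contribution rates as weights, normalized by
#' the retained cumulative contribution so the weights sum to one.
#'
#' @param scores matrix from [component_scores()] (or any matrix/data frame
#'   with one column per retained component).
#' @param pca the matching [run_pca()] result, or a list with elements
#'   `contribution_rates` and `n_retained` (e.g. published contribution
#'   rates, to rescore printed component-score tables).
#' @return Named numeric vector of per-plant Z values.
#' @export
synthesis_score <- function(scores, pca) {
  scores <- as.matrix(scores)
  k <- pca$n_retained %||% ncol(scores)
  w <- pca$contribution_rates[seq_len(k)]
  if (ncol(scores) != k)
    gh_stop(sprintf("`scores` has %d columns but %d components are retained",
                    ncol(scores), k), class = "gh_input_error")
  drop(scores %*% w) / sum(w)
}

#' Rank plants by synthesis score and select backcross-parent candidates
#'
#' Sorts descending by Z with a stable tie-break on plant id, and flags
#' plants with `Z > z_threshold` (strict) as selected.
#'
#' @param z named numeric vector of synthesis scores (names = plant ids).
#' @param z_threshold selection threshold (default 0.80).
#' @param digits Z is reported rounded to this many decimals (default 2);
#'   ranking and selection use the unrounded values.
#' @return Data frame `plant_id`, `Z`, `rank`, `selected`, ordered by rank.
#' @export
rank_and_select <- function(z, z_threshold = 0.80, digits = 2) {
  ids <- names(z) %||% as.character(seq_along(z))
  ord <- order(-z, ids)
  out <- data.frame(plant_id = ids[ord], Z = round(z[ord], digits),
                    rank = seq_along(z), selected = z[ord] > z_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Full trait-evaluation scoring pipeline
#'
#' Convenience wrapper: standardize -> PCA -> component scores -> synthesis
#' score -> ranking. Plants dropped for missing traits appear in the result
#' with `NA` scores and `selected = NA`.
#'
#' @inheritParams standardize
#' @inheritParams run_pca
#' @inheritParams rank_and_select
#' @return A list with `pca` (the [run_pca()] result), `scores` (component
#'   score matrix), and `table` (ranked data frame with Y columns, Z, rank,
#'   selected).
#' @export
score_plants <- function(traits, cumulative_threshold = 0.85,
                         n_components = NULL, z_threshold = 0.80) {
  z <- standardize(traits)
  pca <- run_pca(z, cumulative_threshold, n_components)
  sc <- component_scores(z, pca)
  zz <- synthesis_score(sc, pca)
  names(zz) <- rownames(z)
  tab <- rank_and_select(zz, z_threshold)
  tab <- cbind(tab[, "plant_id", drop = FALSE],
               round(sc[tab$plant_id, , drop = FALSE], 2),
               tab[, c("Z", "rank", "selected")])
  rownames(tab) <- NULL
  dropped <- attr(z, "dropped")
  if (length(dropped)) {
    na_block <- tab[rep(NA_integer_, length(dropped)), ]
    na_block$plant_id <- dropped
    tab <- rbind(tab, na_block)
    rownames(tab) <- NULL
  }
  list(pca = pca, scores = sc, table = tab)
}
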