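#' Dominant-marker band matrix
#'
#' Container for binary presence/absence band calls scored from dominant SSR
#' (or other dominant) markers: one row per individual, one column per band
#' locus, loci grouped by the primer pair that amplified them. Two rows are
#' designated as the female (mother) and male (father) parent; all remaining
#' rows are putative offspring. Cells are 1 (band present), 0 (band absent)
#' or `NA` (lane not interpretable at that locus).
#'
#' @param calls numeric/integer matrix of 0/1/NA values with individual ids as
#'   row names and locus ids as column names.
#' @param primer_map named character vector mapping each locus id (names) to
#'   its primer id (values); must cover every column of `calls`.
#' @param mother_id,father_id row names of the two designated parents.
#'
#' @return An object of class `band_matrix`: a list with elements `calls`
#'   (integer matrix), `primer_map`, `mother_id`, `father_id`, plus helper
#'   accessors via `offspring_ids()`.
#'
#' @examples
#' calls <- rbind(M = c(1, 0, 1), P = c(1, 1, 0), o1 = c(1, 1, 1))
#' colnames(calls) <- c("a", "b", "c")
#' m <- band_matrix(calls, c(a = "p1", b = "p1", c = "p2"), "M", "P")
#' offspring_ids(m)
#' @export
band_matrix <- function(calls, primer_map, mother_id, father_id) {
  if (!is.matrix(calls)) gh_stop("`calls` must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    gh_stop("`calls` must have individual row names and locus column names")
  storage.mode(calls) <- "integer"
  obj <- structure(
    list(calls = calls,
         primer_map = primer_map,
         mother_id = mother_id,
         father_id = father_id),
    class = "band_matrix")
  validate_band_matrix(obj)
}

validate_band_matrix <- function(m) {
  calls <- m$calls
  ids <- rownames(calls)
  loci <- colnames(calls)
  if (anyDuplicated(ids))
    gh_stop(sprintf("duplicate individual id(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (anyDuplicated(loci))
    gh_stop(sprintf("duplicate locus id(s): %s",
                    paste(unique(loci[duplicated(loci)]), collapse = ", ")))
  for (p in c(m$mother_id, m$father_id)) {
    if (sum(ids == p) != 1L)
      gh_stop(sprintf("designated parent '%s' must occur exactly once among individuals", p))
  }
  bad <- calls[!is.na(calls) & !(calls %in% c(0L, 1L))]
  if (length(bad))
    gh_stop("band calls must be 0, 1 or NA")
  missing_map <- setdiff(loci, names(m$primer_map))
  if (length(missing_map))
    gh_stop(sprintf("locus without primer assignment: %s",
                    paste(missing_map, collapse = ", ")))
  m$primer_map <- m$primer_map[loci]  # order + drop extraneous entries
  all_na <- colSums(!is.na(calls)) == 0L
  if (any(all_na))
    gh_stop(sprintf("locus with no non-missing call: %s",
                    paste(loci[all_na], collapse = ", ")))
  m
}

#' @rdname band_matrix
#' @param m a `band_matrix`.
#' @export
offspring_ids <- function(m) {
  setdiff(rownames(m$calls), c(m$mother_id, m$father_id))
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d individuals (%d offspring) x %d loci in %d primer group(s)\n",
              nrow(x$calls), length(offspring_ids(x)), ncol(x$calls),
              length(unique(x$primer_map))))
  cat(sprintf("  mother: %s   father: %s   missing cells: %d\n",
              x$mother_id, x$father_id, sum(is.na(x$calls))))
  invisible(x)
}

#' Read and write band-matrix CSV files
#'
#' The on-disk dialect is a plain CSV whose first column is `individual_id`
#' and whose remaining columns are named `primer__locus` (double underscore
#' separating the primer id from the locus id). Values are 0, 1 or NA.
#'
#' @param path file path.
#' @param mother_id,father_id individual ids of the designated parents;
#'   both must be present in the file.
#' @return `read_band_matrix()` returns a validated [band_matrix()];
#'   `write_band_matrix()` returns `path` invisibly.
#' @export
read_band_matrix <- function(path, mother_id, father_id) {
  if (!file.exists(path))
    gh_stop(sprintf("band matrix file not found: %s", path), class = "gh_input_error")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "individual_id")
    gh_stop(sprintf("%s: first column must be 'individual_id'", path))
  ids <- as.character(df[[1]])
  cols <- names(df)[-1]
  if (!all(grepl("__", cols, fixed = TRUE)))
    gh_stop(sprintf("%s: band columns must be named primer__locus; offending column(s): %s",
                    path, paste(cols[!grepl("__", cols, fixed = TRUE)], collapse = ", ")))
  primer <- sub("__.*$", "", cols)
  locus <- sub("^.*?__", "", cols)  # text after the first '__'
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "integer")
  bad_cells <- which(!is.na(as.matrix(df[, -1, drop = FALSE])) & is.na(vals) |
                       (!is.na(vals) & !(vals %in% c(0L, 1L))), arr.ind = TRUE)
  if (nrow(bad_cells) > 0L)
    gh_stop(sprintf("%s: non-{0,1,NA} cell at row '%s', column '%s'",
                    path, ids[bad_cells[1, 1]], cols[bad_cells[1, 2]]))
  rownames(vals) <- ids
  colnames(vals) <- locus
  for (p in c(mother_id, father_id)) {
    if (!p %in% ids)
      gh_stop(sprintf("%s: designated parent row '%s' not found", path, p))
  }
  band_matrix(vals, stats::setNames(primer, locus), mother_id, father_id)
}

#' @rdname read_band_matrix
#' @param m a `band_matrix`.
#' @export
write_band_matrix <- function(m, path) {
  cols <- paste0(m$primer_map, "__", colnames(m$calls))
  df <- data.frame(individual_id = rownames(m$calls),
                   m$calls, check.names = FALSE)
  names(df)[-1] <- cols
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
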