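#' @keywords internal
"_PACKAGE"

## Classed conditions so the CLI can map failures onto exit codes:
## gh_input_error -> usage / bad arguments (exit 2)
## gh_data_error  -> invalid or inconsistent data (exit 1)
gh_stop <- function(msg, class = "gh_data_error", call. = FALSE) {
  stop(structure(
    class = c(class, "gh_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    gh_stop(sprintf("`%s` must be a single number in [0, 1], got %s",
                    name, deparse(x)), class = "gh_input_error")
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min)
    gh_stop(sprintf("`%s` must be a single integer >= %d", name, min),
            class = "gh_input_error")
  as.integer(x)
}

## Sample SD (n - 1 denominator) is the package-wide convention.
sample_sd <- function(x) stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
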