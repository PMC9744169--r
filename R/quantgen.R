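#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests values against a normal distribution with plug-in sample mean and
#' sample SD. `variant = "estimated_params"` reports the classical asymptotic
#' KS p-value (the convention of consumer statistics software, anticonservative
#' because the parameters are estimated); `variant = "lilliefors"` calibrates
#' the p-value by Monte Carlo simulation of the null with re-estimated
#' parameters, which is the statistically correct reference distribution.
#'
#' @param values numeric vector, at least 8 non-missing values.
#' @param variant `"estimated_params"` (default) or `"lilliefors"`.
#' @param nsim Monte-Carlo replicates for the lilliefors variant.
#' @param mc_seed seed for the Monte-Carlo calibration (lilliefors only).
#' @return A list with `statistic` (the KS distance D) and `p`.
#' @export
ks_normality <- function(values, variant = c("estimated_params", "lilliefors"),
                         nsim = 2000L, mc_seed = 1L) {
  variant <- match.arg(variant)
  x <- values[!is.na(values)]
  if (length(x) < 8L)
    gh_stop("ks_normality needs at least 8 non-missing values",
            class = "gh_input_error")
  s <- sample_sd(x)
  if (s == 0) gh_stop("ks_normality undefined for constant values (zero SD)")
  d <- ks_distance(x, mean(x), s)
  n <- length(x)
  if (variant == "estimated_params") {
    p <- ks_asymptotic_p(d, n)
  } else {
    p <- withr::with_seed(mc_seed, {
      null_d <- vapply(seq_len(nsim), function(i) {
        y <- stats::rnorm(n)
        ks_distance(y, mean(y), sample_sd(y))
      }, 0)
      (1 + sum(null_d >= d)) / (nsim + 1)
    })
  }
  list(statistic = d, p = p, n = n, variant = variant)
}

# sup-distance between the ECDF and Normal(mu, sd)
ks_distance <- function(x, mu, sd) {
  x <- sort(x)
  n <- length(x)
  f <- stats::pnorm(x, mu, sd)
  max(seq_len(n) / n - f, f - (seq_len(n) - 1) / n)
}

# asymptotic two-sided Kolmogorov p-value: 2 * sum (-1)^{k-1} exp(-2 k^2 t^2)
ks_asymptotic_p <- function(d, n) {
  t <- sqrt(n) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Sample moments: mean, SD, skewness and excess kurtosis
#'
#' Moment-based coefficients from the central moments `m_r = mean((x-xbar)^r)`:
#' skewness `g1 = m3 / m2^{3/2}` and excess kurtosis `g2 = m4 / m2^2 - 3`,
#' both approximately 0 for normal data. SD is the sample SD (n-1).
#'
#' @param values numeric vector, at least 3 non-missing values.
#' @return A list with `mean`, `sd`, `skewness`, `kurtosis` (excess), `n`.
#' @export
moments <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3L)
    gh_stop("moments needs at least 3 non-missing values", class = "gh_input_error")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0)
    gh_stop("skewness/kurtosis undefined for zero-variance values")
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  list(mean = mean(x), sd = sample_sd(x),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3,
       n = length(x))
}

#' Coefficient of variation
#'
#' CV = sample SD (n-1) / mean; unitless, scale-invariant under positive
#' rescaling.
#'
#' @param values numeric vector.
#' @return CV as a proportion (multiply by 100 for percent).
#' @export
cv <- function(values) {
  x <- values[!is.na(values)]
  m <- mean(x)
  if (m == 0) gh_stop("CV undefined: mean is zero")
  sample_sd(x) / m
}

#' Per-trait normality report
#'
#' Runs [ks_normality()] and [moments()] on every trait column and attaches a
#' normal/non-normal verdict at the 0.05 level plus histogram bins (Sturges).
#'
#' @param traits data frame whose first column is `individual_id` followed by
#'   numeric trait columns, or a plain numeric data frame/matrix of traits.
#' @inheritParams ks_normality
#' @return An object of class `normality_report`: data frame with one row per
#'   trait (`trait`, `n`, `ks_statistic`, `ks_p`, `skewness`, `kurtosis`,
#'   `verdict`); histogram breaks/counts in attribute `histograms`.
#' @export
normality_report <- function(traits, variant = c("estimated_params", "lilliefors"),
                             nsim = 2000L, mc_seed = 1L) {
  variant <- match.arg(variant)
  vals <- trait_values(traits)
  hist_list <- list()
  rows <- lapply(names(vals), function(tr) {
    x <- vals[[tr]][!is.na(vals[[tr]])]
    ks <- ks_normality(x, variant, nsim = nsim, mc_seed = mc_seed)
    mo <- moments(x)
    h <- graphics::hist(x, plot = FALSE)
    hist_list[[tr]] <<- list(breaks = h$breaks, counts = h$counts)
    data.frame(trait = tr, n = ks$n, ks_statistic = ks$statistic, ks_p = ks$p,
               skewness = mo$skewness, kurtosis = mo$kurtosis,
               verdict = if (ks$p >= 0.05) "normal" else "non-normal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- hist_list
  class(out) <- c("normality_report", "data.frame")
  out
}

trait_values <- function(traits) {
  df <- as.data.frame(traits)
  if ("individual_id" %in% names(df))
    df <- df[setdiff(names(df), "individual_id")]
  not_num <- !vapply(df, is.numeric, TRUE)
  if (any(not_num))
    gh_stop(sprintf("non-numeric trait column(s): %s",
                    paste(names(df)[not_num], collapse = ", ")))
  df
}

#' Pairwise Pearson correlations with significance tiers
#'
#' Pearson `r` over pairwise-complete observations with a two-sided t-test,
#' `t = r sqrt((n-2)/(1-r^2))` on `n-2` df, and tiers `*` (p <= 0.1), `**`
#' (p <= 0.05), `***` (p <= 0.01). Pairs involving a constant trait, or with
#' fewer than 4 complete observations, are reported as `NA`. No
#' multiple-testing correction is applied by default; `adjust = "BH"` applies
#' Benjamini-Hochberg to the off-diagonal p-values before tier assignment.
#'
#' @param traits as in [normality_report()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `correlation_table`: long data frame
#'   (`trait1`, `trait2`, `n`, `r`, `p`, `tier`) covering each unordered pair
#'   once; the square `r` matrix is in attribute `r_matrix`.
#' @export
correlation_matrix <- function(traits, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  vals <- trait_values(traits)
  k <- ncol(vals)
  trs <- names(vals)
  rmat <- diag(1, k)
  dimnames(rmat) <- list(trs, trs)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- !is.na(vals[[i]]) & !is.na(vals[[j]])
      n <- sum(ok)
      x <- vals[[i]][ok]
      y <- vals[[j]][ok]
      if (n < 4L || sample_sd(x) == 0 || sample_sd(y) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- stats::cor(x, y)
        if (abs(r) >= 1) {
          p <- 0
        } else {
          tt <- r * sqrt((n - 2) / (1 - r^2))
          p <- 2 * stats::pt(-abs(tt), df = n - 2)
        }
      }
      rmat[i, j] <- rmat[j, i] <- r
      rows[[length(rows) + 1L]] <- data.frame(
        trait1 = trs[i], trait2 = trs[j], n = n, r = r, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$tier <- correlation_tier(out$p)
  attr(out, "r_matrix") <- rmat
  class(out) <- c("correlation_table", "data.frame")
  out
}

correlation_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p <= 0.01, "***",
                ifelse(p <= 0.05, "**",
                       ifelse(p <= 0.1, "*", "none"))))
}

#' Mid-parent heterosis and heterobeltiosis table
#'
#' Per trait: the F1 population mean, mid-parent value `MP = (mother +
#' father)/2`, higher-parent value `HP = max(mother, father)`, coefficient of
#' variation of the F1 values, mid-parent heterosis `MPH = (F1 - MP)/MP` and
#' heterobeltiosis `HB = (F1 - HP)/HP`, the last three as percentages.
#' Traits missing a parent mean, or with `MP = 0` or `HP = 0`, have their
#' heterosis cells `NA`. The attribute `plus_minus_means` carries the means
#' of the positive and of the negative MPH and HB values across traits.
#'
#' @param f1 trait table (as in [normality_report()]); columns are matched to
#'   `parents$trait` by name.
#' @param parents data frame with columns `trait`, `mother_mean`,
#'   `father_mean`.
#' @return An object of class `heterosis_table`: data frame with columns
#'   `trait`, `father_mean`, `mother_mean`, `f1_mean`, `mp`, `hp`, `cv_pct`,
#'   `mph_pct`, `hb_pct` (percentages rounded to 2 dp).
#' @export
heterosis_table <- function(f1, parents) {
  vals <- trait_values(f1)
  if (!all(c("trait", "mother_mean", "father_mean") %in% names(parents)))
    gh_stop("`parents` needs columns trait, mother_mean, father_mean",
            class = "gh_input_error")
  rows <- lapply(names(vals), function(tr) {
    x <- vals[[tr]][!is.na(vals[[tr]])]
    f1m <- mean(x)
    cvp <- if (f1m != 0) round(100 * sample_sd(x) / f1m, 2) else NA_real_
    pm <- parents[parents$trait == tr, ]
    if (nrow(pm) != 1L || is.na(pm$mother_mean) || is.na(pm$father_mean)) {
      mp <- hp <- mph <- hb <- NA_real_
      mo <- fa <- NA_real_
    } else {
      mo <- pm$mother_mean; fa <- pm$father_mean
      mp <- (mo + fa) / 2
      hp <- max(mo, fa)
      mph <- if (mp != 0) round(100 * (f1m - mp) / mp, 2) else NA_real_
      hb <- if (hp != 0) round(100 * (f1m - hp) / hp, 2) else NA_real_
    }
    data.frame(trait = tr, father_mean = fa, mother_mean = mo,
               f1_mean = f1m, mp = mp, hp = hp, cv_pct = cvp,
               mph_pct = mph, hb_pct = hb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pm_mean <- function(v, sgn) {
    v <- v[!is.na(v)]
    v <- v[sign(v) == sgn]
    if (length(v)) mean(v) else NA_real_
  }
  attr(out, "plus_minus_means") <- list(
    mph_plus = pm_mean(out$mph_pct, 1), mph_minus = pm_mean(out$mph_pct, -1),
    hb_plus = pm_mean(out$hb_pct, 1), hb_minus = pm_mean(out$hb_pct, -1))
  class(out) <- c("heterosis_table", "data.frame")
  out
}

#' Self-fertility rates under bagging isolation
#'
#' Computes per-record self-fertility rate (\%) = 100 x seeds per spike /
#' spikelets per spike, summarizes each level (`parent_spike`, `f1_plant`,
#' `f1_spike`) by max/min/mean/SD, and compares parent-spike vs f1-plant
#' rates with a two-sided Welch t-test.
#'
#' @param records data frame with columns `unit_id`, `level` (one of
#'   `parent_spike`, `f1_plant`, `f1_spike`), `seeds`, `spikelets`. Records
#'   with `spikelets <= 0` are rejected with a message.
#' @return A list with `rates` (input plus `rate`), `summary` (per level),
#'   and `welch` (`statistic`, `df`, `p`) when both compared levels have at
#'   least two records.
#' @export
self_fertility <- function(records) {
  need <- c("unit_id", "level", "seeds", "spikelets")
  if (!all(need %in% names(records)))
    gh_stop(sprintf("`records` needs columns: %s", paste(need, collapse = ", ")),
            class = "gh_input_error")
  bad <- !is.na(records$spikelets) & records$spikelets <= 0
  if (any(bad)) {
    message("rejecting ", sum(bad), " record(s) with non-positive spikelet count: ",
            paste(records$unit_id[bad], collapse = ", "))
    records <- records[!bad, , drop = FALSE]
  }
  records$rate <- 100 * records$seeds / records$spikelets
  summ <- do.call(rbind, lapply(split(records, records$level), function(d)
    data.frame(level = d$level[1], n = nrow(d), max = max(d$rate),
               min = min(d$rate), mean = mean(d$rate),
               sd = if (nrow(d) > 1) sample_sd(d$rate) else NA_real_,
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  out <- list(rates = records, summary = summ)
  a <- records$rate[records$level == "parent_spike"]
  b <- records$rate[records$level == "f1_plant"]
  if (length(a) >= 2L && length(b) >= 2L)
    out$welch <- welch_t(a, b)
  out
}

# two-sided Welch t-test, written out so tests can cross-check stats::t.test
welch_t <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cross-check marker-based false-hybrid proportion against self-fertility
#'
#' A marker-based false-hybrid proportion consistent with the female parent's
#' measured self-fertility range corroborates maternal selfing as the source
#' of the false hybrids. Boundary values count as within the range.
#'
#' @param false_hybrid_proportion percentage of offspring called maternal type.
#' @param selfing_min,selfing_max the observed self-fertility range (\%).
#' @return `"within_range"`, `"below_range"` or `"above_range"`.
#' @export
purity_cross_check <- function(false_hybrid_proportion, selfing_min, selfing_max) {
  if (selfing_min > selfing_max)
    gh_stop("selfing_min must be <= selfing_max", class = "gh_input_error")
  if (false_hybrid_proportion < selfing_min) "below_range"
  else if (false_hybrid_proportion > selfing_max) "above_range"
  else "within_range"
}

#' Per-cross progeny performance summary
#'
#' Simple percentages per hybrid combination: survival = plants surviving
#' after germination and transplanting / seeds harvested, overwintering =
#' overwintered / surviving, fertile proportion = fertile / overwintered.
#' Crosses whose harvested seed count is below `min_seeds` are not evaluated
#' (rates `NA`, the dashes of a summary table), as are rates with a zero
#' denominator.
#'
#' @param records data frame with columns `cross`, `seeds`, `surviving`,
#'   `overwintered`, `fertile` (counts).
#' @param min_seeds seed-count threshold below which a cross is not evaluated.
#' @return Data frame `cross`, `seeds`, `survival_pct`, `overwintering_pct`,
#'   `fertile_pct` (2 dp), plus logical `evaluated`.
#' @export
combination_summary <- function(records, min_seeds = 50L) {
  need <- c("cross", "seeds", "surviving", "overwintered", "fertile")
  if (!all(need %in% names(records)))
    gh_stop(sprintf("`records` needs columns: %s", paste(need, collapse = ", ")),
            class = "gh_input_error")
  pct <- function(num, den) ifelse(!is.na(den) & den > 0,
                                   round(100 * num / den, 2), NA_real_)
  out <- data.frame(cross = records$cross, seeds = records$seeds,
                    survival_pct = pct(records$surviving, records$seeds),
                    overwintering_pct = pct(records$overwintered, records$surviving),
                    fertile_pct = pct(records$fertile, records$overwintered),
                    stringsAsFactors = FALSE)
  below <- records$seeds < min_seeds
  out[below, c("survival_pct", "overwintering_pct", "fertile_pct")] <- NA_real_
  out$evaluated <- !below
  out
}

#' Read a parent trait-means CSV
#'
#' Expects columns `trait`, `mother_mean`, `father_mean`; a JSON fixture
#' config (from [write_fixture_set()]) is also accepted.
#'
#' @param path CSV (or fixture config JSON) path.
#' @return Data frame `trait`, `mother_mean`, `father_mean`.
#' @export
read_parent_means <- function(path) {
  if (!file.exists(path))
    gh_stop(sprintf("parent means file not found: %s", path),
            class = "gh_input_error")
  if (grepl("\\.json$", path)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    pm <- cfg$parent_trait_means
    if (is.null(pm)) gh_stop(sprintf("%s: no parent_trait_means entry", path))
    return(as.data.frame(pm))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("trait", "mother_mean", "father_mean") %in% names(df)))
    gh_stop(sprintf("%s: needs columns trait, mother_mean, father_mean", path))
  df
}

#' Read a trait table CSV
#'
#' First column `individual_id`, remaining columns numeric traits.
#'
#' @param path CSV path.
#' @return Data frame as written by [simulate_traits()].
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path))
    gh_stop(sprintf("trait table not found: %s", path), class = "gh_input_error")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "individual_id")
    gh_stop(sprintf("%s: first column must be 'individual_id'", path))
  trait_values(df)  # validates numeric columns
  df
}
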