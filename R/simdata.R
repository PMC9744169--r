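#' Parent genotypes at dominant band loci
#'
#' Holds the diploid dosage of the band-presence allele (0, 1 or 2) for the
#' two parents of a cross at every band locus, with loci grouped by primer
#' pair. Dominant scoring shows a band whenever dosage > 0, so a
#' "characteristic band" arises at any locus where exactly one parent has
#' dosage > 0.
#'
#' @param primer_ids character vector, one primer id per locus.
#' @param locus_ids character vector of unique locus ids.
#' @param mother_genotype,father_genotype integer vectors of per-locus dosages
#'   in \{0, 1, 2\}.
#' @return An object of class `parent_genotypes`.
#' @export
parent_genotypes <- function(primer_ids, locus_ids, mother_genotype, father_genotype) {
  n <- length(locus_ids)
  if (length(primer_ids) != n || length(mother_genotype) != n ||
      length(father_genotype) != n)
    gh_stop("primer_ids, locus_ids and both genotypes must have equal length",
            class = "gh_input_error")
  if (anyDuplicated(locus_ids))
    gh_stop("locus ids must be unique", class = "gh_input_error")
  for (g in list(mother_genotype, father_genotype)) {
    if (!all(g %in% 0:2))
      gh_stop("dosages must be integers in {0, 1, 2}", class = "gh_input_error")
  }
  structure(
    list(primer_ids = as.character(primer_ids),
         locus_ids = as.character(locus_ids),
         mother_genotype = as.integer(mother_genotype),
         father_genotype = as.integer(father_genotype)),
    class = "parent_genotypes")
}

#' @export
print.parent_genotypes <- function(x, ...) {
  disc <- sum((x$mother_genotype > 0) != (x$father_genotype > 0))
  cat(sprintf("parent_genotypes: %d loci in %d primer group(s), %d with discordant band phenotype\n",
              length(x$locus_ids), length(unique(x$primer_ids)), disc))
  invisible(x)
}

#' Offspring simulation settings
#'
#' @param n_offspring number of offspring to simulate.
#' @param generation `"F1"` (mother x father) or `"BC1"` (an F1 plant used as
#'   female, backcrossed to the recurrent male parent).
#' @param selfing_rate probability that an offspring is a maternal self
#'   (a false hybrid) rather than a true cross. Bagging-isolation
#'   self-fertility measurements in self-incompatible wildrye put this in the
#'   low percent range (roughly 0.018-0.038 per spike).
#' @param missing_rate probability that any band call is missing (lane not
#'   interpretable), applied independently per cell.
#' @param seed integer random seed; identical seeds give identical output.
#' @param mother_id,father_id labels used for the embedded parent rows.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_offspring, generation = c("F1", "BC1"),
                              selfing_rate = 0, missing_rate = 0, seed = 1L,
                              mother_id = "mother", father_id = "father") {
  generation <- match.arg(generation)
  structure(
    list(n_offspring = check_count(n_offspring, "n_offspring"),
         generation = generation,
         selfing_rate = check_proportion(selfing_rate, "selfing_rate"),
         missing_rate = check_proportion(missing_rate, "missing_rate"),
         seed = check_count(seed, "seed", min = 0L),
         mother_id = mother_id, father_id = father_id),
    class = "simulation_config")
}

#' Simulate parent genotypes
#'
#' Draws per-locus parental dosages independently. With probability
#' `p_polymorphic` a locus is made phenotype-discordant: one parent (chosen at
#' random) carries the band with dosage 1 or 2, the other has dosage 0, so the
#' locus yields a characteristic band. Otherwise the locus is concordant: both
#' parents carry the band (dosages drawn from \{1, 2\}) or neither does.
#'
#' @param n_primers number of primer pairs.
#' @param loci_per_primer band loci per primer pair.
#' @param p_polymorphic probability a locus has discordant parental band
#'   phenotype.
#' @param seed integer random seed.
#' @return A [parent_genotypes()] object with `n_primers * loci_per_primer` loci.
#' @export
simulate_parents <- function(n_primers, loci_per_primer, p_polymorphic, seed = 1L) {
  n_primers <- check_count(n_primers, "n_primers")
  loci_per_primer <- check_count(loci_per_primer, "loci_per_primer")
  check_proportion(p_polymorphic, "p_polymorphic")
  n <- n_primers * loci_per_primer
  withr::with_seed(seed, {
    discordant <- stats::runif(n) < p_polymorphic
    mother <- father <- integer(n)
    # discordant loci: band carrier chosen at random, dosage 1 or 2
    carrier_is_father <- stats::runif(n) < 0.5
    dose <- sample(1:2, n, replace = TRUE)
    father[discordant & carrier_is_father] <- dose[discordant & carrier_is_father]
    mother[discordant & !carrier_is_father] <- dose[discordant & !carrier_is_father]
    # concordant loci: both banded (independent dosages) or both absent
    both_banded <- !discordant & stats::runif(n) < 0.5
    mother[both_banded] <- sample(1:2, sum(both_banded), replace = TRUE)
    father[both_banded] <- sample(1:2, sum(both_banded), replace = TRUE)
  })
  parent_genotypes(
    primer_ids = rep(sprintf("P%02d", seq_len(n_primers)), each = loci_per_primer),
    locus_ids = sprintf("P%02d_L%02d",
                        rep(seq_len(n_primers), each = loci_per_primer),
                        rep(seq_len(loci_per_primer), n_primers)),
    mother_genotype = mother, father_genotype = father)
}

dosage_to_alleles <- function(d) {
  # diploid dosage -> the plant's two alleles (1 = band allele, 0 = null)
  rbind(as.integer(d >= 1), as.integer(d == 2))
}

#' Simulate F1 or BC1 offspring band matrices
#'
#' Each offspring is a maternal self with probability `selfing_rate` (both
#' gametes drawn from the female plant), otherwise a true cross (one gamete
#' from each parent). Gametes pick one of the plant's two alleles uniformly,
#' independently per locus (free recombination, no mutation). The dominant
#' band phenotype is 1 whenever the band-allele dosage exceeds 0; cells are
#' then masked missing independently with probability `missing_rate`. The two
#' parent rows (never masked) are embedded in the returned matrix.
#'
#' For `generation = "BC1"` the female plant is an F1 individual whose
#' per-locus dosage must be supplied via `f1_mother_genotype`; the male is
#' the recurrent father from `parents`.
#'
#' @param parents a [parent_genotypes()] object.
#' @param config a [simulation_config()].
#' @param f1_mother_genotype integer dosage vector for the F1 plant acting as
#'   female (BC1 only).
#' @return A list with `matrix` (a [band_matrix()] including the parent rows)
#'   and `truth` (data frame `individual_id`, `truth` in
#'   \{`true_hybrid`, `maternal_self`\}).
#' @export
simulate_offspring <- function(parents, config, f1_mother_genotype = NULL) {
  stopifnot(inherits(parents, "parent_genotypes"),
            inherits(config, "simulation_config"))
  nl <- length(parents$locus_ids)
  if (config$generation == "BC1") {
    if (is.null(f1_mother_genotype))
      gh_stop("BC1 simulation requires `f1_mother_genotype` (the F1 plant used as female)",
              class = "gh_input_error")
    if (length(f1_mother_genotype) != nl || !all(f1_mother_genotype %in% 0:2))
      gh_stop("`f1_mother_genotype` must give a dosage in {0,1,2} for every locus",
              class = "gh_input_error")
    mother_geno <- as.integer(f1_mother_genotype)
  } else {
    mother_geno <- parents$mother_genotype
  }
  father_geno <- parents$father_genotype
  n <- config$n_offspring

  mother_alleles <- dosage_to_alleles(mother_geno)  # 2 x nl
  father_alleles <- dosage_to_alleles(father_geno)

  withr::with_seed(config$seed, {
    is_self <- stats::runif(n) < config$selfing_rate
    pick <- function(alleles) {
      # one gamete per offspring per locus: row index 1 or 2 per cell
      idx <- matrix(sample(1:2, n * nl, replace = TRUE), n, nl)
      t(vapply(seq_len(n), function(i) alleles[cbind(idx[i, ], seq_len(nl))],
               integer(nl)))
    }
    g1 <- pick(mother_alleles)                    # maternal gamete
    g2_cross <- pick(father_alleles)              # paternal gamete
    g2_self <- pick(mother_alleles)               # second maternal gamete
    g2 <- g2_cross
    g2[is_self, ] <- g2_self[is_self, ]
    dosage <- g1 + g2
    pheno <- (dosage > 0L) * 1L
    miss <- matrix(stats::runif(n * nl) < config$missing_rate, n, nl)
    pheno[miss] <- NA_integer_
  })

  off_ids <- sprintf("off%03d", seq_len(n))
  calls <- rbind((mother_geno > 0L) * 1L, (father_geno > 0L) * 1L, pheno)
  rownames(calls) <- c(config$mother_id, config$father_id, off_ids)
  colnames(calls) <- parents$locus_ids
  m <- band_matrix(calls,
                   stats::setNames(parents$primer_ids, parents$locus_ids),
                   config$mother_id, config$father_id)
  truth <- data.frame(
    individual_id = off_ids,
    truth = ifelse(is_self, "maternal_self", "true_hybrid"),
    stringsAsFactors = FALSE)
  list(matrix = m, truth = truth)
}

#' Trait simulation specification
#'
#' Describes the stochastic model behind [simulate_traits()]: per-trait parent
#' means, the mid-parent heterosis each trait should express, a target
#' correlation structure for the residual noise, per-trait coefficients of
#' variation (at the offspring scale), and an optional subset of traits drawn
#' from a right-skewed law.
#'
#' @param trait_names character vector of trait labels.
#' @param mother_means,father_means per-trait parental means (trait units).
#' @param mph_targets per-trait intended mid-parent heterosis, as proportions
#'   (0.5 means the offspring mean targets 1.5 x the mid-parent value).
#' @param correlation target correlation matrix of the trait noise; must be
#'   symmetric with unit diagonal and eigenvalues >= -1e-8.
#' @param cv_targets per-trait coefficient of variation (SD/mean) targets,
#'   all > 0, applied at the offspring mean.
#' @param skew_traits subset of `trait_names` generated through a monotone
#'   right-skewing transform (standardized lognormal tilt) instead of the
#'   plain normal margin.
#' @param skew_lambda tilt strength for skewed traits; the margin is the
#'   standardized lognormal `(exp(lambda*z) - e^{lambda^2/2}) / sd`, whose
#'   skewness at the default 0.75 is about 3.3.
#' @return An object of class `trait_sim_spec`.
#' @export
trait_sim_spec <- function(trait_names, mother_means, father_means,
                           mph_targets = 0, correlation = NULL,
                           cv_targets = 0.1, skew_traits = character(),
                           skew_lambda = 0.75) {
  k <- length(trait_names)
  mph_targets <- rep_len(mph_targets, k)
  cv_targets <- rep_len(cv_targets, k)
  if (length(mother_means) != k || length(father_means) != k)
    gh_stop("parent means must match trait_names in length", class = "gh_input_error")
  if (any(cv_targets <= 0))
    gh_stop("cv_targets must all be > 0", class = "gh_input_error")
  if (is.null(correlation)) correlation <- diag(k)
  if (!isTRUE(all.equal(dim(correlation), c(k, k))) ||
      !isTRUE(all.equal(correlation, t(correlation))) ||
      !isTRUE(all.equal(unname(diag(correlation)), rep(1, k))))
    gh_stop("correlation must be a symmetric matrix with unit diagonal",
            class = "gh_input_error")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    gh_stop(sprintf("correlation is not positive semidefinite: smallest eigenvalue %.3e",
                    min(ev)), class = "gh_input_error")
  if (!all(skew_traits %in% trait_names))
    gh_stop("skew_traits must be a subset of trait_names", class = "gh_input_error")
  structure(
    list(trait_names = trait_names,
         mother_means = as.numeric(mother_means),
         father_means = as.numeric(father_means),
         mph_targets = mph_targets, correlation = unname(correlation),
         cv_targets = cv_targets, skew_traits = skew_traits,
         skew_lambda = skew_lambda),
    class = "trait_sim_spec")
}

#' Reference 12-trait simulation defaults
#'
#' A ready-made [trait_sim_spec()] emulating a published wildrye F1 trial:
#' twelve agronomic traits (four nutritional, eight reproductive), parental
#' means from a real XJ-ALT (female) x BOZOISKY SELECT (male) cross, the
#' mid-parent heterosis and coefficient-of-variation levels observed there,
#' and right-skewed margins for the two traits that failed normality in the
#' field data (reproductive tiller number and seed number per plant). The
#' noise correlation is a two-block exchangeable structure (0.3 within the
#' nutritional and reproductive trait blocks, 0.1 across).
#'
#' @return A `trait_sim_spec` for 12 traits.
#' @export
default_trait_spec <- function() {
  tab <- reference_trait_table()
  k <- nrow(tab)
  corr <- matrix(0.1, k, k)
  blocks <- split(seq_len(k), tab$block)
  for (b in blocks) corr[b, b] <- 0.3
  diag(corr) <- 1
  trait_sim_spec(
    trait_names = tab$trait,
    mother_means = tab$mother_mean,
    father_means = tab$father_mean,
    mph_targets = tab$mph / 100,
    correlation = corr,
    cv_targets = tab$cv / 100,
    skew_traits = c("reproductive_tiller_number", "seed_number_per_plant_k"))
}

# Parental means, CV and mid-parent heterosis of the reference wildrye F1
# trial; units: cm for lengths, g for weights, counts otherwise;
# seed_number_per_plant_k is in thousands.
reference_trait_table <- function() {
  data.frame(
    trait = c("tiller_height_cm", "nutritional_tiller_number",
              "second_leaf_length_cm", "second_leaf_width_cm",
              "reproductive_tiller_number", "spike_length_cm",
              "spike_width_cm", "spikelet_number_per_spike",
              "seed_number_per_spike", "seed_number_per_plant_k",
              "seed_weight_per_spike_g", "thousand_kernel_weight_g"),
    block = c("nutritional", "nutritional", "nutritional", "nutritional",
              "reproductive", "reproductive", "reproductive", "reproductive",
              "reproductive", "reproductive", "reproductive", "reproductive"),
    father_mean = c(128.67, 95.00, 20.70, 0.34, 41.33, 10.00, 0.71, 34.33,
                    126.25, 3.55, 0.27, 2.22),
    mother_mean = c(109.40, 31.33, 17.94, 0.34, 17.67, 9.11, 0.65, 26.33,
                    41.31, 0.77, 0.11, 2.00),
    f1_mean = c(126.94, 171.43, 22.65, 0.35, 63.81, 10.03, 0.59, 30.93,
                84.23, 5.87, 0.23, 2.88),
    cv = c(12.67, 34.14, 17.89, 16.40, 70.18, 15.26, 13.24, 13.82,
           33.30, 99.58, 39.22, 15.75),
    mph = c(6.64, 171.39, 17.21, 2.48, 116.31, 4.90, -12.79, 1.98,
            0.29, 143.17, 18.48, 36.80),
    hb = c(-1.34, 80.45, 9.40, 1.49, 54.39, 0.25, -16.27, -9.90,
           -33.49, 44.72, -16.65, 30.11),
    stringsAsFactors = FALSE)
}

#' Simulate a correlated quantitative trait table
#'
#' Each trait `j` targets an offspring mean of
#' `(1 + mph_target_j) * (mother_mean_j + father_mean_j)/2` and an SD of
#' `cv_target_j` times that mean. Noise is multivariate normal with the
#' spec's target correlation; traits listed in `skew_traits` push their
#' normal margin through a monotone right-skewing lognormal tilt (mean 0,
#' variance 1) after the correlation is imposed, so their realized
#' correlations are attenuated slightly.
#'
#' @param spec a [trait_sim_spec()].
#' @param n_offspring rows to simulate.
#' @param seed integer random seed.
#' @param ids optional individual ids (default `off001`, ...).
#' @return A data frame: `individual_id` plus one numeric column per trait.
#' @export
simulate_traits <- function(spec, n_offspring, seed = 1L, ids = NULL) {
  stopifnot(inherits(spec, "trait_sim_spec"))
  n <- check_count(n_offspring, "n_offspring")
  k <- length(spec$trait_names)
  mp <- (spec$mother_means + spec$father_means) / 2
  mu <- (1 + spec$mph_targets) * mp
  sdv <- spec$cv_targets * mu
  ev <- eigen(spec$correlation, symmetric = TRUE)
  rot <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
  lam <- spec$skew_lambda
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n * k), n, k) %*% rot
  })
  x <- z
  skew_idx <- match(spec$skew_traits, spec$trait_names)
  if (length(skew_idx)) {
    # standardized lognormal tilt: monotone in z, mean 0, variance 1, right-skewed
    s <- sqrt(exp(lam^2) * (exp(lam^2) - 1))
    x[, skew_idx] <- (exp(lam * z[, skew_idx, drop = FALSE]) - exp(lam^2 / 2)) / s
  }
  out <- sweep(sweep(x, 2, sdv, `*`), 2, mu, `+`)
  colnames(out) <- spec$trait_names
  df <- data.frame(individual_id = ids %||% sprintf("off%03d", seq_len(n)),
                   out, check.names = FALSE, stringsAsFactors = FALSE)
  df
}

#' Write a complete synthetic fixture set
#'
#' Generates a parent-genotype file, band matrix, truth labels, trait table
#' and a JSON config snapshot for a named scenario, all deterministic in
#' `seed`. Scenarios:
#' \describe{
#'   \item{`paper-like-F1`}{123 offspring, three primer pairs with 10/16/12
#'     band loci, 3/3/2 homozygous paternal characteristic bands and 2/2/3
#'     maternal ones, selfing rate 0.0325 (about 4 expected maternal selfs),
#'     2\% missing calls, plus the 12-trait table from
#'     [default_trait_spec()].}
#'   \item{`tiny`}{10 offspring, 2 primers x 3 loci, no selfing, no missing
#'     data; loci per primer are (paternal-only, maternal-only, shared).}
#' }
#'
#' @param out_dir output directory (created if needed).
#' @param scenario `"paper-like-F1"` or `"tiny"`.
#' @param seed integer master seed.
#' @return Invisibly, a character vector of the five files written
#'   (`parents.csv`, `band_matrix.csv`, `truth_labels.csv`, `traits.csv`,
#'   `config.json`).
#' @export
write_fixture_set <- function(out_dir, scenario = c("paper-like-F1", "tiny"),
                              seed = 1L) {
  scenario <- match.arg(scenario)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) gh_stop(sprintf("cannot create output directory: %s", out_dir),
                   class = "gh_input_error")
  sc <- fixture_scenario(scenario, seed)
  sim <- simulate_offspring(sc$parents, sc$config)
  traits <- simulate_traits(sc$trait_spec, sc$config$n_offspring,
                            seed = sc$config$seed + 1L,
                            ids = sim$truth$individual_id)
  paths <- file.path(out_dir, c("parents.csv", "band_matrix.csv",
                                "truth_labels.csv", "traits.csv", "config.json"))
  names(paths) <- c("parents", "band_matrix", "truth_labels", "traits", "config")
  utils::write.csv(data.frame(primer_id = sc$parents$primer_ids,
                              locus_id = sc$parents$locus_ids,
                              mother_dosage = sc$parents$mother_genotype,
                              father_dosage = sc$parents$father_genotype),
                   paths[["parents"]], row.names = FALSE, quote = FALSE)
  write_band_matrix(sim$matrix, paths[["band_matrix"]])
  utils::write.csv(sim$truth, paths[["truth_labels"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(traits, paths[["traits"]], row.names = FALSE, quote = FALSE)
  snapshot <- list(
    scenario = scenario, seed = seed,
    config = unclass(sc$config),
    parent_trait_means = data.frame(trait = sc$trait_spec$trait_names,
                                    mother_mean = sc$trait_spec$mother_means,
                                    father_mean = sc$trait_spec$father_means))
  jsonlite::write_json(snapshot, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# Fixed, code-defined parents + config for each named scenario.
fixture_scenario <- function(scenario, seed) {
  if (scenario == "tiny") {
    parents <- parent_genotypes(
      primer_ids = c("p1", "p1", "p1", "p2", "p2", "p2"),
      locus_ids = c("p1_a", "p1_b", "p1_c", "p2_a", "p2_b", "p2_c"),
      mother_genotype = c(0L, 2L, 1L, 0L, 2L, 2L),
      father_genotype = c(2L, 0L, 1L, 2L, 0L, 1L))
    config <- simulation_config(10, "F1", selfing_rate = 0, missing_rate = 0,
                                seed = seed)
    tab <- reference_trait_table()[1:3, ]
    spec <- trait_sim_spec(tab$trait, tab$mother_mean, tab$father_mean,
                           mph_targets = tab$mph / 100, cv_targets = tab$cv / 100)
  } else {
    # three primer pairs; loci counts and characteristic-band counts follow
    # the reference F1 panel (10/16/12 loci, MF1 3/3/2, FF1 2/2/3); paternal
    # characteristic bands are homozygous so every true cross shows them
    prim <- c("28553", "44262", "51628")
    n_loci <- c(10L, 16L, 12L)
    mf1 <- c(3L, 3L, 2L)   # paternal characteristic bands per primer
    ff1 <- c(2L, 2L, 3L)   # maternal characteristic bands per primer
    primer_ids <- rep(prim, n_loci)
    locus_ids <- unlist(lapply(seq_along(prim), function(i)
      sprintf("%s_L%02d", prim[i], seq_len(n_loci[i]))))
    mother <- father <- integer(sum(n_loci))
    shared_cycle <- rbind(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
    off <- 0L
    for (i in seq_along(prim)) {
      idx <- off + seq_len(n_loci[i])
      pat <- idx[seq_len(mf1[i])]
      mat <- idx[mf1[i] + seq_len(ff1[i])]
      sha <- idx[-(seq_len(mf1[i] + ff1[i]))]
      father[pat] <- 2L                       # homozygous paternal bands
      mother[mat] <- 2L
      cyc <- shared_cycle[((seq_along(sha) - 1L) %% 4L) + 1L, , drop = FALSE]
      mother[sha] <- cyc[, 1L]
      father[sha] <- cyc[, 2L]
      off <- off + n_loci[i]
    }
    parents <- parent_genotypes(primer_ids, locus_ids, mother, father)
    config <- simulation_config(123, "F1", selfing_rate = 0.0325,
                                missing_rate = 0.02, seed = seed)
    spec <- default_trait_spec()
  }
  list(parents = parents, config = config, trait_spec = spec)
}
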