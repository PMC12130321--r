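#' Draw a trait architecture
#'
#' Samples the causal configuration of a simulated quantitative trait:
#' which SNPs are causal, their additive weights, and — for epistatic
#' scenarios — a partition of the causal set into disjoint 4-tuples with
#' per-group interaction weights. Weights are i.i.d. standard normal; the
#' overall genetic scale is set later by [simulate_phenotype()] to hit the
#' target heritability.
#'
#' @param panel A `genotype_panel` supplying the candidate SNP ids.
#' @param scenario One of `"additive"`, `"epistatic"`,
#'   `"with_environment"`. Blended architectures are produced by simulating
#'   an additive and an epistatic trait and mixing them with
#'   [blend_phenotypes()].
#' @param n_causal Number of causal SNPs; must be divisible by 4 under the
#'   epistatic scenario.
#' @param target_h2 Genetic fraction of phenotypic variance, in `(0, 1]`.
#' @param seed Integer seed.
#' @param env_spec Optional environmental effect description (see
#'   [simulate_phenotype()]); only used when `scenario =
#'   "with_environment"`.
#' @return A `trait_architecture` object.
#' @export
draw_architecture <- function(panel, scenario = c("additive", "epistatic", "with_environment"),
                              n_causal, target_h2 = 0.5, seed = 1L,
                              env_spec = NULL) {
  scenario <- match.arg(scenario)
  assert_that(n_causal <= nrow(panel$snps),
              "`n_causal` exceeds the number of SNPs on the panel")
  assert_that(target_h2 > 0 && target_h2 <= 1, "`target_h2` must be in (0, 1]")
  if (scenario == "epistatic" && n_causal %% 4 != 0) {
    abort("`n_causal` must be divisible by 4 under the epistatic scenario")
  }
  set.seed(seed)
  causal <- sort(sample(panel$snps$snp_id, n_causal))

  additive_weights <- NULL
  interaction_groups <- list()
  interaction_weights <- numeric(0)
  if (scenario == "epistatic") {
    shuffled <- sample(causal)
    interaction_groups <- split(shuffled, rep(seq_len(n_causal / 4), each = 4))
    names(interaction_groups) <- NULL
    interaction_weights <- rnorm(n_causal / 4)
  } else {
    additive_weights <- stats::setNames(rnorm(n_causal), causal)
  }

  structure(
    list(scenario = scenario, causal_ids = causal,
         additive_weights = additive_weights,
         interaction_groups = interaction_groups,
         interaction_weights = interaction_weights,
         env_spec = env_spec, target_h2 = target_h2, seed = seed),
    class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("<trait_architecture> %s: %d causal SNPs, %d interaction group(s), target h2 = %.2f\n",
              x$scenario, length(x$causal_ids), length(x$interaction_groups), x$target_h2))
  invisible(x)
}

#' Serialize / restore a trait architecture
#'
#' JSON round-trip for reproducibility records.
#'
#' @param arch A `trait_architecture`.
#' @param path Output (input) file path.
#' @return `path` invisibly; `read_architecture()` returns the restored
#'   object.
#' @export
write_architecture <- function(arch, path) {
  jsonlite::write_json(unclass(arch), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$additive_weights <- if (length(x$additive_weights)) unlist(x$additive_weights) else NULL
  x$interaction_groups <- if (length(x$interaction_groups)) {
    lapply(seq_len(nrow(x$interaction_groups)), function(i) x$interaction_groups[i, ])
  } else list()
  structure(x, class = "trait_architecture")
}

# standardized dosages of selected SNPs (population sd)
standardize_dosages <- function(panel, ids) {
  x <- panel$dosages[, ids, drop = FALSE]
  mu <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sds == 0)) {
    abort(sprintf("causal SNP '%s' is monomorphic in the panel",
                  ids[which(sds == 0)[1]]))
  }
  sweep(sweep(x, 2, mu), 2, sds, "/")
}

# environmental design helpers -------------------------------------------

std_cov_column <- function(covariates, col) {
  v <- covariates[[col]]
  if (is.null(v)) abort(sprintf("covariate '%s' not found", col))
  v <- as.numeric(v)
  v[is.na(v)] <- mean(v, na.rm = TRUE)
  s <- pop_sd(v)
  if (s == 0) abort(sprintf("covariate '%s' is constant", col))
  (v - mean(v)) / s
}

#' Simulate a phenotype from a trait architecture
#'
#' Builds the trait as a sum of named components: additive genetic,
#' epistatic genetic, environmental main effects, gene-environment and
#' environment-environment interactions, and i.i.d. Gaussian noise. The
#' phenotype always equals the element-wise sum of its stored components.
#'
#' The additive component is \eqn{\sum_j \beta_j z_j} over standardized
#' causal dosages (so rarer alleles carry larger per-allele effects). The
#' epistatic component is \eqn{\sum_k w_k (x_{k1} x_{k2} x_{k3} x_{k4} -
#' \overline{x_{k1} x_{k2} x_{k3} x_{k4}})} over raw `{0,1,2}` dosages of
#' each 4-tuple, centred per group. Products of raw dosages decompose into
#' additive plus interaction variance, so the simulated epistatic traits
#' carry an additive-appearing signal — the calibration the framework
#' requires (a purely interaction-orthogonal trait would leave every
#' additive baseline at r-squared zero and the relative comparison
#' undefined). The combined genetic part is rescaled so that its empirical
#' variance fraction equals `target_h2`; the Gaussian noise supplies the
#' remainder.
#'
#' @param panel The full (un-reduced) `genotype_panel`; all causal SNPs
#'   must be present and polymorphic.
#' @param arch A [draw_architecture()] result.
#' @param covariates Optional [simulate_covariates()] table; required when
#'   `arch$env_spec` references covariate columns. `env_spec` is a list
#'   with optional entries `main` (tibble `column`, `weight`), `gxe`
#'   (tibble `column`, `snp_id`, `weight`), `exe` (tibble `column_a`,
#'   `column_b`, `weight`) and `env_var` (variance share of the
#'   non-genetic environmental terms, default 0.2).
#' @return A `phenotype_set` tibble with columns `sample_id`, `y`,
#'   `g_additive`, `g_epistatic`, `e_main`, `gxe`, `exe`, `noise`.
#' @export
simulate_phenotype <- function(panel, arch, covariates = NULL) {
  n <- length(panel$sample_ids)
  zero <- numeric(n)
  g_add <- zero; g_epi <- zero; e_main <- zero; gxe <- zero; exe <- zero

  if (!is.null(arch$additive_weights) && length(arch$additive_weights) > 0) {
    z <- standardize_dosages(panel, names(arch$additive_weights))
    g_add <- as.numeric(z %*% arch$additive_weights)
  }
  if (length(arch$interaction_groups) > 0) {
    x <- panel$dosages[, arch$causal_ids, drop = FALSE]
    if (any(apply(x, 2, var) == 0)) abort("a causal SNP is monomorphic in the panel")
    for (k in seq_along(arch$interaction_groups)) {
      g <- arch$interaction_groups[[k]]
      prod_k <- as.numeric(panel$dosages[, g[1]] * panel$dosages[, g[2]] *
                             panel$dosages[, g[3]] * panel$dosages[, g[4]])
      g_epi <- g_epi + arch$interaction_weights[k] * (prod_k - mean(prod_k))
    }
  }

  es <- arch$env_spec
  if (!is.null(es)) {
    if (is.null(covariates)) abort("`covariates` required when the architecture has env_spec")
    if (!is.null(es$main) && nrow(es$main) > 0) {
      for (i in seq_len(nrow(es$main))) {
        e_main <- e_main + es$main$weight[i] * std_cov_column(covariates, es$main$column[i])
      }
    }
    if (!is.null(es$gxe) && nrow(es$gxe) > 0) {
      for (i in seq_len(nrow(es$gxe))) {
        zi <- standardize_dosages(panel, es$gxe$snp_id[i])[, 1]
        gxe <- gxe + es$gxe$weight[i] * zi * std_cov_column(covariates, es$gxe$column[i])
      }
    }
    if (!is.null(es$exe) && nrow(es$exe) > 0) {
      for (i in seq_len(nrow(es$exe))) {
        pr <- std_cov_column(covariates, es$exe$column_a[i]) *
          std_cov_column(covariates, es$exe$column_b[i])
        exe <- exe + es$exe$weight[i] * (pr - mean(pr))
      }
    }
  }

  genetic <- g_add + g_epi + gxe
  sg <- pop_sd(genetic)
  if (sg == 0) abort("var(G) = 0: the genetic component is degenerate")
  scale_g <- sqrt(arch$target_h2) / sg
  g_add <- g_add * scale_g; g_epi <- g_epi * scale_g; gxe <- gxe * scale_g
  genetic <- genetic * scale_g

  env <- e_main + exe
  env_share <- 0
  if (any(env != 0)) {
    env_share <- es$env_var %||% 0.2
    if (arch$target_h2 + env_share > 1) {
      abort("target_h2 + env variance share exceeds 1")
    }
    se <- pop_sd(env)
    scale_e <- sqrt(env_share) / se
    e_main <- e_main * scale_e; exe <- exe * scale_e
  }

  noise_var <- 1 - arch$target_h2 - env_share
  noise <- if (noise_var > 1e-12) rnorm(n, 0, sqrt(noise_var)) else zero

  y <- g_add + g_epi + e_main + gxe + exe + noise
  tibble::new_tibble(
    tibble::tibble(sample_id = panel$sample_ids, y = y,
                   g_additive = g_add, g_epistatic = g_epi,
                   e_main = e_main, gxe = gxe, exe = exe, noise = noise),
    class = "phenotype_set",
    target_h2 = arch$target_h2, scenario = arch$scenario)
}

#' Blend an additive and an epistatic phenotype
#'
#' Mixed architectures are built by standardizing both traits to unit
#' variance and averaging with the requested parts, `y = (a y_add + b
#' y_epi) / (a + b)`; components are carried through with the same
#' coefficients so the component-sum identity is preserved. The supported
#' presets mirror 2:1 and 1:2 additive:epistatic parts; no re-calibration
#' to the target heritability is applied after mixing.
#'
#' @param p_add,p_epi `phenotype_set`s on identical samples.
#' @param ratio Two positive numbers `(additive_parts, epistatic_parts)`.
#' @return A blended `phenotype_set`.
#' @export
blend_phenotypes <- function(p_add, p_epi, ratio = c(2, 1)) {
  if (!identical(p_add$sample_id, p_epi$sample_id)) {
    abort("phenotype sets have mismatched sample ids")
  }
  assert_that(length(ratio) == 2 && all(ratio >= 0) && sum(ratio) > 0,
              "`ratio` must be two non-negative parts with positive sum")
  comp_cols <- c("y", "g_additive", "g_epistatic", "e_main", "gxe", "exe", "noise")
  s1 <- pop_sd(p_add$y); s2 <- pop_sd(p_epi$y)
  a <- ratio[1] / sum(ratio); b <- ratio[2] / sum(ratio)
  out <- p_add
  for (col in comp_cols) {
    out[[col]] <- a * p_add[[col]] / s1 + b * p_epi[[col]] / s2
  }
  attr(out, "scenario") <- "mixed"
  attr(out, "mix_ratio") <- ratio
  out
}

#' Simulate a covariate table
#'
#' Synthetic stand-in for a biobank covariate table: numeric columns are
#' standard normal, binary columns Bernoulli, factor columns uniform
#' categorical; optional completely-at-random missingness.
#'
#' @param n_samples Number of rows.
#' @param spec List with any of `numeric` (count), `binary` (count or
#'   vector of success probabilities), `factor_levels` (integer vector,
#'   one entry per factor column, each >= 2), `missing_rate` (fraction of
#'   covariate cells set to `NA`).
#' @param seed Integer seed.
#' @return A tibble with a `sample_id` key column.
#' @export
simulate_covariates <- function(n_samples, spec = list(numeric = 3), seed = 1L) {
  set.seed(seed)
  out <- tibble::tibble(sample_id = sprintf("id_%06d", seq_len(n_samples)))
  n_num <- spec$numeric %||% 0
  for (i in seq_len(n_num)) out[[paste0("num", i)]] <- rnorm(n_samples)
  pb <- spec$binary %||% numeric(0)
  if (length(pb) == 1 && pb >= 1 && pb == round(pb)) pb <- rep(0.5, pb)
  if (length(pb) == 1 && pb == 0) pb <- numeric(0)
  for (i in seq_along(pb)) out[[paste0("bin", i)]] <- rbinom(n_samples, 1, pb[i])
  fl <- spec$factor_levels %||% integer(0)
  for (i in seq_along(fl)) {
    if (fl[i] < 2) abort(sprintf("factor column %d requested with < 2 levels", i))
    out[[paste0("fac", i)]] <- factor(
      sample(LETTERS[seq_len(fl[i])], n_samples, replace = TRUE),
      levels = LETTERS[seq_len(fl[i])])
  }
  mr <- spec$missing_rate %||% 0
  if (mr > 0) {
    for (col in setdiff(names(out), "sample_id")) {
      out[[col]][runif(n_samples) < mr] <- NA
    }
  }
  # every factor column must keep >= 2 observed levels
  for (col in names(out)) {
    if (is.factor(out[[col]]) && length(unique(stats::na.omit(out[[col]]))) < 2) {
      abort(sprintf("factor column '%s' has < 2 observed levels", col))
    }
  }
  out
}

#' Binarize a continuous trait by liability threshold
#'
#' Cases are the samples whose trait value lies above the
#' `(1 - prevalence)` empirical quantile, so the realized case count is
#' exactly `round(n * prevalence)` (ties broken by sample order).
#'
#' @param p A `phenotype_set` or numeric vector of liabilities.
#' @param prevalence Case fraction in `(0, 1)`.
#' @return An integer 0/1 vector (1 = case), named by sample id when
#'   available.
#' @export
binarize_liability <- function(p, prevalence) {
  assert_that(prevalence > 0 && prevalence < 1, "`prevalence` must be in (0, 1)")
  y <- if (inherits(p, "phenotype_set")) p$y else as.numeric(p)
  if (pop_sd(y) == 0) abort("liability has zero variance")
  n_cases <- round(length(y) * prevalence)
  lab <- as.integer(rank(-y, ties.method = "first") <= n_cases)
  if (inherits(p, "phenotype_set")) names(lab) <- p$sample_id
  lab
}

#' Partition samples into training, validation and test sets
#'
#' Seeded shuffle followed by a contiguous cut at the cumulative ratios
#' (default 6:2:2).
#'
#' @param sample_ids Character vector of ids.
#' @param ratios Three positive parts for train/validation/test.
#' @param seed Integer seed.
#' @return A list with elements `train`, `validation`, `test` forming a
#'   disjoint, exhaustive partition of `sample_ids`.
#' @export
split_samples <- function(sample_ids, ratios = c(6, 2, 2), seed = 1L) {
  n <- length(sample_ids)
  assert_that(n >= 3, "need at least 3 samples to split")
  assert_that(length(ratios) == 3 && all(ratios > 0), "`ratios` must be 3 positive parts")
  set.seed(seed)
  shuffled <- sample(sample_ids)
  cuts <- round(cumsum(ratios) / sum(ratios) * n)
  list(train = shuffled[seq_len(cuts[1])],
       validation = shuffled[(cuts[1] + 1):cuts[2]],
       test = shuffled[(cuts[2] + 1):cuts[3]])
}

#' Mask phenotype outliers by standard-deviation distance
#'
#' Single-pass rule: mean and SD are computed once on the full vector, and
#' values more than `sd_limit` SDs from that mean are masked out.
#'
#' @param y Numeric vector (length >= 2).
#' @param sd_limit SD multiple (default 4).
#' @return Logical retention mask (`TRUE` = keep).
#' @export
filter_phenotype_outliers <- function(y, sd_limit = 4) {
  assert_that(length(y) >= 2, "`y` must have at least 2 values")
  s <- sd(y)
  if (s == 0) {
    warn("phenotype has zero variance; all values retained")
    return(rep(TRUE, length(y)))
  }
  abs(y - mean(y)) <= sd_limit * s
}
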