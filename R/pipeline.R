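#' Configure a simulation scenario
#'
#' Bundles everything one scenario run needs: the genotype spec, the trait
#' architecture, the joint-tagging sub-scenario, the mitigation strategy,
#' the replicate plan and the network configurations. Validated before any
#' compute; every random draw in [run_scenario()] is derived from
#' `base_seed` plus the replicate index.
#'
#' @param n_samples Individuals per replicate.
#' @param genotype An [ld_block_spec()].
#' @param scenario `"additive"`, `"epistatic"` or `"mixed"`.
#' @param mix_ratio Additive:epistatic parts for `"mixed"` (e.g. `c(2, 1)`).
#' @param n_causal Causal SNPs per architecture.
#' @param target_h2 Genetic variance fraction (default 0.5).
#' @param joint_tagging Degrade coverage of causal SNPs via
#'   [reduce_panel_joint_tagging()]?
#' @param jt_r2_threshold,jt_max_removal Joint-tagging parameters
#'   (defaults 0.25 and 0.5).
#' @param mitigation `"none"`, `"snp_dosage_weighting"` or
#'   `"clump_distance"`.
#' @param n_replicates Independent replicates (default 10).
#' @param base_seed Base seed; replicate r uses `base_seed + 17 * r` plus
#'   small fixed offsets per stage.
#' @param nn_large,nn_small [nn_config()]s for the two architectures
#'   (their `nonlinear` flag and seed are set per replicate and arm).
#' @param split_ratios Train/validation/test parts (default 6:2:2).
#' @param pgs List of [fit_pgs_weights()] hyper-parameters.
#' @param clump List with `r2_threshold`, `window_kb`, `min_kb` for the
#'   clump+distance mitigation.
#' @param out_dir Optional directory for per-replicate tables and logs.
#' @return A validated `scenario_config`.
#' @export
scenario_config <- function(n_samples,
                            genotype,
                            scenario = c("additive", "epistatic", "mixed"),
                            mix_ratio = c(2, 1),
                            n_causal,
                            target_h2 = 0.5,
                            joint_tagging = FALSE,
                            jt_r2_threshold = 0.25,
                            jt_max_removal = 0.5,
                            mitigation = c("none", "snp_dosage_weighting", "clump_distance"),
                            n_replicates = 10,
                            base_seed = 1L,
                            nn_large = nn_config_large(),
                            nn_small = nn_config_small(),
                            split_ratios = c(6, 2, 2),
                            pgs = list(),
                            clump = list(r2_threshold = 0.5, window_kb = 500, min_kb = 500),
                            out_dir = NULL) {
  scenario <- match.arg(scenario)
  mitigation <- match.arg(mitigation)
  assert_that(inherits(genotype, "ld_block_spec"), "`genotype` must be an ld_block_spec")
  assert_that(n_replicates >= 1, "`n_replicates` must be >= 1")
  assert_that(n_causal <= genotype$n_snps, "`n_causal` exceeds the panel size")
  assert_that(target_h2 > 0 && target_h2 <= 1, "`target_h2` must be in (0, 1]")
  assert_that(inherits(nn_large, "nn_config") && inherits(nn_small, "nn_config"),
              "network configurations must be nn_config objects")
  if (scenario != "additive" && n_causal %% 4 != 0) {
    abort("`n_causal` must be divisible by 4 when the scenario involves epistasis")
  }
  structure(
    list(n_samples = as.integer(n_samples), genotype = genotype,
         scenario = scenario, mix_ratio = mix_ratio,
         n_causal = as.integer(n_causal), target_h2 = target_h2,
         joint_tagging = joint_tagging, jt_r2_threshold = jt_r2_threshold,
         jt_max_removal = jt_max_removal, mitigation = mitigation,
         n_replicates = as.integer(n_replicates), base_seed = as.integer(base_seed),
         nn_large = nn_large, nn_small = nn_small,
         split_ratios = split_ratios, pgs = pgs, clump = clump,
         out_dir = out_dir),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s%s, mitigation = %s, %d x %d SNPs, %d replicates (seed %d)\n",
              x$scenario,
              if (x$scenario == "mixed") sprintf(" (%d:%d)", x$mix_ratio[1], x$mix_ratio[2]) else "",
              x$mitigation, x$n_samples, x$genotype$n_snps, x$n_replicates, x$base_seed))
  invisible(x)
}

#' Desk-scale scenario presets
#'
#' Ready-made configurations for the scenario grid at a scale that runs in
#' minutes per scenario on a single core while preserving the qualitative
#' contrasts: 4,000 individuals, 80 SNPs in 16 LD blocks of 5 (latent
#' rho 0.9), 24 causal SNPs (six 4-way groups), h2 = 0.5, 10 replicates.
#' At this sample size the networks keep the default architecture,
#' batch size and optimizer but drop dropout, lengthen patience to 30,
#' cap training at 120 epochs and raise the SGD step to 0.005; the
#' default regularisation and step size are calibrated for a
#' 75,000-sample training split and leave plain SGD far from convergence
#' at desk scale, which would confound the capacity comparison with
#' optimization speed (see the methods vignette).
#'
#' `scenario_grid()` returns the eight Table-style rows: pure epistatic
#' and pure additive with and without mitigation strategies, plus the two
#' blends.
#'
#' @param scenario,mix_ratio,joint_tagging,mitigation Forwarded to
#'   [scenario_config()].
#' @param base_seed Base seed.
#' @param scale `"desk"` (default) for the minutes-per-scenario preset;
#'   `"full"` expresses the full-scale reference conditions (125,000
#'   individuals, 500,000 SNPs, 2,000 causal variants, 20 replicates, the
#'   default network hyperparameters) — far beyond a desk budget, but
#'   available for cluster use.
#' @param ... Further [scenario_config()] overrides.
#' @return A `scenario_config` (a named list of them for
#'   `scenario_grid()`).
#' @export
scenario_preset <- function(scenario = "additive", mix_ratio = c(2, 1),
                            joint_tagging = FALSE, mitigation = "none",
                            base_seed = 1L, scale = c("desk", "full"), ...) {
  scale <- match.arg(scale)
  if (scale == "desk") {
    nn_args <- list(dropout_rate = 0, patience_epochs = 30, max_epochs = 120,
                    learning_rate = 0.005)
    defaults <- list(
      n_samples = 4000,
      genotype = ld_block_spec(n_snps = 80, block_size = 5, within_block_rho = 0.9,
                               maf_range = c(0.1, 0.5), bp_spacing = 100000,
                               blocks_per_chrom = 4),
      scenario = scenario, mix_ratio = mix_ratio, n_causal = 24,
      joint_tagging = joint_tagging, mitigation = mitigation,
      n_replicates = 10, base_seed = base_seed,
      nn_large = do.call(nn_config_large, nn_args),
      nn_small = do.call(nn_config_small, nn_args),
      pgs = list(window_snps = 20))
  } else {
    defaults <- list(
      n_samples = 125000,
      genotype = ld_block_spec(n_snps = 500000, block_size = 5,
                               within_block_rho = 0.9, maf_range = c(0.01, 0.5),
                               bp_spacing = 5000, blocks_per_chrom = 5000),
      scenario = scenario, mix_ratio = mix_ratio, n_causal = 2000,
      joint_tagging = joint_tagging, mitigation = mitigation,
      n_replicates = 20, base_seed = base_seed,
      nn_large = nn_config_large(), nn_small = nn_config_small(),
      pgs = list(window_snps = 100))
  }
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

#' @rdname scenario_preset
#' @export
scenario_grid <- function(base_seed = 1L, ...) {
  rows <- list(
    epistatic_none = list(scenario = "epistatic"),
    epistatic_weighted = list(scenario = "epistatic", mitigation = "snp_dosage_weighting"),
    additive_none = list(scenario = "additive"),
    additive_jt_none = list(scenario = "additive", joint_tagging = TRUE),
    additive_jt_weighted = list(scenario = "additive", joint_tagging = TRUE,
                                mitigation = "snp_dosage_weighting"),
    additive_jt_clump = list(scenario = "additive", joint_tagging = TRUE,
                             mitigation = "clump_distance"),
    mixed_2_1_weighted = list(scenario = "mixed", mix_ratio = c(2, 1),
                              mitigation = "snp_dosage_weighting"),
    mixed_1_2_weighted = list(scenario = "mixed", mix_ratio = c(1, 2),
                              mitigation = "snp_dosage_weighting"))
  purrr::imap(rows, function(args, name) {
    do.call(scenario_preset, c(args, list(base_seed = base_seed), list(...)))
  })
}

#' Read / write a scenario configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `scenario_config`.
#' @return `read_scenario_config()` returns a `scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$genotype <- do.call(ld_block_spec, x$genotype)
  for (slot in c("nn_large", "nn_small")) {
    if (!is.null(x[[slot]])) x[[slot]] <- do.call(nn_config, x[[slot]])
  }
  do.call(scenario_config, x)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  x <- unclass(config)
  x$genotype <- unclass(x$genotype)
  x$nn_large <- unclass(x$nn_large)
  x$nn_small <- unclass(x$nn_small)
  yaml::write_yaml(x, path)
  invisible(path)
}

# train the four networks (large/small x nonlinear/linear), select per
# arm on validation, return test r2 and significance per arm
fit_nn_arms <- function(config, inputs, y, splits, rep_seed) {
  ids <- inputs$sample_ids
  te <- resolve_rows(splits$test, ids)
  arms <- list()
  for (nl in c(TRUE, FALSE)) {
    nets <- purrr::imap(list(large = config$nn_large, small = config$nn_small),
                        function(cfg, size) {
      cfg$nonlinear <- nl
      cfg$seed <- rep_seed + ifelse(nl, 0L, 100L) + ifelse(size == "large", 0L, 50L)
      net <- build_network(ncol(inputs$X), cfg)
      train_network(net, inputs, y, splits, cfg)
    })
    chosen <- select_network(nets$large, nets$small, inputs, y, splits$validation)
    pred <- predict(chosen, inputs$X[te, , drop = FALSE])
    ct <- if (pop_sd(pred) > 0) cor.test(y[te], pred) else NULL
    arms[[if (nl) "nonlinear" else "linear"]] <- list(
      net = chosen,
      r2 = r_squared(y[te], pred),
      p = if (is.null(ct)) NA_real_ else ct$p.value)
  }
  arms
}

run_replicate <- function(config, rep) {
  rep_seed <- config$base_seed + 17L * rep

  panel <- simulate_genotypes(config$n_samples, config$genotype, seed = rep_seed)

  phen <- switch(
    config$scenario,
    additive = simulate_phenotype(
      panel, draw_architecture(panel, "additive", config$n_causal,
                               config$target_h2, seed = rep_seed + 1L)),
    epistatic = simulate_phenotype(
      panel, draw_architecture(panel, "epistatic", config$n_causal,
                               config$target_h2, seed = rep_seed + 1L)),
    mixed = {
      arch_a <- draw_architecture(panel, "additive", config$n_causal,
                                  config$target_h2, seed = rep_seed + 1L)
      arch_e <- draw_architecture(panel, "epistatic", config$n_causal,
                                  config$target_h2, seed = rep_seed + 2L)
      blend_phenotypes(simulate_phenotype(panel, arch_a),
                       simulate_phenotype(panel, arch_e),
                       ratio = config$mix_ratio)
    })
  y <- stats::setNames(phen$y, phen$sample_id)

  causal_ids <- if (config$scenario == "additive") {
    draw_architecture(panel, "additive", config$n_causal, config$target_h2,
                      seed = rep_seed + 1L)$causal_ids
  } else NULL

  jt_report <- NULL
  panel_obs <- panel
  if (config$joint_tagging) {
    arch_ids <- switch(config$scenario,
                       additive = causal_ids,
                       epistatic = draw_architecture(panel, "epistatic", config$n_causal,
                                                     config$target_h2,
                                                     seed = rep_seed + 1L)$causal_ids,
                       mixed = union(
                         draw_architecture(panel, "additive", config$n_causal,
                                           config$target_h2, seed = rep_seed + 1L)$causal_ids,
                         draw_architecture(panel, "epistatic", config$n_causal,
                                           config$target_h2, seed = rep_seed + 2L)$causal_ids))
    red <- reduce_panel_joint_tagging(panel, arch_ids,
                                      r2_threshold = config$jt_r2_threshold,
                                      max_removal_fraction = config$jt_max_removal,
                                      seed = rep_seed + 3L)
    panel_obs <- red$panel
    jt_report <- red$report
  }

  splits <- split_samples(panel$sample_ids, config$split_ratios, seed = rep_seed + 4L)

  gwas <- run_gwas(panel_obs, y, subset = splits$train)
  weights <- fit_pgs_weights(gwas, panel_obs, y, splits$validation,
                             method = "blockwise_ridge", hyper = config$pgs)
  score <- score_pgs(panel_obs, weights)
  r2_base <- r_squared(y[splits$test], score[splits$test])
  p_base <- if (pop_sd(score[splits$test]) > 0) {
    cor.test(y[splits$test], score[splits$test])$p.value
  } else NA_real_

  nn_panel <- panel_obs
  if (config$mitigation == "clump_distance") {
    kept <- ld_clump(gwas, panel_obs,
                     r2_threshold = config$clump$r2_threshold %||% 0.5,
                     window_kb = config$clump$window_kb %||% 500)
    meta <- panel_obs$snps[match(kept, panel_obs$snps$snp_id), ]
    kept <- distance_filter(
      tibble::tibble(snp_id = kept, chromosome = meta$chromosome,
                     position = meta$position,
                     p_value = gwas$p_value[match(kept, gwas$snp_id)]),
      min_kb = config$clump$min_kb %||% 500)
    keep <- panel_obs$snps$snp_id %in% kept
    nn_panel <- new_genotype_panel(panel_obs$dosages[, keep, drop = FALSE],
                                   panel_obs$snps[keep, , drop = FALSE],
                                   panel_obs$sample_ids)
  }
  inputs <- build_design_matrix(
    panel = nn_panel,
    weights = if (config$mitigation == "snp_dosage_weighting") weights else NULL,
    weighting_enabled = config$mitigation == "snp_dosage_weighting",
    train_ids = splits$train)

  arms <- fit_nn_arms(config, inputs, unname(y), splits, rep_seed + 5L)

  tibble::tibble(
    replicate = rep, seed = rep_seed,
    r2_nonlinear = arms$nonlinear$r2, r2_linear = arms$linear$r2,
    r2_baseline = r2_base,
    p_nonlinear = arms$nonlinear$p, p_linear = arms$linear$p,
    p_baseline = p_base,
    n_snps_observed = nrow(nn_panel$snps),
    n_removed_jt = if (is.null(jt_report)) 0L else length(jt_report$removed_snp_ids),
    lambda = attr(weights, "provenance")$lambda)
}

#' Run a full simulation scenario
#'
#' Executes the end-to-end comparison for each replicate: simulate
#' genotypes and trait, optionally degrade causal coverage (joint
#' tagging), split 6:2:2, run the GWAS on the training split, fit the
#' LD-aware additive baseline, build the network input under the
#' configured mitigation strategy, train the large and small linear and
#' nonlinear networks, select per arm on validation, and evaluate
#' everything on the held-out test split. Replicates are aggregated into
#' baseline-standardised gaps with a paired t-test.
#'
#' @param config A [scenario_config()].
#' @return A `scenario_result`: per-replicate tibble (`tidy()`), summary
#'   row (`glance()`), the paired-test `comparison_summary` and the
#'   config. `autoplot()` shows per-replicate gaps.
#' @export
run_scenario <- function(config) {
  assert_that(inherits(config, "scenario_config"), "`config` must be a scenario_config")
  reps <- vector("list", config$n_replicates)
  failures <- character(0)
  for (r in seq_len(config$n_replicates)) {
    reps[[r]] <- tryCatch(run_replicate(config, r), error = function(e) {
      warn(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
      failures <<- c(failures, sprintf("replicate %d: %s", r, conditionMessage(e)))
      NULL
    })
  }
  ok <- !purrr::map_lgl(reps, is.null)
  if (sum(ok) < config$n_replicates / 2) {
    abort(sprintf("scenario failed: %d/%d replicates errored (%s)",
                  sum(!ok), config$n_replicates, paste(failures, collapse = "; ")))
  }
  replicates <- dplyr::bind_rows(reps[ok])
  rel <- relative_metrics(replicates$r2_nonlinear, replicates$r2_linear,
                          replicates$r2_baseline)
  replicates <- dplyr::bind_cols(replicates, rel)
  comparison <- paired_t(replicates$gap_percent)

  result <- structure(
    list(replicates = replicates, comparison = comparison, config = config,
         failures = failures, config_hash = rlang::hash(unclass(config))),
    class = "scenario_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(replicates, file.path(config$out_dir, "replicates.tsv"))
    readr::write_tsv(glance(result), file.path(config$out_dir, "summary.tsv"))
    write_scenario_config(config, file.path(config$out_dir, "config.yaml"))
  }
  result
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s%s | mitigation %s | joint tagging %s\n",
              x$config$scenario,
              if (x$config$scenario == "mixed")
                sprintf(" (%d:%d)", x$config$mix_ratio[1], x$config$mix_ratio[2]) else "",
              x$config$mitigation, if (x$config$joint_tagging) "yes" else "no"))
  cat(sprintf("  nonlinear vs linear: %+.2f%% of baseline r2 over %d replicates (p = %.3g)\n",
              x$comparison$mean_gap, x$comparison$n, x$comparison$p_value))
  invisible(x)
}

#' Summarise several scenarios as a results table
#'
#' Mirrors the scenario-grid reporting layout: one row per scenario with
#' its epistatic/additive shares, joint-tagging flag, mitigation strategy,
#' mean nonlinear-vs-linear gap (percent of baseline r-squared) and the
#' paired t-test p-value.
#'
#' @param results Named list of `scenario_result`s.
#' @return A tibble with one row per scenario.
#' @export
scenario_table <- function(results) {
  purrr::imap_dfr(results, function(res, name) {
    cfg <- res$config
    epi_share <- switch(cfg$scenario,
                        additive = 0,
                        epistatic = 1,
                        mixed = cfg$mix_ratio[2] / sum(cfg$mix_ratio))
    tibble::tibble(
      scenario = name,
      epistasis_pct = round(100 * epi_share),
      additive_pct = round(100 * (1 - epi_share)),
      joint_tagging = cfg$joint_tagging,
      mitigation = cfg$mitigation,
      nonlinear_vs_linear_pct = res$comparison$mean_gap,
      t_test_p = res$comparison$p_value,
      n_replicates = res$comparison$n)
  })
}

#' Run the real-data workflow on user-supplied files
#'
#' Applies the full evaluation path to one phenotype: read the
#' additive-dosage genotypes, the phenotype and covariate TSVs and the
#' scoring file; mask 4-SD phenotype outliers (continuous traits); score
#' the PGS; fit the PGS-only and PGS+covariates baselines with p < 0.05
#' covariate retention; train the networks under both input scenarios
#' (weighted SNPs + PGS, and additionally the retained covariates); and
#' report each network's test r-squared as a fraction of its matching
#' baseline.
#'
#' @param genotype_raw,snp_meta Paths to the dosage text file and SNP
#'   metadata TSV (see [write_panel_raw()]).
#' @param phenotype_tsv TSV with columns `sample_id` and `y` (0/1 for a
#'   binary trait).
#' @param covariates_tsv Optional covariate TSV with `sample_id`.
#' @param scoring_file PGS scoring file (see [parse_scoring_file()]).
#' @param nn_large,nn_small Network configurations.
#' @param sd_limit Outlier limit in SDs (default 4; continuous traits).
#' @param alpha Covariate retention threshold (default 0.05).
#' @param split_seed Seed for the 6:2:2 split.
#' @return A tibble with one row per input scenario (`snp`, `snp_cov`):
#'   test r-squared of the nonlinear, linear and baseline models, their
#'   p-values and the fraction-of-baseline metrics.
#' @export
run_real_data <- function(genotype_raw, snp_meta, phenotype_tsv,
                          covariates_tsv = NULL, scoring_file,
                          nn_large = nn_config_large(),
                          nn_small = nn_config_small(),
                          sd_limit = 4, alpha = 0.05, split_seed = 1L) {
  panel <- read_panel_raw(genotype_raw, snp_meta)
  phen <- readr::read_tsv(phenotype_tsv, show_col_types = FALSE)
  if (!all(c("sample_id", "y") %in% names(phen))) {
    abort("phenotype TSV must have columns `sample_id` and `y`")
  }
  covariates <- if (!is.null(covariates_tsv)) {
    readr::read_tsv(covariates_tsv, show_col_types = FALSE)
  } else NULL

  common <- intersect(panel$sample_ids, phen$sample_id)
  if (!is.null(covariates)) common <- intersect(common, covariates$sample_id)
  if (length(common) < length(panel$sample_ids)) {
    n_miss <- length(panel$sample_ids) - length(common)
    if (length(common) < 3) {
      abort(sprintf("sample ids do not match across files (%d panel samples, %d shared)",
                    length(panel$sample_ids), length(common)))
    }
    warn(sprintf("%d panel sample(s) missing phenotype/covariates; dropped", n_miss))
  }
  keep_rows <- match(common, panel$sample_ids)
  panel <- new_genotype_panel(panel$dosages[keep_rows, , drop = FALSE],
                              panel$snps, common)
  y <- stats::setNames(phen$y[match(common, phen$sample_id)], common)
  binary <- all(stats::na.omit(y) %in% c(0, 1))

  if (!binary) {
    mask <- filter_phenotype_outliers(y, sd_limit = sd_limit)
    panel <- new_genotype_panel(panel$dosages[mask, , drop = FALSE],
                                panel$snps, common[mask])
    y <- y[mask]
  }
  if (!is.null(covariates)) {
    covariates <- covariates[match(panel$sample_ids, covariates$sample_id), , drop = FALSE]
  }

  weights <- parse_scoring_file(scoring_file)
  score <- score_pgs(panel, weights)
  splits <- split_samples(panel$sample_ids, seed = split_seed)
  te <- splits$test

  r2_pgs <- r_squared(y[te], score[te])
  p_pgs <- cor.test(y[te], score[te])$p.value

  baseline_cov <- NULL
  if (!is.null(covariates)) {
    tr_rows <- panel$sample_ids %in% c(splits$train, splits$validation)
    baseline_cov <- fit_covariate_baseline(
      score[tr_rows], covariates[tr_rows, , drop = FALSE], y[tr_rows],
      family = if (binary) "logistic" else "linear", alpha = alpha)
  }

  eval_scenario <- function(inputs, label, r2_base, p_base) {
    cfgs <- list(large = nn_large, small = nn_small)
    rows <- resolve_rows(te, inputs$sample_ids)
    arms <- list()
    for (nl in c(TRUE, FALSE)) {
      nets <- purrr::imap(cfgs, function(cfg, size) {
        cfg$nonlinear <- nl
        cfg$oversample_binary <- binary
        cfg$seed <- split_seed + ifelse(nl, 0L, 100L) + ifelse(size == "large", 0L, 50L)
        train_network(build_network(ncol(inputs$X), cfg), inputs, unname(y), splits, cfg)
      })
      chosen <- select_network(nets$large, nets$small, inputs, unname(y), splits$validation)
      pred <- predict(chosen, inputs$X[rows, , drop = FALSE])
      arms[[if (nl) "nl" else "lin"]] <- list(
        r2 = r_squared(y[te], pred),
        p = if (pop_sd(pred) > 0) cor.test(as.numeric(y[te]), pred)$p.value else NA_real_,
        net = chosen)
    }
    tibble::tibble(
      input_scenario = label,
      r2_nonlinear = arms$nl$r2, r2_linear = arms$lin$r2, r2_baseline = r2_base,
      p_nonlinear = arms$nl$p, p_linear = arms$lin$p, p_baseline = p_base,
      fraction_of_baseline_nl = arms$nl$r2 / r2_base,
      fraction_of_baseline_lin = arms$lin$r2 / r2_base,
      mean_case_fraction = if (binary) mean(arms$nl$net$case_fraction) else NA_real_)
  }

  inputs_snp <- build_design_matrix(panel = panel, weights = weights,
                                    pgs_scores = score, weighting_enabled = TRUE,
                                    train_ids = splits$train)
  out <- eval_scenario(inputs_snp, "snp", r2_pgs, p_pgs)

  if (!is.null(covariates)) {
    retained_cols <- c("sample_id", baseline_cov$retained)
    nd <- as.data.frame(covariates)
    nd$.pgs <- as.numeric(score)
    pred_cov <- stats::predict(baseline_cov$fit, newdata = nd,
                               type = "response")
    rows_te <- match(te, panel$sample_ids)
    r2_cov <- r_squared(y[te], pred_cov[rows_te])
    p_cov <- cor.test(as.numeric(y[te]), pred_cov[rows_te])$p.value
    inputs_cov <- build_design_matrix(
      panel = panel, weights = weights,
      covariates = covariates[, retained_cols, drop = FALSE],
      pgs_scores = score, weighting_enabled = TRUE, train_ids = splits$train)
    out <- dplyr::bind_rows(out, eval_scenario(inputs_cov, "snp_cov", r2_cov, p_cov))
  }
  out
}
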