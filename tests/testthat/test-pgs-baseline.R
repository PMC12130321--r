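test_that("GWAS recovers an exact linear relationship", {
  set.seed(1)
  d <- cbind(sample(0:2, 300, TRUE), sample(0:2, 300, TRUE))
  panel <- panel_from_matrix(d)
  y <- 2 * d[, 1]
  g <- run_gwas(panel, y)
  expect_equal(g$beta[1], 2.0, tolerance = 1e-12)
  expect_lt(g$p_value[1], 1e-200)
})

test_that("GWAS beta and se equal the closed-form least-squares oracle", {
  dos <- c(0L, 1L, 2L, 0L, 1L, 2L)
  y <- c(0.3, 1.1, 2.4, -0.2, 1.5, 1.9)
  panel <- panel_from_matrix(cbind(dos, c(1L, 0L, 2L, 1L, 0L, 2L)))
  g <- run_gwas(panel, y)
  # normal-equations oracle
  x <- as.numeric(dos); n <- 6
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - beta * (x - mean(x))
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  expect_equal(g$beta[1], beta, tolerance = 1e-10)
  expect_equal(g$se[1], se, tolerance = 1e-10)
  expect_equal(g$p_value[1], 2 * pt(-abs(beta / se), df = 4), tolerance = 1e-10)
  # cross-check against lm on the second SNP
  fit <- lm(y ~ panel$dosages[, 2])
  expect_equal(g$beta[2], unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(g$p_value[2], summary(fit)$coefficients[2, 4], tolerance = 1e-10)
})

test_that("permuted-phenotype null calibrates the GWAS type-I error", {
  panel <- simulate_genotypes(500, ld_block_spec(n_snps = 50, block_size = 1),
                              seed = 2)
  set.seed(3)
  y <- rnorm(500)
  hits <- replicate(20, {
    g <- run_gwas(panel, sample(y))
    mean(g$p_value < 0.05)
  })
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("GWAS flags monomorphic SNPs instead of failing", {
  d <- cbind(rep(1L, 50), sample(0:2, 50, TRUE))
  panel <- panel_from_matrix(d)
  g <- run_gwas(panel, rnorm(50))
  expect_true(g$monomorphic[1])
  expect_true(is.na(g$beta[1]))
  expect_false(g$monomorphic[2])
})

test_that("clumping keeps the worked three-SNP configuration", {
  # A (p=1e-8) with B in LD (r2 ~ 0.6) inside the window, C independent
  spec <- ld_block_spec(n_snps = 2, block_size = 2, within_block_rho = 0.92,
                        maf_range = c(0.3, 0.4), bp_spacing = 1000)
  set.seed(4)
  ld_pair <- simulate_genotypes(3000, spec, seed = 4)
  r2_ab <- pairwise_r2(ld_pair, "snp_00001", "snp_00002")
  expect_gt(r2_ab, 0.5)  # fixture sanity
  dos <- cbind(ld_pair$dosages, sample(0:2, 3000, TRUE))
  panel <- panel_from_matrix(dos, positions = c(1000L, 2000L, 3000L))
  gwas <- tibble::tibble(snp_id = panel$snps$snp_id, effect_allele = "A",
                         beta = c(1, .5, .4), se = .1,
                         p_value = c(1e-8, 1e-5, 1e-4), n_used = 3000,
                         monomorphic = FALSE)
  kept <- ld_clump(gwas, panel, r2_threshold = 0.5, window_kb = 500)
  expect_setequal(kept, c("snp_00001", "snp_00003"))
  one <- ld_clump(gwas[1, ], panel, 0.5, 500)
  expect_identical(one, "snp_00001")
  expect_identical(formals(ld_clump)$r2_threshold, 0.5)
  expect_identical(formals(ld_clump)$window_kb, 500)
})

test_that("distance filtering keeps the lower-p signal in the worked chain", {
  snps <- tibble::tibble(snp_id = c("a", "b", "c"), chromosome = "chr1",
                         position = c(0L, 300000L, 600000L),
                         p_value = c(1e-9, 1e-4, 1e-6))
  expect_setequal(distance_filter(snps, min_kb = 500), c("a", "c"))
  multi <- tibble::tibble(snp_id = c("a", "b"), chromosome = c("chr1", "chr2"),
                          position = c(0L, 1000L), p_value = c(1e-3, 1e-2))
  expect_setequal(distance_filter(multi, min_kb = 500), c("a", "b"))
  expect_identical(formals(distance_filter)$min_kb, 500)
})

test_that("clump and distance filters match brute-force oracles on fuzzed instances", {
  set.seed(5)
  for (i in 1:120) {
    n_snp <- sample(2:50, 1)
    n <- 60
    dos <- matrix(sample(0:2, n * n_snp, TRUE), n, n_snp)
    # inject LD by duplicating some columns with noise
    if (n_snp > 3) {
      for (k in sample(n_snp, min(4, n_snp %/% 2))) {
        src <- sample(n_snp, 1)
        flip <- sample(n, 6)
        dos[, k] <- dos[, src]
        dos[flip, k] <- sample(0:2, 6, TRUE)
      }
    }
    dos[, 1] <- sample(0:2, n, TRUE)  # guard against all-constant
    keep_poly <- apply(dos, 2, var) > 0
    dos <- dos[, keep_poly, drop = FALSE]
    n_snp <- ncol(dos)
    if (n_snp < 2) next
    chrom <- paste0("chr", sample(1:2, n_snp, TRUE))
    pos <- sample.int(2e6, n_snp)
    panel <- panel_from_matrix(dos, positions = pos, chromosome = chrom)
    p <- signif(runif(n_snp), 3)
    gwas <- tibble::tibble(snp_id = panel$snps$snp_id, effect_allele = "A",
                           beta = rnorm(n_snp), se = 0.1, p_value = p,
                           n_used = n, monomorphic = FALSE)
    r2_tab <- cor(dos)^2
    dimnames(r2_tab) <- list(panel$snps$snp_id, panel$snps$snp_id)
    thr <- sample(c(0.2, 0.5, 0.8), 1)
    win <- sample(c(100, 500, 1500), 1)
    expect_identical(
      sort(ld_clump(gwas, panel, thr, win)),
      sort(clump_oracle(p, pos, chrom, panel$snps$snp_id, r2_tab, thr, win * 1000)))
    expect_identical(
      sort(distance_filter(tibble::tibble(snp_id = panel$snps$snp_id,
                                          chromosome = chrom, position = pos,
                                          p_value = p), win)),
      sort(distance_oracle(p, pos, chrom, panel$snps$snp_id, win * 1000)))
  }
})

test_that("clump output is invariant to input row order", {
  panel <- simulate_genotypes(800, ld_block_spec(n_snps = 30, block_size = 3), seed = 6)
  y <- rnorm(800)
  gwas <- run_gwas(panel, y)
  k1 <- ld_clump(gwas, panel, 0.5, 500)
  k2 <- ld_clump(gwas[sample(nrow(gwas)), ], panel, 0.5, 500)
  expect_identical(sort(k1), sort(k2))
})

test_that("ridge weights equal marginal betas in the LD-free small-lambda limit", {
  panel <- simulate_genotypes(4000, ld_block_spec(n_snps = 20, block_size = 1,
                                                  within_block_rho = 0), seed = 7)
  set.seed(8)
  beta_true <- rnorm(20, 0, 0.1)
  y <- as.numeric(panel$dosages %*% beta_true) + rnorm(4000)
  names(y) <- panel$sample_ids
  sp <- split_samples(panel$sample_ids, seed = 9)
  gwas <- run_gwas(panel, y, sp$train)
  w <- fit_pgs_weights(gwas, panel, y, sp$validation,
                       hyper = list(lambda_grid = 1e-8, window_snps = 20))
  # with R ~ I and lambda ~ 0 the joint solve returns the marginals
  expect_lt(max(abs(w$weight - gwas$beta)), 0.05)
})

test_that("2-SNP ridge window matches the closed-form 2x2 solve", {
  spec <- ld_block_spec(n_snps = 2, block_size = 2, within_block_rho = 0.8,
                        maf_range = c(0.3, 0.3))
  panel <- simulate_genotypes(5000, spec, seed = 10)
  set.seed(11)
  y <- 0.3 * panel$dosages[, 1] + rnorm(5000)
  names(y) <- panel$sample_ids
  sp <- split_samples(panel$sample_ids, seed = 12)
  gwas <- run_gwas(panel, y, sp$train)
  lam <- 0.5
  w <- fit_pgs_weights(gwas, panel, y, sp$validation,
                       hyper = list(lambda_grid = lam, window_snps = 2))
  # direct 2x2 oracle
  n <- attr(gwas, "n")
  tv <- gwas$beta / gwas$se
  r_marg <- tv / sqrt(n - 2 + tv^2)
  R <- cor(panel$dosages)
  sol <- solve(R + diag(lam, 2), r_marg)
  oracle <- unname(sol * gwas$beta / r_marg)
  expect_equal(w$weight, oracle, tolerance = 1e-10)
})

test_that("shrunk scoring beats unshrunk marginals on the joint-tagging panel", {
  wins <- 0
  for (s in 1:5) {
    panel <- simulate_genotypes(4000, ld_block_spec(n_snps = 60, block_size = 5,
                                                    within_block_rho = 0.9), seed = 20 + s)
    arch <- draw_architecture(panel, "additive", 20, seed = 30 + s)
    ph <- simulate_phenotype(panel, arch)
    y <- stats::setNames(ph$y, ph$sample_id)
    red <- reduce_panel_joint_tagging(panel, arch$causal_ids, seed = 40 + s)
    obs <- red$panel
    sp <- split_samples(panel$sample_ids, seed = 50 + s)
    gwas <- run_gwas(obs, y, sp$train)
    w <- fit_pgs_weights(gwas, obs, y, sp$validation, hyper = list(window_snps = 20))
    marg <- w
    marg$weight <- ifelse(is.na(gwas$beta), 0, gwas$beta)
    r2_ridge <- cor(score_pgs(obs, w)[sp$validation], y[sp$validation])^2
    r2_marg <- cor(score_pgs(obs, marg)[sp$validation], y[sp$validation])^2
    wins <- wins + (r2_ridge > r2_marg)
  }
  expect_gte(wins, 4)
})

test_that("scoring is a dot product with allele-flip identity and linearity", {
  dos <- cbind(c(0L, 1L, 2L), c(2L, 0L, 1L), c(1L, 1L, 0L))
  panel <- panel_from_matrix(dos)
  ids <- panel$snps$snp_id
  w0 <- nnpgs:::new_pgs_weight_set(ids, rep("A", 3), rep("G", 3), c(0, 0, 0))
  expect_equal(unname(score_pgs(panel, w0)), c(0, 0, 0))

  w1 <- nnpgs:::new_pgs_weight_set(ids[1], "A", "G", 1)
  expect_equal(unname(score_pgs(panel, w1)), c(0, 1, 2))
  # forced dot product: dosages [0,1,2] with weights [0.5, -1, 0.25]
  wv <- c(0.5, -1, 0.25)
  wall <- nnpgs:::new_pgs_weight_set(ids, rep("A", 3), rep("G", 3), wv)
  expect_equal(unname(score_pgs(panel, wall)), as.numeric(dos %*% wv))

  # swapped alleles flip the dosage contribution to 2 - dosage
  wsw <- nnpgs:::new_pgs_weight_set(ids, c("G", "A", "A"), c("A", "G", "G"), wv)
  flipped <- dos; flipped[, 1] <- 2L - dos[, 1]
  expect_equal(unname(score_pgs(panel, wsw)), as.numeric(flipped %*% wv))

  # linearity in the weights
  set.seed(13)
  wa <- nnpgs:::new_pgs_weight_set(ids, rep("A", 3), rep("G", 3), rnorm(3))
  wb <- nnpgs:::new_pgs_weight_set(ids, rep("A", 3), rep("G", 3), rnorm(3))
  wab <- wa; wab$weight <- wa$weight + wb$weight
  expect_equal(score_pgs(panel, wab), score_pgs(panel, wa) + score_pgs(panel, wb),
               tolerance = 1e-12)

  stray <- nnpgs:::new_pgs_weight_set(c(ids[1], "snp_xx"), c("A", "A"), c("G", "G"),
                                      c(1, 1))
  expect_warning(score_pgs(panel, stray), "not matched")
  none <- nnpgs:::new_pgs_weight_set("snp_xx", "A", "G", 1)
  expect_error(score_pgs(panel, none), "no scoring-file SNP")
})

test_that("scoring files parse minimal and commented inputs and round-trip", {
  f <- tempfile()
  writeLines(c("rsID\teffect_allele\tother_allele\teffect_weight",
               "rs1\tA\tG\t0.123"), f)
  ws <- parse_scoring_file(f)
  expect_equal(nrow(ws), 1)
  expect_equal(ws$weight, 0.123)

  f2 <- tempfile()
  writeLines(c("## PGS metadata", "#trait=example",
               "rsID\teffect_allele\tother_allele\teffect_weight",
               "rs1\tA\tG\t0.5", "rs2\tG\tA\t-0.25"), f2)
  ws2 <- parse_scoring_file(f2)
  expect_equal(ws2$weight, c(0.5, -0.25))

  f3 <- tempfile()
  writeLines(c("rsID\teffect_weight", "rs1\t0.1"), f3)
  expect_error(parse_scoring_file(f3), "effect_allele")
  f4 <- tempfile()
  writeLines(c("rsID\teffect_allele\teffect_weight", "rs1\tA\tnot_a_number"), f4)
  expect_error(parse_scoring_file(f4), "line 2")

  set.seed(14)
  big <- nnpgs:::new_pgs_weight_set(sprintf("rs%04d", 1:1000),
                                    sample(c("A", "C"), 1000, TRUE),
                                    sample(c("G", "T"), 1000, TRUE),
                                    rnorm(1000))
  f5 <- tempfile()
  write_scoring_file(big, f5, metadata = c(method = "test"))
  back <- parse_scoring_file(f5)
  expect_identical(back$snp_id, big$snp_id)
  expect_identical(back$weight, big$weight)  # bit-identical numerics
  expect_identical(back$effect_allele, big$effect_allele)
})

test_that("covariate baseline retains a perfect predictor and calibrates on noise", {
  set.seed(15)
  n <- 5000
  pgs <- rnorm(n)
  covs <- simulate_covariates(n, list(numeric = 20), seed = 16)
  y <- 0.5 * pgs + 2 * covs$num1 + rnorm(n, 0, 0.1)
  fitted <- fit_covariate_baseline(pgs, covs, y)
  expect_true("num1" %in% fitted$retained)
  expect_lt(fitted$screening$min_p[fitted$screening$covariate == "num1"], 1e-100)

  # pure-noise covariates: retention fraction approximately alpha
  y_null <- 0.5 * pgs + rnorm(n)
  fit_null <- fit_covariate_baseline(pgs, covs, y_null)
  # 20 null covariates, alpha = 0.05: expect about 1 retained; allow 3 sd
  expect_lte(length(fit_null$retained), 1 + 3 * sqrt(20 * 0.05 * 0.95))
  expect_identical(formals(fit_covariate_baseline)$alpha, 0.05)

  g <- glance(fitted)
  expect_gt(g$r_squared, 0.9)
  td <- tidy(fitted)
  expect_true(".pgs" %in% td$term)
})

test_that("covariate baseline handles factors, logistic family and no-retention", {
  set.seed(17)
  n <- 2000
  covs <- simulate_covariates(n, list(numeric = 2, factor_levels = 3), seed = 18)
  pgs <- rnorm(n)
  shift <- c(A = -1, B = 0, C = 1)[as.character(covs$fac1)]
  y <- pgs + shift + rnorm(n, 0, 0.5)
  fit <- fit_covariate_baseline(pgs, covs, y)
  expect_true("fac1" %in% fit$retained)

  yb <- as.integer(y + rnorm(n) > 0)
  fitb <- fit_covariate_baseline(pgs, covs, yb, family = "logistic")
  expect_identical(fitb$family, "logistic")
  expect_true(glance(fitb)$deviance_explained > 0)

  y_pure <- pgs + rnorm(n, 0, 0.1)
  covs2 <- simulate_covariates(n, list(numeric = 1), seed = 19)
  fit2 <- fit_covariate_baseline(pgs, covs2, y_pure)
  # no covariate retained -> model reduces to PGS-only and stays valid
  if (length(fit2$retained) == 0) {
    expect_setequal(tidy(fit2)$term, c("(Intercept)", ".pgs"))
  }
  expect_warning(
    fit_covariate_baseline(pgs, dplyr::mutate(covs2, cst = 1), y_pure),
    "constant")
})

test_that("gwas summary TSV round-trips", {
  panel <- simulate_genotypes(200, ld_block_spec(n_snps = 8, block_size = 2), seed = 20)
  g <- run_gwas(panel, rnorm(200))
  f <- tempfile(fileext = ".tsv")
  write_gwas_summary(g, f)
  back <- read_gwas_summary(f)
  expect_equal(back$beta, g$beta, tolerance = 1e-12)
  expect_equal(back$p_value, g$p_value, tolerance = 1e-12)
})
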