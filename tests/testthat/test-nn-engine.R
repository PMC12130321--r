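test_that("design matrix applies z-scores, weighting and one-hot expansion", {
  # training-column z-scores with population sd
  covs <- tibble::tibble(sample_id = c("a", "b", "c"), num1 = c(1, 2, 3))
  mi <- build_design_matrix(covariates = covs, train_ids = c("a", "b", "c"))
  expect_equal(as.numeric(mi$X[, "num1"]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  # SNP weighting: dosage 2 x weight 0.3 -> 0.6; unit weights -> raw dosages
  dos <- cbind(c(0L, 1L, 2L), c(2L, 1L, 0L))
  panel <- panel_from_matrix(dos)
  ids <- panel$snps$snp_id
  w_unit <- nnpgs:::new_pgs_weight_set(ids, rep("A", 2), rep("G", 2), c(1, 1))
  mi_u <- build_design_matrix(panel = panel, weights = w_unit,
                              weighting_enabled = TRUE, train_ids = "id_000001")
  expect_equal(unname(mi_u$X), unname(matrix(as.double(dos), 3, 2)))
  expect_true(all(mi_u$col_meta$type == "weighted_snp"))

  w3 <- nnpgs:::new_pgs_weight_set(ids, rep("A", 2), rep("G", 2), c(0.3, 1))
  mi_w <- build_design_matrix(panel = panel, weights = w3,
                              weighting_enabled = TRUE, train_ids = "id_000001")
  expect_equal(mi_w$X[3, 1], 2 * 0.3)

  # one-hot keeps every level; missing values become an explicit level
  covs2 <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                          fac = factor(c("x", "y", NA, "x")))
  mi2 <- build_design_matrix(covariates = covs2, train_ids = c("a", "b"))
  onehot <- mi2$X[, grepl("^fac", colnames(mi2$X))]
  expect_equal(ncol(onehot), 3)  # x, y, (missing)
  expect_true(all(rowSums(onehot) == 1))
  expect_true(all(mi2$col_meta$type[grepl("^fac", mi2$col_meta$column)] == "onehot_cov"))

  covs3 <- tibble::tibble(sample_id = c("a", "b", "c"), num1 = c(1, 2, 5),
                          cst = c(1, 1, 1))
  expect_warning(mi3 <- build_design_matrix(covariates = covs3,
                                            train_ids = c("a", "b", "c")),
                 "constant")
  expect_identical(colnames(mi3$X), "num1")
})

test_that("network presets and parameter counts match a shape-walk oracle", {
  large <- nn_config_large()
  small <- nn_config_small()
  expect_identical(large$hidden_sizes, c(100L, 50L, 25L))
  expect_identical(small$hidden_sizes, c(24L, 12L, 6L))
  expect_identical(large$batch_size, 32L)
  expect_equal(large$dropout_rate, 0.3)
  expect_equal(large$learning_rate, 0.001)
  expect_identical(large$patience_epochs, 12L)
  expect_identical(large$activation, "softplus")
  expect_identical(large$optimizer, "sgd")
  expect_true(large$batch_norm)

  net <- build_network(10, large)
  # independent shape walk: W + b (+ gamma + beta) per hidden layer, then output
  dims <- c(10, 100, 50, 25)
  oracle <- 0
  for (l in 1:3) oracle <- oracle + dims[l] * dims[l + 1] + 3 * dims[l + 1]
  oracle <- oracle + 25 + 1
  expect_equal(nnpgs:::n_parameters(net), oracle)
  expect_identical(glance(net)$n_parameters, oracle)
  expect_equal(nrow(tidy(net)), 3)
})

test_that("an activation-free network collapses to a single affine map", {
  set.seed(30)
  for (bn in c(TRUE, FALSE)) {
    cfg <- nn_config(hidden_sizes = c(7, 5), nonlinear = FALSE, batch_norm = bn,
                     dropout_rate = 0, max_epochs = 8, patience_epochs = 8,
                     seed = 31)
    X <- matrix(rnorm(600), 100, 6)
    y <- rnorm(100)
    net <- train_network(build_network(6, cfg), X, y,
                         list(train = 1:70, validation = 71:100), cfg)
    cl <- collapse_to_linear(net)
    pred <- predict(net, X)
    expect_lt(max(abs(pred - (X %*% cl$w + cl$intercept))), 1e-5)
  }
  # single hidden layer without batch norm: W_all = W1 %*% w_out exactly
  cfg1 <- nn_config(hidden_sizes = 4, nonlinear = FALSE, batch_norm = FALSE,
                    dropout_rate = 0, seed = 32)
  net1 <- build_network(3, cfg1)
  cl1 <- collapse_to_linear(net1)
  expect_equal(cl1$w, as.numeric(net1$layers[[1]]$W %*% net1$w_out))

  nl <- build_network(3, nn_config(hidden_sizes = 4, seed = 33))
  expect_error(collapse_to_linear(nl), "activation-free")
})

test_that("collapse identity survives nontrivial batch-norm statistics", {
  set.seed(34)
  cfg <- nn_config(hidden_sizes = c(12, 6), nonlinear = FALSE, dropout_rate = 0.2,
                   max_epochs = 15, patience_epochs = 15, seed = 35)
  X <- matrix(rnorm(3000), 300, 10)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(300)
  net <- train_network(build_network(10, cfg), X, y,
                       list(train = 1:200, validation = 201:300), cfg)
  expect_gt(max(abs(net$layers[[1]]$run_mean)), 0)  # stats actually moved
  cl <- collapse_to_linear(net)
  Xnew <- matrix(rnorm(500), 50, 10)
  expect_lt(max(abs(predict(net, Xnew) - (Xnew %*% cl$w + cl$intercept))), 1e-5)
})

test_that("inference is deterministic and a zero input walks the bias path", {
  cfg <- nn_config(hidden_sizes = c(5, 3), batch_norm = FALSE, dropout_rate = 0.5,
                   seed = 36)
  net <- build_network(4, cfg)
  X <- matrix(rnorm(40), 10, 4)
  expect_identical(predict(net, X), predict(net, X))

  # hand forward pass for an all-zero input through the initialized net:
  # biases are zero, so pre-activations are 0, softplus(0) = log(2)
  x0 <- matrix(0, 1, 4)
  h1 <- rep(log(2), 5)
  h2 <- nnpgs:::softplus(as.numeric(h1 %*% net$layers[[2]]$W))
  oracle <- sum(h2 * net$w_out)
  expect_equal(predict(net, x0), oracle, tolerance = 1e-12)

  expect_error(predict(net, matrix(0, 2, 5)), "expects")
})

test_that("training recovers a noiseless linear signal and is reproducible", {
  set.seed(37)
  n <- 5000; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% rnorm(p, 0, 0.3))
  cfg <- nn_config_small(nonlinear = FALSE, dropout_rate = 0,
                         patience_epochs = 12, max_epochs = 120, seed = 38)
  splits <- list(train = 1:3000, validation = 3001:4000)
  net <- train_network(build_network(p, cfg), X, y, splits, cfg)
  pred <- predict(net, X[4001:5000, ])
  expect_gte(r_squared(y[4001:5000], pred), 0.99)

  net2 <- train_network(build_network(p, cfg), X, y, splits, cfg)
  expect_identical(net$val_trajectory, net2$val_trajectory)
  expect_identical(net$layers[[1]]$W, net2$layers[[1]]$W)
})

test_that("a trained linear network approaches the closed-form fit", {
  # matched design: n = 5000, p = 200, h2 = 0.5, no LD; 3 seeds
  for (s in 1:3) {
    set.seed(400 + s)
    n <- 5000; p <- 200
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p)
    g <- as.numeric(X %*% beta)
    g <- g / sd(g) * sqrt(0.5)
    y <- g + rnorm(n, 0, sqrt(0.5))
    tr <- 1:3000; va <- 3001:4000; te <- 4001:5000
    cfg <- nn_config_small(nonlinear = FALSE, dropout_rate = 0,
                           patience_epochs = 30, max_epochs = 200, seed = s)
    net <- train_network(build_network(p, cfg), X, y,
                         list(train = tr, validation = va), cfg)
    r2_net <- r_squared(y[te], predict(net, X[te, ]))
    ols <- lm.fit(cbind(1, X[tr, ]), y[tr])
    r2_ols <- r_squared(y[te], as.numeric(cbind(1, X[te, ]) %*% ols$coefficients))
    expect_lt(abs(r2_net - r2_ols), 0.02)
  }
})

test_that("early stopping respects patience and the halved-lr retrain rule fires", {
  set.seed(39)
  X <- matrix(rnorm(2000), 200, 10)
  y <- rnorm(200)  # pure noise: validation r2 cannot improve for long
  cfg <- fast_nn(patience_epochs = 5, max_epochs = 100, seed = 40)
  net <- train_network(build_network(10, cfg), X, y,
                       list(train = 1:140, validation = 141:200), cfg)
  expect_lte(length(net$val_trajectory), 100)
  expect_gte(length(net$val_trajectory) - net$best_epoch, 0)

  # force best epoch 1 via a single-epoch budget: the rule must retrain once
  cfg1 <- fast_nn(max_epochs = 1, seed = 41)
  net1 <- train_network(build_network(10, cfg1), X, y,
                        list(train = 1:140, validation = 141:200), cfg1)
  expect_false(net1$retrained)  # max_epochs 1 cannot retrain

  cfg2 <- fast_nn(patience_epochs = 1, max_epochs = 30, seed = 42)
  net2 <- train_network(build_network(10, cfg2), X, y,
                        list(train = 1:140, validation = 141:200), cfg2)
  if (net2$best_epoch == 1) {
    expect_true(net2$retrained || net2$best_epoch > 1)
  }
  expect_equal(cfg2$learning_rate / ifelse(net2$retrained, 2, 1), net2$lr_used)
})

test_that("oversampling presents cases and controls 50:50", {
  set.seed(43)
  n <- 4000
  X <- matrix(rnorm(n * 8), n, 8)
  liab <- as.numeric(X %*% rnorm(8)) + rnorm(n)
  lab <- binarize_liability(liab, prevalence = 0.1)
  cfg <- fast_nn(oversample_binary = TRUE, max_epochs = 5, patience_epochs = 5,
                 seed = 44)
  net <- train_network(build_network(8, cfg), X, lab,
                       list(train = 1:2400, validation = 2401:3200), cfg)
  expect_length(net$case_fraction, length(net$val_trajectory))
  expect_true(all(abs(net$case_fraction - 0.5) < 0.05))
  expect_true(net$binary)
  # predictions are probabilities
  pr <- predict(net, X[3201:4000, ])
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("nonlinear networks exploit a pure 2-SNP product where linear ones cannot", {
  gaps <- numeric(5)
  for (s in 1:5) {
    set.seed(500 + s)
    n <- 12000
    panel <- simulate_genotypes(n, ld_block_spec(n_snps = 6, block_size = 1,
                                                 maf_range = c(0.4, 0.5)), seed = 500 + s)
    z <- scale(panel$dosages)
    y <- z[, 1] * z[, 2]
    y <- as.numeric(y / sd(y) * sqrt(0.7) + rnorm(n, 0, sqrt(0.3)))
    splits <- list(train = 1:7200, validation = 7201:9600)
    te <- 9601:12000
    r2 <- c()
    for (nl in c(TRUE, FALSE)) {
      cfg <- nn_config_small(nonlinear = nl, dropout_rate = 0,
                             patience_epochs = 15, max_epochs = 80, seed = s)
      net <- train_network(build_network(6, cfg), panel$dosages, y, splits, cfg)
      r2[ifelse(nl, "nl", "lin")] <- r_squared(y[te], predict(net, panel$dosages[te, ]))
    }
    gaps[s] <- r2["nl"] - r2["lin"]
  }
  ht <- paired_t(gaps)
  expect_gt(ht$mean_gap, 0)
  expect_lt(ht$p_value, 0.05)
})

test_that("model selection picks the higher validation r2 and breaks ties small", {
  set.seed(45)
  X <- matrix(rnorm(1500), 150, 10)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(150, 0, 0.3)
  splits <- list(train = 1:90, validation = 91:120)
  cfg_l <- nn_config_large(dropout_rate = 0, max_epochs = 15, patience_epochs = 15,
                           nonlinear = FALSE, seed = 46)
  cfg_s <- nn_config_small(dropout_rate = 0, max_epochs = 15, patience_epochs = 15,
                           nonlinear = FALSE, seed = 46)
  large <- train_network(build_network(10, cfg_l), X, y, splits, cfg_l)
  small <- train_network(build_network(10, cfg_s), X, y, splits, cfg_s)
  chosen <- select_network(large, small, X, y, 91:120)
  r2s <- attr(chosen, "validation_r2")
  want <- if (r2s[["large"]] > r2s[["small"]]) "large" else "small"
  got <- if (identical(chosen$config$hidden_sizes, c(100L, 50L, 25L))) "large" else "small"
  expect_identical(got, want)
  # swapping the arguments must flip nothing but the labels
  chosen2 <- select_network(small, large, X, y, 91:120)
  expect_identical(
    if (identical(chosen2$config$hidden_sizes, c(100L, 50L, 25L))) "large" else "small",
    want)
  # exact tie goes to the smaller network
  tie <- select_network(small, small, X, y, 91:120)
  expect_identical(tie$config$hidden_sizes, c(24L, 12L, 6L))
})

test_that("network checkpoints and training logs round-trip", {
  set.seed(47)
  X <- matrix(rnorm(800), 100, 8)
  y <- rnorm(100)
  cfg <- fast_nn(seed = 48)
  net <- train_network(build_network(8, cfg), X, y,
                       list(train = 1:70, validation = 71:100), cfg)
  f <- tempfile(fileext = ".json")
  save_network(net, f)
  back <- load_network(f)
  expect_equal(predict(back, X), predict(net, X), tolerance = 1e-12)
  expect_equal(back$best_epoch, net$best_epoch)

  lg <- tempfile(fileext = ".tsv")
  write_training_log(net, lg)
  log <- readr::read_tsv(lg, show_col_types = FALSE)
  expect_equal(nrow(log), length(net$val_trajectory))
  expect_equal(log$val_r2, net$val_trajectory, tolerance = 1e-12)
})
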