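#' Neural-network configuration
#'
#' Holds the multilayer-perceptron hyperparameters. The defaults are the
#' fixed training recipe used throughout: three fully-connected hidden
#' layers, batch size 32, dropout 0.3, learning rate 0.001, batch
#' normalisation enabled, softplus activation and plain stochastic
#' gradient descent, with early stopping after 12 epochs without
#' validation improvement. `nonlinear = FALSE` removes the activation
#' functions — and nothing else — turning the network into its matched
#' linear control (see [collapse_to_linear()]).
#'
#' @param hidden_sizes Hidden-layer widths; `nn_config_large()` uses
#'   `c(100, 50, 25)` and `nn_config_small()` `c(24, 12, 6)`.
#' @param nonlinear Whether activation functions are enabled.
#' @param activation Activation name; only `"softplus"` is implemented.
#' @param dropout_rate Dropout probability in `[0, 1)` (applied after each
#'   hidden activation during training; inactive at inference).
#' @param learning_rate SGD step size (> 0).
#' @param batch_size Mini-batch size.
#' @param batch_norm Whether batch normalisation follows each hidden
#'   affine map (affine at inference, so the linear variant stays linear).
#' @param optimizer Only `"sgd"` is implemented.
#' @param patience_epochs Early-stopping patience (epochs without
#'   validation improvement).
#' @param max_epochs Safety bound on training length.
#' @param oversample_binary For 0/1 traits, present cases and controls
#'   50:50 per batch (sampled with replacement within an epoch).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An `nn_config` object.
#' @export
nn_config <- function(hidden_sizes = c(100, 50, 25), nonlinear = TRUE,
                      activation = "softplus", dropout_rate = 0.3,
                      learning_rate = 0.001, batch_size = 32,
                      batch_norm = TRUE, optimizer = "sgd",
                      patience_epochs = 12, max_epochs = 200,
                      oversample_binary = FALSE, seed = 1L) {
  assert_that(length(hidden_sizes) >= 1 && all(hidden_sizes >= 1),
              "`hidden_sizes` must be a non-empty vector of positive widths")
  assert_that(dropout_rate >= 0 && dropout_rate < 1, "`dropout_rate` must be in [0, 1)")
  assert_that(learning_rate > 0, "`learning_rate` must be > 0")
  assert_that(identical(activation, "softplus"), "only the softplus activation is implemented")
  assert_that(identical(optimizer, "sgd"), "only plain SGD is implemented")
  assert_that(batch_size >= 2, "`batch_size` must be >= 2")
  assert_that(patience_epochs >= 1 && max_epochs >= 1,
              "`patience_epochs` and `max_epochs` must be >= 1")
  structure(
    list(hidden_sizes = as.integer(hidden_sizes), nonlinear = nonlinear,
         activation = activation, dropout_rate = dropout_rate,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         batch_norm = batch_norm, optimizer = optimizer,
         patience_epochs = as.integer(patience_epochs),
         max_epochs = as.integer(max_epochs),
         oversample_binary = oversample_binary, seed = as.integer(seed)),
    class = "nn_config")
}

#' @rdname nn_config
#' @param ... Overrides passed on to [nn_config()].
#' @export
nn_config_large <- function(...) {
  do.call(nn_config, utils::modifyList(list(hidden_sizes = c(100, 50, 25)), list(...)))
}

#' @rdname nn_config
#' @export
nn_config_small <- function(...) {
  do.call(nn_config, utils::modifyList(list(hidden_sizes = c(24, 12, 6)), list(...)))
}

#' Assemble the network design matrix
#'
#' Concatenates `[SNP block | PGS column | covariate block]` with the
#' preprocessing the networks expect: SNP dosages are multiplied by their
#' per-SNP weights when `weighting_enabled` (the joint-tagging mitigation
#' input), the PGS column and numeric covariates are z-scored (population
#' SD) using statistics computed on the training samples only, factor
#' covariates are expanded to a full one-hot block (no reference level
#' dropped; missing values become an explicit level), and missing numeric
#' values are imputed to the training mean.
#'
#' @param panel Optional `genotype_panel` supplying the SNP block.
#' @param weights Optional `pgs_weight_set`; required when
#'   `weighting_enabled`.
#' @param covariates Optional covariate tibble with `sample_id`.
#' @param pgs_scores Optional named per-sample score vector, added as one
#'   z-scored column.
#' @param weighting_enabled Multiply SNP dosages by matched per-SNP
#'   weights (allele-flipped where needed).
#' @param train_ids Sample ids defining the standardization statistics.
#' @return A `model_input`: the design matrix, per-column metadata
#'   (`weighted_snp`, `raw_snp`, `pgs`, `numeric_cov`, `onehot_cov`), the
#'   sample ids and the frozen training statistics.
#' @export
build_design_matrix <- function(panel = NULL, weights = NULL, covariates = NULL,
                                pgs_scores = NULL, weighting_enabled = FALSE,
                                train_ids) {
  blocks <- list(); meta <- list()
  sample_ids <- NULL

  if (!is.null(panel)) {
    sample_ids <- panel$sample_ids
    snp_block <- panel$dosages
    storage.mode(snp_block) <- "double"
    type <- "raw_snp"
    if (weighting_enabled) {
      if (is.null(weights)) abort("`weighting_enabled` requires a pgs_weight_set")
      m <- match(panel$snps$snp_id, weights$snp_id)
      aligned <- !is.na(m) & panel$snps$effect_allele == weights$effect_allele[m]
      swapped <- !is.na(m) & !aligned &
        panel$snps$effect_allele == weights$other_allele[m]
      keep <- aligned | swapped
      if (!any(keep)) abort("no panel SNP matches the weight set")
      if (any(!keep)) {
        warn(sprintf("%d panel SNP(s) without a matched weight were dropped", sum(!keep)))
      }
      w <- numeric(ncol(snp_block))
      w[aligned] <- weights$weight[m[aligned]]
      w[swapped] <- -weights$weight[m[swapped]]  # flip: w*(2-x) = const - w*x
      snp_block <- sweep(snp_block[, keep, drop = FALSE], 2, w[keep], "*")
      type <- "weighted_snp"
    }
    blocks <- c(blocks, list(snp_block))
    meta <- c(meta, list(tibble::tibble(column = colnames(snp_block), type = type)))
  }

  train_stats <- list()
  if (!is.null(pgs_scores)) {
    if (is.null(sample_ids)) sample_ids <- names(pgs_scores)
    v <- as.numeric(pgs_scores[sample_ids])
    mu <- mean(v[sample_ids %in% train_ids]); s <- pop_sd(v[sample_ids %in% train_ids])
    if (s == 0) abort("PGS column is constant on the training split")
    blocks <- c(blocks, list(matrix((v - mu) / s, ncol = 1, dimnames = list(NULL, "pgs"))))
    meta <- c(meta, list(tibble::tibble(column = "pgs", type = "pgs")))
    train_stats$pgs <- c(mean = mu, sd = s)
  }

  if (!is.null(covariates)) {
    if (is.null(sample_ids)) sample_ids <- covariates$sample_id
    cov <- covariates[match(sample_ids, covariates$sample_id), , drop = FALSE]
    in_train <- sample_ids %in% train_ids
    for (col in setdiff(names(cov), "sample_id")) {
      v <- cov[[col]]
      if (is.factor(v) || is.character(v)) {
        v <- as.character(v)
        v[is.na(v)] <- "(missing)"
        levs <- sort(unique(v))
        onehot <- matrix(0, length(v), length(levs),
                         dimnames = list(NULL, paste0(col, ".", levs)))
        onehot[cbind(seq_along(v), match(v, levs))] <- 1
        blocks <- c(blocks, list(onehot))
        meta <- c(meta, list(tibble::tibble(column = colnames(onehot), type = "onehot_cov")))
        train_stats[[col]] <- levs
      } else {
        v <- as.numeric(v)
        mu <- mean(v[in_train], na.rm = TRUE)
        v[is.na(v)] <- mu
        s <- pop_sd(v[in_train])
        if (s == 0) {
          warn(sprintf("covariate '%s' is constant on the training split; dropped", col))
          next
        }
        blocks <- c(blocks, list(matrix((v - mu) / s, ncol = 1,
                                        dimnames = list(NULL, col))))
        meta <- c(meta, list(tibble::tibble(column = col, type = "numeric_cov")))
        train_stats[[col]] <- c(mean = mu, sd = s)
      }
    }
  }

  if (length(blocks) == 0) abort("no input blocks supplied")
  X <- do.call(cbind, blocks)
  rownames(X) <- sample_ids
  structure(
    list(X = X, col_meta = dplyr::bind_rows(meta), sample_ids = sample_ids,
         train_ids = train_ids, train_stats = train_stats),
    class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  tab <- table(x$col_meta$type)
  cat(sprintf("<model_input> %d samples x %d columns (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

init_layer_params <- function(fan_in, fan_out) {
  sd <- sqrt(2 / (fan_in + fan_out))
  list(W = matrix(rnorm(fan_in * fan_out, 0, sd), fan_in, fan_out),
       b = rep(0, fan_out), gamma = rep(1, fan_out), beta = rep(0, fan_out),
       run_mean = rep(0, fan_out), run_var = rep(1, fan_out))
}

#' Build an (untrained) network
#'
#' Constructs the fully-connected stack `input_dim -> hidden_sizes -> 1`
#' with seeded Glorot-style initialization. Activations sit between layers
#' iff `config$nonlinear`; dropout and batch normalisation are present in
#' both the linear and nonlinear variants so that the two differ by the
#' activation functions alone.
#'
#' @param input_dim Number of input columns (>= 1).
#' @param config An [nn_config()].
#' @return An `nn_network` with `trained = FALSE`.
#' @export
build_network <- function(input_dim, config) {
  assert_that(inherits(config, "nn_config"), "`config` must be an nn_config")
  assert_that(input_dim >= 1, "`input_dim` must be >= 1")
  set.seed(config$seed)
  dims <- c(input_dim, config$hidden_sizes)
  layers <- purrr::map(seq_along(config$hidden_sizes),
                       function(l) init_layer_params(dims[l], dims[l + 1]))
  out_fan <- utils::tail(config$hidden_sizes, 1)
  w_out <- rnorm(out_fan, 0, sqrt(2 / (out_fan + 1)))
  structure(
    list(layers = layers, w_out = w_out, b_out = 0,
         nonlinear = config$nonlinear, batch_norm = config$batch_norm,
         input_dim = as.integer(input_dim), config = config,
         trained = FALSE, binary = FALSE, best_epoch = NA_integer_,
         val_trajectory = numeric(0), train_loss = numeric(0),
         case_fraction = numeric(0), lr_used = config$learning_rate,
         retrained = FALSE, col_meta = NULL),
    class = "nn_network")
}

#' @export
print.nn_network <- function(x, ...) {
  cat(sprintf("<nn_network> %s, layers %s -> 1, %s%s\n",
              if (x$nonlinear) "nonlinear (softplus)" else "linear (no activations)",
              paste(c(x$input_dim, purrr::map_int(x$layers, ~ncol(.x$W))), collapse = " -> "),
              if (x$trained) sprintf("trained (best epoch %d, val r2 %.4f)",
                                     x$best_epoch, max(x$val_trajectory))
              else "untrained",
              if (x$retrained) ", retrained at halved learning rate" else ""))
  invisible(x)
}

n_parameters <- function(net) {
  sum(purrr::map_dbl(net$layers, function(l) {
    length(l$W) + length(l$b) + if (net$batch_norm) length(l$gamma) + length(l$beta) else 0
  })) + length(net$w_out) + 1
}

resolve_rows <- function(ids, sample_ids) {
  if (is.character(ids)) {
    idx <- match(ids, sample_ids)
    if (anyNA(idx)) abort("split contains ids absent from the model input")
    idx
  } else as.integer(ids)
}

#' Train a network
#'
#' Mini-batch SGD with the configured hyperparameters. After each epoch
#' the validation r-squared (squared Pearson correlation between
#' prediction and outcome; for binary traits, between predicted
#' probability and label) is recorded; training stops when it has not
#' improved for `patience_epochs` epochs and the best-epoch weights are
#' restored. A model whose best validation performance falls in its very
#' first epoch is re-trained once from scratch with the initial learning
#' rate halved. Loss is mean squared error for continuous traits and
#' cross-entropy for binary ones; binary traits may be oversampled to a
#' 50:50 case:control presentation per batch.
#'
#' @param net An `nn_network` from [build_network()] (supplies the
#'   architecture; training re-initializes from the config seed).
#' @param inputs A `model_input` or plain numeric matrix.
#' @param y Outcome vector aligned to the input rows (0/1 for binary).
#' @param splits List with `train` and `validation` elements: sample ids
#'   (when the input carries ids) or row indices.
#' @param config Optional [nn_config()] override (defaults to the
#'   network's own).
#' @return The trained `nn_network`, including the validation trajectory,
#'   per-epoch training loss and (for oversampled binary traits) the
#'   realized per-epoch case fraction.
#' @export
train_network <- function(net, inputs, y, splits, config = net$config) {
  X <- if (inherits(inputs, "model_input")) inputs$X else as.matrix(inputs)
  sample_ids <- if (inherits(inputs, "model_input")) inputs$sample_ids else rownames(X)
  tr <- resolve_rows(splits$train, sample_ids)
  va <- resolve_rows(splits$validation, sample_ids)
  y <- as.numeric(y)
  assert_that(length(y) == nrow(X), "`y` must align with the input rows")
  if (pop_sd(y[tr]) == 0) abort("training phenotype has zero variance")
  binary <- all(y %in% c(0, 1))

  run_once <- function(lr) {
    fit <- .mlp_train_cpp(
      X, y, tr - 1L, va - 1L, config$hidden_sizes, config$nonlinear,
      config$dropout_rate, lr, config$batch_size, config$batch_norm,
      config$patience_epochs, config$max_epochs, binary,
      binary && config$oversample_binary)
    if (isTRUE(fit$diverged)) {
      abort(sprintf("training diverged (non-finite loss) at epoch %d with lr = %g",
                    fit$epochs_run + 1L, lr))
    }
    fit
  }

  set.seed(config$seed)
  fit <- run_once(config$learning_rate)
  lr_used <- config$learning_rate
  retrained <- FALSE
  if (fit$best_epoch == 1L && config$max_epochs > 1L) {
    # best performance in the very first epoch: one retrain, halved lr
    fit <- run_once(config$learning_rate / 2)
    lr_used <- config$learning_rate / 2
    retrained <- TRUE
  }

  net$layers <- purrr::map(fit$hidden, function(l) {
    list(W = l$W, b = as.numeric(l$b), gamma = as.numeric(l$gamma),
         beta = as.numeric(l$beta), run_mean = as.numeric(l$run_mean),
         run_var = as.numeric(l$run_var))
  })
  net$w_out <- as.numeric(fit$w_out)
  net$b_out <- fit$b_out
  net$input_dim <- ncol(X)
  net$trained <- TRUE
  net$binary <- binary
  net$best_epoch <- fit$best_epoch
  net$val_trajectory <- as.numeric(fit$val_trajectory)
  net$train_loss <- as.numeric(fit$train_loss)
  net$case_fraction <- as.numeric(fit$case_fraction)
  net$lr_used <- lr_used
  net$retrained <- retrained
  net$config <- config
  net$col_meta <- if (inherits(inputs, "model_input")) inputs$col_meta else NULL
  net
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))

forward_pass <- function(net, X) {
  A <- X
  for (l in net$layers) {
    Z <- sweep(A %*% l$W, 2, l$b, "+")
    if (net$batch_norm) {
      s <- l$gamma / sqrt(l$run_var + 1e-5)
      Z <- sweep(sweep(Z, 2, l$run_mean), 2, s, "*")
      Z <- sweep(Z, 2, l$beta, "+")
    }
    A <- if (net$nonlinear) softplus(Z) else Z
  }
  as.numeric(A %*% net$w_out + net$b_out)
}

#' Predict from a trained network
#'
#' Deterministic inference forward pass: dropout off, batch normalisation
#' using its running statistics. Binary networks return predicted
#' probabilities.
#'
#' @param object An `nn_network`.
#' @param newdata A `model_input` or numeric matrix whose columns match
#'   the training design.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.nn_network <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "model_input")) newdata$X else as.matrix(newdata)
  if (ncol(X) != object$input_dim) {
    abort(sprintf("input has %d columns but the network expects %d",
                  ncol(X), object$input_dim))
  }
  if (!is.null(object$col_meta) && !is.null(colnames(X))) {
    mismatch <- colnames(X) != object$col_meta$column
    if (any(mismatch)) {
      abort(sprintf("input column mismatch (first: '%s' vs expected '%s')",
                    colnames(X)[which(mismatch)[1]],
                    object$col_meta$column[which(mismatch)[1]]))
    }
  }
  out <- forward_pass(object, X)
  if (isTRUE(object$binary)) out <- 1 / (1 + exp(-out))
  out
}

#' Collapse an activation-free network to its linear map
#'
#' With activations disabled the layered map is a composition of affine
#' transformations (batch normalisation is affine at inference), so the
#' whole network reduces to a single weight vector and intercept:
#' predictions equal `X %*% w + intercept` exactly. This is the algebraic
#' identity that makes the linear network a valid nonlinearity control.
#'
#' @param net A linear (`nonlinear = FALSE`) `nn_network`.
#' @return A list with `w` (length `input_dim`) and `intercept`.
#' @export
collapse_to_linear <- function(net) {
  if (net$nonlinear) abort("collapse_to_linear() requires an activation-free network")
  M <- NULL; v <- NULL
  for (l in net$layers) {
    W <- l$W; b <- l$b
    if (net$batch_norm) {
      s <- l$gamma / sqrt(l$run_var + 1e-5)
      t_shift <- l$beta - l$run_mean * s
      W <- sweep(W, 2, s, "*")
      b <- b * s + t_shift
    }
    if (is.null(M)) { M <- W; v <- b } else { v <- as.numeric(v %*% W) + b; M <- M %*% W }
  }
  list(w = as.numeric(M %*% net$w_out),
       intercept = as.numeric(v %*% net$w_out) + net$b_out)
}

#' Choose between the large and small network
#'
#' Returns whichever of two trained networks has the higher validation
#' r-squared; an exact tie goes to the smaller model (fewer parameters).
#'
#' @param large,small Trained `nn_network`s fitted on identical inputs and
#'   splits.
#' @param inputs The shared `model_input` (or matrix).
#' @param y Outcome vector.
#' @param validation_ids Validation sample ids or row indices.
#' @return The selected `nn_network`, with attribute
#'   `validation_r2` (named vector for both candidates).
#' @export
select_network <- function(large, small, inputs, y, validation_ids) {
  meta_l <- large$col_meta; meta_s <- small$col_meta
  if (!is.null(meta_l) && !is.null(meta_s) && !identical(meta_l, meta_s)) {
    abort("candidate networks were trained on different input metadata")
  }
  if (large$input_dim != small$input_dim) {
    abort("candidate networks expect different input widths")
  }
  X <- if (inherits(inputs, "model_input")) inputs$X else as.matrix(inputs)
  ids <- if (inherits(inputs, "model_input")) inputs$sample_ids else rownames(X)
  rows <- resolve_rows(validation_ids, ids)
  r2 <- c(large = r_squared(y[rows], predict(large, X[rows, , drop = FALSE])),
          small = r_squared(y[rows], predict(small, X[rows, , drop = FALSE])))
  chosen <- if (r2[["large"]] > r2[["small"]]) large else small
  attr(chosen, "validation_r2") <- r2
  chosen
}

#' Save / load a network checkpoint
#'
#' Plain-text (JSON) serialization of the weights, batch-norm statistics,
#' configuration and column metadata.
#'
#' @param net A trained `nn_network`.
#' @param path File path.
#' @return `path` invisibly; `load_network()` returns the restored
#'   `nn_network`.
#' @export
save_network <- function(net, path) {
  payload <- unclass(net)
  payload$config <- unclass(payload$config)
  payload$col_meta <- if (!is.null(net$col_meta)) as.data.frame(net$col_meta) else NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # layers come back as a data frame of list-columns, one row per layer
  lay <- x$layers
  x$layers <- purrr::map(seq_along(lay$W), function(i) {
    W <- lay$W[[i]]
    if (!is.matrix(W)) W <- matrix(W, nrow = 1)
    list(W = W, b = as.numeric(lay$b[[i]]), gamma = as.numeric(lay$gamma[[i]]),
         beta = as.numeric(lay$beta[[i]]), run_mean = as.numeric(lay$run_mean[[i]]),
         run_var = as.numeric(lay$run_var[[i]]))
  })
  x$config <- do.call(nn_config, x$config[names(x$config) %in% names(formals(nn_config))])
  x$col_meta <- if (!is.null(x$col_meta)) tibble::as_tibble(x$col_meta) else NULL
  structure(x, class = "nn_network")
}

#' Write the per-epoch training log
#'
#' TSV with epoch, training loss, validation r-squared and (when
#' oversampling a binary trait) the realized case fraction.
#'
#' @param net A trained `nn_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(net, path) {
  n <- length(net$val_trajectory)
  log <- tibble::tibble(
    epoch = seq_len(n),
    train_loss = net$train_loss,
    val_r2 = net$val_trajectory)
  if (length(net$case_fraction) == n) log$case_fraction <- net$case_fraction
  readr::write_tsv(log, path)
  invisible(path)
}
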