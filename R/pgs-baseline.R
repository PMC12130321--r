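#' Per-SNP association scan (GWAS)
#'
#' Simple linear regression of the phenotype on each SNP's dosage
#' (intercept included, no covariates), returning per-allele effect,
#' standard error and two-sided p-value. Computed with closed-form
#' least-squares over all SNPs at once.
#'
#' @param panel A `genotype_panel`.
#' @param y Phenotype vector aligned with `panel$sample_ids`, or a
#'   `phenotype_set`.
#' @param subset Optional sample ids to restrict the scan to (e.g. the
#'   training split).
#' @return A `gwas_summary` tibble: `snp_id`, `effect_allele`, `beta`,
#'   `se`, `p_value`, `n_used`, `monomorphic`. Monomorphic SNPs are
#'   flagged and carry `NA` estimates; downstream steps skip them.
#' @export
run_gwas <- function(panel, y, subset = NULL) {
  if (inherits(y, "phenotype_set")) y <- stats::setNames(y$y, y$sample_id)
  if (is.null(names(y))) names(y) <- panel$sample_ids
  ids <- subset %||% panel$sample_ids
  missing_ids <- setdiff(ids, panel$sample_ids)
  if (length(missing_ids) > 0) abort("`subset` contains ids absent from the panel")

  x <- panel$dosages[ids, , drop = FALSE]
  yy <- y[ids]
  n <- length(ids)
  yc <- yy - mean(yy)
  xc <- sweep(x, 2, colMeans(x))
  sxx <- colSums(xc^2)
  sxy <- as.numeric(crossprod(xc, yc))
  syy <- sum(yc^2)

  mono <- unname(sxx == 0)
  sxx <- unname(sxx)
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  sse <- pmax(syy - beta * sxy, 0)
  se <- ifelse(mono, NA_real_, sqrt(sse / (n - 2) / sxx))
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[!mono & se == 0] <- 0  # exact fit underflow

  tibble::new_tibble(
    tibble::tibble(snp_id = panel$snps$snp_id,
                   effect_allele = panel$snps$effect_allele,
                   beta = beta, se = se, p_value = p,
                   n_used = n, monomorphic = mono),
    class = "gwas_summary", n = n)
}

#' Write / read a GWAS summary TSV
#'
#' Columns `snp_id a1 beta se p n`.
#'
#' @param gwas A `gwas_summary`.
#' @param path File path.
#' @return `path` invisibly; the reader returns a `gwas_summary`.
#' @export
write_gwas_summary <- function(gwas, path) {
  readr::write_tsv(
    tibble::tibble(snp_id = gwas$snp_id, a1 = gwas$effect_allele,
                   beta = gwas$beta, se = gwas$se, p = gwas$p_value,
                   n = gwas$n_used),
    path)
  invisible(path)
}

#' @rdname write_gwas_summary
#' @export
read_gwas_summary <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::new_tibble(
    tibble::tibble(snp_id = x$snp_id, effect_allele = x$a1, beta = x$beta,
                   se = x$se, p_value = x$p, n_used = x$n,
                   monomorphic = is.na(x$beta)),
    class = "gwas_summary", n = max(x$n))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the most significant unassigned SNP as an index
#' variant and assigns to its clump every unassigned SNP within
#' `window_kb` on the same chromosome whose dosage r-squared with the
#' index exceeds `r2_threshold`; only index variants are kept. P-value
#' ties break by lower position, then lexicographic SNP id.
#'
#' @param gwas A `gwas_summary`.
#' @param panel The `genotype_panel` the scan was run on (supplies dosage
#'   correlations and positions).
#' @param r2_threshold Clumping r-squared threshold (default 0.5).
#' @param window_kb Clumping window in kilobases (default 500).
#' @return Character vector of retained (index) SNP ids, in selection
#'   order.
#' @export
ld_clump <- function(gwas, panel, r2_threshold = 0.5, window_kb = 500) {
  dat <- dplyr::inner_join(
    dplyr::filter(gwas, !.data$monomorphic, !is.na(.data$p_value)),
    panel$snps[, c("snp_id", "chromosome", "position")], by = "snp_id")
  if (nrow(dat) == 0) return(character(0))
  dat <- dat[order_by_p(dat$p_value, dat$position, dat$snp_id), ]

  assigned <- rep(FALSE, nrow(dat))
  kept <- character(0)
  window_bp <- window_kb * 1000
  while (any(!assigned)) {
    i <- which(!assigned)[1]
    kept <- c(kept, dat$snp_id[i])
    assigned[i] <- TRUE
    cand <- which(!assigned & dat$chromosome == dat$chromosome[i] &
                    abs(dat$position - dat$position[i]) <= window_bp)
    if (length(cand) > 0) {
      r2 <- suppressWarnings(
        cor(panel$dosages[, dat$snp_id[i]],
            panel$dosages[, dat$snp_id[cand], drop = FALSE])^2)
      assigned[cand[!is.na(r2) & r2 > r2_threshold]] <- TRUE
    }
  }
  kept
}

#' Greedy distance filtering
#'
#' Visits SNPs by ascending p-value (ties by position, then id) and keeps
#' a SNP only if no already-kept SNP on the same chromosome lies closer
#' than `min_kb` kilobases — i.e. the lower p-value signal always wins.
#'
#' @param snps A tibble with columns `snp_id`, `chromosome`, `position`,
#'   `p_value`.
#' @param min_kb Minimum allowed distance in kilobases (default 500).
#' @return Character vector of retained SNP ids.
#' @export
distance_filter <- function(snps, min_kb = 500) {
  req <- c("snp_id", "chromosome", "position", "p_value")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols) > 0) {
    abort(sprintf("`snps` lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(snps$position))) abort("missing positions in `snps`")
  dat <- snps[order_by_p(snps$p_value, snps$position, snps$snp_id), ]
  min_bp <- min_kb * 1000
  kept_idx <- integer(0)
  for (i in seq_len(nrow(dat))) {
    same <- kept_idx[dat$chromosome[kept_idx] == dat$chromosome[i]]
    if (length(same) == 0 || all(abs(dat$position[same] - dat$position[i]) >= min_bp)) {
      kept_idx <- c(kept_idx, i)
    }
  }
  dat$snp_id[kept_idx]
}

new_pgs_weight_set <- function(snp_id, effect_allele, other_allele, weight,
                               provenance = list()) {
  assert_that(!anyDuplicated(snp_id), "duplicate snp ids in weight set")
  assert_that(all(is.finite(weight)), "weights must be finite")
  tibble::new_tibble(
    tibble::tibble(snp_id = snp_id, effect_allele = effect_allele,
                   other_allele = other_allele, weight = weight),
    class = "pgs_weight_set", provenance = provenance)
}

#' Fit per-SNP polygenic score weights from summary statistics
#'
#' The LD-aware baseline: within contiguous windows of SNPs, joint
#' standardized effects are obtained as \eqn{(R + \lambda I)^{-1} r},
#' where `R` is the window's dosage correlation matrix and `r` the
#' marginal standardized (correlation-scale) effects recovered from the
#' GWAS t-statistics. The ridge penalty \eqn{\lambda} is selected from a
#' grid by validation-set r-squared of the resulting score. This windowed
#' summary-statistic ridge is the package's LD-aware shrinkage method;
#' every relative metric downstream is defined against it.
#'
#' `method = "clump_threshold"` instead assigns the marginal GWAS betas to
#' LD-clump index variants only.
#'
#' @param gwas A `gwas_summary`.
#' @param panel `genotype_panel` used as the LD reference and for scoring.
#' @param y Phenotype vector aligned to the panel (named or positional).
#' @param validation_ids Sample ids used to tune `lambda`.
#' @param method `"blockwise_ridge"` (default) or `"clump_threshold"`.
#' @param hyper List of shrinkage settings: `lambda_grid` (default
#'   `c(0.01, 0.05, 0.2, 1, 5, 20)`), `window_snps` (contiguous SNPs per
#'   ridge window, default 100), and for the clump method `r2_threshold` /
#'   `window_kb` forwarded to [ld_clump()].
#' @return A `pgs_weight_set` tibble with a provenance attribute recording
#'   the method and chosen lambda.
#' @export
fit_pgs_weights <- function(gwas, panel, y, validation_ids,
                            method = c("blockwise_ridge", "clump_threshold"),
                            hyper = list()) {
  method <- match.arg(method)
  if (inherits(y, "phenotype_set")) y <- stats::setNames(y$y, y$sample_id)
  if (is.null(names(y))) names(y) <- panel$sample_ids
  stopifnot(all(gwas$snp_id %in% panel$snps$snp_id))

  weight <- rep(0, nrow(gwas))
  names(weight) <- gwas$snp_id
  chosen_lambda <- NA_real_

  if (method == "clump_threshold") {
    kept <- ld_clump(gwas, panel,
                     r2_threshold = hyper$r2_threshold %||% 0.5,
                     window_kb = hyper$window_kb %||% 500)
    weight[kept] <- gwas$beta[match(kept, gwas$snp_id)]
  } else {
    lambda_grid <- hyper$lambda_grid %||% c(0.01, 0.05, 0.2, 1, 5, 20)
    window_snps <- hyper$window_snps %||% 100

    ok <- !gwas$monomorphic & !is.na(gwas$beta)
    n <- attr(gwas, "n") %||% max(gwas$n_used)
    tval <- gwas$beta / gwas$se
    r_marg <- tval / sqrt(n - 2 + tval^2)          # correlation-scale effect
    scale_back <- ifelse(ok & r_marg != 0, gwas$beta / r_marg, 0)

    ord <- match(gwas$snp_id, panel$snps$snp_id)
    chrom <- panel$snps$chromosome[ord]
    pos <- panel$snps$position[ord]
    windows <- split(seq_len(nrow(gwas)),
                     paste0(chrom, "_w", ceiling(stats::ave(
                       pos, chrom, FUN = function(p) rank(p, ties.method = "first")) /
                         window_snps)))

    w_std_by_lambda <- lapply(lambda_grid, function(l) rep(0, nrow(gwas)))
    for (win in windows) {
      use <- win[ok[win]]
      if (length(use) == 0) next
      R <- suppressWarnings(cor(panel$dosages[, gwas$snp_id[use], drop = FALSE]))
      for (li in seq_along(lambda_grid)) {
        l <- lambda_grid[li]
        sol <- tryCatch(
          solve(R + diag(l, length(use)), r_marg[use]),
          error = function(e) NULL)
        while (is.null(sol)) { # singular despite ridge: escalate lambda
          l <- l * 10
          sol <- tryCatch(solve(R + diag(l, length(use)), r_marg[use]),
                          error = function(e) NULL)
        }
        w_std_by_lambda[[li]][use] <- sol
      }
    }

    val_r2 <- vapply(seq_along(lambda_grid), function(li) {
      w_allele <- w_std_by_lambda[[li]] * scale_back
      score <- as.numeric(panel$dosages[validation_ids, gwas$snp_id, drop = FALSE] %*% w_allele)
      if (pop_sd(score) == 0) return(0)
      cor(score, y[validation_ids])^2
    }, numeric(1))
    best <- which.max(val_r2)
    chosen_lambda <- lambda_grid[best]
    weight <- w_std_by_lambda[[best]] * scale_back
  }

  snp_rows <- match(gwas$snp_id, panel$snps$snp_id)
  new_pgs_weight_set(
    gwas$snp_id, gwas$effect_allele, panel$snps$other_allele[snp_rows], unname(weight),
    provenance = list(method = method, lambda = chosen_lambda,
                      source = "summary-statistic ridge (LD-aware shrinkage; not PRS-CS)",
                      data_hash = rlang::hash(gwas$beta)))
}

#' Score samples with a polygenic weight set
#'
#' Sum-mode scoring: `score = sum_j w_j * dosage_j` over SNPs matched by
#' id with effect-allele alignment; when a weight's effect/other alleles
#' are swapped relative to the panel, the dosage contribution is flipped
#' to `2 - dosage`. (PLINK's `--score` averages over non-missing alleles;
#' with complete hard calls the two differ by a constant factor, which
#' cancels in every r-squared-based metric.)
#'
#' @param panel A `genotype_panel`.
#' @param weights A `pgs_weight_set`.
#' @return Named numeric vector of per-sample scores.
#' @export
score_pgs <- function(panel, weights) {
  m <- match(weights$snp_id, panel$snps$snp_id)
  aligned <- !is.na(m) & weights$effect_allele == panel$snps$effect_allele[m]
  swapped <- !is.na(m) & !aligned &
    weights$effect_allele == panel$snps$other_allele[m] &
    weights$other_allele == panel$snps$effect_allele[m]
  matched <- aligned | swapped
  if (!any(matched)) abort("no scoring-file SNP matches the panel")
  if (any(!matched)) {
    warn(sprintf("%d scoring-file SNP(s) not matched to the panel (e.g. %s)",
                 sum(!matched),
                 paste(head(weights$snp_id[!matched], 3), collapse = ", ")))
  }
  score <- rep(0, length(panel$sample_ids))
  if (any(aligned)) {
    score <- score + as.numeric(
      panel$dosages[, m[aligned], drop = FALSE] %*% weights$weight[aligned])
  }
  if (any(swapped)) {
    score <- score + as.numeric(
      (2 - panel$dosages[, m[swapped], drop = FALSE]) %*% weights$weight[swapped])
  }
  stats::setNames(score, panel$sample_ids)
}

#' Read a PGS scoring file
#'
#' Parses the PGS Catalog scoring-file layout: optional `#` metadata
#' preamble, then a tab-separated table with a variant identifier column
#' (`rsID`, or `chr_name` + `chr_position`), `effect_allele`,
#' `effect_weight` and optionally `other_allele`.
#'
#' @param path File path (or literal text containing a tab character).
#' @return A `pgs_weight_set`.
#' @export
parse_scoring_file <- function(path) {
  txt <- if (length(path) == 1 && !grepl("[\t\n]", path)) readr::read_lines(path)
         else unlist(strsplit(paste(path, collapse = "\n"), "\n"))
  body_idx <- which(!grepl("^#", txt) & nzchar(txt))
  if (length(body_idx) < 2) abort("scoring file has no data rows")
  body <- txt[body_idx]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]

  required <- c("effect_allele", "effect_weight")
  missing_cols <- setdiff(required, header)
  has_rsid <- "rsID" %in% header
  has_pos <- all(c("chr_name", "chr_position") %in% header)
  if (!has_rsid && !has_pos) missing_cols <- c(missing_cols, "rsID (or chr_name + chr_position)")
  if (length(missing_cols) > 0) {
    abort(sprintf("scoring file is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }

  fields <- lapply(body[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- header

  w <- suppressWarnings(as.numeric(tab$effect_weight))
  bad <- which(is.na(w) & !is.na(tab$effect_weight))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric effect_weight at line %d of the scoring table",
                  body_idx[bad[1] + 1]))
  }
  snp_id <- if (has_rsid) tab$rsID else paste0(tab$chr_name, ":", tab$chr_position)
  other <- if ("other_allele" %in% header) tab$other_allele else NA_character_
  new_pgs_weight_set(snp_id, tab$effect_allele, other, w,
                     provenance = list(method = "scoring_file",
                                       file = if (length(path) == 1) path else NA))
}

#' Write a PGS scoring file
#'
#' Serializes a weight set in PGS Catalog layout. Weights are printed with
#' 17 significant digits so that write-then-parse reproduces the numeric
#' values bit-identically.
#'
#' @param weights A `pgs_weight_set`.
#' @param path Output path.
#' @param metadata Optional named character vector written as `#key=value`
#'   preamble lines.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(weights, path, metadata = NULL) {
  lines <- character(0)
  if (!is.null(metadata)) {
    lines <- paste0("#", names(metadata), "=", unname(metadata))
  }
  lines <- c(lines, paste(c("rsID", "effect_allele", "other_allele", "effect_weight"),
                          collapse = "\t"))
  lines <- c(lines, paste(weights$snp_id, weights$effect_allele,
                          weights$other_allele,
                          sprintf("%.17g", weights$weight), sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Fit the PGS + covariates regression baseline
#'
#' Two-stage fit: first a full multiple regression of the phenotype on the
#' PGS score and every covariate (factors expanded); then a refit keeping
#' the PGS plus only covariates that had a valid (non-`NA`), significant
#' (`p < alpha`) coefficient in the full model — a multi-level factor is
#' retained when any of its levels passes. The retained covariate list is
#' what the matching neural networks receive as environmental input.
#'
#' @param pgs_scores Numeric score vector (named by sample id, or aligned
#'   to `covariates`).
#' @param covariates Covariate tibble with `sample_id` column.
#' @param y Phenotype vector aligned to `covariates` rows (or named).
#' @param family `"linear"` for continuous traits, `"logistic"` for 0/1.
#' @param alpha Retention threshold on covariate p-values (default 0.05).
#' @return A `baseline_model`: the refit, the retained covariate names,
#'   the screening table, family and diagnostics. `tidy()` and `glance()`
#'   methods are provided.
#' @export
fit_covariate_baseline <- function(pgs_scores, covariates, y,
                                   family = c("linear", "logistic"),
                                   alpha = 0.05) {
  family <- match.arg(family)
  dat <- as.data.frame(covariates[, setdiff(names(covariates), "sample_id"), drop = FALSE])
  cov_names <- names(dat)
  realign <- function(v) {
    if (!is.null(names(v)) && "sample_id" %in% names(covariates) &&
        all(covariates$sample_id %in% names(v))) v[covariates$sample_id] else v
  }
  pgs_scores <- realign(pgs_scores)
  y <- realign(y)
  dat$.pgs <- as.numeric(pgs_scores)
  dat$.y <- as.numeric(y)

  # drop degenerate columns up front
  for (col in cov_names) {
    v <- dat[[col]]
    if (length(unique(stats::na.omit(v))) < 2) {
      warn(sprintf("covariate '%s' is constant; dropped", col))
      dat[[col]] <- NULL
      cov_names <- setdiff(cov_names, col)
    }
  }

  fitter <- function(formula, data) {
    if (family == "linear") stats::lm(formula, data = data)
    else stats::glm(formula, data = data, family = stats::binomial())
  }
  full <- fitter(stats::as.formula(paste(".y ~ .pgs +",
                                         paste(sprintf("`%s`", cov_names), collapse = " + "))),
                 dat)
  coefs <- summary(full)$coefficients
  pcol <- grep("^Pr\\(", colnames(coefs))
  term_p <- stats::setNames(coefs[, pcol], rownames(coefs))
  # map each coefficient to the covariate it expands from (factor-safe)
  assign_vec <- attr(stats::model.matrix(full), "assign")
  term_labels <- gsub("`", "", attr(stats::terms(full), "term.labels"))
  coef_names <- colnames(stats::model.matrix(full))
  coef_term <- ifelse(assign_vec == 0, "(Intercept)", term_labels[pmax(assign_vec, 1)])
  names(coef_term) <- coef_names

  screening <- purrr::map_dfr(cov_names, function(col) {
    terms <- names(coef_term)[coef_term == col]
    pv <- term_p[intersect(terms, names(term_p))]
    tibble::tibble(covariate = col,
                   min_p = if (length(pv) == 0 || all(is.na(pv))) NA_real_ else min(pv, na.rm = TRUE))
  })
  retained <- screening$covariate[!is.na(screening$min_p) & screening$min_p < alpha]

  refit_formula <- if (length(retained) > 0) {
    stats::as.formula(paste(".y ~ .pgs +", paste(sprintf("`%s`", retained), collapse = " + ")))
  } else {
    stats::as.formula(".y ~ .pgs")
  }
  refit <- fitter(refit_formula, dat)

  structure(
    list(fit = refit, retained = retained, screening = screening,
         family = family, alpha = alpha),
    class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> %s regression: PGS + %d retained covariate(s) (alpha = %g)\n",
              x$family, length(x$retained), x$alpha))
  invisible(x)
}
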