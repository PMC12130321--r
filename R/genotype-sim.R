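#' Specify a block-LD genotype panel
#'
#' Describes a synthetic SNP panel whose linkage disequilibrium (LD) arises
#' from a latent-Gaussian (copula) model: SNPs within a block share a latent
#' factor with correlation `within_block_rho`, blocks are mutually
#' independent. Chromosome and base-pair bookkeeping is synthetic
#' (`blocks_per_chrom` blocks per chromosome, adjacent SNPs `bp_spacing`
#' base pairs apart) so that distance-based filters operate as on real data.
#'
#' @param n_snps Total number of SNPs on the panel.
#' @param block_size SNPs per LD block (>= 1; 1 means no LD).
#' @param within_block_rho Latent pairwise correlation inside a block, in
#'   `[0, 1)`. The realized dosage r-squared is lower than `rho` because of
#'   the threshold (hard-call) transform; use [pairwise_r2()] to measure it.
#' @param maf_range Minor (effect) allele frequency range, drawn uniformly
#'   per SNP; both ends in `(0, 0.5]`.
#' @param bp_spacing Base pairs between adjacent SNPs.
#' @param blocks_per_chrom Number of blocks placed on each synthetic
#'   chromosome.
#' @return An object of class `ld_block_spec`.
#' @seealso [simulate_genotypes()]
#' @export
ld_block_spec <- function(n_snps,
                          block_size = 5,
                          within_block_rho = 0.9,
                          maf_range = c(0.1, 0.5),
                          bp_spacing = 100000,
                          blocks_per_chrom = 4) {
  assert_that(is.numeric(n_snps) && n_snps >= 1, "`n_snps` must be a positive integer")
  assert_that(block_size >= 1, "`block_size` must be >= 1")
  assert_that(within_block_rho >= 0 && within_block_rho < 1,
              "`within_block_rho` must be in [0, 1)")
  assert_that(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2],
              "`maf_range` must be (low, high) within (0, 0.5]")
  assert_that(bp_spacing >= 1, "`bp_spacing` must be >= 1")
  assert_that(blocks_per_chrom >= 1, "`blocks_per_chrom` must be >= 1")
  structure(
    list(n_snps = as.integer(n_snps), block_size = as.integer(block_size),
         within_block_rho = within_block_rho, maf_range = maf_range,
         bp_spacing = as.integer(bp_spacing),
         blocks_per_chrom = as.integer(blocks_per_chrom)),
    class = "ld_block_spec")
}

new_genotype_panel <- function(dosages, snps, sample_ids) {
  stopifnot(nrow(dosages) == length(sample_ids), ncol(dosages) == nrow(snps))
  dimnames(dosages) <- list(sample_ids, snps$snp_id)
  structure(list(dosages = dosages, snps = snps, sample_ids = sample_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d SNPs on %d chromosome(s)\n",
              length(x$sample_ids), nrow(x$snps), length(unique(x$snps$chromosome))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

# draw one block of hard-call dosages under the latent-Gaussian copula.
# Two haploid draws per sample share the block's latent factor pair.
draw_block <- function(n, mafs, rho) {
  m <- length(mafs)
  thr <- qnorm(mafs)
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    common <- rnorm(n)
    z <- sqrt(rho) * common +
      sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
    dos <- dos + (z < matrix(thr, n, m, byrow = TRUE))
  }
  storage.mode(dos) <- "integer"
  dos
}

#' Simulate a hard-call diploid genotype panel with block LD
#'
#' Generates `{0,1,2}` effect-allele dosages under Hardy-Weinberg
#' equilibrium with block LD: per block, each of the two haploid allele
#' draws comes from a multivariate normal with pairwise latent correlation
#' `within_block_rho`, thresholded at the quantile implied by each SNP's
#' MAF. Dosage is the sum of the two haploid draws. Blocks are independent;
#' the same `(spec, seed)` pair reproduces the panel bit-identically.
#'
#' A SNP that comes out monomorphic is re-drawn with a freshly sampled MAF a
#' bounded number of times before failing.
#'
#' @param n_samples Number of individuals (>= 2).
#' @param spec An [ld_block_spec()].
#' @param seed Integer seed.
#' @param max_retries Redraw attempts per monomorphic SNP.
#' @return A `genotype_panel`: integer dosage matrix plus a tibble of SNP
#'   metadata (`snp_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `maf`).
#' @examples
#' panel <- simulate_genotypes(200, ld_block_spec(20), seed = 1)
#' panel
#' @export
simulate_genotypes <- function(n_samples, spec, seed, max_retries = 10L) {
  assert_that(inherits(spec, "ld_block_spec"), "`spec` must be an ld_block_spec")
  assert_that(n_samples >= 2, "`n_samples` must be >= 2")
  set.seed(seed)

  n_blocks <- ceiling(spec$n_snps / spec$block_size)
  block_of <- rep(seq_len(n_blocks), each = spec$block_size)[seq_len(spec$n_snps)]
  dosages <- matrix(0L, n_samples, spec$n_snps)
  mafs <- numeric(spec$n_snps)

  for (b in seq_len(n_blocks)) {
    cols <- which(block_of == b)
    m <- runif(length(cols), spec$maf_range[1], spec$maf_range[2])
    dos <- draw_block(n_samples, m, spec$within_block_rho)
    for (j in seq_along(cols)) {
      tries <- 0L
      while (length(unique(dos[, j])) < 2L) {
        tries <- tries + 1L
        if (tries > max_retries) {
          abort(sprintf(
            "SNP %d is monomorphic after %d MAF redraws; increase n_samples or maf_range",
            cols[j], max_retries))
        }
        m[j] <- runif(1, spec$maf_range[1], spec$maf_range[2])
        thr <- qnorm(m[j])
        # redraw the SNP's column with fresh latents (block factor kept
        # implicit; a redrawn column is independent of its block)
        dos[, j] <- (rnorm(n_samples) < thr) + (rnorm(n_samples) < thr)
      }
    }
    dosages[, cols] <- dos
    mafs[cols] <- m
  }

  width <- max(5L, nchar(spec$n_snps))
  chrom_of_block <- ceiling(seq_len(n_blocks) / spec$blocks_per_chrom)
  chrom <- paste0("chr", chrom_of_block[block_of])
  idx_on_chrom <- stats::ave(seq_len(spec$n_snps), chrom, FUN = seq_along)
  snps <- tibble::tibble(
    snp_id = sprintf("snp_%0*d", width, seq_len(spec$n_snps)),
    chromosome = chrom,
    position = as.integer(idx_on_chrom * spec$bp_spacing),
    effect_allele = "A",
    other_allele = "G",
    maf = mafs)

  new_genotype_panel(dosages, snps, sprintf("id_%06d", seq_len(n_samples)))
}

#' Squared dosage correlation between two SNPs
#'
#' The LD measure used throughout: squared Pearson correlation of the two
#' dosage columns.
#'
#' @param panel A `genotype_panel`.
#' @param snp_a,snp_b SNP identifiers present on the panel.
#' @return A single number in `[0, 1]`.
#' @export
pairwise_r2 <- function(panel, snp_a, snp_b) {
  for (s in c(snp_a, snp_b)) {
    if (!s %in% panel$snps$snp_id) abort(sprintf("SNP '%s' is not on the panel", s))
  }
  xa <- panel$dosages[, snp_a]
  xb <- panel$dosages[, snp_b]
  if (var(xa) == 0 || var(xb) == 0) {
    abort("correlation undefined: at least one SNP is monomorphic")
  }
  if (identical(snp_a, snp_b)) return(1)
  cor(xa, xb)^2
}

#' Construct the joint-tagging-effect reduced panel
#'
#' Recreates incomplete coverage of causal variants: a causal SNP is
#' *eligible* when at least two other panel SNPs tag it with
#' `r2 > r2_threshold`; up to `max_removal_fraction` of the eligible SNPs
#' are then removed at random from the observed panel. Effects attached to
#' removed SNPs remain in any phenotype simulated from the full panel —
#' removal changes what the models get to see, not the trait.
#'
#' The removed count is drawn `Binomial(n_eligible, max_removal_fraction)`
#' and truncated at `floor(max_removal_fraction * n_eligible)`, so the
#' fraction removed is "up to" the configured maximum on every run.
#'
#' @param panel A `genotype_panel`.
#' @param causal_ids SNP ids whose coverage should be degraded.
#' @param r2_threshold Tagging threshold (default 0.25).
#' @param max_removal_fraction Upper bound on the removed fraction of
#'   eligible SNPs (default 0.5).
#' @param seed Integer seed for the removal draw.
#' @return A list with elements `panel` (the reduced `genotype_panel`) and
#'   `report` (a `reduced_panel_report`: removed ids, their tagging variants
#'   with r-squared, eligible count, and the seed).
#' @export
reduce_panel_joint_tagging <- function(panel, causal_ids,
                                       r2_threshold = 0.25,
                                       max_removal_fraction = 0.5,
                                       seed = 1L) {
  missing_ids <- setdiff(causal_ids, panel$snps$snp_id)
  if (length(missing_ids) > 0) {
    abort(sprintf("causal SNP(s) absent from panel: %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  assert_that(r2_threshold > 0 && r2_threshold <= 1, "`r2_threshold` must be in (0, 1]")
  assert_that(max_removal_fraction > 0 && max_removal_fraction <= 1,
              "`max_removal_fraction` must be in (0, 1]")

  r2 <- suppressWarnings(
    cor(panel$dosages[, causal_ids, drop = FALSE], panel$dosages)^2)
  tags <- purrr::map(causal_ids, function(id) {
    row <- r2[match(id, causal_ids), ]
    hit <- names(row)[!is.na(row) & row > r2_threshold & names(row) != id]
    tibble::tibble(causal_id = id, tag_id = hit,
                   r2 = unname(row[hit]))
  })
  tags <- dplyr::bind_rows(tags)
  eligible <- tags |>
    dplyr::count(.data$causal_id) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull(.data$causal_id)

  set.seed(seed)
  cap <- floor(max_removal_fraction * length(eligible))
  n_remove <- min(rbinom(1, length(eligible), max_removal_fraction), cap)
  removed <- if (n_remove > 0) sort(sample(eligible, n_remove)) else character(0)

  keep <- !panel$snps$snp_id %in% removed
  reduced <- new_genotype_panel(
    panel$dosages[, keep, drop = FALSE],
    panel$snps[keep, , drop = FALSE],
    panel$sample_ids)

  report <- structure(
    list(removed_snp_ids = removed,
         tags = dplyr::filter(tags, .data$causal_id %in% removed),
         eligible_ids = eligible,
         eligible_count = length(eligible),
         r2_threshold = r2_threshold,
         max_removal_fraction = max_removal_fraction,
         removal_seed = seed),
    class = "reduced_panel_report")
  list(panel = reduced, report = report)
}

#' @export
print.reduced_panel_report <- function(x, ...) {
  cat(sprintf("<reduced_panel_report> %d/%d eligible causal SNPs removed (r2 > %.2f, up to %.0f%%)\n",
              length(x$removed_snp_ids), x$eligible_count,
              x$r2_threshold, 100 * x$max_removal_fraction))
  invisible(x)
}

#' Write a genotype panel as additive-dosage text
#'
#' Writes the PLINK `.raw`-style additive coding (header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one `<snp>_<allele>` column
#' per SNP) plus, optionally, the paired SNP metadata TSV and a
#' `.bim`-compatible variant file.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path for the `.raw`-style file.
#' @param meta_path Optional path for the SNP metadata TSV
#'   (`snp_id chromosome position effect_allele other_allele maf`).
#' @param bim_path Optional path for a PLINK `.bim`-compatible file.
#' @param phenotype Optional numeric vector for the PHENOTYPE column
#'   (defaults to `-9`, PLINK's missing code).
#' @return `path`, invisibly.
#' @export
write_panel_raw <- function(panel, path, meta_path = NULL, bim_path = NULL,
                            phenotype = NULL) {
  n <- length(panel$sample_ids)
  pheno <- phenotype %||% rep(-9, n)
  raw <- data.frame(FID = panel$sample_ids, IID = panel$sample_ids,
                    PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = pheno)
  dos <- as.data.frame(panel$dosages)
  names(dos) <- paste0(panel$snps$snp_id, "_", panel$snps$effect_allele)
  utils::write.table(cbind(raw, dos), path, quote = FALSE, sep = " ",
                     row.names = FALSE)
  if (!is.null(meta_path)) {
    readr::write_tsv(panel$snps, meta_path)
  }
  if (!is.null(bim_path)) {
    bim <- data.frame(chrom = sub("^chr", "", panel$snps$chromosome),
                      snp_id = panel$snps$snp_id, cm = 0,
                      pos = panel$snps$position,
                      a1 = panel$snps$effect_allele,
                      a2 = panel$snps$other_allele)
    utils::write.table(bim, bim_path, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read an additive-dosage text panel
#'
#' Counterpart of [write_panel_raw()]: reads a PLINK `.raw`-style file and
#' its SNP metadata TSV back into a `genotype_panel`.
#'
#' @param path `.raw`-style dosage file.
#' @param meta_path SNP metadata TSV written by [write_panel_raw()].
#' @return A `genotype_panel`.
#' @export
read_panel_raw <- function(path, meta_path) {
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE)
  snps <- readr::read_tsv(meta_path, show_col_types = FALSE)
  snp_cols <- paste0(snps$snp_id, "_", snps$effect_allele)
  missing_cols <- setdiff(snp_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("dosage file lacks %d column(s) named in the metadata (e.g. %s)",
                  length(missing_cols), missing_cols[1]))
  }
  dosages <- as.matrix(raw[, snp_cols, drop = FALSE])
  storage.mode(dosages) <- "integer"
  new_genotype_panel(dosages, tibble::as_tibble(snps), as.character(raw$IID))
}
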