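# Small fixtures built in code, shared across test files.

# panel from an explicit dosage matrix (one chromosome, evenly spaced)
panel_from_matrix <- function(dosages, positions = NULL, chromosome = NULL,
                              maf = NULL) {
  n_snp <- ncol(dosages)
  storage.mode(dosages) <- "integer"
  snps <- tibble::tibble(
    snp_id = sprintf("snp_%05d", seq_len(n_snp)),
    chromosome = chromosome %||% rep("chr1", n_snp),
    position = as.integer(positions %||% (seq_len(n_snp) * 1000L)),
    effect_allele = "A", other_allele = "G",
    maf = maf %||% pmin(colMeans(dosages) / 2, 1 - colMeans(dosages) / 2))
  nnpgs:::new_genotype_panel(dosages, snps, sprintf("id_%06d", seq_len(nrow(dosages))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force greedy clumping oracle working purely off a precomputed
# r-squared table, independent of the package implementation
clump_oracle <- function(p, pos, chrom, id, r2_table, r2_threshold, window_bp) {
  ord <- order(p, pos, id, method = "radix")
  assigned <- rep(FALSE, length(p))
  kept <- character(0)
  for (i in ord) {
    if (assigned[i]) next
    kept <- c(kept, id[i])
    assigned[i] <- TRUE
    for (j in ord) {
      if (assigned[j]) next
      if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= window_bp &&
          r2_table[id[i], id[j]] > r2_threshold) {
        assigned[j] <- TRUE
      }
    }
  }
  kept
}

# brute-force distance-filter oracle
distance_oracle <- function(p, pos, chrom, id, min_bp) {
  ord <- order(p, pos, id, method = "radix")
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) < min_bp) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  id[kept]
}

# quick settings that keep unit-test networks cheap
fast_nn <- function(...) {
  nn_config_small(dropout_rate = 0, patience_epochs = 8, max_epochs = 25, ...)
}
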