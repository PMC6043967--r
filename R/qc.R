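#' Remove sex-chromosome sites
#'
#' Drops all sites whose chromosome label matches (case-insensitively) one of
#' the sex-chromosome aliases. The default alias list covers the usual `X`/`Y`
#' labels plus their `chr`-prefixed forms; dog data sometimes labels X as
#' `39`, which can be added via `aliases`.
#'
#' @param gm A [genotype_matrix()].
#' @param aliases Chromosome labels to drop (case-insensitive).
#' @return A [genotype_matrix()].
#' @export
drop_sex_chromosomes <- function(gm, aliases = c("X", "Y", "chrX", "chrY")) {
  drop <- tolower(gm$sites$chrom) %in% tolower(aliases)
  if (!any(drop)) return(gm)
  gm[, !drop]
}

#' Call-rate filtering of samples then sites
#'
#' Reproduces the SNP-array cleaning step "discard samples and SNPs with call
#' rates <= threshold", read literally: a call rate strictly greater than the
#' threshold survives. Samples are filtered first, then sites are re-assessed
#' over the surviving samples (the order is fixed and documented).
#'
#' @param gm A [genotype_matrix()].
#' @param threshold Call-rate threshold in `(0, 1]` (default 0.95).
#' @return A [genotype_matrix()]; aborts if no sample survives.
#' @export
filter_call_rate <- function(gm, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  keep_s <- rowMeans(!is.na(gm$calls)) > threshold
  if (!any(keep_s)) abort("call-rate filter removed every sample")
  gm <- gm[keep_s, ]
  keep_v <- colMeans(!is.na(gm$calls)) > threshold
  gm[, keep_v]
}

#' Sliding-window LD pruning
#'
#' Greedy left-to-right pruning in the PLINK `indep-pairwise` idiom: within
#' each window of `window_snps` consecutive surviving sites, every pair with
#' genotypic `r^2 >` `r2_max` loses one member — the site with the lower call
#' rate, ties removing the later (right-hand) site. The window then advances
#' by `step_snps` surviving sites. Sweeps repeat until a full pass removes
#' nothing, so pruning an already-pruned matrix is a no-op.
#'
#' @param gm A [genotype_matrix()].
#' @param window_snps Window size in SNPs (`>= 2`, default 50).
#' @param step_snps Window step in SNPs (default 5).
#' @param r2_max Maximum tolerated pairwise `r^2` (default 0.2).
#' @return A [genotype_matrix()].
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5, r2_max = 0.2) {
  stopifnot(window_snps >= 2, step_snps >= 1)
  x <- gm$calls
  call_rate <- colMeans(!is.na(x))
  chrom <- gm$sites$chrom
  keep <- rep(TRUE, ncol(x))

  prune_window <- function(idx) {
    # returns indices (into the full site set) to drop within this window
    drop <- logical(length(idx))
    r2 <- suppressWarnings(cor(x[, idx, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    repeat {
      live <- which(!drop)
      if (length(live) < 2L) break
      off <- which(r2[live, live, drop = FALSE] > r2_max, arr.ind = TRUE)
      off <- off[off[, 1] < off[, 2], , drop = FALSE]
      if (nrow(off) == 0L) break
      # first offending pair in scan order
      o <- off[order(off[, 1], off[, 2]), , drop = FALSE][1, ]
      i <- live[o[1]]
      j <- live[o[2]]
      cri <- call_rate[idx[i]]
      crj <- call_rate[idx[j]]
      victim <- if (cri < crj) i else if (crj < cri) j else j # tie: later site
      drop[victim] <- TRUE
    }
    idx[drop]
  }

  repeat {
    removed_any <- FALSE
    for (ch in unique(chrom)) {
      live <- which(keep & chrom == ch)
      pos <- 1L
      while (pos <= length(live)) {
        win <- live[pos:min(pos + window_snps - 1L, length(live))]
        win <- win[keep[win]]
        if (length(win) >= 2L) {
          dropped <- prune_window(win)
          if (length(dropped)) {
            keep[dropped] <- FALSE
            removed_any <- TRUE
          }
        }
        pos <- pos + step_snps
      }
    }
    if (!removed_any) break
  }
  gm[, keep]
}

#' Keep only sites with zero missing calls
#'
#' @param gm A [genotype_matrix()].
#' @return A [genotype_matrix()] restricted to complete-case sites.
#' @export
remove_missing_sites <- function(gm) {
  gm[, colSums(is.na(gm$calls)) == 0L]
}

#' Run the full filtering cascade with a stage report
#'
#' Sex-chromosome removal, call-rate filtering, LD pruning and (optionally)
#' complete-case site selection, returning both the filtered matrix and a
#' per-stage count table mirroring the usual "n SNPs retained" reporting.
#'
#' @param gm A [genotype_matrix()].
#' @param call_rate Call-rate threshold (see [filter_call_rate()]).
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters (see [ld_prune()]).
#' @param drop_sex Drop sex chromosomes first?
#' @param complete_cases Also produce the complete-case (no missing data)
#'   stage?
#' @return A list with `genotypes` (after call-rate + sex filtering,
#'   the "quality-pruned" set), `ld_pruned`, `complete` (or `NULL`), and
#'   `report` (tibble of stage, n_samples, n_sites).
#' @export
qc_cascade <- function(gm, call_rate = 0.95, ld_window = 50, ld_step = 5,
                       ld_r2 = 0.2, drop_sex = TRUE, complete_cases = TRUE) {
  stages <- list(input = gm)
  if (drop_sex) gm <- drop_sex_chromosomes(gm)
  stages$autosomal <- gm
  gm <- filter_call_rate(gm, call_rate)
  stages$quality_pruned <- gm
  ld <- ld_prune(gm, ld_window, ld_step, ld_r2)
  stages$ld_pruned <- ld
  comp <- NULL
  if (complete_cases) {
    comp <- remove_missing_sites(ld)
    stages$complete_cases <- comp
  }
  report <- tibble(
    stage = names(stages),
    n_samples = vapply(stages, n_samples, 1L),
    n_sites = vapply(stages, n_sites, 1L)
  )
  list(genotypes = stages$quality_pruned, ld_pruned = ld, complete = comp,
       report = report)
}
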