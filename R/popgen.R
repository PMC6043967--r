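#' Per-group per-site allele frequencies
#'
#' Allele-2 frequency, called chromosome counts and observed heterozygote
#' counts per site, within each sample group (or overall).
#'
#' @param gm A [genotype_matrix()].
#' @param by_group Split by sample group (default) or pool all samples.
#' @return A tibble with `group`, `site` (index), `chrom`, `pos`, `n_chrom`,
#'   `freq`, `n_het`.
#' @export
site_frequencies <- function(gm, by_group = TRUE) {
  groups <- if (by_group) unique(gm$samples$group) else "all"
  purrr::map(groups, function(g) {
    rows <- if (by_group) gm$samples$group == g else rep(TRUE, n_samples(gm))
    x <- gm$calls[rows, , drop = FALSE]
    n_called <- colSums(!is.na(x))
    gm$sites |>
      transmute(
        group = g,
        site = dplyr::row_number(),
        chrom = .data$chrom, pos = .data$pos,
        n_chrom = 2L * n_called,
        freq = ifelse(n_called > 0, colSums(x, na.rm = TRUE) / (2 * n_called), NA_real_),
        n_het = colSums(x == 1L, na.rm = TRUE)
      )
  }) |> list_rbind()
}

#' Observed heterozygosity per sample and per group
#'
#' Fraction of called sites that are heterozygous. The group value is the
#' mean over its members.
#'
#' @param gm A [genotype_matrix()].
#' @param by `"sample"` (default) or `"group"`.
#' @return A tibble: per sample (`id`, `group`, `n_called`, `h_obs`) or per
#'   group (`group`, `n`, `h_obs`, `sd`). Samples with zero called sites get
#'   `NA` with a warning.
#' @export
observed_heterozygosity <- function(gm, by = c("sample", "group")) {
  by <- match.arg(by)
  n_called <- rowSums(!is.na(gm$calls))
  h <- rowSums(gm$calls == 1L, na.rm = TRUE) / n_called
  if (any(n_called == 0L)) {
    warn("sample(s) with zero called sites; heterozygosity undefined (NA)")
    h[n_called == 0L] <- NA_real_
  }
  per_sample <- tibble(
    id = gm$samples$id, group = gm$samples$group,
    n_called = unname(n_called), h_obs = unname(h)
  )
  if (by == "sample") return(per_sample)
  per_sample |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), sd = sd(.data$h_obs, na.rm = TRUE),
              h_obs = mean(.data$h_obs, na.rm = TRUE), .groups = "drop") |>
    select("group", "n", "h_obs", "sd")
}

#' Method-of-moments individual inbreeding coefficient F
#'
#' For each sample, `F = (O_hom - E_hom) / (n_called - E_hom)` where `E_hom`
#' is the Hardy–Weinberg expected homozygote count `sum(1 - 2 p q)` over the
#' sample's called sites, with reference frequencies taken from the sample's
#' own group unless an explicit frequency table is supplied. Values are not
#' clipped; sites monomorphic in the reference contribute nothing to the
#' denominator, and a sample whose called sites are all monomorphic gets `NA`
#' with a flag.
#'
#' @param gm A [genotype_matrix()].
#' @param reference_freqs Optional frequency table as from
#'   [site_frequencies()] (`group = "all"` rows are used if present), or
#'   `NULL` to use each sample's own group.
#' @return A tibble with `id`, `group`, `n_called`, `f`, `flag`.
#' @export
inbreeding_f <- function(gm, reference_freqs = NULL) {
  if (is.null(reference_freqs)) {
    fr <- site_frequencies(gm, by_group = TRUE)
    freq_of <- function(g) fr$freq[fr$group == g]
  } else {
    fr <- reference_freqs
    if ("group" %in% names(fr) && "all" %in% fr$group) fr <- filter(fr, .data$group == "all")
    freq_of <- function(g) fr$freq
  }
  out <- purrr::map(seq_len(n_samples(gm)), function(i) {
    p <- freq_of(gm$samples$group[i])
    x <- gm$calls[i, ]
    called <- !is.na(x) & !is.na(p)
    exp_het <- 2 * p[called] * (1 - p[called])
    denom <- sum(exp_het)
    obs_hom <- sum(x[called] != 1L)
    n <- sum(called)
    if (denom <= 0) {
      tibble(n_called = n, f = NA_real_, flag = "monomorphic_reference")
    } else {
      # (O_hom - E_hom) / (n - E_hom); n - E_hom == sum of expected het
      tibble(n_called = n, f = (obs_hom - (n - denom)) / denom, flag = NA_character_)
    }
  }) |> list_rbind()
  tibble(id = gm$samples$id, group = gm$samples$group) |> dplyr::bind_cols(out)
}

# Weir & Cockerham (1984) per-site variance components for one pair of groups.
# Returns tibble with a, b, c per site.
wc_components <- function(x1, x2) {
  n1 <- colSums(!is.na(x1))
  n2 <- colSums(!is.na(x2))
  p1 <- colSums(x1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(x2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(x1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(x2 == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tibble(a = a, b = b, c = cc, n1 = n1, n2 = n2)
}

#' Pairwise Weir–Cockerham F_ST
#'
#' Per-site Weir & Cockerham (1984) variance components and the genome-wide
#' estimate as a ratio of summed components (not a mean of per-site ratios).
#' Per-site values are retained (and may be negative) for downstream
#' ancestry-informative-marker selection.
#'
#' @param gm A [genotype_matrix()].
#' @param groups Groups to include (default: all groups with >= 2 samples).
#' @return An object of class `fst_result`: list with `matrix` (symmetric
#'   genome-wide F_ST), `pairs` (tibble `group1`, `group2`, `fst`) and
#'   `per_site` (tibble with per-site components and `fst` per pair).
#' @export
pairwise_fst <- function(gm, groups = NULL) {
  tab <- table(gm$samples$group)
  groups <- groups %||% names(tab)[tab >= 2]
  if (length(groups) < 2L) abort("need >= 2 groups with >= 2 samples")
  if (any(tab[groups] < 2L)) abort("every group needs >= 2 samples")
  combos <- utils::combn(groups, 2)
  per_site <- purrr::map(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1, k]
    g2 <- combos[2, k]
    x1 <- gm$calls[gm$samples$group == g1, , drop = FALSE]
    x2 <- gm$calls[gm$samples$group == g2, , drop = FALSE]
    wc <- wc_components(x1, x2)
    if (all(wc$n1 < 2 | wc$n2 < 2)) {
      abort(sprintf("groups %s/%s never have >= 2 called samples at a site", g1, g2))
    }
    gm$sites |>
      transmute(
        group1 = g1, group2 = g2,
        site = dplyr::row_number(), chrom = .data$chrom, pos = .data$pos,
        a = wc$a, b = wc$b, c = wc$c,
        fst = ifelse(wc$a + wc$b + wc$c == 0, NA_real_,
                     wc$a / (wc$a + wc$b + wc$c))
      )
  }) |> list_rbind()
  pairs <- per_site |>
    group_by(.data$group1, .data$group2) |>
    summarise(
      fst = sum(.data$a, na.rm = TRUE) /
        sum(.data$a + .data$b + .data$c, na.rm = TRUE),
      .groups = "drop"
    )
  m <- matrix(0, length(groups), length(groups), dimnames = list(groups, groups))
  for (k in seq_len(nrow(pairs))) {
    m[pairs$group1[k], pairs$group2[k]] <- pairs$fst[k]
    m[pairs$group2[k], pairs$group1[k]] <- pairs$fst[k]
  }
  structure(list(matrix = m, pairs = pairs, per_site = per_site),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> genome-wide Weir-Cockerham F_ST\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' PCA of the dosage matrix
#'
#' Missing calls are mean-imputed per site; sites are centered (and
#' optionally standardized by `sqrt(p(1-p))`) before eigendecomposition.
#' Zero-variance sites are dropped.
#'
#' @param gm A [genotype_matrix()].
#' @param standardize Standardize by the binomial frequency scale?
#'   Default `FALSE` (plain centering under the additive model).
#' @param n_pc Number of components to return.
#' @return An object of class `gm_pca`: list with `scores` (tibble `id`,
#'   `group`, `PC1`, ...), `var_explained`, `sdev`.
#' @export
pca_genotypes <- function(gm, standardize = FALSE, n_pc = 10) {
  x <- gm$calls
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0L)) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, mu)
  if (standardize) {
    p <- mu / 2
    sc <- sqrt(pmax(p * (1 - p), .Machine$double.eps))
    x <- sweep(x, 2, sc, "/")
  }
  keep <- apply(x, 2, function(v) var(v) > 0)
  if (!any(keep)) abort("zero-variance matrix; PCA undefined")
  x <- x[, keep, drop = FALSE]
  n_pc <- min(n_pc, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pc)
  ev <- pc$sdev^2
  scores <- as_tibble(pc$x[, seq_len(n_pc), drop = FALSE])
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble(id = gm$samples$id, group = gm$samples$group), scores
      ),
      var_explained = ev[seq_len(n_pc)] / sum(ev),
      sdev = pc$sdev
    ),
    class = "gm_pca"
  )
}

#' @export
print.gm_pca <- function(x, ...) {
  cat(sprintf(
    "<gm_pca> %d samples, %d PCs; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$scores), length(x$var_explained),
    100 * x$var_explained[1],
    if (length(x$var_explained) > 1) 100 * x$var_explained[2] else NA
  ))
  invisible(x)
}

#' Genotypic LD r-squared between two sites
#'
#' Squared Pearson correlation of 0/1/2 dosages over samples called at both
#' sites ("genotypic association" r^2, not haplotype r^2).
#'
#' @param gm A [genotype_matrix()].
#' @param site_i,site_j Site indices.
#' @return `r^2` in `[0, 1]`, or `NA` (with a warning) if either site has no
#'   dosage variance among shared called samples.
#' @export
ld_r2 <- function(gm, site_i, site_j) {
  x <- gm$calls[, site_i]
  y <- gm$calls[, site_j]
  ok <- !is.na(x) & !is.na(y)
  if (var(x[ok]) == 0 || var(y[ok]) == 0) {
    warn("zero dosage variance; r^2 undefined")
    return(NA_real_)
  }
  cor(x[ok], y[ok])^2
}

#' PLINK-style method-of-moments IBD (pi-hat)
#'
#' Estimates the IBD state probabilities (P0, P1, P2) from identity-by-state
#' counts and reference allele frequencies (method of moments as in PLINK's
#' `--genome`, without the finite-sample bias-correction factors), and
#' reports `pi-hat = P1/2 + P2`, truncated to `[0, 1]`.
#'
#' @param gm A [genotype_matrix()].
#' @param pairs Optional two-column structure of sample-id pairs; default all
#'   pairs within `gm`.
#' @param freqs Optional per-site frequency vector; default frequencies over
#'   all samples of `gm`.
#' @param min_sites Pairs sharing fewer called sites than this are flagged
#'   low-confidence (default 100).
#' @return A tibble with `id1`, `id2`, `n_shared`, `p0`, `p1`, `p2`, `pihat`,
#'   `low_confidence`.
#' @export
ibd_pihat <- function(gm, pairs = NULL, freqs = NULL, min_sites = 100) {
  if (is.null(freqs)) {
    n_called <- colSums(!is.na(gm$calls))
    freqs <- colSums(gm$calls, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  }
  if (is.null(pairs)) {
    cmb <- utils::combn(gm$samples$id, 2)
    pairs <- tibble(id1 = cmb[1, ], id2 = cmb[2, ])
  } else {
    pairs <- as_tibble(as.data.frame(pairs, stringsAsFactors = FALSE))
    names(pairs)[1:2] <- c("id1", "id2")
  }
  p <- freqs
  q <- 1 - p
  # expected IBS-class probabilities given IBD state, per site
  e0_z0 <- 2 * p^2 * q^2
  e1_z0 <- 4 * p^3 * q + 4 * p * q^3
  e2_z0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_z1 <- 2 * p^2 * q + 2 * p * q^2
  e2_z1 <- p^3 + q^3 + p^2 * q + p * q^2
  purrr::map(seq_len(nrow(pairs)), function(k) {
    i <- match(pairs$id1[k], gm$samples$id)
    j <- match(pairs$id2[k], gm$samples$id)
    x <- gm$calls[i, ]
    y <- gm$calls[j, ]
    ok <- !is.na(x) & !is.na(y) & p > 0 & p < 1
    ibs <- 2L - abs(x[ok] - y[ok]) # 0/2 -> IBS0, 0/1 or 1/2 -> IBS1, equal -> IBS2
    n <- sum(ok)
    N0 <- sum(ibs == 0L)
    N1 <- sum(ibs == 1L)
    N2 <- sum(ibs == 2L)
    z0 <- N0 / sum(e0_z0[ok])
    z1 <- (N1 - z0 * sum(e1_z0[ok])) / sum(e1_z1[ok])
    z2 <- (N2 - z0 * sum(e2_z0[ok]) - z1 * sum(e2_z1[ok])) / n
    z <- pmin(pmax(c(z0, z1, z2), 0), 1)
    z <- z / sum(z)
    tibble(
      id1 = pairs$id1[k], id2 = pairs$id2[k], n_shared = n,
      p0 = z[1], p1 = z[2], p2 = z[3],
      pihat = min(max(z[2] / 2 + z[3], 0), 1),
      low_confidence = n < min_sites
    )
  }) |> list_rbind()
}
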