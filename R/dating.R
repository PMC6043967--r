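#' LD-based effective population size trajectory
#'
#' Within-chromosome SNP pairs are binned by genetic distance `c` with bin
#' edges `1/(2 (t +- 0.5))` so that bin `t` represents `t = 1/(2 c)`
#' generations ago (the Sved/Hayes mapping between recombination distance and
#' look-back time). In each bin the mean genotypic `r^2` is inverted through
#' `E(r^2) = 1/(1 + 4 N_E c) + 1/n`, where `1/n` is the small-sample
#' correction with `n` the number of sampled chromosomes, giving
#' `N_E = (1/(rbar^2 - 1/n) - 1) / (4 c)`. Bins with `rbar^2 <= 1/n` (or no
#' pairs) are flagged undefined rather than extrapolated.
#'
#' @param gm A [genotype_matrix()] of the population to profile.
#' @param map A `genetic_map` (default linear over the observed site range).
#' @param t_range Integer look-back range in generations (default `c(1, 20)`).
#' @return A tibble of class `ne_trajectory`: `t`, `c_morgans`, `mean_r2`,
#'   `n_pairs`, `ne`, `flag`; attribute `n_chromosomes_sampled`.
#' @export
ne_trajectory <- function(gm, map = NULL, t_range = c(1, 20)) {
  n_chr_sampled <- 2L * n_samples(gm)
  if (n_chr_sampled < 4L) abort("need >= 4 sampled chromosomes (2 individuals)")
  if (is.null(map)) {
    lens <- gm$sites |> group_by(.data$chrom) |> summarise(len = max(.data$pos))
    map <- linear_map(setNames(lens$len, lens$chrom))
  }
  ts <- seq(t_range[1], t_range[2])
  edges_hi <- 1 / (2 * (ts - 0.5)) # upper c edge for bin t
  edges_lo <- 1 / (2 * (ts + 0.5))
  sums <- numeric(length(ts))
  counts <- integer(length(ts))
  for (ch in unique(gm$sites$chrom)) {
    jdx <- which(gm$sites$chrom == ch)
    if (length(jdx) < 2L) next
    x <- gm$calls[, jdx, drop = FALSE]
    keep <- apply(x, 2, function(v) var(v, na.rm = TRUE) > 0 && sum(!is.na(v)) >= 2)
    jdx <- jdx[keep]
    if (length(jdx) < 2L) next
    x <- gm$calls[, jdx, drop = FALSE]
    r2 <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))^2
    cm <- bp_to_morgans(map, ch, gm$sites$pos[jdx])
    dmat <- abs(outer(cm, cm, "-"))
    ut <- upper.tri(dmat)
    d <- dmat[ut]
    r <- r2[ut]
    ok <- !is.na(r)
    d <- d[ok]
    r <- r[ok]
    for (k in seq_along(ts)) {
      inb <- d >= edges_lo[k] & d < edges_hi[k]
      sums[k] <- sums[k] + sum(r[inb])
      counts[k] <- counts[k] + sum(inb)
    }
  }
  corr <- 1 / n_chr_sampled
  out <- tibble(
    t = ts,
    c_morgans = 1 / (2 * ts),
    mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
    n_pairs = counts
  ) |>
    mutate(
      ne = ifelse(!is.na(.data$mean_r2) & .data$mean_r2 > corr,
                  (1 / (.data$mean_r2 - corr) - 1) / (4 * .data$c_morgans),
                  NA_real_),
      flag = dplyr::case_when(
        counts == 0L ~ "empty_bin",
        is.na(.data$ne) ~ "r2_below_correction",
        TRUE ~ NA_character_
      )
    )
  attr(out, "n_chromosomes_sampled") <- n_chr_sampled
  class(out) <- c("ne_trajectory", class(out))
  out
}

#' Invert the expected-r2 model at known quantities
#'
#' Closed-form helper `N_E = (1/(rbar^2 - 1/n) - 1)/(4 c)`; exposed for the
#' model-inversion round trip and quick calculations.
#'
#' @param mean_r2 Mean `r^2` in a distance bin.
#' @param c_morgans Genetic distance of the bin, Morgans.
#' @param n_chromosomes Number of sampled chromosomes.
#' @return `N_E`, or `NA` when `mean_r2 <= 1/n`.
#' @export
ne_from_r2 <- function(mean_r2, c_morgans, n_chromosomes) {
  corr <- 1 / n_chromosomes
  ifelse(mean_r2 > corr, (1 / (mean_r2 - corr) - 1) / (4 * c_morgans), NA_real_)
}

#' @rdname ne_from_r2
#' @param ne Effective size, for the forward direction.
#' @export
r2_from_ne <- function(ne, c_morgans, n_chromosomes) {
  1 / (1 + 4 * ne * c_morgans) + 1 / n_chromosomes
}

#' Weighted-LD decay dating of admixture
#'
#' Computes, per genetic-distance bin, the mean over within-chromosome SNP
#' pairs of the admixture-LD statistic `cov(g_i, g_j) w_i w_j`, with weights
#' `w = p_wolf - p_dog` from the parental reference frequencies (drift LD is
#' sign-incoherent under this weighting and averages out, while
#' admixture-induced LD decays as `exp(-g d)` with generations `g` since
#' admixture). The binned curve is fitted by nonlinear least squares to
#' `a exp(-g d) + k` (starts: `g = 10`, `a` = first-bin amplitude minus the
#' tail, `k` = tail mean), with a leave-chromosomes-out bootstrap CI.
#'
#' @param gm A [genotype_matrix()] of the admixed cohort.
#' @param parental_freqs Tibble with per-site `p_wolf`, `p_dog` aligned to
#'   `gm`'s sites.
#' @param map A `genetic_map` (default linear).
#' @param bin_morgans Distance bin width (default 0.005).
#' @param max_morgans Largest pair distance used (default 0.3).
#' @param min_morgans Smallest pair distance used (default 0.001; very tight
#'   pairs carry founder and array artefacts).
#' @param n_boot Bootstrap replicates over chromosomes (default 100).
#' @param seed Seed for the bootstrap.
#' @return An object of class `admixture_date` with `method = "weighted_ld"`:
#'   list with `generations`, `ci` (2-vector), `amplitude`, `tail`, `bins`
#'   (tibble `d`, `stat`, `n_pairs`), `fit`, `flag`.
#' @export
admixture_ld_decay <- function(gm, parental_freqs, map = NULL,
                               bin_morgans = 0.005, max_morgans = 0.3,
                               min_morgans = 0.001, n_boot = 100, seed = 1) {
  if (is.null(map)) {
    lens <- gm$sites |> group_by(.data$chrom) |> summarise(len = max(.data$pos))
    map <- linear_map(setNames(lens$len, lens$chrom))
  }
  w_all <- parental_freqs$p_wolf - parental_freqs$p_dog
  chroms <- unique(gm$sites$chrom)
  # per-chromosome binned sums so the chromosome bootstrap never revisits
  # raw pairs
  per_chrom <- purrr::map(chroms, function(ch) {
    jdx <- which(gm$sites$chrom == ch)
    if (length(jdx) < 2L) return(NULL)
    x <- gm$calls[, jdx, drop = FALSE]
    cv <- suppressWarnings(stats::cov(x, use = "pairwise.complete.obs"))
    w <- w_all[jdx]
    wmat <- outer(w, w)
    cm <- bp_to_morgans(map, ch, gm$sites$pos[jdx])
    dmat <- abs(outer(cm, cm, "-"))
    ut <- upper.tri(dmat)
    d <- dmat[ut]
    stat <- (cv * wmat)[ut]
    keep <- !is.na(stat) & d >= min_morgans & d <= max_morgans
    bin_of <- floor(d[keep] / bin_morgans)
    sums <- tapply(stat[keep], bin_of, sum)
    tibble(
      chrom = ch,
      bin = as.integer(names(sums)),
      sum_stat = as.numeric(sums),
      n_pairs = as.integer(table(bin_of))
    )
  }) |> list_rbind()

  bin_curve <- function(binned) {
    binned |>
      group_by(.data$bin) |>
      summarise(stat = sum(.data$sum_stat) / sum(.data$n_pairs),
                n_pairs = sum(.data$n_pairs), .groups = "drop") |>
      mutate(d = (.data$bin + 0.5) * bin_morgans) |>
      select("d", "stat", "n_pairs")
  }
  fit_curve <- function(bins) {
    fit_exp_decay(bins$d, bins$stat, weights = bins$n_pairs)
  }

  bins <- bin_curve(per_chrom)
  co <- fit_curve(bins)
  # amplitude indistinguishable from zero makes the decay rate unidentifiable
  flag <- if (abs(co[["a"]]) < max(1e-10, 1e-3 * abs(co[["k"]]))) {
    "zero_amplitude"
  } else NA_character_
  set.seed(seed)
  split_chrom <- split(per_chrom, per_chrom$chrom)
  boots <- purrr::map_dbl(seq_len(n_boot), function(b) {
    chs <- sample(names(split_chrom), length(split_chrom), replace = TRUE)
    pb <- dplyr::bind_rows(split_chrom[chs])
    tryCatch(fit_curve(bin_curve(pb))[["g"]], error = function(e) NA_real_)
  })
  ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  structure(
    list(
      method = "weighted_ld",
      generations = unname(co[["g"]]),
      ci = ci,
      amplitude = unname(co[["a"]]), tail = unname(co[["k"]]),
      bins = bins, fit = co, flag = flag
    ),
    class = "admixture_date"
  )
}

#' Fit an exponential decay curve `a exp(-g d) + k`
#'
#' Nonlinear least squares (Levenberg–Marquardt) with the package's
#' documented starting values: `g = g_start` (default 10 generations), `k` =
#' mean of the top-quartile distances (the tail), `a` = first point minus the
#' tail. Used by [admixture_ld_decay()] and exposed for curve-level checks.
#'
#' @param d Distances (Morgans).
#' @param stat Curve values.
#' @param weights Optional fit weights (e.g. pair counts per bin).
#' @param g_start Starting decay rate.
#' @return Named coefficients `a`, `g`, `k`.
#' @export
fit_exp_decay <- function(d, stat, weights = NULL, g_start = 10) {
  if (length(d) < 4L) abort("fewer than 4 usable distance bins")
  ord <- order(d)
  d <- d[ord]
  stat <- stat[ord]
  tail_k <- mean(stat[d >= quantile(d, 0.75)])
  a0 <- stat[1] - tail_k
  if (!is.finite(a0) || abs(a0) < .Machine$double.eps) a0 <- 1e-6
  dat <- data.frame(d = d, stat = stat)
  fit <- minpack.lm::nlsLM(
    stat ~ a * exp(-g * d) + k,
    data = dat,
    start = list(a = a0, g = g_start, k = tail_k),
    weights = if (is.null(weights)) rep(1, nrow(dat)) else weights[ord],
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  coef(fit)
}

#' @export
print.admixture_date <- function(x, ...) {
  cat(sprintf("<admixture_date> method %s: g = %.2f", x$method, x$generations))
  if (!is.null(x$ci) && all(is.finite(x$ci))) {
    cat(sprintf(" (95%% CI %.2f-%.2f)", x$ci[1], x$ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' Ancestry-switch dating
#'
#' Junction-count dating of individual admixture times:
#' `g = 1 + S / (4 L q (1 - q))` with `S` the diploid total of ancestry
#' switches, `L` the map length of the included autosomes in Morgans and `q`
#' the individual's admixed-ancestry proportion. An F1 (`S = 0`) dates to
#' `g = 1`. The formula assumes a single admixture pulse followed by random
#' mating (junctions accrue at `2 q (1-q)` per Morgan per haplotype per
#' generation) and is kept in this one function so an alternative form can be
#' substituted.
#'
#' @param switches Switch count(s) `S` (diploid totals).
#' @param q Admixed-ancestry proportion(s) in `(0, 1)`.
#' @param map_length_morgans Genome map length `L` in Morgans.
#' @param ids Optional ids for the output.
#' @return A tibble of class `admixture_date_switches`: `id`, `switches`,
#'   `q`, `generations`; attributes hold the cohort mean and SD.
#' @export
switch_dating <- function(switches, q, map_length_morgans, ids = NULL) {
  if (any(q <= 0 | q >= 1)) abort("q must be strictly inside (0, 1)")
  if (map_length_morgans <= 0) abort("map length must be > 0")
  if (any(switches < 0)) abort("switch counts must be >= 0")
  g <- 1 + switches / (4 * map_length_morgans * q * (1 - q))
  out <- tibble(
    id = ids %||% as.character(seq_along(g)),
    switches = switches, q = q, generations = g
  )
  attr(out, "mean_generations") <- mean(g)
  attr(out, "sd_generations") <- sd(g)
  class(out) <- c("admixture_date_switches", class(out))
  out
}

#' Convert generations before sampling to calendar years
#'
#' @param g Generations before the reference year (scalar or vector).
#' @param ci Optional half-width (same units) for an interval.
#' @param generation_time Years per generation (default 3, the usual dog and
#'   wolf value).
#' @param reference_year Calendar year of sampling; required, no default.
#' @return A tibble with `generations`, `years_before`, `year`, and when `ci`
#'   is given `year_lo`, `year_hi`.
#' @export
generations_to_years <- function(g, ci = NULL, generation_time = 3,
                                 reference_year) {
  if (missing(reference_year)) abort("reference_year must be given explicitly")
  out <- tibble(
    generations = g,
    years_before = g * generation_time,
    year = round(reference_year - g * generation_time)
  )
  if (!is.null(ci)) {
    out$year_lo <- round(reference_year - (g + ci) * generation_time)
    out$year_hi <- round(reference_year - (g - ci) * generation_time)
  }
  out
}

#' Expected accumulation of new variants
#'
#' `p = mu * n_generations * N_E`: the expected fraction of new variation
#' contributed by mutation over the breed's short history (negligible at
#' SNP-array scale).
#'
#' @param mu Per-site per-generation mutation rate.
#' @param n_generations Number of generations.
#' @param ne Effective population size.
#' @return Expected new-variant fraction.
#' @export
drift_accumulation <- function(mu, n_generations, ne) {
  stopifnot(mu >= 0, n_generations >= 0, ne >= 0)
  mu * n_generations * ne
}
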