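#' Build a PCA block reference panel from parental haplotypes
#'
#' Sites are cut into consecutive, non-overlapping blocks of `block_size`
#' SNPs within each chromosome (trailing partial blocks are dropped). In each
#' block, a PCA is run over the pooled parental haplotype vectors and the
#' parental classes are summarized by the mean and SD of their scores on the
#' top component. Blocks whose class score distributions are inseparable
#' (absolute mean difference below `min_separation` pooled SDs) are flagged
#' uninformative.
#'
#' @param wolf_haps,dog_haps [haplotype_set()]s of the two parental panels
#'   over identical sites.
#' @param block_size SNPs per block (default 10, `>= 2`).
#' @param min_separation Minimum class separation (in pooled SD units) for a
#'   block to count as informative (default 0.5).
#' @param map Optional `genetic_map` for block genetic lengths (default
#'   linear, 100 Mb = 1 Morgan).
#' @return An object of class `ancestry_reference`.
#' @export
build_reference <- function(wolf_haps, dog_haps, block_size = 10,
                            min_separation = 0.5, map = NULL) {
  stopifnot(block_size >= 2)
  if (!identical(wolf_haps$sites[, c("chrom", "pos")],
                 dog_haps$sites[, c("chrom", "pos")])) {
    abort("parental haplotype sets must share the same sites")
  }
  if (nrow(wolf_haps$haps) == 0L || nrow(dog_haps$haps) == 0L) {
    abort("both parental panels must be represented")
  }
  sites <- wolf_haps$sites
  if (is.null(map)) {
    lens <- sites |>
      group_by(.data$chrom) |>
      summarise(len = max(.data$pos))
    map <- linear_map(setNames(lens$len, lens$chrom))
  }
  W <- wolf_haps$haps
  D <- dog_haps$haps
  blocks <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    n_blk <- length(idx) %/% block_size
    for (b in seq_len(n_blk)) {
      cols <- idx[((b - 1L) * block_size + 1L):(b * block_size)]
      X <- rbind(W[, cols, drop = FALSE], D[, cols, drop = FALSE])
      mu <- colMeans(X)
      Xc <- sweep(X, 2, mu)
      sv <- svd(Xc, nu = 0, nv = 1)
      v <- sv$v[, 1]
      sc <- Xc %*% v
      sw <- sc[seq_len(nrow(W))]
      sd_ <- sc[-seq_len(nrow(W))]
      m_w <- mean(sw)
      m_d <- mean(sd_)
      s_w <- sd(sw)
      s_d <- sd(sd_)
      pooled <- sqrt((s_w^2 + s_d^2) / 2)
      floor_sd <- 0.05 * max(sd(sc), .Machine$double.eps)
      informative <- abs(m_w - m_d) > min_separation * max(pooled, floor_sd)
      first <- cols[1]
      last <- cols[block_size]
      d_len <- bp_to_morgans(map, ch, sites$pos[last]) -
        bp_to_morgans(map, ch, sites$pos[first])
      blocks[[length(blocks) + 1L]] <- list(
        chrom = ch, block = b, cols = cols,
        start = sites$pos[first], end = sites$pos[last],
        mid_morgans = (bp_to_morgans(map, ch, sites$pos[first]) +
                         bp_to_morgans(map, ch, sites$pos[last])) / 2,
        mu = mu, v = v,
        m_w = m_w, m_d = m_d,
        s_w = max(s_w, floor_sd), s_d = max(s_d, floor_sd),
        informative = informative
      )
    }
  }
  structure(
    list(blocks = blocks, sites = sites, block_size = block_size, map = map),
    class = "ancestry_reference"
  )
}

#' @export
print.ancestry_reference <- function(x, ...) {
  inf <- mean(vapply(x$blocks, `[[`, TRUE, "informative"))
  cat(sprintf(
    "<ancestry_reference> %d blocks of %d SNPs, %.0f%% informative\n",
    length(x$blocks), x$block_size, 100 * inf
  ))
  invisible(x)
}

# forward-backward smoothing of per-block wolf posteriors along one
# chromosome; transition prob between adjacent blocks 1 - exp(-g * d)
hmm_smooth <- function(p_wolf, d_gaps, g) {
  n <- length(p_wolf)
  if (n <= 1L) return(p_wolf)
  # emissions proportional to the unsmoothed posteriors (equal priors)
  em <- rbind(pmin(pmax(p_wolf, 1e-6), 1 - 1e-6),
              1 - pmin(pmax(p_wolf, 1e-6), 1 - 1e-6))
  t_sw <- pmin(pmax((1 - exp(-g * d_gaps)) / 2, 1e-9), 0.5)
  fwd <- matrix(0, 2, n)
  bwd <- matrix(0, 2, n)
  fwd[, 1] <- em[, 1] / sum(em[, 1])
  for (k in 2:n) {
    ts <- t_sw[k - 1L]
    pred <- c(
      fwd[1, k - 1] * (1 - ts) + fwd[2, k - 1] * ts,
      fwd[1, k - 1] * ts + fwd[2, k - 1] * (1 - ts)
    )
    f <- pred * em[, k]
    fwd[, k] <- f / sum(f)
  }
  bwd[, n] <- c(1, 1)
  for (k in (n - 1L):1L) {
    ts <- t_sw[k]
    b <- c(
      (1 - ts) * em[1, k + 1] * bwd[1, k + 1] + ts * em[2, k + 1] * bwd[2, k + 1],
      ts * em[1, k + 1] * bwd[1, k + 1] + (1 - ts) * em[2, k + 1] * bwd[2, k + 1]
    )
    bwd[, k] <- b / sum(b)
  }
  post <- fwd * bwd
  post[1, ] / colSums(post)
}

#' Deconvolve phased haplotypes into parental-ancestry blocks
#'
#' Each query haplotype is scored on every reference block's top principal
#' component; Gaussian class likelihoods of the score under the wolf and dog
#' reference distributions give a per-block posterior (equal priors), which
#' an optional 2-state HMM smooths along each chromosome with switch
#' probability `1 - exp(-g d)` for block gap `d` Morgans and prior `g`
#' generations since admixture. Blocks are hard-called `wolf` or `dog` when
#' the posterior clears `call_threshold`, else `uncalled`; uninformative
#' blocks always stay at posterior 0.5.
#'
#' @param haps A [haplotype_set()] over the reference's sites.
#' @param ref An [build_reference()] panel.
#' @param smooth Apply HMM smoothing (default `TRUE`).
#' @param hmm_generations Prior generations since admixture for the
#'   transition model (default 10).
#' @param call_threshold Posterior needed for a hard call (default 0.8).
#' @return A tibble of class `ancestry_track`: `hap_id`, `id`, `chrom`,
#'   `block`, `start`, `end`, `p_wolf`, `call`.
#' @export
deconvolve <- function(haps, ref, smooth = TRUE, hmm_generations = 10,
                       call_threshold = 0.8) {
  if (!identical(haps$sites[, c("chrom", "pos")],
                 ref$sites[, c("chrom", "pos")])) {
    abort("query sites do not match the reference panel")
  }
  H <- haps$haps
  n_hap <- nrow(H)
  blocks <- ref$blocks
  n_blk <- length(blocks)
  p_raw <- matrix(0.5, n_hap, n_blk)
  for (k in seq_len(n_blk)) {
    bl <- blocks[[k]]
    if (!bl$informative) next
    sc <- sweep(H[, bl$cols, drop = FALSE], 2, bl$mu) %*% bl$v
    lw <- dnorm(sc, bl$m_w, bl$s_w)
    ld <- dnorm(sc, bl$m_d, bl$s_d)
    tot <- lw + ld
    p <- ifelse(tot > 0, lw / tot, 0.5)
    p_raw[, k] <- p
  }
  blk_tab <- tibble(
    chrom = vapply(blocks, `[[`, "", "chrom"),
    block = vapply(blocks, `[[`, 1L, "block"),
    start = vapply(blocks, `[[`, 1, "start"),
    end = vapply(blocks, `[[`, 1, "end"),
    mid = vapply(blocks, `[[`, 1, "mid_morgans")
  )
  hap_ids <- rownames(H)
  out <- purrr::map(seq_len(n_hap), function(h) {
    p <- p_raw[h, ]
    if (smooth) {
      for (ch in unique(blk_tab$chrom)) {
        kdx <- which(blk_tab$chrom == ch)
        if (length(kdx) > 1L) {
          d_gaps <- diff(blk_tab$mid[kdx])
          p[kdx] <- hmm_smooth(p[kdx], d_gaps, hmm_generations)
        }
      }
    }
    blk_tab |>
      transmute(
        hap_id = hap_ids[h],
        id = sub("_[12]$", "", hap_ids[h]),
        chrom = .data$chrom, block = .data$block,
        start = .data$start, end = .data$end,
        p_wolf = p,
        call = ifelse(p >= call_threshold, "wolf",
                      ifelse(1 - p >= call_threshold, "dog", "uncalled"))
      )
  }) |> list_rbind()
  class(out) <- c("ancestry_track", class(out))
  out
}

#' Genome-wide ancestry proportion from an ancestry track
#'
#' Per individual: the fraction of called blocks assigned to the wolf class,
#' averaged over both haplotypes, plus a block-length-weighted version.
#'
#' @param track An [deconvolve()] result.
#' @return A tibble with `id`, `q`, `q_weighted`, `n_called`, `n_blocks`,
#'   `flag` (`"all_uncalled"` when undefined).
#' @export
genome_wide_ancestry <- function(track) {
  track |>
    group_by(.data$id) |>
    summarise(
      n_blocks = dplyr::n(),
      n_called = sum(.data$call != "uncalled"),
      q = ifelse(.data$n_called > 0,
                 sum(.data$call == "wolf") / .data$n_called, NA_real_),
      q_weighted = {
        called <- .data$call != "uncalled"
        len <- (.data$end - .data$start)[called]
        if (sum(called) > 0) {
          sum(len * (.data$call[called] == "wolf")) / sum(len)
        } else NA_real_
      },
      .groups = "drop"
    ) |>
    mutate(flag = ifelse(.data$n_called == 0, "all_uncalled", NA_character_)) |>
    select("id", "q", "q_weighted", "n_called", "n_blocks", "flag")
}

#' Supervised maximum-likelihood ancestry proportion
#'
#' For each individual, maximizes the binomial log-likelihood of its dosages
#' given per-site mixture frequencies `q p_wolf + (1-q) p_dog` over
#' `q` in `[0, 1]` (1-D bounded optimization, tolerance 1e-6). Parental
#' frequencies are clipped away from 0/1 by `1/(2 n + 1)` of the respective
#' reference sample.
#'
#' @param gm A [genotype_matrix()] of the individuals to score.
#' @param parental_freqs Tibble with per-site `p_wolf`, `p_dog` and optional
#'   `n_wolf`, `n_dog` (reference sample sizes in individuals; default 12).
#' @return A tibble with `id`, `q`, `loglik`, `n_sites`.
#' @export
supervised_q <- function(gm, parental_freqs) {
  pf <- parental_freqs
  n_w <- if ("n_wolf" %in% names(pf)) pf$n_wolf else rep(12, nrow(pf))
  n_d <- if ("n_dog" %in% names(pf)) pf$n_dog else rep(12, nrow(pf))
  clip <- function(p, n) pmin(pmax(p, 1 / (2 * n + 1)), 1 - 1 / (2 * n + 1))
  pw <- clip(pf$p_wolf, n_w)
  pd <- clip(pf$p_dog, n_d)
  informative <- abs(pw - pd) > 1e-12
  if (!any(informative)) abort("no informative sites (parental frequencies identical)")
  purrr::map(seq_len(n_samples(gm)), function(i) {
    x <- gm$calls[i, ]
    ok <- !is.na(x)
    if (!any(ok & informative)) abort("no informative called sites for a sample")
    xo <- x[ok]
    pwo <- pw[ok]
    pdo <- pd[ok]
    nll <- function(q) {
      p <- q * pwo + (1 - q) * pdo
      -sum(xo * log(p) + (2 - xo) * log(1 - p))
    }
    opt <- optimize(nll, c(0, 1), tol = 1e-6)
    tibble(id = gm$samples$id[i], q = opt$minimum, loglik = -opt$objective,
           n_sites = sum(ok))
  }) |> list_rbind()
}

#' Count ancestry switches along called blocks
#'
#' Adjacent called blocks with different hard calls count one switch;
#' uncalled blocks are skipped (the flanking called blocks are compared
#' directly). Counts are summed over both haplotypes and all chromosomes.
#'
#' @param track An [deconvolve()] result.
#' @return A tibble with `id`, `switches`.
#' @export
count_switches <- function(track) {
  track |>
    filter(.data$call != "uncalled") |>
    group_by(.data$id, .data$hap_id, .data$chrom) |>
    summarise(
      sw = {
        calls <- .data$call[order(.data$block)]
        if (length(calls) < 2L) 0L else sum(calls[-1] != calls[-length(calls)])
      },
      .groups = "drop"
    ) |>
    group_by(.data$id) |>
    summarise(switches = sum(.data$sw))
}

#' Blocks fixed for one parental ancestry across a cohort
#'
#' A block is wolf-fixed (dog-fixed) when every haplotype of every listed
#' individual is hard-called wolf (dog) there; a single uncalled or
#' discordant haplotype removes the block.
#'
#' @param track An [deconvolve()] result covering the cohort.
#' @param ids Individuals making up the cohort (default: all in `track`).
#' @return A tibble with `chrom`, `block`, `start`, `end`, `direction`
#'   (`wolf_like` / `dog_like`).
#' @export
fixed_ancestry_blocks <- function(track, ids = unique(track$id)) {
  track |>
    filter(.data$id %in% ids) |>
    group_by(.data$chrom, .data$block, .data$start, .data$end) |>
    summarise(
      direction = ifelse(all(.data$call == "wolf"), "wolf_like",
                         ifelse(all(.data$call == "dog"), "dog_like",
                                NA_character_)),
      .groups = "drop"
    ) |>
    filter(!is.na(.data$direction)) |>
    arrange(.data$chrom, .data$block)
}

#' Ancestry of truth segments at block resolution
#'
#' Assigns each reference block the majority-bp true origin per haplotype —
#' the ground-truth analogue of a deconvolution hard call, for accuracy
#' scoring.
#'
#' @param truth_segments `truth_segments` tibble from [simulate_breed()].
#' @param ref An [build_reference()] panel (defines the blocks).
#' @return A tibble with `hap_id`, `chrom`, `block`, `true_origin`.
#' @export
truth_block_origin <- function(truth_segments, ref) {
  blk <- tibble(
    chrom = vapply(ref$blocks, `[[`, "", "chrom"),
    block = vapply(ref$blocks, `[[`, 1L, "block"),
    start = vapply(ref$blocks, `[[`, 1, "start"),
    end = vapply(ref$blocks, `[[`, 1, "end")
  )
  # cumulative wolf-coverage function per haplotype x chromosome:
  # wolf bp in [a, b) = W(b) - W(a), evaluated by locating a and b in the
  # sorted segment table
  purrr::map(unique(truth_segments$hap_id), function(h) {
    segs_h <- filter(truth_segments, .data$hap_id == h)
    res <- purrr::map(unique(blk$chrom), function(ch) {
      b <- filter(blk, .data$chrom == ch)
      s <- segs_h |> filter(.data$chrom == ch) |> arrange(.data$start)
      wolf_len <- (s$end - s$start) * (s$origin == "wolf")
      cw <- c(0, cumsum(wolf_len))
      W <- function(x) {
        i <- findInterval(x, s$start)
        i <- pmax(i, 1L)
        cw[i] + ifelse(s$origin[i] == "wolf",
                       pmin(pmax(x - s$start[i], 0), s$end[i] - s$start[i]), 0)
      }
      wolf_bp <- W(b$end) - W(b$start)
      b |>
        mutate(
          hap_id = h,
          true_origin = ifelse(wolf_bp >= (b$end - b$start) / 2, "wolf", "dog")
        ) |>
        select("hap_id", "chrom", "block", "true_origin")
    }) |> list_rbind()
    res
  }) |> list_rbind()
}
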