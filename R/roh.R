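#' ROH detection parameters
#'
#' Defaults chosen to resolve the 1–7 Mb ROH regime of SNP-array breed data:
#' at least 25 SNPs and 500 kb per run, at most 1 heterozygote and 2 missing
#' calls inside a run, and no gap between consecutive SNPs larger than 1 Mb.
#'
#' @param min_snps Minimum SNPs per run.
#' @param min_kb Minimum run length, kb.
#' @param max_het Maximum heterozygous calls tolerated inside a run.
#' @param max_missing Maximum missing calls tolerated inside a run.
#' @param max_gap_kb Maximum gap between consecutive SNPs inside a run, kb.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 25, min_kb = 500, max_het = 1,
                       max_missing = 2, max_gap_kb = 1000) {
  p <- list(min_snps = min_snps, min_kb = min_kb, max_het = max_het,
            max_missing = max_missing, max_gap_kb = max_gap_kb)
  if (any(unlist(p) < 0)) abort("roh parameters must be non-negative")
  structure(p, class = "roh_params")
}

# greedy leftmost-maximal scan of one sample on one chromosome.
# is_het / is_mis are logical vectors over the chromosome's sites (position-
# sorted); returns first/last site indices of raw runs before length filters.
scan_runs <- function(is_het, is_mis, pos, params) {
  n <- length(pos)
  runs <- list()
  i <- 1L
  while (i <= n) {
    het <- 0L
    mis <- 0L
    j <- i
    while (j <= n) {
      if (j > i && (pos[j] - pos[j - 1L]) > params$max_gap_kb * 1000) break
      het2 <- het + (!is_mis[j] && is_het[j])
      mis2 <- mis + is_mis[j]
      if (het2 > params$max_het || mis2 > params$max_missing) break
      het <- het2
      mis <- mis2
      j <- j + 1L
    }
    # run is [i, j-1]
    if (j - i > 0L) runs[[length(runs) + 1L]] <- c(i, j - 1L, het, mis)
    i <- max(j, i + 1L)
  }
  runs
}

#' Detect runs of homozygosity
#'
#' Greedy leftmost-maximal scan along each chromosome: a run extends over
#' consecutive sites while its heterozygote and missing-call budgets hold and
#' no inter-SNP gap exceeds `max_gap_kb`; the next run starts after the
#' previous one ends, so runs never overlap. Raw runs are then filtered by
#' `min_snps` and `min_kb`. Run coordinates are the first and last SNP
#' positions (bp, 1-based inclusive).
#'
#' @param gm A [genotype_matrix()] with position-sorted sites.
#' @param samples Sample ids (default all).
#' @param params A [roh_params()].
#' @return A tibble of class `roh_set`: `id`, `group`, `chrom`, `start`,
#'   `end`, `length_bp`, `n_snps`, `n_het`, `n_missing`.
#' @export
detect_roh <- function(gm, samples = gm$samples$id, params = roh_params()) {
  chroms <- unique(gm$sites$chrom)
  out <- purrr::map(samples, function(id) {
    i <- match(id, gm$samples$id)
    grp <- gm$samples$group[i]
    purrr::map(chroms, function(ch) {
      jdx <- which(gm$sites$chrom == ch)
      pos <- gm$sites$pos[jdx]
      x <- gm$calls[i, jdx]
      runs <- scan_runs(!is.na(x) & x == 1L, is.na(x), pos, params)
      if (!length(runs)) return(NULL)
      m <- do.call(rbind, runs)
      tibble(
        id = id, group = grp, chrom = ch,
        start = pos[m[, 1]], end = pos[m[, 2]],
        n_snps = m[, 2] - m[, 1] + 1L, n_het = m[, 3], n_missing = m[, 4]
      )
    }) |> list_rbind()
  }) |> list_rbind()
  if (nrow(out) == 0L) {
    out <- tibble(
      id = character(), group = character(), chrom = character(),
      start = integer(), end = integer(), n_snps = integer(),
      n_het = integer(), n_missing = integer()
    )
  }
  out <- out |>
    mutate(length_bp = .data$end - .data$start) |>
    filter(.data$n_snps >= params$min_snps,
           .data$length_bp >= params$min_kb * 1000) |>
    select("id", "group", "chrom", "start", "end", "length_bp",
           "n_snps", "n_het", "n_missing")
  class(out) <- c("roh_set", class(out))
  out
}

#' Genome length spanned by the analysed SNPs
#' @param gm A [genotype_matrix()].
#' @return Total bp from first to last SNP per chromosome, summed.
#' @export
covered_length <- function(gm) {
  gm$sites |>
    group_by(.data$chrom) |>
    summarise(span = max(.data$pos) - min(.data$pos)) |>
    pull(.data$span) |>
    sum()
}

#' F_ROH: fraction of the SNP-covered genome in runs of homozygosity
#'
#' @param rohset A [detect_roh()] result.
#' @param covered Covered genome length in bp (see [covered_length()]), or a
#'   [genotype_matrix()] from which to compute it.
#' @param samples Sample ids to report (default: those present in `rohset`;
#'   pass explicitly to include zero-ROH samples).
#' @return A tibble with `id`, `group`, `froh`.
#' @export
froh <- function(rohset, covered, samples = NULL) {
  if (inherits(covered, "genotype_matrix")) covered <- covered_length(covered)
  if (covered <= 0) abort("covered length must be > 0")
  per <- rohset |>
    group_by(.data$id, .data$group) |>
    summarise(froh = sum(.data$length_bp) / covered, .groups = "drop")
  if (!is.null(samples)) {
    per <- tibble(id = samples) |>
      dplyr::left_join(per, by = "id") |>
      mutate(froh = ifelse(is.na(.data$froh), 0, .data$froh))
  }
  per
}

#' Per-group ROH summaries
#'
#' Mean per-individual ROH count and length (with SDs) and a pooled length
#' histogram in fixed kb bins.
#'
#' @param rohset A [detect_roh()] result.
#' @param bin_kb Histogram bin width in kb (default 500).
#' @return A list with `by_group` (tibble `group`, `n_ind`, `mean_count`,
#'   `sd_count`, `mean_length_kb`, `sd_length_kb`) and `histogram` (tibble
#'   `group`, `bin_start_kb`, `n`).
#' @export
roh_summary <- function(rohset, bin_kb = 500) {
  per_ind <- rohset |>
    group_by(.data$group, .data$id) |>
    summarise(count = dplyr::n(),
              mean_len = mean(.data$length_bp) / 1000, .groups = "drop")
  by_group <- per_ind |>
    group_by(.data$group) |>
    summarise(
      n_ind = dplyr::n(),
      mean_count = mean(.data$count), sd_count = sd(.data$count),
      mean_length_kb = mean(.data$mean_len), sd_length_kb = sd(.data$mean_len),
      .groups = "drop"
    )
  histogram <- rohset |>
    mutate(bin_start_kb = floor(.data$length_bp / 1000 / bin_kb) * bin_kb) |>
    count(.data$group, .data$bin_start_kb, name = "n")
  list(by_group = by_group, histogram = histogram)
}

#' Genomic regions inside a ROH in every listed sample
#'
#' Intersects, across samples, the union of each sample's runs — the regions
#' autozygous in all of them (used for the shared-ROH outlier panel). Returns
#' half-open 0-based intervals.
#'
#' @param rohset A [detect_roh()] result.
#' @param samples Sample ids to intersect over (default: all in `rohset`).
#' @return A tibble with `chrom`, `start`, `end` (may be empty).
#' @export
shared_roh_regions <- function(rohset, samples = unique(rohset$id)) {
  if (!all(samples %in% rohset$id)) {
    # a sample without any run makes the intersection empty
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  sub <- filter(rohset, .data$id %in% samples)
  chroms <- unique(sub$chrom)
  out <- purrr::map(chroms, function(ch) {
    per_sample <- sub |>
      filter(.data$chrom == ch) |>
      group_by(.data$id) |>
      group_split()
    if (length(per_sample) < length(samples)) return(NULL)
    ir <- purrr::map(per_sample, function(d) {
      IRanges::reduce(IRanges::IRanges(start = d$start, end = d$end))
    })
    inter <- Reduce(IRanges::intersect, ir)
    if (length(inter) == 0L) return(NULL)
    tibble(chrom = ch,
           start = as.numeric(IRanges::start(inter)) - 1, # half-open 0-based
           end = as.numeric(IRanges::end(inter)))
  }) |> list_rbind()
  if (nrow(out) == 0L) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric())
  }
  out
}
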