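#' Sites fixed for opposite alleles in the two parental groups
#'
#' A fixed-difference site has per-site parental F_ST of 1: each parental
#' group is monomorphic on its called chromosomes and the two groups carry
#' different alleles.
#'
#' @param freqs A [site_frequencies()] table containing groups
#'   `wild_parent` and `dom_parent` (or the groups named in `groups`).
#' @param groups Length-2 character: the parental group labels.
#' @return A tibble with `site`, `chrom`, `pos`, `p_wolf`, `p_dog`.
#' @export
fixed_diff_sites <- function(freqs, groups = c("wild_parent", "dom_parent")) {
  w <- filter(freqs, .data$group == groups[1])
  d <- filter(freqs, .data$group == groups[2])
  if (nrow(w) == 0L || nrow(d) == 0L) abort("both parental groups needed")
  stopifnot(identical(w$site, d$site))
  called <- w$n_chrom > 0 & d$n_chrom > 0
  fixed <- called &
    (w$freq %in% c(0, 1)) & (d$freq %in% c(0, 1)) & (w$freq != d$freq)
  tibble(
    site = w$site[fixed], chrom = w$chrom[fixed], pos = w$pos[fixed],
    p_wolf = w$freq[fixed], p_dog = d$freq[fixed]
  )
}

#' Select ancestry-informative markers by minimal breed-to-parent F_ST
#'
#' Among the fixed-difference sites (or among 10-SNP blocks scored by the
#' mean per-site F_ST of their fixed-difference sites), retains the lowest
#' `fraction` quantile of F_ST(breed, wolf) as the wolf-like panel and of
#' F_ST(breed, dog) as the dog-like panel. Ties at the quantile boundary are
#' all retained and the realized counts reported.
#'
#' @param fixed_sites A [fixed_diff_sites()] table.
#' @param fst_breed_wolf,fst_breed_dog Per-site F_ST tables for the breed
#'   against each parent, as rows of `pairwise_fst()$per_site` (must carry
#'   `site` and `fst`).
#' @param fraction Quantile retained (default 0.01).
#' @param unit `"snp"` (default) or `"block10"`.
#' @param block_size Sites per block for `unit = "block10"`.
#' @return A list with `wolf_like` and `dog_like` tibbles (per site: `site`,
#'   `chrom`, `pos`, `fst`; per block: `chrom`, `block`, `start`, `end`,
#'   `fst`, `n_fixed`) and `counts`.
#' @export
aim_select <- function(fixed_sites, fst_breed_wolf, fst_breed_dog,
                       fraction = 0.01, unit = c("snp", "block10"),
                       block_size = 10) {
  unit <- match.arg(unit)
  if (nrow(fixed_sites) == 0L) abort("no fixed-difference sites")
  stopifnot(fraction > 0, fraction <= 1)

  score_one <- function(fst_tab) {
    sc <- fst_tab[match(fixed_sites$site, fst_tab$site), ]
    scored <- fixed_sites |> mutate(fst = sc$fst)
    if (unit == "snp") {
      scored <- filter(scored, !is.na(.data$fst))
      cut <- quantile(scored$fst, fraction, type = 1)
      scored |>
        filter(.data$fst <= cut) |>
        arrange(.data$fst) |>
        select("site", "chrom", "pos", "fst")
    } else {
      # block index from the full site grid: consecutive runs of block_size
      blocks <- scored |>
        mutate(block_id = paste(.data$chrom, (.data$site - 1L) %/% block_size)) |>
        group_by(.data$chrom, .data$block_id) |>
        summarise(
          start = min(.data$pos), end = max(.data$pos),
          fst = mean(.data$fst, na.rm = TRUE), n_fixed = dplyr::n(),
          .groups = "drop"
        ) |>
        filter(is.finite(.data$fst))
      cut <- quantile(blocks$fst, fraction, type = 1)
      blocks |>
        filter(.data$fst <= cut) |>
        arrange(.data$fst) |>
        rename(block = "block_id")
    }
  }
  wolf_like <- score_one(fst_breed_wolf)
  dog_like <- score_one(fst_breed_dog)
  both <- if (unit == "snp") intersect(wolf_like$site, dog_like$site) else character()
  if (length(both)) {
    warn(sprintf("%d site(s) fall in both panels (low F_ST to both parents)",
                 length(both)))
  }
  list(
    wolf_like = wolf_like, dog_like = dog_like,
    counts = tibble(
      panel = c("wolf_like", "dog_like"),
      n = c(nrow(wolf_like), nrow(dog_like)),
      n_candidates = nrow(fixed_sites)
    )
  )
}

#' Expand sites or blocks into flanked genomic intervals
#'
#' Adds `flank_bp` on each side (the gene-search window), clipping at
#' chromosome bounds. Outputs half-open 0-based intervals: a site at 1-based
#' position `pos` becomes `[pos - 1 - flank, pos + flank)`; a block from
#' `start` to `end` becomes `[start - 1 - flank, end + flank)`.
#'
#' @param x Tibble with `chrom` and either `pos` (sites) or `start`/`end`
#'   (blocks; 1-based SNP positions).
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param flank_bp Flank on each side (default 50000).
#' @param merge Merge overlapping output intervals (default `FALSE`).
#' @return A tibble with `chrom`, `start`, `end` (half-open 0-based).
#' @export
expand_intervals <- function(x, chrom_lengths, flank_bp = 50000, merge = FALSE) {
  if (!all(unique(x$chrom) %in% names(chrom_lengths))) {
    abort("unknown chromosome length for some interval")
  }
  lo <- if ("pos" %in% names(x)) x$pos else x$start
  hi <- if ("pos" %in% names(x)) x$pos else x$end
  out <- tibble(
    chrom = x$chrom,
    start = pmax(0, lo - 1 - flank_bp),
    end = pmin(unname(chrom_lengths[x$chrom]), hi + flank_bp)
  )
  if (merge && nrow(out)) {
    out <- purrr::map(unique(out$chrom), function(ch) {
      d <- filter(out, .data$chrom == ch)
      ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
      tibble(chrom = ch, start = IRanges::start(ir) - 1,
             end = as.numeric(IRanges::end(ir)))
    }) |> list_rbind()
  }
  arrange(out, .data$chrom, .data$start)
}

#' Consolidate outlier panels into one provenance-tagged table
#'
#' Groups intervals from several panels by transitive overlap (within
#' chromosome); each merged record spans the union of its members and lists
#' the contributing panel names. Records whose members disagree on direction
#' are kept separate per direction and flagged.
#'
#' @param panels Named list of tibbles, each with `chrom`, `start`, `end`
#'   (half-open 0-based) and optionally `direction`.
#' @return A tibble with `chrom`, `start`, `end`, `direction`, `methods`
#'   (comma-separated), `n_methods`, `conflict`.
#' @export
consolidate_panels <- function(panels) {
  stopifnot(length(panels) >= 1, !is.null(names(panels)))
  recs <- purrr::imap(panels, function(d, nm) {
    if (nrow(d) == 0L) return(NULL)
    tibble(
      chrom = d$chrom, start = d$start, end = d$end,
      direction = if ("direction" %in% names(d)) d$direction else NA_character_,
      method = nm
    )
  }) |> list_rbind()
  if (is.null(recs) || nrow(recs) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  direction = character(), methods = character(),
                  n_methods = integer(), conflict = logical()))
  }
  out <- purrr::map(unique(recs$chrom), function(ch) {
    d <- filter(recs, .data$chrom == ch)
    ir <- IRanges::IRanges(start = d$start + 1, end = d$end)
    # transitive overlap closure = connected components = reduce() bins;
    # min.gapwidth = 0 keeps merely abutting intervals separate
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    grp <- IRanges::findOverlaps(ir, red, select = "first")
    d |>
      mutate(cluster = grp) |>
      group_by(.data$cluster) |>
      group_split() |>
      purrr::map(function(cl) {
        dirs <- unique(na.omit(cl$direction))
        conflict <- length(dirs) > 1L
        split_by <- if (conflict) dirs else list(NULL)
        purrr::map(split_by, function(dd) {
          sub <- if (is.null(dd)) cl else filter(cl, .data$direction == dd)
          tibble(
            chrom = ch,
            start = min(sub$start), end = max(sub$end),
            direction = if (is.null(dd)) {
              if (length(dirs)) dirs else NA_character_
            } else dd,
            methods = paste(sort(unique(sub$method)), collapse = ","),
            n_methods = dplyr::n_distinct(sub$method),
            conflict = conflict
          )
        }) |> list_rbind()
      }) |> list_rbind()
  }) |> list_rbind()
  arrange(out, .data$chrom, .data$start)
}
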