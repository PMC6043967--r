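#' Diploid genotype matrix with sample groups and a site table
#'
#' The central container of the package: diploid calls for a set of samples at
#' a set of biallelic sites. Calls count copies of `a2` (0, 1, 2) with `NA` for
#' missing. Samples carry a group label (`breed`, `wild_parent`, `dom_parent`
#' or `other`) used by every per-group statistic.
#'
#' @param calls Integer matrix, samples x sites, values 0/1/2/`NA`.
#' @param sites Data frame with columns `chrom`, `pos` (1-based bp), `a1`,
#'   `a2`. Positions must be strictly increasing within each chromosome.
#' @param samples Data frame with columns `id` (unique) and `group`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
#' @examples
#' gm <- genotype_matrix(
#'   calls = rbind(c(0, 1, 2), c(2, NA, 0)),
#'   sites = tibble::tibble(chrom = "1", pos = c(100L, 200L, 300L),
#'                          a1 = "A", a2 = "B"),
#'   samples = tibble::tibble(id = c("s1", "s2"), group = "breed")
#' )
#' gm
genotype_matrix <- function(calls, sites, samples) {
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(
    all(c("chrom", "pos", "a1", "a2") %in% names(sites)),
    all(c("id", "group") %in% names(samples))
  )
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(sites)) {
    abort("`calls` must be samples x sites.")
  }
  if (anyDuplicated(samples$id)) abort("duplicate sample ids")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("calls must be 0, 1, 2 or NA")
  }
  ord_ok <- sites |>
    mutate(.i = dplyr::row_number()) |>
    group_by(.data$chrom) |>
    summarise(ok = all(diff(.data$pos) > 0) || dplyr::n() == 1L) |>
    pull(.data$ok)
  if (!all(ord_ok)) abort("positions must be strictly increasing within chromosome")
  dimnames(calls) <- list(samples$id, NULL)
  structure(
    list(calls = calls, sites = sites, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d sites on %d chromosome(s)\n",
    n_samples(x), n_sites(x), dplyr::n_distinct(x$sites$chrom)
  ))
  grp <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Numbers of samples and sites
#' @param gm A [genotype_matrix()].
#' @return Integer scalar.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_sites <- function(gm) ncol(gm$calls)

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param i Sample index (logical, integer or sample ids).
#' @param j Site index (logical or integer).
#' @param ... Unused.
#' @return A [genotype_matrix()].
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_sites(x))
  if (is.character(i)) i <- match(i, x$samples$id)
  genotype_matrix(
    x$calls[i, j, drop = FALSE],
    x$sites[j, , drop = FALSE],
    x$samples[i, , drop = FALSE]
  )
}

#' Dosage matrix (copies of the second allele)
#' @param gm A [genotype_matrix()].
#' @return Integer matrix samples x sites with `NA` for missing calls.
#' @export
dosage <- function(gm) gm$calls

#' Per-sample and per-site call rates
#' @param gm A [genotype_matrix()].
#' @return A tibble with `id`/`site` and `call_rate`.
#' @export
sample_call_rate <- function(gm) {
  tibble(
    id = gm$samples$id,
    group = gm$samples$group,
    call_rate = rowMeans(!is.na(gm$calls))
  )
}

#' @rdname sample_call_rate
#' @export
site_call_rate <- function(gm) {
  gm$sites |>
    mutate(site = dplyr::row_number(), call_rate = colMeans(!is.na(gm$calls))) |>
    select("site", "chrom", "pos", "call_rate")
}

#' Restrict a genotype matrix to one or more sample groups
#' @param gm A [genotype_matrix()].
#' @param groups Character vector of group labels to keep.
#' @return A [genotype_matrix()].
#' @export
filter_groups <- function(gm, groups) {
  keep <- gm$samples$group %in% groups
  if (!any(keep)) abort("no samples in requested group(s)")
  gm[keep, ]
}
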