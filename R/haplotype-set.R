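#' Phased haplotypes aligned to a site table
#'
#' Two binary haplotypes per sample over the same site index as a
#' [genotype_matrix()]. Row order is `id_1`, `id_2` for each sample in order;
#' alleles are 0/1 counting copies of `a2`.
#'
#' @param haps Integer matrix, (2 x samples) rows x sites, values 0/1.
#' @param sites Site table as in [genotype_matrix()].
#' @param sample_ids Character vector of sample ids (half the row count).
#' @param phased Logical flag; `TRUE` for truly phased data.
#'
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(haps, sites, sample_ids, phased = TRUE) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  sites <- as_tibble(sites)
  if (nrow(haps) != 2L * length(sample_ids)) {
    abort("`haps` must have two rows per sample")
  }
  if (ncol(haps) != nrow(sites)) abort("`haps` columns must match `sites` rows")
  vals <- haps[!is.na(haps)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 1L)) {
    abort("haplotype alleles must be 0/1")
  }
  hap_ids <- paste(rep(sample_ids, each = 2L), rep(1:2, length(sample_ids)), sep = "_")
  dimnames(haps) <- list(hap_ids, NULL)
  structure(
    list(haps = haps, sites = sites, sample_ids = sample_ids, phased = phased),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf(
    "<haplotype_set> %d haplotypes (%d samples) x %d sites%s\n",
    nrow(x$haps), length(x$sample_ids), ncol(x$haps),
    if (x$phased) ", phased" else ""
  ))
  invisible(x)
}

#' Collapse haplotypes to diploid genotypes
#'
#' @param hs A [haplotype_set()].
#' @param groups Optional named vector / tibble mapping sample id to group;
#'   defaults to `"other"`.
#' @return A [genotype_matrix()].
#' @export
haps_to_genotypes <- function(hs, groups = NULL) {
  idx1 <- seq(1L, nrow(hs$haps), by = 2L)
  calls <- hs$haps[idx1, , drop = FALSE] + hs$haps[idx1 + 1L, , drop = FALSE]
  grp <- rep("other", length(hs$sample_ids))
  if (!is.null(groups)) {
    if (is.data.frame(groups)) groups <- setNames(groups$group, groups$id)
    grp <- unname(groups[hs$sample_ids])
  }
  genotype_matrix(calls, hs$sites, tibble(id = hs$sample_ids, group = grp))
}

#' Check that a haplotype set is consistent with diploid calls
#'
#' At every non-missing genotype call the two haplotype alleles must sum to
#' the call.
#'
#' @param hs A [haplotype_set()].
#' @param gm A [genotype_matrix()] over the same samples and sites.
#' @return `TRUE` invisibly; aborts with the first offending sample/site
#'   otherwise.
#' @export
check_hap_consistency <- function(hs, gm) {
  if (!identical(hs$sample_ids, gm$samples$id)) abort("sample ids differ")
  if (n_sites(gm) != ncol(hs$haps)) abort("site counts differ")
  idx1 <- seq(1L, nrow(hs$haps), by = 2L)
  sums <- hs$haps[idx1, , drop = FALSE] + hs$haps[idx1 + 1L, , drop = FALSE]
  bad <- which(!is.na(gm$calls) & sums != gm$calls, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "haplotype pair does not sum to genotype for sample '%s' at site %d",
      gm$samples$id[bad[1, 1]], bad[1, 2]
    ))
  }
  invisible(TRUE)
}

#' Subset haplotypes to a sample set
#' @param hs A [haplotype_set()].
#' @param ids Sample ids to keep.
#' @return A [haplotype_set()].
#' @export
subset_haplotypes <- function(hs, ids) {
  i <- match(ids, hs$sample_ids)
  if (anyNA(i)) abort("unknown sample id")
  rows <- as.vector(rbind(2L * i - 1L, 2L * i))
  haplotype_set(hs$haps[rows, , drop = FALSE], hs$sites, ids, hs$phased)
}
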