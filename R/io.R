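#' Read PLINK text PED/MAP files
#'
#' Parses the classic 6-column-header PED format (family id, individual id,
#' father, mother, sex, phenotype, then two allele columns per site) together
#' with its MAP file (chrom, snp id, genetic position, bp). The family-id
#' column is used as the sample group when it matches one of the package's
#' group labels. A `0 0` genotype is a missing call. Allele coding is
#' normalized per site so that `a1 < a2` alphabetically and calls count copies
#' of `a2`; sites observed with more than two alleles are an error. MAP files
#' with out-of-order positions are reordered (ascending bp within chromosome)
#' with a warning.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- read.table(map_path, header = FALSE, sep = "",
                    colClasses = c("character", "character", "numeric", "integer"))
  names(map) <- c("chrom", "snp", "cm", "pos")
  n_site <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * n_site
  lens <- lengths(toks)
  if (any(lens != want)) {
    bad <- which(lens != want)[1]
    abort(sprintf(
      "PED line %d has %d fields, expected %d (ragged PED)", bad, lens[bad], want
    ))
  }
  n_samp <- length(toks)
  meta <- t(vapply(toks, function(x) x[1:6], character(6)))
  al <- matrix("", n_samp, 2L * n_site)
  for (i in seq_len(n_samp)) al[i, ] <- toks[[i]][-(1:6)]
  a_first <- al[, seq(1L, 2L * n_site, by = 2L), drop = FALSE]
  a_second <- al[, seq(2L, 2L * n_site, by = 2L), drop = FALSE]

  calls <- matrix(NA_integer_, n_samp, n_site)
  a1 <- a2 <- character(n_site)
  for (j in seq_len(n_site)) {
    x <- a_first[, j]
    y <- a_second[, j]
    miss <- x == "0" | y == "0"
    obs <- sort(unique(c(x[!miss], y[!miss])))
    if (length(obs) > 2L) {
      abort(sprintf("site %s has > 2 alleles: %s", map$snp[j],
                    paste(obs, collapse = ",")))
    }
    if (length(obs) == 2L) {
      a1[j] <- obs[1]
      a2[j] <- obs[2]
      calls[, j] <- (x == a2[j]) + (y == a2[j])
    } else {
      # monomorphic (or fully missing) site: the observed allele becomes a1
      # and the unseen second allele is unknown ("0"); dosage of a2 is 0
      a1[j] <- if (length(obs)) obs[1] else "0"
      a2[j] <- "0"
      calls[, j] <- 0L
    }
    calls[miss, j] <- NA_integer_
  }

  sites <- tibble(chrom = map$chrom, pos = map$pos, a1 = a1, a2 = a2)
  grp <- ifelse(meta[, 1] %in% .group_levels, meta[, 1], "other")
  samples <- tibble(id = meta[, 2], group = grp)

  # enforce the container's site order: ascending bp within chromosome
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(ord, seq_len(n_site))) {
    warn("MAP positions out of order; sites reordered by position within chromosome")
    sites <- sites[ord, ]
    calls <- calls[, ord, drop = FALSE]
  }
  genotype_matrix(calls, sites, samples)
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of [read_plink_text()]: group label as family id, unknown parents
#' and phenotype as `0`/`-9`, missing genotypes as `0 0`.
#'
#' @param gm A [genotype_matrix()].
#' @param ped_path,map_path Output paths.
#' @return The paths, invisibly.
#' @export
write_plink_text <- function(gm, ped_path, map_path) {
  sites <- gm$sites
  map <- data.frame(
    chrom = sites$chrom,
    snp = sprintf("snp_%s_%d", sites$chrom, sites$pos),
    cm = 0,
    pos = sites$pos
  )
  write.table(map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  n_site <- n_sites(gm)
  allele_str <- function(call, a1, a2) {
    out <- character(length(call))
    out[is.na(call)] <- "0 0"
    out[!is.na(call) & call == 0L] <- paste(a1, a1)[!is.na(call) & call == 0L]
    out[!is.na(call) & call == 1L] <- paste(a1, a2)[!is.na(call) & call == 1L]
    out[!is.na(call) & call == 2L] <- paste(a2, a2)[!is.na(call) & call == 2L]
    out
  }
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n_samples(gm))) {
    geno <- allele_str(gm$calls[i, ], sites$a1, sites$a2)
    writeLines(paste(
      gm$samples$group[i], gm$samples$id[i], "0", "0", "0", "-9",
      paste(geno, collapse = " ")
    ), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Write genomic intervals as BED3+
#'
#' Intervals are half-open, 0-based (BED convention). Records are written
#' sorted by chromosome then start; overlapping intervals are preserved as
#' given (no merging).
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally further
#'   annotation columns (written as extra BED columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(intervals, path) {
  intervals <- as_tibble(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    abort("intervals must satisfy start < end")
  }
  extra <- setdiff(names(intervals), c("chrom", "start", "end"))
  out <- intervals |>
    arrange(.data$chrom, .data$start) |>
    select(dplyr::all_of(c("chrom", "start", "end", extra)))
  if (nrow(out) == 0L) {
    file.create(path)
  } else {
    write.table(format(as.data.frame(out), scientific = FALSE, trim = TRUE),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read/write phased haplotypes as TSV
#'
#' The interchange format is a TSV with header: `chrom`, `pos`, then one 0/1
#' column per haplotype named `<sample>_1`, `<sample>_2`.
#'
#' @param hs A [haplotype_set()].
#' @param path File path.
#' @return For the reader, a [haplotype_set()]; for the writer, `path`.
#' @export
write_haplotypes_tsv <- function(hs, path) {
  out <- cbind(
    hs$sites[, c("chrom", "pos")],
    as.data.frame(t(hs$haps))
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotypes_tsv
#' @param a1,a2 Allele labels to attach to the site table (defaults `"A"`,
#'   `"B"`).
#' @export
read_haplotypes_tsv <- function(path, a1 = "A", a2 = "B") {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  hap_cols <- setdiff(names(tab), c("chrom", "pos"))
  ids <- unique(sub("_[12]$", "", hap_cols))
  expect <- paste(rep(ids, each = 2), rep(1:2, length(ids)), sep = "_")
  if (!identical(hap_cols, expect)) {
    abort("haplotype columns must come in <sample>_1, <sample>_2 pairs")
  }
  haps <- t(vapply(tab[hap_cols], as.integer, integer(nrow(tab))))
  sites <- tibble(
    chrom = tab$chrom, pos = as.integer(tab$pos), a1 = a1, a2 = a2
  )
  haplotype_set(haps, sites, ids)
}

#' Read/write pedigree tables
#'
#' TSV with header `id`, `sire`, `dam`, `founder_pop`, `generation`; unknown
#' parents are `0`, non-founders have an empty `founder_pop`.
#'
#' @param ped A pedigree tibble (see [pedigree_table()]).
#' @param path File path.
#' @return For the reader, a validated pedigree tibble; for the writer,
#'   `path`.
#' @export
write_pedigree_tsv <- function(ped, path) {
  out <- ped |>
    mutate(
      sire = ifelse(is.na(.data$sire), "0", .data$sire),
      dam = ifelse(is.na(.data$dam), "0", .data$dam),
      founder_pop = ifelse(is.na(.data$founder_pop), "", .data$founder_pop)
    )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", na.strings = NULL)
  pedigree_table(
    id = tab$id,
    sire = ifelse(tab$sire == "0", NA, tab$sire),
    dam = ifelse(tab$dam == "0", NA, tab$dam),
    founder_pop = ifelse(tab$founder_pop == "", NA, tab$founder_pop),
    generation = as.integer(tab$generation)
  )
}
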