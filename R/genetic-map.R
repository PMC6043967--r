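#' Genetic maps: bp to Morgans
#'
#' The default map is linear at 1 Morgan per 100 Mb (`rate = 1e-8`
#' Morgan/bp), the usual SNP-array convention for the dog genome when no
#' recombination map is supplied. A table map interpolates linearly between
#' (bp, cM) anchors read from a map file.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param rate Morgans per bp (default `1e-8`, i.e. 100 Mb = 1 Morgan).
#' @return An object of class `genetic_map`.
#' @export
#' @examples
#' map <- linear_map(c("1" = 50e6))
#' bp_to_morgans(map, "1", 100e6) # 1 Morgan
linear_map <- function(chrom_lengths, rate = 1e-8) {
  stopifnot(all(chrom_lengths > 0), rate > 0)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  }
  structure(
    list(type = "linear", rate = rate, chrom_lengths = chrom_lengths),
    class = "genetic_map"
  )
}

#' Read a genetic map table (chrom, bp, cM)
#'
#' Tab-separated with a header. Within each chromosome the anchors must be
#' non-decreasing in both bp and cM; positions outside the anchored range are
#' extrapolated with the boundary interval's rate.
#'
#' @param path Path to the TSV file.
#' @param chrom_lengths Named lengths (bp); defaults to the last anchor.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, chrom_lengths = NULL) {
  tab <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                              colClasses = c("character", "numeric", "numeric")))
  names(tab) <- c("chrom", "bp", "cM")
  tab <- arrange(tab, .data$chrom, .data$bp)
  ok <- tab |>
    group_by(.data$chrom) |>
    summarise(mono = all(diff(.data$cM) >= 0)) |>
    pull(.data$mono)
  if (!all(ok)) abort("map cM values must be non-decreasing within chromosome")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tab |>
      group_by(.data$chrom) |>
      summarise(len = max(.data$bp)) |>
      (\(d) setNames(d$len, d$chrom))()
  }
  structure(
    list(type = "table", table = tab, chrom_lengths = chrom_lengths),
    class = "genetic_map"
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf(
    "<genetic_map> %s, %d chromosome(s), total %.1f Morgans\n",
    x$type, length(x$chrom_lengths), total_map_length(x)
  ))
  invisible(x)
}

#' Convert physical to genetic position
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome label (scalar).
#' @param bp Physical position(s), bp, `>= 0`.
#' @return Genetic position(s) in Morgans.
#' @export
bp_to_morgans <- function(map, chrom, bp) {
  chrom <- as.character(chrom)
  if (!chrom %in% names(map$chrom_lengths)) {
    abort(sprintf("unknown chromosome '%s'", chrom))
  }
  if (any(bp < 0)) abort("bp must be >= 0")
  if (map$type == "linear") return(bp * map$rate)
  anchors <- filter(map$table, .data$chrom == !!chrom)
  if (nrow(anchors) < 2L) abort(sprintf("chromosome '%s' has < 2 map anchors", chrom))
  # linear interpolation with boundary-rate extrapolation, cM -> Morgans
  approx_ext(anchors$bp, anchors$cM, bp) / 100
}

# approx() with linear extrapolation beyond the anchored range
approx_ext <- function(x, y, xout) {
  res <- stats::approx(x, y, xout, rule = 2, ties = "ordered")$y
  lo <- xout < x[1]
  hi <- xout > x[length(x)]
  if (any(lo)) {
    r <- (y[2] - y[1]) / (x[2] - x[1])
    res[lo] <- y[1] + (xout[lo] - x[1]) * r
  }
  if (any(hi)) {
    n <- length(x)
    r <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    res[hi] <- y[n] + (xout[hi] - x[n]) * r
  }
  res
}

#' Total genetic length of the mapped genome
#' @param map A `genetic_map`.
#' @param chroms Chromosomes to include (default all).
#' @return Length in Morgans.
#' @export
total_map_length <- function(map, chroms = names(map$chrom_lengths)) {
  sum(vapply(
    chroms,
    function(ch) bp_to_morgans(map, ch, map$chrom_lengths[[ch]]),
    numeric(1)
  ))
}

# invert a genetic position (Morgans) to bp; linear maps only need the rate,
# table maps invert by interpolation on the anchor grid
morgans_to_bp <- function(map, chrom, m) {
  if (map$type == "linear") return(m / map$rate)
  anchors <- filter(map$table, .data$chrom == !!chrom)
  approx_ext(anchors$cM / 100, anchors$bp, m)
}
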