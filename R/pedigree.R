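#' Construct and validate a pedigree table
#'
#' A pedigree is a tibble with one row per individual: `id`, `sire`, `dam`
#' (`NA` for unknown), `founder_pop` (population label for founders, `NA`
#' otherwise) and `generation` (birth generation; founders brought in from
#' outside carry the generation before their first offspring). The table must
#' be acyclic with parents listed before offspring.
#'
#' @param id,sire,dam Character vectors (or a data frame via `ped`).
#' @param founder_pop Character vector, `NA` for non-founders.
#' @param generation Integer vector.
#' @return A tibble of class `pedigree`.
#' @export
pedigree_table <- function(id, sire = NA, dam = NA, founder_pop = NA,
                           generation = NA_integer_) {
  ped <- tibble(
    id = as.character(id),
    sire = as.character(sire),
    dam = as.character(dam),
    founder_pop = as.character(founder_pop),
    generation = as.integer(generation)
  )
  if (anyDuplicated(ped$id)) abort("duplicate pedigree ids")
  known <- c(NA, ped$id)
  if (!all(ped$sire %in% known) || !all(ped$dam %in% known)) {
    abort("sire/dam ids must appear in the pedigree (or be NA)")
  }
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  par_pos <- cbind(pos[ped$sire], pos[ped$dam])
  bad <- which(par_pos >= pos, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "pedigree cycle or unordered record: '%s' listed before its parent",
      ped$id[bad[1, 1]]
    ))
  }
  founders <- is.na(ped$sire) & is.na(ped$dam)
  class(ped) <- c("pedigree", class(ped))
  ped
}

#' Wright's kinship matrix from a pedigree
#'
#' Recursive path-counting kinship: founders have `f(i,i) = 0.5` and zero
#' kinship to everyone earlier; for a non-founder,
#' `f(i,j) = (f(sire_i, j) + f(dam_i, j)) / 2` for earlier `j`, and
#' `f(i,i) = (1 + f(sire_i, dam_i)) / 2`. Missing parents contribute zero
#' kinship.
#'
#' @param ped A [pedigree_table()].
#' @return A symmetric numeric matrix with dimnames = ids.
#' @export
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  ids <- ped$id
  pos <- setNames(seq_len(n), ids)
  si <- pos[ped$sire]
  di <- pos[ped$dam]
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  kin_par <- function(p, j) if (is.na(p)) 0 else K[p, j]
  for (i in seq_len(n)) {
    if (is.na(si[i]) && is.na(di[i])) {
      K[i, i] <- 0.5
    } else {
      for (j in seq_len(i - 1L)) {
        K[i, j] <- K[j, i] <- (kin_par(si[i], j) + kin_par(di[i], j)) / 2
      }
      fsd <- if (is.na(si[i]) || is.na(di[i])) 0 else K[si[i], di[i]]
      K[i, i] <- (1 + fsd) / 2
    }
  }
  K
}

#' Pedigree coefficient of inbreeding (COI)
#'
#' COI of an individual is the kinship of its parents; zero when either
#' parent is unknown.
#'
#' @param ped A [pedigree_table()].
#' @param ids Individuals to report (default all).
#' @param kin Optional precomputed [kinship_matrix()].
#' @return A tibble with `id`, `coi`.
#' @export
ped_coi <- function(ped, ids = ped$id, kin = NULL) {
  if (!all(ids %in% ped$id)) abort("unknown id in `ids`")
  kin <- kin %||% kinship_matrix(ped)
  rec <- ped[match(ids, ped$id), ]
  coi <- ifelse(
    is.na(rec$sire) | is.na(rec$dam), 0,
    kin[cbind(rec$sire, rec$dam)]
  )
  tibble(id = ids, coi = unname(coi))
}

#' Pedigree coefficient of relatedness (COR)
#'
#' Wright's relationship coefficient
#' `COR(i,j) = 2 f(i,j) / sqrt((1 + COI_i)(1 + COI_j))`. The un-normalized
#' numerator relationship `2 f(i,j)` is reported alongside, since pedigree
#' software differs in which of the two it prints.
#'
#' @param ped A [pedigree_table()].
#' @param pairs Optional two-column data frame / matrix of id pairs; default
#'   all unordered pairs of `ids`.
#' @param ids Individuals over which to form all pairs when `pairs` is `NULL`.
#' @return A tibble with `id1`, `id2`, `cor`, `relationship` (raw `2 f`).
#' @export
ped_cor <- function(ped, pairs = NULL, ids = ped$id) {
  kin <- kinship_matrix(ped)
  if (is.null(pairs)) {
    if (!all(ids %in% ped$id)) abort("unknown id in `ids`")
    if (length(ids) < 2L) abort("need at least two individuals")
    cmb <- utils::combn(ids, 2)
    pairs <- tibble(id1 = cmb[1, ], id2 = cmb[2, ])
  } else {
    pairs <- as_tibble(as.data.frame(pairs, stringsAsFactors = FALSE))
    names(pairs)[1:2] <- c("id1", "id2")
    if (!all(c(pairs$id1, pairs$id2) %in% ped$id)) abort("unknown id in `pairs`")
  }
  coi <- setNames(ped_coi(ped, kin = kin)$coi, ped$id)
  f <- kin[cbind(pairs$id1, pairs$id2)]
  pairs |>
    mutate(
      relationship = 2 * f,
      cor = unname(2 * f / sqrt((1 + coi[.data$id1]) * (1 + coi[.data$id2])))
    ) |>
    select("id1", "id2", "cor", "relationship")
}

#' Expected founder-ancestry fraction down a pedigree
#'
#' The expected fraction of the genome inherited from founders carrying a
#' given population label: founders score 1 (that label) or 0, every
#' non-founder is the mean of its parents. All founders must be labelled.
#'
#' @param ped A [pedigree_table()].
#' @param founder_label Founder population of interest (e.g. `"wolf"`).
#' @return A tibble with `id`, `generation`, `expected_fraction`.
#' @export
expected_ancestry_fraction <- function(ped, founder_label) {
  founder <- is.na(ped$sire) & is.na(ped$dam)
  if (any(founder & is.na(ped$founder_pop))) {
    abort("all founders must carry a founder_pop label")
  }
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$id)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    if (founder[i]) {
      frac[i] <- as.numeric(ped$founder_pop[i] == founder_label)
    } else {
      fs <- if (is.na(ped$sire[i])) NA else frac[pos[ped$sire[i]]]
      fd <- if (is.na(ped$dam[i])) NA else frac[pos[ped$dam[i]]]
      if (is.na(fs) || is.na(fd)) {
        abort(sprintf("individual '%s' has a single unknown parent; cannot average", ped$id[i]))
      }
      frac[i] <- (fs + fd) / 2
    }
  }
  tibble(id = ped$id, generation = ped$generation, expected_fraction = frac)
}
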