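# shared fixtures and independent oracles, all built in code

suppressMessages({
  library(dplyr)
})

# small genotype matrix from a call matrix (one chromosome by default)
gm_from_calls <- function(calls, groups = NULL, chrom = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  s <- ncol(calls)
  genotype_matrix(
    calls,
    sites = tibble::tibble(
      chrom = chrom %||% rep("1", s),
      pos = pos %||% as.integer(seq_len(s) * 1000L),
      a1 = "A", a2 = "B"
    ),
    samples = tibble::tibble(
      id = sprintf("s%02d", seq_len(n)),
      group = groups %||% rep("breed", n)
    )
  )
}

`%||%` <- rlang::`%||%`

# the default study simulation is expensive enough to share across files
.fixture_env <- new.env(parent = emptyenv())
get_default_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_study(seed = 1234)
  }
  .fixture_env$study
}

# a small, fast study (2 chromosomes, 600 sites each) for seed-loop tests
small_model <- function() {
  founder_model(n_sites = 600,
                chrom_lengths = setNames(rep(50e6, 2), c("1", "2")))
}

# ---- independent Weir-Cockerham oracle -------------------------------------
# three-level nested ANOVA (pops / individuals / gametes) on allele
# indicators via base aov(), then method of moments on the expected mean
# squares. Independent of the implementation's per-site a/b/c algebra.
wc_fst_anova <- function(x1, x2) {
  site_theta <- function(g1, g2) {
    mk <- function(g, pop) {
      g <- g[!is.na(g)]
      if (length(g) == 0L) return(NULL)
      data.frame(
        y = as.vector(rbind(as.integer(g >= 1), as.integer(g == 2))),
        pop = pop,
        ind = paste0(pop, rep(seq_along(g), each = 2))
      )
    }
    d <- rbind(mk(g1, "p1"), mk(g2, "p2"))
    n1 <- sum(!is.na(g1))
    n2 <- sum(!is.na(g2))
    if (n1 == 0 || n2 == 0) return(NA_real_)
    if (var(d$y) == 0) return(NA_real_) # monomorphic: theta undefined
    d$pop <- factor(d$pop)
    d$ind <- factor(d$ind)
    an <- suppressWarnings(anova(aov(y ~ pop + pop:ind, data = d)))
    msp <- an["pop", "Mean Sq"]
    msi <- an["pop:ind", "Mean Sq"]
    msg <- an["Residuals", "Mean Sq"]
    N <- n1 + n2
    nc <- (N - (n1^2 + n2^2) / N) / 1
    s_p <- (msp - msi) / (2 * nc)
    s_i <- (msi - msg) / 2
    s_g <- msg
    tot <- s_p + s_i + s_g
    if (tot == 0) NA_real_ else s_p / tot
  }
  # allele-copy encoding: genotype 0 -> (0,0), 1 -> (1,0), 2 -> (1,1); which
  # copy carries the alternate allele is exchangeable for the ANOVA
  vapply(seq_len(ncol(x1)), function(j) site_theta(x1[, j], x2[, j]), 0)
}

# ---- exhaustive ROH oracle --------------------------------------------------
# greedy leftmost-maximal runs, but every candidate window is re-validated
# from scratch (no incremental budgets), then filtered.
roh_oracle <- function(calls, pos, params) {
  feasible <- function(i, j) {
    seg <- calls[i:j]
    if (j > i && any(diff(pos[i:j]) > params$max_gap_kb * 1000)) return(FALSE)
    sum(!is.na(seg) & seg == 1L) <= params$max_het &&
      sum(is.na(seg)) <= params$max_missing
  }
  runs <- NULL
  i <- 1L
  n <- length(pos)
  while (i <= n) {
    j_max <- NA
    for (j in i:n) if (feasible(i, j)) j_max <- j else break
    if (!is.na(j_max)) {
      runs <- rbind(runs, c(i, j_max))
      i <- j_max + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(runs)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  out <- tibble::tibble(
    start = pos[runs[, 1]], end = pos[runs[, 2]],
    n_snps = runs[, 2] - runs[, 1] + 1L
  )
  dplyr::filter(out, .data$n_snps >= params$min_snps,
                (.data$end - .data$start) >= params$min_kb * 1000)
}

# ---- readable LD-pruning oracle --------------------------------------------
# direct translation of the documented contract with explicit loops
ld_prune_oracle <- function(gm, window = 50, step = 5, r2_max = 0.2) {
  call_rate <- colMeans(!is.na(gm$calls))
  keep <- rep(TRUE, n_sites(gm))
  repeat {
    removed <- FALSE
    for (ch in unique(gm$sites$chrom)) {
      live <- which(keep & gm$sites$chrom == ch)
      pos <- 1L
      while (pos <= length(live)) {
        win <- live[pos:min(pos + window - 1L, length(live))]
        win <- win[keep[win]]
        repeat {
          victim <- NULL
          if (length(win) >= 2L) {
            for (ii in seq_len(length(win) - 1L)) {
              for (jj in (ii + 1L):length(win)) {
                a <- gm$calls[, win[ii]]
                b <- gm$calls[, win[jj]]
                ok <- !is.na(a) & !is.na(b)
                if (sum(ok) < 2 || var(a[ok]) == 0 || var(b[ok]) == 0) next
                if (cor(a[ok], b[ok])^2 > r2_max) {
                  victim <- if (call_rate[win[ii]] < call_rate[win[jj]]) {
                    win[ii]
                  } else win[jj] # ties remove the later site
                  break
                }
              }
              if (!is.null(victim)) break
            }
          }
          if (is.null(victim)) break
          keep[victim] <- FALSE
          win <- setdiff(win, victim)
          removed <- TRUE
        }
        pos <- pos + step
      }
    }
    if (!removed) break
  }
  which(keep)
}

# ---- gene-dropping oracles --------------------------------------------------
# drop n_loci unlinked loci through a pedigree; returns list of two allele
# matrices (individuals x loci) with founder alleles uniquely labelled
gene_drop <- function(ped, n_loci, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$id)
  h1 <- matrix(0L, n, n_loci)
  h2 <- matrix(0L, n, n_loci)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (is.na(ped$sire[i]) && is.na(ped$dam[i])) {
      h1[i, ] <- next_allele
      h2[i, ] <- next_allele + 1L
      next_allele <- next_allele + 2L
    } else {
      si <- pos[ped$sire[i]]
      di <- pos[ped$dam[i]]
      pick1 <- runif(n_loci) < 0.5
      pick2 <- runif(n_loci) < 0.5
      h1[i, ] <- ifelse(pick1, h1[si, ], h2[si, ])
      h2[i, ] <- ifelse(pick2, h1[di, ], h2[di, ])
    }
  }
  list(h1 = h1, h2 = h2)
}

# gene-dropping estimate of kinship f(i,j): P(random allele of i IBD to
# random allele of j), averaged over loci
kinship_drop <- function(drop, i, j) {
  mean((drop$h1[i, ] == drop$h1[j, ]) + (drop$h1[i, ] == drop$h2[j, ]) +
         (drop$h2[i, ] == drop$h1[j, ]) + (drop$h2[i, ] == drop$h2[j, ])) / 4
}

# random valid pedigree for property tests
random_pedigree <- function(n_founders = 4, n_gens = 3, n_per_gen = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("F%d", seq_len(n_founders))
  ped <- tibble::tibble(
    id = ids, sire = NA_character_, dam = NA_character_,
    founder_pop = rep(c("wolf", "dog"), length.out = n_founders),
    generation = 0L
  )
  prev <- ids
  for (g in seq_len(n_gens)) {
    new <- sprintf("G%d_%d", g, seq_len(n_per_gen))
    parents <- t(vapply(new, function(x) sample(prev, 2), character(2)))
    ped <- dplyr::bind_rows(ped, tibble::tibble(
      id = new, sire = parents[, 1], dam = parents[, 2],
      founder_pop = NA_character_, generation = g
    ))
    prev <- new
  }
  pedigree_table(ped$id, ped$sire, ped$dam, ped$founder_pop, ped$generation)
}
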