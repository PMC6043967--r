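#' Founder model for the two parental gene pools
#'
#' Parental (wild and domestic) allele frequencies are generated under the
#' Balding–Nichols divergence model: an ancestral frequency is drawn from a
#' Beta distribution per site, and each parental population's frequency is
#' drawn around it with dispersion set by `divergence_fst`, so that the
#' realized pairwise Weir–Cockerham F_ST between the two parental populations
#' matches `divergence_fst` in expectation.
#'
#' @param n_sites Sites per chromosome.
#' @param chrom_lengths Named chromosome lengths in bp. The default test-scale
#'   genome is 5 chromosomes of 50 Mb; `preset = "full"` gives a 38-autosome,
#'   2.2 Gb genome for demonstrations.
#' @param ancestral_freq_shape Two Beta shape parameters for the ancestral
#'   allele frequency (default `c(1.5, 1.5)`, keeping most sites common as on
#'   a SNP array).
#' @param divergence_fst Target parental divergence, in `[0, 1)`.
#' @param preset `"test"` (default) or `"full"`.
#' @return An object of class `founder_model`.
#' @export
founder_model <- function(n_sites = 2000,
                          chrom_lengths = NULL,
                          ancestral_freq_shape = c(1.5, 1.5),
                          divergence_fst = 0.35,
                          preset = c("test", "full")) {
  preset <- match.arg(preset)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- switch(preset,
      test = setNames(rep(50e6, 5), as.character(1:5)),
      full = setNames(rep(2.2e9 / 38, 38), as.character(1:38))
    )
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  }
  if (divergence_fst < 0 || divergence_fst >= 1) {
    abort("divergence_fst must be in [0, 1)")
  }
  stopifnot(n_sites >= 1, all(chrom_lengths > 0),
            length(ancestral_freq_shape) == 2, all(ancestral_freq_shape > 0))
  structure(
    list(
      n_sites = as.integer(n_sites), chrom_lengths = chrom_lengths,
      ancestral_freq_shape = ancestral_freq_shape,
      divergence_fst = divergence_fst
    ),
    class = "founder_model"
  )
}

#' Draw per-site parental allele frequencies
#'
#' @param model A [founder_model()].
#' @param seed Integer seed (optional).
#' @return A tibble with `chrom`, `pos`, `p_anc`, `p_wolf`, `p_dog`. Sites are
#'   evenly spaced along each chromosome.
#' @export
simulate_founder_freqs <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(model$chrom_lengths)
  sites <- purrr::map(chroms, function(ch) {
    len <- model$chrom_lengths[[ch]]
    pos <- round(seq_len(model$n_sites) * len / (model$n_sites + 1))
    tibble(chrom = ch, pos = as.integer(pos))
  }) |> list_rbind()
  s <- model$ancestral_freq_shape
  fst <- model$divergence_fst
  p_anc <- rbeta(nrow(sites), s[1], s[2])
  if (fst == 0) {
    p_wolf <- p_dog <- p_anc
  } else {
    lambda <- (1 - fst) / fst
    p_wolf <- rbeta(nrow(sites), p_anc * lambda, (1 - p_anc) * lambda)
    p_dog <- rbeta(nrow(sites), p_anc * lambda, (1 - p_anc) * lambda)
  }
  sites |> mutate(p_anc = p_anc, p_wolf = p_wolf, p_dog = p_dog)
}

#' Breeding schedule for the hybrid breed
#'
#' One event per generation, ordered and strictly increasing from generation
#' 0, which must be the founding cross. Event kinds: `found_f1` (wild x
#' domestic F1 litters, or a mixed founding pool, see
#' [simulate_breed()]'s `founding` argument), `wolf_introgression` /
#' `dog_introgression` (new labelled founders crossed into the breed) and
#' `closed_breeding`. `sire_concentration` is the Dirichlet concentration of
#' per-sire usage weights: small values give a strong popular-sire effect,
#' large values approach equal usage.
#'
#' @param generation Integer vector, strictly increasing from 0.
#' @param kind Character vector of event kinds.
#' @param census Offspring census per generation (`>= 2`).
#' @param sire_concentration Positive Dirichlet concentration (recycled).
#' @param introgression_fraction Fraction of the generation's litters that
#'   get one of the event's new founders as a parent (recycled; ignored for
#'   non-introgression events).
#' @return A tibble of class `breeding_schedule`.
#' @export
breeding_schedule <- function(generation, kind, census, sire_concentration = 1,
                              introgression_fraction = 0.25) {
  kinds <- c("found_f1", "wolf_introgression", "dog_introgression", "closed_breeding")
  sch <- tibble(
    generation = as.integer(generation),
    kind = as.character(kind),
    census = as.integer(census),
    sire_concentration = as.numeric(sire_concentration),
    introgression_fraction = as.numeric(introgression_fraction)
  )
  if (nrow(sch) == 0L) abort("empty schedule")
  if (!all(sch$kind %in% kinds)) {
    abort(sprintf("unknown event kind; must be one of %s", paste(kinds, collapse = ", ")))
  }
  if (sch$generation[1] != 0L || sch$kind[1] != "found_f1") {
    abort("schedule must start with found_f1 at generation 0")
  }
  if (any(diff(sch$generation) <= 0)) abort("generations must be strictly increasing")
  if (any(sch$census < 2L)) abort("census must be >= 2")
  if (any(sch$sire_concentration <= 0)) abort("sire_concentration must be > 0")
  if (any(sch$introgression_fraction < 0 | sch$introgression_fraction > 1)) {
    abort("introgression_fraction must be in [0, 1]")
  }
  class(sch) <- c("breeding_schedule", class(sch))
  sch
}

#' Default wolfdog-like breeding schedule
#'
#' Mirrors the documented breed history at 3 years per generation: founding F1
#' litters in 1958 (generation 0); wolf introgressions at generations 1, 3, 5
#' and 8 (about 1960, 1968, 1974 and 1983, each a single new wolf mated into
#' a modest fraction of the litters); heavy backcross waves into German
#' Shepherd dams at generations 2 and 4 (the hybrid litters were absorbed
#' into the dog population, which is what keeps the breed's wolf fraction
#' near 0.3 rather than 0.5); closed breeding up to generation 18 (sampling
#' about 2010), with census declining from 40 to 20 and sire concentration 1
#' (a marked popular-sire effect).
#'
#' @param n_generations Last generation index (default 18).
#' @param census_start,census_end Linear census decline endpoints.
#' @param wolf_generations Generations with wolf introgression.
#' @param backcross_generations Generations with dog backcross waves.
#' @param wolf_fraction,backcross_fraction Litter fractions for the two event
#'   types.
#' @param sire_concentration Dirichlet concentration for sire usage.
#' @return A [breeding_schedule()].
#' @export
cwd_schedule <- function(n_generations = 18, census_start = 40, census_end = 20,
                         wolf_generations = c(1, 3, 5, 8),
                         backcross_generations = c(2, 4),
                         wolf_fraction = 0.1, backcross_fraction = 0.7,
                         sire_concentration = 1) {
  gens <- 0:n_generations
  kind <- ifelse(gens == 0, "found_f1",
                 ifelse(gens %in% wolf_generations, "wolf_introgression",
                        ifelse(gens %in% backcross_generations,
                               "dog_introgression", "closed_breeding")))
  frac <- ifelse(kind == "wolf_introgression", wolf_fraction,
                 ifelse(kind == "dog_introgression", backcross_fraction, 0))
  census <- round(seq(census_start, census_end, length.out = length(gens)))
  breeding_schedule(gens, kind, census, sire_concentration, frac)
}

# ---- internal machinery -----------------------------------------------------

# ancestry segments: per chromosome a 3-column matrix (start, end, origin)
# with half-open 0-based bp intervals tiling [0, chrom_len); origin 1 = wolf,
# 2 = dog. A haplotype is list(al = 0/1 allele vector, segs = list of those).
.origin_levels <- c("wolf", "dog")

new_founder_hap <- function(p, chroms, chrom_lengths, origin_code) {
  segs <- lapply(chroms, function(ch) {
    matrix(c(0, chrom_lengths[[ch]], origin_code), 1, 3,
           dimnames = list(NULL, c("start", "end", "origin")))
  })
  names(segs) <- chroms
  list(al = rbinom(length(p), 1L, p), segs = segs)
}

# clip a segment matrix to [a, b) and shift nothing (absolute coords kept)
clip_segs <- function(m, a, b) {
  keep <- m[, 2] > a & m[, 1] < b
  m <- m[keep, , drop = FALSE]
  if (nrow(m)) {
    m[1, 1] <- max(m[1, 1], a)
    m[nrow(m), 2] <- min(m[nrow(m), 2], b)
    m[, 1] <- pmax(m[, 1], a)
    m[, 2] <- pmin(m[, 2], b)
  }
  m
}

merge_segs <- function(m) {
  if (nrow(m) <= 1L) return(m)
  keep <- c(TRUE, m[-1, 3] != m[-nrow(m), 3])
  idx <- cumsum(keep)
  out <- cbind(
    start = tapply(m[, 1], idx, min),
    end = tapply(m[, 2], idx, max),
    origin = m[keep, 3]
  )
  rownames(out) <- NULL
  out
}

# one meiosis: recombine parent's two haplotypes on the genetic map
make_gamete <- function(parent, sites_by_chrom, map) {
  chroms <- names(parent$h1$segs)
  al <- integer(0)
  segs <- vector("list", length(chroms))
  names(segs) <- chroms
  for (ch in chroms) {
    len <- map$chrom_lengths[[ch]]
    L <- bp_to_morgans(map, ch, len)
    k <- rpois(1L, L)
    info <- sites_by_chrom[[ch]]
    start_h <- sample(1:2, 1L)
    if (k == 0L) {
      h <- if (start_h == 1L) parent$h1 else parent$h2
      al <- c(al, h$al[info$idx])
      segs[[ch]] <- h$segs[[ch]]
      next
    }
    # crossover positions uniform on the genetic map
    bks <- sort(morgans_to_bp(map, ch, runif(k, 0, L)))
    bounds <- c(0, bks, len)
    hap_of_seg <- rep(c(start_h, 3L - start_h), length.out = length(bounds) - 1L)
    # alleles: which template each site falls on
    seg_idx <- findInterval(info$pos - 0.5, bounds, rightmost.closed = FALSE)
    use1 <- hap_of_seg[seg_idx] == 1L
    new_al <- integer(nrow(info))
    new_al[use1] <- parent$h1$al[info$idx[use1]]
    new_al[!use1] <- parent$h2$al[info$idx[!use1]]
    al <- c(al, new_al)
    # ancestry segments: splice the inherited intervals
    pieces <- lapply(seq_along(hap_of_seg), function(s) {
      src <- if (hap_of_seg[s] == 1L) parent$h1$segs[[ch]] else parent$h2$segs[[ch]]
      clip_segs(src, bounds[s], bounds[s + 1L])
    })
    segs[[ch]] <- merge_segs(do.call(rbind, pieces))
  }
  list(al = al, segs = segs)
}

segs_to_tibble <- function(hap, hap_id) {
  purrr::imap(hap$segs, function(m, ch) {
    tibble(hap_id = hap_id, chrom = ch, start = m[, 1], end = m[, 2],
           origin = .origin_levels[m[, 3]])
  }) |> list_rbind()
}

wolf_fraction <- function(ind) {
  tot <- 0
  wolf <- 0
  for (h in list(ind$h1, ind$h2)) {
    for (m in h$segs) {
      tot <- tot + sum(m[, 2] - m[, 1])
      wolf <- wolf + sum((m[, 2] - m[, 1])[m[, 3] == 1])
    }
  }
  wolf / tot
}

#' Forward simulation of the hybrid breed with pedigree and ancestry truth
#'
#' Simulates the breed forward in time under a [breeding_schedule()]: gametes
#' are generated by Poisson-crossover meiosis on the genetic map (no
#' interference), parental ancestry segments are tracked exactly, and sires
#' are drawn within each generation with Dirichlet usage weights
#' (popular-sire effect). Introgression events add new labelled founders that
#' are mated into a fraction of the litters. The result carries the final
#' generation's genotypes, phased haplotypes, the full pedigree, exact
#' per-haplotype ancestry tracks and per-individual wolf fractions.
#'
#' @param model A [founder_model()].
#' @param schedule A [breeding_schedule()].
#' @param map A `genetic_map` (default: linear, 100 Mb = 1 Morgan, over the
#'   model's chromosomes).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param freqs Optional precomputed [simulate_founder_freqs()] table.
#' @param n_wolf_founders,n_dog_founders Founders available at the F1
#'   founding (wolf sires, dog dams).
#' @param n_introgression_founders New wolf founders added per wolf
#'   introgression event (historically a single registered wolf).
#' @param n_backcross_founders New dog dams added per dog backcross event.
#' @param introgression_fraction Default fraction of a generation's litters
#'   with one of the event's new founders as a parent; overridden by the
#'   schedule's `introgression_fraction` column when present.
#' @param founding `"f1"` (every founding litter is wild x domestic) or
#'   `"mixture"` (the founding generation is drawn from a randomly mating
#'   pool of wolf and dog founders — the canonical single-pulse admixture
#'   model used by the dating methods).
#' @param mixture_wolf_fraction Wolf fraction of the founding pool when
#'   `founding = "mixture"`.
#' @return An object of class `breed_sim`: a list with elements `genotypes`
#'   ([genotype_matrix()], group `breed`), `haplotypes` ([haplotype_set()]),
#'   `pedigree` ([pedigree_table()]), `truth_segments` (tibble `hap_id`,
#'   `chrom`, `start`, `end`, `origin`; half-open 0-based bp), `truth_q`
#'   (tibble `id`, `truth_q`), `founder_freqs`, `map`, `schedule`, `seed`.
#' @export
simulate_breed <- function(model, schedule, map = NULL, seed = 1,
                           freqs = NULL,
                           n_wolf_founders = 4, n_dog_founders = 16,
                           n_introgression_founders = 1,
                           n_backcross_founders = 6,
                           introgression_fraction = 0.25,
                           founding = c("f1", "mixture"),
                           mixture_wolf_fraction = 0.3) {
  founding <- match.arg(founding)
  if (nrow(schedule) == 0L) abort("empty schedule")
  set.seed(seed)
  map <- map %||% linear_map(model$chrom_lengths)
  freqs <- freqs %||% simulate_founder_freqs(model)
  chroms <- names(model$chrom_lengths)
  sites_by_chrom <- lapply(chroms, function(ch) {
    idx <- which(freqs$chrom == ch)
    tibble(idx = idx, pos = freqs$pos[idx])
  })
  names(sites_by_chrom) <- chroms

  ped <- list()
  founder_count <- c(wolf = 0L, dog = 0L)
  new_founders <- function(pop, n, generation, sex) {
    p <- if (pop == "wolf") freqs$p_wolf else freqs$p_dog
    code <- match(pop, .origin_levels)
    lapply(seq_len(n), function(k) {
      founder_count[[pop]] <<- founder_count[[pop]] + 1L
      id <- sprintf("%s%03d", toupper(substr(pop, 1, 1)), founder_count[[pop]])
      ped[[length(ped) + 1L]] <<- tibble(
        id = id, sire = NA_character_, dam = NA_character_,
        founder_pop = pop, generation = generation
      )
      list(
        id = id, sex = sex[(k - 1L) %% length(sex) + 1L],
        h1 = new_founder_hap(p, chroms, model$chrom_lengths, code),
        h2 = new_founder_hap(p, chroms, model$chrom_lengths, code)
      )
    })
  }

  breed_offspring <- function(sires, dams, n, generation, conc, prefix) {
    if (length(sires) == 0L || length(dams) == 0L) {
      abort(sprintf("census collapse at generation %d: no available parents", generation))
    }
    w <- rgamma(length(sires), shape = conc)
    if (sum(w) == 0) w <- rep(1, length(sires))
    lapply(seq_len(n), function(k) {
      sire <- sires[[sample.int(length(sires), 1L, prob = w)]]
      dam <- dams[[sample.int(length(dams), 1L)]]
      id <- sprintf("%s_g%02d_%03d", prefix, generation, k)
      ped[[length(ped) + 1L]] <<- tibble(
        id = id, sire = sire$id, dam = dam$id,
        founder_pop = NA_character_, generation = generation
      )
      list(
        id = id, sex = c("M", "F")[(k - 1L) %% 2L + 1L],
        h1 = make_gamete(sire, sites_by_chrom, map),
        h2 = make_gamete(dam, sites_by_chrom, map)
      )
    })
  }

  pool <- NULL
  for (e in seq_len(nrow(schedule))) {
    ev <- schedule[e, ]
    g <- ev$generation
    n_g <- ev$census
    conc <- ev$sire_concentration
    if (ev$kind == "found_f1") {
      if (founding == "f1") {
        wolves <- new_founders("wolf", n_wolf_founders, g - 1L, "M")
        dogs <- new_founders("dog", n_dog_founders, g - 1L, "F")
        pool <- breed_offspring(wolves, dogs, n_g, g, conc, "B")
      } else {
        n_w <- max(1L, round(mixture_wolf_fraction * n_g))
        wolves <- new_founders("wolf", n_w, g - 1L, c("M", "F"))
        dogs <- new_founders("dog", n_g - n_w, g - 1L, c("F", "M"))
        all_f <- c(wolves, dogs)
        sires <- all_f[vapply(all_f, `[[`, "", "sex") == "M"]
        dams <- all_f[vapply(all_f, `[[`, "", "sex") == "F"]
        pool <- breed_offspring(sires, dams, n_g, g, conc, "B")
      }
      next
    }
    sexes <- vapply(pool, `[[`, "", "sex")
    sires <- pool[sexes == "M"]
    dams <- pool[sexes == "F"]
    if (ev$kind == "closed_breeding") {
      pool <- breed_offspring(sires, dams, n_g, g, conc, "B")
    } else {
      frac <- ev$introgression_fraction %||% introgression_fraction
      if (is.na(frac)) frac <- introgression_fraction
      n_intro <- min(n_g, ceiling(frac * n_g))
      if (ev$kind == "wolf_introgression") {
        # new wolf sires over breed dams
        intro <- new_founders("wolf", n_introgression_founders, g - 1L, "M")
        off1 <- if (n_intro > 0L) {
          breed_offspring(intro, dams, n_intro, g, conc, "X")
        } else list()
      } else {
        # breed sires over new dog dams (backcross wave)
        intro <- new_founders("dog", n_backcross_founders, g - 1L, "F")
        off1 <- if (n_intro > 0L) {
          breed_offspring(sires, intro, n_intro, g, conc, "X")
        } else list()
      }
      off2 <- if (n_g - n_intro > 0L) {
        breed_offspring(sires, dams, n_g - n_intro, g, conc, "B")
      } else list()
      pool <- c(off1, off2)
    }
  }

  ped_tab <- pedigree_table(
    id = vapply(ped, `[[`, "", "id"),
    sire = vapply(ped, function(x) x$sire %||% NA_character_, ""),
    dam = vapply(ped, function(x) x$dam %||% NA_character_, ""),
    founder_pop = vapply(ped, `[[`, "", "founder_pop"),
    generation = vapply(ped, function(x) as.integer(x$generation), 1L)
  )

  sites <- freqs |>
    transmute(chrom = .data$chrom, pos = .data$pos, a1 = "A", a2 = "B")
  ids <- vapply(pool, `[[`, "", "id")
  haps <- do.call(rbind, lapply(pool, function(ind) rbind(ind$h1$al, ind$h2$al)))
  hs <- haplotype_set(haps, sites, ids)
  gm <- haps_to_genotypes(hs, tibble(id = ids, group = "breed"))

  truth_segments <- purrr::map(pool, function(ind) {
    dplyr::bind_rows(
      segs_to_tibble(ind$h1, paste0(ind$id, "_1")),
      segs_to_tibble(ind$h2, paste0(ind$id, "_2"))
    )
  }) |> list_rbind()
  truth_q <- tibble(id = ids, truth_q = vapply(pool, wolf_fraction, 0))

  structure(
    list(
      genotypes = gm, haplotypes = hs, pedigree = ped_tab,
      truth_segments = truth_segments, truth_q = truth_q,
      founder_freqs = freqs, map = map, schedule = schedule, seed = seed
    ),
    class = "breed_sim"
  )
}

#' @export
print.breed_sim <- function(x, ...) {
  cat(sprintf(
    "<breed_sim> %d breed individuals, %d sites, %d pedigree records, seed %d\n",
    n_samples(x$genotypes), n_sites(x$genotypes), nrow(x$pedigree), x$seed
  ))
  cat(sprintf("  mean truth wolf fraction: %.3f\n", mean(x$truth_q$truth_q)))
  invisible(x)
}

#' Sample parental reference individuals from founder frequencies
#'
#' Draws wild and domestic reference individuals by per-site Bernoulli
#' sampling of haplotypes from the parental frequencies (founders carry no
#' background LD; breed LD arises from admixture and drift). Real parental
#' populations — a heavily managed dog breed and a small wolf population —
#' are themselves inbred, so each individual's second allele copies the first
#' with probability `inbreeding` (heterozygosity `2pq(1 - F)`), zero for
#' fully panmictic references.
#'
#' @param freqs A [simulate_founder_freqs()] table.
#' @param n_wolf,n_dog Individuals per parental group.
#' @param inbreeding Named within-population inbreeding coefficients
#'   (defaults `wolf = 0.10`, `dog = 0.15`, the regime reported for wild wolf
#'   populations and closed dog breeds).
#' @param seed Optional seed.
#' @return List with `genotypes` (groups `wild_parent`/`dom_parent`) and
#'   `haplotypes`.
#' @export
simulate_parental_samples <- function(freqs, n_wolf = 12, n_dog = 12,
                                      inbreeding = c(wolf = 0.10, dog = 0.15),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(freqs)
  ids <- c(sprintf("WREF%02d", seq_len(n_wolf)), sprintf("DREF%02d", seq_len(n_dog)))
  groups <- c(rep("wild_parent", n_wolf), rep("dom_parent", n_dog))
  p <- c(rep(list(freqs$p_wolf), n_wolf), rep(list(freqs$p_dog), n_dog))
  fs <- c(rep(inbreeding[["wolf"]], n_wolf), rep(inbreeding[["dog"]], n_dog))
  haps <- do.call(rbind, mapply(function(pp, f) {
    h1 <- rbinom(S, 1L, pp)
    copy <- runif(S) < f
    h2 <- ifelse(copy, h1, rbinom(S, 1L, pp))
    rbind(h1, as.integer(h2))
  }, p, fs, SIMPLIFY = FALSE))
  sites <- freqs |>
    transmute(chrom = .data$chrom, pos = .data$pos, a1 = "A", a2 = "B")
  hs <- haplotype_set(haps, sites, ids)
  list(
    genotypes = haps_to_genotypes(hs, tibble(id = ids, group = groups)),
    haplotypes = hs
  )
}

#' Simulate the full three-group study
#'
#' Convenience wrapper: simulates the breed under the schedule, then samples
#' parental reference individuals, and combines everything into one
#' three-group genotype matrix and haplotype set.
#'
#' @inheritParams simulate_breed
#' @param n_wolf_ref,n_dog_ref Reference individuals per parental group.
#' @param parental_inbreeding Within-population inbreeding of the reference
#'   samples (see [simulate_parental_samples()]).
#' @param ... Passed to [simulate_breed()].
#' @return A list with `genotypes` (groups `breed`, `wild_parent`,
#'   `dom_parent`), `haplotypes`, `sim` (the [simulate_breed()] result) and
#'   `ref` (the parental sample).
#' @export
simulate_study <- function(model = founder_model(),
                           schedule = cwd_schedule(),
                           n_wolf_ref = 12, n_dog_ref = 12,
                           parental_inbreeding = c(wolf = 0.10, dog = 0.15),
                           seed = 1, ...) {
  sim <- simulate_breed(model, schedule, seed = seed, ...)
  ref <- simulate_parental_samples(sim$founder_freqs, n_wolf_ref, n_dog_ref,
                                   inbreeding = parental_inbreeding,
                                   seed = derive_seed(seed, 101))
  gm <- genotype_matrix(
    rbind(sim$genotypes$calls, ref$genotypes$calls),
    sim$genotypes$sites,
    dplyr::bind_rows(sim$genotypes$samples, ref$genotypes$samples)
  )
  hs <- haplotype_set(
    rbind(sim$haplotypes$haps, ref$haplotypes$haps),
    sim$haplotypes$sites,
    c(sim$haplotypes$sample_ids, ref$haplotypes$sample_ids)
  )
  list(genotypes = gm, haplotypes = hs, sim = sim, ref = ref)
}

#' Inject missing calls at random
#'
#' Each call is independently set missing with probability `rate`; used to
#' emulate SNP-array no-calls so the call-rate filter and complete-case path
#' have something to do.
#'
#' @param gm A [genotype_matrix()].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Optional seed.
#' @return A [genotype_matrix()].
#' @export
inject_missingness <- function(gm, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) abort("rate must be in [0, 1)")
  if (rate == 0) return(gm)
  if (!is.null(seed)) set.seed(seed)
  calls <- gm$calls
  drop <- runif(length(calls)) < rate
  calls[drop] <- NA_integer_
  genotype_matrix(calls, gm$sites, gm$samples)
}

#' True ancestry-switch counts from simulation truth
#'
#' Counts junctions (boundaries between wolf and dog segments) over both
#' haplotypes of each simulated individual.
#'
#' @param sim A `breed_sim`.
#' @return Tibble with `id`, `true_switches`.
#' @export
truth_switch_counts <- function(sim) {
  sim$truth_segments |>
    mutate(id = sub("_[12]$", "", .data$hap_id)) |>
    group_by(.data$id, .data$hap_id, .data$chrom) |>
    summarise(sw = dplyr::n() - 1L, .groups = "drop") |>
    group_by(.data$id) |>
    summarise(true_switches = sum(.data$sw))
}

# deterministic per-stage seed derivation (kept below .Machine integer range)
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)
}
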