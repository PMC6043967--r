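# fixed-difference toy panel: wolves all-1, dogs all-0 over `s` sites
fixed_panel <- function(s = 40, n_w = 6, n_d = 6, spacing = 100000L) {
  sites <- tibble::tibble(chrom = "1", pos = as.integer(seq_len(s) * spacing),
                          a1 = "A", a2 = "B")
  wolf <- haplotype_set(matrix(1L, 2 * n_w, s), sites,
                        sprintf("W%02d", seq_len(n_w)))
  dog <- haplotype_set(matrix(0L, 2 * n_d, s), sites,
                       sprintf("D%02d", seq_len(n_d)))
  list(wolf = wolf, dog = dog, sites = sites)
}

test_that("reference blocks separate fixed-different parents and flag identical ones", {
  fx <- fixed_panel()
  ref <- build_reference(fx$wolf, fx$dog, block_size = 10)
  expect_length(ref$blocks, 4L)
  expect_true(all(vapply(ref$blocks, `[[`, TRUE, "informative")))

  same <- haplotype_set(matrix(rep(c(0L, 1L), each = 6, times = 40), 12, 40),
                        fx$sites, sprintf("X%02d", 1:6))
  ref2 <- build_reference(same, same, block_size = 10)
  expect_false(any(vapply(ref2$blocks, `[[`, TRUE, "informative")))
  expect_error(build_reference(fx$wolf, fx$dog, block_size = 1), "block_size")
})

test_that("informative-block fraction rises with parental divergence", {
  frac <- purrr::map_dbl(c(0.05, 0.5), function(fst) {
    model <- founder_model(n_sites = 400,
                           chrom_lengths = c("1" = 50e6),
                           divergence_fst = fst)
    freqs <- simulate_founder_freqs(model, seed = 5)
    ref_s <- simulate_parental_samples(freqs, 8, 8, seed = 6)
    w <- subset_haplotypes(ref_s$haplotypes, sprintf("WREF%02d", 1:8))
    d <- subset_haplotypes(ref_s$haplotypes, sprintf("DREF%02d", 1:8))
    ref <- build_reference(w, d)
    mean(vapply(ref$blocks, `[[`, TRUE, "informative"))
  })
  expect_gt(frac[2], frac[1])
})

test_that("a wolf haplotype deconvolves to wolf everywhere with high posterior", {
  fx <- fixed_panel()
  ref <- build_reference(fx$wolf, fx$dog, block_size = 10)
  query <- haplotype_set(rbind(rep(1L, 40), rep(0L, 40)), fx$sites, "q1")
  tr <- deconvolve(query, ref, smooth = FALSE)
  wolf_hap <- dplyr::filter(tr, hap_id == "q1_1")
  dog_hap <- dplyr::filter(tr, hap_id == "q1_2")
  expect_true(all(wolf_hap$call == "wolf" & wolf_hap$p_wolf > 0.99))
  expect_true(all(dog_hap$call == "dog" & dog_hap$p_wolf < 0.01))

  # mismatched sites are rejected
  other <- haplotype_set(rbind(rep(1L, 40), rep(0L, 40)),
                         dplyr::mutate(fx$sites, pos = pos + 1L), "q1")
  expect_error(deconvolve(other, ref), "match the reference")
})

test_that("uninformative blocks stay at posterior 1/2 and are uncalled", {
  fx <- fixed_panel(s = 20)
  # second block identical in both parents
  fx$wolf$haps[, 11:20] <- 1L
  fx$dog$haps[, 11:20] <- 1L
  ref <- build_reference(fx$wolf, fx$dog, block_size = 10)
  query <- haplotype_set(rbind(rep(1L, 20), rep(1L, 20)), fx$sites, "q1")
  tr <- deconvolve(query, ref, smooth = FALSE)
  blk2 <- dplyr::filter(tr, block == 2)
  expect_true(all(blk2$p_wolf == 0.5 & blk2$call == "uncalled"))
})

test_that("posteriors are normalized and blocks tile the site index", {
  fx <- fixed_panel(s = 40)
  ref <- build_reference(fx$wolf, fx$dog)
  q <- haplotype_set(rbind(rep(1L, 40), rep(0L, 40)), fx$sites, "q1")
  tr <- deconvolve(q, ref, smooth = TRUE)
  expect_true(all(tr$p_wolf >= 0 & tr$p_wolf <= 1))
  cols <- sort(unlist(lapply(ref$blocks, `[[`, "cols")))
  expect_equal(cols, 1:40)
})

test_that("genome-wide ancestry summarizes hard calls", {
  track <- tibble::tibble(
    hap_id = rep(c("a_1", "a_2"), each = 3),
    id = "a", chrom = "1", block = rep(1:3, 2),
    start = rep(c(1, 11, 21) * 1e5, 2), end = rep(c(10, 20, 30) * 1e5, 2),
    p_wolf = 1, call = c("wolf", "wolf", "wolf", "wolf", "dog", "uncalled")
  )
  q <- genome_wide_ancestry(track)
  expect_equal(q$q, 4 / 5)
  all_un <- dplyr::mutate(track, call = "uncalled")
  expect_true(is.na(genome_wide_ancestry(all_un)$q))
  expect_equal(genome_wide_ancestry(all_un)$flag, "all_uncalled")
})

test_that("supervised q matches its limits and a fine grid search", {
  pf <- tibble::tibble(p_wolf = rep(1, 30), p_dog = rep(0, 30),
                       n_wolf = 1000, n_dog = 1000)
  hom_wolf <- gm_from_calls(matrix(2L, 1, 30))
  expect_gt(supervised_q(hom_wolf, pf)$q, 0.99)
  het <- gm_from_calls(matrix(1L, 1, 30))
  expect_equal(supervised_q(het, pf)$q, 0.5, tolerance = 1e-4)

  set.seed(2)
  pf2 <- tibble::tibble(p_wolf = runif(20), p_dog = runif(20),
                        n_wolf = 12, n_dog = 12)
  x <- sample(0:2, 20, TRUE)
  got <- supervised_q(gm_from_calls(matrix(as.integer(x), 1, 20)), pf2)$q
  clip <- function(p, n) pmin(pmax(p, 1 / (2 * n + 1)), 1 - 1 / (2 * n + 1))
  pw <- clip(pf2$p_wolf, 12)
  pd <- clip(pf2$p_dog, 12)
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, function(qq) {
    p <- qq * pw + (1 - qq) * pd
    sum(x * log(p) + (2 - x) * log(1 - p))
  }, 0)
  expect_equal(got, grid[which.max(ll)], tolerance = 2e-4)

  same <- tibble::tibble(p_wolf = rep(0.5, 5), p_dog = rep(0.5, 5))
  expect_error(supervised_q(het[, 1:5], same), "no informative")
})

test_that("switch counting skips uncalled blocks and ignores chromosome order", {
  track <- tibble::tibble(
    hap_id = "a_1", id = "a", chrom = "1", block = 1:5,
    start = (1:5) * 1e5, end = (1:5) * 1e5 + 9e4,
    p_wolf = 1,
    call = c("wolf", "uncalled", "dog", "dog", "wolf") # W.DDW -> 2 switches
  )
  expect_equal(count_switches(track)$switches, 2L)
  # chromosome processing order must not matter
  two <- dplyr::bind_rows(track,
                          dplyr::mutate(track, chrom = "0", call = "wolf"))
  expect_equal(count_switches(two)$switches,
               count_switches(dplyr::arrange(two, chrom))$switches)
  f1 <- dplyr::mutate(track, call = "wolf")
  expect_equal(count_switches(f1)$switches, 0L)
})

test_that("fixed-ancestry blocks require unanimity", {
  base <- tidyr::expand_grid(
    hap_id = c("a_1", "a_2", "b_1", "b_2"), block = 1:3
  ) |>
    dplyr::mutate(id = substr(hap_id, 1, 1), chrom = "1",
                  start = block * 1e5, end = block * 1e5 + 9e4,
                  p_wolf = 1, call = "wolf")
  base$call[base$block == 2 & base$hap_id == "b_2"] <- "dog"
  base$call[base$block == 3 & base$hap_id == "a_1"] <- "uncalled"
  fb <- fixed_ancestry_blocks(base)
  expect_equal(fb$block, 1L)
  expect_equal(fb$direction, "wolf_like")
  all_dog <- dplyr::mutate(base, call = "dog")
  expect_equal(fixed_ancestry_blocks(all_dog)$direction, rep("dog_like", 3))
})
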