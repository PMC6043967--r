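freq_row <- function(group, site, freq, n_chrom = 24L) {
  tibble::tibble(group = group, site = site, chrom = "1",
                 pos = site * 100000L, n_chrom = n_chrom, freq = freq,
                 n_het = 0L)
}

test_that("fixed-difference sites need opposite fixation", {
  freqs <- dplyr::bind_rows(
    freq_row("wild_parent", 1:4, c(1, 0.95, 1, 0)),
    freq_row("dom_parent", 1:4, c(0, 0, 1, 1))
  )
  fx <- fixed_diff_sites(freqs)
  expect_equal(fx$site, c(1L, 4L))   # site 2 not fixed in wolf; site 3 same allele
  expect_equal(fx$p_wolf, c(1, 0))

  # brute-force scan over a random 20-site table
  set.seed(9)
  fw <- sample(c(0, 1, runif(5)), 20, TRUE)
  fd <- sample(c(0, 1, runif(5)), 20, TRUE)
  freqs2 <- dplyr::bind_rows(freq_row("wild_parent", 1:20, fw),
                             freq_row("dom_parent", 1:20, fd))
  want <- which((fw %in% c(0, 1)) & (fd %in% c(0, 1)) & fw != fd)
  expect_equal(fixed_diff_sites(freqs2)$site, want)
})

test_that("AIM selection keeps the lowest-F_ST quantile with ties", {
  n <- 200
  fixed <- tibble::tibble(site = 1:n, chrom = "1", pos = (1:n) * 100000L,
                          p_wolf = 1, p_dog = 0)
  set.seed(4)
  fst_w <- tibble::tibble(site = 1:n, fst = runif(n))
  fst_d <- tibble::tibble(site = 1:n, fst = runif(n))
  out <- suppressWarnings(aim_select(fixed, fst_w, fst_d, fraction = 0.05))
  # sort-and-slice oracle
  expect_setequal(out$wolf_like$site, order(fst_w$fst)[1:10])
  expect_setequal(out$dog_like$site, order(fst_d$fst)[1:10])

  # fraction 1 returns everything on both sides, flagging the full overlap
  expect_warning(all_out <- aim_select(fixed, fst_w, fst_d, fraction = 1),
                 "both panels")
  expect_equal(nrow(all_out$wolf_like), n)
  expect_equal(nrow(all_out$dog_like), n)

  # boundary ties are all retained
  tied <- tibble::tibble(site = 1:n, fst = rep(c(0.1, 0.9), each = n / 2))
  out2 <- suppressWarnings(aim_select(fixed, tied, fst_d, fraction = 0.01))
  expect_equal(nrow(out2$wolf_like), n / 2)

  expect_error(aim_select(fixed[0, ], fst_w, fst_d), "no fixed-difference")
})

test_that("block scoring averages fixed-site F_ST within 10-SNP blocks", {
  fixed <- tibble::tibble(site = c(1:5, 11:15), chrom = "1",
                          pos = c(1:5, 11:15) * 100000L, p_wolf = 1, p_dog = 0)
  fst_w <- tibble::tibble(site = 1:20, fst = c(rep(0.1, 10), rep(0.8, 10)))
  out <- aim_select(fixed, fst_w, fst_w, fraction = 0.5, unit = "block10")
  expect_equal(nrow(out$wolf_like), 1L)
  expect_equal(out$wolf_like$fst, 0.1)
  expect_equal(out$wolf_like$n_fixed, 5L)
})

test_that("interval expansion adds 50-kb flanks with boundary clipping", {
  lens <- c("1" = 60e6)
  got <- expand_intervals(tibble::tibble(chrom = "1", pos = 1000000L), lens)
  expect_equal(got$start, 949999)
  expect_equal(got$end, 1050000)
  clipped <- expand_intervals(tibble::tibble(chrom = "1", pos = 20000L), lens)
  expect_equal(clipped$start, 0)
  expect_equal(clipped$end, 70000)
  # block input spans first to last site
  blk <- expand_intervals(tibble::tibble(chrom = "1", start = 2e6, end = 3e6),
                          lens)
  expect_equal(blk$start, 2e6 - 1 - 50000)
  expect_equal(blk$end, 3e6 + 50000)
  # merge flag unions overlapping windows
  two <- tibble::tibble(chrom = "1", pos = c(1000000L, 1060000L))
  merged <- expand_intervals(two, lens, merge = TRUE)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 949999)
  expect_equal(merged$end, 1110000)
  expect_error(expand_intervals(tibble::tibble(chrom = "9", pos = 1L), lens),
               "unknown chromosome")
})

test_that("panel consolidation groups by transitive overlap with provenance", {
  panels <- list(
    fst_snp = tibble::tibble(chrom = "1", start = c(100, 5000), end = c(300, 5100),
                             direction = "wolf_like"),
    pcadmix = tibble::tibble(chrom = "1", start = 250, end = 400,
                             direction = "wolf_like"),
    roh = tibble::tibble(chrom = "2", start = 10, end = 20,
                         direction = NA_character_)
  )
  out <- consolidate_panels(panels)
  hit <- dplyr::filter(out, chrom == "1", start == 100)
  expect_equal(hit$methods, "fst_snp,pcadmix")
  expect_equal(hit$n_methods, 2L)
  expect_equal(hit$end, 400)
  expect_equal(nrow(out), 3L)  # chained region, lone region, chr2 region

  # brute-force pairwise-overlap closure on random intervals
  set.seed(6)
  riv <- tibble::tibble(chrom = "1",
                        start = sample(1:500, 12),
                        end = 0)
  riv$end <- riv$start + sample(20:120, 12, TRUE)
  got <- consolidate_panels(list(p = riv))
  overlaps <- function(a, b) riv$start[a] < riv$end[b] & riv$start[b] < riv$end[a]
  adj <- outer(1:12, 1:12, Vectorize(overlaps))
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj))$membership
  expect_equal(nrow(got), length(unique(comp)))
  want_spans <- tapply(seq_len(12), comp, function(ix) {
    c(min(riv$start[ix]), max(riv$end[ix]))
  })
  expect_setequal(got$start, vapply(want_spans, `[`, 0, 1))
  expect_setequal(got$end, vapply(want_spans, `[`, 0, 2))

  # conflicting directions split into flagged records
  conf <- list(
    a = tibble::tibble(chrom = "1", start = 1, end = 100, direction = "wolf_like"),
    b = tibble::tibble(chrom = "1", start = 50, end = 150, direction = "dog_like")
  )
  out2 <- consolidate_panels(conf)
  expect_equal(nrow(out2), 2L)
  expect_true(all(out2$conflict))
})
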