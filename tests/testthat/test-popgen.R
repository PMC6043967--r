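test_that("observed heterozygosity hits its limits", {
  gm <- gm_from_calls(rbind(rep(1L, 10), rep(2L, 10)))
  h <- observed_heterozygosity(gm)
  expect_equal(h$h_obs, c(1, 0))
  g <- observed_heterozygosity(gm, by = "group")
  expect_equal(g$h_obs, 0.5)
  none <- gm_from_calls(rbind(rep(NA_integer_, 4), rep(1L, 4)))
  expect_warning(h0 <- observed_heterozygosity(none), "zero called")
  expect_true(is.na(h0$h_obs[1]))
})

test_that("inbreeding F matches limits and a hand-computed toy", {
  # fully homozygous at freq-0.5 sites -> F = 1
  freqs <- tibble::tibble(freq = rep(0.5, 6))
  gm <- gm_from_calls(rbind(c(0L, 2L, 0L, 2L, 0L, 2L)))
  f <- inbreeding_f(gm, reference_freqs = freqs)
  expect_equal(f$f, 1)

  # a Hardy-Weinberg-looking sample: one het per two sites at p = 0.5
  gm2 <- gm_from_calls(rbind(c(1L, 0L, 1L, 2L)))
  f2 <- inbreeding_f(gm2, reference_freqs = tibble::tibble(freq = rep(0.5, 4)))
  expect_equal(f2$f, 0) # observed hom 2, expected hom 4 * 0.5 = 2

  # 3-site hand oracle: freqs 0.2/0.5/0.8, genotypes 0/1/2
  p <- c(0.2, 0.5, 0.8)
  gm3 <- gm_from_calls(rbind(c(0L, 1L, 2L)))
  ehet <- sum(2 * p * (1 - p))      # 0.32 + 0.5 + 0.32 = 1.14
  f3 <- inbreeding_f(gm3, reference_freqs = tibble::tibble(freq = p))
  expect_equal(f3$f, (2 - (3 - ehet)) / ehet)

  # monomorphic-only reference flagged undefined
  gm4 <- gm_from_calls(rbind(c(0L, 0L)))
  f4 <- inbreeding_f(gm4, reference_freqs = tibble::tibble(freq = c(0, 1)))
  expect_true(is.na(f4$f) && f4$flag == "monomorphic_reference")
})

test_that("F_ST reaches 1 for fixed opposite alleles and ~0 for identical groups", {
  calls <- rbind(matrix(0L, 4, 20), matrix(2L, 4, 20))
  gm <- gm_from_calls(calls, groups = rep(c("breed", "wild_parent"), each = 4))
  expect_equal(pairwise_fst(gm)$matrix["breed", "wild_parent"], 1)

  # two independent samples from one panmictic population
  set.seed(3)
  p <- runif(800, 0.1, 0.9)
  draw <- function(n) t(vapply(seq_len(n), function(i) rbinom(800, 2L, p),
                               integer(800)))
  gm2 <- gm_from_calls(rbind(draw(8), draw(8)),
                       groups = rep(c("breed", "dom_parent"), each = 8))
  expect_lt(abs(pairwise_fst(gm2)$matrix["breed", "dom_parent"]), 0.02)
})

test_that("per-site Weir-Cockerham equals the nested-ANOVA oracle", {
  # spec's one-site toy: group1 AA,AA,Aa,aa ; group2 aa,aa,aa,Aa
  x1 <- matrix(c(0L, 0L, 1L, 2L), 4, 1)
  x2 <- matrix(c(2L, 2L, 2L, 1L), 4, 1)
  gm <- gm_from_calls(rbind(x1, x2),
                      groups = rep(c("breed", "wild_parent"), each = 4))
  got <- pairwise_fst(gm)$per_site$fst
  expect_equal(got, wc_fst_anova(x1, x2), tolerance = 1e-12)

  # exhaustive small instances: random <=6-sample two-group toys
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(2:3, 1)
    n2 <- sample(2:3, 1)
    y1 <- matrix(sample(0:2, n1 * 4, TRUE), n1, 4)
    y2 <- matrix(sample(0:2, n2 * 4, TRUE), n2, 4)
    gm <- gm_from_calls(rbind(y1, y2),
                        groups = rep(c("breed", "wild_parent"), c(n1, n2)))
    res <- pairwise_fst(gm)
    oracle <- wc_fst_anova(y1, y2)
    expect_equal(res$per_site$fst, oracle, tolerance = 1e-9)
    # genome-wide value is a ratio of sums, not a mean of ratios
    ps <- res$per_site
    expect_equal(res$pairs$fst,
                 sum(ps$a, na.rm = TRUE) /
                   sum(ps$a + ps$b + ps$c, na.rm = TRUE))
  }
})

test_that("the F_ST matrix is symmetric with a zero diagonal and value <= 1", {
  fst <- pairwise_fst(get_default_study()$genotypes[, 1:1500])
  expect_identical(fst$matrix, t(fst$matrix))
  expect_true(all(diag(fst$matrix) == 0))
  expect_true(all(fst$pairs$fst <= 1))
})

test_that("PCA separates duplicated clusters and orders eigenvalues", {
  set.seed(4)
  a <- sample(0:2, 60, TRUE)
  b <- sample(0:2, 60, TRUE)
  calls <- rbind(matrix(rep(a, 4), 4, byrow = TRUE),
                 matrix(rep(b, 4), 4, byrow = TRUE))
  gm <- gm_from_calls(calls, groups = rep(c("breed", "wild_parent"), each = 4))
  pc <- pca_genotypes(gm, n_pc = 4)
  s <- pc$scores
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-8)
  # within-cluster coordinates coincide; clusters split on PC1
  expect_equal(diff(range(s$PC1[1:4])), 0, tolerance = 1e-8)
  expect_equal(diff(range(s$PC1[5:8])), 0, tolerance = 1e-8)
  expect_gt(abs(mean(s$PC1[1:4]) - mean(s$PC1[5:8])), 1)
  expect_error(pca_genotypes(gm_from_calls(matrix(1L, 3, 5))), "zero-variance")
})

test_that("the breed sits between its parental clusters on PC1", {
  pc <- pca_genotypes(get_default_study()$genotypes)
  centers <- pc$scores |>
    group_by(group) |>
    summarise(m = mean(PC1))
  m <- setNames(centers$m, centers$group)
  expect_true(
    (m["breed"] > min(m[c("wild_parent", "dom_parent")])) &&
      (m["breed"] < max(m[c("wild_parent", "dom_parent")]))
  )
})

test_that("genotypic r2 matches hand computation and its limits", {
  gm <- gm_from_calls(rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L), c(1L, 1L)))
  expect_equal(ld_r2(gm, 1, 2), 1)
  ortho <- gm_from_calls(rbind(c(0L, 0L), c(0L, 2L), c(2L, 0L), c(2L, 2L)))
  expect_equal(ld_r2(ortho, 1, 2), 0)
  hand <- gm_from_calls(rbind(c(0L, 1L), c(1L, 0L), c(2L, 2L), c(1L, 1L)))
  expect_equal(ld_r2(hand, 1, 2), cor(c(0, 1, 2, 1), c(1, 0, 2, 1))^2)
  mono <- gm_from_calls(rbind(c(0L, 1L), c(0L, 0L), c(0L, 2L)))
  expect_warning(r <- ld_r2(mono, 1, 2), "undefined")
  expect_true(is.na(r))
})

test_that("pi-hat finds duplicates, unrelateds and parent-offspring", {
  set.seed(12)
  n_sites <- 5000
  p <- runif(n_sites, 0.2, 0.8)
  draw <- function() rbinom(n_sites, 1L, p) + rbinom(n_sites, 1L, p)
  dup <- draw()
  calls <- rbind(dup, dup, draw(), draw())
  gm <- gm_from_calls(calls)
  res <- ibd_pihat(gm, freqs = p)
  pick <- function(i, j) res$pihat[res$id1 == sprintf("s%02d", i) &
                                     res$id2 == sprintf("s%02d", j)]
  expect_gt(pick(1, 2), 0.95)
  expect_lt(pick(3, 4), 0.1)

  # parent-offspring and full sibs by explicit allele dropping
  ph1 <- rbinom(n_sites, 1L, p); ph2 <- rbinom(n_sites, 1L, p) # parent A
  qh1 <- rbinom(n_sites, 1L, p); qh2 <- rbinom(n_sites, 1L, p) # parent B
  inherit <- function(h1, h2) ifelse(runif(n_sites) < 0.5, h1, h2)
  child1 <- inherit(ph1, ph2) + inherit(qh1, qh2)
  child2 <- inherit(ph1, ph2) + inherit(qh1, qh2)
  fam <- gm_from_calls(rbind(ph1 + ph2, child1, child2))
  res2 <- ibd_pihat(fam, freqs = p)
  po <- res2$pihat[1]    # s01-s02 parent-offspring
  sibs <- res2$pihat[3]  # s02-s03 full sibs
  expect_lt(abs(po - 0.5), 0.05)
  expect_lt(abs(sibs - 0.5), 0.05)
  # half sibs share one parent
  child3 <- inherit(ph1, ph2) + rbinom(n_sites, 1L, p)
  hs <- gm_from_calls(rbind(child1, child3))
  expect_lt(abs(ibd_pihat(hs, freqs = p)$pihat - 0.25), 0.05)

  few <- gm_from_calls(matrix(c(0L, 1L, 2L, 1L), 2, 2))
  expect_true(all(ibd_pihat(few, freqs = c(0.5, 0.5))$low_confidence))
})
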