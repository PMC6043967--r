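test_that("founder model validates parameters", {
  expect_error(founder_model(divergence_fst = 1), "\\[0, 1\\)")
  expect_error(founder_model(divergence_fst = -0.1), "\\[0, 1\\)")
  expect_s3_class(founder_model(divergence_fst = 0), "founder_model")
  full <- founder_model(preset = "full")
  expect_length(full$chrom_lengths, 38)
  expect_equal(sum(full$chrom_lengths), 2.2e9)
})

test_that("zero divergence gives identical parental frequencies", {
  f <- simulate_founder_freqs(founder_model(divergence_fst = 0), seed = 1)
  expect_identical(f$p_wolf, f$p_anc)
  expect_identical(f$p_dog, f$p_anc)
})

test_that("extreme divergence drives parental frequencies toward fixation", {
  f <- simulate_founder_freqs(founder_model(divergence_fst = 0.99), seed = 1)
  near_fixed <- abs(f$p_wolf - 0.5) > 0.45
  expect_gt(mean(near_fixed), 0.9)
})

test_that("realized parental F_ST tracks the divergence target", {
  model <- founder_model(n_sites = 10000, divergence_fst = 0.35)
  freqs <- simulate_founder_freqs(model, seed = 99)
  ref <- simulate_parental_samples(freqs, n_wolf = 20, n_dog = 20,
                                   inbreeding = c(wolf = 0, dog = 0), seed = 3)
  fst <- pairwise_fst(ref$genotypes)
  realized <- fst$matrix["wild_parent", "dom_parent"]
  expect_gt(realized, 0.30)
  expect_lt(realized, 0.40)
})

test_that("breeding schedules enforce their invariants", {
  expect_error(breeding_schedule(integer(), character(), integer()), "empty")
  expect_error(breeding_schedule(0, "closed_breeding", 10),
               "start with found_f1")
  expect_error(breeding_schedule(c(0, 0), c("found_f1", "closed_breeding"),
                                 10), "strictly increasing")
  expect_error(breeding_schedule(0, "found_f1", 1), "census")
  expect_error(breeding_schedule(0, "found_f1", 10, sire_concentration = 0),
               "> 0")
  sch <- cwd_schedule()
  expect_equal(sch$generation, 0:18)
  expect_equal(sum(sch$kind == "wolf_introgression"), 4L)
})

test_that("an F1-only founding gives q = 1/2 exactly and zero switches", {
  sch <- breeding_schedule(0, "found_f1", 12)
  sim <- simulate_breed(small_model(), sch, seed = 5)
  expect_true(all(sim$truth_q$truth_q == 0.5))
  expect_true(all(truth_switch_counts(sim)$true_switches == 0L))
})

test_that("a full backcross to dog founders halves the wolf fraction", {
  sch <- breeding_schedule(0:1, c("found_f1", "dog_introgression"),
                           census = 40, introgression_fraction = 1)
  q <- purrr::map_dbl(1:6, function(s) {
    mean(simulate_breed(small_model(), sch, seed = s)$truth_q$truth_q)
  })
  expect_equal(mean(q), 0.25, tolerance = 0.1)
})

test_that("ancestry segments tile every chromosome without gaps", {
  sim <- simulate_breed(small_model(), cwd_schedule(n_generations = 6),
                        seed = 17)
  lens <- sim$truth_segments |>
    group_by(hap_id, chrom) |>
    summarise(len = sum(end - start),
              sorted = all(diff(start) > 0), .groups = "drop")
  expect_true(all(abs(lens$len - 50e6) < 1e-6))
  expect_true(all(lens$sorted))
  # truth_q equals wolf length over total length
  q2 <- sim$truth_segments |>
    mutate(id = sub("_[12]$", "", hap_id)) |>
    group_by(id) |>
    summarise(q = sum((end - start) * (origin == "wolf")) / sum(end - start))
  expect_equal(q2$q[match(sim$truth_q$id, q2$id)], sim$truth_q$truth_q)
})

test_that("every non-founder has both parents recorded", {
  sim <- simulate_breed(small_model(), cwd_schedule(n_generations = 5), seed = 2)
  ped <- sim$pedigree
  non_founder <- is.na(ped$founder_pop)
  expect_true(all(!is.na(ped$sire[non_founder])))
  expect_true(all(!is.na(ped$dam[non_founder])))
  expect_true(all(ped$sire[non_founder] %in% ped$id))
})

test_that("mean truth_q matches the pedigree expectation over replicates", {
  # allele-dropping consistency: across replicate simulations the Mendelian
  # mean must match each pedigree's own expected wolf fraction
  diffs <- purrr::map_dbl(1:40, function(s) {
    sim <- simulate_breed(
      founder_model(n_sites = 40,
                    chrom_lengths = setNames(rep(50e6, 2), c("1", "2"))),
      cwd_schedule(n_generations = 8), seed = s
    )
    ef <- expected_ancestry_fraction(sim$pedigree, "wolf")
    mean(sim$truth_q$truth_q) -
      mean(ef$expected_fraction[ef$id %in% sim$truth_q$id])
  })
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("within-haplotype switch counts grow with closed-breeding time", {
  mean_switch <- purrr::map_dbl(c(1, 3, 6, 10), function(g) {
    kinds <- c("found_f1", rep("closed_breeding", g))
    sim <- simulate_breed(small_model(),
                          breeding_schedule(0:g, kinds, census = 30),
                          seed = 400 + g)
    mean(truth_switch_counts(sim)$true_switches)
  })
  expect_true(all(diff(mean_switch) >= 0))
})

test_that("identical seeds give bit-identical simulations", {
  a <- simulate_breed(small_model(), cwd_schedule(n_generations = 4), seed = 9)
  b <- simulate_breed(small_model(), cwd_schedule(n_generations = 4), seed = 9)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$truth_segments, b$truth_segments)
  expect_identical(a$pedigree, b$pedigree)
})

test_that("census collapse aborts with a clear error", {
  # a founding with no males in the next pool cannot continue
  sch <- breeding_schedule(c(0, 1), c("found_f1", "closed_breeding"),
                           census = c(2, 5))
  # census 2 gives one male + one female, fine; forcing an empty pool must fail
  expect_error(
    simulate_breed(small_model(), sch, seed = 1, n_wolf_founders = 0),
    "census collapse|no available parents"
  )
})

test_that("inject_missingness hits binomial bounds and rate 0 is identity", {
  gm <- get_default_study()$genotypes
  expect_identical(inject_missingness(gm, 0), gm)
  gm2 <- inject_missingness(gm[, 1:2500], rate = 0.05, seed = 8)
  n_calls <- length(gm2$calls) # 44 x 2500 = 110,000
  n_miss <- sum(is.na(gm2$calls))
  expected <- n_calls * 0.05
  band <- 2.58 * sqrt(n_calls * 0.05 * 0.95)
  expect_gt(n_miss, expected - band)
  expect_lt(n_miss, expected + band)
  expect_error(inject_missingness(gm, 1), "rate")
})

test_that("heavy missingness at a site is removed by the complete-case filter", {
  gm <- gm_from_calls(matrix(1L, 10, 1))
  gm2 <- inject_missingness(gm, 0.5, seed = 42)
  if (any(is.na(gm2$calls))) {
    expect_equal(n_sites(remove_missing_sites(gm2)), 0L)
  }
})
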