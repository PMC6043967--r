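test_that("genotype_matrix validates its invariants", {
  expect_s3_class(gm_from_calls(rbind(c(0, 1, 2))), "genotype_matrix")
  expect_error(gm_from_calls(rbind(c(0, 3, 2))), "0, 1, 2 or NA")
  expect_error(
    genotype_matrix(
      rbind(c(0, 1)),
      tibble::tibble(chrom = "1", pos = c(200L, 100L), a1 = "A", a2 = "B"),
      tibble::tibble(id = "s1", group = "breed")
    ),
    "strictly increasing"
  )
  expect_error(
    genotype_matrix(
      rbind(c(0), c(1)),
      tibble::tibble(chrom = "1", pos = 1L, a1 = "A", a2 = "B"),
      tibble::tibble(id = c("dup", "dup"), group = "breed")
    ),
    "duplicate"
  )
})

test_that("subsetting keeps samples, sites and calls aligned", {
  gm <- gm_from_calls(rbind(c(0, 1, 2), c(2, NA, 0)),
                      groups = c("breed", "wild_parent"))
  sub <- gm["s02", c(1, 3)]
  expect_equal(n_samples(sub), 1L)
  expect_equal(unname(sub$calls[1, ]), c(2L, 0L))
  expect_equal(sub$samples$group, "wild_parent")
  expect_equal(sub$sites$pos, c(1000L, 3000L))
})

test_that("PED/MAP round-trips preserve calls, sites and missingness", {
  set.seed(42)
  for (rep in 1:3) {
    calls <- matrix(sample(c(0:2, NA), 5 * 12, replace = TRUE), 5, 12)
    calls[1, ] <- 0L # keep every site polymorphic with both homozygotes
    calls[2, ] <- 2L # observed, so allele orientation is recoverable
    gm <- gm_from_calls(calls,
                        groups = sample(c("breed", "wild_parent"), 5, TRUE),
                        chrom = rep(c("1", "2"), each = 6),
                        pos = rep(as.integer((1:6) * 5e5), 2))
    ped <- withr::local_tempfile(fileext = ".ped")
    map <- withr::local_tempfile(fileext = ".map")
    write_plink_text(gm, ped, map)
    back <- read_plink_text(ped, map)
    # sites that are entirely missing or monomorphic lose allele labels, but
    # calls and coordinates must survive exactly
    expect_equal(back$calls, gm$calls)
    expect_equal(back$sites[, c("chrom", "pos")], gm$sites[, c("chrom", "pos")])
    expect_equal(back$samples, gm$samples)
  }
})

test_that("'0 0' genotypes read as missing and ragged PED lines error", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200"), map)
  writeLines(c("breed s1 0 0 0 -9 A A 0 0",
               "breed s2 0 0 0 -9 A B B B"), ped)
  gm <- read_plink_text(ped, map)
  expect_true(is.na(gm$calls["s1", 2]))
  expect_equal(unname(gm$calls["s2", 1]), 1L)
  # site 2 is observed with a single allele: orientation is unknowable, the
  # observed allele becomes a1 and the dosage of the unseen allele is 0
  expect_equal(unname(gm$calls["s2", 2]), 0L)
  expect_equal(gm$sites$a2[2], "0")

  writeLines(c("breed s1 0 0 0 -9 A A 0 0",
               "breed s2 0 0 0 -9 A B"), ped)
  expect_error(read_plink_text(ped, map), "line 2.*ragged|ragged")
})

test_that("a site observed with three alleles is rejected by name", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines("1\tbad_snp\t0\t100", map)
  writeLines(c("breed s1 0 0 0 -9 A C", "breed s2 0 0 0 -9 G G"), ped)
  expect_error(read_plink_text(ped, map), "bad_snp")
})

test_that("out-of-order MAP positions are sorted with a warning", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\tsnp1\t0\t300", "1\tsnp2\t0\t100"), map)
  writeLines(c("breed s1 0 0 0 -9 A A B B",
               "breed s2 0 0 0 -9 A B A A"), ped)
  expect_warning(gm <- read_plink_text(ped, map), "reordered")
  expect_equal(gm$sites$pos, c(100L, 300L))
  # snp2 (pos 100): s1 = BB -> 2, s2 = AA -> 0; snp1 (pos 300): AA -> 0, AB -> 1
  expect_equal(unname(gm$calls[, 1]), c(2L, 0L))
  expect_equal(unname(gm$calls[, 2]), c(0L, 1L))
})

test_that("BED output is half-open 0-based, sorted, unmerged", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed_intervals(
    tibble::tibble(chrom = c("chr2", "chr1", "chr1"),
                   start = c(10, 949999, 900000),
                   end = c(20, 1050000, 1000000)),
    path
  )
  lines <- readLines(path)
  expect_equal(lines[2], "chr1\t949999\t1050000")
  expect_length(lines, 3) # overlapping intervals preserved
  # empty set -> empty file
  write_bed_intervals(tibble::tibble(chrom = character(), start = numeric(),
                                     end = numeric()), path)
  expect_length(readLines(path), 0)
  expect_error(
    write_bed_intervals(tibble::tibble(chrom = "1", start = 5, end = 5), path),
    "start < end"
  )
})

test_that("haplotype TSV round-trips and consistency checking works", {
  haps <- rbind(c(0L, 1L, 1L), c(1L, 0L, 1L), c(0L, 0L, 0L), c(1L, 1L, 0L))
  sites <- tibble::tibble(chrom = "1", pos = c(10L, 20L, 30L), a1 = "A", a2 = "B")
  hs <- haplotype_set(haps, sites, c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotypes_tsv(hs, path)
  back <- read_haplotypes_tsv(path)
  expect_equal(back$haps, hs$haps)
  expect_equal(back$sample_ids, hs$sample_ids)

  gm <- haps_to_genotypes(hs)
  expect_true(check_hap_consistency(hs, gm))
  gm$calls[1, 1] <- 2L
  expect_error(check_hap_consistency(hs, gm), "does not sum")
})

test_that("pedigree TSV round-trips with unknown parents as 0", {
  ped <- pedigree_table(
    id = c("W1", "D1", "B1"), sire = c(NA, NA, "W1"), dam = c(NA, NA, "D1"),
    founder_pop = c("wolf", "dog", NA), generation = c(-1L, -1L, 0L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree_tsv(ped, path)
  back <- read_pedigree_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(ped))
})
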