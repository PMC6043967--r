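#' Default end-to-end pipeline configuration
#'
#' Every stage's parameters with their package defaults; unknown keys in a
#' user-supplied config are rejected by [run_pipeline()]. The single global
#' `seed` fans out to deterministic per-stage seeds so stages can be re-run
#' in isolation.
#'
#' @param seed Global seed.
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    simulate = list(
      n_sites = 2000, n_chrom = 5, chrom_length = 50e6,
      divergence_fst = 0.35, schedule = "cwd",
      n_wolf_ref = 12, n_dog_ref = 12, missing_rate = 0.04
    ),
    qc = list(
      enabled = TRUE, call_rate = 0.95, drop_sex = TRUE,
      ld_window = 50, ld_step = 5, ld_r2 = 0.2
    ),
    roh = list(min_snps = 25, min_kb = 500, max_het = 1, max_missing = 2,
               max_gap_kb = 1000),
    ancestry = list(block_size = 10, smooth = TRUE, hmm_generations = 10,
                    call_threshold = 0.8),
    dating = list(t_min = 1, t_max = 20, reference_year = 2010,
                  generation_time = 3, n_boot = 50),
    outliers = list(fraction = 0.01, flank_bp = 50000)
  ), class = "pipeline_config")
}

check_config <- function(config) {
  ref <- default_config()
  extra <- setdiff(names(config), names(ref))
  if (length(extra)) abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  for (sec in setdiff(names(config), "seed")) {
    extra <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(extra)) {
      abort(sprintf("unknown config key(s) in %s: %s", sec, paste(extra, collapse = ", ")))
    }
  }
  # fill unset keys with defaults
  out <- ref
  out$seed <- config$seed %||% ref$seed
  for (sec in setdiff(names(ref), "seed")) {
    for (k in names(config[[sec]])) out[[sec]][[k]] <- config[[sec]][[k]]
  }
  out
}

match_site_columns <- function(sites_a, sites_b) {
  match(paste(sites_a$chrom, sites_a$pos), paste(sites_b$chrom, sites_b$pos))
}

#' Run the full characterization pipeline on simulated data
#'
#' Simulate, filter, and compute every downstream analysis in order:
#' summary statistics, ROH and F_ROH, pedigree comparisons, local-ancestry
#' deconvolution, the three dating procedures and the outlier panels. Fully
#' deterministic under a fixed config.
#'
#' @param config A config as from [default_config()] (partial configs are
#'   completed with defaults; unknown keys are an error).
#' @return A list of class `pipeline_result` with `report` (JSON-ready
#'   summary), `data` (intermediate objects) and `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- check_config(unclass(config))
  seed <- config$seed

  # --- simulate -------------------------------------------------------------
  sc <- config$simulate
  model <- founder_model(
    n_sites = sc$n_sites,
    chrom_lengths = setNames(rep(sc$chrom_length, sc$n_chrom),
                             as.character(seq_len(sc$n_chrom))),
    divergence_fst = sc$divergence_fst
  )
  schedule <- if (identical(sc$schedule, "cwd")) cwd_schedule() else sc$schedule
  study <- simulate_study(
    model, schedule,
    n_wolf_ref = sc$n_wolf_ref, n_dog_ref = sc$n_dog_ref,
    seed = derive_seed(seed, 1)
  )
  gm_raw <- inject_missingness(study$genotypes, sc$missing_rate,
                               seed = derive_seed(seed, 2))

  # --- qc -------------------------------------------------------------------
  if (config$qc$enabled) {
    qc <- qc_cascade(gm_raw, call_rate = config$qc$call_rate,
                     ld_window = config$qc$ld_window,
                     ld_step = config$qc$ld_step, ld_r2 = config$qc$ld_r2,
                     drop_sex = config$qc$drop_sex)
    gm_quality <- qc$genotypes
    gm_complete <- qc$complete
    qc_report <- qc$report
  } else {
    gm_quality <- gm_raw
    gm_complete <- remove_missing_sites(gm_raw)
    qc_report <- tibble(stage = "qc_disabled",
                        n_samples = n_samples(gm_raw), n_sites = n_sites(gm_raw))
  }

  # --- summary statistics ---------------------------------------------------
  het_group <- observed_heterozygosity(gm_quality, by = "group")
  f_sample <- inbreeding_f(gm_quality)
  fst <- pairwise_fst(gm_quality)
  pca <- pca_genotypes(gm_quality)
  breed_ids <- gm_quality$samples$id[gm_quality$samples$group == "breed"]
  ibd <- ibd_pihat(filter_groups(gm_quality, "breed"))

  # --- pedigree -------------------------------------------------------------
  ped <- study$sim$pedigree
  coi <- ped_coi(ped, ids = breed_ids[breed_ids %in% ped$id])
  cor_ped <- ped_cor(ped, ids = breed_ids[breed_ids %in% ped$id])
  exp_frac <- expected_ancestry_fraction(ped, "wolf")

  # --- roh ------------------------------------------------------------------
  rp <- do.call(roh_params, config$roh)
  rohs <- detect_roh(gm_quality, params = rp)
  froh_tab <- froh(rohs, gm_quality, samples = gm_quality$samples$id) |>
    dplyr::left_join(gm_quality$samples, by = "id") |>
    mutate(group = dplyr::coalesce(.data$group.y, .data$group.x)) |>
    select("id", "group", "froh")
  roh_sum <- roh_summary(rohs)
  shared <- shared_roh_regions(filter(rohs, .data$group == "breed"),
                               samples = breed_ids)

  # --- local ancestry -------------------------------------------------------
  # deconvolution works on the phased quality-pruned data (complete-case
  # sites): LD pruning would strip exactly the admixture LD that carries the
  # ancestry signal
  ac <- config$ancestry
  gm_anc <- remove_missing_sites(gm_quality)
  jdx <- match_site_columns(gm_anc$sites, study$haplotypes$sites)
  hs_sub <- haplotype_set(study$haplotypes$haps[, jdx, drop = FALSE],
                          gm_anc$sites, study$haplotypes$sample_ids)
  wolf_hs <- subset_haplotypes(hs_sub, grep("^WREF", hs_sub$sample_ids, value = TRUE))
  dog_hs <- subset_haplotypes(hs_sub, grep("^DREF", hs_sub$sample_ids, value = TRUE))
  breed_hs <- subset_haplotypes(hs_sub,
                                intersect(hs_sub$sample_ids, study$sim$truth_q$id))
  ref_panel <- build_reference(wolf_hs, dog_hs, block_size = ac$block_size,
                               map = study$sim$map)
  track <- deconvolve(breed_hs, ref_panel, smooth = ac$smooth,
                      hmm_generations = ac$hmm_generations,
                      call_threshold = ac$call_threshold)
  q_tab <- genome_wide_ancestry(track)
  ref_freq <- site_frequencies(filter_groups(gm_anc,
                                             c("wild_parent", "dom_parent"))) |>
    select("group", "site", "freq") |>
    pivot_wider(names_from = "group", values_from = "freq") |>
    transmute(p_wolf = .data$wild_parent, p_dog = .data$dom_parent)
  q_sup <- supervised_q(filter_groups(gm_anc, "breed"), ref_freq)
  switches <- count_switches(track)
  fixed_blocks <- fixed_ancestry_blocks(track)

  # --- dating ---------------------------------------------------------------
  dc <- config$dating
  gm_breed_q <- filter_groups(gm_quality, "breed")
  ne <- ne_trajectory(gm_breed_q, study$sim$map, t_range = c(dc$t_min, dc$t_max))
  ref_freq_q <- tibble(
    p_wolf = study$sim$founder_freqs$p_wolf[
      match_site_columns(gm_quality$sites, study$sim$founder_freqs)],
    p_dog = study$sim$founder_freqs$p_dog[
      match_site_columns(gm_quality$sites, study$sim$founder_freqs)]
  )
  ald <- admixture_ld_decay(gm_breed_q, ref_freq_q, study$sim$map,
                            n_boot = dc$n_boot, seed = derive_seed(seed, 3))
  L <- total_map_length(study$sim$map)
  sw_in <- switches |> dplyr::inner_join(q_tab, by = "id") |>
    filter(.data$q > 0, .data$q < 1)
  sw_date <- switch_dating(sw_in$switches, sw_in$q, L, ids = sw_in$id)
  dating_years <- generations_to_years(
    c(alder_like = ald$generations,
      switches = mean(sw_date$generations)),
    generation_time = dc$generation_time, reference_year = dc$reference_year
  )

  # --- outlier panels -------------------------------------------------------
  oc <- config$outliers
  freqs_q <- site_frequencies(gm_quality)
  fixed <- fixed_diff_sites(freqs_q)
  chrom_lengths <- study$sim$map$chrom_lengths
  panels <- list()
  if (nrow(fixed) > 0) {
    fbw <- filter(fst$per_site, .data$group1 == "breed",
                  .data$group2 == "wild_parent") |>
      dplyr::bind_rows(filter(fst$per_site, .data$group1 == "wild_parent",
                              .data$group2 == "breed"))
    fbd <- filter(fst$per_site, .data$group1 == "breed",
                  .data$group2 == "dom_parent") |>
      dplyr::bind_rows(filter(fst$per_site, .data$group1 == "dom_parent",
                              .data$group2 == "breed"))
    aims <- aim_select(fixed, fbw, fbd, fraction = oc$fraction)
    if (nrow(aims$wolf_like)) {
      panels$fst_snp_wolf <- expand_intervals(aims$wolf_like, chrom_lengths,
                                              oc$flank_bp) |>
        mutate(direction = "wolf_like")
    }
    if (nrow(aims$dog_like)) {
      panels$fst_snp_dog <- expand_intervals(aims$dog_like, chrom_lengths,
                                             oc$flank_bp) |>
        mutate(direction = "dog_like")
    }
  } else {
    aims <- NULL
  }
  if (nrow(fixed_blocks)) {
    panels$pcadmix_fixed <- expand_intervals(fixed_blocks, chrom_lengths,
                                             oc$flank_bp) |>
      mutate(direction = fixed_blocks$direction)
  }
  if (nrow(shared)) {
    panels$shared_roh <- shared |>
      mutate(start = pmax(0, .data$start - oc$flank_bp),
             end = pmin(unname(chrom_lengths[.data$chrom]),
                        .data$end + oc$flank_bp),
             direction = NA_character_)
  }
  consolidated <- if (length(panels)) consolidate_panels(panels) else NULL

  # --- report ---------------------------------------------------------------
  report <- list(
    seed = seed,
    qc = as.data.frame(qc_report),
    fst_matrix = fst$matrix,
    h_obs = as.data.frame(het_group),
    f_mean_by_group = as.data.frame(
      f_sample |> group_by(.data$group) |>
        summarise(f = mean(.data$f, na.rm = TRUE))
    ),
    froh_by_group = as.data.frame(
      froh_tab |> group_by(.data$group) |>
        summarise(froh = mean(.data$froh), .groups = "drop")
    ),
    q_mean = mean(q_tab$q, na.rm = TRUE),
    q_supervised_mean = mean(q_sup$q),
    truth_q_mean = mean(study$sim$truth_q$truth_q),
    pedigree_wolf_fraction_mean = mean(
      exp_frac$expected_fraction[exp_frac$id %in% breed_ids]),
    switches_mean = mean(switches$switches),
    dating = list(
      weighted_ld_generations = ald$generations,
      weighted_ld_ci = unname(ald$ci),
      switch_generations_mean = mean(sw_date$generations),
      years = as.data.frame(dating_years)
    ),
    ne_trajectory = as.data.frame(ne),
    panel_counts = if (length(panels)) {
      data.frame(panel = names(panels),
                 n = vapply(panels, nrow, 1L), row.names = NULL)
    } else data.frame(panel = character(), n = integer()),
    n_fixed_diff_sites = nrow(fixed),
    n_fixed_blocks = nrow(fixed_blocks)
  )
  structure(
    list(
      report = report,
      data = list(
        study = study, qc_report = qc_report, gm_quality = gm_quality,
        gm_complete = gm_complete, het_group = het_group,
        f_sample = f_sample, fst = fst, pca = pca, ibd = ibd,
        coi = coi, cor_ped = cor_ped, expected_fraction = exp_frac,
        roh = rohs, froh = froh_tab, roh_summary = roh_sum,
        shared_roh = shared, reference = ref_panel, track = track,
        q = q_tab, q_supervised = q_sup, switches = switches,
        fixed_blocks = fixed_blocks, ne = ne, weighted_ld = ald,
        switch_dating = sw_date, aims = aims, panels = panels,
        consolidated = consolidated
      ),
      config = config
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("<pipeline_result>\n")
  cat(sprintf("  breed wolf ancestry: q = %.3f (truth %.3f, pedigree %.3f)\n",
              r$q_mean, r$truth_q_mean, r$pedigree_wolf_fraction_mean))
  cat(sprintf("  weighted-LD dating: %.1f generations; switch dating: %.1f\n",
              r$dating$weighted_ld_generations, r$dating$switch_generations_mean))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' TSVs for the tabular results, BED files for interval panels, and a JSON
#' run report with every parameter and seed.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, name) {
    write.table(as.data.frame(d), file.path(dir, paste0(name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  d <- result$data
  w(d$het_group, "het_by_group")
  w(d$f_sample, "f_by_sample")
  w(d$fst$pairs, "fst_pairs")
  w(d$pca$scores, "pca_coords")
  w(d$ibd, "ibd_pairs")
  w(d$roh, "roh")
  w(d$froh, "froh")
  w(d$q, "ancestry_q")
  w(d$q_supervised, "ancestry_q_supervised")
  w(d$switches, "switch_counts")
  w(d$ne, "ne_trajectory")
  w(d$switch_dating, "switch_dating")
  if (!is.null(d$consolidated) && nrow(d$consolidated)) {
    write_bed_intervals(d$consolidated, file.path(dir, "outlier_panels.bed"))
  }
  if (nrow(d$shared_roh)) {
    write_bed_intervals(d$shared_roh, file.path(dir, "shared_roh.bed"))
  }
  write_plink_text(d$gm_quality, file.path(dir, "quality_pruned.ped"),
                   file.path(dir, "quality_pruned.map"))
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
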