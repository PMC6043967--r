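#' Tidiers for package result objects
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns the
#' observation-level tibble of a result, `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name admixbreed-tidiers
NULL

#' @rdname admixbreed-tidiers
#' @method tidy fst_result
#' @export
tidy.fst_result <- function(x, ...) x$pairs

#' @rdname admixbreed-tidiers
#' @method glance fst_result
#' @export
glance.fst_result <- function(x, ...) {
  tibble(
    n_groups = nrow(x$matrix),
    n_pairs = nrow(x$pairs),
    max_fst = max(x$pairs$fst),
    min_fst = min(x$pairs$fst)
  )
}

#' @rdname admixbreed-tidiers
#' @method tidy gm_pca
#' @export
tidy.gm_pca <- function(x, ...) {
  x$scores |>
    pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                 values_to = "score")
}

#' @rdname admixbreed-tidiers
#' @method glance gm_pca
#' @export
glance.gm_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_components = length(x$var_explained),
    pc1_var = x$var_explained[1],
    pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_
  )
}

#' @rdname admixbreed-tidiers
#' @method tidy ne_trajectory
#' @export
tidy.ne_trajectory <- function(x, ...) as_tibble(x)

#' @rdname admixbreed-tidiers
#' @method glance ne_trajectory
#' @export
glance.ne_trajectory <- function(x, ...) {
  ok <- !is.na(x$ne)
  tibble(
    n_bins = nrow(x),
    n_defined = sum(ok),
    ne_min = if (any(ok)) min(x$ne[ok]) else NA_real_,
    ne_max = if (any(ok)) max(x$ne[ok]) else NA_real_,
    n_chromosomes_sampled = attr(x, "n_chromosomes_sampled")
  )
}

#' @rdname admixbreed-tidiers
#' @method tidy admixture_date
#' @export
tidy.admixture_date <- function(x, ...) x$bins

#' @rdname admixbreed-tidiers
#' @method glance admixture_date
#' @export
glance.admixture_date <- function(x, ...) {
  tibble(
    method = x$method,
    generations = x$generations,
    ci_lo = x$ci[1], ci_hi = x$ci[2],
    amplitude = x$amplitude, tail = x$tail,
    flag = x$flag
  )
}

#' @rdname admixbreed-tidiers
#' @method tidy admixture_date_switches
#' @export
tidy.admixture_date_switches <- function(x, ...) as_tibble(x)

#' @rdname admixbreed-tidiers
#' @method glance admixture_date_switches
#' @export
glance.admixture_date_switches <- function(x, ...) {
  tibble(
    method = "switches",
    generations = attr(x, "mean_generations"),
    sd = attr(x, "sd_generations"),
    n = nrow(x)
  )
}

#' @rdname admixbreed-tidiers
#' @method tidy breed_sim
#' @export
tidy.breed_sim <- function(x, ...) {
  x$truth_q |>
    dplyr::left_join(
      truth_switch_counts(x), by = "id"
    )
}

#' @rdname admixbreed-tidiers
#' @method glance breed_sim
#' @export
glance.breed_sim <- function(x, ...) {
  tibble(
    n_individuals = n_samples(x$genotypes),
    n_sites = n_sites(x$genotypes),
    n_pedigree = nrow(x$pedigree),
    mean_truth_q = mean(x$truth_q$truth_q),
    seed = x$seed
  )
}
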