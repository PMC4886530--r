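# Synthetic fermentation cohorts: per-batch genus time courses in which
# poorly fermenting batches become Lactobacillus-dominated by day 7.

DEFAULT_GENERA <- c(
  "Lactobacillus", "Thermoactinomyces", "Bacillus", "Weissella",
  "Pediococcus", "Leuconostoc", "Staphylococcus", "Acetobacter",
  "Enterobacter", "Saccharopolyspora"
)

#' Specify a synthetic fermentation cohort
#'
#' Describes the study conditions for [simulate_cohort()]: how many batches
#' ferment well or spoil, on which days each batch is sampled, and the
#' Lactobacillus relative-abundance ranges that the two outcomes reach from
#' day 7 onwards. Before day 7 both classes draw Lactobacillus from the same
#' `early_range`, reflecting that community divergence only becomes
#' diagnostic at day 7. Remaining abundance mass is Dirichlet-distributed
#' over the other genera.
#'
#' @param n_good_batches,n_poor_batches Number of batches per final quality.
#' @param sampling_days Ascending integer day offsets at which each batch is
#'   sampled.
#' @param genus_names Genus vocabulary; must contain `"Lactobacillus"`.
#' @param lactobacillus_good_range,lactobacillus_poor_range Intervals in
#'   `[0, 1]` from which day >= 7 Lactobacillus abundance is drawn per class.
#'   Overlap is allowed.
#' @param early_range Interval used for both classes before day 7.
#' @param dirichlet_concentration Symmetric Dirichlet concentration for the
#'   non-Lactobacillus mass split.
#' @param seed Integer seed making the cohort reproducible.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_good_batches = 6,
                        n_poor_batches = 6,
                        sampling_days = c(1, 4, 7, 14),
                        genus_names = DEFAULT_GENERA,
                        lactobacillus_good_range = c(0.05, 0.60),
                        lactobacillus_poor_range = c(0.88, 0.99),
                        early_range = c(0.02, 0.25),
                        dirichlet_concentration = 5,
                        seed = 1L) {
  if (length(genus_names) == 0L) abort("`genus_names` must be non-empty")
  if (!"Lactobacillus" %in% genus_names) {
    abort("`genus_names` must include \"Lactobacillus\"")
  }
  check_range01(lactobacillus_good_range, "lactobacillus_good_range")
  check_range01(lactobacillus_poor_range, "lactobacillus_poor_range")
  check_range01(early_range, "early_range")
  if (is.unsorted(sampling_days)) abort("`sampling_days` must be ascending")
  if (dirichlet_concentration <= 0) {
    abort("`dirichlet_concentration` must be positive")
  }
  structure(
    list(
      n_good_batches = as.integer(n_good_batches),
      n_poor_batches = as.integer(n_poor_batches),
      sampling_days = as.integer(sampling_days),
      genus_names = genus_names,
      lactobacillus_good_range = lactobacillus_good_range,
      lactobacillus_poor_range = lactobacillus_poor_range,
      early_range = early_range,
      dirichlet_concentration = dirichlet_concentration,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Simulate a genus-level fermentation cohort
#'
#' Draws one compositional genus profile per (batch, day). From day 7 on,
#' Lactobacillus abundance comes from the class-specific range of the batch's
#' final quality; the remaining mass is split over the other genera by a
#' symmetric Dirichlet draw. Rows sum to 1 and the table is reproducible
#' bit-for-bit under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return Wide tibble with `sample_id`, `batch`, `day`, `quality` metadata
#'   columns and one relative-abundance column per genus.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  batches <- tibble(
    batch = c(
      sprintf("good_%02d", seq_len(spec$n_good_batches)),
      sprintf("poor_%02d", seq_len(spec$n_poor_batches))
    ),
    quality = rep(c("good", "poor"),
                  c(spec$n_good_batches, spec$n_poor_batches))
  )
  grid <- tidyr::crossing(batches, day = spec$sampling_days)
  others <- setdiff(spec$genus_names, "Lactobacillus")
  with_seed_maybe(spec$seed, {
    rows <- purrr::pmap(grid, function(batch, quality, day) {
      rng <- if (day >= 7) {
        if (quality == "good") spec$lactobacillus_good_range
        else spec$lactobacillus_poor_range
      } else {
        spec$early_range
      }
      lact <- runif(1, rng[1], rng[2])
      p <- setNames(numeric(length(spec$genus_names)), spec$genus_names)
      p["Lactobacillus"] <- lact
      if (length(others) > 0L) {
        w <- rgamma(length(others), shape = spec$dirichlet_concentration)
        p[others] <- (1 - lact) * w / sum(w)
      } else {
        # single-genus vocabulary: all mass on Lactobacillus
        p["Lactobacillus"] <- 1
      }
      as_tibble(as.list(p))
    })
  })
  dplyr::bind_cols(
    grid |>
      mutate(sample_id = sprintf("%s_d%02d", .data$batch, .data$day)) |>
      select("sample_id", "batch", "day", "quality"),
    dplyr::bind_rows(rows)
  )
}
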