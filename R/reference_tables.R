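# Published benchmark dose statistics for the C-shape and mock-prostate
# phantoms: mean doses achieved by the static (FIS) and trained (ANFIS)
# controllers at each of five prescription levels, and the level goals they
# are scored against. These are the inputs for the percentage-to-goal
# benchmark reproduced by the acceptance tests.

#' Benchmark mean doses by controller, level and structure
#'
#' Mean doses (% of the target prescription) achieved by the static (`fis`)
#' and trained (`anfis`) fuzzy controllers on the original C-shape and
#' mock-prostate benchmark phantoms at each prescription level.
#'
#' @return Tibble with columns `site`, `system`, `level`, `structure`,
#'   `mean_dose`.
#' @export
reference_dose_means <- function() {
  cshape <- tibble(
    site = "cshape",
    system = rep(c("fis", "anfis"), each = 15),
    level = rep(rep(1:5, each = 3), 2),
    structure = rep(c("ptv", "oar", "nt"), 10),
    mean_dose = c(
      # fis, levels 1-5
      101.1, 23.3, 10.0,
      101.1, 35.3, 10.0,
      100.6, 40.6, 10.2,
      100.3, 36.7, 10.4,
      100.2, 32.2, 10.5,
      # anfis, levels 1-5
      100.0, 21.1, 9.2,
      100.0, 20.9, 10.6,
      100.0, 24.7, 10.7,
      100.0, 29.3, 10.0,
      100.0, 31.8, 10.0
    )
  )
  prostate <- tibble(
    site = "prostate",
    system = rep(c("fis", "anfis"), each = 20),
    level = rep(rep(1:5, each = 4), 2),
    structure = rep(c("ptv", "rectum", "bladder", "nt"), 10),
    mean_dose = c(
      # fis, levels 1-5
      100.0, 51.8, 38.3, 7.0,
      100.0, 35.0, 39.1, 7.1,
      100.0, 34.7, 38.4, 7.0,
      100.0, 36.6, 34.8, 7.1,
      100.0, 38.8, 38.7, 6.6,
      # anfis, levels 1-5
      100.0, 42.8, 34.5, 6.9,
      100.0, 31.2, 36.9, 7.2,
      100.0, 29.7, 28.3, 6.7,
      100.0, 33.9, 34.4, 7.1,
      100.0, 37.8, 35.5, 7.0
    )
  )
  dplyr::bind_rows(cshape, prostate)
}

#' Benchmark level goals by site, level and structure
#'
#' The per-structure dosimetric goals of the five evaluation prescription
#' levels (see [gip_levels()]): the target goal is 100 at every level, each
#' OAR carries the level's OAR target, and the normal tissue its
#' normal-tissue target.
#'
#' @return Tibble with columns `site`, `level`, `structure`, `goal`.
#' @export
reference_level_goals <- function() {
  expand_site <- function(site, structures) {
    lv <- gip_levels(site)
    dplyr::bind_rows(lapply(structures, function(st) {
      tibble(site = site, level = lv$level, structure = st,
             goal = if (st == "ptv") lv$ptv else if (st == "nt") lv$nt else lv$oar)
    }))
  }
  dplyr::bind_rows(
    expand_site("cshape", c("ptv", "oar", "nt")),
    expand_site("prostate", c("ptv", "rectum", "bladder", "nt"))
  )
}

#' Percentage-to-goal benchmark table
#'
#' Recomputes the signed percentage-to-goal for every benchmark cell from the
#' mean doses of [reference_dose_means()] and the goals of
#' [reference_level_goals()], rounded to one decimal (half away from zero, the
#' convention of the printed benchmark).
#'
#' @return Tibble with columns `site`, `system`, `level`, `structure`,
#'   `mean_dose`, `goal`, `pct_to_goal`.
#' @export
reference_percent_to_goal <- function() {
  df <- dplyr::inner_join(reference_dose_means(), reference_level_goals(),
                          by = c("site", "level", "structure"))
  dplyr::mutate(df,
                pct_to_goal = round_half_up(
                  percent_to_goal(.data$mean_dose, .data$goal), 1))
}

#' Headline five-level improvements of the trained controller
#'
#' For each site and structure, the five-level average percentage-to-goal of
#' the static controller minus that of the trained controller (positive values
#' favor the trained controller), computed from unrounded percentages and
#' rounded to one decimal. The C-shape target entry is the mean-dose
#' conformity improvement; OAR entries are mean-dose reductions.
#'
#' @return Tibble with columns `site`, `structure`, `improvement`.
#' @export
reference_headlines <- function() {
  df <- dplyr::inner_join(reference_dose_means(), reference_level_goals(),
                          by = c("site", "level", "structure"))
  df <- dplyr::mutate(df, pct = percent_to_goal(.data$mean_dose, .data$goal))
  wide <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(df, .data$site, .data$structure,
                                     .data$system),
                     avg = mean(.data$pct), .groups = "drop"),
    names_from = "system", values_from = "avg"
  )
  dplyr::transmute(wide, site = .data$site, structure = .data$structure,
                   improvement = round_half_up(.data$fis - .data$anfis, 1))
}
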