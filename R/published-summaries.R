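#' @include cohort-stats.R
NULL

#' Reference group summaries for the modeled population
#'
#' Published per-group summary statistics (mean and SD per outcome group,
#' with availability counts) for the headline sensor features of the
#' 154-patient subacute-rehabilitation cohort this package models, plus the
#' cohort bookkeeping constants (184 consented, 30 excluded by the inclusion
#' criteria, 145 community / 9 hospital). These summaries are inputs: they
#' let standardized effect sizes be recomputed from printed group summaries
#' and they seed the synthetic generator's group-effect defaults.
#'
#' @return List with `features` (data.frame: `feature, mean_C, sd_C, mean_H,
#'   sd_H, n_C, n_H`) and `cohort` (named counts).
#' @examples
#' s <- referenceGroupSummaries()
#' with(s$features[1, ], cohensD(mean_C, sd_C, mean_H, sd_H))
#' @export
referenceGroupSummaries <- function() {
  features <- data.frame(
    feature = c("time_pct_standing", "time_pct_laying",
                "ei_resident_room", "time_pct_active", "time_pct_sitting"),
    mean_C = c(44.22, 46.83, 43.32, 12.92, 8.60),
    sd_C = c(7.94, 9.83, 17.44, 6.52, 8.36),
    mean_H = c(32.68, 60.99, 26.99, 6.94, 6.16),
    sd_H = c(7.30, 11.11, 6.05, 4.01, 7.36),
    n_C = rep(145L, 5L), n_H = rep(9L, 5L))
  cohort <- c(consented = 184L, excluded = 30L, included = 154L,
              community = 145L, hospital = 9L)
  list(features = features, cohort = cohort)
}
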