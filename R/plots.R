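#' @export
autoplot.decision_curve <- function(object, ...) {
  long <- object %>%
    tidyr::pivot_longer(c("nb_model", "nb_all", "nb_none"),
                        names_to = "policy", values_to = "net_benefit")
  ggplot(long, aes(x = .data$threshold, y = .data$net_benefit,
                   colour = .data$policy)) +
    geom_line() +
    coord_cartesian(ylim = c(-0.05, attr(object, "prevalence") * 1.2)) +
    scale_colour_manual(values = c(nb_model = "black", nb_all = "grey55",
                                   nb_none = "grey80"),
                        labels = c(nb_model = "model", nb_all = "treat all",
                                   nb_none = "treat none")) +
    labs(x = "probability threshold", y = "net benefit", colour = NULL) +
    theme_minimal()
}

#' Histograms of facility misutilization rates
#'
#' @param profiles Output of [facility_rates()].
#' @return ggplot of the per-facility mis-, over-, and under-utilization
#'   rate distributions.
#' @export
plot_facility_rates <- function(profiles) {
  long <- profiles %>%
    tidyr::pivot_longer(c("rate_mis", "rate_over", "rate_under"),
                        names_to = "kind", values_to = "rate") %>%
    mutate(kind = sub("^rate_", "", .data$kind))
  ggplot(long, aes(x = .data$rate)) +
    geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    facet_wrap(~kind, ncol = 1, scales = "free_y") +
    labs(x = "facility rate", y = "facilities") +
    theme_minimal()
}

#' Bubble plot of flagged facilities: expected vs actual counts
#'
#' @param flags Output of [flag_facilities()].
#' @param kind Misutilization kind.
#' @return ggplot with bubble size log volume and the identity line
#'   marking counts aligned with the common-rate expectation.
#' @export
plot_flagged_bubbles <- function(flags, kind = c("mis", "over", "under")) {
  kind <- match.arg(kind)
  bd <- bubble_data(flags, kind)
  ggplot(bd, aes(x = .data$actual, y = .data$expected,
                 size = .data$log_volume)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6, colour = "firebrick") +
    labs(x = "actual count", y = "expected count", size = "log volume",
         title = paste0(kind, "-utilization, flagged facilities")) +
    theme_minimal()
}

#' Back-to-back log-volume distributions
#'
#' All facilities (up) versus facilities flagged for misutilization
#' (down), on the log-volume axis.
#'
#' @param profiles Output of [facility_rates()].
#' @param flags Output of [flag_facilities()].
#' @param kind Misutilization kind.
#' @return ggplot.
#' @export
plot_volume_flag_comparison <- function(profiles, flags,
                                        kind = c("mis", "over", "under")) {
  kind <- match.arg(kind)
  flagged_ids <- flags %>%
    filter(.data$kind == !!kind, .data$flagged) %>%
    pull("facility_id")
  all_lv <- tibble(group = "all facilities", log_volume = log(profiles$volume))
  flg_lv <- tibble(group = "flagged",
                   log_volume = log(profiles$volume[
                     profiles$facility_id %in% flagged_ids]))
  brk <- pretty(all_lv$log_volume, 25)
  up <- ggplot2::ggplot_build(
    ggplot(all_lv, aes(x = .data$log_volume)) + geom_histogram(breaks = brk)
  )$data[[1]]
  dn <- ggplot2::ggplot_build(
    ggplot(flg_lv, aes(x = .data$log_volume)) + geom_histogram(breaks = brk)
  )$data[[1]]
  df <- dplyr::bind_rows(
    tibble(x = up$x, y = up$count, group = "all facilities"),
    tibble(x = dn$x, y = -dn$count, group = "flagged")
  )
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$group)) +
    geom_col(width = diff(brk)[1]) +
    scale_fill_manual(values = c(`all facilities` = "steelblue",
                                 flagged = "firebrick")) +
    labs(x = "log(volume)", y = "facilities (flagged shown downward)",
         fill = NULL) +
    theme_minimal()
}

#' Under- vs over-utilization rates by facility
#'
#' @param profiles Output of [facility_rates()].
#' @return ggplot bubble plot, bubble size log volume.
#' @export
plot_under_over <- function(profiles) {
  ggplot(profiles, aes(x = .data$rate_over, y = .data$rate_under,
                       size = log(.data$volume))) +
    geom_point(alpha = 0.4, colour = "steelblue") +
    labs(x = "over-utilization rate", y = "under-utilization rate",
         size = "log volume") +
    theme_minimal()
}
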