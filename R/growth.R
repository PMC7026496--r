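#' Tumor volume from caliper length and width
#'
#' The standard ellipsoid approximation `volume = length x width^2 / 2`
#' (mm^3 from mm inputs). Warns when width exceeds length (caliper
#' convention: length is the longer axis).
#'
#' @param length,width Caliper measurements in mm (vectorized, >= 0).
#' @return Volumes in mm^3.
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0, na.rm = TRUE) || any(width < 0, na.rm = TRUE)) {
    abort("Caliper measurements must be non-negative.")
  }
  if (any(width > length, na.rm = TRUE)) {
    warn("width > length for some records; check caliper axis convention.")
  }
  length * width^2 / 2
}

# ensure a `volume` column exists on a growth record tibble
ensure_volume <- function(records) {
  records <- as_tibble(records)
  if (!"volume" %in% names(records)) {
    stopifnot(all(c("length_mm", "width_mm") %in% names(records)))
    records$volume <- tumor_volume(records$length_mm, records$width_mm)
  }
  records
}

#' Apply study censoring rules to growth records
#'
#' Per animal, measurements strictly after the first day the volume
#' reaches `max_volume`, and any measurements after `max_day`, are dropped
#' and logged (animals are sacrificed at day `max_day` or on reaching the
#' volume limit).
#'
#' @param records Growth tibble with `animal`, `day` and either `volume`
#'   or `length_mm`/`width_mm`.
#' @param max_volume Censor volume in mm^3.
#' @param max_day Last study day.
#' @return List: `records` (kept rows, per-animal chronological order) and
#'   `censor_log` (tibble: animal, censor_day, reason, n_dropped).
#' @export
apply_censoring <- function(records, max_volume = 1500, max_day = 18) {
  records <- ensure_volume(records)
  split_recs <- split(records, records$animal)
  kept <- list()
  log <- list()
  for (an in names(split_recs)) {
    r <- arrange(split_recs[[an]], .data$day)
    over_day <- r$day > max_day
    cross <- which(r$day <= max_day & r$volume >= max_volume)
    cutoff_day <- if (length(cross) > 0) r$day[cross[1]] else max_day
    reason <- if (length(cross) > 0) "volume" else "end_of_study"
    drop <- r$day > cutoff_day | over_day
    kept[[an]] <- r[!drop, , drop = FALSE]
    if (any(drop) || length(cross) > 0) {
      log[[an]] <- tibble(animal = an, censor_day = cutoff_day,
                          reason = reason, n_dropped = sum(drop))
    }
  }
  empty_log <- tibble(animal = character(), censor_day = numeric(),
                      reason = character(), n_dropped = integer())
  list(records = list_rbind(kept),
       censor_log = if (length(log) == 0) empty_log else list_rbind(log))
}

#' Two-way ANOVA of tumor volume on treatment arm and day
#'
#' Fixed-effects two-way ANOVA `volume ~ arm * day` with day treated as a
#' categorical factor, on a balanced design (equal animals per arm x day
#' cell; unbalanced or incomplete designs are rejected with the offending
#' cells named). Repeated measures within animals are not modelled.
#'
#' @param records Growth tibble with `arm`, `day` and volume (or calipers).
#' @return A `growth_anova` tibble: term, df, sumsq, meansq, statistic,
#'   p.value; the fitted [stats::aov] model is kept as attribute `model`.
#' @export
two_way_anova <- function(records) {
  records <- ensure_volume(records)
  records$day <- factor(records$day)
  records$arm <- factor(records$arm)
  if (nlevels(records$arm) < 2) abort("Need >= 2 arms.")
  if (nlevels(records$day) < 2) abort("Need >= 2 time points.")
  cells <- records |>
    dplyr::count(.data$arm, .data$day, .drop = FALSE)
  empty <- filter(cells, .data$n == 0)
  if (nrow(empty) > 0) {
    abort(sprintf("Empty (arm, day) cell(s): %s",
                  paste(sprintf("(%s, %s)", empty$arm, empty$day),
                        collapse = ", ")))
  }
  if (any(cells$n < 2)) {
    abort("Need >= 2 animals per (arm, day) cell.")
  }
  if (length(unique(cells$n)) > 1) {
    abort(paste("Unbalanced design: unequal cell sizes. Censoring truncates",
                "animals at different days; analyse the common uncensored",
                "window or pre-balance the records."))
  }
  fit <- aov(volume ~ arm * day, data = records)
  s <- summary(fit)[[1]]
  out <- tibble(
    term = trimws(rownames(s)),
    df = s$Df, sumsq = s$`Sum Sq`, meansq = s$`Mean Sq`,
    statistic = s$`F value`, p.value = s$`Pr(>F)`
  ) |>
    mutate(term = dplyr::recode(.data$term, arm = "treatment",
                                `arm:day` = "treatment:day"))
  attr(out, "model") <- fit
  class(out) <- c("growth_anova", class(out))
  out
}

#' Per-arm, per-day growth summary
#'
#' @param records Growth tibble.
#' @return Tibble: arm, day, n, mean_volume, sd_volume.
#' @export
growth_summary <- function(records) {
  ensure_volume(records) |>
    group_by(.data$arm, .data$day) |>
    summarise(n = n(), mean_volume = mean(.data$volume),
              sd_volume = sd(.data$volume), .groups = "drop")
}
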