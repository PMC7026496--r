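#' Ground truth for a simulated PDX efficacy study
#'
#' @param arms Named list; each arm is `list(n_animals, growth_rate,
#'   treatment_multiplier)`. `growth_rate` is the exponential rate per day
#'   of the untreated tumor; the multiplier scales it in that arm (1 =
#'   no effect).
#' @param enrollment_volume_range Enrollment volume (mm^3) range; animals
#'   start at a uniform draw within it (the conventional 100-150 mm^3
#'   randomization window by default).
#' @param schedule Measurement days (strictly increasing, day 0 =
#'   enrollment); default three measurements a week to day 18.
#' @param measurement_cv CV of multiplicative lognormal caliper noise.
#' @param censor_volume Volume at which an animal leaves the study (its
#'   crossing measurement is kept, later ones dropped).
#' @param seed Integer seed.
#' @return Object of class `growth_truth`.
#' @export
growth_truth <- function(arms = list(
                           vehicle = list(n_animals = 5L, growth_rate = 0.12,
                                          treatment_multiplier = 1),
                           treated = list(n_animals = 5L, growth_rate = 0.12,
                                          treatment_multiplier = 0.3)
                         ),
                         enrollment_volume_range = c(100, 150),
                         schedule = c(0, 2, 4, 7, 9, 11, 14, 16, 18),
                         measurement_cv = 0.1,
                         censor_volume = 1500,
                         seed = 1L) {
  if (length(schedule) == 0) abort("`schedule` must be non-empty.")
  if (any(diff(schedule) <= 0)) abort("`schedule` must be strictly increasing.")
  stopifnot(length(enrollment_volume_range) == 2,
            enrollment_volume_range[1] > 0,
            enrollment_volume_range[2] >= enrollment_volume_range[1],
            enrollment_volume_range[2] < censor_volume)
  for (a in arms) {
    stopifnot(a$n_animals >= 1, a$growth_rate > 0)
  }
  check_scalar_number(measurement_cv, "measurement_cv", lower = 0)
  structure(
    list(arms = arms, enrollment_volume_range = enrollment_volume_range,
         schedule = schedule, measurement_cv = measurement_cv,
         censor_volume = censor_volume, seed = as.integer(seed)),
    class = "growth_truth"
  )
}

#' Simulate caliper growth curves for a PDX treatment study
#'
#' Underlying volumes follow `V(t) = V0 * exp(growth_rate *
#' treatment_multiplier * t)`. Measured volumes are jittered by
#' multiplicative lognormal noise, then calipers are back-solved under the
#' fixed aspect ratio length = 2 x width (so `V = length x width^2 / 2 =
#' width^3`). Per animal, measurements strictly after the first crossing of
#' the censor volume are not recorded.
#'
#' @param truth A [growth_truth()].
#' @return List with `measurements` (tibble: animal, arm, day, length_mm,
#'   width_mm) and `truth`.
#' @export
simulate_growth <- function(truth) {
  stopifnot(inherits(truth, "growth_truth"))
  with_seed(truth$seed, {
    rows <- imap(truth$arms, function(a, arm) {
      map(seq_len(a$n_animals), function(i) {
        v0 <- runif(1, truth$enrollment_volume_range[1],
                    truth$enrollment_volume_range[2])
        rate <- a$growth_rate * a$treatment_multiplier
        v_true <- v0 * exp(rate * truth$schedule)
        v_meas <- v_true * rlnorm_cv(length(v_true), truth$measurement_cv)
        crossed <- which(v_meas >= truth$censor_volume)
        keep <- if (length(crossed) == 0) {
          seq_along(v_meas)
        } else {
          seq_len(crossed[1])
        }
        width <- v_meas[keep]^(1 / 3)
        tibble(
          animal = sprintf("%s_%02d", arm, i),
          arm = arm,
          day = truth$schedule[keep],
          length_mm = 2 * width,
          width_mm = width
        )
      }) |> list_rbind()
    }) |> list_rbind()
    list(measurements = rows, truth = truth)
  })
}
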