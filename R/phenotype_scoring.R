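#' Overall musical-aptitude composite
#'
#' Standardizes the pitch (0-27), melody (0-18) and rhythm (0-18)
#' discrimination subtest scores across samples and returns the mean of the
#' three z-scores. Missingness propagates: a sample missing any subtest gets
#' a missing composite, never a silent zero.
#'
#' @param scores Data frame with columns `pitch`, `melody`, `rhythm` (and
#'   optionally `sample_id`, passed through).
#' @return Numeric vector of composites, or a data frame with `sample_id`
#'   and `aptitude` when `sample_id` is present.
#' @export
aptitude_composite <- function(scores) {
  needed <- c("pitch", "melody", "rhythm")
  if (!all(needed %in% names(scores))) {
    stop("scores must have columns pitch, melody, rhythm")
  }
  if (nrow(scores) < 2) stop("need at least 2 samples")
  zs <- sapply(needed, function(nm) {
    x <- scores[[nm]]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) stop("zero-variance subtest: ", nm)
    (x - mean(x, na.rm = TRUE)) / s
  })
  comp <- rowMeans(zs)  # na.rm = FALSE: missing item -> missing composite
  if ("sample_id" %in% names(scores)) {
    return(data.frame(sample_id = scores$sample_id, aptitude = comp,
                      stringsAsFactors = FALSE))
  }
  comp
}

## coefficient of variation of one trial's self-paced intervals
trial_cv <- function(intervals) {
  intervals <- intervals[!is.na(intervals)]
  if (length(intervals) < 3) stop("each trial needs at least 3 intervals")
  m <- mean(intervals)
  if (m <= 0) stop("non-positive mean inter-tap interval")
  stats::sd(intervals) / m
}

#' Motor-timing score from tapping trials
#'
#' Per trial, the coefficient of variation (SD/mean) of the self-paced
#' inter-tap intervals; the score is the negated mean CV across trials, so
#' higher = more regular tapping, with 0 the ceiling attained by perfectly
#' isochronous taps.
#'
#' @param trials A list of numeric vectors (one vector of intervals per
#'   trial) for a single subject.
#' @return Scalar score (<= 0).
#' @export
isip_score <- function(trials) {
  if (!is.list(trials)) trials <- list(trials)
  if (!length(trials)) stop("need at least 1 trial")
  -mean(vapply(trials, trial_cv, numeric(1)))
}

#' Motor-timing scores for a long-format trial table
#'
#' @param isip Data frame with columns `sample_id`, `trial`, `interval`
#'   (self-paced phase only).
#' @return Data frame `sample_id`, `motor_timing`.
#' @export
isip_scores <- function(isip) {
  stopifnot(all(c("sample_id", "trial", "interval") %in% names(isip)))
  by_sample <- split(isip, isip$sample_id)
  data.frame(sample_id = names(by_sample),
             motor_timing = vapply(by_sample, function(d) {
               isip_score(split(d$interval, d$trial))
             }, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Global flow proneness
#'
#' Arithmetic mean of the work, leisure and maintenance flow subscale means
#' (the music subscale is analyzed separately). Vectorized; a missing
#' subscale yields a missing output with a warning.
#'
#' @param work,leisure,maintenance Subscale means.
#' @return Numeric vector of global flow scores.
#' @export
global_flow <- function(work, leisure, maintenance) {
  out <- (work + leisure + maintenance) / 3
  if (anyNA(out)) warning(sum(is.na(out)), " global flow value(s) missing")
  out
}

#' Default weekly-practice category midpoints
#'
#' Midpoint hours/week for the ten response categories ("0 h" up to "more
#' than 40 h"). The instrument does not define numeric midpoints, so this
#' table is a declared, configurable approximation.
#' @export
practice_midpoints_default <- c(0, 0.5, 1.5, 3.5, 5.5, 7.5, 11, 17.5, 30, 45)

#' Lifetime music-practice estimate
#'
#' Total practice hours accumulated over the playing career: for each of the
#' four age intervals (0-5, 6-11, 12-17, 18+ up to the age at measurement),
#' the category's midpoint hours/week times 52 weeks times the years of
#' overlap between the playing span `[start_age, end_age]` (inclusive years)
#' and the interval. Category 1 ("0 h") contributes nothing; someone who
#' never played scores 0.
#'
#' @param start_age,end_age First and last age of playing (inclusive);
#'   `NA` start age means never played.
#' @param categories Matrix or data frame (subjects x 4) of category levels
#'   `1..10`, one column per age interval.
#' @param age_at_measurement Age when surveyed.
#' @param midpoints Hours/week per category
#'   (default [practice_midpoints_default]).
#' @return Numeric vector of lifetime practice hours; missing inputs
#'   propagate.
#' @export
lifetime_practice <- function(start_age, end_age, categories,
                              age_at_measurement,
                              midpoints = practice_midpoints_default) {
  categories <- as.matrix(categories)
  n <- length(start_age)
  stopifnot(length(end_age) == n, nrow(categories) == n,
            length(age_at_measurement) == n, ncol(categories) == 4)
  played <- !is.na(start_age)
  bad <- played & (!is.na(end_age)) &
    (start_age > end_age | end_age > age_at_measurement)
  if (any(bad, na.rm = TRUE)) {
    stop("inconsistent ages: need start_age <= end_age <= age_at_measurement")
  }
  lo <- c(0, 6, 12, 18)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (!played[i]) { out[i] <- 0; next }
    if (is.na(end_age[i]) || anyNA(categories[i, ]) ||
        is.na(age_at_measurement[i])) { out[i] <- NA_real_; next }
    hi <- c(6, 12, 18, age_at_measurement[i] + 1)
    total <- 0
    for (b in 1:4) {
      years <- max(0, min(end_age[i] + 1, hi[b]) - max(start_age[i], lo[b]))
      total <- total + midpoints[categories[i, b]] * 52 * years
    }
    out[i] <- total
  }
  out
}
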