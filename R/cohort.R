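#' Scan schedule configuration for the synthetic cohort
#'
#' Defaults reproduce the sampling structure of the emulated longitudinal
#' fetal MRI study: 162 fetuses (81 male, 81 female) contributing 268 scans,
#' with 88/42/32 fetuses having one/two/three scans (41/22/18 male,
#' 47/20/14 female), ages spanning 18.0-36.8 gestational weeks and repeat
#' scans separated by 4-6 weeks.
#'
#' @param n_male,n_female Integer vectors of per-sex counts of subjects with
#'   1, 2 and 3 scans.
#' @param age_range Gestational-week range for scans.
#' @param gap_range Range of the revisit interval between consecutive scans,
#'   in weeks.
#' @return A `cohort_schedule` list.
#' @export
#' @examples
#' sched <- cohort_schedule()
#' sum((1:3) * (sched$n_male + sched$n_female))  # 268 scans
cohort_schedule <- function(n_male = c(41, 22, 18),
                            n_female = c(47, 20, 14),
                            age_range = c(18.0, 36.8),
                            gap_range = c(4.0, 6.0)) {
  if (length(n_male) != 3 || length(n_female) != 3 ||
      any(n_male < 0) || any(n_female < 0)) {
    stop("per-sex scan-count vectors must be 3 non-negative integers.",
         call. = FALSE)
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop("`age_range` must be an increasing pair of weeks.", call. = FALSE)
  }
  if (length(gap_range) != 2 || gap_range[1] > gap_range[2] ||
      gap_range[1] <= 0) {
    stop("`gap_range` must be a positive, non-decreasing pair.", call. = FALSE)
  }
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 age_range = age_range, gap_range = gap_range),
            class = "cohort_schedule")
}

#' Generate a synthetic cohort of subjects and scan records
#'
#' Subjects are assigned 1-3 scans per the schedule. A subject's first scan
#' age is uniform on `[min_age, max_age - mean_gap * (n_scans - 1)]` so
#' later scans with uniform 4-6-week gaps stay in range; a later scan
#' falling past the maximum age is truncated to it (the preceding gap then
#' stays within the allowed range by construction of the first-scan window).
#'
#' @param schedule A [cohort_schedule()].
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return A list with tibbles `subjects` (subject_id, sex, n_scans) and
#'   `scans` (scan_id, subject_id, sex, scan_index, gest_week).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_schedule(), seed = 1)
#' nrow(coh$scans)  # 268
generate_cohort <- function(schedule = cohort_schedule(), seed) {
  stopifnot(inherits(schedule, "cohort_schedule"))
  counts <- tibble::tibble(
    sex = rep(c("M", "F"), each = 3),
    n_scans = rep(1:3, 2),
    n_subjects = c(schedule$n_male, schedule$n_female)
  )
  subjects <- counts |>
    tidyr::uncount(.data$n_subjects) |>
    dplyr::arrange(dplyr::desc(.data$sex), .data$n_scans) |>
    dplyr::mutate(subject_id = sprintf("S%03d", dplyr::row_number()),
                  sex = sex_factor(.data$sex)) |>
    dplyr::select("subject_id", "sex", "n_scans")

  if (nrow(subjects) == 0) {
    scans <- tibble::tibble(scan_id = character(), subject_id = character(),
                            sex = sex_factor(character()),
                            scan_index = integer(), gest_week = numeric())
    return(list(subjects = subjects, scans = scans))
  }

  amin <- schedule$age_range[1]
  amax <- schedule$age_range[2]
  mean_gap <- mean(schedule$gap_range)

  scans <- with_seed(seed, {
    purrr::pmap_dfr(subjects, function(subject_id, sex, n_scans) {
      first_max <- amax - mean_gap * (n_scans - 1)
      ages <- runif(1, amin, first_max)
      if (n_scans > 1) {
        gaps <- runif(n_scans - 1, schedule$gap_range[1], schedule$gap_range[2])
        for (g in gaps) ages <- c(ages, min(ages[length(ages)] + g, amax))
      }
      tibble::tibble(subject_id = subject_id, sex = sex,
                     scan_index = seq_len(n_scans),
                     gest_week = ages)
    })
  })
  scans <- scans |>
    dplyr::mutate(scan_id = sprintf("%s_T%d", .data$subject_id, .data$scan_index),
                  .before = 1)
  list(subjects = subjects, scans = scans)
}
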