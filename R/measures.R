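# Synthetic measure generation: multiplicative log-normal growth with
# subject random effects, exact sum composition, softmax lobe shares and
# left/right asymmetric variants.

REFERENCE_WEEK <- 27.0

# Polynomial trajectory on centred weeks.
poly_traj <- function(cw, g1, g2, g3, g4) {
  g1 * cw + g2 * cw^2 + g3 * cw^3 + g4 * cw^4
}

#' Generate a synthetic long-format measure table
#'
#' For every region in `spec`, draws
#' `log Q = baseline + growth(W - 27) + delta * male + interaction * (W-27) * male
#'  + u_subject + eps` and exponentiates, so all values are strictly
#' positive and growth is multiplicative (heteroscedastic in the raw
#' domain, homoscedastic in the log domain). Composite measures are then
#' built as exact sums: `ICV = CORT + WM + DGM + CEREB + VENT + SCSF` and
#' `TBV = CORT + WM + DGM + CEREB` (when the components are present).
#' Lobe decompositions (softmax shares summing exactly to the parent) and
#' left/right asymmetric variants are generated when specs are supplied.
#'
#' @param cohort Output of [generate_cohort()], or a scans tibble with
#'   columns scan_id, subject_id, sex, gest_week.
#' @param spec Effect-specification tibble, e.g. [default_effect_spec()].
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param lobes Optional list of [lobe_spec()]s.
#' @param asymmetry Optional list of [asymmetry_spec()]s.
#' @param compose If `TRUE`, add ICV/TBV sum rows when components exist.
#' @return A tibble with columns scan_id, subject_id, sex, gest_week,
#'   region, measure_kind, value.
#' @export
#' @examples
#' coh <- generate_cohort(seed = 1)
#' tab <- generate_measures(coh, default_effect_spec(), seed = 2)
#' dplyr::count(tab, region)
generate_measures <- function(cohort, spec, seed, lobes = NULL,
                              asymmetry = NULL, compose = TRUE) {
  scans <- if (is.list(cohort) && !is.data.frame(cohort)) cohort$scans else cohort
  stopifnot(all(c("scan_id", "subject_id", "sex", "gest_week") %in% names(scans)))
  if (any(spec$subject_sd < 0) || any(spec$residual_sd < 0)) {
    stop("variance components must be non-negative.", call. = FALSE)
  }
  if (nrow(scans) == 0) {
    return(tibble::tibble(scan_id = character(), subject_id = character(),
                          sex = sex_factor(character()), gest_week = numeric(),
                          region = character(), measure_kind = character(),
                          value = numeric()))
  }
  scans <- dplyr::mutate(scans, sex = sex_factor(.data$sex))
  subjects <- unique(scans$subject_id)
  cw <- scans$gest_week - REFERENCE_WEEK
  male <- as.numeric(scans$sex == "M")

  with_seed(seed, {
    direct <- purrr::pmap_dfr(spec, function(region, measure_kind, baseline_log,
                                             growth1, growth2, growth3, growth4,
                                             sex_log_effect, sex_age_interaction,
                                             subject_sd, residual_sd) {
      u <- setNames(rnorm(length(subjects), 0, subject_sd), subjects)
      logq <- baseline_log +
        poly_traj(cw, growth1, growth2, growth3, growth4) +
        sex_log_effect * male + sex_age_interaction * cw * male +
        u[scans$subject_id] + rnorm(nrow(scans), 0, residual_sd)
      dplyr::mutate(scans[c("scan_id", "subject_id", "sex", "gest_week")],
                    region = region, measure_kind = measure_kind,
                    value = exp(unname(logq)))
    })

    out <- direct
    if (!is.null(lobes)) {
      lobe_rows <- purrr::map_dfr(lobes, function(ls) {
        parent_rows <- dplyr::filter(out, .data$region == ls$parent)
        if (nrow(parent_rows) == 0) {
          stop("lobe spec parent region not generated: ", ls$parent,
               call. = FALSE)
        }
        k <- length(ls$lobes)
        us <- matrix(rnorm(length(subjects) * k, 0, ls$logit_subject_sd),
                     length(subjects), k, dimnames = list(subjects, NULL))
        logits <- vapply(seq_len(k), function(j) {
          log(ls$base_share[j]) +
            poly_traj(cw, ls$logit_growth[j, 1], ls$logit_growth[j, 2],
                      ls$logit_growth[j, 3], ls$logit_growth[j, 4]) +
            ls$sex_logit_offset[j] * male +
            us[scans$subject_id, j] +
            rnorm(nrow(scans), 0, ls$logit_residual_sd)
        }, numeric(nrow(scans)))
        shares <- exp(logits) / rowSums(exp(logits))
        dimnames(shares) <- NULL
        purrr::map_dfr(seq_len(k), function(j) {
          dplyr::mutate(parent_rows,
                        region = paste0(ls$lobes[j], "_", ls$parent),
                        value = .data$value * shares[, j])
        })
      })
      out <- dplyr::bind_rows(out, lobe_rows)
    }

    if (!is.null(asymmetry)) {
      asym_rows <- purrr::map_dfr(asymmetry, function(as) {
        parent_rows <- dplyr::filter(out, .data$region == as$region)
        if (nrow(parent_rows) == 0) {
          stop("asymmetry spec region not generated: ", as$region,
               call. = FALSE)
        }
        m <- as.numeric(parent_rows$sex == "M")
        eta_l <- rnorm(nrow(parent_rows), 0, as$hemi_sd)
        eta_r <- rnorm(nrow(parent_rows), 0, as$hemi_sd)
        dplyr::bind_rows(
          dplyr::mutate(parent_rows,
                        region = paste0(.data$region, "_left"),
                        value = .data$value / 2 *
                          exp(-as$offset / 2 * m + eta_l)),
          dplyr::mutate(parent_rows,
                        region = paste0(.data$region, "_right"),
                        value = .data$value / 2 *
                          exp(as$offset / 2 * m + eta_r))
        )
      })
      out <- dplyr::bind_rows(out, asym_rows)
    }

    if (compose) {
      out <- dplyr::bind_rows(out,
                              compose_sum(out, "TBV", c("CORT", "WM", "DGM", "CEREB")),
                              compose_sum(out, "ICV", c("CORT", "WM", "DGM", "CEREB",
                                                        "VENT", "SCSF")))
    }
    dplyr::arrange(out, .data$scan_id, .data$region)
  })
}

# Exact per-scan sum of component regions; NULL if any component missing.
compose_sum <- function(table, name, components) {
  present <- intersect(components, unique(table$region))
  if (length(present) < length(components)) return(NULL)
  table |>
    dplyr::filter(.data$region %in% components) |>
    dplyr::summarise(value = sum(.data$value),
                     .by = c("scan_id", "subject_id", "sex", "gest_week")) |>
    dplyr::mutate(region = name, measure_kind = "volume_mm3")
}

#' Read or write a long-format measure table as CSV
#'
#' The CSV carries the canonical header
#' `subject_id, sex, gest_week, region, measure_kind, value` with sex coded
#' F/M. `read_measures()` reconstructs a per-scan id from subject and week.
#'
#' @param table A measure tibble as produced by [generate_measures()].
#' @param path File path.
#' @return `read_measures()` returns the measure tibble.
#' @export
write_measures <- function(table, path) {
  out <- table[c("subject_id", "sex", "gest_week", "region",
                 "measure_kind", "value")]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measures
#' @export
read_measures <- function(path) {
  raw <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("subject_id", "sex", "gest_week", "region",
                  "measure_kind", "value") %in% names(raw)))
  raw |>
    dplyr::mutate(sex = sex_factor(.data$sex)) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(scan_id = sprintf("%s_T%d", .data$subject_id,
                                    match(.data$gest_week,
                                          sort(unique(.data$gest_week))))) |>
    dplyr::ungroup() |>
    dplyr::relocate("scan_id")
}
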