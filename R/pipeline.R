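#' Full morphometry + texture of one stack
#'
#' Segments the nucleus and reports morphometry (volume, thickness, area,
#' shape factor) together with the texture metrics (altitude peak counts,
#' lateral bumpiness, surface roughness) as one tibble row.
#'
#' @param stack An [image_stack()].
#' @param ... Passed to [segment_nucleus()].
#' @return One-row tibble.
#' @export
run_morphometry <- function(stack, ...) {
  mask <- segment_nucleus(stack, ...)
  ps <- project_area_shape(mask)
  dplyr::bind_cols(
    tibble::tibble(volume = measure_volume(mask),
                   thickness = unname(measure_thickness(mask)),
                   area = ps$area, shape_factor = ps$shape_factor,
                   threshold_sensitivity = attr(mask, "threshold_sensitivity")),
    nuclear_texture(mask))
}

#' Phantom stretch study
#'
#' Generates replicate nucleus phantoms for named conditions (e.g. smooth
#' vs. lobed vs. flattened, standing in for wild-type, lamin-deficient and
#' stretched cells), runs the full morphometry + texture pipeline on each,
#' and summarizes mean and standard error per condition.
#'
#' @param conditions Named list of [nucleus_phantom_spec()]s (the `seed`
#'   field of each spec is re-derived per replicate from `seed`).
#' @param n_per_condition Replicates per condition.
#' @param seed Integer seed; replicate seeds are derived deterministically.
#' @return List with `cells` (per-phantom tibble) and `summary`
#'   (per-condition mean +/- SEM of volume, thickness, bumpiness,
#'   roughness; SEM is 0 for n = 1).
#' @export
stretch_study <- function(conditions, n_per_condition = 3L, seed = 1L) {
  check_that(is.list(conditions) && length(conditions) >= 1 &&
               !is.null(names(conditions)) && all(nzchar(names(conditions))),
             "conditions", "must be a named list of nucleus_phantom_spec")
  cells <- purrr::imap_dfr(conditions, function(spec, cond) {
    check_that(inherits(spec, "nucleus_phantom_spec"),
               sprintf("conditions$%s", cond), "must be a nucleus_phantom_spec")
    purrr::map_dfr(seq_len(n_per_condition), function(r) {
      sp <- spec
      sp$seed <- as.integer((seed * 1000L + match(cond, names(conditions)) * 100L + r) %% .Machine$integer.max)
      st <- make_nucleus_stack(sp)
      dplyr::bind_cols(tibble::tibble(condition = cond, replicate = r),
                       run_morphometry(st))
    })
  })
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  summary <- cells |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(c("volume", "thickness", "bumpiness", "roughness"),
                                   list(mean = mean, sem = sem),
                                   .names = "{.col}_{.fn}"),
                     n = dplyr::n(), .groups = "drop")
  list(cells = cells, summary = summary)
}
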