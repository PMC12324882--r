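# End-to-end orchestration: per-case descriptor extraction and the
# multi-case statistical study.

#' Extract all per-segment descriptors for one case
#'
#' Runs the full post-processing chain on one case: (optional) numerical
#' vorticity reconstruction, bulk helicity descriptors per volume segment,
#' wall shear descriptors with adverse-exposure fractions per wall segment,
#' and (optional) centerline geometry. Deterministic given its inputs.
#'
#' @param field Flow-field tibble (cell, time, x, y, z, volume, segment,
#'   vx, vy, vz and optionally wx, wy, wz). A `swirl_phantom` may be passed
#'   directly, in which case `wall` and `neighbors` default to its own.
#' @param wall Long wall-series tibble (element, time, taux, tauy, tauz,
#'   area, segment).
#' @param centerline Optional [centerline()] tibble (or list of them) for
#'   geometric descriptors.
#' @param neighbors Neighbour pairs for [add_vorticity()] when the field
#'   carries no vorticity columns.
#' @param thresholds An [adverse_thresholds()] set.
#' @param case_id Case identifier written into the output rows.
#' @param verbose Log the effective parameters to stderr.
#' @return A tidy segment table: tibble (case, segment, descriptor, value).
#' @export
run_case <- function(field, wall = NULL, centerline = NULL, neighbors = NULL,
                     thresholds = adverse_thresholds(), case_id = "case",
                     verbose = FALSE) {
  if (inherits(field, "swirl_phantom")) {
    ph <- field
    field <- ph$field
    wall <- wall %||% ph$wall
    neighbors <- neighbors %||% ph$mesh$neighbors
  }
  if (is.null(wall)) abort("`wall` series is required.")
  nt_f <- dplyr::n_distinct(field$time)
  nt_w <- dplyr::n_distinct(wall$time)
  if (nt_f > 1L && nt_w > 1L) {
    Tf <- max(field$time) - min(field$time)
    Tw <- max(wall$time) - min(wall$time)
    if (abs(Tf - Tw) > 1e-9 * max(Tf, Tw)) {
      abort(sprintf(
        "cycle period mismatch: volume series spans %g s, wall series %g s.",
        Tf, Tw))
    }
  }
  if (!all(c("wx", "wy", "wz") %in% names(field))) {
    if (is.null(neighbors)) {
      abort("field has no vorticity and no `neighbors` were supplied.")
    }
    field <- add_vorticity(field, neighbors)
  }
  if (verbose) {
    message(sprintf(
      "[%s] thresholds: lowTAESS<%g Pa, highTAESS>%g Pa, OSI>%g, RRT>%g 1/Pa",
      case_id, thresholds$low_taess, thresholds$high_taess,
      thresholds$high_osi, thresholds$high_rrt))
  }

  hel <- field |>
    helicity_density() |>
    (\(hd) purrr::map_dfr(unique(hd$segment), function(s) {
      bulk_descriptors(hd, segment = s) |> mutate(segment = s)
    }))() |>
    select("segment", h1 = "h1", h2 = "h2", h3 = "h3", h4 = "h4") |>
    tidyr::pivot_longer(-"segment", names_to = "descriptor",
                        values_to = "value")

  wd <- wall_descriptors(wall)
  ws <- dplyr::inner_join(segment_mean_taess(wd),
                          adverse_area_fractions(wd, thresholds),
                          by = "segment") |>
    select("segment", "taess_avg", "low_taess_pct", "high_taess_pct",
           "osi_pct", "rrt_pct") |>
    tidyr::pivot_longer(-"segment", names_to = "descriptor",
                        values_to = "value")

  geo <- NULL
  if (!is.null(centerline)) {
    cls <- if (is_tibble(centerline)) list(centerline) else centerline
    geo <- purrr::map_dfr(cls, geometry_descriptors) |>
      select(segment = "label", curvature = "curvature",
             torsion = "torsion", diameter = "mean_diameter") |>
      tidyr::pivot_longer(-"segment", names_to = "descriptor",
                          values_to = "value")
  }

  bind_rows(hel, ws, geo) |>
    mutate(case = case_id) |>
    select("case", "segment", "descriptor", "value")
}

#' Run the multi-case study workflow
#'
#' Aggregates per-case segment tables, attaches group labels and executes
#' the contrast plan (group comparisons and Spearman correlations with Holm
#' adjustment per family). With a single group the comparisons are skipped
#' and only correlations run.
#'
#' @param tables A list of per-case segment tables from [run_case()], or one
#'   combined tidy table with a `case` column.
#' @param groups Named character vector mapping case ids to group labels
#'   (e.g. `c(case_001 = "non_stenosed", ...)`); ignored if the table already
#'   has a `group` column.
#' @param plan Contrast plan; defaults to [default_contrast_plan()] on the
#'   combined table.
#' @param correlate_with Passed to [default_contrast_plan()].
#' @param min_per_group Minimum cases per group for comparisons.
#' @return A list of class `coro_study`: `table` (combined segment table)
#'   and `results` (a `coro_contrasts` tibble).
#' @export
run_study <- function(tables, groups = NULL, plan = NULL,
                      correlate_with = "h2", min_per_group = 3L) {
  tbl <- if (is.data.frame(tables)) as_tibble(tables) else bind_rows(tables)
  if (!"group" %in% names(tbl)) {
    if (is.null(groups)) abort("supply `groups` or a `group` column.")
    tbl$group <- unname(groups[tbl$case])
    if (any(is.na(tbl$group))) abort("every case needs a group label.")
  }
  glv <- unique(tbl$group)
  if (length(glv) > 2L) abort("at most two groups are supported.")
  two_groups <- length(glv) == 2L
  if (two_groups) {
    n_cases <- tbl |> distinct(.data$case, .data$group) |>
      dplyr::count(.data$group)
    if (any(n_cases$n < min_per_group)) {
      abort(sprintf("each group needs at least %d cases.", min_per_group))
    }
  }
  if (is.null(plan)) {
    plan <- default_contrast_plan(tbl, correlate_with = correlate_with)
    if (!two_groups) plan <- filter(plan, .data$type != "group")
  }
  results <- run_contrast_matrix(tbl, plan,
                                 groups = if (two_groups) sort(glv) else glv)
  structure(list(table = tbl, results = results), class = "coro_study")
}

#' @export
print.coro_study <- function(x, ...) {
  cat(sprintf(
    "<coro_study> %d cases, %d segments, %d contrasts (%d significant)\n",
    dplyr::n_distinct(x$table$case), dplyr::n_distinct(x$table$segment),
    nrow(x$results), sum(x$results$significant, na.rm = TRUE)))
  invisible(x)
}
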