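#' Radius-corrected internalization score
#'
#' The event-level feature separating membrane-bound from internalized
#' particles: the distance `d` between the cell and particle centroids,
#' corrected for the cell radius `R` as a measure of cell size.  The default
#' form is the dimensionless ratio `s = R / max(d, eps)` with `eps` one pixel
#' in micrometres: a particle centred on the membrane gives `s = 1`, halfway
#' to the centre gives `s = 2` (the classification boundary), and coincident
#' centroids give the large finite ceiling `R / eps`.  The alternative depth
#' reading `s = R - d` (um) is available via `formula = "depth"`.
#'
#' `s` is monotonically non-increasing in `d` and, for the ratio form,
#' invariant under a common rescaling of `R` and `d`.
#'
#' @param R cell radius, um (> 0).
#' @param d centroid distance, um (>= 0).  Vectorized over `R` and `d`.
#' @param eps distance floor in um; by convention one pixel.
#' @param formula `"ratio"` (default) or `"depth"`.
#' @return numeric score(s).
#' @examples
#' internalization_score(R = 3.5, d = 3.5, eps = 0.33)  # on the membrane: 1
#' internalization_score(R = 3.5, d = 1.75, eps = 0.33) # boundary value: 2
#' @export
internalization_score <- function(R, d, eps = 0.33,
                                  formula = c("ratio", "depth")) {
  formula <- match.arg(formula)
  if (any(!is.finite(R)) || any(R <= 0)) abort("`R` must be finite and > 0.")
  if (any(is.na(d))) abort("score undefined without particle: `d` is missing.")
  if (any(d < 0)) abort("`d` must be >= 0.")
  switch(formula, ratio = R / pmax(d, eps), depth = R - d)
}

#' Classify one event from its score and focus gate
#'
#' Gate precedence: an unfocused event is `excluded_unfocused` regardless of
#' any score; an event without a detected particle is `no_particle`; a scored
#' event is `internalized` when `s >= tau` (the stated cutoff reads
#' "similar to or >2", taken as >= 2) and `bound` otherwise.
#'
#' @param score numeric score or `NA` when no particle was detected.
#' @param focused logical, focus-gate result.
#' @param tau internalization threshold (> 0, default 2).
#' @return one of `"excluded_unfocused"`, `"no_particle"`, `"bound"`,
#'   `"internalized"`.
#' @export
classify_event <- function(score, focused, tau = 2) {
  if (tau <= 0) abort("`tau` must be > 0.")
  dplyr::case_when(
    !focused ~ "excluded_unfocused",
    is.na(score) ~ "no_particle",
    score >= tau ~ "internalized",
    .default = "bound"
  )
}

#' Score every event of a cohort
#'
#' Runs segmentation, the focus gate, the internalization score and the
#' classifier over an event tibble, returning one feature row per event.
#'
#' @param events tibble with columns `event_id` and `image` (list of
#'   [event_image]), e.g. from [generate_cohort()] or [read_events()].
#' @param tau internalization threshold (default 2).
#' @param eps score distance floor in um; default one pixel of the first
#'   event.
#' @param formula score form, see [internalization_score()].
#' @param cutoffs focus-gate cutoffs, see [focus_gate()].
#' @return the input tibble (minus `image`) with columns `R_um`, `d_um`,
#'   `score`, `focus_cell`, `focus_particle`, `focus_pass`, `label_pred`.
#' @examples
#' cohort <- generate_cohort(6, c(0, 0.5, 0.5, 0), noise_sd = 0, seed = 3)
#' score_events(cohort)[, c("label", "score", "label_pred")]
#' @export
score_events <- function(events, tau = 2, eps = NULL,
                         formula = c("ratio", "depth"),
                         cutoffs = focus_cutoff_defaults()) {
  stopifnot(is.data.frame(events), all(c("event_id", "image") %in% names(events)))
  formula <- match.arg(formula)
  eps <- eps %||% events$image[[1]]$pixel_size

  feats <- purrr::map(events$image, function(img) {
    cell <- segment_cell(img)
    part <- segment_particle(img)
    gate <- focus_gate(img, cell, part, cutoffs = cutoffs)
    d <- if (is.null(part)) NA_real_ else euclid(cell$centroid_um, part$centroid_um)
    s <- if (is.na(d)) NA_real_ else
      internalization_score(cell$radius_um, d, eps = eps, formula = formula)
    tibble(
      R_um = cell$radius_um, d_um = d, score = s,
      focus_cell = gate$focus_cell, focus_particle = gate$focus_particle,
      focus_pass = gate$pass,
      label_pred = classify_event(s, gate$pass, tau = tau)
    )
  })
  dplyr::bind_cols(events[setdiff(names(events), "image")],
                   dplyr::bind_rows(feats))
}

#' Cohort gating summary
#'
#' Collapses per-event classifications into the gating chain and the two
#' headline percentages: the proportion of focused cells interacting with a
#' particle, and the proportion of internalization among particle-positive
#' cells.  `pct_internalized` is `NA` (undefined, not zero) when no event is
#' particle-positive.
#'
#' @param classified a scored tibble with a `label_pred` column (from
#'   [score_events()]), or a character vector of labels.
#' @return one-row tibble: `n_total`, `n_focused`, `n_particle_positive`,
#'   `n_internalized`, `pct_interacting`, `pct_internalized`.
#' @export
summarize_cohort <- function(classified) {
  labels <- if (is.data.frame(classified)) classified$label_pred else classified
  if (length(labels) == 0) abort("empty input: no events to summarize.")
  known <- c("excluded_unfocused", "no_particle", "bound", "internalized")
  if (!all(labels %in% known)) abort("unknown classification label.")
  n_total <- length(labels)
  n_focused <- sum(labels != "excluded_unfocused")
  n_pp <- sum(labels %in% c("bound", "internalized"))
  n_int <- sum(labels == "internalized")
  tibble(
    n_total = n_total, n_focused = n_focused,
    n_particle_positive = n_pp, n_internalized = n_int,
    pct_interacting = if (n_focused > 0) 100 * n_pp / n_focused else NA_real_,
    pct_internalized = if (n_pp > 0) 100 * n_int / n_pp else NA_real_
  )
}

#' Area under an internalization time course
#'
#' Trapezoidal integral of percent internalization over time, the scalar
#' used to compare uptake kinetics between conditions.
#'
#' @param times time points in minutes, strictly increasing, length >= 2.
#' @param values percent internalized at each time point.
#' @return AUC in percent-minutes.
#' @examples
#' auc_time_course(c(5, 10, 20, 30), c(10, 20, 40, 40))
#' @export
auc_time_course <- function(times, values) {
  if (length(times) < 2 || length(times) != length(values)) {
    abort("need >= 2 time points with matching values.")
  }
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}
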