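#' Extract the symbolic itinerary of a trajectory
#'
#' A cell is *active* while its activation level `phi(y_j)` (or `J_j`) is
#' high. Activity is detected with per-cell hysteresis: a cell joins the
#' active set when its level rises through `on_level` and leaves when it
#' falls through `off_level`, which prevents chatter during the fast
#' switching between states. An event is recorded at every change of the
#' active set.
#'
#' @param traj An `exna_trajectory` (`y`- or `J`-coordinates).
#' @param spec An `exna_activation`; required for `y`-coordinates.
#' @param on_level,off_level Hysteresis levels, `off_level < on_level`
#'   (defaults 0.8 / 0.2).
#' @return An `exna_itinerary`: a tibble with columns `time`, `active`
#'   (list column of integer vectors) and `label` (e.g. `"{1}"`,
#'   `"{3,4}"`), one row per event. The active set at the first sample is
#'   always recorded.
#' @export
itinerary <- function(traj, spec = NULL, on_level = 0.8, off_level = 0.2) {
  if (off_level >= on_level) exna_abort("off_level must be < on_level", "exna_domain")
  lv <- traj_states(traj)
  dimnames(lv) <- NULL
  if (attr(traj, "coords") == "y") {
    if (is.null(spec)) exna_abort("spec is required for y-coordinate trajectories", "exna_domain")
    lv <- activation(lv, spec)
  }
  times <- traj$time
  n <- ncol(lv)
  active <- unname(lv[1, ] >= on_level)
  events_t <- times[1]
  events_set <- list(which(active))
  for (r in seq_len(nrow(lv))[-1]) {
    newly_on <- !active & lv[r, ] >= on_level
    newly_off <- active & lv[r, ] <= off_level
    if (any(newly_on) || any(newly_off)) {
      active <- (active | newly_on) & !newly_off
      events_t <- c(events_t, times[r])
      events_set[[length(events_set) + 1L]] <- which(active)
    }
  }
  out <- tibble::tibble(
    time = events_t,
    active = events_set,
    label = vapply(events_set, function(s) paste0("{", paste(s, collapse = ","), "}"), "")
  )
  structure(out, class = c("exna_itinerary", class(out)),
            hysteresis = c(on_level = on_level, off_level = off_level),
            t_end = times[length(times)], n_cells = n)
}

#' @export
autoplot.exna_itinerary <- function(object, ...) {
  df <- itinerary_segments(object)
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                   ymin = .data$cell - 0.4, ymax = .data$cell + 0.4)) +
    ggplot2::geom_rect(fill = "goldenrod") +
    ggplot2::scale_y_continuous(breaks = seq_len(attr(object, "n_cells"))) +
    ggplot2::labs(x = "time", y = "cell (active segments)") +
    ggplot2::theme_minimal()
}

# per-cell active segments (start, end) from an itinerary
itinerary_segments <- function(itin) {
  t_end <- attr(itin, "t_end")
  rows <- list()
  for (i in seq_len(nrow(itin))) {
    s <- itin$active[[i]]
    e_t <- if (i < nrow(itin)) itin$time[i + 1] else t_end
    for (cell in s) {
      rows[[length(rows) + 1L]] <- tibble::tibble(cell = cell, start = itin$time[i], end = e_t)
    }
  }
  if (!length(rows)) return(tibble::tibble(cell = integer(), start = numeric(), end = numeric()))
  dplyr::bind_rows(rows)
}

# event durations (time to the next event, last one to the end of the run)
event_durations <- function(itin) {
  t_end <- attr(itin, "t_end")
  c(diff(itin$time), t_end - itin$time[nrow(itin)])
}

# sequence of debounced single-active labels (integer vector); events
# shorter than min_duration are dropped, consecutive repeats merged
debounced_singletons <- function(itin, min_duration = 1) {
  keep <- event_durations(itin) >= min_duration
  sets <- itin$active[keep]
  sets <- Filter(function(s) length(s) == 1L, sets)
  labs <- vapply(sets, identity, 1L)
  if (!length(labs)) return(integer())
  as.integer(labs[c(TRUE, diff(labs) != 0)])
}

#' Double-activation events of an itinerary
#'
#' During a transition along an edge `k -> l` the incoming and outgoing
#' active cells overlap briefly, so two-cell active sets `{k, l}` with
#' `k -> l` an edge are an ordinary part of every handover. A genuine
#' *double-activation* state (the suppression target of a negative
#' transverse weight `w_t`) is an active set containing two cells with no
#' edge between them in either direction, such as the two leading cells of
#' a branching vertex. This returns the events whose active set contains at
#' least one mutually non-adjacent pair.
#'
#' @param itin An `exna_itinerary`.
#' @param graph The realised `exna_digraph`.
#' @param min_duration Ignore events shorter than this (default 0).
#' @return The subset of itinerary rows that are double-activation events.
#' @export
double_activation_events <- function(itin, graph, min_duration = 0) {
  A <- graph$adjacency
  durs <- event_durations(itin)
  is_double <- vapply(seq_len(nrow(itin)), function(i) {
    s <- itin$active[[i]]
    if (length(s) < 2 || durs[i] < min_duration) return(FALSE)
    for (a in seq_len(length(s) - 1)) {
      for (b in (a + 1):length(s)) {
        if (A[s[a], s[b]] == 0L && A[s[b], s[a]] == 0L) return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  itin[is_double, ]
}

#' Transition statistics between regions of the network
#'
#' Counts, across a collection of itineraries, how often the trajectory
#' moves from a designated `source` active set directly into each of the
#' named `targets` (for instance from the bottleneck at vertex 2 of the
#' Kirk-Silber network into `{3}`, `{4}` or the double-activation state
#' `{3,4}`). Events shorter than `debounce` time units are ignored, so
#' brief threshold chatter during switching does not count as an entry.
#' Ratios are normalised over the named targets.
#'
#' @param itineraries A list of `exna_itinerary` objects (or a single one).
#' @param targets List of integer vectors naming the target active sets.
#' @param source Integer vector: the source active set (default `2`).
#' @param debounce Minimum event duration counted, in time units.
#' @return Tibble with columns `target`, `count`, `ratio`.
#' @export
transition_statistics <- function(itineraries, targets, source = 2L, debounce = 1) {
  if (inherits(itineraries, "exna_itinerary")) itineraries <- list(itineraries)
  tkey <- vapply(targets, function(s) paste(sort(s), collapse = ","), "")
  skey <- paste(sort(source), collapse = ",")
  counts <- setNames(rep(0L, length(targets)), tkey)
  for (itin in itineraries) {
    if (!nrow(itin)) next
    keep <- event_durations(itin) >= debounce
    sets <- itin$active[keep]
    keys <- vapply(sets, function(s) paste(sort(s), collapse = ","), "")
    if (length(keys) < 2) next
    keys <- keys[c(TRUE, keys[-1] != keys[-length(keys)])]
    for (i in seq_len(length(keys) - 1)) {
      if (keys[i] == skey && keys[i + 1] %in% tkey) {
        counts[keys[i + 1]] <- counts[keys[i + 1]] + 1L
      }
    }
  }
  total <- sum(counts)
  tibble::tibble(
    target = vapply(targets, function(s) paste0("{", paste(sort(s), collapse = ","), "}"), ""),
    count = as.integer(counts),
    ratio = if (total > 0) as.numeric(counts) / total else rep(NA_real_, length(counts))
  )
}

#' Detect bottleneck (saddle-node ghost) passages along a trajectory
#'
#' Past a saddle-node bifurcation the destroyed equilibrium leaves a
#' bottleneck: a region where the speed `|dy/dt|` has a pronounced local
#' minimum and trajectories linger. This scans a deterministic trajectory
#' for strict local minima of the field norm that lie below `speed_ceiling`
#' (so fast transits do not count) and above `speed_floor` (so resting at a
#' genuine equilibrium does not count), merging minima closer than
#' `refractory` time units.
#'
#' @param traj A deterministic `exna_trajectory` in `y`-coordinates.
#' @param weights An `exna_weights`.
#' @param spec An `exna_activation`.
#' @param speed_ceiling Upper bound on a bottleneck's minimum speed.
#' @param speed_floor Lower bound separating passages from equilibria.
#' @param refractory Merge window in time units.
#' @return Tibble with one row per passage: `time`, `min_speed` and
#'   `location` (list column with the state).
#' @export
detect_bottlenecks <- function(traj, weights, spec, speed_ceiling = 0.2,
                               speed_floor = 1e-6, refractory = 5) {
  states <- traj_states(traj)
  speed <- apply(states, 1, function(s) sqrt(sum(field_y(s, weights$w, spec)^2)))
  m <- length(speed)
  if (m < 3) return(tibble::tibble(time = numeric(), min_speed = numeric(), location = list()))
  is_min <- c(FALSE, speed[2:(m - 1)] < speed[1:(m - 2)] & speed[2:(m - 1)] < speed[3:m], FALSE)
  cand <- which(is_min & speed < speed_ceiling & speed > speed_floor)
  if (!length(cand)) {
    return(tibble::tibble(time = numeric(), min_speed = numeric(), location = list()))
  }
  # merge within refractory window, keeping the slowest representative
  ord <- cand[order(traj$time[cand])]
  kept <- integer()
  for (i in ord) {
    if (length(kept) && traj$time[i] - traj$time[kept[length(kept)]] < refractory) {
      if (speed[i] < speed[kept[length(kept)]]) kept[length(kept)] <- i
    } else {
      kept <- c(kept, i)
    }
  }
  tibble::tibble(
    time = traj$time[kept],
    min_speed = speed[kept],
    location = lapply(kept, function(i) states[i, ])
  )
}
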