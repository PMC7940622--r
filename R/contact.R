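# Penalty-based viscoelastic foot-ground contact: per-point force law,
# GRF/COP aggregation, offline touchdown/toe-off event detection, and the
# swing-phase phalangeal penetration policy.

#' Viscoelastic contact forces at foot contact points
#'
#' For each enabled, penetrating point the vertical force is
#' `max(0, k_vert * penetration + c_vert * penetration_rate)` (unilateral:
#' never tensile) and the horizontal force is a sticking spring-damper about
#' the anchor set at touchdown: `-k_horz * (x - anchor) - c_horz * vx`.
#' Non-penetrating or disabled points transmit nothing.
#'
#' @param params contact parameter list (`k_vert`, `c_vert`, `k_horz`,
#'   `c_horz`), e.g. `model$contact$params`.
#' @param points data.frame with columns `x`, `y` (world position, m),
#'   `vx`, `vy` (m/s), `anchor` (anchor x, m) and `enabled` (logical).
#' @return data.frame with per-point `fx`, `fy` (N).
#' @export
contact_forces <- function(params, points) {
  pen <- points$y < 0 & points$enabled
  fy <- ifelse(pen, pmax(0, params$k_vert * (-points$y) +
                            params$c_vert * (-points$vy)), 0)
  fx <- ifelse(pen, -params$k_horz * (points$x - points$anchor) -
                    params$c_horz * points$vx, 0)
  data.frame(fx = fx, fy = fy)
}

#' Total ground reaction force and centre of pressure
#'
#' @param forces data.frame with `fx`, `fy` per point.
#' @param x world x-coordinates of the points (m).
#' @return list with `fx`, `fy` totals (N) and `cop` (m); `cop` is `NA` when
#'   the total vertical load is zero (undefined, not 0).
#' @export
grf_summary <- function(forces, x) {
  fy <- sum(forces$fy)
  list(fx = sum(forces$fx), fy = fy,
       cop = if (fy > 0) sum(forces$fy * x) / fy else NA_real_)
}

#' Detect touchdown and toe-off events from a vertical GRF trace
#'
#' Offline detector for recorded or synthetic traces: a touchdown is a
#' crossing of the force threshold from below that stays above it for at
#' least the debounce window; a toe-off is the symmetric downward crossing.
#' Shorter excursions (blips) produce no event.
#'
#' @param time time vector (s).
#' @param grf_vert vertical GRF (N), same length.
#' @param leg label stored in the output (default `"R"`).
#' @param threshold force threshold (N), default 1.
#' @param debounce minimum dwell time on the new side (s), default 0.020.
#' @return data.frame with `time`, `leg`, `type` (`"touchdown"`/`"toeoff"`).
#' @export
detect_events <- function(time, grf_vert, leg = "R", threshold = 1,
                          debounce = 0.020) {
  stopifnot(length(time) == length(grf_vert))
  above <- grf_vert > threshold
  out <- data.frame(time = numeric(0), leg = character(0),
                    type = character(0), stringsAsFactors = FALSE)
  if (!length(above)) return(out)
  r <- rle(above)
  starts <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  ends <- cumsum(r$lengths)
  n <- length(above)
  state <- r$values[1]
  for (k in seq_along(r$values)[-1]) {
    if (r$values[k] == state) next
    dwell <- time[min(ends[k] + 1, n)] - time[starts[k]]
    if (dwell >= debounce) {
      state <- r$values[k]
      out <- rbind(out, data.frame(
        time = time[starts[k]], leg = leg,
        type = if (state) "touchdown" else "toeoff",
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Apply the swing-phase phalangeal penetration policy
#'
#' The model has no interphalangeal joints, so the phalangeal contact points
#' of a leg are disabled (allowed to penetrate the ground without force) from
#' that leg's toe-off until its next sole-point touchdown; sole points are
#' always enabled.
#'
#' @param contact_state data.frame with per-point `segment`
#'   (`"foot"`/`"phalanges"`) and `enabled`.
#' @param event `"toeoff"` or `"touchdown"` for this leg (or `NULL` for no
#'   event).
#' @return updated `contact_state`.
#' @export
update_swing_policy <- function(contact_state, event = NULL) {
  phal <- contact_state$segment == "phalanges"
  contact_state$enabled[!phal] <- TRUE
  if (is.null(event)) return(contact_state)
  if (event == "toeoff") contact_state$enabled[phal] <- FALSE
  if (event == "touchdown") contact_state$enabled[phal] <- TRUE
  contact_state
}
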