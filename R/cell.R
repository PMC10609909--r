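#' Create a cambial cell
#'
#' One cell of the radial file. The initial cell sits at position 0; mother
#' cells occupy positions 1 onward. A cell's phase is tied to its diameter
#' band (see [cambium_params()]); `regime` distinguishes the dormant initial
#' cell's first, constant-rate cycle (`"constant"`) from the ordinary
#' cell-cycle machinery (`"cycle"`: Gompertz G1 rate, then `V0` through
#' S, G2 and M).
#'
#' @param id lineage identifier; daughters append `".p"` (proximal) or
#'   `".d"` (distal) to their mother's id.
#' @param diameter radial diameter, micrometres.
#' @param inhibitor inhibitor amount, relative units.
#' @param position index in the radial file (initial cell = 0).
#' @param params a [cambium_params()] object (sets the phase from the
#'   diameter).
#' @param mother_id id of the mother cell (`NA` for the season's initial
#'   cell).
#' @param born_at birth time, days from season start.
#' @param stressed logical; was the creating division stress-flagged?
#' @param regime `"cycle"` or `"constant"` (see above).
#' @return an object of class `cambial_cell`.
#' @export
cambial_cell <- function(id, diameter, inhibitor, position = 0L,
                         params = cambium_params(), mother_id = NA_character_,
                         born_at = 0, stressed = FALSE, regime = "cycle") {
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  if (inhibitor < 0) stop("inhibitor must be non-negative", call. = FALSE)
  if (!regime %in% c("cycle", "constant")) {
    stop("regime must be 'cycle' or 'constant'", call. = FALSE)
  }
  ph <- phase_of(diameter, params)
  entry <- c(G1 = NA_real_, S = NA_real_, G2 = NA_real_, M = NA_real_)
  entry[[ph]] <- born_at
  cell <- list(id = id, mother_id = mother_id,
               position = as.integer(position), diameter = diameter,
               phase = ph, inhibitor = inhibitor, born_at = born_at,
               phase_entry = entry, stressed = isTRUE(stressed),
               regime = regime, g1_rate_birth = NA_real_, halted = FALSE)
  class(cell) <- "cambial_cell"
  cell
}

#' Cell-cycle phase from diameter
#'
#' Maps a diameter to the phase band: G1 below `D_S`, S below `D_G2`, G2
#' below `D_M`, M from `D_M` up to the division diameter.
#'
#' @param diameter diameter in micrometres.
#' @param params a [cambium_params()] object.
#' @return one of `"G1"`, `"S"`, `"G2"`, `"M"`.
#' @export
phase_of <- function(diameter, params) {
  if (diameter < params$D_S) "G1"
  else if (diameter < params$D_G2) "S"
  else if (diameter < params$D_M) "G2"
  else "M"
}

#' Inhibitor concentration in a cell
#'
#' Concentration is the inhibitor amount divided by the radial cell size.
#' Because the amount is fixed between divisions while the cell grows, a
#' cell's concentration falls as it progresses through its cycle.
#'
#' @param inhibitor inhibitor amount (relative units).
#' @param diameter radial diameter (micrometres), must be positive.
#' @return concentration in relative units.
#' @examples
#' concentration(0.8286, 4.75)
#' @export
concentration <- function(inhibitor, diameter) {
  if (any(diameter <= 0)) stop("diameter must be positive", call. = FALSE)
  inhibitor / diameter
}

#' Gompertz growth rate in phase G1
#'
#' The G1 growth rate is a Gompertz function of the cell's inhibitor
#' concentration `C`: `exp(-exp(-c * C))` micrometres/day, rising from
#' `exp(-1)` at `C = 0` toward 1 as `C` grows. For cells born from a
#' stress-flagged division the stress coefficient `S` enters the exponent:
#' literally as a multiplier (`c * S * C`, the printed form) or, in
#' `"reciprocal"` mode, as a divisor (`c * C / S`), which slows stressed
#' cells as climate stress is expected to. With
#' `g1_env_coupling = "multiplicative"` the rate is additionally scaled by
#' the day's integral growth rate.
#'
#' @param C inhibitor concentration (non-negative).
#' @param stressed logical stress flag of the cell.
#' @param gr_today the day's integral growth rate in \[0, 1\].
#' @param params a [cambium_params()] object.
#' @return growth rate in micrometres/day, in (0, 1].
#' @examples
#' g1_rate(0)                       # exp(-1)
#' g1_rate(1, params = cambium_params(c_g1 = 0.071))
#' @export
g1_rate <- function(C, stressed = FALSE, gr_today = 1,
                    params = cambium_params()) {
  if (any(C < 0)) stop("concentration must be non-negative", call. = FALSE)
  arg <- if (isTRUE(stressed)) {
    if (params$stress_mode == "literal") params$c_g1 * params$S_stress * C
    else params$c_g1 * C / params$S_stress
  } else {
    params$c_g1 * C
  }
  v <- exp(-exp(-arg))
  if (params$g1_env_coupling == "multiplicative") v <- v * gr_today
  v
}

#' Constant growth rate of the initial cell's first cycle
#'
#' After dormancy the initial cell is carried from its initial diameter to
#' its first division at the constant rate `(D_div - D_init) / d_init`,
#' where `d_init` is the configured period of the initial division.
#'
#' @param params a [cambium_params()] object.
#' @return rate in micrometres/day.
#' @examples
#' initial_linear_rate(cambium_params(d_init = 7.5))  # 1.0
#' @export
initial_linear_rate <- function(params) {
  if (params$d_init <= 0) stop("d_init must be positive", call. = FALSE)
  (params$D_div - params$D_init) / params$d_init
}

#' Advance a cell through its diameter bands
#'
#' Piecewise-analytic integration of one cell over a time budget. Within the
#' budget the diameter grows linearly at the regime rate: the supplied
#' `rate` while the cell stays in its current regime (its G1 rate for a
#' cycling G1 cell, or the constant initial rate for the initial cell's
#' first cycle) and `V0` once a cycling cell has left G1. Phase-boundary
#' crossing times are solved exactly as `(threshold - diameter) / rate` and
#' emitted in order; a cell reaching the division diameter stops there with
#' a `"ready_to_divide"` event and any remaining budget unused.
#'
#' @param cell a [cambial_cell()].
#' @param rate rate for the cell's current regime (micrometres/day,
#'   non-negative). Ignored after the cell leaves its current phase, except
#'   in the `"constant"` regime where it applies up to division.
#' @param time_budget available time, days (positive).
#' @param params a [cambium_params()] object.
#' @return a list with elements `cell` (the updated cell; `phase_entry`
#'   times are offsets from the start of this call) and `events`, a data
#'   frame with columns `offset` (days from the call start), `type` (one of
#'   `"phase_S"`, `"phase_G2"`, `"phase_M"`, `"ready_to_divide"`) and
#'   `diameter`.
#' @export
advance_cell <- function(cell, rate, time_budget, params = cambium_params()) {
  res <- advance_cell_core(cell, rate, time_budget, params)
  list(cell = res$cell,
       events = data.frame(offset = res$ev_t, type = res$ev_ty,
                           diameter = res$ev_d, stringsAsFactors = FALSE))
}

# Lean kernel shared by advance_cell() and the season engine: identical
# semantics, but events come back as parallel vectors.
advance_cell_core <- function(cell, rate, time_budget, params) {
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  if (time_budget <= 0) stop("time_budget must be positive", call. = FALSE)
  ev_t <- numeric(0); ev_ty <- character(0); ev_d <- numeric(0)
  t <- 0
  nxt <- c(G1 = "S", S = "G2", G2 = "M")
  repeat {
    if (cell$diameter >= params$D_div) break
    r <- if (cell$regime == "constant") rate
         else if (cell$phase == "G1") rate
         else params$V0
    if (r <= 0) { t <- time_budget; break }
    target <- switch(cell$phase, G1 = params$D_S, S = params$D_G2,
                     G2 = params$D_M, M = params$D_div)
    dt <- (target - cell$diameter) / r
    if (t + dt <= time_budget) {
      t <- t + dt
      cell$diameter <- target
      if (target >= params$D_div) {
        ev_t <- c(ev_t, t); ev_ty <- c(ev_ty, "ready_to_divide")
        ev_d <- c(ev_d, target)
        break
      }
      new_phase <- nxt[[cell$phase]]
      cell$phase <- new_phase
      cell$phase_entry[[new_phase]] <- t
      ev_t <- c(ev_t, t); ev_ty <- c(ev_ty, paste0("phase_", new_phase))
      ev_d <- c(ev_d, target)
    } else {
      cell$diameter <- cell$diameter + r * (time_budget - t)
      t <- time_budget
      break
    }
  }
  list(cell = cell, ev_t = ev_t, ev_ty = ev_ty, ev_d = ev_d)
}

#' Divide a cell
#'
#' Splits a mother cell that has reached the division diameter into two
#' daughters of half its size, both starting a new cycle in G1. The
#' inhibitor is partitioned asymmetrically: the proximal daughter (the one
#' taking the mother's position, closer to the initial cell) receives the
#' proportion `alpha` of the mother's amount, the distal daughter the
#' remaining `1 - alpha`; the sum is conserved exactly. Daughters carry the
#' stress flag of the creating division; lineage ids extend the mother's id
#' with `".p"` / `".d"`.
#'
#' @param mother a [cambial_cell()] at the division diameter with
#'   concentration at least `C_min`.
#' @param alpha proportion of inhibitor for the proximal daughter, in
#'   (0, 1).
#' @param stress_flag was the division stress-flagged?
#' @param at division time (days from season start), recorded as the
#'   daughters' birth time.
#' @param params a [cambium_params()] object.
#' @return list with elements `proximal` and `distal`, both `cambial_cell`s
#'   occupying positions `i` and `i + 1`.
#' @examples
#' p <- cambium_params()
#' m <- cambial_cell("0", p$D_div, 1.0, 0L, p)
#' divide_cell(m, alpha = p$alpha)
#' @export
divide_cell <- function(mother, alpha, stress_flag = FALSE, at = 0,
                        params = cambium_params()) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (mother$diameter < params$D_div - 1e-9) {
    stop("cell ", mother$id, " has not reached the division diameter",
         call. = FALSE)
  }
  if (concentration(mother$inhibitor, mother$diameter) < params$C_min) {
    stop("cell ", mother$id, " is below the minimum inhibitor ",
         "concentration; it must exit, not divide", call. = FALSE)
  }
  half <- mother$diameter / 2
  proximal <- cambial_cell(paste0(mother$id, ".p"), half,
                           mother$inhibitor * alpha,
                           position = mother$position, params = params,
                           mother_id = mother$id, born_at = at,
                           stressed = stress_flag)
  distal <- cambial_cell(paste0(mother$id, ".d"), half,
                         mother$inhibitor * (1 - alpha),
                         position = mother$position + 1L, params = params,
                         mother_id = mother$id, born_at = at,
                         stressed = stress_flag)
  list(proximal = proximal, distal = distal)
}

#' Should a cell exit to the enlargement zone?
#'
#' A cell loses its ability to divide and transfers to the enlargement zone
#' when its inhibitor concentration is strictly below the threshold `C_min`
#' (exact equality retains division ability). The season simulator evaluates
#' this at birth and again when the cell reaches the division diameter.
#'
#' @param cell a [cambial_cell()].
#' @param params a [cambium_params()] object.
#' @return `TRUE` if the cell must exit.
#' @export
should_exit <- function(cell, params = cambium_params()) {
  concentration(cell$inhibitor, cell$diameter) < params$C_min
}
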