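#' The hemodynamic/geometric feature registry
#'
#' The 73 per-animal features entering the statistics stage: 7 bifurcation
#' angles, 22 section areas, 22 sectional maximum velocities, 11 per-vessel
#' mass flows (one per same-vessel plane pair, e.g. `Q_15_16`), and 11
#' pairwise hydraulic resistances over the same plane pairs (e.g. `R_5_6`).
#'
#' @return data.frame with columns `feature`, `kind`
#'   (`angle`/`area`/`vmax`/`Q`/`R`), `mode_dependent` (whether the value
#'   depends on the steady vs transient solve), `units`.
#' @export
feature_registry <- function() {
  pairs <- section_pairs()
  pn <- vapply(pairs, function(p) paste0(p[1], "_", p[2]), "")
  rbind(
    data.frame(feature = paste0("angle_", 1:7), kind = "angle",
               mode_dependent = FALSE, units = "degree"),
    data.frame(feature = paste0("area_S", 1:22), kind = "area",
               mode_dependent = FALSE, units = "mm^2"),
    data.frame(feature = paste0("vmax_S", 1:22), kind = "vmax",
               mode_dependent = TRUE, units = "cm/s"),
    data.frame(feature = paste0("Q_", pn), kind = "Q",
               mode_dependent = TRUE, units = "mg/s"),
    data.frame(feature = paste0("R_", pn), kind = "R",
               mode_dependent = TRUE, units = "mmHg.s/g"))
}

#' Same-vessel section-plane pairs
#'
#' The default resistance/mass-flow pair registry: the two planes of each of
#' the 11 sectioned vessels, which includes the pairs (5,6) and (15,16).
#' @return list of length-2 integer vectors.
#' @export
section_pairs <- function() {
  lapply(seq(1, 21, by = 2), function(i) c(i, i + 1L))
}

#' Sectional mass flow
#'
#' `Q_i = integral over the plane of rho (v . n) dS`: for the lumped model,
#' blood density times the volumetric flow of the section's segment, signed
#' by the section normal (oriented with the segment, from `from` to `to`).
#' For a transient state the cycle-averaged flow is used.
#'
#' @param state a solved state.
#' @param net the network.
#' @param index section plane index.
#' @param blood a [blood_properties()] object.
#' @return mass flow, mg/s.
#' @export
mass_flow <- function(state, net, index, blood = blood_properties()) {
  i <- match(index, net$sections$index)
  if (is.na(i)) stop("unknown section index ", index)
  seg <- net$sections$segment_id[i]
  q <- if (inherits(state, "time_series_state"))
    Re(state$steady$flows[[seg]]) else Re(state$flows[[seg]])
  q * blood$rho_g_mm3 * 1000           # mm^3/s * mg/mm^3
}

## pressure (mmHg) at a section plane, linearly interpolated between the
## segment's endpoint nodal pressures; kind "total" adds the dynamic head
## rho v^2 / 2 computed from the sectional mean velocity.
.section_pressure_series <- function(state, net, index, blood,
                                     kind = c("total", "static")) {
  kind <- match.arg(kind)
  i <- match(index, net$sections$index)
  if (is.na(i)) stop("unknown section index ", index)
  seg <- net$sections$segment_id[i]
  e <- match(seg, net$segments$id)
  pos <- net$sections$position[i]
  A <- net$sections$area[i]
  if (inherits(state, "time_series_state")) {
    pf <- state$pressures[net$segments$from[e], ]
    pt <- state$pressures[net$segments$to[e], ]
    q <- state$flows[seg, ]
  } else {
    pf <- Re(state$pressures[[net$segments$from[e]]])
    pt <- Re(state$pressures[[net$segments$to[e]]])
    q <- Re(state$flows[[seg]])
  }
  p <- pf + pos * (pt - pf)
  if (kind == "total") {
    v <- q / A                                  # mm/s
    p <- p + 0.5 * blood$rho_g_mm3 * v^2 / .PA_PER_MMHG
  }
  list(pressure = p, flow = q)
}

#' Pairwise hydraulic resistance
#'
#' `R_ij = dP_ij / Q_i` in mmHg.s/g, where `dP_ij` is the pressure drop from
#' plane `i` to plane `j` and `Q_i` the mass flow at plane `i` (converted to
#' g/s). By default the drop is in *total* pressure (static plus dynamic
#' head); `kind = "static"` uses nodal static pressure only. For transient
#' states the instantaneous ratio `dP(t)/Q(t)` is averaged over the cycle;
#' when the flow nears zero during the cycle the ratio of cycle means is
#' used instead.
#'
#' @param state a solved state.
#' @param net the network.
#' @param i,j section plane indices.
#' @param blood a [blood_properties()] object.
#' @param kind `"total"` (default) or `"static"` pressure drop.
#' @return resistance, mmHg.s/g; error if `Q_i` vanishes.
#' @export
hydraulic_resistance <- function(state, net, i, j,
                                 blood = blood_properties(),
                                 kind = c("total", "static")) {
  kind <- match.arg(kind)
  si <- .section_pressure_series(state, net, i, blood, kind)
  sj <- .section_pressure_series(state, net, j, blood, kind)
  qm <- si$flow * blood$rho_g_mm3                 # g/s
  scale <- max(abs(Re(unlist(state$steady$boundary$inlet %||%
                               state$boundary$inlet))) *
                 blood$rho_g_mm3, 1e-300)
  if (max(abs(qm)) < 1e-9 * scale)
    stop("hydraulic resistance undefined: zero mass flow at section ", i)
  dp <- si$pressure - sj$pressure
  if (length(qm) > 1L) {                          # transient series
    if (min(abs(qm)) < 0.05 * abs(mean(qm)) || any(sign(qm) != sign(qm[1])))
      return(mean(dp) / mean(qm))
    return(mean(dp / qm))
  }
  dp / qm
}

#' Compute the full metric set of a solved animal
#'
#' Evaluates every feature of [feature_registry()] on a solved state:
#' angles and section areas from the network, maximum velocities per plane,
#' mass flow at the first plane of each same-vessel pair, and pairwise
#' hydraulic resistance over each pair. Metrics that are undefined (e.g.
#' resistance across a dead branch) are reported as `NA` with a warning and
#' do not affect the rest.
#'
#' @param state a `pressure_flow_state` (steady) or `time_series_state`.
#' @param net the network the state was solved on.
#' @param blood a [blood_properties()] object.
#' @param pressure_kind passed to [hydraulic_resistance()].
#' @return data.frame `feature`, `value`, `units`, `mode`.
#' @export
compute_metric_set <- function(state, net, blood = blood_properties(),
                               pressure_kind = "total") {
  reg <- feature_registry()
  mode <- if (inherits(state, "time_series_state")) "transient" else "steady"
  val <- numeric(nrow(reg))
  grab <- function(expr, what) tryCatch(expr, error = function(e) {
    warning("metric ", what, " unavailable: ", conditionMessage(e),
            call. = FALSE)
    NA_real_
  })
  for (r in seq_len(nrow(reg))) {
    f <- reg$feature[r]
    val[r] <- switch(
      reg$kind[r],
      angle = grab(vessel_angle(net, as.integer(sub("angle_", "", f))), f),
      area = grab(section_area(net, as.integer(sub("area_S", "", f))), f),
      vmax = grab(max_velocity(state, net, as.integer(sub("vmax_S", "", f)),
                               blood), f),
      Q = {
        ij <- as.integer(strsplit(sub("Q_", "", f), "_")[[1]])
        grab(abs(mass_flow(state, net, ij[1], blood)), f)
      },
      R = {
        ij <- as.integer(strsplit(sub("R_", "", f), "_")[[1]])
        grab(abs(hydraulic_resistance(state, net, ij[1], ij[2], blood,
                                      pressure_kind)), f)
      })
  }
  data.frame(feature = reg$feature, value = val, units = reg$units,
             mode = mode, stringsAsFactors = FALSE)
}
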