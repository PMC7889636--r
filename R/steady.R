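#' Poiseuille conductance of a vessel segment
#'
#' Fully developed laminar flow in a rigid circular tube of the segment's
#' equivalent radius: `G = pi r^4 / (8 mu L)`, converted so that flow in
#' mm^3/s equals `G` times the pressure drop in mmHg. Conductance halves when
#' length doubles and scales with the square of the lumen area.
#'
#' @param seg one row of a network's `segments` table (or any list with
#'   `area` (mm^2) and `length` (mm)).
#' @param blood a [blood_properties()] object.
#' @return conductance, mm^3 s^-1 mmHg^-1.
#' @export
segment_conductance <- function(seg, blood = blood_properties()) {
  r <- equivalent_radius(seg$area)
  if (!is.finite(seg$length) || seg$length <= 0) stop("length must be > 0")
  pi * r^4 / (8 * blood$mu_Pa_s * seg$length) * .PA_PER_MMHG
}

.conductances <- function(net, blood) {
  r4 <- (net$segments$area / pi)^2
  pi * r4 / (8 * blood$mu_Pa_s * net$segments$length) * .PA_PER_MMHG
}

#' Boundary volumetric flows from inlet velocities
#'
#' Each inlet contributes `v * A` (velocity in cm/s times the attached
#' segment's lumen area in mm^2, i.e. a flat inflow profile); the total
#' inflow is distributed over the outlets in proportion to their attached
#' segments' cross-section areas, so outflow balances inflow exactly.
#'
#' @param net a `vascular_network`.
#' @param inlets named numeric vector of mean velocities (cm/s), named by
#'   inlet node id; every network inlet must be present.
#' @return object of class `boundary_flows`: list with `inlet` and `outlet`
#'   (positive magnitudes, mm^3/s, named by terminal node id) and
#'   `injection` (signed net injection for every terminal; inlets positive).
#' @export
boundary_flows <- function(net, inlets) {
  miss <- setdiff(net$inlets, names(inlets))
  if (length(miss))
    stop("missing inlet velocities for: ", paste(miss, collapse = ", "))
  if (any(!is.finite(unlist(inlets))) || any(unlist(inlets) <= 0))
    stop("inlet velocities must be positive and finite")
  in_area <- vapply(net$inlets, function(t)
    net$segments$area[.terminal_segment(net, t)], 0)
  qin <- unlist(inlets)[net$inlets] * .CMS_TO_MMS * in_area
  names(qin) <- net$inlets
  out_area <- vapply(net$outlets, function(t)
    net$segments$area[.terminal_segment(net, t)], 0)
  if (sum(out_area) <= 0) stop("degenerate network: zero total outlet area")
  total <- sum(qin)
  qout <- total * out_area / sum(out_area)
  ## enforce exact balance against rounding
  qout[length(qout)] <- total - sum(qout[-length(qout)])
  names(qout) <- net$outlets
  structure(list(inlet = qin, outlet = qout,
                 injection = c(qin, -qout)),
            class = "boundary_flows")
}

#' Lengthen outlet segments
#'
#' Returns a network in which the segment attached to each named outlet
#' terminal is extended by `extra_length` mm at unchanged lumen area (node
#' positions are nominal; segment `length` is authoritative). All other
#' structure is untouched.
#'
#' @param net a `vascular_network`.
#' @param terminals character vector of outlet node ids.
#' @param extra_length added length, mm (>= 0).
#' @return modified `vascular_network`.
#' @export
lengthen_outlets <- function(net, terminals, extra_length = 1) {
  if (extra_length < 0) stop("extra_length must be >= 0")
  for (t in terminals) {
    if (!t %in% net$outlets)
      stop("terminal '", t, "' is not an outlet of this network")
    i <- .terminal_segment(net, t)
    net$segments$length[i] <- net$segments$length[i] + extra_length
  }
  net
}

#' Steady network blood-flow solve
#'
#' Mass conservation (`div v = 0`) on the lumped network: nodal pressures
#' solve the conductance-weighted graph Laplacian with Neumann data given by
#' the boundary flows; the first outlet terminal is the grounded pressure
#' reference (0 mmHg). Segment flow equals conductance times pressure drop.
#'
#' @param net a `vascular_network` (must pass [validate_network()]).
#' @param inlets named inlet velocities, cm/s (see [boundary_flows()]).
#' @param blood a [blood_properties()] object.
#' @return object of class `pressure_flow_state`: list with `pressures`
#'   (mmHg, named by node), `flows` (mm^3/s, named by segment id, signed
#'   positive from `from` to `to`), `boundary`, `blood`.
#' @export
solve_steady <- function(net, inlets, blood = blood_properties()) {
  viol <- validate_network(net)
  if (length(viol))
    stop("invalid network: ", paste(viol, collapse = "; "))
  bf <- boundary_flows(net, inlets)
  .solve_injection(net, bf$injection, blood, boundary = bf)
}

## core linear solve shared by the steady and per-harmonic paths;
## `injection` is a named (possibly complex) net inflow per terminal node
.solve_injection <- function(net, injection, blood, boundary = NULL,
                             weights = NULL) {
  g <- weights %||% .conductances(net, blood)
  ids <- net$nodes$id
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  cplx <- is.complex(injection) || is.complex(g)
  L <- matrix(if (cplx) 0i else 0, n, n)
  fi <- idx[net$segments$from]; ti <- idx[net$segments$to]
  for (e in seq_along(g)) {
    i <- fi[e]; j <- ti[e]
    L[i, i] <- L[i, i] + g[e]; L[j, j] <- L[j, j] + g[e]
    L[i, j] <- L[i, j] - g[e]; L[j, i] <- L[j, i] - g[e]
  }
  b <- if (cplx) complex(n) else numeric(n)
  b[idx[names(injection)]] <- injection
  ground <- idx[[net$outlets[1]]]
  p <- if (cplx) complex(n) else numeric(n)
  sol <- tryCatch(solve(L[-ground, -ground, drop = FALSE], b[-ground]),
                  error = function(e)
                    stop("singular pressure system (disconnected component?): ",
                         conditionMessage(e)))
  p[-ground] <- sol
  names(p) <- ids
  q <- g * (p[fi] - p[ti])
  names(q) <- net$segments$id
  ## conservation assertion at interior nodes
  resid <- as.vector(L %*% p) - b
  interior <- setdiff(ids, c(net$inlets, net$outlets))
  scale <- max(abs(injection), 1e-300)
  if (length(interior) && max(abs(resid[idx[interior]])) > 1e-9 * scale)
    stop("internal error: interior flow residual exceeds tolerance")
  structure(list(pressures = p, flows = q, boundary = boundary,
                 blood = blood),
            class = "pressure_flow_state")
}

#' @export
print.pressure_flow_state <- function(x, ...) {
  cat("<pressure_flow_state> ", length(x$pressures), " nodal pressures, ",
      length(x$flows), " segment flows\n", sep = "")
  cat("  pressure range [mmHg]: ",
      paste(signif(range(Re(x$pressures)), 4), collapse = " .. "), "\n",
      sep = "")
  invisible(x)
}
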