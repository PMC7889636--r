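#' Canonical section-plane registry
#'
#' 22 planes, two per named vessel over 11 vessels. The labelled anatomy
#' fixes planes 1 (basilar base), 3 (left ICA, cervical C1) and 6 (right ICA,
#' C1); the remaining placement is a documented, overridable convention:
#' 1-2 BA (base, distal), 3-4 ICA_L (C1, intracranial), 5-6 ICA_R
#' (intracranial, C1), 7-8 MCA_L, 9-10 MCA_R, 11-12 ACA_L, 13-14 ACA_R,
#' 15-16 PcoA_R, 17-18 PcoA_L, 19-20 PCA_L, 21-22 PCA_R.
#'
#' @return data.frame with columns `index`, `segment`, `position`.
#' @export
default_section_registry <- function() {
  data.frame(
    index = 1:22,
    segment = c("BA", "BA", "ICA_L", "ICA_L", "ICA_R", "ICA_R",
                "MCA_L", "MCA_L", "MCA_R", "MCA_R", "ACA_L", "ACA_L",
                "ACA_R", "ACA_R", "PcoA_R", "PcoA_R", "PcoA_L", "PcoA_L",
                "PCA_L", "PCA_L", "PCA_R", "PCA_R"),
    position = c(0.05, 0.75, 0.25, 0.75, 0.75, 0.25,
                 rep(c(0.25, 0.75), 8)),
    stringsAsFactors = FALSE)
}

## nominal (control) template dimensions, mm and mm^2
.TEMPLATE_AREAS <- c(
  CCA_L = 0.15, CCA_R = 0.15, VA_L = 0.035, VA_R = 0.035, BA = 0.06,
  ICA_L = 0.12, ICA_R = 0.10, MCA_L = 0.05, MCA_R = 0.05,
  ACA_L = 0.05, ACA_R = 0.05, AcoA = 0.02,
  ACA_L_dist = 0.04, ACA_R_dist = 0.04, PcoA_L = 0.03, PcoA_R = 0.03,
  PCA_L = 0.04, PCA_R = 0.04, PCA_L_dist = 0.035, PCA_R_dist = 0.035,
  SCA_L = 0.02, SCA_R = 0.02)

## nominal bifurcation angles (degrees); angle 2 is the published control
## mean, angle 1 mirrors it, the rest are anatomical conventions
.TEMPLATE_ANGLES <- c(`1` = 67.6, `2` = 67.6, `3` = 112, `4` = 112,
                      `5` = 148, `6` = 148, `7` = 96)

## which segment of each angle pair gets rotated when an angle is imposed,
## and the order of application (anchor chain ICA -> PcoA -> ACA -> MCA)
.ANGLE_ROTATE <- c(`1` = "MCA_L", `2` = "MCA_R", `3` = "ACA_L", `4` = "ACA_R",
                   `5` = "PcoA_L", `6` = "PcoA_R", `7` = "PCA_R")
.ANGLE_ORDER <- c(5, 6, 3, 4, 1, 2, 7)

#' Template mouse circle-of-Willis network
#'
#' A 22-segment, 22-node network: CCA/VA inlets, ICA and basilar conduits,
#' the communicating ring (ACA, AcoA, PcoA, PCA), and eight outlets ordered
#' MCA_L, MCA_R, ACA_L, ACA_R, PCA_L, PCA_R, SCA_L, SCA_R (the superior
#' cerebellar pair, outlets 7 and 8, leaves the basilar terminus right at the
#' PCA bifurcation). Dimensions are nominal adult-mouse values; section areas
#' equal their segment's lumen area.
#'
#' When `group` is given, the group's mean section areas and bifurcation
#' angles from `params` (see [default_group_params()]) are imposed on the
#' template, so e.g. the 2-month diabetic template carries the reduced ICA
#' lumen of that arm.
#'
#' @param group optional experimental arm (`"1c"`, `"1d"`, `"2c"`, `"2d"`).
#' @param params group-parameter table used when `group` is given; defaults
#'   to the packaged table.
#' @return a `vascular_network`.
#' @export
cow_template <- function(group = NULL, params = NULL) {
  nd <- function(id, x, y, z, kind) data.frame(id = id, x = x, y = y, z = z,
                                               kind = kind,
                                               stringsAsFactors = FALSE)
  nodes <- rbind(
    nd("in_ccaL", -2.8, -4.5, -8.0, "inlet"),
    nd("in_ccaR", 2.8, -4.5, -8.0, "inlet"),
    nd("in_vaL", -0.8, -7.0, -2.0, "inlet"),
    nd("in_vaR", 0.8, -7.0, -2.0, "inlet"),
    nd("j_icaL0", -2.2, -2.0, -3.0, "junction"),
    nd("j_icaR0", 2.2, -2.0, -3.0, "junction"),
    nd("j_icaL1", -1.4, -0.5, 0.0, "junction"),
    nd("j_icaR1", 1.4, -0.5, 0.0, "junction"),
    nd("j_vab", 0.0, -4.5, -0.5, "junction"),
    nd("j_bat", 0.0, -3.0, 0.0, "junction"),
    nd("j_pcaL", -1.0, -2.4, 0.0, "junction"),
    nd("j_pcaR", 1.0, -2.4, 0.0, "junction"),
    nd("j_acaL", -0.25, 1.2, 0.2, "junction"),
    nd("j_acaR", 0.25, 1.2, 0.2, "junction"),
    nd("out_mcaL", -3.4, -0.2, 0.6, "outlet"),
    nd("out_mcaR", 3.4, -0.2, 0.6, "outlet"),
    nd("out_acaL", -0.4, 3.0, 1.0, "outlet"),
    nd("out_acaR", 0.4, 3.0, 1.0, "outlet"),
    nd("out_pcaL", -2.4, -2.8, 0.5, "outlet"),
    nd("out_pcaR", 2.4, -2.8, 0.5, "outlet"),
    nd("out_scaL", -2.0, -4.0, 0.0, "outlet"),
    nd("out_scaR", 2.0, -4.0, 0.0, "outlet"))
  sg <- function(name, from, to) data.frame(id = name, name = name,
                                            from = from, to = to,
                                            area = .TEMPLATE_AREAS[[name]],
                                            stringsAsFactors = FALSE)
  segments <- rbind(
    sg("CCA_L", "in_ccaL", "j_icaL0"), sg("CCA_R", "in_ccaR", "j_icaR0"),
    sg("ICA_L", "j_icaL0", "j_icaL1"), sg("ICA_R", "j_icaR0", "j_icaR1"),
    sg("VA_L", "in_vaL", "j_vab"), sg("VA_R", "in_vaR", "j_vab"),
    sg("BA", "j_vab", "j_bat"),
    sg("PCA_L", "j_bat", "j_pcaL"), sg("PCA_R", "j_bat", "j_pcaR"),
    sg("PCA_L_dist", "j_pcaL", "out_pcaL"),
    sg("PCA_R_dist", "j_pcaR", "out_pcaR"),
    sg("SCA_L", "j_bat", "out_scaL"), sg("SCA_R", "j_bat", "out_scaR"),
    sg("PcoA_L", "j_icaL1", "j_pcaL"), sg("PcoA_R", "j_icaR1", "j_pcaR"),
    sg("MCA_L", "j_icaL1", "out_mcaL"), sg("MCA_R", "j_icaR1", "out_mcaR"),
    sg("ACA_L", "j_icaL1", "j_acaL"), sg("ACA_R", "j_icaR1", "j_acaR"),
    sg("AcoA", "j_acaL", "j_acaR"),
    sg("ACA_L_dist", "j_acaL", "out_acaL"),
    sg("ACA_R_dist", "j_acaR", "out_acaR"))
  reg <- default_section_registry()
  sections <- data.frame(index = reg$index, segment_id = reg$segment,
                         position = reg$position,
                         area = unname(.TEMPLATE_AREAS[reg$segment]),
                         stringsAsFactors = FALSE)
  net <- vascular_network(
    nodes, segments, sections,
    inlets = c("in_ccaL", "in_ccaR", "in_vaL", "in_vaR"),
    outlets = c("out_mcaL", "out_mcaR", "out_acaL", "out_acaR",
                "out_pcaL", "out_pcaR", "out_scaL", "out_scaR"))
  ## impose the nominal angle registry values on the chord directions
  net <- .apply_geometry(net, angles = .TEMPLATE_ANGLES)
  if (!is.null(group)) {
    if (is.null(params)) params <- default_group_params()
    net <- .apply_group_means(net, params, group)
  }
  net
}

## Rotate segment `rot` at its junction with `anchor` so that the angle
## between their into-vessel directions is `degrees`. The rotation stays in
## the plane spanned by the two current directions.
.set_vessel_angle <- function(net, pair_index, degrees) {
  if (degrees <= 0 || degrees >= 180)
    stop("angle must lie strictly inside (0, 180) degrees")
  a <- net$angles[net$angles$index == pair_index, ]
  rot_name <- .ANGLE_ROTATE[[as.character(pair_index)]]
  anchor_name <- setdiff(c(a$seg_a, a$seg_b), rot_name)
  ia <- which(net$segments$name == anchor_name)
  ib <- which(net$segments$name == rot_name)
  sg <- net$segments
  shared <- intersect(c(sg$from[ia], sg$to[ia]), c(sg$from[ib], sg$to[ib]))[1]
  u <- .dir_at(net, ia, shared)
  v <- .dir_at(net, ib, shared)
  w <- v - sum(v * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) {                      # collinear: pick any orthogonal
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- w - sum(w * u) * u
    nw <- sqrt(sum(w^2))
  }
  th <- degrees * pi / 180
  vnew <- cos(th) * u + sin(th) * (w / nw)
  end <- if (sg$from[ib] == shared) "f" else "t"
  net$segments[ib, paste0("d", end, c("x", "y", "z"))] <- vnew
  net
}

## apply named section areas (by index) and/or angles (by pair index)
.apply_geometry <- function(net, areas = NULL, angles = NULL) {
  if (!is.null(areas)) {
    idx <- as.integer(names(areas))
    net$sections$area[match(idx, net$sections$index)] <- unname(areas)
    ## segment lumen = mean of its planes (conductance uses segment area)
    for (s in unique(net$sections$segment_id[net$sections$index %in% idx])) {
      net$segments$area[net$segments$id == s] <-
        mean(net$sections$area[net$sections$segment_id == s])
    }
  }
  if (!is.null(angles)) {
    for (k in .ANGLE_ORDER) {
      key <- as.character(k)
      if (key %in% names(angles))
        net <- .set_vessel_angle(net, k, angles[[key]])
    }
  }
  net
}

## set template geometry to a group's mean values from the parameter table
.apply_group_means <- function(net, params, group) {
  rows <- params[params$group == group & params$mode == "any", ]
  ar <- rows[grepl("^area_S", rows$feature), ]
  areas <- setNames(ar$mean, sub("^area_S", "", ar$feature))
  an <- rows[grepl("^angle_", rows$feature), ]
  angles <- setNames(an$mean, sub("^angle_", "", an$feature))
  .apply_geometry(net, areas = areas, angles = angles)
}
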