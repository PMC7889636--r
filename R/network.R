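#' Construct a vascular network
#'
#' A directed graph of straight vessel segments with endpoint direction
#' vectors, a registry of cross-section planes, and a registry of the seven
#' named bifurcation-angle pairs. Coordinates are 3D Cartesian in mm;
#' centerline curvature is folded into `length`, so stored lengths may exceed
#' chord lengths and stored endpoint directions (unit vectors pointing from
#' the endpoint node *into* the vessel) are authoritative for angles.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z`, `kind`
#'   (`junction`, `inlet` or `outlet`).
#' @param segments data.frame with columns `id`, `name`, `from`, `to`,
#'   `length` (mm), `area` (mm^2); optional direction columns
#'   `dfx,dfy,dfz,dtx,dty,dtz`. Missing lengths/directions are filled from
#'   node positions (straight chords).
#' @param sections data.frame with columns `index` (1..22), `segment_id`,
#'   `position` (fraction in `[0,1]` along the segment) and `area` (mm^2).
#' @param inlets,outlets character vectors of terminal node ids; `outlets`
#'   order is meaningful (outlet 1 is the solver's pressure reference).
#' @param angles data.frame with columns `index` (1..7), `seg_a`, `seg_b`
#'   (segment names). Defaults to [default_angle_registry()]; `NULL` for a
#'   network without a bifurcation-angle registry.
#' @return object of class `vascular_network`.
#' @seealso [validate_network()], [cow_template()]
#' @export
vascular_network <- function(nodes, segments, sections, inlets, outlets,
                             angles = default_angle_registry()) {
  if (is.null(angles))
    angles <- data.frame(index = integer(), seg_a = character(),
                         seg_b = character(), stringsAsFactors = FALSE)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  sections <- as.data.frame(sections, stringsAsFactors = FALSE)
  pos <- function(id) {
    i <- match(id, nodes$id)
    cbind(nodes$x[i], nodes$y[i], nodes$z[i])
  }
  chord <- pos(segments$to) - pos(segments$from)
  clen <- sqrt(rowSums(chord^2))
  if (is.null(segments$length)) segments$length <- clen
  segments$length[is.na(segments$length)] <- clen[is.na(segments$length)]
  if (is.null(segments$dfx)) {
    u <- chord / clen
    segments$dfx <- u[, 1]; segments$dfy <- u[, 2]; segments$dfz <- u[, 3]
    segments$dtx <- -u[, 1]; segments$dty <- -u[, 2]; segments$dtz <- -u[, 3]
  }
  structure(list(schema = "cowhemo-net-1", nodes = nodes, segments = segments,
                 sections = sections, inlets = as.character(inlets),
                 outlets = as.character(outlets),
                 angles = as.data.frame(angles, stringsAsFactors = FALSE)),
            class = "vascular_network")
}

#' The canonical bifurcation-angle registry
#'
#' Seven ordered pairs of segment names: 1 ACA_L-MCA_L, 2 ACA_R-MCA_R,
#' 3 ACA_L-PcoA_L, 4 ACA_R-PcoA_R, 5 ICA_L-PcoA_L, 6 ICA_R-PcoA_R,
#' 7 PCA_L-PCA_R.
#' @return data.frame with columns `index`, `seg_a`, `seg_b`.
#' @export
default_angle_registry <- function() {
  data.frame(
    index = 1:7,
    seg_a = c("ACA_L", "ACA_R", "ACA_L", "ACA_R", "ICA_L", "ICA_R", "PCA_L"),
    seg_b = c("MCA_L", "MCA_R", "PcoA_L", "PcoA_R", "PcoA_L", "PcoA_R", "PCA_R"),
    stringsAsFactors = FALSE)
}

.node_degree <- function(net) {
  tab <- table(c(net$segments$from, net$segments$to))
  deg <- setNames(rep(0L, nrow(net$nodes)), net$nodes$id)
  deg[names(tab)] <- as.integer(tab)
  deg
}

## the single segment attached to a degree-1 terminal node
.terminal_segment <- function(net, node_id) {
  hit <- which(net$segments$from == node_id | net$segments$to == node_id)
  if (length(hit) != 1L)
    stop("node '", node_id, "' is not a degree-1 terminal")
  hit
}

## direction (unit 3-vector) of segment row `i` at node `node_id`,
## pointing from the node into the vessel
.dir_at <- function(net, i, node_id) {
  s <- net$segments[i, ]
  if (s$from == node_id) c(s$dfx, s$dfy, s$dfz)
  else if (s$to == node_id) c(s$dtx, s$dty, s$dtz)
  else stop("segment '", s$id, "' does not touch node '", node_id, "'")
}

#' Validate a vascular network
#'
#' Diagnostic check of all structural invariants: unique ids, positive
#' lengths and areas, unit direction vectors, section indices within 1..22
#' referencing existing segments, degree-1 inlet/outlet terminals, graph
#' connectivity, and angle-registry pairs sharing a junction node.
#'
#' @param net a `vascular_network`.
#' @return character vector of violation descriptions; empty if the network
#'   is well formed.
#' @export
validate_network <- function(net) {
  v <- character()
  say <- function(...) v[[length(v) + 1L]] <<- paste0(...)
  nd <- net$nodes; sg <- net$segments; sc <- net$sections
  if (anyDuplicated(nd$id)) say("duplicate node ids")
  if (anyDuplicated(sg$id)) say("duplicate segment ids")
  if (anyDuplicated(sc$index)) say("duplicate section indices")
  bad <- setdiff(c(sg$from, sg$to), nd$id)
  if (length(bad)) say("segment endpoint references unknown node(s): ",
                       paste(bad, collapse = ", "))
  for (i in seq_len(nrow(sg))) {
    if (!is.finite(sg$length[i]) || sg$length[i] <= 0)
      say("segment '", sg$id[i], "' has non-positive length")
    if (!is.finite(sg$area[i]) || sg$area[i] <= 0)
      say("segment '", sg$id[i], "' has non-positive area")
    for (nrm in list(c(sg$dfx[i], sg$dfy[i], sg$dfz[i]),
                     c(sg$dtx[i], sg$dty[i], sg$dtz[i])))
      if (abs(sqrt(sum(nrm^2)) - 1) > 1e-9)
        say("segment '", sg$id[i], "' direction is not a unit vector")
  }
  for (i in seq_len(nrow(sc))) {
    if (!(sc$index[i] %in% 1:22))
      say("section index ", sc$index[i], " out of range 1..22")
    if (!(sc$segment_id[i] %in% sg$id))
      say("section ", sc$index[i], " references unknown segment '",
          sc$segment_id[i], "'")
    if (sc$position[i] < 0 || sc$position[i] > 1)
      say("section ", sc$index[i], " position outside [0,1]")
    if (!is.finite(sc$area[i]) || sc$area[i] <= 0)
      say("section ", sc$index[i], " has non-positive area")
  }
  if (length(net$inlets) < 1L) say("network has no inlets")
  if (length(net$outlets) < 1L) say("network has no outlets")
  deg <- .node_degree(net)
  for (t in c(net$inlets, net$outlets)) {
    if (!t %in% nd$id) say("terminal '", t, "' is not a node")
    else if (deg[[t]] != 1L) say("terminal '", t, "' has degree ", deg[[t]],
                                 " (must be 1)")
  }
  ## connectivity (undirected BFS)
  if (nrow(sg) && nrow(nd)) {
    adj <- split(c(sg$to, sg$from), c(sg$from, sg$to))
    seen <- nd$id[1]; frontier <- seen
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) < nrow(nd)) say("graph is not connected")
  }
  ## angle registry: absent entirely, or the full 7-pair set
  if (!(nrow(net$angles) %in% c(0L, 7L)))
    say("angle registry must have exactly 7 entries")
  for (i in seq_len(nrow(net$angles))) {
    a <- net$angles[i, ]
    ia <- which(sg$name == a$seg_a); ib <- which(sg$name == a$seg_b)
    if (length(ia) != 1L || length(ib) != 1L) {
      say("angle ", a$index, " references unknown segment name(s)")
      next
    }
    shared <- intersect(c(sg$from[ia], sg$to[ia]), c(sg$from[ib], sg$to[ib]))
    if (!length(shared))
      say("angle ", a$index, " segments do not share a junction node")
  }
  v
}

#' Bifurcation angle between two vessels
#'
#' The angle between the direction vectors of the two registered segments at
#' their shared junction node (each direction points from the junction into
#' its vessel), in degrees.
#'
#' @param net a `vascular_network`.
#' @param pair_index angle registry index, 1..7.
#' @return angle in degrees, in `[0, 180]`.
#' @export
vessel_angle <- function(net, pair_index) {
  a <- net$angles[net$angles$index == pair_index, ]
  if (nrow(a) != 1L) stop("unknown angle pair index ", pair_index)
  ia <- which(net$segments$name == a$seg_a)
  ib <- which(net$segments$name == a$seg_b)
  if (length(ia) != 1L || length(ib) != 1L)
    stop("angle ", pair_index, ": segment names not found in network")
  sg <- net$segments
  shared <- intersect(c(sg$from[ia], sg$to[ia]), c(sg$from[ib], sg$to[ib]))
  if (!length(shared))
    stop("angle ", pair_index, ": segments '", a$seg_a, "' and '", a$seg_b,
         "' do not share a node")
  u <- .dir_at(net, ia, shared[1]); w <- .dir_at(net, ib, shared[1])
  cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Cross-section plane lumen area
#'
#' @param net a `vascular_network`.
#' @param index section plane index, 1..22.
#' @return orthogonal lumen area at that plane, mm^2.
#' @export
section_area <- function(net, index) {
  i <- match(index, net$sections$index)
  if (is.na(i)) stop("unknown section index ", index)
  net$sections$area[i]
}

#' Equivalent circular radius of a lumen area
#'
#' @param area lumen area, mm^2 (> 0).
#' @return radius `sqrt(area/pi)`, mm.
#' @export
equivalent_radius <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("area must be strictly positive")
  sqrt(area / pi)
}

#' Serialize / read a vascular network as JSON
#'
#' The schema (`"cowhemo-net-1"`) stores nodes, segments (with endpoint
#' directions), section planes, ordered inlet/outlet terminal ids and the
#' angle registry; lengths in mm, areas in mm^2.
#'
#' @param net a `vascular_network`.
#' @param path file path.
#' @return `write_network_json` returns `path` invisibly;
#'   `read_network_json` returns a `vascular_network`.
#' @export
write_network_json <- function(net, path) {
  obj <- list(schema = net$schema, nodes = net$nodes, segments = net$segments,
              sections = net$sections, inlets = net$inlets,
              outlets = net$outlets, angles = net$angles)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "cowhemo-net-1"))
    stop("not a cowhemo-net-1 file: ", path)
  vascular_network(obj$nodes, obj$segments, obj$sections, obj$inlets,
                   obj$outlets, obj$angles)
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network> ", nrow(x$nodes), " nodes, ", nrow(x$segments),
      " segments, ", nrow(x$sections), " section planes; ",
      length(x$inlets), " inlets, ", length(x$outlets), " outlets\n", sep = "")
  invisible(x)
}
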