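# Fixture networks built in code, plus independent numerical oracles used
# against the package's own implementations.

# straight tube: one inlet, one outlet, section planes at 0.25 and 0.75
tube_network <- function(length = 10, area = 0.1256637, positions = c(0.25, 0.75)) {
  nodes <- data.frame(id = c("in", "out"),
                      x = c(0, length), y = 0, z = 0,
                      kind = c("inlet", "outlet"))
  segments <- data.frame(id = "T", name = "T", from = "in", to = "out",
                         length = length, area = area)
  sections <- data.frame(index = seq_along(positions), segment_id = "T",
                         position = positions, area = area)
  vascular_network(nodes, segments, sections, inlets = "in",
                   outlets = "out", angles = NULL)
}

# symmetric Y bifurcation: one inlet segment, two identical daughters
y_network <- function(parent_area = 0.2, daughter_area = 0.08) {
  nodes <- data.frame(
    id = c("in", "j", "o1", "o2"),
    x = c(0, 5, 9, 9), y = c(0, 0, 2, -2), z = 0,
    kind = c("inlet", "junction", "outlet", "outlet"))
  segments <- data.frame(
    id = c("P", "D1", "D2"), name = c("P", "D1", "D2"),
    from = c("in", "j", "j"), to = c("j", "o1", "o2"),
    length = c(5, 4.5, 4.5), area = c(parent_area, daughter_area,
                                      daughter_area))
  sections <- data.frame(index = 1:3, segment_id = c("P", "D1", "D2"),
                         position = 0.5,
                         area = c(parent_area, daughter_area, daughter_area))
  vascular_network(nodes, segments, sections, "in", c("o1", "o2"),
                   angles = NULL)
}

# minimal looped ring: inlet feeder, two arcs, a communicating cross
# branch, one outlet (5 segments, one independent cycle)
ring5_network <- function() {
  nodes <- data.frame(
    id = c("in", "a", "b", "c", "out"),
    x = c(-4, 0, 2, 2, 6), y = c(0, 0, 2, -2, 2), z = 0,
    kind = c("inlet", "junction", "junction", "junction", "outlet"))
  segments <- data.frame(
    id = c("F", "AB", "AC", "BC", "BO"),
    name = c("F", "AB", "AC", "BC", "BO"),
    from = c("in", "a", "a", "b", "b"),
    to = c("a", "b", "c", "c", "out"),
    length = c(4, 3, 3.5, 2, 4.2),
    area = c(0.12, 0.06, 0.05, 0.03, 0.09))
  sections <- data.frame(index = 1, segment_id = "F", position = 0.5,
                         area = 0.12)
  vascular_network(nodes, segments, sections, "in", "out", angles = NULL)
}

# random perturbation of the CoW template (valid by construction)
random_cow_network <- function(seed) {
  set.seed(seed)
  net <- cow_template()
  net$segments$area <- net$segments$area * runif(nrow(net$segments), 0.7, 1.3)
  net$segments$length <- net$segments$length * runif(nrow(net$segments), 0.8, 1.2)
  for (i in seq_len(nrow(net$sections))) {
    seg <- net$sections$segment_id[i]
    net$sections$area[i] <- net$segments$area[net$segments$id == seg]
  }
  net
}

random_inlet_velocities <- function(net, seed) {
  set.seed(seed + 1)
  setNames(runif(length(net$inlets), 3, 20), net$inlets)
}

# --- independent Bessel oracles (integral representations, Simpson rule) ---
# J0(z) = (1/pi) Int_0^pi cos(z sin h) dh ; J1(z) = (1/pi) Int_0^pi
# cos(h - z sin h) dh. Valid for complex z; 4000 panels is far beyond the
# accuracy needed at |z| <= 6.
.simpson <- function(f, a, b, n = 4000) {
  h <- (b - a) / n
  xs <- a + h * (0:n)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(w * f(xs)) * h / 3
}
oracle_J0 <- function(z) .simpson(function(h) cos(z * sin(h)), 0, pi) / pi
oracle_J1 <- function(z) .simpson(function(h) cos(h - z * sin(h)), 0, pi) / pi

# independent Womersley bracket 1 - 2 J1(L)/(L J0(L)) from the oracles
oracle_womersley_factor <- function(alpha) {
  L <- complex(modulus = alpha, argument = 3 * pi / 4)
  1 - 2 * oracle_J1(L) / (L * oracle_J0(L))
}

# conversion constant shared by hand-computed expectations
PA_PER_MMHG <- 133.322387415
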