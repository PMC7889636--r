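test_that("segment conductance matches the Hagen-Poiseuille closed form", {
  blood <- blood_properties(mu_mPas = 3.5)
  r <- 0.2; L <- 10
  seg <- list(area = pi * r^2, length = L)
  # hand conversion: pi r^4 / (8 mu L) in mm^3/s per Pa, times Pa per mmHg
  expected <- pi * r^4 / (8 * 3.5e-3 * L) * PA_PER_MMHG
  expect_equal(segment_conductance(seg, blood), expected, tolerance = 1e-12)

  # series law: two identical tubes in series -> half the conductance
  expect_equal(segment_conductance(list(area = pi * r^2, length = 2 * L), blood),
               expected / 2, tolerance = 1e-12)
  # area scaling: G ~ area^2 (r^4)
  expect_equal(segment_conductance(list(area = 4 * pi * r^2, length = L), blood),
               16 * expected, tolerance = 1e-12)
})

test_that("boundary flows split inflow over outlets by area, exactly", {
  net <- y_network(parent_area = 0.2, daughter_area = 0.08)
  bf <- boundary_flows(net, c(`in` = 10))
  expect_equal(unname(bf$inlet), 10 * 10 * 0.2)   # v A, cm/s -> mm/s
  expect_equal(unname(bf$outlet), c(10, 10))      # equal areas: 50/50
  expect_identical(sum(bf$inlet), sum(bf$outlet)) # exact balance

  # 2:1 outlet areas -> 2/3 : 1/3
  net$segments$area[net$segments$id == "D1"] <- 0.16
  bf <- boundary_flows(net, c(`in` = 10))
  expect_equal(unname(bf$outlet / sum(bf$outlet)), c(2, 1) / 3,
               tolerance = 1e-12)

  expect_error(boundary_flows(net, c(`in` = -1)), "positive")
  expect_error(boundary_flows(net, c(bogus = 10)), "missing inlet")
})

test_that("a single tube reproduces the Poiseuille pressure drop", {
  net <- tube_network(length = 10, area = pi * 0.2^2)
  blood <- blood_properties()
  st <- solve_steady(net, c(`in` = 10), blood)
  Q <- unname(st$flows["T"])
  G <- segment_conductance(net$segments[1, ], blood)
  dP <- st$pressures[["in"]] - st$pressures[["out"]]
  expect_equal(dP, Q / G, tolerance = 1e-12)
  expect_equal(Q, 10 * 10 * pi * 0.2^2, tolerance = 1e-12)
})

test_that("a symmetric bifurcation splits flow equally", {
  st <- solve_steady(y_network(), c(`in` = 8))
  expect_equal(unname(st$flows["D1"]), unname(st$flows["D2"]),
               tolerance = 1e-12)
  expect_equal(unname(st$flows["P"]),
               unname(st$flows["D1"] + st$flows["D2"]), tolerance = 1e-12)
})

test_that("the looped ring matches a hand-assembled nodal system", {
  net <- ring5_network()
  blood <- blood_properties()
  st <- solve_steady(net, c(`in` = 10), blood)

  # independent assembly: unknown pressures at in, a, b, c (out grounded);
  # conductances computed directly from the closed form
  g <- sapply(1:5, function(i) {
    r <- sqrt(net$segments$area[i] / pi)
    pi * r^4 / (8 * blood$mu_Pa_s * net$segments$length[i]) * PA_PER_MMHG
  })
  names(g) <- net$segments$id
  Qin <- 10 * 10 * 0.12
  # order: in, a, b, c
  A <- rbind(
    c(g["F"], -g["F"], 0, 0),
    c(-g["F"], g["F"] + g["AB"] + g["AC"], -g["AB"], -g["AC"]),
    c(0, -g["AB"], g["AB"] + g["BC"] + g["BO"], -g["BC"]),
    c(0, -g["AC"], -g["BC"], g["AC"] + g["BC"]))
  b <- c(Qin, 0, 0, 0)
  p <- unname(solve(A, b))
  q_exp <- c(F = g[["F"]] * (p[1] - p[2]),
             AB = g[["AB"]] * (p[2] - p[3]),
             AC = g[["AC"]] * (p[2] - p[4]),
             BC = g[["BC"]] * (p[3] - p[4]),
             BO = g[["BO"]] * p[3])
  expect_equal(unname(st$flows[names(q_exp)]), unname(q_exp),
               tolerance = 1e-10)
})

test_that("acyclic networks carry combinatorially determined flows", {
  # Y tree: daughter flows are fixed by the outlet split alone
  net <- y_network(parent_area = 0.2, daughter_area = 0.08)
  net$segments$area[net$segments$id == "D1"] <- 0.24  # asymmetric areas
  bf <- boundary_flows(net, c(`in` = 12))
  st <- solve_steady(net, c(`in` = 12))
  expect_equal(unname(st$flows["P"]), unname(sum(bf$inlet)), tolerance = 1e-12)
  expect_equal(unname(st$flows["D1"]), unname(bf$outlet["o1"]),
               tolerance = 1e-12)
  expect_equal(unname(st$flows["D2"]), unname(bf$outlet["o2"]),
               tolerance = 1e-12)
})

test_that("the steady model is linear in the inlet velocities", {
  net <- cow_template()
  v <- c(in_ccaL = 12, in_ccaR = 11, in_vaL = 7, in_vaR = 6)
  s1 <- solve_steady(net, v)
  s3 <- solve_steady(net, 3 * v)
  expect_equal(unname(s3$flows), unname(3 * s1$flows), tolerance = 1e-9)
  expect_equal(unname(s3$pressures), unname(3 * s1$pressures),
               tolerance = 1e-9)
})

test_that("narrowing an ICA never lowers the pressure drop across it", {
  v <- c(in_ccaL = 12, in_ccaR = 12, in_vaL = 7, in_vaR = 7)
  drop_for <- function(scale) {
    net <- cow_template()
    i <- which(net$segments$id == "ICA_R")
    net$segments$area[i] <- net$segments$area[i] * scale
    st <- solve_steady(net, v)
    st$pressures[[net$segments$from[i]]] - st$pressures[[net$segments$to[i]]]
  }
  drops <- vapply(c(1, 0.8, 0.6, 0.4, 0.25), drop_for, 0)
  expect_true(all(diff(drops) > 0))
})

test_that("outlet lengthening is local: only the extended outlets' pressures move", {
  net <- cow_template()
  v <- c(in_ccaL = 12, in_ccaR = 12, in_vaL = 7, in_vaR = 7)
  base <- solve_steady(net, v)
  ext <- lengthen_outlets(net, c("out_scaL", "out_scaR"), 1)
  expect_equal(ext$segments$length[ext$segments$id == "SCA_L"],
               net$segments$length[net$segments$id == "SCA_L"] + 1)
  # identity at zero extension
  expect_equal(lengthen_outlets(net, "out_scaL", 0)$segments$length,
               net$segments$length)
  expect_error(lengthen_outlets(net, "j_bat", 1), "not an outlet")

  st <- solve_steady(ext, v)
  # boundary flows are area-determined, so flows are unchanged ...
  expect_equal(unname(st$flows), unname(base$flows), tolerance = 1e-9)
  # ... and only the SCA outlet pressures change
  moved <- abs(st$pressures - base$pressures) > 1e-9
  expect_setequal(names(st$pressures)[moved], c("out_scaL", "out_scaR"))
})
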