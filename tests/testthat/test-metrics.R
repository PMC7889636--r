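test_that("sectional mass flow is rho v A with the right units and sign", {
  # uniform v = 10 cm/s over A = 0.1 mm^2, rho = 1.05 mg/mm^3 -> 10.5 mg/s
  net <- tube_network(length = 10, area = 0.1)
  blood <- blood_properties()
  st <- solve_steady(net, c(`in` = 10), blood)
  expect_equal(mass_flow(st, net, 1, blood), 10.5, tolerance = 1e-12)

  # reversing the segment orientation (the section normal) negates Q
  rev <- net
  rev$segments$from <- "out"; rev$segments$to <- "in"
  # same physical flow, but the oriented normal now points upstream
  st2 <- solve_steady(rev, c(`in` = 10), blood)
  expect_equal(mass_flow(st2, rev, 1, blood), -10.5, tolerance = 1e-12)

  # series planes on an unbranched path agree (conservation)
  expect_equal(mass_flow(st, net, 1, blood), mass_flow(st, net, 2, blood),
               tolerance = 1e-12)
})

test_that("hydraulic resistance divides pressure drop by mass flow in g/s", {
  net <- tube_network(length = 10, area = pi * 0.2^2)
  blood <- blood_properties()
  st <- solve_steady(net, c(`in` = 10), blood)
  Q <- unname(st$flows["T"])                       # mm^3/s
  G <- segment_conductance(net$segments[1, ], blood)
  # planes at 0.25 and 0.75 span half the tube; same area so the dynamic
  # head cancels and total = static drop
  R_exp <- (0.5 * Q / G) / (Q * blood$rho_g_mm3)
  expect_equal(hydraulic_resistance(st, net, 1, 2, blood), R_exp,
               tolerance = 1e-12)
  # unit sanity: dP = 1 mmHg over Q = 10 mg/s would give 100 mmHg.s/g
  expect_equal(1 / (10 / 1000), 100)
  # static and total variants agree on equal-area planes
  expect_equal(hydraulic_resistance(st, net, 1, 2, blood, kind = "static"),
               hydraulic_resistance(st, net, 1, 2, blood, kind = "total"),
               tolerance = 1e-12)
})

test_that("dead branches give missing resistances without poisoning the rest", {
  # symmetric H: two identical inlet->outlet limbs joined by a crossbar
  # that carries exactly zero flow by symmetry
  nodes <- data.frame(id = c("i1", "i2", "a", "b", "o1", "o2"),
                      x = c(0, 0, 5, 5, 10, 10),
                      y = c(1, -1, 1, -1, 1, -1), z = 0,
                      kind = c("inlet", "inlet", "junction", "junction",
                               "outlet", "outlet"))
  segs <- data.frame(id = c("L1", "L2", "X", "R1", "R2"),
                     name = c("L1", "L2", "X", "R1", "R2"),
                     from = c("i1", "i2", "a", "a", "b"),
                     to = c("a", "b", "b", "o1", "o2"),
                     length = c(5, 5, 2, 5, 5),
                     area = c(0.1, 0.1, 0.05, 0.1, 0.1))
  secs <- data.frame(index = 1:4, segment_id = c("X", "X", "L1", "R1"),
                     position = c(0.25, 0.75, 0.5, 0.5),
                     area = c(0.05, 0.05, 0.1, 0.1))
  net <- vascular_network(nodes, segs, secs, c("i1", "i2"), c("o1", "o2"),
                          angles = NULL)
  st <- solve_steady(net, c(i1 = 10, i2 = 10))
  expect_lt(abs(st$flows[["X"]]), 1e-12)
  expect_error(hydraulic_resistance(st, net, 1, 2), "zero mass flow")
  # the healthy limb is still fine
  expect_gt(hydraulic_resistance(st, net, 3, 4), 0)
})

test_that("the metric set covers the full 73-feature registry", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 73)
  expect_equal(as.integer(table(reg$kind)[c("angle", "area", "vmax", "Q", "R")]),
               c(7L, 22L, 22L, 11L, 11L))
  expect_true("R_5_6" %in% reg$feature && "Q_15_16" %in% reg$feature)

  net <- cow_template()
  v <- c(in_ccaL = 12, in_ccaR = 12, in_vaL = 7, in_vaR = 7)
  m <- compute_metric_set(solve_steady(net, v), net)
  expect_equal(nrow(m), 73)
  expect_true(all(is.finite(m$value)))
  expect_equal(m$feature, reg$feature)  # deterministic ordering

  # resistances along the flow direction are positive
  expect_true(all(m$value[m$feature %in% paste0("R_", seq(1, 21, 2), "_",
                                                seq(2, 22, 2))] > 0,
                  na.rm = TRUE))
})

test_that("metrics are invariant to node and segment relabeling order", {
  net <- cow_template()
  v <- c(in_ccaL = 12, in_ccaR = 12, in_vaL = 7, in_vaR = 7)
  m1 <- compute_metric_set(solve_steady(net, v), net)

  perm <- net
  set.seed(7)
  perm$nodes <- perm$nodes[sample(nrow(perm$nodes)), ]
  perm$segments <- perm$segments[sample(nrow(perm$segments)), ]
  perm$sections <- perm$sections[sample(nrow(perm$sections)), ]
  m2 <- compute_metric_set(solve_steady(perm, v), perm)
  expect_equal(m2$value, m1$value, tolerance = 1e-9)
})

test_that("transient metrics track steady ones within a bounded factor", {
  net <- cow_template()
  v <- c(in_ccaL = 12, in_ccaR = 12, in_vaL = 7, in_vaR = 7)
  ms <- compute_metric_set(solve_steady(net, v), net)
  mt <- compute_metric_set(solve_transient(net, v), net)
  for (f in c("R_5_6", "vmax_S1", "vmax_S15")) {
    ratio <- mt$value[mt$feature == f] / ms$value[ms$feature == f]
    expect_gt(ratio, 0.75); expect_lt(ratio, 1.35)
  }
  # mass flows are cycle averages, hence exactly the steady values
  qf <- grepl("^Q_", ms$feature)
  expect_equal(mt$value[qf], ms$value[qf], tolerance = 1e-9)
})
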