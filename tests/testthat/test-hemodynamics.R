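test_that("viscous coefficient matches closed-form Poiseuille and its scalings", {
  f <- viscous_coefficient(make_straight_vessel(3, 30, 31))
  poiseuille <- 128 * 0.0035 * 0.03 / (pi * 0.003^4) * 1e-6 / 133.322
  expect_equal(f, poiseuille, tolerance = 1e-3)
  expect_equal(f, 0.3962, tolerance = 1e-3)

  f2 <- viscous_coefficient(make_straight_vessel(3, 60, 61))
  expect_equal(f2, 2 * f, tolerance = 1e-12)

  f3 <- viscous_coefficient(make_straight_vessel(1.5, 30, 31))
  expect_equal(f3, 16 * f, tolerance = 1e-12)
})

test_that("separation coefficient follows the Young-Tsai expansion loss", {
  expect_identical(separation_coefficient(make_straight_vessel(3, 30, 31)), 0)

  s <- separation_coefficient(ref_stenosed_vessel(0.7))
  a0 <- pi / 4 * 0.003^2
  expected <- 1050 * 1.52 / (2 * a0^2) * (1 / 0.3 - 1)^2 * 1e-12 / 133.322
  expect_equal(s, expected, tolerance = 1e-3)
  expect_equal(s, 0.6522, tolerance = 1e-3)

  # depends only on reference and minimal area, not on healthy length
  long <- apply_stenosis(make_straight_vessel(3, 60, 401), stenosis_spec(30, 10, 0.7))
  expect_equal(separation_coefficient(long), s, tolerance = 1e-6)
})

test_that("pressure-drop fitting recovers the model class and matches a grid search", {
  fit <- fit_pressure_drop(quad_samples(2, 1))
  expect_equal(fit$f, 2, tolerance = 1e-9)
  expect_equal(fit$s, 1, tolerance = 1e-9)

  zero <- fit_pressure_drop(quad_samples(0, 0))
  expect_equal(c(zero$f, zero$s), c(0, 0))

  set.seed(5)
  noisy <- quad_samples(1.5, 0.8)
  noisy$pd_mmhg <- noisy$pd_mmhg + rnorm(4, 0, 0.5)
  fit <- fit_pressure_drop(noisy)
  # independent oracle: exhaustive grid search over (f, s)
  dp <- noisy$pa_mmhg - noisy$pd_mmhg
  grid <- expand.grid(f = seq(0, 4, by = 0.005), s = seq(0, 2, by = 0.005))
  rss <- vapply(seq_len(nrow(grid)), function(i) {
    sum((dp - grid$f[i] * noisy$flow_mls - grid$s[i] * noisy$flow_mls^2)^2)
  }, 0)
  best <- grid[which.min(rss), ]
  expect_equal(fit$f, best$f, tolerance = 0.005)
  expect_equal(fit$s, best$s, tolerance = 0.005)

  one_flow <- quad_samples(2, 1, flows = c(3, 3, 3))
  expect_error(fit_pressure_drop(one_flow), class = "smartffr_invalid_argument")
})

test_that("Murray's law splits flow with the cube of the diameter ratio", {
  even <- murray_split(3, 3)
  expect_identical(even$q_fraction_1, 0.5)
  expect_identical(even$q_fraction_2, 0.5)

  m <- murray_split(1, 2)
  expect_equal(m$q_fraction_2 / m$q_fraction_1, 8, tolerance = 1e-12)

  m2 <- murray_split(3, 2)
  expect_equal(m2$q_fraction_1, 27 / 35, tolerance = 1e-12)

  set.seed(9)
  for (i in 1:20) {
    d <- runif(2, 0.5, 5)
    a <- murray_split(d[1], d[2])
    b <- murray_split(d[2], d[1])
    expect_equal(a$q_fraction_1, b$q_fraction_2, tolerance = 1e-15)
    expect_equal(a$q_fraction_1 + a$q_fraction_2, 1, tolerance = 1e-12)
  }
  expect_error(murray_split(0, 2), class = "smartffr_invalid_argument")
})

test_that("the single-vessel protocol is internally consistent with its quadratic law", {
  # healthy tube: only the small Poiseuille drop, ratio ~1 at every step
  tube <- make_straight_vessel(3, 30, 31)
  healthy <- run_single_vessel_protocol(tube)
  f0 <- viscous_coefficient(tube)
  expect_equal(healthy$pd_mmhg / healthy$pa_mmhg, 1 - f0 * (1:4) / 100,
               tolerance = 1e-12)
  expect_true(all(healthy$pd_mmhg / healthy$pa_mmhg > 0.98))

  seg <- ref_stenosed_vessel(0.7)
  model <- segment_pressure_drop_model(seg)
  samples <- run_single_vessel_protocol(seg)
  expect_equal(samples$pa_mmhg - samples$pd_mmhg,
               delta_p(model, samples$flow_mls), tolerance = 1e-12)
  expect_equal(samples$pa_mmhg, rep(100, 4))

  # near-occlusive lesion: drop exceeds 100 mmHg, distal pressure clamps at 0
  severe <- ref_stenosed_vessel(0.97)
  s_samples <- run_single_vessel_protocol(severe)
  expect_equal(s_samples$pd_mmhg[4], 0)
  expect_equal(s_samples$pd_mmhg[4] / s_samples$pa_mmhg[4], 0)
})

test_that("pressure drop grows with flow, severity and length", {
  set.seed(13)
  for (i in 1:10) {
    d <- runif(1, 2, 4)
    len <- runif(1, 20, 50)
    sas <- sort(runif(3, 0.1, 0.9))
    drops <- vapply(sas, function(sa) {
      seg <- apply_stenosis(make_straight_vessel(d, len, 201),
                            stenosis_spec(len / 2, min(10, len / 3), sa))
      delta_p(segment_pressure_drop_model(seg), 4)
    }, 0)
    expect_true(all(diff(drops) > 0))

    seg <- apply_stenosis(make_straight_vessel(d, len, 201),
                          stenosis_spec(len / 2, min(10, len / 3), sas[2]))
    model <- segment_pressure_drop_model(seg)
    q <- sort(runif(4, 0, 8))
    expect_true(all(diff(delta_p(model, q)) >= 0))

    longer <- apply_stenosis(make_straight_vessel(d, len * 2, 401),
                             stenosis_spec(len, min(10, len / 3), sas[2]))
    expect_gt(delta_p(segment_pressure_drop_model(longer), 4), drops[2])
  }
})

test_that("the bifurcation protocol conserves flow and pressure continuity", {
  tree <- symmetric_tree(sa = 0.5)
  out <- run_bifurcation_protocol(tree)
  expect_named(out, c("LAD", "LCx"))
  # even split: each branch sees exactly 1,2,3,4 ml/s out of totals 2,4,6,8
  expect_equal(out$LAD$flow_mls, c(1, 2, 3, 4))
  expect_identical(out$LAD$flow_mls + out$LCx$flow_mls, c(2, 4, 6, 8))

  parent_model <- segment_pressure_drop_model(tree$segments$LM)
  expect_equal(out$LAD$pa_mmhg, 100 - delta_p(parent_model, c(2, 4, 6, 8)),
               tolerance = 1e-12)
  expect_identical(out$LAD$pa_mmhg, out$LCx$pa_mmhg)

  # 3 mm vs 2 mm branches: Murray fractions 27/35 and 8/35 of the total
  tree2 <- coronary_tree(
    segments = list(LM = make_straight_vessel(3.5, 20, 101),
                    D1 = make_straight_vessel(3, 30, 101),
                    D2 = make_straight_vessel(2, 30, 101)),
    root = "LM", children = list(LM = c("D1", "D2"))
  )
  out2 <- run_bifurcation_protocol(tree2)
  expect_equal(out2$D1$flow_mls[4], 8 * 27 / 35, tolerance = 1e-6)
  expect_equal(out2$D2$flow_mls[4], 8 * 8 / 35, tolerance = 1e-6)
  expect_identical(out2$D1$flow_mls + out2$D2$flow_mls, c(2, 4, 6, 8))

  chain <- coronary_tree(
    segments = list(a = make_straight_vessel(3, 30, 11),
                    b = make_straight_vessel(3, 30, 11)),
    root = "a", children = list(a = "b")
  )
  expect_error(run_bifurcation_protocol(chain), class = "smartffr_unsupported_topology")
})
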