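test_that("heading updates encode the compass with the configured noise", {
  h <- update_heading(pi / 2, 0)
  expect_equal(phasor_decode(h$tb1)$angle, pi / 2, tolerance = 1e-12)
  expect_equal(h$kappa, pi / 2)

  set.seed(7); a <- replicate(5, update_heading(1, 0.2)$kappa)
  set.seed(7); b <- replicate(5, update_heading(1, 0.2)$kappa)
  expect_identical(a, b)

  set.seed(9)
  draws <- replicate(10000, phasor_decode(update_heading(0.3, 0.1)$tb1)$angle)
  circ_sd <- sqrt(-2 * log(Mod(mean(exp(1i * draws)))))
  expect_lt(abs(circ_sd - 0.1) / 0.1, 0.05)
})

test_that("travel direction adds egocentric drift to the heading", {
  h <- update_heading(0, 0)
  expect_equal(phasor_decode(travel_direction(h, 0, 1))$angle, 0,
               tolerance = 1e-9)
  expect_equal(phasor_decode(travel_direction(h, pi / 2, 1))$angle, pi / 2,
               tolerance = 1e-9)
  set.seed(13)
  for (i in 1:200) {
    kap <- runif(1, -pi, pi); drift <- runif(1, -pi, pi); sp <- runif(1, 0, 2)
    tv <- travel_direction(update_heading(kap, 0), drift, sp)
    expect_lt(Mod(decode_z(tv) - sp * exp(1i * (kap + drift))), 1e-9)
  }
})

test_that("path integration accumulates displacement exactly without noise", {
  hv <- home_vector_state(8L, 100)
  h <- update_heading(0, 0)
  for (i in 1:10) hv <- pi_step(hv, travel_direction(h, 0, 1), 1)
  d <- home_vector(hv)
  expect_equal(d$length, 10, tolerance = 1e-9)
  expect_equal(d$angle, 0, tolerance = 1e-9)

  # closed square loop returns a zero home vector
  hv2 <- home_vector_state(8L, 100)
  for (ang in c(0, pi / 2, pi, -pi / 2))
    for (i in 1:5)
      hv2 <- pi_step(hv2, travel_direction(update_heading(ang, 0), 0, 1), 1)
  expect_lt(home_vector(hv2)$length, 1e-9)
})

test_that("long random walks match the cumulative-sum oracle", {
  set.seed(17)
  hv <- home_vector_state(8L, 10000)
  z <- 0 + 0i
  for (i in 1:10000) {
    kap <- runif(1, -pi, pi); sp <- runif(1, 0, 1.5)
    hv <- pi_step(hv, travel_direction(update_heading(kap, 0), 0, sp), 0.1)
    z <- z + sp * 0.1 * exp(1i * kap)
  }
  d <- home_vector(hv)
  expect_lt(Mod(d$length * exp(1i * d$angle) - z), 1e-6)
})

test_that("CPU4 saturation raises instead of silently clipping", {
  hv <- home_vector_state(8L, 5)
  h <- update_heading(0, 0)
  expect_error({
    for (i in 1:10) hv <- pi_step(hv, travel_direction(h, 0, 1), 1)
  }, "saturation")
})

test_that("vector memories imprint and recall the stored displacement", {
  s <- vector_memory_store(4L, 8L, 100)
  hv0 <- home_vector_state(8L, 100)
  s <- store_vector_memory(s, hv0)
  expect_equal(memory_vector(s, 1)$magnitude, 0)

  hv <- home_vector_state(8L, 100)
  hv$cpu4 <- phasor_encode(atan2(4, 3), 5, 8L, 100)
  s <- store_vector_memory(s, hv, "f1")
  m <- memory_vector(s, 2)
  expect_equal(m$angle, atan2(4, 3), tolerance = 1e-9)
  expect_equal(m$magnitude, 5, tolerance = 1e-9)

  # imprints equal CPU4 snapshots over random storage events
  set.seed(19)
  for (i in 1:100) {
    st <- vector_memory_store(1L, 8L, 100)
    ang <- runif(1, -pi, pi); len <- runif(1, 0, 50)
    hv$cpu4 <- phasor_encode(ang, len, 8L, 100)
    st <- store_vector_memory(st, hv)
    mm <- memory_vector(st, 1)
    expect_lt(Mod(mm$magnitude * exp(1i * mm$angle) - len * exp(1i * ang)),
              1e-9)
  }
})

test_that("the store refuses to evict at capacity", {
  s <- vector_memory_store(1L, 8L, 100)
  hv <- home_vector_state(8L, 100)
  s <- store_vector_memory(s, hv)
  expect_error(store_vector_memory(s, hv), "capacity")
})

test_that("goal vectors compute the direct shortcut", {
  hv <- home_vector_state(8L, 100)
  s <- vector_memory_store(2L, 8L, 100)
  hv$cpu4 <- phasor_encode(0, 3, 8L, 100)          # memory at (3, 0)
  s <- store_vector_memory(s, hv)

  # standing at the remembered location: zero goal
  g0 <- goal_vector(hv, s, 1)
  expect_lt(phasor_decode(g0)$magnitude, 1e-9)

  # from the nest the goal is the memory itself
  g1 <- goal_vector(home_vector_state(8L, 100), s, 1)
  expect_lt(Mod(decode_z(g1) - 3), 1e-9)

  # h = (3,4), m = (3,0): goal decodes to (0, -4)
  hv$cpu4 <- phasor_encode(atan2(4, 3), 5, 8L, 100)
  g2 <- goal_vector(hv, s, 1)
  expect_lt(Mod(decode_z(g2) - (0 - 4i)), 1e-9)

  # no memory selected: homing drive is minus the home vector
  g3 <- goal_vector(hv)
  expect_lt(Mod(decode_z(g3) + (3 + 4i)), 1e-9)
})

test_that("shortcut identity holds for random home vectors and memories", {
  set.seed(23)
  for (i in 1:1000) {
    hv <- home_vector_state(8L, 100)
    s <- vector_memory_store(1L, 8L, 100)
    m_ang <- runif(1, -pi, pi); m_len <- runif(1, 0, 40)
    hv$cpu4 <- phasor_encode(m_ang, m_len, 8L, 100)
    s <- store_vector_memory(s, hv)
    h_ang <- runif(1, -pi, pi); h_len <- runif(1, 0, 40)
    hv$cpu4 <- phasor_encode(h_ang, h_len, 8L, 100)
    g <- decode_z(goal_vector(hv, s, 1))
    expect_lt(Mod(g + h_len * exp(1i * h_ang) - m_len * exp(1i * m_ang)),
              1e-9)
  }
})

test_that("the left/right comparator splits by the sign of the goal bearing", {
  goal_ahead <- phasor_encode(0, 1, 8L, 1)
  r0 <- internal_lr_reward(0, goal_ahead, "binary")
  expect_equal(c(r0$r_left, r0$r_right), c(0, 0))

  goal_left <- phasor_encode(pi / 2, 1, 8L, 1)
  rb <- internal_lr_reward(0, goal_left, "binary")
  expect_equal(c(rb$r_left, rb$r_right), c(1, 0))
  rg <- internal_lr_reward(0, goal_left, "graded")
  expect_equal(c(rg$r_left, rg$r_right), c(1, 0))

  # 1-degree sweep: exactly one channel active except straight ahead/behind
  for (deg in seq(-179, 180)) {
    delta <- deg * pi / 180
    r <- internal_lr_reward(0, phasor_encode(delta, 1, 8L, 1), "binary")
    if (deg %in% c(0, 180)) {
      expect_equal(r$r_left + r$r_right, 0)
    } else {
      expect_equal(r$r_left + r$r_right, 1)
      expect_equal(r$r_left > 0, deg > 0)
    }
  }

  # undefined goal yields no reward
  rz <- internal_lr_reward(1, phasor_encode(0, 0, 8L, 1))
  expect_equal(c(rz$r_left, rz$r_right), c(0, 0))
})

test_that("compass noise degrades the home vector sublinearly in path length", {
  set.seed(29)
  lengths <- c(30, 100, 300, 1000)
  err <- sapply(lengths, function(L) {
    mean(replicate(20, {
      hv <- home_vector_state(8L, 1e5)
      for (i in seq_len(L))
        hv <- pi_step(hv, travel_direction(update_heading(0, 0.1), 0, 1), 1)
      abs(wrap_angle(home_vector(hv)$angle - 0))
    }))
  })
  slope <- stats::coef(stats::lm(log(err) ~ log(lengths)))[2]
  expect_lt(slope, 0.5)
})
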