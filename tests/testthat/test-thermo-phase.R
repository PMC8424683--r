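test_that("weight/mole conversion reproduces the reference compositions and round-trips", {
  # certified molar masses: EZB 409.4, SVT 418.6, FEN 360.83 g/mol
  expect_equal(round(weight_to_mole(c(0.10, 0.90), c(409.4, 360.83))[1], 3),
               0.089)
  expect_equal(round(weight_to_mole(c(0.20, 0.80), c(418.6, 360.83))[1], 3),
               0.177)
  # symmetry: equal masses, equal molar mass
  expect_equal(weight_to_mole(c(0.5, 0.5), c(200, 200)), c(0.5, 0.5))

  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    w <- stats::runif(k); w <- w / sum(w)
    mm <- stats::runif(k, 100, 700)
    expect_equal(mole_to_weight(weight_to_mole(w, mm), mm), w,
                 tolerance = 1e-12)
  }
  expect_error(weight_to_mole(c(0.5, 0.5), c(-1, 200)), "positive")
  expect_error(weight_to_mole(c(0.6, 0.6), c(100, 200)), "sum to 1")
})

test_that("SVL liquidus matches a bisection oracle and is monotone", {
  cmp <- pure_component("A", 300, 400, 25000)
  expect_equal(svl_liquidus(1, cmp), 400)
  # independent oracle: bisection on ln x + (dH/R)(1/T - 1/T0) = 0
  for (x in c(0.9, 0.5, 0.2, 0.05)) {
    oracle <- stats::uniroot(
      function(T) log(x) + 25000 / 8.314 * (1 / T - 1 / 400),
      c(50, 400), tol = 1e-12)$root
    expect_equal(svl_liquidus(x, cmp), oracle, tolerance = 1e-9)
  }
  xs <- seq(0.01, 1, length.out = 200)
  expect_true(all(diff(svl_liquidus(xs, cmp)) > 0))
  expect_error(svl_liquidus(0, cmp), "\\(0, 1\\]")
  # extreme dilution: the ideal liquidus stays positive but collapses
  expect_lt(svl_liquidus(1e-300, cmp), 10)
})

test_that("binary eutectic solver agrees with the dense grid oracle", {
  A <- pure_component("A", 300, 400, 25000)
  B <- pure_component("B", 300, 350, 20000)
  e <- binary_eutectic(A, B)
  o <- grid_binary_eutectic(A, B)
  expect_lt(abs(e$x_e - o$x_e), o$spacing)
  expect_lt(e$T_e, 350)
  expect_lt(e$residual_K, 1e-6)
  # identical components: symmetry
  es <- binary_eutectic(A, pure_component("A2", 300, 400, 25000))
  expect_equal(es$x_e, 0.5, tolerance = 1e-9)
})

test_that("ternary eutectic solver matches the barycentric grid oracle", {
  set.seed(21)
  A <- random_component("A"); B <- random_component("B")
  C <- random_component("C")
  t3 <- ternary_eutectic(A, B, C, surface = FALSE)
  o <- grid_ternary_eutectic(A, B, C)
  if (o$boundary) expect_lte(t3$T_e, o$T_e + 1e-9) else
    expect_true(all(abs(t3$x_e - o$x_e) <= o$spacing))
  expect_lt(t3$residual_K, 1e-6)
  # three identical components: symmetric eutectic
  mk <- function(n) pure_component(n, 300, 420, 30000)
  ts <- ternary_eutectic(mk("a"), mk("b"), mk("c"), surface = FALSE)
  expect_equal(ts$x_e, rep(1 / 3, 3), tolerance = 1e-9)
  # a very low-T0 / low-enthalpy component dominates the eutectic
  low <- pure_component("low", 300, 310, 11000)
  hi1 <- pure_component("h1", 300, 470, 45000)
  hi2 <- pure_component("h2", 300, 450, 40000)
  td <- ternary_eutectic(hi1, hi2, low, surface = FALSE)
  od <- grid_ternary_eutectic(hi1, hi2, low)
  if (od$boundary) expect_lte(td$T_e, od$T_e + 1e-9) else
    expect_true(all(abs(td$x_e - od$x_e) <= od$spacing))
  expect_gt(td$x_e[3], td$x_e[1])
  expect_gt(td$x_e[3], td$x_e[2])
})

test_that("liquidus surface grid takes the max branch and covers the simplex", {
  A <- pure_component("A", 300, 430, 30000)
  B <- pure_component("B", 300, 400, 25000)
  C <- pure_component("C", 300, 370, 20000)
  g <- liquidus_surface(A, B, C, resolution = 0.1)
  expect_true(all(abs(g$x1 + g$x2 + g$x3 - 1) < 1e-9))
  i <- which(abs(g$x1 - 0.5) < 1e-9 & abs(g$x2 - 0.3) < 1e-9)[1]
  expect_equal(g$T_liquidus_K[i],
               max(svl_liquidus(0.5, A), svl_liquidus(0.3, B),
                   svl_liquidus(0.2, C)))
  # pure corners melt at their own T0 under their own governance
  corner <- which(g$x1 == 1)
  expect_equal(g$T_liquidus_K[corner], 430)
  expect_equal(g$governing_component[corner], 1)
})

test_that("expected endotherm count follows the distance from the eutectic", {
  A <- pure_component("A", 300, 430, 30000)
  B <- pure_component("B", 300, 380, 24000)
  e <- binary_eutectic(A, B)
  expect_equal(expected_endotherm_count(c(e$x_e, 1 - e$x_e), list(A, B)), 1L)
  expect_equal(expected_endotherm_count(c(0.9, 0.1), list(A, B)), 2L)
  C <- pure_component("C", 300, 360, 20000)
  t3 <- ternary_eutectic(A, B, C, surface = FALSE)
  expect_equal(expected_endotherm_count(t3$x_e, list(A, B, C)), 1L)
  # both A and B well above their eutectic fractions: eutectic melt plus
  # two dissolution endotherms
  expect_equal(expected_endotherm_count(c(0.40, 0.45, 0.15),
                                        list(A, B, C)), 3L)
})

test_that("experimental diagram assembly flags the eutectic record", {
  # single-endotherm record wins outright
  rec <- data.frame(x = c(0.2, 0.4, 0.6),
                    solidus_K = c(350, 350.5, 350),
                    liquidus_K = c(365, 351.2, 372))
  a <- assemble_experimental_diagram(rec)
  expect_equal(a$eutectic$x, 0.4)
  expect_equal(a$eutectic$method, "single-endotherm")
  expect_equal(a$records$n_events, c(2L, 1L, 2L))

  # records sampled from a known SVL pair recover the eutectic within a step
  A <- pure_component("A", 300, 420, 28000)
  B <- pure_component("B", 300, 380, 22000)
  e <- binary_eutectic(A, B)
  xs <- seq(0.05, 0.95, by = 0.05)
  liq <- pmax(svl_liquidus(xs, A), svl_liquidus(1 - xs, B))
  rec2 <- data.frame(x = xs, solidus_K = e$T_e, liquidus_K = liq)
  a2 <- assemble_experimental_diagram(rec2)
  expect_lt(abs(a2$eutectic$x - e$x_e), 0.05 + 1e-9)
  expect_error(assemble_experimental_diagram(
    data.frame(x = 1:3 / 10, solidus_K = 1:3,
               liquidus_K = rep(NA_real_, 3))), "missing")
})

test_that("randomized eutectic solving respects the pairwise temperature ordering", {
  set.seed(33)
  for (i in 1:20) {
    A <- random_component(); B <- random_component(); C <- random_component()
    t3 <- ternary_eutectic(A, B, C, surface = FALSE)
    pair_T <- c(binary_eutectic(A, B)$T_e, binary_eutectic(A, C)$T_e,
                binary_eutectic(B, C)$T_e)
    expect_true(t3$T_e <= min(pair_T) + 1e-9)
    expect_true(t3$T_e <= min(A$melt_temperature, B$melt_temperature,
                              C$melt_temperature))
  }
})
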