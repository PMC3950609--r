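test_that("gating rates reproduce hand-evaluated values", {
  l <- gate_kinetics("l", -75)
  expect_equal(l$alpha, 1)
  expect_equal(l$beta, 1)
  expect_equal(l$x_inf, 0.5)

  m <- gate_kinetics("m", -30)            # removable singularity
  expect_equal(m$alpha, 6, tolerance = 1e-9)
  expect_equal(m$beta, 20 * exp(-25 / 18), tolerance = 1e-12)

  mt <- gate_kinetics("m_T", -28.8)       # exponent vanishes
  expect_equal(mt$alpha, 1 / 2.7, tolerance = 1e-12)

  # analytic limits of the other singular alphas
  expect_equal(gate_kinetics("c", -13)$alpha, 3, tolerance = 1e-9)
  expect_equal(gate_kinetics("n", -40)$alpha, 0.2, tolerance = 1e-9)
  expect_equal(gate_kinetics("a", -90)$alpha, 0.06, tolerance = 1e-9)

  expect_error(gate_kinetics("z", -60), "unknown gate")
})

test_that("x_inf and tau are continuous at singularities and the NaP branch", {
  for (spec in list(c("m", -30), c("c", -13), c("n", -40), c("a", -90),
                    c("p", -40))) {
    g <- spec[1]
    v0 <- as.numeric(spec[2])
    v <- v0 + c(-1e-7, 0, 1e-7)
    k <- gate_kinetics(g, v)
    expect_lt(max(abs(diff(k$x_inf))), 1e-6, label = paste("x_inf jump", g))
    expect_lt(max(abs(diff(k$tau))) / k$tau[2], 1e-6,
              label = paste("tau jump", g))
  }
})

test_that("gate advancement relaxes exponentially and fixes its steady state", {
  st <- steady_gating(-60)
  expect_equal(advance_gates(st, -60, 0.5), st, tolerance = 1e-12)

  st0 <- st
  st0[["l"]] <- 0
  out <- advance_gates(st0, -75, 0.5)
  # l_inf = 0.5, tau = 0.5 ms at -75: closed-form relaxation from zero
  expect_equal(out[["l"]], 0.5 * (1 - exp(-1)), tolerance = 1e-12)

  # (h_T, d) equilibrium computed independently from the rate definitions
  v <- -72.3
  ht <- gate_kinetics("h_T", v)
  dd <- gate_kinetics("d", v)
  u <- 1 / (1 + ht$alpha / ht$beta + dd$beta / dd$alpha)
  eq <- c(h_T = ht$alpha / ht$beta * u, d = dd$beta / dd$alpha * u)
  st2 <- steady_gating(v)
  expect_equal(st2[["h_T"]], eq[["h_T"]], tolerance = 1e-12)
  out2 <- advance_gates(st2, v, 0.1)
  expect_equal(out2[["h_T"]], eq[["h_T"]], tolerance = 1e-10)
  expect_equal(out2[["d"]], eq[["d"]], tolerance = 1e-10)
})

test_that("gates stay in [0,1] with h_T + d <= 1 under random clamp histories", {
  set.seed(11)
  for (rep in 1:5) {
    st <- steady_gating(-65)
    for (step in 1:200) {
      v <- runif(1, -120, 60)
      st <- advance_gates(st, v, runif(1, 0.01, 1))
      expect_true(all(st >= 0 & st <= 1))
      expect_lte(st[["h_T"]] + st[["d"]], 1 + 1e-12)
    }
  }
})

test_that("the calcium Nernst potential follows the two-valence form", {
  const <- membrane_constants()
  expect_equal(nernst_vca(1.8e-3), 0)
  rt2f <- 1000 * 8.314 * 305.15 / (2 * 9.684e4)
  expect_equal(nernst_vca(1e-7), rt2f * log(1.8e-3 / 1e-7), tolerance = 1e-12)
  expect_gt(nernst_vca(1e-7), 128)  # approximately 128.3 mV at the residual
  expect_lt(nernst_vca(1e-7), 129)
  expect_equal(nernst_vca(1.8e-4), rt2f * log(10), tolerance = 1e-12)
  expect_error(nernst_vca(0), "positive")
})

test_that("calcium dynamics relax to their closed-form fixed points", {
  const <- membrane_constants()
  expect_equal(advance_calcium(1e-7, 0, 5), 1e-7, tolerance = 1e-18)
  # pure decay with tau_Ca = 1.5 ms
  expect_equal(advance_calcium(2e-7, 0, 1.5), 1e-7 + 1e-7 * exp(-1),
               tolerance = 1e-18)
  # steady state under constant inward current (r = 1e-5 cm)
  fp <- 1e-7 + 1.5 * 3e-3 * 1e-3 / (2 * 9.684e4 * 1e-5)
  ca <- 1e-7
  for (i in 1:100) ca <- advance_calcium(ca, -1e-3, 5)
  expect_equal(ca, fp, tolerance = 1e-9)
  expect_equal(fp, 2.42e-6, tolerance = 0.01)
  # positivity for strong outward current
  expect_gt(advance_calcium(1e-9, 10, 100), 0)
})

test_that("K(Ca) activation is half-maximal at the dissociation constant", {
  expect_equal(kca_conductance(1e-6, 5e-5), 2.5e-5)
  expect_equal(kca_conductance(1e-12, 5e-5), 0, tolerance = 1e-15)
  expect_equal(kca_conductance(2e-6, 5e-5), 4e-5)
  ca <- 10^seq(-9, -4, length.out = 50)
  g <- kca_conductance(ca, 5e-5)
  expect_true(all(diff(g) > 0))
  expect_true(all(g <= 5e-5))
})

test_that("regional densities follow the distribution table", {
  tab <- distribution_table()
  triple <- c(1e-5, 1e-4, 1e-6)
  socb <- compartment_conductances(tab, "narrow_segment", TRUE, triple)
  expect_equal(socb[["na"]], 0.4)              # 5 x 0.08
  expect_equal(socb[["nap"]], 5e-5)            # 5 x g_NaP
  expect_equal(unname(socb[c("ca", "k", "ka", "kca_max")]), rep(0, 4))
  expect_equal(socb[["h"]], 1e-6)              # h uniform everywhere

  distal <- compartment_conductances(tab, "distal_axon", FALSE, triple)
  expect_equal(distal[["l"]], 25 * 8e-6)
  expect_equal(distal[["nap"]], 0.05 * 1e-5)
  expect_equal(distal[["t"]], 1e-4)

  dend <- compartment_conductances(tab, "dendrite", FALSE, triple)
  expect_equal(dend[["t"]], 5e-4)              # 5 x g_T in dendrites
  expect_equal(dend[["l"]], 15 * 8e-6)

  expect_error(compartment_conductances(tab, "axon_hillock", FALSE, triple),
               "unknown region")
})

test_that("the total membrane current matches an independent summation", {
  const <- membrane_constants()
  dens <- compartment_conductances(distribution_table(), "soma", FALSE,
                                   c(2e-5, 3e-4, 1e-6))
  # leak at its reversal with everything else off
  leak_only <- setNames(c(rep(0, 5), dens[["l"]], 0, 0, 0), names(dens))
  r <- total_ionic_current(-60, steady_gating(-60), list(ca_i = 1e-7),
                           leak_only, const)
  expect_equal(r$total, 0, tolerance = 1e-15)

  # all gating variables zero: only leak and K(Ca) survive
  zero_gates <- setNames(rep(0, 11), names(steady_gating(-60)))
  r2 <- total_ionic_current(-40, zero_gates, list(ca_i = 5e-7), dens, const)
  on <- r2$currents[abs(r2$currents) > 0]
  expect_setequal(names(on), c("l", "kca"))

  # randomized states against a term-by-term oracle written from scratch
  set.seed(4)
  for (i in 1:20) {
    v <- runif(1, -100, 50)
    g <- setNames(runif(11), names(zero_gates))
    ca <- runif(1, 1e-8, 1e-5)
    r3 <- total_ionic_current(v, g, list(ca_i = ca), dens, const)
    vca <- (1000 * 8.314 * 305.15 / (2 * 9.684e4)) * log(1.8e-3 / ca)
    y <- (ca / 1e-6)^2
    oracle <- dens[["na"]] * g[["m"]]^3 * g[["h"]] * (v - 35) +
      dens[["ca"]] * g[["c"]]^3 * (v - vca) +
      dens[["k"]] * g[["n"]]^4 * (v + 70) +
      dens[["ka"]] * g[["a"]]^3 * g[["h_A"]] * (v + 70) +
      dens[["kca_max"]] * y / (1 + y) * (v + 70) +
      dens[["l"]] * (v + 60) +
      dens[["h"]] * g[["l"]] * v +
      dens[["nap"]] * g[["p"]] * (v - 35) +
      dens[["t"]] * g[["m_T"]]^3 * g[["h_T"]] * (v - 120)
    expect_equal(r3$total, unname(oracle), tolerance = 1e-10)
  }
})
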