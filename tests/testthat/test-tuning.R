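mk_report <- function(rest, spont, step_spikes = 0, rebound = 0, c0 = TRUE) {
  structure(list(c0_pass = c0, rest_mV = rest, spont_Hz = spont,
                 spikes_during_hyp = step_spikes, rebound_rate_Hz = rebound,
                 on_pass = c0 && spont == 0 && rest >= -70 && rest <= -62 &&
                   step_spikes == 0 && rebound == 0,
                 offT_pass = c0 && spont >= 15 && spont <= 23 &&
                   rest >= -62 && rest <= -50 && step_spikes == 0 &&
                   rebound >= 2 * spont,
                 offS_pass = c0 && spont >= 40 && spont <= 48 &&
                   rest >= -62 && rest <= -50 && step_spikes == 0 &&
                   rebound >= 2 * spont),
            class = "rgc_constraint_report")
}

test_that("classification follows the constraint bands", {
  expect_equal(classify_point(mk_report(-65, 0)), "ON")
  expect_equal(classify_point(mk_report(-55, 20, rebound = 60)), "OFF_T")
  expect_equal(classify_point(mk_report(-55, 44, rebound = 90)), "OFF_S")
  expect_equal(classify_point(mk_report(-55, 30, rebound = 90)), "none")
  expect_equal(classify_point(mk_report(-55, 20, rebound = 30)), "none")
  expect_equal(classify_point(mk_report(-65, 0, c0 = FALSE)), "none")
  expect_equal(classify_point(mk_report(-58, 0)), "none")  # between bands

  # pass flags are mutually exclusive for any report
  set.seed(9)
  for (i in 1:200) {
    r <- mk_report(runif(1, -75, -45), sample(0:60, 1),
                   sample(0:2, 1), runif(1, 0, 120))
    expect_lte(r$on_pass + r$offT_pass + r$offS_pass, 1)
  }
})

test_that("point evaluation measures the phenotype of the reference cell", {
  m <- fixture_morph()
  quiet <- evaluate_point(m, c(0, 0, 0))
  expect_equal(quiet$spont_Hz, 0)
  expect_equal(quiet$spikes_during_hyp, 0)
  expect_true(quiet$c0_pass)

  offt <- evaluate_point(m, OFF_T_TRIPLE)
  expect_equal(classify_point(offt), "OFF_T")
  expect_gte(offt$spont_Hz, 15)
  expect_lte(offt$spont_Hz, 23)
  expect_gte(offt$rebound_rate_Hz, 2 * offt$spont_Hz)
  expect_gte(offt$rest_mV, -62)
  expect_lte(offt$rest_mV, -50)

  offs <- evaluate_point(m, OFF_S_TRIPLE)
  expect_equal(classify_point(offs), "OFF_S")

  # determinism: identical evaluation on replay
  offt2 <- evaluate_point(m, OFF_T_TRIPLE)
  expect_equal(offt$spont_Hz, offt2$spont_Hz)
  expect_equal(offt$rest_mV, offt2$rest_mV)
})

test_that("a dead grid is labelled none everywhere and order-independently", {
  m <- fixture_morph()
  g1 <- grid_search(m, gnap = c(0, 1e-6), gt = c(0, 1e-6), gh = 0)
  expect_true(all(g1$points$label == "none"))
  cache <- new.env()
  g2 <- grid_search(m, gnap = c(0, 1e-6), gt = c(0, 1e-6), gh = 0,
                    cache = cache)
  expect_identical(g1$points$label, g2$points$label)
  # resumed search reuses the cache without re-simulating
  t0 <- Sys.time()
  g3 <- grid_search(m, gnap = c(0, 1e-6), gt = c(0, 1e-6), gh = 0,
                    cache = cache)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_identical(g3$points$label, g1$points$label)
})

test_that("connected-set extraction equals brute-force flood fill", {
  mk_grid <- function(pts) {
    structure(list(axes = list(gnap = 1:6, gt = 1:6, gh = 1:6),
                   points = pts), class = "rgc_grid")
  }
  # two separated 2x2x2 blocks
  blk <- function(i0, j0, k0) expand.grid(i = i0 + 0:1, j = j0 + 0:1,
                                          k = k0 + 0:1)
  pts <- rbind(cbind(blk(1, 1, 1), label = "OFF_S"),
               cbind(blk(4, 4, 4), label = "OFF_S"))
  pts$gnap <- pts$i
  pts$gt <- pts$j
  pts$gh <- pts$k
  vs <- extract_valid_sets(mk_grid(pts))
  expect_length(vs$OFF_S$components, 2)
  expect_equal(vapply(vs$OFF_S$components, nrow, 1L), c(8L, 8L))
  expect_equal(nrow(vs$OFF_S$singletons), 0)
  expect_length(vs$ON$components, 0)

  # a full labelled plane is one component
  plane <- expand.grid(i = 1:5, j = 1:5, k = 3)
  plane$label <- "ON"
  plane$gnap <- plane$i
  plane$gt <- plane$j
  plane$gh <- plane$k
  vp <- extract_valid_sets(mk_grid(plane))
  expect_length(vp$ON$components, 1)
  expect_equal(nrow(vp$ON$components[[1]]), 25)

  # random labelings against an independent flood fill
  flood <- function(pts) {
    n <- nrow(pts)
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (s in seq_len(n)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        a <- queue[1]
        queue <- queue[-1]
        nb <- which(is.na(comp) &
                      abs(pts$i - pts$i[a]) + abs(pts$j - pts$j[a]) +
                      abs(pts$k - pts$k[a]) == 1)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
    comp
  }
  set.seed(13)
  for (rep in 1:5) {
    lat <- expand.grid(i = 1:4, j = 1:4, k = 1:4)
    keep <- runif(nrow(lat)) < 0.4
    pts <- lat[keep, , drop = FALSE]
    pts$label <- "OFF_T"
    pts$gnap <- pts$i
    pts$gt <- pts$j
    pts$gh <- pts$k
    vs <- extract_valid_sets(mk_grid(pts))
    comp <- flood(pts)
    sizes_oracle <- sort(as.integer(table(comp)))
    sizes_got <- sort(c(vapply(vs$OFF_T$components, nrow, 1L),
                        rep(1L, nrow(vs$OFF_T$singletons))))
    expect_equal(sizes_got, sizes_oracle)
  }
})

test_that("refinement axes span the labelled bounding box plus one coarse cell", {
  pts <- expand.grid(i = 1:4, j = 1:4, k = 1:3)
  pts$label <- "none"
  pts$label[pts$i %in% 2:3 & pts$j == 2 & pts$k == 2] <- "OFF_T"
  axes <- list(gnap = c(1e-6, 1e-5, 1e-4, 1e-3), gt = c(1e-6, 1e-5, 1e-4, 1e-3),
               gh = c(1e-9, 1e-7, 1e-5))
  pts$gnap <- axes$gnap[pts$i]
  pts$gt <- axes$gt[pts$j]
  pts$gh <- axes$gh[pts$k]
  grid <- structure(list(axes = axes, points = pts), class = "rgc_grid")
  ref <- refinement_axes(grid, n = 5)
  expect_equal(range(ref$gnap), c(1e-6, 1e-3))   # 2:3 widened to 1:4
  expect_equal(range(ref$gt), c(1e-6, 1e-4))     # 2 widened to 1:3
  expect_equal(range(ref$gh), c(1e-9, 1e-5))
  expect_length(ref$gt, 5)
  expect_true(all(diff(diff(ref$gt)) < 1e-12))   # linear spacing
  empty <- grid
  empty$points$label <- "none"
  expect_error(refinement_axes(empty), "no labelled")
})

test_that("validation runs only on OFF points and records the transition", {
  m <- fixture_morph()
  expect_error(validate_point(m, c(0, 0, 0),
                              report = mk_report(-65, 0)),
               "OFF")
  rep_off <- evaluate_point(m, OFF_S_TRIPLE)
  vr <- validate_point(m, OFF_S_TRIPLE, cv_hold_duration = 2000,
                       report = rep_off)
  expect_equal(vr$label, "OFF_S")
  expect_length(vr$v1, 7)
  expect_length(vr$v2, 7)
  # increasing hyperpolarization ends in silence, starting from firing
  expect_false(vr$v2[1] == "silent")
  expect_equal(vr$v2[7], "silent")
  expect_equal(nrow(vr$v3), 4)
  expect_true(all(diff(vr$v3$mean_vm) < 0))  # deeper steps hyperpolarize more
})

test_that("the morphology-reduction experiment reproduces the baseline at factor 1", {
  m <- fixture_morph()
  tab <- morphology_reduction_experiment(m, OFF_S_TRIPLE,
                                         targets = "dendrite_diameter",
                                         factors = c(1, 0.6))
  base <- evaluate_point(m, OFF_S_TRIPLE)
  expect_equal(tab$spont_Hz[1], base$spont_Hz)
  expect_equal(tab$rebound_rate_Hz[1], base$rebound_rate_Hz)
  # shrinking dendrites strengthens rebound bursting and sharpens spikes
  expect_gte(tab$rebound_rate_Hz[2], tab$rebound_rate_Hz[1])
  expect_gt(tab$spike_peak_mV[2], tab$spike_peak_mV[1])
  expect_gt(tab$max_dvdt[2], tab$max_dvdt[1])
})
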