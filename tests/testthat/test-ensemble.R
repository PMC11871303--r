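test_that("weighted shift follows the volume-weighted mean", {
  expect_equal(weighted_shift(data.frame(delta_H = 8.20, volume = 5)), 8.20)
  expect_equal(weighted_shift(data.frame(delta_H = c(8.0, 8.2), volume = c(1, 1))), 8.10)
  expect_equal(weighted_shift(data.frame(delta_H = c(8.0, 8.2), volume = c(3, 1))), 8.05)
  expect_error(weighted_shift(data.frame(delta_H = 8, volume = 0)), "volume")
})

test_that("weighted shift is invariant to volume scaling and peak order", {
  pk <- data.frame(delta_H = c(8.0, 8.31), volume = c(2.5, 7.1))
  expect_equal(weighted_shift(pk),
               weighted_shift(data.frame(delta_H = pk$delta_H, volume = 13 * pk$volume)))
  expect_equal(weighted_shift(pk), weighted_shift(pk[2:1, ]))
})

test_that("state populations normalise labeled volumes", {
  expect_equal(state_populations(data.frame(state = c("rep", "act"), volume = c(1, 1))),
               c(p_rep = 0.5, p_act = 0.5))
  expect_equal(state_populations(data.frame(state = "rep", volume = 3)),
               c(p_rep = 1, p_act = 0))
  expect_equal(state_populations(data.frame(state = c("rep", "act"), volume = c(3, 1))),
               c(p_rep = 0.75, p_act = 0.25))
  # sub-threshold second state is treated as absent
  expect_equal(state_populations(data.frame(state = c("rep", "act"), volume = c(99, 1)),
                                 min_volume_fraction = 0.02),
               c(p_rep = 1, p_act = 0))
  expect_error(state_populations(data.frame(state = c("x", "act"), volume = c(1, 1))),
               "label")
})

test_that("peaks at the anchors are labeled by their anchors", {
  anchors <- default_anchors()
  pk <- data.frame(center_H = c(anchors$rep[1], anchors$act[1]),
                   center_N = c(anchors$rep[2], anchors$act[2]),
                   volume = c(1, 1))
  lab <- label_states(pk, anchors)
  expect_equal(lab$state, c("rep", "act"))
})

test_that("a midpoint peak takes the repressive label by the tie-break", {
  anchors <- default_anchors()
  mid <- data.frame(center_H = mean(c(anchors$rep[1], anchors$act[1])),
                    center_N = mean(c(anchors$rep[2], anchors$act[2])),
                    volume = 1)
  expect_equal(label_states(mid, anchors)$state, "rep")
  expect_error(label_states(mid, list(rep = c(8, 109), act = c(8, 109))), "distinct")
})

test_that("labeling equals brute-force minimal-total-distance labeling", {
  anchors <- default_anchors()
  brute <- function(pk) {
    # all labelings with at most one peak per state
    opts <- if (nrow(pk) == 1) list("rep", "act") else
      list(c("rep", "act"), c("act", "rep"))
    costs <- vapply(opts, function(lb) {
      sum(vapply(seq_len(nrow(pk)), function(i)
        csp(anchors[[lb[i]]], c(pk$center_H[i], pk$center_N[i])), numeric(1)))
    }, numeric(1))
    opts[[which.min(costs)]]
  }
  for (s in 1:20) {
    set.seed(300 + s)
    n <- sample(1:2, 1)
    t_ <- runif(n)  # positions along the rep-act axis with scatter
    pk <- data.frame(
      center_H = anchors$act[1] + t_ * (anchors$rep[1] - anchors$act[1]) + rnorm(n, 0, 0.01),
      center_N = anchors$act[2] + t_ * (anchors$rep[2] - anchors$act[2]) + rnorm(n, 0, 0.05),
      volume = runif(n, 0.5, 2))
    expect_equal(label_states(pk, anchors)$state, brute(pk))
  }
})

test_that("ensemble table recovers populations on a noiseless mini-series", {
  anchors <- default_anchors()
  lists <- lapply(c(L0 = 0, Lh = 0.5, L1 = 1), function(f) {
    sp <- simulate_spectrum(list(ligand_id = "x", f_rep = f), snr = Inf)
    process_spectrum(sp)
  })
  tab <- ensemble_table(lists, anchors)
  expect_equal(tab$p_rep, c(0, 0.5, 1), tolerance = 0.01)
  # single-peak endpoint: weighted shift equals the single state's shift
  expect_equal(tab$delta_bar_H[1], anchors$act[1], tolerance = 1e-4)
  expect_equal(tab$delta_bar_H[3], anchors$rep[1], tolerance = 1e-4)
})

test_that("weighted shift is strictly monotone across a noiseless series", {
  anchors <- default_anchors()
  fr <- seq(0, 1, length.out = 9)
  lists <- lapply(fr, function(f)
    process_spectrum(simulate_spectrum(list(ligand_id = "x", f_rep = f), snr = Inf)))
  names(lists) <- sprintf("L%02d", seq_along(fr))
  tab <- ensemble_table(lists, anchors)
  expect_true(all(diff(tab$delta_bar_H) > 0))
  # consistency: delta_bar = p_rep * dH_rep + p_act * dH_act at the anchors
  expect_equal(tab$delta_bar_H,
               tab$p_rep * anchors$rep[1] + (1 - tab$p_rep) * anchors$act[1],
               tolerance = 1e-3)
})

test_that("missing ligands yield flagged rows, not errors", {
  anchors <- default_anchors()
  lists <- list(L1 = process_spectrum(
    simulate_spectrum(list(ligand_id = "L1", f_rep = 1), snr = Inf)),
    L2 = NULL)
  tab <- ensemble_table(lists, anchors)
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$p_rep[tab$ligand_id == "L2"]))
  expect_match(tab$flags[tab$ligand_id == "L2"], "missing")
})

test_that("fast-exchange peak position agrees with the slow-exchange weighted shift", {
  # same populations, same site offsets: the single fast-exchange peak must
  # sit where the two-peak volume-weighted mean sits
  wA <- -500; wB <- 500
  for (pA in c(0.2, 0.5, 0.8)) {
    fast <- exchange_params(k_ex = 500 * abs(wA - wB), p_A = pA,
                            omega_A = wA, omega_B = wB)
    pos <- lineshape_areas(simulate_lineshape_mcconnell(fast, n_points = 2^15))$peak_position
    dbar <- weighted_shift(data.frame(delta_H = c(wA, wB), volume = c(pA, 1 - pA)))
    expect_lt(abs(pos - dbar), 0.01 * abs(wA - wB))
  }
})
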