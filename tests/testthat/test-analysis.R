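test_that("honest rate is the honest-cell fraction", {
  expect_equal(h_rate(shgame:::new_sh_state(matrix(1L, 5, 5))), 1)
  expect_equal(h_rate(shgame:::new_sh_state(matrix(0L, 5, 5))), 0)
  expect_equal(h_rate(random_state(10, 10, 0.5, seed = 1)), 0.5)
})

test_that("granularity hits its closed-form anchors", {
  expect_equal(granularity(shgame:::new_sh_state(matrix(1L, 6, 6))), 1)
  checker <- shgame:::new_sh_state(
    outer(1:6, 1:6, function(i, j) (i + j) %% 2L))
  expect_equal(granularity(checker), 0)
  # half-and-half split by columns: one change per row
  halves <- state_from_rows(rep("HHHDDD", 6))
  expect_equal(granularity(halves), 1 - 1 / 5)
  expect_error(granularity(shgame:::new_sh_state(matrix(1L, 3, 1))),
               "2 columns")
})

test_that("granularity of uniform random 50% states is near one half", {
  g <- vapply(1:100, function(k)
    granularity(random_state(100, 100, 0.5, seed = k)), numeric(1))
  expect_lt(abs(mean(g) - 0.5), 0.02)
})

test_that("granularity is invariant under relabeling and row permutation", {
  for (k in 1:5) {
    st <- random_state(20, 20, 0.3, seed = k)
    flipped <- shgame:::new_sh_state(1L - unclass(st))
    expect_equal(granularity(flipped), granularity(st))
    perm <- shgame:::new_sh_state(unclass(st)[sample(20), ])
    expect_equal(granularity(perm), granularity(st))
    expect_gte(granularity(st), 0)
    expect_lte(granularity(st), 1)
  }
})

test_that("sweeps are deterministic, validated, and ordered", {
  cfg <- sh_config(rows = 15, cols = 15, rounds = 30, seed = 5)
  sw1 <- sweep_param(cfg, "p", grid = c(0, 0.5, 1), n_runs = 2)
  sw2 <- sweep_param(cfg, "p", grid = c(0, 0.5, 1), n_runs = 2)
  expect_identical(sw1$final_rates, sw2$final_rates)
  expect_equal(dim(sw1$final_rates), c(2L, 3L))
  expect_true(all(sw1$mean_rate >= 0 & sw1$mean_rate <= 1))
  expect_error(sweep_param(cfg, "p", grid = numeric(0)), "empty")
  expect_error(sweep_param(cfg, "p", grid = c(0.3, 0.1)), "increasing")
  expect_error(sweep_param(cfg, "p", grid = c(0, 1), n_runs = 0), "n_runs")
})

test_that("sweep endpoints behave as the payoff structure dictates", {
  cfg <- sh_config(rows = 30, cols = 30, rounds = 200, seed = 5)
  # no punishment: the dishonest advantage b > R wipes honesty out
  sw0 <- sweep_param(cfg, "p", grid = 0, n_runs = 3)
  expect_lt(sw0$mean_rate, 0.05)
  # certain severe punishment: honesty fixates in every run
  cfg8 <- sh_config(rows = 30, cols = 30, rounds = 200,
                    params = sh_params(s = 8), seed = 5)
  sw1 <- sweep_param(cfg8, "p", grid = 1, n_runs = 3)
  expect_equal(sw1$mean_rate, 1)
})

test_that("transition intervals are read off sweep summaries correctly", {
  fake <- structure(list(
    param = "p", grid = seq(0, 0.5, 0.1),
    final_rates = rbind(c(0, 0, 0.2, 0.7, 1, 1), c(0, 0, 0.4, 0.9, 1, 1)),
    mean_rate = c(0, 0, 0.3, 0.8, 1, 1), n_runs = 2L), class = "sh_sweep")
  ti <- transition_interval(fake)
  expect_equal(ti$lower, 0.1)
  expect_equal(ti$upper, 0.4)

  none <- fake; none$final_rates[] <- 0; none$mean_rate[] <- 0
  expect_error(transition_interval(none), "domination")

  all1 <- fake; all1$final_rates[] <- 1; all1$mean_rate[] <- 1
  ti1 <- transition_interval(all1)
  expect_equal(ti1$lower, -Inf)
  expect_equal(ti1$upper, 0)

  # mean-threshold mode accepts near-fixation means without full fixation
  near <- fake; near$final_rates[, 5] <- c(0.995, 0.997)
  near$mean_rate <- colMeans(near$final_rates)
  expect_equal(transition_interval(near, eps_low = 0.01,
                                   domination = "mean_ge_threshold")$upper,
               0.4)
  expect_equal(transition_interval(near)$upper, 0.5)
})

test_that("non-monotone sweeps past the crossing raise a warning", {
  fake <- structure(list(
    param = "p", grid = seq(0, 0.5, 0.1),
    final_rates = rbind(c(0, 0.2, 1, 0.5, 1, 1), c(0, 0.2, 1, 0.5, 1, 1)),
    mean_rate = c(0, 0.2, 1, 0.5, 1, 1), n_runs = 2L), class = "sh_sweep")
  expect_warning(transition_interval(fake), "decrease")
})

test_that("critical probability scan refines a known stub threshold", {
  # stub oracle: fixation iff p >= 0.3
  runner <- function(p) if (p >= 0.3) c(1, 1, 1) else c(0, 0.4, 1)
  pc <- critical_probability(sh_config(), p_lo = 0, p_hi = 1, step = 0.1,
                             runner = runner)
  expect_lte(abs(pc - 0.3), 0.02 + 1e-9)
  expect_error(
    critical_probability(sh_config(), p_lo = 0, p_hi = 0.2, step = 0.1,
                         runner = function(p) c(0, 0)),
    "no fixation")
  expect_error(critical_probability(sh_config(), p_lo = 0.5, p_hi = 0.1),
               "p_lo")
})

test_that("transition color grids follow the fixed palette", {
  all_h <- shgame:::new_sh_state(matrix(1L, 3, 3))
  all_d <- shgame:::new_sh_state(matrix(0L, 3, 3))
  expect_true(all(transition_color_grid(all_h, all_h) == "blue"))
  expect_true(all(transition_color_grid(all_d, all_d) == "red"))
  expect_true(all(transition_color_grid(all_d, all_h) == "green"))
  expect_true(all(transition_color_grid(all_h, all_d) == "yellow"))
  expect_error(transition_color_grid(all_h, shgame:::new_sh_state(matrix(1L, 2, 3))),
               "shapes")
})

test_that("color grids render to PNG with the right geometry", {
  prev <- random_state(8, 8, 0.5, seed = 1)
  curr <- random_state(8, 8, 0.5, seed = 2)
  path <- withr::local_tempfile(fileext = ".png")
  render_transition_png(prev, curr, path, scale = 2)
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], c(16, 16))
})
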