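test_that("marginal contributions match direct two-call evaluation", {
  g_add <- coalition_game(4, function(S) length(S))
  expect_equal(marginal_contribution(g_add, 2, c(1, 3)), 1)
  expect_error(marginal_contribution(g_add, 1, c(1, 2)), "already in")

  # dummy player: value ignores player 3
  g_dummy <- coalition_game(3, function(S) sum(c(1, 2, 0)[S]))
  for (coal in list(integer(0), 1L, 2L, c(1L, 2L)))
    expect_equal(marginal_contribution(g_dummy, 3, coal), 0)

  g5 <- make_random_game(5, seed = 21)
  raw <- shapaal:::local_seed(21, stats::rnorm(2^5)); raw[1] <- 0
  for (n in 1:5) {
    others <- setdiff(1:5, n)
    for (rep in 1:8) {
      coal <- sort(sample(others, sample(0:4, 1)))
      direct <- (raw[sum(2^(c(coal, n) - 1)) + 1] - raw[1]) -
        (if (length(coal)) raw[sum(2^(coal - 1)) + 1] - raw[1] else 0)
      expect_equal(marginal_contribution(g5, n, coal), direct, tolerance = 1e-12)
    }
  }
})

test_that("the two exact routes agree with each other and with brute force", {
  g_add <- coalition_game(3, function(S) length(S))
  expect_equal(exact_shapley(g_add)$values, c(1, 1, 1))
  g_dummy <- coalition_game(3, function(S) sum(c(3, 1, 0)[S]))
  expect_equal(exact_shapley(g_dummy)$values[3], 0)

  for (seed in c(31, 32, 33)) {
    g <- make_random_game(6, seed = seed)
    vs <- exact_shapley(g, "subset_formula")$values
    vp <- exact_shapley(make_random_game(6, seed = seed),
                        "permutation_enumeration")$values
    expect_lt(max(abs(vs - vp)), 1e-9)
  }

  # independent brute-force oracle on a small game
  tbl <- shapaal:::local_seed(55, stats::rnorm(2^4)); tbl[1] <- 0
  value <- function(S) if (length(S) == 0L) 0 else tbl[sum(2^(S - 1)) + 1]
  expect_equal(exact_shapley(game_from_table(4, tbl))$values,
               brute_force_shapley(4, value), tolerance = 1e-12)

  expect_error(exact_shapley(make_random_game(13, 1)), "monte_carlo")
})

test_that("exact values satisfy efficiency, null-player, symmetry and linearity", {
  for (seed in 1:10) {
    N <- 3 + (seed %% 6)
    g <- make_random_game(N, seed = 100 + seed)
    res <- exact_shapley(g)
    expect_lt(abs(sum(res$values) - shapaal:::game_value(g, seq_len(N))), 1e-9)
  }

  # constructed null player: player N never changes the value
  tbl5 <- shapaal:::local_seed(9, stats::rnorm(2^4)); tbl5[1] <- 0
  g_null <- coalition_game(5, function(S) {
    S <- setdiff(S, 5L)
    if (length(S) == 0L) 0 else tbl5[sum(2^(S - 1)) + 1]
  })
  expect_lt(abs(exact_shapley(g_null)$values[5]), 1e-12)

  # symmetric players by construction: 4 and 5 interchangeable
  g_sym <- coalition_game(5, function(S) {
    length(setdiff(S, c(4L, 5L))) + 2.5 * sum(c(4L, 5L) %in% S)
  })
  v <- exact_shapley(g_sym)$values
  expect_lt(abs(v[4] - v[5]), 1e-9)

  # linearity: phi_{u+w} = phi_u + phi_w
  tu <- shapaal:::local_seed(41, stats::rnorm(2^5)); tu[1] <- 0
  tw <- shapaal:::local_seed(42, stats::rnorm(2^5)); tw[1] <- 0
  pu <- exact_shapley(game_from_table(5, tu))$values
  pw <- exact_shapley(game_from_table(5, tw))$values
  puw <- exact_shapley(game_from_table(5, tu + tw))$values
  expect_equal(puw, pu + pw, tolerance = 1e-9)
})

test_that("Monte-Carlo estimation is unbiased, seeded, and tightens with samples", {
  g_add <- coalition_game(5, function(S) length(S))
  mc <- monte_carlo_shapley(g_add, 100, seed = 1)
  expect_equal(mc$values, rep(1, 5))           # constant marginals, exactly
  expect_equal(mc$std_errors, rep(0, 5))

  g <- make_random_game(6, seed = 77)
  exact <- exact_shapley(g)$values
  mc1 <- monte_carlo_shapley(make_random_game(6, seed = 77), 5000, seed = 2)
  expect_true(all(abs(mc1$values - exact) <= 3 * pmax(mc1$std_errors, 1e-12)))
  mc1b <- monte_carlo_shapley(make_random_game(6, seed = 77), 5000, seed = 2)
  expect_identical(mc1$values, mc1b$values)

  # 10x the permutations shrinks the mean absolute error
  err <- function(n_perm, seed) {
    m <- monte_carlo_shapley(make_random_game(6, seed = 77), n_perm, seed = seed)
    mean(abs(m$values - exact))
  }
  e_small <- mean(vapply(1:3, function(s) err(100, s), numeric(1)))
  e_big <- mean(vapply(1:3, function(s) err(1000, s), numeric(1)))
  expect_lt(e_big, e_small)
})

test_that("the retraining game scores coalitions as held-out accuracy", {
  gen <- make_separable(n = 12L, seed = 14)
  game <- retrain_value_fn(gen$train, gen$test, surrogate = "1nn")
  # empty coalition is worth exactly zero by construction
  expect_identical(shapaal:::game_value(game, integer(0)), 0)
  # the full coalition of a separable problem nearly saturates accuracy
  full <- shapaal:::game_value(game, seq_len(12)) + game$v_empty
  expect_gte(full, 0.9)

  # duplicate-instance players are symmetric and get equal exact values
  base <- gen$train$series[1:5, ]
  dup <- ts_dataset(rbind(base, base[5, ]), c(gen$train$labels[1:5],
                                              gen$train$labels[5]),
                    role = "train")
  dup$label_levels <- gen$train$label_levels; dup$n_classes <- 2L
  g_dup <- retrain_value_fn(dup, gen$test, surrogate = "1nn")
  vals <- exact_shapley(g_dup)$values
  expect_lt(abs(vals[5] - vals[6]), 1e-9)
})

test_that("model attribution values are functional and vanish for a dead head", {
  gen <- make_separable(n = 16L, seed = 19)
  st <- compute_norm_stats(gen$train)
  m <- build_resnet(tiny_resnet_cfg(seed = 4, epochs = 15L), gen$train$len, 2L)
  m <- fit_resnet(m, gen$train, st)
  res <- model_attribution_values(m, gen$train, seed = 3)
  expect_length(res$values, 16L)
  expect_identical(res$estimator, "model_attribution")
  r2 <- model_attribution_values(m, gen$train, seed = 3)
  expect_identical(res$values, r2$values)

  # duplicated sample receives the identical value
  dup <- ts_dataset(gen$train$series[c(1:16, 1), ],
                    c(gen$train$labels, gen$train$labels[1]), role = "train")
  dup$label_levels <- gen$train$label_levels; dup$n_classes <- 2L
  vd <- model_attribution_values(m, dup, background_size = 17L, seed = 3)
  expect_equal(vd$values[1], vd$values[17], tolerance = 1e-12)

  # zero classifier head => no signal to attribute
  m0 <- m
  m0$net$head$W[] <- 0
  m0$net$head$b[] <- 0
  expect_equal(model_attribution_values(m0, gen$train, seed = 3)$values,
               rep(0, 16L))
  expect_error(model_attribution_values(m, gen$train, background_size = 99L),
               "background_size")
})
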