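# Fixtures built in code; no files shipped.

# small well-separated two-class set (sinusoid templates, light noise)
make_separable <- function(n = 20L, len = 24L, noise_sd = 0.3, seed = 1L) {
  spec <- synthetic_spec(n_train = n, n_test = n, length_T = len,
                         n_classes = 2L, noise_sd = noise_sd, seed = seed)
  generate_synthetic(spec, name = "separable")
}

# random coalition game from a full value table indexed by bitmask; v(empty)=0
make_random_game <- function(n_players, seed) {
  tbl <- shapaal:::local_seed(seed, stats::rnorm(2^n_players))
  tbl[1] <- 0
  game_from_table(n_players, tbl)
}

game_from_table <- function(n_players, tbl) {
  coalition_game(n_players, function(S) {
    if (length(S) == 0L) return(tbl[1])
    tbl[sum(2^(S - 1L)) + 1L]
  })
}

# tiny quick-to-train network configuration
tiny_resnet_cfg <- function(seed = 1L, epochs = 40L) {
  resnet_config(n_blocks = 2L, filters = 4L, epochs = epochs, seed = seed)
}

# independent brute-force Shapley via direct permutation definition,
# written against the raw table (not via the package's enumeration)
brute_force_shapley <- function(n_players, value) {
  perms <- NULL
  gen <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(gen(v[-i]), function(p) c(v[i], p)))
    out
  }
  phi <- numeric(n_players)
  for (ord in gen(seq_len(n_players))) {
    prev <- value(integer(0))
    for (pos in seq_len(n_players)) {
      cur <- value(sort(ord[seq_len(pos)]))
      phi[ord[pos]] <- phi[ord[pos]] + (cur - prev)
      prev <- cur
    }
  }
  phi / factorial(n_players)
}
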