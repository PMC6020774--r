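# Shared lazy fixtures (built once per test run).

.fixture_env <- new.env(parent = emptyenv())

# Small noise-free phantom with default subject parameters.
tiny_phantom <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- build_phantom(default_phantom_layout(c(16L, 16L, 16L)),
                                       noise_sd = 0, seed = 101)
  }
  .fixture_env$tiny
}

default_phantom_cached <- function() {
  if (is.null(.fixture_env$full)) {
    .fixture_env$full <- build_phantom(noise_sd = 0, seed = 202)
  }
  .fixture_env$full
}

# The worked-example recall record: four words recalled, values 12, 10, 11, 12.
worked_example_record <- function(design = study_design()) {
  v <- design$list_values
  idx <- c(which(v == 12)[1:2], which(v == 10)[1], which(v == 11)[1])
  recall_record(v, idx)
}

# Brute-force list scorer used as the independent oracle: enumerates the
# definition directly (sum over recalled, mean * count, top-n sum).
brute_force_score <- function(values, recalled_idx) {
  rec <- values[recalled_idx]
  n <- length(rec)
  actual <- sum(rec)
  chance <- mean(values) * n
  ideal <- sum(sort(values, decreasing = TRUE)[seq_len(n)])
  sel <- if (ideal == chance) NA_real_ else (actual - chance) / (ideal - chance)
  list(actual = actual, chance = chance, ideal = ideal, selectivity = sel)
}

# Brute-force BH step-up adjustment straight from the definition.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(ord == i) # rank of p[i]
    adj[i] <- min(1, min(p[ord][j:m] * m / (j:m)))
  }
  adj
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
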