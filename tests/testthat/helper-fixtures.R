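# Shared fixtures and closed-form potentials used across test files.

# A quadratic potential p(x) = 0.5 * a * ||x||^2 + c . x, whose gradient is
# the affine map a * x + c. Plugs into the potential interface so solver
# operations can be exercised against exact maps.
quad_potential <- function(d, a = 1, c = rep(0, d)) {
  structure(list(d = d, a = a, c = c), class = "quad_potential")
}

potential_value.quad_potential <- function(potential, x) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = potential$d)
  0.5 * potential$a * rowSums(X^2) + as.numeric(X %*% potential$c)
}

potential_gradient.quad_potential <- function(potential, x) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = potential$d)
  potential$a * X + rep(potential$c, each = nrow(X))
}

negativity_penalty.quad_potential <- function(net) 0

registerS3method("potential_value", "quad_potential",
                 potential_value.quad_potential,
                 envir = asNamespace("perturbOT"))
registerS3method("potential_gradient", "quad_potential",
                 potential_gradient.quad_potential,
                 envir = asNamespace("perturbOT"))
registerS3method("negativity_penalty", "quad_potential",
                 negativity_penalty.quad_potential,
                 envir = asNamespace("perturbOT"))

# A transport-map shell around an arbitrary potential g (f unused).
fake_map <- function(g, d) {
  structure(list(g = g, f = quad_potential(d, a = 0), input_dim = d,
                 feature_names = paste0("feature_", seq_len(d)),
                 config = ot_train_config(n_iter = 0L, warmstart_steps = 0L),
                 log = tibble::tibble(iteration = integer(), loss_f = double(),
                                      loss_g = double(), penalty = double()),
                 selected_iteration = 0L),
            class = "transport_map")
}

# Minimal 1-D ICNN with one hidden unit and hand-set weights:
#   h1 = sigma(wx1 * x + b1);  out = wx2 * x + wz2 * h1 + b2
tiny_icnn <- function(wx1 = 1, b1 = 0, wx2 = 0, wz2 = 1, b2 = 0,
                      slope = 1) {
  net <- icnn_init(1L, 1L, "leaky_relu", slope = slope, seed = 0L)
  net$Wx[[1]][] <- wx1
  net$b[[1]][] <- b1
  net$Wx[[2]][] <- wx2
  net$Wz[[2]][] <- wz2
  net$b[[2]][] <- b2
  net
}

# Gaussian-shift populations used by several files.
shift_pair <- function(n = 500, d = 2, shift = c(3, rep(0, d - 1)), seed = 1) {
  sample_gaussian_pair(gaussian_spec(rep(0, d), diag(d), shift, diag(d),
                                     n_source = n, n_target = n, seed = seed))
}

# Brute-force unbiased MMD: explicit double loops (independent oracle).
mmd_bruteforce <- function(X, Y, gamma) {
  n <- nrow(X); m <- nrow(Y)
  k <- function(a, b) exp(-gamma * sum((a - b)^2))
  sxx <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    sxx <- sxx + k(X[i, ], X[j, ])
  syy <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    syy <- syy + k(Y[i, ], Y[j, ])
  sxy <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    sxy <- sxy + k(X[i, ], Y[j, ])
  sxx / (n * (n - 1)) + syy / (m * (m - 1)) - 2 * sxy / (n * m)
}

# Session-level cache for expensive trained maps shared across test blocks.
trained_cache <- new.env(parent = emptyenv())

cached_fit <- function(key, fit_fun) {
  if (!exists(key, envir = trained_cache))
    assign(key, fit_fun(), envir = trained_cache)
  get(key, envir = trained_cache)
}
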