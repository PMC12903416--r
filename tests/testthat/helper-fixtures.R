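# Shared helpers: random tangent vectors, finite-difference gradients, and a
# lazily trained small model reused by the analysis contract tests.

h2 <- curvature_space("hyperbolic", -2, 2)

# Random tangent vectors at given base points (rows), correct metric.
random_tangents <- function(base, space, scale = 1) {
  n <- nrow(base)
  v <- matrix(rnorm(n * ncol(base)), n, ncol(base))
  if (space$kind == "euclidean") return(scale * v)
  ip <- if (space$kind == "hyperbolic") lorentz_inner(base, v) else rowSums(base * v)
  vt <- v - space$K * ip * base
  nrm <- sqrt(pmax(abs(if (space$kind == "hyperbolic") lorentz_inner(vt, vt)
                       else rowSums(vt^2)), 1e-12))
  vt * (scale * runif(n) / nrm)
}

# Central finite difference of f at x (scalar-valued f, vector x).
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# A tiny two-component model and data for contract tests (not trained).
tiny_setup <- function(seed = 5L, n = 7L, G = 12L, batch = TRUE) {
  set.seed(seed + 100L)
  prt <- gene_partition(G, list(cycle = 1:5))
  specs <- list(latent_spec(curvature_space("hyperbolic", -2, 2), "rown"),
                latent_spec(curvature_space("euclidean", 0, 3)))
  cfg <- train_config(seed = seed, enc_widths = c(8L, 6L, 5L),
                      dec_widths = c(6L, 8L))
  bd <- if (batch) batch_design(data.frame(b = c("x", "y"))) else NULL
  m <- build_model(prt, specs, batch = bd, config = cfg)
  X <- matrix(rpois(n * G, 5), n, G)
  bdf <- if (batch) data.frame(b = sample(c("x", "y"), n, TRUE)) else NULL
  list(model = m, X = X, batch = bdf, n = n, G = G)
}

# Lazily trained small model on a compact cyclic fixture, shared across
# analysis tests to keep the suite fast.
.cached <- new.env(parent = emptyenv())
small_trained <- function() {
  if (!is.null(.cached$fit)) return(.cached$fit)
  sim <- simulate_cells(sim_config(n_cells = 400L, n_cycle_genes = 40L,
                                   n_other_genes = 120L, n_cell_types = 2L,
                                   n_batches = 1L, seed = 42L))
  prt <- gene_partition(ncol(sim$counts), list(cycle = which(sim$genes$marker)),
                        gene_names = sim$genes$name)
  specs <- list(latent_spec(curvature_space("hyperbolic", -2, 2), "rown"),
                latent_spec(curvature_space("euclidean", 0, 4)))
  m <- build_model(prt, specs, config = train_config(seed = 2L))
  m <- train_model(m, sim$counts, epochs = 100L)
  .cached$fit <- list(model = m, sim = sim)
  .cached$fit
}
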