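# Gene partition, masked encoders, decoder wiring, NB likelihood, ELBO.

test_that("gene partition validates and deduplicates shared sets", {
  p <- gene_partition(10, list(a = 1:3, b = 1:3))
  expect_equal(p$k, 3L)
  expect_equal(p$sets$rest, 4:10)
  expect_false(p$modeled[2])            # identical set is not re-modelled
  expect_equal(p$owner[2], 1L)
  expect_error(gene_partition(10, list(a = 1:3, b = 2:5)),
               class = "curvae_invalid_argument")   # overlapping, not identical
  expect_error(gene_partition(10, list(a = integer(0))),
               class = "curvae_invalid_argument")
  expect_error(gene_partition(4, list(a = 1:4)),
               class = "curvae_invalid_argument")   # nothing left for the rest
  expect_warning(gene_partition(5, list(a = c("g1", "zz")),
                                gene_names = paste0("g", 1:5)),
                 "not found")
})

test_that("partition_counts splits and reassembles count vectors", {
  p <- gene_partition(4, list(m = 1:2))
  out <- partition_counts(c(5, 0, 2, 1), p)
  expect_equal(out$m, c(5, 0))
  expect_equal(out$rest, c(2, 1))
  # shared sets give identical blocks
  p2 <- gene_partition(4, list(a = 1:2, b = 1:2))
  out2 <- partition_counts(c(5, 0, 2, 1), p2)
  expect_identical(out2$a, out2$b)
  expect_error(partition_counts(1:3, p), class = "curvae_invalid_argument")
})

test_that("encoders are masked: posteriors depend only on their own block", {
  ts <- tiny_setup()
  enc1 <- encode_cells(ts$model, ts$X)
  X2 <- ts$X; X2[, 8] <- X2[, 8] + 17   # perturb a non-marker gene
  enc2 <- encode_cells(ts$model, X2)
  expect_identical(enc1$cycle, enc2$cycle)
  expect_false(identical(enc1$rest$tangent, enc2$rest$tangent))
  # all-zero cells give finite parameters
  X0 <- ts$X; X0[1, ] <- 0
  enc0 <- encode_cells(ts$model, X0)
  expect_true(all(is.finite(unlist(enc0$cycle))) &&
                all(is.finite(unlist(enc0$rest))))
})

test_that("curved posterior locations satisfy the manifold constraint", {
  set.seed(30)
  prt <- gene_partition(20, list(cycle = 1:8))
  specs <- list(latent_spec(curvature_space("hyperbolic", -2, 2), "rown"),
                latent_spec(curvature_space("euclidean", 0, 3)))
  m <- build_model(prt, specs, config = train_config(seed = 1, enc_widths = c(8L, 6L),
                                                     dec_widths = c(6L, 5L)))
  X <- matrix(rpois(256 * 20, 3), 256, 20)
  enc <- encode_cells(m, X)
  expect_lt(max(abs(lorentz_inner(enc$cycle$location, enc$cycle$location) + 0.5)),
            1e-5)
})

test_that("decoder wiring: block normalisation and component isolation", {
  ts <- tiny_setup()
  m <- ts$model
  sp1 <- m$specs[[1]]$space
  n <- 5
  set.seed(31)
  z1 <- exp_map(matrix(space_origin(sp1), 1),
                cbind(0, matrix(rnorm(n * 2, sd = 0.5), n, 2)), sp1)
  z2 <- matrix(rnorm(n * 3), n, 3)
  bdf <- data.frame(b = rep("x", n))
  lib <- c(100, 200, 50, 1000, 10)
  dec <- decode_cells(m, list(z1, z2), lib, bdf)
  expect_equal(rowSums(dec$cycle$mean), lib, tolerance = 1e-9)
  expect_equal(rowSums(dec$rest$mean), lib, tolerance = 1e-9)
  # changing z2 leaves the signal block untouched
  dec2 <- decode_cells(m, list(z1, z2 + 1), lib, bdf)
  expect_identical(dec$cycle$mean, dec2$cycle$mean)
  expect_false(identical(dec$rest$mean, dec2$rest$mean))
  expect_error(decode_cells(m, list(z1, z2), lib, data.frame(b = rep("zzz", n))),
               class = "curvae_invalid_argument")
})

test_that("covariates reach only the components they apply to", {
  set.seed(32)
  prt <- gene_partition(10, list(m = 1:4))
  specs <- list(latent_spec(curvature_space("euclidean", 0, 2)),
                latent_spec(curvature_space("euclidean", 0, 2)))
  app <- matrix(c(TRUE, FALSE,   # comp 1: covariate 1 only
                  TRUE, TRUE), 2, 2, byrow = TRUE)
  bd <- batch_design(data.frame(c1 = c("a", "b"), c2 = c("u", "v")),
                     applicability = app)
  m <- build_model(prt, specs, batch = bd,
                   config = train_config(seed = 3, enc_widths = c(6L, 5L),
                                         dec_widths = c(5L, 6L)))
  z <- list(matrix(rnorm(6), 3, 2), matrix(rnorm(6), 3, 2))
  d1 <- decode_cells(m, z, rep(100, 3), data.frame(c1 = "a", c2 = "u"))
  d2 <- decode_cells(m, z, rep(100, 3), data.frame(c1 = "a", c2 = "v"))
  expect_identical(d1$m$mean, d2$m$mean)
  expect_false(identical(d1$rest$mean, d2$rest$mean))
})

test_that("NB log-likelihood has the right closed forms and limits", {
  # pmf at zero: theta * log(theta / (theta + mu))
  expect_equal(nb_log_likelihood(0, 3.2, 1.7), 1.7 * log(1.7 / (1.7 + 3.2)))
  # matches an independent evaluation through dnbinom
  expect_equal(nb_log_likelihood(3, 2.0, 1.5),
               dnbinom(3, size = 1.5, mu = 2.0, log = TRUE), tolerance = 1e-12)
  set.seed(33)
  x <- rpois(20, 4); mu <- runif(20, 0.5, 8); th <- runif(20, 0.5, 10)
  expect_equal(nb_log_likelihood(x, mu, th),
               sum(dnbinom(x, size = th, mu = mu, log = TRUE)), tolerance = 1e-10)
  # Poisson limit as dispersion grows
  expect_equal(nb_log_likelihood(5, 3.0, 1e6), dpois(5, 3.0, log = TRUE),
               tolerance = 1e-3)
  expect_error(nb_log_likelihood(2.5, 1, 1), class = "curvae_invalid_argument")
  expect_error(nb_log_likelihood(2, -1, 1), class = "curvae_invalid_argument")
})

test_that("loss is invariant to duplicated cells and gene-block permutation", {
  ts <- tiny_setup(batch = FALSE)
  m <- ts$model
  x <- ts$X[3, , drop = FALSE]
  eps1 <- list(matrix(rnorm(2), 1, 2), matrix(rnorm(3), 1, 3))
  l1 <- elbo_loss(m, x, eps = eps1)
  xd <- x[rep(1, 4), ]
  epsd <- lapply(eps1, function(e) e[rep(1, 4), , drop = FALSE])
  ld <- elbo_loss(m, xd, eps = epsd)
  expect_equal(ld$loss, l1$loss, tolerance = 1e-12)
  # permute the gene blocks (rest first), remapping the partition: with the
  # same weights and noise, the loss is unchanged
  perm <- c(6:12, 1:5)
  prt2 <- gene_partition(12, list(cycle = 8:12))
  m2 <- m; m2$partition <- prt2
  eps2 <- list(matrix(rnorm(ts$n * 2), ts$n, 2), matrix(rnorm(ts$n * 3), ts$n, 3))
  expect_equal(elbo_loss(m2, ts$X[, perm], eps = eps2)$loss,
               elbo_loss(m, ts$X, eps = eps2)$loss, tolerance = 1e-12)
  # degenerate cells keep the loss finite
  Xz <- ts$X; Xz[1, ] <- 0; Xz[2, 7] <- 50000
  expect_true(is.finite(elbo_loss(m, Xz)$loss))
})

test_that("the ELBO lower-bounds the quadrature evidence on a toy model", {
  set.seed(34)
  for (rep in 1:10) {
    prt <- gene_partition(3)               # single component, all genes
    specs <- list(latent_spec(curvature_space("euclidean", 0, 1)))
    m <- build_model(prt, specs,
                     config = train_config(seed = 100 + rep,
                                           enc_widths = c(5L, 4L), dec_widths = c(4L, 5L)))
    x <- matrix(rpois(3, c(4, 1, 7)), 1, 3)
    lib <- sum(x)
    zg <- matrix(seq(-10, 10, length.out = 2001), ncol = 1)
    dec <- decode_cells(m, list(zg), rep(lib, 2001))
    ll <- vapply(seq_len(2001), function(i)
      sum(dnbinom(drop(x), size = dec[[1]]$dispersion[i, ],
                  mu = dec[[1]]$mean[i, ], log = TRUE)), numeric(1))
    logp <- log(sum(dnorm(zg) * exp(ll)) * (20 / 2000))
    draws <- replicate(200, -elbo_loss(m, x)$loss)
    expect_lt(mean(draws), logp + 3 * sd(draws) / sqrt(200))
  }
})

test_that("the single-euclidean configuration matches an independent NB-VAE", {
  set.seed(35)
  G <- 6L; n <- 5L
  prt <- gene_partition(G)
  specs <- list(latent_spec(curvature_space("euclidean", 0, 2)))
  m <- build_model(prt, specs, config = train_config(seed = 9, enc_widths = c(7L, 5L),
                                                     dec_widths = c(5L, 7L)))
  X <- matrix(rpois(n * G, 6), n, G)
  eps <- list(matrix(rnorm(n * 2), n, 2))
  ours <- elbo_loss(m, X, eps = eps)$loss
  # --- independent minimal NB-VAE forward pass -----------------------------
  p <- m$params
  gelu_ref <- function(a) 0.5 * a * (1 + tanh(sqrt(2 / pi) * (a + 0.044715 * a^3)))
  lin <- function(H, W, b) H %*% t(W) + matrix(b, nrow(H), length(b), byrow = TRUE)
  H <- log1p(X)
  for (l in 1:2) H <- gelu_ref(lin(H, p[[sprintf("e1.t%d.W", l)]],
                                   p[[sprintf("e1.t%d.b", l)]]))
  mu <- lin(H, p[["e1.loc.W"]], p[["e1.loc.b"]])
  sr <- lin(H, p[["e1.sc.W"]], p[["e1.sc.b"]])
  sig <- log1p(exp(-abs(sr))) + pmax(sr, 0) + 1e-4
  z <- mu + sig * eps[[1]]
  kl <- vapply(seq_len(n), function(i)
    sum(dnorm(z[i, ], mu[i, ], sig[i, ], log = TRUE)) -
      sum(dnorm(z[i, ], 0, 1, log = TRUE)), numeric(1))
  Hd <- z
  for (l in 1:2) Hd <- gelu_ref(lin(Hd, p[[sprintf("d1.t%d.W", l)]],
                                    p[[sprintf("d1.t%d.b", l)]]))
  logits <- lin(Hd, p[["d1.out.W"]], p[["d1.out.b"]])
  sm <- exp(logits) / rowSums(exp(logits))
  mean_mat <- sm * rowSums(X)
  theta <- matrix(exp(p[["th1"]][, 1]), n, G, byrow = TRUE)
  ll <- vapply(seq_len(n), function(i)
    sum(dnbinom(X[i, ], size = theta[i, ], mu = mean_mat[i, ], log = TRUE)), numeric(1))
  ref_loss <- mean(kl) - mean(ll)
  expect_equal(ours, ref_loss, tolerance = 1e-5)
})
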