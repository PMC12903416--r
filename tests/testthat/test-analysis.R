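# Pseudotime, alignment, decoding procedures, classification, k-NN,
# upregulated-gene discovery.

test_that("pseudotime is the disk angle in [0, 2*pi)", {
  sp <- curvature_space("hyperbolic", -1, 2)
  expect_equal(pseudotime(matrix(c(0.5, 0), 1), sp, poincare = TRUE), 0)
  expect_equal(pseudotime(matrix(c(0, 0.5), 1), sp, poincare = TRUE), pi / 2)
  expect_equal(pseudotime(matrix(c(cosh(1), 0, sinh(1)), 1), sp), pi / 2,
               tolerance = 1e-12)
  set.seed(50)
  ang <- pseudotime(curvae:::.random_points(h2, 100), h2)
  expect_true(all(ang >= 0 & ang < 2 * pi))
  expect_warning(pseudotime(matrix(c(0, 0), 1), sp, poincare = TRUE), "origin")
  expect_error(pseudotime(matrix(0, 1, 3), curvature_space("euclidean", 0, 3)),
               class = "curvae_invalid_argument")
})

test_that("pseudotime after recentering follows the angle around the new origin", {
  # points on a ring around c(0.3, -0.2): recentering there recovers their angles
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  ctr <- c(0.3, -0.2)
  ring <- recenter(cbind(0.35 * cos(th), 0.35 * sin(th)), -ctr, -1) # place around ctr
  sp <- curvature_space("hyperbolic", -1, 2)
  ang <- pseudotime(ring, sp, recenter_origin = ctr, poincare = TRUE)
  expect_equal(ang, th, tolerance = 1e-9)
})

test_that("alignment search recovers rotations and flips exactly", {
  set.seed(51)
  truth <- runif(200, 0, 2 * pi)
  al0 <- align_pseudotime(truth, truth)
  expect_equal(al0$r, 1, tolerance = 1e-12)
  expect_equal(al0$rotation, 0)
  expect_false(al0$flip)
  al1 <- align_pseudotime((truth + 1.0) %% (2 * pi), truth)
  expect_gt(al1$r, 1 - 1e-4)
  al2 <- align_pseudotime((-truth) %% (2 * pi), truth)
  expect_gt(al2$r, 1 - 1e-4)
  expect_true(al2$flip)
  expect_gt(al2$sin_r, 1 - 1e-3)
  # never exceeds 1, and the optimum is stable under grid refinement
  est <- (truth + 0.7 + rnorm(200, sd = 0.2)) %% (2 * pi)
  a <- align_pseudotime(est, truth)
  expect_lte(a$r, 1 + 1e-12)
  expect_equal(align_pseudotime(est, truth, n_grid = 1440)$r, a$r,
               tolerance = 1e-3)
  expect_error(align_pseudotime(rep(1, 10), runif(10)),
               class = "curvae_degenerate_input")
})

test_that("central/portal ratio classification follows the printed thresholds", {
  out <- central_portal_classify(c(1, 0, 2, 9, 0), c(1, 3, 6, 1, 0))
  expect_equal(out$ratio, c(0.5, 0, 0.25, 0.9, 0.5))
  expect_equal(out$label,
               c("unclassified", "central", "unclassified", "portal", "unclassified"))
  expect_error(central_portal_classify(c(-1, 0), c(0, 0)),
               class = "curvae_invalid_argument")
})

test_that("k-NN identity transfer applies the unanimity rule", {
  ref <- matrix(c(0, -1, -2, 0.8, 0.9, 1.0), ncol = 1)
  labs <- c("A", "A", "A", "B", "B", "B")
  # pure reference: any query gets the single label
  expect_equal(knn_identity(ref, rep("A", 6), matrix(c(0.3, 5), ncol = 1),
                            k_list = c(1, 3, 5)),
               c("A", "A"))
  # k = 1 with a query equal to a reference point returns that point's label
  expect_equal(knn_identity(ref, labs, matrix(0.9, 1, 1), k_list = 1), "B")
  # query where k = 1 votes A but k = 3 votes B: uncertain
  expect_equal(knn_identity(ref, labs, matrix(0.35, 1, 1), k_list = c(1, 3)),
               "uncertain")
  expect_error(knn_identity(ref[0, , drop = FALSE], character(0),
                            matrix(0, 1, 1)), class = "curvae_invalid_argument")
  expect_error(knn_identity(ref, labs, matrix(0, 1, 1), k_list = 99),
               class = "curvae_invalid_argument")
})

test_that("selective decoding contracts hold on a trained model", {
  fit <- small_trained()
  m <- fit$model; sim <- fit$sim
  nm <- names(m$partition$sets)
  # keeping every component reproduces the ordinary posterior reconstruction
  full <- selective_decode(m, sim$counts, keep = nm)
  enc <- encode_cells(m, sim$counts)
  ref <- decoded_matrix(m, decode_cells(m, list(enc$cycle$location, enc$rest$location),
                                        pmax(rowSums(sim$counts), 1)))
  expect_equal(full, ref, tolerance = 1e-12)
  expect_error(selective_decode(m, sim$counts, keep = "nope"),
               class = "curvae_invalid_argument")
  expect_error(selective_decode(m, sim$counts, keep = character(0)),
               class = "curvae_invalid_argument")
  # dropping the signal component erases phase information from marker genes
  lib0 <- rep(1e4, nrow(sim$counts))
  only2 <- selective_decode(m, sim$counts, keep = "rest", lib_size = lib0)
  only1 <- selective_decode(m, sim$counts, keep = "cycle", lib_size = lib0)
  cyc <- sim$truth$cycling
  mk <- which(sim$genes$marker & sim$genes$amplitude > 0.5)
  drive <- function(g) cos(sim$truth$phase[cyc] - sim$genes$offset[g])
  safe_cor <- function(x, y) if (sd(x) == 0) 0 else abs(cor(x, y))
  r2 <- vapply(mk, function(g) safe_cor(only2[cyc, g], drive(g)), numeric(1))
  r1 <- vapply(mk, function(g) safe_cor(only1[cyc, g], drive(g)), numeric(1))
  expect_lt(median(r2), 0.15)
  expect_gt(median(r1), 0.6)
})

test_that("counterfactual overrides exactly one coordinate", {
  fit <- small_trained()
  m <- fit$model; sim <- fit$sim
  enc <- encode_cells(m, sim$counts)
  # overwriting with each cell's own coordinate is the identity
  lib <- pmax(rowSums(sim$counts), 1)
  ref <- decoded_matrix(m, decode_cells(m, list(enc$cycle$location, enc$rest$location), lib))
  same <- counterfactual_decode(m, sim$counts[1:3, ], "rest", 2,
                                enc$rest$tangent[1, 2], lib_size = lib[1:3])
  # cell 1's row matches the ordinary reconstruction
  expect_equal(same[1, ], ref[1, ], tolerance = 1e-9)
  expect_error(counterfactual_decode(m, sim$counts[1:3, ], "rest", 99, 0),
               class = "curvae_invalid_argument")
  expect_error(counterfactual_decode(m, sim$counts[1:3, ], "nope", 1, 0),
               class = "curvae_invalid_argument")
})

test_that("counterfactual decoding orders a gradient fixture correctly", {
  cf <- sim_config(n_cells = 500L, n_cycle_genes = 60L, n_other_genes = 140L,
                   fraction_cycling = 1, n_cell_types = 2L,
                   kind = "linear-gradient", amplitude_range = c(1, 2),
                   n_batches = 1L, seed = 11L)
  sim <- simulate_cells(cf)
  prt <- gene_partition(ncol(sim$counts), list(zone = which(sim$genes$marker)),
                        gene_names = sim$genes$name)
  specs <- list(latent_spec(curvature_space("euclidean", 0, 2)),
                latent_spec(curvature_space("euclidean", 0, 6)))
  m <- build_model(prt, specs, config = train_config(seed = 4))
  m <- train_model(m, sim$counts, epochs = 100)
  enc <- encode_cells(m, sim$counts)
  pos <- sim$truth$phase
  cors <- cor(enc$zone$tangent, pos)
  ci <- which.max(abs(cors))
  expect_gt(max(abs(cors)), 0.9)          # the gradient is captured
  s <- sign(cors[ci]); sdv <- sd(enc$zone$tangent[, ci])
  lib0 <- rep(1e4, 500)
  hi <- counterfactual_decode(m, sim$counts, "zone", ci, s * 2 * sdv, lib_size = lib0)
  lo <- counterfactual_decode(m, sim$counts, "zone", ci, -s * 2 * sdv, lib_size = lib0)
  up <- which(sim$genes$marker & sim$genes$amplitude > 0.5 &
                sim$genes$gradient_sign > 0)
  frac <- vapply(up, function(g) mean(hi[, g] > lo[, g]), numeric(1))
  expect_gt(mean(frac >= 0.9), 0.9)       # increasing genes decode higher
  # ratio classification separates the two ends for the simulated markers
  dn <- which(sim$genes$marker & sim$genes$amplitude > 0.5 &
                sim$genes$gradient_sign < 0)
  cl <- central_portal_classify(colMeans(hi), colMeans(lo))
  expect_gt(median(cl$ratio[up]), 0.6)
  expect_lt(median(cl$ratio[dn]), 0.4)
})

test_that("discovery tallies are bounded and degenerate input is flagged", {
  fit <- small_trained()
  m <- fit$model; sim <- fit$sim
  enc <- encode_cells(m, sim$counts)
  grp <- ifelse(sim$truth$cell_type == 1, "A", "B")
  res <- discover_upregulated(m, enc$rest$tangent, "rest", grp,
                              n_cells_per_group = 50L, top_n = 20L)
  expect_true(all(res$frequency <= attr(res, "pairs")))
  expect_true(all(res$frequency >= 0))
  # identical groups (duplicated embedding) produce all-zero differences
  zdup <- enc$rest$tangent[rep(1, 120), ]
  expect_warning(discover_upregulated(m, zdup, "rest",
                                      rep(c("A", "B"), each = 60),
                                      n_cells_per_group = 50L),
                 "degenerate")
  expect_error(discover_upregulated(m, enc$rest$tangent, "rest", grp,
                                    n_cells_per_group = 1e5),
               class = "curvae_invalid_argument")
})
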