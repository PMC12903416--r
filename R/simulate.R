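# Synthetic scRNA-seq generator with ground truth: cycling cells whose
# marker genes follow a single log-scale harmonic of a latent phase,
# non-cycling cells with flat marker expression, discrete cell-type programs
# on the remaining genes, per-cell library sizes, multiplicative batch
# effects, and negative-binomial sampling noise.

#' Simulation configuration
#'
#' Defaults describe a droplet-scale experiment: 1,500 cells of which two
#' thirds cycle, 120 signal (marker) genes and 280 others, 3 cell types,
#' 2 batches, log-normal library sizes around 8,000 UMIs.
#'
#' @param n_cells Total number of cells.
#' @param fraction_cycling Fraction of cells carrying the latent signal.
#' @param n_cycle_genes,n_other_genes Marker and non-marker gene counts.
#' @param n_cell_types Discrete programs on the non-marker genes.
#' @param kind Latent-signal shape on the marker genes: `"cyclic"` (one
#'   harmonic of a phase), `"linear-gradient"` (zonation-style monotone
#'   trend) or `"categorical"` (two discrete signal states).
#' @param amplitude_range Range of per-gene log-scale amplitudes for the
#'   signal genes.
#' @param type_effect_sd Standard deviation of per-gene, per-type log-fold
#'   effects on non-marker genes.
#' @param n_spiked_genes,spike_lfc Optional: the first `n_spiked_genes`
#'   non-marker genes get an extra `spike_lfc` log-fold increase in cells of
#'   cell type 1 (used to benchmark upregulated-gene discovery).
#' @param n_batches,batch_sd Batches and the SD of their per-gene log-normal
#'   multiplicative effects.
#' @param lib_meanlog,lib_sdlog Log-normal library-size parameters.
#' @param dispersion_range Range of per-gene NB dispersions (gamma shapes).
#' @param seed Random seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 1500L, fraction_cycling = 2 / 3,
                       n_cycle_genes = 120L, n_other_genes = 280L,
                       n_cell_types = 3L,
                       kind = c("cyclic", "linear-gradient", "categorical"),
                       amplitude_range = c(0.5, 1.5),
                       type_effect_sd = 0.5,
                       n_spiked_genes = 0L, spike_lfc = 1.5,
                       n_batches = 2L, batch_sd = 0.3,
                       lib_meanlog = 9, lib_sdlog = 0.3,
                       dispersion_range = c(5, 50), seed = 1L) {
  kind <- match.arg(kind)
  if (fraction_cycling < 0 || fraction_cycling > 1)
    .err_invalid("fraction_cycling must be in [0, 1]")
  if (n_cells < 2L || n_cycle_genes < 1L || n_other_genes < 1L)
    .err_invalid("cell and gene counts must be positive")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a single-cell count matrix with ground truth
#'
#' Signal (marker) gene `g` in a signal-carrying cell `c` has NB mean
#' `s_c * w_g * exp(b_g * cos(phi_c - psi_g))` for the cyclic kind (with a
#' per-gene phase offset `psi_g` and amplitude `b_g`), where `s_c` is the
#' cell's library-size factor and `w_g` a baseline rate. Cells without the
#' signal use `b_g = 0`. The linear-gradient kind replaces the harmonic with
#' `b_g * sign_g * (pos_c - 0.5)`; the categorical kind with a two-level
#' shift. Non-marker genes carry cell-type log-fold effects; batches act as
#' per-gene multiplicative log-normal factors; counts are NB draws.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (cells x genes integer matrix), `genes` (data
#'   frame: name, marker flag, amplitude, offset, spiked flag), and `truth`
#'   (data frame per cell: phase / position, cycling flag, cell type, batch,
#'   library size).
#' @export
simulate_cells <- function(config = sim_config()) {
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_cells
  Gm <- cf$n_cycle_genes; Go <- cf$n_other_genes; G <- Gm + Go
  cycling <- rep(FALSE, n)
  cycling[sample.int(n, round(cf$fraction_cycling * n))] <- TRUE
  phase <- rep(NA_real_, n)
  if (cf$kind == "cyclic") {
    phase[cycling] <- stats::runif(sum(cycling), 0, 2 * pi)
  } else if (cf$kind == "linear-gradient") {
    phase[cycling] <- stats::runif(sum(cycling))
  } else {
    phase[cycling] <- sample(0:1, sum(cycling), replace = TRUE)
  }
  ctype <- sample.int(cf$n_cell_types, n, replace = TRUE)
  batch <- sample.int(cf$n_batches, n, replace = TRUE)
  lib <- stats::rlnorm(n, cf$lib_meanlog, cf$lib_sdlog)

  # baseline gene weights, normalised so each cell's expected total ~ lib
  w <- stats::rlnorm(G, 0, 1)
  w <- w / sum(w)
  amp <- stats::runif(Gm, cf$amplitude_range[1], cf$amplitude_range[2])
  psi <- stats::runif(Gm, 0, 2 * pi)
  grad_sign <- sample(c(-1, 1), Gm, replace = TRUE)
  type_eff <- matrix(stats::rnorm(Go * cf$n_cell_types, 0, cf$type_effect_sd),
                     Go, cf$n_cell_types)
  spiked <- rep(FALSE, Go)
  if (cf$n_spiked_genes > 0L) {
    spiked[seq_len(min(cf$n_spiked_genes, Go))] <- TRUE
    type_eff[spiked, 1L] <- type_eff[spiked, 1L] + cf$spike_lfc
    # spiked genes are adequately expressed: discovery ranks genes by the
    # raw decoded difference, which is only meaningful above noise level
    # (real stimulation-response panels consist of robustly expressed genes)
    wo <- w[Gm + seq_len(Go)]
    floor_w <- stats::quantile(wo, 0.75)
    w[Gm + which(spiked)] <- pmax(w[Gm + which(spiked)], floor_w)
    w <- w / sum(w)
  }
  batch_eff <- matrix(stats::rnorm(G * cf$n_batches, 0, cf$batch_sd), G, cf$n_batches)
  theta <- stats::runif(G, cf$dispersion_range[1], cf$dispersion_range[2])

  # log-rate matrix (cells x genes)
  eta <- matrix(rep(log(w), each = n), n, G)
  ph <- ifelse(cycling, phase, 0)
  if (cf$kind == "cyclic") {
    sig <- outer(ph, psi, function(p, q) cos(p - q)) * rep(amp, each = n)
  } else if (cf$kind == "linear-gradient") {
    sig <- outer(ph - 0.5, grad_sign) * rep(amp, each = n)
  } else {
    sig <- outer(ph - 0.5, grad_sign) * rep(amp, each = n)
  }
  sig[!cycling, ] <- 0
  eta[, seq_len(Gm)] <- eta[, seq_len(Gm)] + sig
  eta[, Gm + seq_len(Go)] <- eta[, Gm + seq_len(Go)] + t(type_eff[, ctype])
  eta <- eta + t(batch_eff[, batch])
  mu <- lib * exp(eta)
  counts <- matrix(stats::rnbinom(n * G, mu = mu, size = rep(theta, each = n)), n, G)
  gene_names <- c(sprintf("MK%03d", seq_len(Gm)), sprintf("OT%03d", seq_len(Go)))
  colnames(counts) <- gene_names
  rownames(counts) <- sprintf("cell%04d", seq_len(n))
  genes <- data.frame(
    name = gene_names,
    marker = c(rep(TRUE, Gm), rep(FALSE, Go)),
    baseline = w,
    amplitude = c(amp, rep(0, Go)),
    offset = c(psi, rep(NA_real_, Go)),
    gradient_sign = c(grad_sign, rep(NA_real_, Go)),
    spiked = c(rep(FALSE, Gm), spiked),
    dispersion = theta)
  truth <- data.frame(
    cell = rownames(counts),
    phase = phase,
    cycling = cycling,
    cell_type = ctype,
    batch = factor(paste0("b", batch)),
    lib_size = lib)
  list(counts = counts, genes = genes, truth = truth, config = cf,
       batch_effects = batch_eff)
}

#' Canonical small test fixture
#'
#' Deterministic dataset used throughout the test-suite: 1,500 cells (1,000
#' cycling, 500 non-cycling, all spread over 3 cell types), 120 cycle-marker
#' genes, 280 other genes, 2 batches.
#'
#' @param seed Seed (fixed default for the canonical fixture).
#' @return See [simulate_cells()].
#' @export
fixture_small <- function(seed = 20240501L) {
  simulate_cells(sim_config(seed = seed))
}
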