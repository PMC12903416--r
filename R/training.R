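# Optimisation loop: AdamW over shuffled minibatches with a single
# reparameterised Monte-Carlo sample per cell per step, stop-gradient
# scheduling, and a per-epoch loss history.

#' Train a decomposed-latent model
#'
#' Runs the published recipe: AdamW (learning rate and weight decay from the
#' model's [train_config()]) over shuffled minibatches, one reparameterised
#' sample per cell per step, for `epochs` epochs. Stop-gradient is active for
#' component `j` during its first `stop_grad_epochs` epochs, blocking the
#' gradients of `j`'s reconstruction from reaching the other components'
#' encoders. Fully deterministic given the config seed (single-threaded).
#'
#' @param model A [build_model()] result.
#' @param counts Cells-by-genes UMI count matrix (dense or `Matrix` sparse).
#' @param batch_df Data frame of batch covariates (if the model uses any).
#' @param epochs Number of epochs; defaults to the config value.
#' @param verbose Print a progress line every `verbose` epochs (0 = quiet).
#' @return The model with trained parameters, `trained_epochs` updated and a
#'   `history` data frame (epoch, loss, kl, recon, seconds).
#' @export
train_model <- function(model, counts, batch_df = NULL,
                        epochs = model$config$epochs, verbose = 0L) {
  cfg <- model$config
  dat <- .prep_data(model, counts, batch_df)
  if (dat$n < 1L) .err_invalid("empty dataset")
  epochs <- as.integer(epochs)
  if (epochs == 0L) {
    model$history <- data.frame(epoch = integer(), loss = numeric(),
                                kl = numeric(), recon = numeric(),
                                seconds = numeric())
    return(model)
  }
  set.seed(cfg$seed + 1L)
  state <- .adamw_init(model$params)
  hist <- matrix(NA_real_, epochs, 4L)
  n <- dat$n
  bs <- min(cfg$batch_size, n)
  for (ep in seq_len(epochs)) {
    t0 <- proc.time()[["elapsed"]]
    perm <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    ep_loss <- ep_kl <- ep_rec <- 0
    for (s in starts) {
      idx <- perm[s:min(s + bs - 1L, n)]
      fb <- .model_fb(model, dat, idx, epoch = ep, want_grads = TRUE)
      upd <- .adamw_step(model$params, fb$grads, state,
                         lr = cfg$lr, weight_decay = cfg$weight_decay)
      model$params <- upd$params
      state <- upd$state
      wgt <- length(idx) / n
      ep_loss <- ep_loss + fb$loss * wgt
      ep_kl <- ep_kl + fb$kl * wgt
      ep_rec <- ep_rec + fb$recon * wgt
    }
    hist[ep, ] <- c(ep_loss, ep_kl, ep_rec, proc.time()[["elapsed"]] - t0)
    if (verbose > 0L && ep %% verbose == 0L)
      message(sprintf("epoch %4d  -ELBO %.3f  KL %.3f  recon %.3f  (%.2fs)",
                      ep, ep_loss, ep_kl, ep_rec, hist[ep, 4L]))
  }
  model$trained_epochs <- model$trained_epochs + epochs
  model$history <- rbind(model$history,
                         data.frame(epoch = seq_len(epochs) +
                                      (model$trained_epochs - epochs),
                                    loss = hist[, 1L], kl = hist[, 2L],
                                    recon = hist[, 3L], seconds = hist[, 4L]))
  model
}
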