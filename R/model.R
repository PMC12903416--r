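# The decomposed-latent variational autoencoder: gene partition, masked
# per-component encoders, per-component decoders with a negative-binomial
# likelihood and batch covariates, and the evidence lower bound with
# hand-derived backpropagation (including through the Lorentz-model
# exponential map, parallel transport and wrapped-normal densities).

# ---- gene partition --------------------------------------------------------

#' Partition genes into latent components
#'
#' The first `length(markers)` components own the supplied marker-gene sets;
#' a final component implicitly owns every gene not claimed earlier. Any two
#' marker sets must be identical or disjoint; identical sets share one
#' decoder (the duplicate block is not re-modelled).
#'
#' @param G Total number of genes.
#' @param markers Named list of integer index vectors (1-based) or character
#'   vectors resolved against `gene_names`.
#' @param gene_names Optional character vector of length `G`.
#' @return An object of class `gene_partition`.
#' @export
gene_partition <- function(G, markers = list(), gene_names = NULL) {
  G <- as.integer(G)
  if (length(markers) && (is.null(names(markers)) || any(names(markers) == "")))
    names(markers) <- paste0("signal", seq_along(markers))
  sets <- lapply(markers, function(m) {
    if (is.character(m)) {
      if (is.null(gene_names)) .err_invalid("character markers require gene_names")
      idx <- match(m, gene_names)
      n_missing <- sum(is.na(idx))
      if (n_missing > 0)
        warning(sprintf("%d marker symbols not found in the matrix; excluded", n_missing))
      idx <- idx[!is.na(idx)]
    } else idx <- as.integer(m)
    idx <- sort(unique(idx))
    if (!length(idx)) .err_invalid("empty marker set")
    if (any(idx < 1L | idx > G)) .err_invalid("marker index out of range")
    idx
  })
  for (a in seq_along(sets)) for (b in seq_len(a - 1L)) {
    ov <- length(intersect(sets[[a]], sets[[b]]))
    if (ov > 0 && !(identical(sets[[a]], sets[[b]])))
      .err_invalid("marker sets must be identical or disjoint")
  }
  rest <- setdiff(seq_len(G), unique(unlist(sets)))
  if (!length(rest)) .err_invalid("no genes left for the final component")
  sets <- c(sets, list(rest))
  names(sets)[length(sets)] <- "rest"
  k <- length(sets)
  owner <- integer(k); modeled <- logical(k)
  seen <- list()
  for (j in seq_len(k)) {
    hit <- 0L
    for (s in seq_along(seen)) if (identical(sets[[j]], sets[[seen[[s]]]])) hit <- seen[[s]]
    if (hit > 0L) { owner[j] <- hit; modeled[j] <- FALSE }
    else { owner[j] <- j; modeled[j] <- TRUE; seen <- c(seen, list(j)) }
  }
  structure(list(sets = sets, G = G, k = k, owner = owner, modeled = modeled,
                 gene_names = gene_names),
            class = "gene_partition")
}

#' Split a count vector by partition components
#'
#' @param x Count vector of length `G` (or a cells-by-genes matrix).
#' @param partition A [gene_partition()].
#' @return List of per-component count vectors (or matrices).
#' @export
partition_counts <- function(x, partition) {
  single <- is.null(dim(x))
  xm <- if (single) matrix(x, 1L) else as.matrix(x)
  if (ncol(xm) != partition$G) .err_invalid("length of x does not match partition G")
  out <- lapply(partition$sets, function(s) {
    blk <- xm[, s, drop = FALSE]
    if (single) drop(blk) else blk
  })
  out
}

# ---- latent specification --------------------------------------------------

#' Specify one latent component
#'
#' @param space A [curvature_space()].
#' @param distribution `"normal"` (Euclidean), `"wrapped-normal"` (curved),
#'   or `"rown"` (hyperbolic, radially rotated covariance). Defaults by
#'   geometry.
#' @param decode_inputs Indices of latent components fed to this component's
#'   decoder. Defaults: a non-final component is decoded from the components
#'   sharing its gene set (normally just itself); the final component from
#'   all latents.
#' @param stop_grad_epochs Number of initial epochs during which gradients
#'   from reconstructing this component's genes are blocked from reaching the
#'   other components' latents.
#' @return An object of class `latent_spec`.
#' @export
latent_spec <- function(space, distribution = NULL, decode_inputs = NULL,
                        stop_grad_epochs = 0L) {
  if (is.null(distribution))
    distribution <- if (space$kind == "euclidean") "normal" else "wrapped-normal"
  distribution <- match.arg(distribution, c("normal", "wrapped-normal", "rown"))
  if (distribution == "normal" && space$kind != "euclidean")
    .err_invalid("'normal' distribution requires a euclidean space")
  if (distribution != "normal" && space$kind == "euclidean")
    .err_invalid("wrapped distributions require a curved space")
  if (distribution == "rown" && space$kind != "hyperbolic")
    .err_invalid("'rown' requires a hyperbolic space")
  structure(list(space = space, distribution = distribution,
                 decode_inputs = decode_inputs,
                 stop_grad_epochs = as.integer(stop_grad_epochs)),
            class = "latent_spec")
}

#' Per-cell batch covariates
#'
#' @param data Data frame of categorical covariates (one row per cell), or
#'   `NULL` for none.
#' @param applicability Optional logical matrix `k x ncol(data)` saying which
#'   covariates are appended to each component's decoder (default: all).
#' @return An object of class `batch_design`.
#' @export
batch_design <- function(data = NULL, applicability = NULL) {
  if (is.null(data)) {
    return(structure(list(levels = list(), applicability = NULL),
                     class = "batch_design"))
  }
  data <- as.data.frame(data)
  levels <- lapply(data, function(col) levels(factor(col)))
  structure(list(levels = levels, applicability = applicability),
            class = "batch_design")
}

#' Training configuration
#'
#' Defaults follow the published recipe: 500 epochs of AdamW (learning rate
#' 1e-3, weight decay 0.01) on minibatches of 128 cells, encoder widths
#' 128-64-32 and decoder widths 64-128 with GELU activations, and a single
#' reparameterised Monte-Carlo sample per cell per step.
#'
#' @param epochs,batch_size,lr,weight_decay,seed Optimisation settings.
#' @param enc_widths,dec_widths Hidden-layer widths.
#' @param sigma_floor Additive floor on posterior scales after softplus.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 500L, batch_size = 128L, lr = 1e-3,
                         weight_decay = 0.01, seed = 1L,
                         enc_widths = c(128L, 64L, 32L),
                         dec_widths = c(64L, 128L),
                         sigma_floor = 1e-4) {
  if (epochs < 0L) .err_invalid("epochs must be >= 0")
  if (lr <= 0) .err_invalid("lr must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, seed = as.integer(seed),
                 enc_widths = as.integer(enc_widths),
                 dec_widths = as.integer(dec_widths),
                 sigma_floor = sigma_floor),
            class = "train_config")
}

# ---- model construction ----------------------------------------------------

#' Build and initialise a decomposed-latent model
#'
#' Weights use the framework-style fan-in uniform initialisation, except the
#' layers emitting the posterior parameters of the first (signal) component,
#' which use Xavier-normal. Initialisation is deterministic given
#' `config$seed`.
#'
#' @param partition A [gene_partition()].
#' @param specs List of [latent_spec()], one per component (including the
#'   final remainder component).
#' @param batch A [batch_design()] or `NULL`.
#' @param config A [train_config()].
#' @return An object of class `curvae_model`.
#' @export
build_model <- function(partition, specs, batch = NULL, config = train_config()) {
  k <- partition$k
  if (length(specs) != k) .err_invalid(sprintf("need %d latent specs, got %d", k, length(specs)))
  if (is.null(batch)) batch <- batch_design(NULL)
  ncov <- length(batch$levels)
  app <- batch$applicability
  if (is.null(app)) app <- matrix(TRUE, k, max(ncov, 0L))
  if (ncov > 0 && (nrow(app) != k || ncol(app) != ncov))
    .err_invalid("applicability must be k x n_covariates")
  # default decoder wiring: sharers of the same gene set; final gets all
  for (j in seq_len(k)) {
    if (is.null(specs[[j]]$decode_inputs)) {
      specs[[j]]$decode_inputs <-
        if (j == k) seq_len(k) else which(vapply(seq_len(k), function(l)
          identical(partition$sets[[l]], partition$sets[[j]]), logical(1)))
    }
    if (!(j %in% specs[[j]]$decode_inputs))
      .err_invalid("a component's own latent must be among its decode inputs")
  }
  amb <- vapply(specs, function(s) s$space$ambient, integer(1))
  onehot_w <- vapply(batch$levels, length, integer(1))
  disp_levels <- if (ncov > 0) length(batch$levels[[1]]) else 1L

  set.seed(config$seed)
  params <- list()
  for (j in which(partition$modeled)) {
    m <- length(partition$sets[[j]])
    widths <- c(m, config$enc_widths)
    for (l in seq_along(config$enc_widths)) {
      params[[sprintf("e%d.t%d", j, l)]] <- .init_linear(widths[l], widths[l + 1L])
    }
    head_init <- if (j == 1L) "xavier" else "default"
    d <- specs[[j]]$space$d
    last <- widths[length(widths)]
    params[[sprintf("e%d.loc", j)]] <- .init_linear(last, d, head_init)
    params[[sprintf("e%d.sc", j)]] <- .init_linear(last, d, head_init)
    din <- sum(amb[specs[[j]]$decode_inputs]) +
      if (ncov > 0) sum(onehot_w[app[j, ]]) else 0L
    dwidths <- c(din, config$dec_widths)
    for (l in seq_along(config$dec_widths)) {
      params[[sprintf("d%d.t%d", j, l)]] <- .init_linear(dwidths[l], dwidths[l + 1L])
    }
    params[[sprintf("d%d.out", j)]] <- .init_linear(dwidths[length(dwidths)], m)
    params[[sprintf("th%d", j)]] <- matrix(0, m, disp_levels)
  }
  # flatten list(W,b) pairs into the flat parameter list
  flat <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p)) { flat[[paste0(nm, ".W")]] <- p$W; flat[[paste0(nm, ".b")]] <- p$b }
    else flat[[nm]] <- p
  }
  structure(list(partition = partition, specs = specs, batch = batch,
                 applicability = app, config = config, params = flat,
                 disp_levels = disp_levels, trained_epochs = 0L,
                 history = NULL),
            class = "curvae_model")
}

#' @export
print.curvae_model <- function(x, ...) {
  cat(sprintf("<curvae_model> %d components over %d genes; trained %d epochs\n",
              x$partition$k, x$partition$G, x$trained_epochs))
  for (j in seq_len(x$partition$k)) {
    s <- x$specs[[j]]
    cat(sprintf("  [%d] %s (%s, K=%g, d=%d): %d genes%s\n", j,
                names(x$partition$sets)[j], s$space$kind, s$space$K, s$space$d,
                length(x$partition$sets[[j]]),
                if (!x$partition$modeled[j]) " (shared, not re-modelled)" else ""))
  }
  invisible(x)
}

# ---- data preparation ------------------------------------------------------

# Dense per-component views of the counts plus covariate one-hots.
.prep_data <- function(model, counts, batch_df = NULL) {
  X <- as.matrix(counts)
  if (any(!is.finite(X))) .err_invalid("counts contain non-finite values")
  if (any(X < 0) || any(abs(X - round(X)) > 1e-8))
    .err_invalid("counts must be nonnegative integers")
  if (ncol(X) != model$partition$G) .err_invalid("gene dimension does not match the partition")
  n <- nrow(X)
  lev <- model$batch$levels
  ncov <- length(lev)
  if (ncov > 0) {
    if (is.null(batch_df)) .err_invalid("model expects batch covariates")
    batch_df <- as.data.frame(batch_df)
    if (nrow(batch_df) != n) .err_invalid("batch covariates must have one row per cell")
    onehot <- vector("list", ncov)
    for (cvi in seq_len(ncov)) {
      vals <- as.character(batch_df[[cvi]])
      bad <- setdiff(unique(vals), lev[[cvi]])
      if (length(bad)) .err_invalid(sprintf("unknown batch level '%s'", bad[1]))
      f <- factor(vals, levels = lev[[cvi]])
      oh <- matrix(0, n, length(lev[[cvi]]))
      oh[cbind(seq_len(n), as.integer(f))] <- 1
      onehot[[cvi]] <- oh
    }
    disp_lev <- as.integer(factor(as.character(batch_df[[1]]), levels = lev[[1]]))
  } else {
    onehot <- list()
    disp_lev <- rep(1L, n)
  }
  mod <- which(model$partition$modeled)
  Xin <- Xct <- Xlg <- setNames(vector("list", model$partition$k),
                                names(model$partition$sets))
  for (j in mod) {
    Xct[[j]] <- X[, model$partition$sets[[j]], drop = FALSE]
    Xin[[j]] <- log1p(Xct[[j]])
    Xlg[[j]] <- lgamma(Xct[[j]] + 1)   # constant term, hoisted out of the loop
  }
  list(n = n, lib = rowSums(X), Xin = Xin, Xct = Xct, Xlg = Xlg,
       onehot = onehot, disp_lev = disp_lev)
}

# ---- geometry helpers for the fused forward/backward ----------------------

# d/da log( sn(a)/a ): coth(a) - 1/a (hyperbolic), cot(a) - 1/a (sphere).
.hlogsnc <- function(kind, a) {
  small <- abs(a) < 1e-4
  if (kind == "hyperbolic") {
    out <- ifelse(small, a / 3, 1 / tanh(pmax(a, 1e-12)) - 1 / pmax(a, 1e-12))
  } else {
    out <- ifelse(small, -a / 3, 1 / tan(pmax(a, 1e-12)) - 1 / pmax(a, 1e-12))
  }
  out
}

# d/dr of sn(sqrt(c) r)/(sqrt(c) r): (sqrt(c)/a) (cs(a) - snc(a)).
.dsnc_dr <- function(space, a, sqc) {
  small <- abs(a) < 1e-4
  sgn <- if (space$kind == "hyperbolic") 1 else -1
  ifelse(small, sgn * sqc * a / 3,
         (sqc / pmax(a, 1e-12)) * (.cs(space, a) - .snc(space, a)))
}

# derivative of cs(a): sinh (hyperbolic) or -sin (sphere)
.csp <- function(space, a) if (space$kind == "hyperbolic") sinh(a) else -sin(a)

# ---- fused forward (and optional backward) ---------------------------------

# Runs the whole model on the cells indexed by `idx`. Returns loss parts,
# per-component posteriors and latent samples, and (optionally) flat
# gradients. `eps_list` injects the reparameterisation noise for tests.
.model_fb <- function(model, dat, idx, eps_list = NULL, epoch = Inf,
                      want_grads = FALSE, sample_latent = TRUE) {
  prt <- model$partition; specs <- model$specs; prm <- model$params
  cfg <- model$config
  mod <- which(prt$modeled)
  k <- prt$k
  n <- length(idx)
  lam <- 1 / n
  lib <- dat$lib[idx]
  nenc <- length(cfg$enc_widths); ndec <- length(cfg$dec_widths)

  enc_layers <- function(j) lapply(seq_len(nenc), function(l)
    list(W = prm[[sprintf("e%d.t%d.W", j, l)]], b = prm[[sprintf("e%d.t%d.b", j, l)]]))
  dec_layers <- function(j) lapply(seq_len(ndec), function(l)
    list(W = prm[[sprintf("d%d.t%d.W", j, l)]], b = prm[[sprintf("d%d.t%d.b", j, l)]]))
  layer <- function(nm) list(W = prm[[paste0(nm, ".W")]], b = prm[[paste0(nm, ".b")]])

  C <- vector("list", k)
  kl_sum <- numeric(n)
  for (j in mod) {
    sp <- specs[[j]]$space
    d <- sp$d
    el <- enc_layers(j)
    tr <- .trunk_forward(dat$Xin[[j]][idx, , drop = FALSE], el)
    tloc <- .linear_forward(tr$out, layer(sprintf("e%d.loc", j)))
    sraw <- .linear_forward(tr$out, layer(sprintf("e%d.sc", j)))
    sig <- .softplus(sraw) + cfg$sigma_floor
    eps <- if (!is.null(eps_list)) eps_list[[j]] else if (sample_latent)
      matrix(stats::rnorm(n * d), n, d) else matrix(0, n, d)
    cc <- list(tr = tr, tloc = tloc, sraw = sraw, sig = sig, eps = eps, el = el)
    if (sp$kind == "euclidean") {
      z <- tloc + sig * eps
      cc$z <- z
      cc$kl <- -rowSums(log(sig)) - 0.5 * rowSums(eps^2) + 0.5 * rowSums(z^2)
    } else {
      c0 <- abs(sp$K); sqc <- sqrt(c0)
      w <- sig * eps
      rq <- sqrt(rowSums(w^2))
      vt <- if (specs[[j]]$distribution == "rown") .rown_apply(w, tloc) else w
      tn <- pmax(sqrt(rowSums(tloc^2)), 1e-12)
      a0 <- sqc * tn
      mu <- cbind(.cs(sp, a0) / sqc, .snc(sp, a0) * tloc, deparse.level = 0)
      alpha <- sqc * mu[, 1L]
      pt_sign <- if (sp$kind == "hyperbolic") 1 else -1
      q1 <- rowSums(mu[, -1L, drop = FALSE] * vt)
      gam <- pt_sign * c0 * q1 / (1 + alpha)
      u0 <- gam * (1 / sqc + mu[, 1L])
      usp <- vt + gam * mu[, -1L, drop = FALSE]
      a <- sqc * rq
      csa <- .cs(sp, a); Sa <- .snc(sp, a)
      z <- csa * mu + Sa * cbind(u0, usp, deparse.level = 0)
      if (sp$kind == "hyperbolic") {
        alphap <- pmax(sqc * z[, 1L], 1 + 1e-9)
        rp <- acosh(alphap) / sqc
      } else {
        alphap <- pmin(pmax(sqc * z[, 1L], -1 + 1e-9), 1 - 1e-9)
        rp <- acos(alphap) / sqc
      }
      cc <- c(cc, list(w = w, rq = rq, vt = vt, tn = tn, a0 = a0, mu = mu,
                       alpha = alpha, q1 = q1, gam = gam, u0 = u0, usp = usp,
                       a = a, csa = csa, Sa = Sa, z = z, alphap = alphap,
                       rp = rp, pt_sign = pt_sign, c0 = c0, sqc = sqc))
      cc$kl <- -rowSums(log(sig)) - 0.5 * rowSums(eps^2) -
        (d - 1) * log(.snc(sp, a)) + 0.5 * rp^2 + (d - 1) * log(.snc(sp, sqc * rp))
    }
    C[[j]] <- cc
    kl_sum <- kl_sum + cc$kl
  }

  # decoders
  recon_sum <- numeric(n)
  D <- vector("list", k)
  app <- model$applicability
  disp_lev <- dat$disp_lev[idx]
  for (j in mod) {
    din_parts <- lapply(specs[[j]]$decode_inputs, function(l) C[[prt$owner[l]]]$z)
    cov_idx <- if (length(dat$onehot)) which(app[j, ]) else integer(0)
    oh_parts <- lapply(cov_idx, function(cvi) dat$onehot[[cvi]][idx, , drop = FALSE])
    Din <- do.call(cbind, c(din_parts, oh_parts))
    dl <- dec_layers(j)
    dtr <- .trunk_forward(Din, dl)
    out_layer <- layer(sprintf("d%d.out", j))
    logits <- .linear_forward(dtr$out, out_layer)
    P <- .softmax_rows(logits)
    Mu <- pmax(P * lib, 1e-12)
    th_lev <- exp(prm[[sprintf("th%d", j)]])        # genes x dispersion levels
    theta <- t(th_lev[, disp_lev, drop = FALSE])
    lg_th <- t(lgamma(th_lev)[, disp_lev, drop = FALSE])
    log_th <- t(log(th_lev)[, disp_lev, drop = FALSE])
    Xj <- dat$Xct[[j]][idx, , drop = FALSE]
    log_tm <- log(theta + Mu)
    ll <- lgamma(Xj + theta) - lg_th - dat$Xlg[[j]][idx, , drop = FALSE] +
      theta * (log_th - log_tm) + Xj * (log(Mu) - log_tm)
    recon <- rowSums(ll)
    D[[j]] <- list(Din = Din, dtr = dtr, P = P, Mu = Mu, theta = theta,
                   log_th = log_th, log_tm = log_tm, th_lev = th_lev,
                   Xj = Xj, dl = dl, out_layer = out_layer, recon = recon,
                   din_widths = vapply(specs[[j]]$decode_inputs, function(l)
                     specs[[l]]$space$ambient, integer(1)))
    recon_sum <- recon_sum + recon
  }

  res <- list(loss = mean(kl_sum) - mean(recon_sum),
              kl = mean(kl_sum), recon = mean(recon_sum),
              comps = C, dec = D)
  if (!want_grads) return(res)

  # ---- backward -----------------------------------------------------------
  grads <- list()
  dz <- vector("list", k)
  for (j in mod) dz[[j]] <- matrix(0, n, ncol(C[[j]]$z))

  for (j in mod) {
    dd <- D[[j]]
    ratio <- (dd$Xj + dd$theta) / (dd$theta + dd$Mu)
    dMu <- -lam * (dd$Xj / dd$Mu - ratio)
    di_th <- t(digamma(dd$th_lev)[, disp_lev, drop = FALSE])
    dTh_ll <- digamma(dd$Xj + dd$theta) - di_th +
      dd$log_th + 1 - dd$log_tm - ratio
    dLogTheta <- -lam * dTh_ll * dd$theta
    agg <- rowsum(dLogTheta, group = disp_lev)
    gth <- matrix(0, ncol(dd$Xj), model$disp_levels)
    gth[, as.integer(rownames(agg))] <- t(agg)
    grads[[sprintf("th%d", j)]] <- gth
    dP <- dMu * lib
    dlogits <- dd$P * (dP - rowSums(dP * dd$P))
    lb <- .linear_backward(dlogits, dd$dtr$out, dd$out_layer)
    grads[[sprintf("d%d.out.W", j)]] <- lb$grads$W
    grads[[sprintf("d%d.out.b", j)]] <- lb$grads$b
    tb <- .trunk_backward(lb$dX, dd$dtr, dd$dl)
    for (l in seq_len(ndec)) {
      grads[[sprintf("d%d.t%d.W", j, l)]] <- tb$grads[[l]]$W
      grads[[sprintf("d%d.t%d.b", j, l)]] <- tb$grads[[l]]$b
    }
    # split decoder-input gradient back to the latents (stop-gradient aware)
    off <- 0L
    sg_active <- epoch <= model$specs[[j]]$stop_grad_epochs
    for (ii in seq_along(model$specs[[j]]$decode_inputs)) {
      l <- model$specs[[j]]$decode_inputs[ii]
      wdt <- dd$din_widths[ii]
      slice <- tb$dX[, off + seq_len(wdt), drop = FALSE]
      off <- off + wdt
      tgt <- prt$owner[l]
      if (!(sg_active && tgt != j)) dz[[tgt]] <- dz[[tgt]] + slice
    }
  }

  # prior (KL) path through z, then back through the sampling chain
  for (j in mod) {
    sp <- specs[[j]]$space; d <- sp$d
    cc <- C[[j]]
    sig <- cc$sig; eps <- cc$eps
    if (sp$kind == "euclidean") {
      dzj <- dz[[j]] + lam * cc$z
      dt <- dzj
      dsig <- dzj * eps - lam / sig
    } else {
      c0 <- cc$c0; sqc <- cc$sqc
      dzj <- dz[[j]]
      fac <- lam * (cc$rp + (d - 1) * sqc * .hlogsnc(sp$kind, sqc * cc$rp))
      drp_dz0 <- if (sp$kind == "hyperbolic") 1 / sqrt(cc$alphap^2 - 1) else
        -1 / sqrt(1 - cc$alphap^2)
      dzj[, 1L] <- dzj[, 1L] + fac * drp_dz0
      # z = cs(a) mu + snc(a) u
      mu <- cc$mu; Umat <- cbind(cc$u0, cc$usp, deparse.level = 0)
      dmu <- cc$csa * dzj
      du <- cc$Sa * dzj
      dz_dr <- sqc * .csp(sp, cc$a) * mu + .dsnc_dr(sp, cc$a, sqc) * Umat
      scal <- rowSums(dzj * dz_dr)
      jsign <- if (sp$kind == "hyperbolic") -1 else 1
      rsafe <- pmax(cc$rq, 1e-12)
      du[, 1L] <- du[, 1L] + (scal / rsafe) * (jsign * cc$u0)
      du[, -1L] <- du[, -1L] + (scal / rsafe) * cc$usp
      # parallel transport: u = v + gam (mu0 + mu)
      ggam <- du[, 1L] * (1 / sqc + mu[, 1L]) +
        rowSums(du[, -1L, drop = FALSE] * mu[, -1L, drop = FALSE])
      coefv <- cc$pt_sign * c0 / (1 + cc$alpha)
      dvt <- du[, -1L, drop = FALSE] + (ggam * coefv) * mu[, -1L, drop = FALSE]
      dmu[, -1L] <- dmu[, -1L, drop = FALSE] + cc$gam * du[, -1L, drop = FALSE] +
        (ggam * coefv) * cc$vt
      dmu[, 1L] <- dmu[, 1L] + cc$gam * du[, 1L] -
        ggam * cc$gam * sqc / (1 + cc$alpha)
      # rotated covariance: vt = R(t) w; gradient flows to w through R^T and
      # to the location through the rotation's dependence on the direction
      dt_rown <- 0
      if (specs[[j]]$distribution == "rown") {
        dw <- .rown_apply(dvt, cc$tloc, transpose = TRUE)
        dt_rown <- .rown_backward_t(dvt, cc$w, cc$tloc)
      } else dw <- dvt
      # sigma: sampling path + the variational-entropy terms of the KL
      hq <- .hlogsnc(sp$kind, cc$a)
      dsig <- dw * eps - lam / sig -
        lam * (d - 1) * hq * sqc * (sig * eps^2) / pmax(cc$rq, 1e-12)
      # mu = exp_map at origin of (0, tloc)
      tdir <- cc$tloc / cc$tn
      dt <- dmu[, 1L] * .csp(sp, cc$a0) * tdir +
        .snc(sp, cc$a0) * dmu[, -1L, drop = FALSE] +
        (rowSums(dmu[, -1L, drop = FALSE] * cc$tloc) * .dsnc_dr(sp, cc$a0, sqc)) * tdir +
        dt_rown
    }
    dsraw <- dsig * .sigmoid(cc$sraw)
    lb_loc <- .linear_backward(dt, cc$tr$out, layer(sprintf("e%d.loc", j)))
    lb_sc <- .linear_backward(dsraw, cc$tr$out, layer(sprintf("e%d.sc", j)))
    grads[[sprintf("e%d.loc.W", j)]] <- lb_loc$grads$W
    grads[[sprintf("e%d.loc.b", j)]] <- lb_loc$grads$b
    grads[[sprintf("e%d.sc.W", j)]] <- lb_sc$grads$W
    grads[[sprintf("e%d.sc.b", j)]] <- lb_sc$grads$b
    tb <- .trunk_backward(lb_loc$dX + lb_sc$dX, cc$tr, cc$el)
    for (l in seq_len(nenc)) {
      grads[[sprintf("e%d.t%d.W", j, l)]] <- tb$grads[[l]]$W
      grads[[sprintf("e%d.t%d.b", j, l)]] <- tb$grads[[l]]$b
    }
  }
  res$grads <- grads
  res
}

# ---- public forward interfaces --------------------------------------------

#' Negative-binomial log-likelihood
#'
#' Sum over genes of the NB log-pmf in the mean/dispersion parameterisation
#' (`dispersion` is the gamma shape; the Poisson limit is reached as it
#' grows).
#'
#' @param x Nonnegative integer count vector (or matrix, cells in rows).
#' @param mean,dispersion Positive vectors (or matrices) conforming to `x`.
#' @return Scalar (or per-cell vector) log-likelihood.
#' @export
nb_log_likelihood <- function(x, mean, dispersion) {
  single <- is.null(dim(x))
  xm <- if (single) matrix(x, 1L) else as.matrix(x)
  if (any(xm < 0) || any(abs(xm - round(xm)) > 1e-8))
    .err_invalid("counts must be nonnegative integers")
  mu <- if (is.null(dim(mean))) matrix(mean, nrow(xm), ncol(xm), byrow = single) else as.matrix(mean)
  th <- if (is.null(dim(dispersion))) matrix(dispersion, nrow(xm), ncol(xm), byrow = single) else as.matrix(dispersion)
  if (any(mu <= 0) || any(th <= 0)) .err_invalid("mean and dispersion must be positive")
  ll <- lgamma(xm + th) - lgamma(th) - lgamma(xm + 1) +
    th * log(th / (th + mu)) + xm * log(mu / (th + mu))
  out <- rowSums(ll)
  if (single) sum(out) else out
}

#' Encode cells into per-component posteriors
#'
#' Each component's posterior depends only on its own gene block (all other
#' genes are masked), matching the model's factorised variational family.
#'
#' @param model A [build_model()] result (trained or not).
#' @param counts Cells-by-genes count matrix.
#' @return List per modelled component with elements `tangent` (location in
#'   tangent coordinates at the origin), `sigma`, and `location` (ambient
#'   coordinates for curved spaces, identical to `tangent` for Euclidean).
#' @export
encode_cells <- function(model, counts) {
  dat <- .prep_data_encode(model, counts)
  res <- .model_fb(model, dat, seq_len(dat$n), sample_latent = FALSE)
  out <- list()
  for (j in which(model$partition$modeled)) {
    cc <- res$comps[[j]]
    loc <- if (model$specs[[j]]$space$kind == "euclidean") cc$tloc else cc$mu
    out[[names(model$partition$sets)[j]]] <-
      list(tangent = cc$tloc, sigma = cc$sig, location = loc)
  }
  out
}

# Encoding needs no covariates or likelihood; build a minimal data bundle.
.prep_data_encode <- function(model, counts) {
  X <- as.matrix(counts)
  if (any(!is.finite(X))) .err_invalid("counts contain non-finite values")
  if (ncol(X) != model$partition$G) .err_invalid("gene dimension does not match the partition")
  n <- nrow(X)
  mod <- which(model$partition$modeled)
  Xin <- Xct <- Xlg <- vector("list", model$partition$k)
  for (j in mod) {
    Xct[[j]] <- X[, model$partition$sets[[j]], drop = FALSE]
    Xin[[j]] <- log1p(Xct[[j]])
    Xlg[[j]] <- lgamma(Xct[[j]] + 1)
  }
  list(n = n, lib = pmax(rowSums(X), 1), Xin = Xin, Xct = Xct, Xlg = Xlg,
       onehot = lapply(model$batch$levels, function(lv) matrix(0, n, length(lv))),
       disp_lev = rep(1L, n))
}

#' Decode latent points into negative-binomial means
#'
#' Runs each component's decoder on the designated latents (ambient
#' coordinates) concatenated with the applicable one-hot covariates. Softmax
#' over each gene block times the library size gives the block means.
#'
#' @param model A `curvae_model`.
#' @param z List of latent coordinate matrices, one per component (entries
#'   for non-modelled duplicates may be `NULL`).
#' @param lib_size Per-cell library sizes (positive).
#' @param batch_df Covariate data frame (required if the model has batches).
#' @return List per modelled component: `mean` (cells x block genes) and
#'   `dispersion`; plus attribute-free helper [decoded_matrix()] assembles a
#'   full cells-by-genes matrix.
#' @export
decode_cells <- function(model, z, lib_size, batch_df = NULL) {
  prt <- model$partition
  mod <- which(prt$modeled)
  n <- nrow(z[[mod[1]]])
  if (any(lib_size <= 0)) .err_invalid("library sizes must be positive")
  lev <- model$batch$levels
  if (length(lev) > 0 && is.null(batch_df)) .err_invalid("model expects batch covariates")
  onehot <- list(); disp_lev <- rep(1L, n)
  if (length(lev) > 0) {
    batch_df <- as.data.frame(batch_df)
    for (cvi in seq_along(lev)) {
      vals <- as.character(batch_df[[cvi]])
      bad <- setdiff(unique(vals), lev[[cvi]])
      if (length(bad)) .err_invalid(sprintf("unknown batch level '%s'", bad[1]))
      f <- factor(vals, levels = lev[[cvi]])
      oh <- matrix(0, n, length(lev[[cvi]]))
      oh[cbind(seq_len(n), as.integer(f))] <- 1
      onehot[[cvi]] <- oh
    }
    disp_lev <- as.integer(factor(as.character(batch_df[[1]]), levels = lev[[1]]))
  }
  prm <- model$params
  ndec <- length(model$config$dec_widths)
  out <- setNames(vector("list", length(mod)), names(prt$sets)[mod])
  for (j in mod) {
    din_parts <- lapply(model$specs[[j]]$decode_inputs, function(l) {
      zl <- z[[prt$owner[l]]]
      if (is.null(zl)) .err_invalid("missing latent coordinates for a decode input")
      zl
    })
    cov_idx <- if (length(onehot)) which(model$applicability[j, ]) else integer(0)
    Din <- do.call(cbind, c(din_parts, onehot[cov_idx]))
    dl <- lapply(seq_len(ndec), function(l)
      list(W = prm[[sprintf("d%d.t%d.W", j, l)]], b = prm[[sprintf("d%d.t%d.b", j, l)]]))
    dtr <- .trunk_forward(Din, dl)
    logits <- .linear_forward(dtr$out, list(W = prm[[sprintf("d%d.out.W", j)]],
                                            b = prm[[sprintf("d%d.out.b", j)]]))
    P <- .softmax_rows(logits)
    out[[names(prt$sets)[j]]] <- list(
      mean = P * lib_size,
      dispersion = t(exp(prm[[sprintf("th%d", j)]])[, disp_lev, drop = FALSE]))
  }
  out
}

#' Assemble per-component decoded means into a full gene matrix
#'
#' @param model A `curvae_model`.
#' @param decoded Output of [decode_cells()].
#' @return Cells-by-genes matrix of negative-binomial means.
#' @export
decoded_matrix <- function(model, decoded) {
  prt <- model$partition
  mod <- which(prt$modeled)
  n <- nrow(decoded[[1]]$mean)
  out <- matrix(0, n, prt$G)
  if (!is.null(prt$gene_names)) colnames(out) <- prt$gene_names
  for (j in mod) out[, prt$sets[[j]]] <- decoded[[names(prt$sets)[j]]]$mean
  out
}

#' Evidence lower bound of a minibatch
#'
#' Returns the negative loss parts (`loss = -ELBO`): Monte-Carlo KL plus
#' negative reconstruction, averaged over cells and over `n_mc` independent
#' reparameterisation draws.
#'
#' @param model A `curvae_model`.
#' @param counts Cells-by-genes counts.
#' @param batch_df Covariates (if the model uses batches).
#' @param n_mc Number of Monte-Carlo draws to average over.
#' @param eps Optional list (per modelled component) of fixed noise matrices;
#'   overrides sampling and forces `n_mc = 1`.
#' @return List with `loss`, `kl`, `recon` (per-cell means).
#' @export
elbo_loss <- function(model, counts, batch_df = NULL, n_mc = 1L, eps = NULL) {
  dat <- .prep_data(model, counts, batch_df)
  idx <- seq_len(dat$n)
  if (!is.null(eps)) {
    r <- .model_fb(model, dat, idx, eps_list = eps)
    return(list(loss = r$loss, kl = r$kl, recon = r$recon))
  }
  acc <- c(loss = 0, kl = 0, recon = 0)
  for (s in seq_len(n_mc)) {
    r <- .model_fb(model, dat, idx)
    acc <- acc + c(r$loss, r$kl, r$recon)
  }
  as.list(acc / n_mc)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the weights, partition, latent specification, batch
#' levels and configuration; loading restores bit-identical forward passes.
#'
#' @param model A `curvae_model`.
#' @param path File path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "curvae_model")) .err_invalid("not a curvae model checkpoint")
  m
}
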