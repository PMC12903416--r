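# Post-hoc procedures on trained embeddings: circular pseudotime on the
# Poincare disk, rotation/flip alignment against a reference phase,
# selective and counterfactual decoding, central/portal ratio
# classification, k-NN identity transfer, and paired decode-and-rank
# discovery of upregulated genes.

#' Circular pseudotime from a 2-D hyperbolic embedding
#'
#' Projects Lorentz coordinates onto the Poincare disk and returns the angle
#' of each cell relative to the positive x-axis, in `[0, 2*pi)`. Optionally
#' recenters the disk at a new origin first (gyro-translation).
#'
#' @param z Lorentz coordinates (cells x 3) of a 2-D hyperbolic component,
#'   or 2-column Poincare coordinates when `poincare = TRUE`.
#' @param space The hyperbolic [curvature_space()] (d must be 2).
#' @param recenter_origin Optional disk point used to recenter before
#'   measuring angles.
#' @param poincare Set if `z` is already on the disk.
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
pseudotime <- function(z, space, recenter_origin = NULL, poincare = FALSE) {
  if (space$kind != "hyperbolic" || space$d != 2L)
    .err_invalid("pseudotime requires a 2-D hyperbolic component")
  p <- if (poincare) .as_mat(z, 2L) else lorentz_to_poincare(.as_mat(z, 3L), space)
  if (!is.null(recenter_origin)) p <- recenter(p, recenter_origin, space$K)
  at_origin <- rowSums(p^2) < 1e-24
  if (any(at_origin))
    warning(sprintf("%d cell(s) exactly at the origin: angle undefined, set to 0",
                    sum(at_origin)))
  ang <- atan2(p[, 2L], p[, 1L]) %% (2 * pi)
  ang[at_origin] <- 0
  ang
}

#' Align an estimated circular pseudotime with a reference
#'
#' Searches a grid of rotations combined with an optional direction flip and
#' returns the transform maximising the Pearson correlation between the
#' (rotated) estimated angles and the reference, together with the
#' correlation of the sines at that transform (which treats 0 and `2*pi` as
#' identical).
#'
#' @param est,truth Angle vectors in radians, equal length >= 3.
#' @param n_grid Number of rotation grid steps (default 720, i.e. 0.5 deg).
#' @return List: `rotation`, `flip` (logical), `r`, `sin_r`, and `aligned`
#'   (the transformed estimate).
#' @export
align_pseudotime <- function(est, truth, n_grid = 720L) {
  if (length(est) != length(truth) || length(est) < 3L)
    .err_invalid("est and truth must have equal length >= 3")
  if (stats::sd(truth) == 0 || stats::sd(est) == 0)
    .err_degenerate("constant pseudotime: correlation undefined")
  rots <- seq(0, 2 * pi, length.out = n_grid + 1L)[-(n_grid + 1L)]
  best <- list(r = -Inf)
  for (flip in c(FALSE, TRUE)) {
    base <- if (flip) (-est) else est
    for (rot in rots) {
      cand <- (base + rot) %% (2 * pi)
      r <- suppressWarnings(stats::cor(cand, truth))
      if (!is.na(r) && r > best$r)
        best <- list(rotation = rot, flip = flip, r = r, aligned = cand)
    }
  }
  best$sin_r <- suppressWarnings(stats::cor(sin(best$aligned), sin(truth)))
  best[c("rotation", "flip", "r", "sin_r", "aligned")]
}

# Resolve per-component fill points (ambient coordinates) from intrinsic
# override coordinates; default is the component's origin.
.fill_point <- function(model, j, fill, n) {
  sp <- model$specs[[j]]$space
  if (!is.null(fill[[names(model$partition$sets)[j]]])) {
    f <- as.numeric(fill[[names(model$partition$sets)[j]]])
    if (length(f) != sp$d) .err_invalid("fill override has wrong dimension")
    pt <- if (sp$kind == "euclidean") f else
      exp_map(space_origin(sp), c(0, f), sp)
  } else {
    pt <- space_origin(sp)
  }
  matrix(pt, n, length(pt), byrow = TRUE)
}

#' Selective decoding: reconstruct expression from a subset of components
#'
#' Kept components contribute each cell's posterior location; dropped
#' components are replaced by a fixed point (their origin by default, or an
#' override in intrinsic/tangent coordinates via `fill`). Decoding the
#' signal component alone enhances the signal in the reconstruction;
#' decoding the others alone filters it out.
#'
#' @param model A trained `curvae_model`.
#' @param counts Cells-by-genes counts (used for the posterior locations and
#'   library sizes).
#' @param keep Character vector of component names to keep (nonempty).
#' @param fill Optional named list of per-component override coordinates for
#'   dropped components.
#' @param batch_df Covariates (if the model uses batches).
#' @param lib_size Optional per-cell library sizes; defaults to the observed
#'   totals.
#' @return Cells-by-genes matrix of decoded negative-binomial means.
#' @export
selective_decode <- function(model, counts, keep, fill = list(),
                             batch_df = NULL, lib_size = NULL) {
  prt <- model$partition
  nm <- names(prt$sets)
  if (!length(keep)) .err_invalid("keep must name at least one component")
  if (!all(keep %in% nm)) .err_invalid("unknown component name in keep")
  enc <- encode_cells(model, counts)
  n <- nrow(as.matrix(counts))
  if (is.null(lib_size)) lib_size <- pmax(rowSums(as.matrix(counts)), 1)
  z <- vector("list", prt$k)
  for (j in which(prt$modeled)) {
    z[[j]] <- if (nm[j] %in% keep) enc[[nm[j]]]$location else
      .fill_point(model, j, fill, n)
  }
  decoded_matrix(model, decode_cells(model, z, lib_size, batch_df))
}

#' Counterfactual decoding: overwrite one latent coordinate
#'
#' Sets the named coordinate of one component to a fixed value for every
#' cell (all other coordinates and components keep their posterior values)
#' and decodes. Coordinates are intrinsic: for curved components the
#' posterior tangent location is edited and re-mapped through the
#' exponential map.
#'
#' @param model A trained `curvae_model`.
#' @param counts Cells-by-genes counts.
#' @param component Component name.
#' @param coordinate_index 1-based coordinate within the component.
#' @param value Replacement value.
#' @param batch_df,lib_size As in [selective_decode()].
#' @return Cells-by-genes matrix of decoded negative-binomial means.
#' @export
counterfactual_decode <- function(model, counts, component, coordinate_index,
                                  value, batch_df = NULL, lib_size = NULL) {
  prt <- model$partition
  nm <- names(prt$sets)
  if (!component %in% nm) .err_invalid("unknown component name")
  jc <- match(component, nm)
  sp <- model$specs[[jc]]$space
  if (coordinate_index < 1L || coordinate_index > sp$d)
    .err_invalid("coordinate index out of range")
  enc <- encode_cells(model, counts)
  n <- nrow(as.matrix(counts))
  if (is.null(lib_size)) lib_size <- pmax(rowSums(as.matrix(counts)), 1)
  z <- vector("list", prt$k)
  for (j in which(prt$modeled)) {
    if (j == prt$owner[jc]) {
      tng <- enc[[nm[j]]]$tangent
      tng[, coordinate_index] <- value
      z[[j]] <- if (sp$kind == "euclidean") tng else
        exp_map(matrix(space_origin(sp), 1L), cbind(0, tng), sp)
    } else {
      z[[j]] <- enc[[nm[j]]]$location
    }
  }
  decoded_matrix(model, decode_cells(model, z, lib_size, batch_df))
}

#' Classify genes by their central-to-total expression ratio
#'
#' For each gene, `ratio = central / (central + portal)`; genes with
#' `ratio < 0.2` are labelled central markers and genes with `ratio > 0.8`
#' portal markers, following the published thresholds. Genes with zero
#' expression in both conditions get ratio 0.5 and stay unclassified.
#'
#' @param expr_central,expr_portal Nonnegative per-gene mean expression
#'   under the central and portal counterfactuals.
#' @return Data frame: `gene` (names if available), `ratio`, `label`.
#' @export
central_portal_classify <- function(expr_central, expr_portal) {
  if (length(expr_central) != length(expr_portal))
    .err_invalid("length mismatch")
  if (any(expr_central < 0) || any(expr_portal < 0))
    .err_invalid("expression means must be nonnegative")
  tot <- expr_central + expr_portal
  ratio <- ifelse(tot == 0, 0.5, expr_central / ifelse(tot == 0, 1, tot))
  label <- ifelse(ratio < 0.2, "central", ifelse(ratio > 0.8, "portal", "unclassified"))
  data.frame(gene = if (!is.null(names(expr_central))) names(expr_central)
             else seq_along(expr_central),
             ratio = ratio, label = label)
}

#' k-NN identity transfer with an uncertainty rule
#'
#' Classifies each query by majority vote among its `k` nearest reference
#' cells (Euclidean distance in the embedding), once per `k` in `k_list`; a
#' query is labelled `"uncertain"` unless every `k` yields the same label.
#'
#' @param ref_embeddings,ref_labels Reference cells and their labels.
#' @param query_embeddings Query cells (same embedding space).
#' @param k_list Values of `k`; default is the published list.
#' @return Character vector of predicted labels (or `"uncertain"`).
#' @export
knn_identity <- function(ref_embeddings, ref_labels, query_embeddings,
                         k_list = c(5, 11, 17, 23, 29, 35, 41, 47, 53, 59, 65, 71, 73)) {
  ref <- as.matrix(ref_embeddings); qry <- as.matrix(query_embeddings)
  if (nrow(ref) < 1L) .err_invalid("empty reference")
  if (any(k_list > nrow(ref))) .err_invalid("k exceeds reference size")
  labs <- as.character(ref_labels)
  # squared Euclidean distances query x ref
  d2 <- outer(rowSums(qry^2), rowSums(ref^2), "+") - 2 * tcrossprod(qry, ref)
  kmax <- max(k_list)
  out <- character(nrow(qry))
  for (i in seq_len(nrow(qry))) {
    ord <- order(d2[i, ])[seq_len(kmax)]
    votes <- vapply(k_list, function(k) {
      tab <- sort(table(labs[ord[seq_len(k)]]), decreasing = TRUE)
      names(tab)[1L]
    }, character(1))
    out[i] <- if (length(unique(votes)) == 1L) votes[1L] else "uncertain"
  }
  out
}

#' Discover upregulated genes by paired counterfactual decoding
#'
#' Decomposes the non-signal embedding by PCA, selects the most extreme
#' cells of each group along the group-separating direction within the
#' designated axes (non-designated axes among the first `n_pcs` are zeroed),
#' reconstructs the embedding from `n_pcs` components, decodes with the
#' other components held at `fill` (their origin by default), pairs the two
#' groups by rank, and tallies how often each gene lands in the top `top_n`
#' positive differences (group A minus group B) across pairs.
#'
#' @param model A trained `curvae_model`.
#' @param z2 Embedding matrix of the component to decompose (cells x d).
#' @param component Name of that component.
#' @param group_labels Two-level factor/character vector over the rows of
#'   `z2`; the first level is the upregulated ("stimulated") group A.
#' @param n_cells_per_group Cells selected from each group (default 100).
#' @param n_pcs Principal components used for reconstruction (default 4).
#' @param pc_axes Designated axes among the first `n_pcs` (default all).
#' @param top_n Genes tallied per pair (default 50).
#' @param exclude Gene names removed before ranking.
#' @param fill Named list of override coordinates for the other components.
#' @param batch_df Covariate data frame aligned with `z2` rows (if the model
#'   uses batches).
#' @param lib_size Library size used for decoding every selected cell
#'   (default: 10,000).
#' @return Data frame `gene`, `frequency`, sorted decreasing; attribute
#'   `"pairs"` gives the number of pairs.
#' @export
discover_upregulated <- function(model, z2, component, group_labels,
                                 n_cells_per_group = 100L, n_pcs = 4L,
                                 pc_axes = seq_len(n_pcs), top_n = 50L,
                                 exclude = character(), fill = list(),
                                 batch_df = NULL, lib_size = 1e4) {
  z2 <- as.matrix(z2)
  gf <- factor(group_labels)
  glev <- levels(gf)
  groups <- as.character(gf)
  if (length(glev) != 2L) .err_invalid("group_labels must have exactly two levels")
  nA <- sum(groups == glev[1]); nB <- sum(groups == glev[2])
  if (min(nA, nB) < n_cells_per_group)
    .err_invalid("a group has fewer cells than n_cells_per_group")
  n_pcs <- min(n_pcs, ncol(z2))
  pc_axes <- intersect(pc_axes, seq_len(n_pcs))
  pca <- stats::prcomp(z2, center = TRUE, scale. = FALSE)
  S <- pca$x[, seq_len(n_pcs), drop = FALSE]
  S[, setdiff(seq_len(n_pcs), pc_axes)] <- 0
  # separating direction: difference of group means in the designated axes
  dir <- colMeans(S[groups == glev[1], , drop = FALSE]) -
    colMeans(S[groups == glev[2], , drop = FALSE])
  dn <- sqrt(sum(dir^2))
  proj <- if (dn < 1e-12) S[, 1L] else drop(S %*% (dir / dn))
  selA <- which(groups == glev[1])[order(proj[groups == glev[1]],
                                         decreasing = TRUE)][seq_len(n_cells_per_group)]
  selB <- which(groups == glev[2])[order(proj[groups == glev[2]],
                                         decreasing = FALSE)][seq_len(n_cells_per_group)]
  # pair by rank along the separating direction within each selection
  selA <- selA[order(proj[selA], decreasing = TRUE)]
  selB <- selB[order(proj[selB], decreasing = TRUE)]
  # reconstruct the embedding from the retained components
  Zrec <- S %*% t(pca$rotation[, seq_len(n_pcs), drop = FALSE])
  Zrec <- sweep(Zrec, 2L, pca$center, "+")
  sel <- c(selA, selB)
  prt <- model$partition; nm <- names(prt$sets)
  jc <- match(component, nm)
  if (is.na(jc)) .err_invalid("unknown component name")
  sp <- model$specs[[jc]]$space
  zsel <- Zrec[sel, , drop = FALSE]
  z <- vector("list", prt$k)
  for (j in which(prt$modeled)) {
    z[[j]] <- if (j == prt$owner[jc]) {
      if (sp$kind == "euclidean") zsel else
        exp_map(matrix(space_origin(sp), 1L), cbind(0, zsel), sp)
    } else .fill_point(model, j, fill, length(sel))
  }
  bsel <- if (!is.null(batch_df)) as.data.frame(batch_df)[sel, , drop = FALSE] else NULL
  expr <- decoded_matrix(model, decode_cells(model, z, rep(lib_size, length(sel)), bsel))
  gene_names <- prt$gene_names
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(prt$G))
  colnames(expr) <- gene_names
  keep_genes <- setdiff(gene_names, exclude)
  npair <- n_cells_per_group
  exprA <- expr[seq_len(npair), keep_genes, drop = FALSE]
  exprB <- expr[npair + seq_len(npair), keep_genes, drop = FALSE]
  diffs <- exprA - exprB
  if (all(abs(diffs) < 1e-12))
    warning("all paired differences are zero; ranking is degenerate")
  tally <- integer(length(keep_genes)); names(tally) <- keep_genes
  for (p in seq_len(npair)) {
    top <- order(diffs[p, ], decreasing = TRUE)[seq_len(min(top_n, ncol(diffs)))]
    tally[top] <- tally[top] + 1L
  }
  out <- data.frame(gene = names(tally), frequency = as.integer(tally))
  out <- out[order(-out$frequency, out$gene), ]
  rownames(out) <- NULL
  attr(out, "pairs") <- npair
  out
}

#' Export embeddings or pseudotime as a delimited table
#'
#' Coordinates are written with full double precision so downstream checks
#' round-trip exactly.
#'
#' @param x Matrix (embeddings) or numeric vector (angles).
#' @param path Output TSV path.
#' @param cell_ids Optional cell identifiers.
#' @return The path, invisibly.
#' @export
write_table_tsv <- function(x, path, cell_ids = NULL) {
  df <- if (is.null(dim(x))) data.frame(value = format(x, digits = 17)) else
    as.data.frame(apply(as.matrix(x), 2L, format, digits = 17))
  if (!is.null(cell_ids)) df <- cbind(cell = cell_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
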