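# Randomized multimodal fusion.  Each modality's 192-length fully-connected
# feature is mapped by a seeded random linear projection into a common
# target dimension; the projected features are combined (sum by default, or
# concatenate-then-project) and classified by a freshly initialized
# fully-connected + softmax head.  The backbones are the trained
# single-modal networks, copied in (parameter transfer) and frozen by
# default; the projections are drawn once at build time and frozen, which is
# the "random function, not learned" reading of the construction.

#' Fusion operator specification
#'
#' @param target_dim dimension of the fused feature (default 192, matching
#'   the backbone feature length).
#' @param seed integer seed for the projection draw and head initialization.
#' @param scale entries of the projection matrices are uniform on
#'   `[-scale, scale]`.  The default `sqrt(3/192)` gives projection columns
#'   unit expected squared norm at the default dimensions, so fused features
#'   keep the same scale as the backbone features.
#' @param combine_mode `"sum"` (two projections added) or `"concat_project"`
#'   (one projection of the concatenated 384-vector).
#' @return An object of class `fusion_spec`.
#' @export
fusion_spec <- function(target_dim = 192L, seed = 1L, scale = NULL,
                        combine_mode = c("sum", "concat_project")) {
  target_dim <- as.integer(target_dim)
  if (is.na(target_dim) || target_dim < 1L) stop("target_dim must be >= 1")
  combine_mode <- match.arg(combine_mode)
  if (is.null(scale)) scale <- sqrt(3 / target_dim)
  if (scale <= 0) stop("scale must be positive")
  structure(list(target_dim = target_dim, seed = as.integer(seed),
                 scale = scale, combine_mode = combine_mode),
            class = "fusion_spec")
}

#' Build the fusion model by parameter transfer
#'
#' Copies the two trained backbones, draws the frozen random projections
#' from the seeded uniform distribution, and freshly initializes the
#' trainable head (a sigmoid fully-connected layer of width `target_dim`
#' followed by the classification layer).
#'
#' @param ct_net,xray_net trained `network_params` backbones conforming to
#'   the standard layer schedule.
#' @param spec a [fusion_spec()].
#' @param n_classes number of output classes (default 2).
#' @param freeze_backbones if `TRUE` (default) training updates only the
#'   head; if `FALSE` gradients flow into the backbones (fine-tuning).
#' @param trainable_projections if `TRUE` the projections receive gradient
#'   updates; default `FALSE` (random-projection reading).
#' @return An object of class `fusion_model`.
#' @export
build_fusion_model <- function(ct_net, xray_net, spec = fusion_spec(),
                               n_classes = 2L, freeze_backbones = TRUE,
                               trainable_projections = FALSE) {
  stopifnot(inherits(ct_net, "network_params"),
            inherits(xray_net, "network_params"),
            inherits(spec, "fusion_spec"))
  for (net in list(ct_net, xray_net))
    if (tail_shape(net) != FEATURE_DIM)
      stop("backbone does not emit the 192-length feature contract")
  n_classes <- as.integer(n_classes)
  d <- spec$target_dim
  withr::with_seed(spec$seed, {
    draw <- function(nr, nc) matrix(stats::runif(nr * nc, -spec$scale, spec$scale), nr, nc)
    proj <- if (spec$combine_mode == "sum")
      list(ct = draw(d, FEATURE_DIM), xray = draw(d, FEATURE_DIM))
    else list(cat = draw(d, 2L * FEATURE_DIM))
    # head_fc sees the fused projection of mean-0.5 sigmoid features; its
    # input is approximately centered because projection entries are
    # zero-mean, so only head_out (fed by sigmoid outputs) needs the
    # centering bias offset used throughout the backbones
    head_fc <- dense_layer_params(glorot_uniform(c(d, d), d, d), numeric(d))
    w_out <- glorot_uniform(c(n_classes, d), d, n_classes)
    head_out <- dense_layer_params(w_out, biases = -0.5 * rowSums(w_out))
    structure(list(ct_backbone = ct_net, xray_backbone = xray_net,
                   proj = proj, head_fc = head_fc, head_out = head_out,
                   spec = spec, n_classes = n_classes,
                   freeze_backbones = isTRUE(freeze_backbones),
                   trainable_projections = isTRUE(trainable_projections)),
              class = "fusion_model")
  })
}

tail_shape <- function(net) nrow(net$fc1$weights)

#' Randomized fusion of two modality feature vectors
#'
#' Applies the model's frozen projections: in `"sum"` mode
#' `proj_ct %*% f_ct + proj_xray %*% f_xray`; in `"concat_project"` mode a
#' single projection of the concatenation.  Linear, no bias, deterministic
#' given the built model.
#'
#' @param f_ct,f_xray length-192 feature vectors (or 192 x n matrices).
#' @param model a `fusion_model`.
#' @return The fused feature, length `target_dim` (or `target_dim x n`).
#' @export
randomized_fuse <- function(f_ct, f_xray, model) {
  fc <- if (is.matrix(f_ct)) f_ct else matrix(f_ct, ncol = 1L)
  fx <- if (is.matrix(f_xray)) f_xray else matrix(f_xray, ncol = 1L)
  if (nrow(fc) != FEATURE_DIM || nrow(fx) != FEATURE_DIM ||
      ncol(fc) != ncol(fx))
    stop("feature vectors must both have length 192 (and equal batch size)")
  out <- if (model$spec$combine_mode == "sum")
    model$proj$ct %*% fc + model$proj$xray %*% fx
  else model$proj$cat %*% rbind(fc, fx)
  if (is.matrix(f_ct)) out else drop(out)
}

# Cached forward pass over a list of labeled pairs (or prepared batches).
fusion_forward_batch <- function(model, pairs, labels = NULL,
                                 ct_batch = NULL, xray_batch = NULL,
                                 features = NULL) {
  if (is.null(features)) {
    if (is.null(ct_batch)) ct_batch <- images_to_batch(model$ct_backbone, pairs)
    if (is.null(xray_batch)) xray_batch <- images_to_batch(model$xray_backbone, pairs)
    fw_ct <- net_forward(model$ct_backbone, ct_batch)
    fw_xr <- net_forward(model$xray_backbone, xray_batch)
    f_ct <- fw_ct$features; f_xr <- fw_xr$features
  } else {
    fw_ct <- fw_xr <- NULL
    f_ct <- features$ct; f_xr <- features$xray
  }
  fused <- randomized_fuse(f_ct, f_xr, model)
  fused <- if (is.matrix(fused)) fused else matrix(fused, ncol = 1L)
  z <- dense_forward(fused, model$head_fc)
  h <- sigmoid(z)
  logits <- dense_forward(h, model$head_out)
  sm <- softmax_xent(logits, labels %||% integer(ncol(logits)))
  list(probabilities = sm$probabilities,
       loss = if (is.null(labels)) NA_real_ else sm$loss,
       d_logits = sm$d_logits,
       cache = list(f_ct = f_ct, f_xr = f_xr, fused = fused, h = h,
                    fw_ct = fw_ct, fw_xr = fw_xr))
}

# Gradients for the head (and optionally projections / backbones).
fusion_backward <- function(model, fw) {
  gout <- dense_backward(fw$d_logits, model$head_out, fw$cache$h)
  dz <- sigmoid_backward(gout$d_input, fw$cache$h)
  gfc <- dense_backward(dz, model$head_fc, fw$cache$fused)
  grads <- list(head_out = list(weights = gout$d_weights, biases = gout$d_biases),
                head_fc = list(weights = gfc$d_weights, biases = gfc$d_biases))
  dfused <- gfc$d_input
  if (model$trainable_projections) {
    grads$proj <- if (model$spec$combine_mode == "sum")
      list(ct = tcrossprod(dfused, fw$cache$f_ct),
           xray = tcrossprod(dfused, fw$cache$f_xr))
    else list(cat = tcrossprod(dfused, rbind(fw$cache$f_ct, fw$cache$f_xr)))
  }
  if (!model$freeze_backbones) {
    if (model$spec$combine_mode == "sum") {
      d_fct <- crossprod(model$proj$ct, dfused)
      d_fxr <- crossprod(model$proj$xray, dfused)
    } else {
      dcat <- crossprod(model$proj$cat, dfused)
      d_fct <- dcat[seq_len(FEATURE_DIM), , drop = FALSE]
      d_fxr <- dcat[FEATURE_DIM + seq_len(FEATURE_DIM), , drop = FALSE]
    }
    grads$ct_backbone <- net_backward_from_feature(model$ct_backbone,
                                                   fw$cache$fw_ct$cache, d_fct)
    grads$xray_backbone <- net_backward_from_feature(model$xray_backbone,
                                                     fw$cache$fw_xr$cache, d_fxr)
  }
  grads
}

#' Fusion model forward pass for one subject
#'
#' Pipeline: backbone feature extraction of both modalities,
#' [randomized_fuse()], sigmoid fully-connected head, classification layer,
#' softmax.
#'
#' @param model a `fusion_model`.
#' @param pair a [labeled_image_pair()].
#' @return Class-probability vector on the simplex.
#' @export
fusion_forward <- function(model, pair) {
  stopifnot(inherits(model, "fusion_model"),
            inherits(pair, "labeled_image_pair"))
  drop(fusion_forward_batch(model, list(pair))$probabilities)
}

#' Predict class labels with the fusion model
#'
#' @param object a `fusion_model`.
#' @param pairs a [labeled_image_pair()] or list of them.
#' @param ... unused.
#' @return Integer vector of 0-based class labels (argmax, ties to the
#'   lower index).
#' @export
predict.fusion_model <- function(object, pairs, ...) {
  if (inherits(pairs, "labeled_image_pair")) pairs <- list(pairs)
  fw <- fusion_forward_batch(object, pairs)
  max.col(t(fw$probabilities), ties.method = "first") - 1L
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion model> %s combine, target_dim %d, %d classes, backbones %s\n",
              x$spec$combine_mode, x$spec$target_dim, x$n_classes,
              if (x$freeze_backbones) "frozen" else "fine-tuned"))
  invisible(x)
}
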