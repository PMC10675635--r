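#' Inverse-frequency class weights for cost-sensitive training
#'
#' With heavily mid-scale-concentrated BCS data, an unweighted classifier
#' drifts toward the majority classes. Cost-sensitive learning applies
#' per-class loss weights inversely proportional to the training count:
#' `w_c = (N / K) / n_c` for the `K` non-empty classes (empty classes get
#' weight 0), normalised so that `sum(w_c * n_c) = N`. Every class then
#' contributes the same total weight to the loss.
#'
#' @param counts Non-negative integer per-class training counts, at least
#'   one positive.
#' @return Numeric weight vector, same length as `counts`.
#' @export
#' @examples
#' class_weights(c(320, 452, 1196, 1468, 2516, 1780, 368, 112))
class_weights <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) <= 0) {
    stop("class_weights needs at least one positive count", call. = FALSE)
  }
  k <- sum(counts > 0)
  w <- numeric(length(counts))
  w[counts > 0] <- (sum(counts) / k) / counts[counts > 0]
  w
}

#' Backbone configuration
#'
#' The compact per-camera classifier: three conv(3x3) + ReLU + max-pool(2x2)
#' blocks with 16, 32 and 64 filters, a flatten, a 64-unit ReLU dense layer
#' and an 8-class softmax head. Input height and width must be divisible by
#' 8 (three pooling stages).
#'
#' @param input_shapes Named list (by camera view) of `c(H, W, C)` input
#'   shapes; `C` is 3 for single-camera stacks.
#' @param conv_filters Filters per conv block.
#' @param kernel Conv kernel size (odd).
#' @param dense_units Width of the penultimate dense layer.
#' @param n_classes Number of BCS classes (default 8, the label grid).
#' @return A list of class `backbone_config`.
#' @export
backbone_config <- function(input_shapes, conv_filters = c(16L, 32L, 64L),
                            kernel = 3L, dense_units = 64L, n_classes = 8L) {
  stopifnot(is.list(input_shapes), length(input_shapes) >= 1L,
            !is.null(names(input_shapes)))
  names(input_shapes) <- match_camera(names(input_shapes))
  for (sh in input_shapes) {
    stopifnot(length(sh) == 3L, all(sh > 0))
    div <- 2L^length(conv_filters)
    if (sh[1] %% div || sh[2] %% div) {
      stop("input height/width must be divisible by ", div,
           " for ", length(conv_filters), " pooling stages; got ",
           paste(sh[1:2], collapse = "x"), call. = FALSE)
    }
  }
  structure(list(input_shapes = input_shapes,
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes)),
            class = "backbone_config")
}

trunk_spec <- function(config) {
  spec <- list()
  for (f in config$conv_filters) {
    spec[[length(spec) + 1L]] <- layer_conv(f, config$kernel)
    spec[[length(spec) + 1L]] <- layer_pool()
  }
  spec[[length(spec) + 1L]] <- layer_flatten()
  spec
}

head_spec <- function(config) {
  list(layer_dense(config$dense_units, "relu"),
       layer_dense(config$n_classes, "linear"))
}

# One trainable network: one or more conv trunks whose flattened features
# are concatenated and fed to a shared dense head.
new_cnn <- function(branch_shapes, config, seed) {
  with_local_seed(seed, {
    branches <- lapply(branch_shapes, function(sh) {
      init_layers(trunk_spec(config), sh)
    })
    feat <- sum(vapply(branches, function(b) attr(b, "output_shape"),
                       numeric(1)))
    head <- init_layers(head_spec(config), feat)
    list(branches = branches, head = head, feature_widths =
           vapply(branches, function(b) attr(b, "output_shape"), numeric(1)))
  })
}

#' Build a fusion model
#'
#' Three ways of combining the camera views:
#' * `EARLY`: the per-camera three-channel stacks are resampled to a common
#'   shape (the smallest selected crop, nearest-neighbour) and stacked into
#'   a single `3 * n_cameras`-channel input for one backbone.
#' * `MID`: each camera keeps its own conv trunk; the flattened features
#'   are concatenated and fed into one shared dense head.
#' * `LATE`: each camera gets a complete independent classifier; their
#'   softmax outputs are combined by [ensemble_average()] at prediction
#'   time. With a single camera this reduces exactly to that camera's
#'   classifier.
#'
#' @param kind One of `"EARLY"`, `"MID"`, `"LATE"`.
#' @param cameras Non-empty subset of [CAMERA_VIEWS].
#' @param config A [backbone_config()] covering those cameras.
#' @param seed Integer seed for weight initialisation.
#' @return A list of class `fusion_model`.
#' @export
build_model <- function(kind = c("LATE", "EARLY", "MID"), cameras,
                        config, seed = 1L) {
  kind <- match.arg(toupper(kind[1]), c("LATE", "EARLY", "MID"))
  if (length(cameras) < 1L) {
    stop("fusion model needs a non-empty camera set", call. = FALSE)
  }
  cameras <- match_camera(cameras)
  stopifnot(inherits(config, "backbone_config"),
            all(cameras %in% names(config$input_shapes)))
  model <- if (kind == "EARLY") {
    shapes <- config$input_shapes[cameras]
    areas <- vapply(shapes, function(s) s[1] * s[2], numeric(1))
    target <- shapes[[which.min(areas)]][1:2]
    in_shape <- c(target, 3L * length(cameras))
    list(net = new_cnn(list(in_shape), config, seed), target_hw = target)
  } else if (kind == "MID") {
    list(net = new_cnn(config$input_shapes[cameras], config, seed))
  } else {
    members <- list()
    for (i in seq_along(cameras)) {
      members[[cameras[i]]] <-
        new_cnn(config$input_shapes[cameras[i]], config, seed + i - 1L)
    }
    list(members = members)
  }
  structure(c(model, list(kind = kind, cameras = cameras, config = config,
                          trained = FALSE)),
            class = "fusion_model")
}

# Nearest-neighbour resample of an H x W x C (x N) array.
resize_stack <- function(x, hw) {
  d <- dim(x)
  ri <- pmin(d[1], pmax(1L, round((seq_len(hw[1]) - 0.5) * d[1] / hw[1] + 0.5)))
  ci <- pmin(d[2], pmax(1L, round((seq_len(hw[2]) - 0.5) * d[2] / hw[2] + 0.5)))
  if (length(d) == 3L) x[ri, ci, , drop = FALSE]
  else x[ri, ci, , , drop = FALSE]
}

# Arrange a named list of per-camera batches into per-branch inputs.
branch_inputs <- function(model, xlist) {
  miss <- setdiff(model$cameras, names(xlist))
  if (length(miss)) {
    stop("missing input for camera(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (model$kind == "EARLY") {
    parts <- lapply(model$cameras, function(cam) {
      resize_stack(xlist[[cam]], model$target_hw)
    })
    d1 <- dim(parts[[1L]])
    out <- array(0, c(d1[1], d1[2], 3L * length(parts), d1[4]))
    for (i in seq_along(parts)) {
      out[, , (i - 1L) * 3L + 1:3, ] <- parts[[i]]
    }
    list(out)
  } else {
    xlist[model$cameras]
  }
}

cnn_forward <- function(net, xb, train = FALSE) {
  feats <- vector("list", length(net$branches))
  caches <- vector("list", length(net$branches))
  for (i in seq_along(net$branches)) {
    r <- forward_layers(net$branches[[i]], xb[[i]])
    feats[[i]] <- r$out
    caches[[i]] <- r$caches
  }
  feat <- do.call(cbind, feats)
  rh <- forward_layers(net$head, feat)
  list(logits = rh$out, feat = feat, branch_caches = caches,
       head_caches = rh$caches)
}

cnn_predict_proba <- function(net, xb) {
  softmax_rows(cnn_forward(net, xb)$logits)
}

#' Average per-camera probability vectors into an ensemble prediction
#'
#' Decision-level fusion: the fused class distribution is the element-wise
#' (by default equal-weight) mean of the member distributions, and the
#' predicted class is its argmax with lowest-index tie-break.
#'
#' @param prob_vectors List of probability vectors (or matrices with one
#'   row per sample), all the same length, each row summing to 1.
#' @param weights Optional member weights (normalised internally).
#' @return List with `prob` (fused distribution(s)) and `class`
#'   (0-based predicted class index/indices).
#' @export
ensemble_average <- function(prob_vectors, weights = NULL) {
  stopifnot(length(prob_vectors) >= 1L)
  mats <- lapply(prob_vectors, function(p) {
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    p
  })
  d <- dim(mats[[1L]])
  for (p in mats) {
    if (!identical(dim(p), d)) {
      stop("probability vectors differ in shape", call. = FALSE)
    }
    if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-6)) {
      stop("inputs must be probability vectors summing to 1", call. = FALSE)
    }
  }
  if (is.null(weights)) weights <- rep(1, length(mats))
  stopifnot(length(weights) == length(mats), all(weights >= 0),
            sum(weights) > 0)
  weights <- weights / sum(weights)
  fused <- Reduce(`+`, Map(function(p, w) p * w, mats, weights))
  cls <- apply(fused, 1L, which.max) - 1L
  list(prob = fused, class = as.integer(cls))
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param epochs Training epochs (default 30; the checkpoint is the lowest
#'   validation loss from epoch 5 onward, the band where these small models
#'   peak before overfitting).
#' @param batch_size Mini-batch size (8, 16 or 32 are the tested settings;
#'   default 32).
#' @param class_weighting Apply [class_weights()] to the loss (default
#'   TRUE).
#' @param seed Seed driving initial shuffling and all training randomness.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 30L,
                         batch_size = 32L, class_weighting = TRUE,
                         seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed)),
            class = "train_config")
}

eval_loss <- function(net, xb, y, class_w) {
  f <- cnn_forward(net, xb)
  weighted_ce(f$logits, y, class_w)$loss
}

slice_batch <- function(xb, idx) {
  lapply(xb, function(a) a[, , , idx, drop = FALSE])
}

train_single_net <- function(net, xb, y, val_xb, val_y, tconfig, class_w) {
  n <- length(y)
  state_b <- lapply(net$branches, function(...) adam_state())
  state_h <- adam_state()
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, net = net, epoch = NA_integer_)
  sel_from <- min(5L, tconfig$epochs)  # selection window start
  t_step <- 0L
  with_local_seed(tconfig$seed, {
    for (epoch in seq_len(tconfig$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = tconfig$batch_size)) {
        idx <- ord[start:min(start + tconfig$batch_size - 1L, n)]
        batch <- slice_batch(xb, idx)
        fw <- cnn_forward(net, batch)
        ls <- weighted_ce(fw$logits, y[idx], class_w)
        bh <- backward_layers(net$head, ls$dlogits, fw$head_caches)
        t_step <- t_step + 1L
        net$head <- adam_update(net$head, bh$grads, state_h,
                                tconfig$learning_rate, t_step)
        off <- 0L
        for (i in seq_along(net$branches)) {
          wfeat <- net$feature_widths[i]
          dfeat <- bh$dx[, off + seq_len(wfeat), drop = FALSE]
          off <- off + wfeat
          bb <- backward_layers(net$branches[[i]], dfeat,
                                fw$branch_caches[[i]])
          net$branches[[i]] <- adam_update(net$branches[[i]], bb$grads,
                                           state_b[[i]],
                                           tconfig$learning_rate, t_step)
        }
        tot_loss <- tot_loss + ls$loss
        nb <- nb + 1L
      }
      vl <- eval_loss(net, val_xb, val_y, class_w)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = tot_loss / nb,
                                  val_loss = vl))
      if (epoch >= sel_from && vl < best$loss) {
        best <- list(loss = vl, net = net, epoch = epoch)
      }
    }
  })
  list(net = best$net, history = history, best_epoch = best$epoch)
}

#' Train a fusion model
#'
#' Minimises class-weighted cross-entropy over the 8 BCS classes with Adam
#' at the configured learning rate. The returned model carries the
#' parameters from the epoch with the lowest validation loss (from epoch 5
#' onward) and a per-epoch loss history. `LATE` models train each camera
#' member independently (seeds offset per member); `EARLY`/`MID` train as
#' one network.
#'
#' @param model A [build_model()] result.
#' @param train_set,val_set Lists with `x` (named per-camera list of
#'   `H x W x 3 x N` arrays) and `y` (0-based class vector).
#' @param tconfig A [train_config()].
#' @return The trained `fusion_model`, with `history` attached.
#' @export
train_model <- function(model, train_set, val_set, tconfig = train_config()) {
  stopifnot(inherits(model, "fusion_model"))
  y <- as.integer(train_set$y)
  if (length(y) == 0L) stop("empty training set", call. = FALSE)
  nc <- model$config$n_classes
  counts <- tabulate(y + 1L, nbins = nc)
  class_w <- if (tconfig$class_weighting) class_weights(counts)
             else rep(1, nc)
  if (model$kind == "LATE") {
    model$history <- list()
    for (i in seq_along(model$cameras)) {
      cam <- model$cameras[i]
      sub <- structure(list(net = NULL, kind = "MID", cameras = cam,
                            config = model$config), class = "fusion_model")
      xb <- branch_inputs(sub, train_set$x)
      vb <- branch_inputs(sub, val_set$x)
      tc <- tconfig
      tc$seed <- tconfig$seed + i - 1L
      fit <- train_single_net(model$members[[cam]], xb, y, vb,
                              as.integer(val_set$y), tc, class_w)
      model$members[[cam]] <- fit$net
      model$history[[cam]] <- fit$history
    }
  } else {
    xb <- branch_inputs(model, train_set$x)
    vb <- branch_inputs(model, val_set$x)
    fit <- train_single_net(model$net, xb, y, vb, as.integer(val_set$y),
                            tconfig, class_w)
    model$net <- fit$net
    model$history <- fit$history
  }
  model$trained <- TRUE
  model
}

#' Predict BCS class probabilities
#'
#' @param object A trained [build_model()] result.
#' @param xlist Named per-camera list of `H x W x 3 x N` arrays.
#' @param fuse For `LATE` models: `"prob"` (default) averages member
#'   probability vectors; `"score"` averages the members' numeric BCS
#'   predictions and snaps to the nearest grid class.
#' @param ... Unused.
#' @return List with `prob` (N x 8 matrix), `class` (0-based classes) and,
#'   for `LATE`, `member_prob` (per-camera matrices).
#' @export
predict.fusion_model <- function(object, xlist, fuse = c("prob", "score"),
                                 ...) {
  fuse <- match.arg(fuse)
  if (object$kind == "LATE") {
    member_prob <- lapply(object$cameras, function(cam) {
      sub <- structure(list(net = NULL, kind = "MID", cameras = cam,
                            config = object$config), class = "fusion_model")
      cnn_predict_proba(object$members[[cam]], branch_inputs(sub, xlist))
    })
    names(member_prob) <- object$cameras
    if (fuse == "prob") {
      fused <- ensemble_average(member_prob)
    } else {
      grid <- bcs_grid()
      scores <- vapply(member_prob, function(p) {
        grid[apply(p, 1L, which.max)]
      }, numeric(nrow(member_prob[[1L]])))
      mean_score <- if (is.null(dim(scores))) mean(scores)
                    else rowMeans(scores)
      cls <- vapply(mean_score, function(s) which.min(abs(grid - s)) - 1L,
                    integer(1))
      fused <- list(prob = Reduce(`+`, member_prob) / length(member_prob),
                    class = cls)
    }
    list(prob = fused$prob, class = fused$class, member_prob = member_prob)
  } else {
    p <- cnn_predict_proba(object$net, branch_inputs(object, xlist))
    list(prob = p, class = as.integer(apply(p, 1L, which.max) - 1L))
  }
}

#' Model size and compute statistics
#'
#' Exact trainable-parameter count and a FLOP estimate (2 multiply-adds per
#' weight application: convolutions at their input raster, dense layers at
#' their width) for a fusion model; `LATE` statistics are the sum over the
#' member classifiers.
#'
#' @param model A [build_model()] result.
#' @return List with `parameters` and `flops`.
#' @export
model_stats <- function(model) {
  stopifnot(inherits(model, "fusion_model"))
  net_stats <- function(net) {
    p <- sum(vapply(net$branches, layer_param_count, numeric(1))) +
      layer_param_count(net$head)
    f <- sum(vapply(net$branches, layer_flops, numeric(1))) +
      layer_flops(net$head)
    c(p, f)
  }
  s <- if (model$kind == "LATE") {
    Reduce(`+`, lapply(model$members, net_stats))
  } else {
    net_stats(model$net)
  }
  list(parameters = s[1], flops = s[2])
}
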