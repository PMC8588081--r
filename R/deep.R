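# Transfer-learning-style image branch.
#
# The full-scale design follows the standard transfer-learning recipe for a
# VGG-style backbone: fixed-size RGB input, a convolutional feature
# extractor, global average pooling of the final feature map, then a small
# dense classifier head (three dense layers interleaved with two dropout
# layers at probability 0.5, softmax output). Pretrained backbone weights
# are an optional runtime dependency; the in-package backbone is a small
# seeded random convolutional filter bank with the same head, which keeps
# the branch architectural and testable on one CPU.

#' Deep-branch architecture settings
#'
#' @param input_size Height/width of the model input in pixels.
#' @param n_filters Number of random 3x3 convolution filters in the small
#'   backbone.
#' @param stride Convolution stride of the backbone.
#' @param head Sizes of the two hidden dense layers of the classifier head
#'   (the third dense layer is the 2-unit softmax output); dropout 0.5 is
#'   applied after each hidden layer.
#' @return An object of class `deep_head_spec`.
#' @export
deep_head_spec <- function(input_size = c(64L, 64L), n_filters = 64L,
                           stride = 4L, head = c(128L, 64L)) {
  stopifnot(length(input_size) == 2, length(head) == 2)
  structure(list(input_size = as.integer(input_size),
                 n_filters = as.integer(n_filters), stride = as.integer(stride),
                 head = as.integer(head), dropout = 0.5),
            class = "deep_head_spec")
}

as_ebimage <- function(img) {
  EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
}

from_ebimage <- function(e) {
  aperm(as.array(e), c(2, 1, 3)) * 255
}

resize_image <- function(img, height, width) {
  from_ebimage(EBImage::resize(as_ebimage(img), w = width, h = height))
}

rotate_image <- function(img, angle) {
  h <- dim(img)[1]; w <- dim(img)[2]
  from_ebimage(EBImage::rotate(as_ebimage(img), angle,
                               output.dim = c(w, h), bg.col = "black"))
}

flip_image_horizontal <- function(img) {
  img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
}

crop_to_mask <- function(img, mask) {
  if (inherits(mask, "region_mask")) mask <- mask$mask
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  img[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
}

compose_deep_input <- function(img, rois, feature_set, input_size) {
  H <- input_size[1]; W <- input_size[2]
  switch(feature_set,
    skin = resize_image(crop_to_mask(img, rois$forehead), H, W),
    eye = {
      half <- W %/% 2L
      left <- resize_image(crop_to_mask(img, rois$left_sclera), H, half)
      right <- resize_image(crop_to_mask(img, rois$right_sclera), H, W - half)
      out <- array(0, dim = c(H, W, 3))
      out[, seq_len(half), ] <- left
      out[, (half + 1L):W, ] <- right
      out
    },
    fusion = {
      # fixed layout: forehead on the top half, the two sclerae side by
      # side on the bottom half
      top <- resize_image(crop_to_mask(img, rois$forehead), H %/% 2L, W)
      half <- W %/% 2L
      left <- resize_image(crop_to_mask(img, rois$left_sclera), H - H %/% 2L, half)
      right <- resize_image(crop_to_mask(img, rois$right_sclera), H - H %/% 2L, W - half)
      out <- array(0, dim = c(H, W, 3))
      out[seq_len(H %/% 2L), , ] <- top
      out[(H %/% 2L + 1L):H, seq_len(half), ] <- left
      out[(H %/% 2L + 1L):H, (half + 1L):W, ] <- right
      out
    })
}

augment_image <- function(img, what, amount) {
  switch(what,
         flip = flip_image_horizontal(img),
         rotate = rotate_image(img, amount),
         brightness = clip(img + amount, 0, 255))
}

#' Build the image dataset for the deep branch
#'
#' Calibrates each scene, crops its regions of interest, composes the model
#' input for the requested feature set (skin: forehead crop; eye: the two
#' sclera crops side by side; fusion: forehead over both sclerae on a fixed
#' canvas), resizes to `input_size`, and augments the minority class with
#' flips, small rotations (within 10 degrees), and brightness jitter until
#' the classes balance. Scenes whose ROIs cannot be segmented are skipped
#' with a warning.
#'
#' @param scenes List of `jaundice_scene` objects.
#' @param feature_set `"skin"`, `"eye"`, or `"fusion"`.
#' @param input_size Height/width of the composed inputs.
#' @param augment Balance classes by augmenting the minority class.
#' @param seed Seed for the augmentation draws.
#' @return List with `images` (n x H x W x 3 array), `labels` (factor), and
#'   `augmented` (logical vector marking synthetic samples).
#' @export
image_dataset_for_deep <- function(scenes, feature_set = c("fusion", "skin", "eye"),
                                   input_size = c(64L, 64L), augment = TRUE,
                                   seed = 1L) {
  feature_set <- match.arg(feature_set)
  imgs <- list(); labs <- character(0)
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    ok <- tryCatch({
      img <- calibrate_image(sc$image, sc$params$card_geometry)
      rois <- segment_rois(sc$landmarks)
      imgs[[length(imgs) + 1L]] <- compose_deep_input(img, rois, feature_set, input_size)
      labs <- c(labs, as.character(sc$label))
      TRUE
    }, error = function(e) {
      warning("skipping scene ", i, ": ", conditionMessage(e), call. = FALSE)
      FALSE
    })
  }
  labs <- as_label_factor(labs)
  augmented <- rep(FALSE, length(imgs))
  if (augment && nlevels(droplevels(labs)) == 2) {
    counts <- table(labs)
    minority <- names(which.min(counts))
    deficit <- max(counts) - min(counts)
    if (deficit > 0) {
      set.seed(seed)
      minority_idx <- which(labs == minority)
      for (j in seq_len(deficit)) {
        src <- imgs[[minority_idx[(j - 1L) %% length(minority_idx) + 1L]]]
        what <- sample(c("flip", "rotate", "brightness"), 1)
        amount <- switch(what, flip = 0, rotate = stats::runif(1, -10, 10),
                         brightness = stats::runif(1, -20, 20))
        imgs[[length(imgs) + 1L]] <- augment_image(src, what, amount)
        labs <- as_label_factor(c(as.character(labs), minority))
        augmented <- c(augmented, TRUE)
      }
    }
  }
  arr <- array(0, dim = c(length(imgs), input_size[1], input_size[2], 3))
  for (i in seq_along(imgs)) arr[i, , , ] <- imgs[[i]]
  list(images = arr, labels = labs, augmented = augmented)
}

# Random 3x3 convolutional filter bank + ReLU + global average pooling.
backbone_features <- function(images, n_filters, stride, seed) {
  set.seed(seed)
  filters <- matrix(stats::rnorm(27 * n_filters, 0, sqrt(2 / 27)), 27, n_filters)
  n <- dim(images)[1]; H <- dim(images)[2]; W <- dim(images)[3]
  ri <- seq(2L, H - 1L, by = stride)
  ci <- seq(2L, W - 1L, by = stride)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  out <- matrix(0, n, n_filters)
  grid <- expand.grid(r = ri, c = ci)
  for (i in seq_len(n)) {
    img <- images[i, , , ] / 255
    patches <- matrix(0, nrow(grid), 27)
    k <- 0L
    for (ch in 1:3) for (o in seq_len(9)) {
      k <- k + 1L
      patches[, k] <- img[cbind(grid$r + offs$dr[o], grid$c + offs$dc[o], ch)]
    }
    out[i, ] <- colMeans(pmax(patches %*% filters, 0))
  }
  out
}

#' Train the deep branch on composed image inputs
#'
#' Extracts backbone features (global-average-pooled random convolutional
#' responses) and trains the dense classifier head: two hidden dense layers,
#' each followed by dropout 0.5, then a softmax output layer.
#'
#' @param images n x H x W x 3 array from [image_dataset_for_deep()].
#' @param labels Factor of `"healthy"` / `"jaundiced"`.
#' @param spec A [deep_head_spec()].
#' @param epochs,batch_size,learning_rate Head training settings.
#' @param seed Integer seed.
#' @return A `jaundice_model` of kind `"deep"`; [predict_proba_deep()]
#'   scores new image arrays.
#' @export
train_deep_model <- function(images, labels, spec = deep_head_spec(),
                             epochs = 5L, batch_size = 16L,
                             learning_rate = 1e-3, seed = 1L) {
  stopifnot(inherits(spec, "deep_head_spec"))
  y <- as_label_factor(labels)
  if (any(table(y) < 2)) stop("at least 2 samples per class are required", call. = FALSE)
  feats <- backbone_features(images, spec$n_filters, spec$stride,
                             seed = derive_seed(seed, 1L))
  st <- standardizer(feats)
  fit <- mlp_fit(apply_standardizer(feats, st), y, hidden = spec$head,
                 dropout = spec$dropout, epochs = epochs,
                 batch_size = batch_size, lr = learning_rate,
                 seed = derive_seed(seed, 2L))
  structure(list(model_kind = "deep", fit = fit, standardizer = st,
                 spec = spec, seed = as.integer(seed)),
            class = c("jaundice_deep_model", "jaundice_model"))
}

#' Class probabilities of the deep branch
#'
#' @param model A model from [train_deep_model()].
#' @param images n x H x W x 3 array matching the training input size.
#' @return Matrix with columns `healthy`, `jaundiced`, rows summing to 1.
#' @export
predict_proba_deep <- function(model, images) {
  stopifnot(inherits(model, "jaundice_deep_model"))
  feats <- backbone_features(images, model$spec$n_filters, model$spec$stride,
                             seed = derive_seed(model$seed, 1L))
  p <- mlp_predict(model$fit, apply_standardizer(feats, model$standardizer))
  colnames(p) <- CLASS_LEVELS
  p
}
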