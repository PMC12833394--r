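#' Brightness normalization of a radiograph
#'
#' Rescales pixel intensities to the unit range using the observed minimum
#' and maximum, then multiplies by a scaling factor `K`:
#' `S = K * (r - r_min) / (r_max - r_min)`. Radiographs straight off the
#' archive are often dark and low-contrast; with `K = 1` the output spans
#' exactly \[0, 1\], `K > 1` brightens and `K < 1` darkens. A constant image
#' (zero dynamic range) maps to all zeros rather than erroring.
#'
#' @param image Numeric matrix (or [gray_image()]).
#' @param params A [normalization_params()], or a bare numeric `K`.
#' @return Numeric matrix of normalized intensities.
#' @examples
#' brightness_normalize(matrix(c(0, 128, 255), 1), 1)
#' @export
brightness_normalize <- function(image, params = normalization_params()) {
  m <- as_pixel_matrix(image)
  if (is.numeric(params) && length(params) == 1L)
    params <- normalization_params(params)
  rng <- range(m)
  if (rng[2] == rng[1]) return(matrix(0, nrow(m), ncol(m)))
  params$K * (m - rng[1]) / (rng[2] - rng[1])
}

#' @rdname brightness_normalize
#' @param K Positive scaling factor; 1 is neutral.
#' @export
normalization_params <- function(K = 1) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("K must be a positive scalar", call. = FALSE)
  structure(list(K = K), class = "normalization_params")
}

#' Augmentation policy
#'
#' Ranges for the stochastic transforms applied to training images and their
#' boxes: rotation, random cropping retaining 80% of each side, isotropic
#' scaling, horizontal flipping with probability 0.5, and
#' brightness/contrast/saturation jitter within +/-20%. Geometric transforms
#' are applied identically to the bounding boxes; photometric jitter leaves
#' them untouched. The rotation and scaling ranges are free parameters of the
#' pipeline; the defaults (+/-10 degrees, 0.9-1.1) are modest enough that a
#' diaphyseal fracture never leaves the frame.
#'
#' @param rotation_range Degrees, `c(lo, hi)`; `c(0, 0)` disables rotation.
#' @param crop_fraction Fraction of each side retained by the random crop.
#' @param flip_prob Horizontal flip probability.
#' @param scale_range Isotropic scale factor range.
#' @param jitter Maximum relative brightness/contrast/saturation change.
#' @return An `augmentation_policy` object.
#' @export
augmentation_policy <- function(rotation_range = c(-10, 10),
                                crop_fraction = 0.80,
                                flip_prob = 0.5,
                                scale_range = c(0.9, 1.1),
                                jitter = 0.20) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, jitter >= 0, jitter <= 1,
            crop_fraction > 0, crop_fraction <= 1,
            length(rotation_range) == 2L, length(scale_range) == 2L,
            all(scale_range > 0))
  structure(list(rotation_range = rotation_range,
                 crop_fraction = crop_fraction, flip_prob = flip_prob,
                 scale_range = scale_range, jitter = jitter),
            class = "augmentation_policy")
}

identity_policy <- function() {
  augmentation_policy(rotation_range = c(0, 0), crop_fraction = 1,
                      flip_prob = 0, scale_range = c(1, 1), jitter = 0)
}

#' Augment an image together with its bounding boxes
#'
#' Applies, in order: isotropic scaling, rotation about the image centre
#' (output canvas keeps the input size; boxes become the enclosing
#' axis-aligned box of their rotated corners), a random crop retaining
#' `crop_fraction` of each side, a horizontal flip, and photometric
#' brightness/contrast jitter. Every geometric step transforms the boxes
#' through exactly the same map as the pixels; boxes falling entirely outside
#' the crop are dropped. The transform draw is governed by `seed`, so a fixed
#' seed reproduces the output bit for bit.
#'
#' @param image Numeric matrix.
#' @param boxes Matrix with columns `x_min`, `y_min`, `x_max`, `y_max` (may
#'   have zero rows).
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed for the transform draw.
#' @return List with elements `image`, `boxes` (possibly fewer rows) and
#'   `kept` (indices of surviving input boxes).
#' @export
augment <- function(image, boxes, policy = augmentation_policy(), seed = 1L) {
  image <- as_pixel_matrix(image)
  if (is.null(boxes)) boxes <- matrix(numeric(0), 0, 4)
  boxes <- as.matrix(boxes)
  if (ncol(boxes) != 4 && nrow(boxes) > 0)
    stop("boxes must have 4 columns", call. = FALSE)
  rng <- local_rng(seed)
  h <- nrow(image); w <- ncol(image)

  s <- rng$unif(policy$scale_range[1], policy$scale_range[2])
  theta <- rng$unif(policy$rotation_range[1], policy$rotation_range[2]) * pi / 180
  do_flip <- rng$unif(0, 1) < policy$flip_prob
  cf <- policy$crop_fraction
  cw <- round(w * s * cf); ch <- round(h * s * cf)
  ox <- rng$unif(0, w * s - cw)
  oy <- rng$unif(0, h * s - ch)
  bfac <- 1 + rng$unif(-policy$jitter, policy$jitter)
  cfac <- 1 + rng$unif(-policy$jitter, policy$jitter)

  # forward map: scale about origin, rotate about the scaled-image centre,
  # then translate by the crop offset
  ct <- cos(theta); st <- sin(theta)
  cx <- w * s / 2; cy <- h * s / 2
  # rotation about (cx, cy) applied to scaled coords
  M <- matrix(c(ct * s, -st * s, cx - ct * cx + st * cy - ox,
                st * s,  ct * s, cy - st * cx - ct * cy - oy),
              2, 3, byrow = TRUE)
  identity_geom <- s == 1 && theta == 0 && cf == 1
  if (identity_geom) {
    out <- image
  } else {
    # invert the affine map for output -> input sampling
    A <- M[, 1:2]; b <- M[, 3]
    Ai <- solve(A)
    Minv <- cbind(Ai, -Ai %*% b)
    out <- affine_warp(image, Minv, ch, cw)
  }
  new_boxes <- matrix(numeric(0), 0, 4)
  kept <- integer(0)
  if (nrow(boxes) > 0) {
    tb <- t(apply(boxes, 1, function(bb) transform_box_affine(bb, M)))
    tb <- t(apply(tb, 1, function(bb) clip_box(bb, ncol(out), nrow(out))))
    ok <- tb[, 3] > tb[, 1] & tb[, 4] > tb[, 2]
    new_boxes <- tb[ok, , drop = FALSE]
    kept <- which(ok)
  }
  if (do_flip) {
    out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
    if (nrow(new_boxes) > 0) {
      x0 <- new_boxes[, 1]
      new_boxes[, 1] <- ncol(out) - new_boxes[, 3]
      new_boxes[, 3] <- ncol(out) - x0
    }
  }
  if (policy$jitter > 0) {
    out <- out * bfac
    out <- (out - mean(out)) * cfac + mean(out)
    out <- pmin(pmax(out, 0), 1)
  }
  colnames(new_boxes) <- c("x_min", "y_min", "x_max", "y_max")
  list(image = out, boxes = new_boxes, kept = kept)
}

# Self-contained RNG: draws from an xorshift-style stream seeded explicitly,
# leaving the global .Random.seed untouched.
local_rng <- function(seed) {
  state <- as.integer(seed)
  if (is.na(state)) stop("seed must be an integer", call. = FALSE)
  if (state == 0L) state <- 748291L
  nxt <- function() {
    # 32-bit xorshift in double arithmetic
    x <- state
    x <- bitwXor(x, bitwAnd(bitwShiftL(x, 13L), -1L))
    x <- bitwXor(x, bitwShiftR(x, 17L))
    x <- bitwXor(x, bitwAnd(bitwShiftL(x, 5L), -1L))
    state <<- x
    (x / 4294967296) + 0.5  # map to [0, 1)
  }
  list(unif = function(lo = 0, hi = 1) lo + (hi - lo) * nxt(),
       int = function(n) as.integer(floor(nxt() * n)) + 1L)
}

# Run code with a temporarily-set global seed, restoring the prior RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified train/validation/test split
#'
#' Splits item indices class by class at the given ratios. Within each class
#' the counts are floor allocations of `ratio * n`, with leftover items
#' assigned by largest fractional remainder; remainder ties are resolved in
#' favour of validation, then testing, then training. Shuffling within class
#' is governed by `seed`.
#'
#' @param labels Vector of per-item class labels.
#' @param ratios Numeric `(train, validation, test)` summing to 1.
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `validation`, `test`
#'   forming a partition of `seq_along(labels)`.
#' @examples
#' s <- stratified_split(rep("a", 1004))
#' lengths(s)  # 602, 201, 201
#' @export
stratified_split <- function(labels, ratios = c(0.60, 0.20, 0.20), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be three numbers summing to 1", call. = FALSE)
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  # tie preference: validation, then testing, then training
  tie_order <- c(2L, 3L, 1L)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n <- length(idx)
      if (n < 3L)
        warning(sprintf("class '%s' has %d item(s); degenerate allocation", cl, n))
      idx <- idx[sample.int(n)]
      exact <- ratios * n
      base <- floor(exact)
      rem <- exact - base
      left <- n - sum(base)
      if (left > 0) {
        pr <- order(-rem, match(seq_len(3L), tie_order))
        base[pr[seq_len(left)]] <- base[pr[seq_len(left)]] + 1
      }
      cuts <- cumsum(base)
      out$train <- c(out$train, idx[seq_len(base[1])])
      if (base[2] > 0)
        out$validation <- c(out$validation, idx[(cuts[1] + 1):cuts[2]])
      if (base[3] > 0)
        out$test <- c(out$test, idx[(cuts[2] + 1):cuts[3]])
    }
  })
  out
}

#' Stratified k-fold partition
#'
#' Deals the shuffled items of each class round-robin over `k` folds, so
#' per-class fold sizes differ by at most one and every fold preserves the
#' class proportions up to one item. Augmentation, when used with
#' cross-validation, belongs inside the training folds only — this function
#' just produces the partition.
#'
#' @param labels Vector of per-item class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  if (!is.numeric(k) || k < 2) stop("k must be at least 2", call. = FALSE)
  k <- as.integer(k)
  folds <- vector("list", k)
  with_seed(seed, {
    start <- 0L
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        warning(sprintf("class '%s' has fewer than %d items; distributing round-robin",
                        cl, k))
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold between classes to balance fold totals
      f <- ((seq_along(idx) - 1L + start) %% k) + 1L
      for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], idx[f == j])
      start <- (start + length(idx)) %% k
    }
  })
  folds
}

#' Class weights for imbalanced treatment classes
#'
#' Cost-sensitive weighting that penalises mistakes on under-represented
#' treatment classes more heavily. Two schemes:
#'
#' * `"paper_table"` (default): the published lookup — supports
#'   (314, 602, 891, 602) for classes I (ORIF FAD), II (ORIF IMN),
#'   III (ORIF plate), IV (Casting) map to weights
#'   (1.76, 0.92, 0.62, 0.92). Any other support vector is refused, because
#'   these weights are a fixed published table, not a formula.
#' * `"inverse_mean"`: `weight_c = mean(supports) / support_c`, the standard
#'   derivable alternative; `weight_c * support_c` is constant across
#'   classes.
#'
#' @param supports Positive per-class training-image counts.
#' @param scheme `"paper_table"` or `"inverse_mean"`.
#' @return A `class_weight_table`: data frame with columns `class`,
#'   `support`, `weight`, plus a `scheme` attribute.
#' @examples
#' class_weights()                          # published table
#' class_weights(c(100, 300), "inverse_mean")
#' @export
class_weights <- function(supports = c(314, 602, 891, 602),
                          scheme = c("paper_table", "inverse_mean")) {
  scheme <- match.arg(scheme)
  if (any(supports <= 0)) stop("supports must be positive", call. = FALSE)
  cls <- names(supports)
  if (is.null(cls))
    cls <- if (length(supports) == 4L) c("I", "II", "III", "IV")
           else as.character(seq_along(supports))
  if (scheme == "paper_table") {
    if (length(supports) != 4L || any(supports != c(314, 602, 891, 602)))
      stop("paper_table weights are defined only for supports (314, 602, 891, 602); use scheme = \"inverse_mean\"",
           call. = FALSE)
    w <- c(1.76, 0.92, 0.62, 0.92)
  } else {
    w <- mean(supports) / supports
  }
  structure(data.frame(class = cls, support = as.numeric(supports),
                       weight = as.numeric(w)),
            scheme = scheme, class = c("class_weight_table", "data.frame"))
}
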