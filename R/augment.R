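#' Augmentation policy
#'
#' Augmentations used during contrastive training: random mirroring and
#' rotation of the simplified images. Rotations are restricted to multiples
#' of 90 degrees so no interpolation touches the values; together with the
#' two mirror states this gives the 8 elements of the dihedral group of the
#' square.
#'
#' @param hflip,vflip,rot90 logical; which operations are allowed.
#' @return An object of class `augmentation_policy` listing the allowed
#'   dihedral elements (0-7; element 0 is the identity).
#' @export
augmentation_policy <- function(hflip = TRUE, vflip = TRUE, rot90 = TRUE) {
  elems <- 0L
  if (rot90) elems <- c(elems, 1:3)
  if (hflip) elems <- c(elems, 4L)
  if (vflip) elems <- c(elems, 6L)  # horizontal flip composed with rot180
  if ((hflip || vflip) && rot90) elems <- c(elems, 4:7)
  structure(list(elements = sort(unique(as.integer(elems)))),
            class = "augmentation_policy")
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Apply a dihedral transform to an image
#'
#' Element `k` in 0-7: `k %% 4` clockwise quarter turns, preceded by a
#' horizontal flip when `k >= 4`. Values are untouched, so the per-channel
#' multiset of pixel values is preserved exactly.
#'
#' @param img a `simplified_image` (or plain H x W x C array).
#' @param k dihedral element in 0-7.
#' @return The transformed image.
#' @export
dihedral_transform <- function(img, k) {
  d <- dim(img)
  if (k %% 4 != 0 && d[1] != d[2])
    stop("rotations require a square image")
  out <- img
  if (k >= 4) out <- out[, ncol(out):1, , drop = FALSE]
  r <- k %% 4
  if (r > 0) {
    planes <- lapply(seq_len(d[3]), function(c) {
      m <- out[, , c]
      for (i in seq_len(r)) m <- rot90cw(m)
      m
    })
    out <- array(unlist(planes), dim = dim(img))
  }
  attributes(out) <- attributes(img)
  if (!is.null(dim(img))) dim(out) <- dim(img)
  out
}

#' Randomly augment a simplified image
#'
#' Draws one of the allowed dihedral transforms uniformly (using R's current
#' RNG stream) and applies it.
#'
#' @param img a `simplified_image`.
#' @param policy an [augmentation_policy()].
#' @return The augmented image.
#' @export
augment_image <- function(img, policy = augmentation_policy()) {
  k <- policy$elements[sample.int(length(policy$elements), 1)]
  dihedral_transform(img, k)
}
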