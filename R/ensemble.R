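#' Train an ensemble of contrastive encoders
#'
#' Trains `n_members` encoders on the same images; members differ only by
#' their training seed (initialization, shuffling, augmentation draws). At
#' fitting time the member distances are averaged, which smooths out the
#' idiosyncrasies of any single projection.
#'
#' @param images list of `simplified_image`s.
#' @param cfg an [encoder_config()].
#' @param n_members number of encoders (the full-scale protocol uses 50;
#'   scaled-down fits use 3-5).
#' @param seed master seed; member `i` trains with seed `seed + 7919 * i`.
#' @return An `encoder_ensemble`.
#' @export
train_ensemble <- function(images, cfg, n_members = 50, seed = 1) {
  if (n_members < 1) stop("'n_members' must be at least 1")
  members <- lapply(seq_len(n_members), function(i)
    train_encoder(images, cfg, seed = as.integer(seed + 7919 * i)))
  structure(list(members = members, seed = seed), class = "encoder_ensemble")
}

#' Ensemble-averaged embedding distance
#'
#' The calibration objective: the mean over ensemble members of the Euclidean
#' distance between the two images' projections. At inference this is a
#' pseudo-metric -- non-negative, symmetric, zero for identical inputs (and,
#' as an average of norms, it satisfies the triangle inequality).
#'
#' @param ens an `encoder_ensemble`.
#' @param a,b `simplified_image`s compatible with the ensemble's input shape.
#' @return Non-negative scalar; the per-member distances are attached as
#'   attribute `"member_distances"`.
#' @export
ensemble_distance <- function(ens, a, b) {
  if (!inherits(ens, "encoder_ensemble") || length(ens$members) == 0)
    stop("'ens' must be a non-empty encoder_ensemble")
  d <- vapply(ens$members, function(m) {
    pa <- project_image(m, a)
    pb <- project_image(m, b)
    sqrt(sum((pa - pb)^2))
  }, numeric(1))
  structure(mean(d), member_distances = d)
}

#' Distances from one target to many images
#'
#' Vectorized form of [ensemble_distance()] used when ranking a training set
#' against a target: projects everything once per member and averages the
#' member-wise Euclidean distances.
#'
#' @param ens an `encoder_ensemble`.
#' @param target a `simplified_image`.
#' @param imgs list of `simplified_image`s.
#' @return Numeric vector of length `length(imgs)`.
#' @export
ensemble_distances <- function(ens, target, imgs) {
  acc <- numeric(length(imgs))
  for (m in ens$members) {
    pt <- project_image(m, target)
    pm <- project_images(m, imgs)
    dif <- pm - matrix(pt, nrow(pm), length(pt), byrow = TRUE)
    acc <- acc + sqrt(rowSums(dif^2))
  }
  acc / length(ens$members)
}

#' @export
print.encoder_ensemble <- function(x, ...) {
  cat(sprintf("<encoder_ensemble> %d member(s), input %s, embed_dim %d\n",
              length(x$members),
              paste(x$members[[1]]$cfg$input_shape, collapse = "x"),
              x$members[[1]]$cfg$embed_dim))
  invisible(x)
}

#' Save / load an ensemble directory
#'
#' One JSON checkpoint per member plus a `manifest.json` with the member
#' list and master seed.
#'
#' @param ens an `encoder_ensemble`.
#' @param dir directory path (created if needed).
#' @return `dir` (write) or an `encoder_ensemble` (read).
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("member_%03d.json", seq_along(ens$members))
  for (i in seq_along(ens$members))
    write_encoder(ens$members[[i]], file.path(dir, files[i]))
  jsonlite::write_json(list(members = files, seed = ens$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  members <- lapply(man$members, function(f) read_encoder(file.path(dir, f)))
  structure(list(members = members, seed = man$seed),
            class = "encoder_ensemble")
}
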