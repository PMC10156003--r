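toy_image <- function(h = 8, c = 2, seed = 1) {
  set.seed(seed)
  structure(array(runif(h * h * c), c(h, h, c)),
            channels = paste0("ch", seq_len(c)), class = "simplified_image")
}

test_that("dihedral augmentations preserve values and compose correctly", {
  img <- toy_image()
  expect_identical(unclass(dihedral_transform(img, 0)), unclass(img))
  # horizontal flip is an involution
  expect_equal(unclass(dihedral_transform(dihedral_transform(img, 4), 4)),
               unclass(img))
  # four quarter turns return to the identity
  r <- img
  for (i in 1:4) r <- dihedral_transform(r, 1)
  expect_equal(unclass(r), unclass(img))
  # every element preserves the per-channel multiset of values
  for (k in 0:7) {
    tr <- dihedral_transform(img, k)
    for (c in 1:2) expect_equal(sort(tr[, , c]), sort(img[, , c]))
  }
  # rotation of a non-square image is refused
  rect <- structure(array(runif(8 * 6 * 1), c(8, 6, 1)),
                    class = "simplified_image")
  expect_error(dihedral_transform(rect, 1), "square")
  expect_silent(dihedral_transform(rect, 0))
})

test_that("NT-Xent matches its closed form and the double-loop oracle", {
  # all embeddings identical: every similarity equal, loss = log(2N - 1)
  for (N in c(2, 4, 8)) {
    z <- matrix(rep(c(1, 2), each = 2 * N), 2 * N, 2)
    expect_equal(nt_xent_loss(z, 0.5), log(2 * N - 1))
  }

  set.seed(88)
  for (rep in 1:5) {
    N <- sample(3:8, 1)
    tau <- runif(1, 0.2, 1)
    z <- matrix(rnorm(2 * N * 2), 2 * N, 2)
    expect_equal(nt_xent_loss(z, tau), nt_xent_oracle(z, tau),
                 tolerance = 1e-6)
  }

  # permuting the pairs leaves the loss unchanged
  N <- 5
  z <- matrix(rnorm(2 * N * 2), 2 * N, 2)
  perm <- sample(N)
  zp <- z[c(perm, perm + N), ]
  expect_equal(nt_xent_loss(zp, 0.5), nt_xent_loss(z, 0.5))

  # cosine similarity: per-vector rescaling is irrelevant
  zs <- z * runif(2 * N, 0.1, 10)
  expect_equal(nt_xent_loss(zs, 0.5), nt_xent_loss(z, 0.5))

  expect_error(nt_xent_loss(matrix(0, 4, 2), 0.5), "zero-norm")
  expect_error(nt_xent_loss(matrix(rnorm(4), 2, 2), 0.5), "at least 2 pairs")
})

test_that("the NT-Xent gradient matches finite differences", {
  set.seed(21)
  z <- matrix(rnorm(12), 6, 2)
  g <- abmcal:::nt_xent_grad(z, 0.7)
  eps <- 1e-6
  fd <- matrix(0, 6, 2)
  for (i in 1:6) for (j in 1:2) {
    zp <- z; zp[i, j] <- zp[i, j] + eps
    zm <- z; zm[i, j] <- zm[i, j] - eps
    fd[i, j] <- (nt_xent_loss(zp, 0.7) - nt_xent_loss(zm, 0.7)) / (2 * eps)
  }
  expect_equal(g, fd, tolerance = 1e-6)
})

test_that("projection matches an explicit layer-arithmetic forward pass", {
  cfg <- encoder_config(input_shape = c(8, 8, 2), conv_filters = c(3, 4),
                        hidden = 5, batch_size = 4, epochs = 1)
  enc <- abmcal:::init_encoder(cfg, seed = 2)
  img <- toy_image(8, 2, seed = 3)
  got <- project_image(enc, img)
  want <- naive_encoder_forward(enc, img)
  expect_equal(got, want, tolerance = 1e-10)
  expect_length(got, 2)

  # projecting twice is identical; batched equals single
  expect_identical(project_image(enc, img), got)
  imgs <- lapply(1:3, function(s) toy_image(8, 2, seed = s))
  batch <- project_images(enc, imgs)
  for (i in 1:3) expect_equal(as.vector(batch[i, ]), project_image(enc, imgs[[i]]))

  bad <- toy_image(6, 2)
  expect_error(project_image(enc, bad), "shape")
})

test_that("training is deterministic in the seed and leaves the RNG alone", {
  imgs <- lapply(1:16, function(s) toy_image(8, 2, seed = s))
  cfg <- encoder_config(input_shape = c(8, 8, 2), conv_filters = c(3, 4),
                        hidden = 5, batch_size = 8, epochs = 2)
  set.seed(1234)
  before <- .Random.seed
  e1 <- train_encoder(imgs, cfg, seed = 1)
  expect_identical(.Random.seed, before)
  e2 <- train_encoder(imgs, cfg, seed = 1)
  expect_identical(e1$params, e2$params)
  e3 <- train_encoder(imgs, cfg, seed = 2)
  expect_false(identical(e1$params, e3$params))

  expect_error(train_encoder(imgs[1:10], cfg, seed = 1), "at least")
})

test_that("trained encoders separate structurally distinct image families", {
  fam <- ring_disk_families()
  cfg <- encoder_config(input_shape = c(16, 16, 2), conv_filters = c(8, 16),
                        hidden = 16, batch_size = 16, epochs = 12, lr = 2e-3)
  enc <- train_encoder(c(fam$A, fam$B), cfg, seed = 4)
  # training reduced the contrastive loss on the held-out batch
  expect_lte(enc$heldout_loss[2], enc$heldout_loss[1])

  pa <- project_images(enc, fam$A)
  pb <- project_images(enc, fam$B)
  within <- (mean(dist(pa)) + mean(dist(pb))) / 2
  between <- mean(sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
                       outer(pa[, 2], pb[, 2], "-")^2))
  expect_lt(within, between)
})

test_that("ensemble distance is a pseudo-metric and averages member distances", {
  ens <- family_ensemble()
  fam <- ring_disk_families()
  a <- fam$A[[1]]; b <- fam$B[[1]]; c3 <- fam$A[[2]]

  expect_equal(as.numeric(ensemble_distance(ens, a, a)), 0)
  dab <- ensemble_distance(ens, a, b)
  expect_equal(as.numeric(dab), as.numeric(ensemble_distance(ens, b, a)))
  expect_gte(as.numeric(dab), 0)

  # the reported value is exactly the mean of the member distances, and each
  # member distance reproduces from its own projections
  md <- attr(dab, "member_distances")
  expect_equal(as.numeric(dab), mean(md))
  for (i in seq_along(ens$members)) {
    m <- ens$members[[i]]
    expect_equal(md[i], sqrt(sum((project_image(m, a) - project_image(m, b))^2)))
  }

  # triangle inequality on random triples (averages of norms satisfy it)
  trip <- list(a, b, c3)
  for (p in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))) {
    d12 <- as.numeric(ensemble_distance(ens, trip[[p[1]]], trip[[p[2]]]))
    d13 <- as.numeric(ensemble_distance(ens, trip[[p[1]]], trip[[p[3]]]))
    d32 <- as.numeric(ensemble_distance(ens, trip[[p[3]]], trip[[p[2]]]))
    expect_lte(d12, d13 + d32 + 1e-12)
  }

  # member vs ensemble rankings of a probe set correlate positively
  probes <- c(fam$A[2:6], fam$B[2:6])
  d_ens <- ensemble_distances(ens, a, probes)
  m1 <- ens$members[[1]]
  pa1 <- project_image(m1, a)
  d_m1 <- vapply(probes, function(im)
    sqrt(sum((project_image(m1, im) - pa1)^2)), numeric(1))
  expect_gt(cor(rank(d_ens), rank(d_m1)), 0)

  expect_error(ensemble_distance(structure(list(members = list()),
                                           class = "encoder_ensemble"), a, b),
               "non-empty")
})

test_that("encoders and ensembles round-trip through JSON checkpoints", {
  imgs <- lapply(1:16, function(s) toy_image(8, 2, seed = s))
  cfg <- encoder_config(input_shape = c(8, 8, 2), conv_filters = c(3, 4),
                        hidden = 5, batch_size = 8, epochs = 1)
  enc <- train_encoder(imgs, cfg, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_encoder(enc, tmp)
  back <- read_encoder(tmp)
  img <- toy_image(8, 2, seed = 99)
  expect_equal(project_image(back, img), project_image(enc, img))

  dir <- withr::local_tempdir()
  ens <- structure(list(members = list(enc, back), seed = 1),
                   class = "encoder_ensemble")
  write_ensemble(ens, dir)
  ens2 <- read_ensemble(dir)
  expect_equal(length(ens2$members), 2)
  expect_equal(as.numeric(ensemble_distance(ens2, img, imgs[[1]])),
               as.numeric(ensemble_distance(ens, img, imgs[[1]])))
})
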