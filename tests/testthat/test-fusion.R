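backbone_pair <- function(seed = 1L) {
  list(ct = build_network(2L, seed = seed, "CT"),
       xray = build_network(2L, seed = seed + 100L, "XRAY"))
}

test_that("fusion build is deterministic and transfers backbone parameters verbatim", {
  bb <- backbone_pair()
  m1 <- build_fusion_model(bb$ct, bb$xray, fusion_spec(seed = 5L))
  m2 <- build_fusion_model(bb$ct, bb$xray, fusion_spec(seed = 5L))
  expect_identical(m1, m2)
  m3 <- build_fusion_model(bb$ct, bb$xray, fusion_spec(seed = 6L))
  expect_false(identical(m1$proj, m3$proj))

  # copy contract: the transferred backbone produces the same features
  img <- matrix(runif(784), 28, 28)
  expect_identical(forward(m1$ct_backbone, img)$fc_feature,
                   forward(bb$ct, img)$fc_feature)
})

test_that("randomized_fuse is the stated linear map and deterministic", {
  bb <- backbone_pair()
  m <- build_fusion_model(bb$ct, bb$xray, fusion_spec(seed = 2L))
  f_ct <- runif(192); f_xr <- runif(192)
  expect_equal(randomized_fuse(f_ct, f_xr, m),
               as.vector(m$proj$ct %*% f_ct + m$proj$xray %*% f_xr),
               tolerance = 1e-12)
  # zero features map to the zero vector (linear, no bias)
  expect_equal(randomized_fuse(numeric(192), numeric(192), m), numeric(192))
  # proj_xray = 0 makes the output depend on CT only (matrix-product oracle)
  m0 <- m; m0$proj$xray[] <- 0
  expect_equal(randomized_fuse(f_ct, f_xr, m0), as.vector(m$proj$ct %*% f_ct),
               tolerance = 1e-12)
  expect_error(randomized_fuse(runif(100), f_xr, m), "192")
})

test_that("sum-mode fusion is symmetric under swapping modalities with their projections", {
  bb <- backbone_pair()
  m <- build_fusion_model(bb$ct, bb$xray, fusion_spec(seed = 3L))
  f_ct <- runif(192); f_xr <- runif(192)
  sw <- m; sw$proj$ct <- m$proj$xray; sw$proj$xray <- m$proj$ct
  expect_equal(randomized_fuse(f_ct, f_xr, m), randomized_fuse(f_xr, f_ct, sw),
               tolerance = 1e-12)
})

test_that("fusion output is linear in each feature vector (superposition)", {
  bb <- backbone_pair()
  for (mode in c("sum", "concat_project")) {
    m <- build_fusion_model(bb$ct, bb$xray, fusion_spec(seed = 4L, combine_mode = mode))
    a <- runif(192); b <- runif(192); c2 <- runif(192)
    expect_equal(randomized_fuse(a + 2 * b, c2, m),
                 randomized_fuse(a, c2 * 0, m) + 2 * randomized_fuse(b, c2 * 0, m) +
                   randomized_fuse(a * 0, c2, m),
                 tolerance = 1e-10)
  }
})

test_that("fusion_forward composes extraction, fusion, sigmoid head and softmax", {
  bb <- backbone_pair()
  m <- build_fusion_model(bb$ct, bb$xray, fusion_spec(seed = 9L))
  pair <- tiny_cohort(2L)[[1]]
  p <- fusion_forward(m, pair)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # hand-traced composition
  f_ct <- forward(m$ct_backbone, pair$ct_image)$fc_feature
  f_xr <- forward(m$xray_backbone, pair$xray_image)$fc_feature
  h <- sigmoid(dense_forward(randomized_fuse(f_ct, f_xr, m), m$head_fc))
  ref <- softmax_xent(dense_forward(h, m$head_out), 0L)$probabilities
  expect_equal(p, ref, tolerance = 1e-12)
})

test_that("zero backbones give all-0.5 features and a head-determined constant output", {
  bb <- backbone_pair()
  zero <- function(net) {
    for (l in c("conv1", "conv2")) { net[[l]]$kernels[] <- 0; net[[l]]$biases[] <- 0 }
    for (l in c("fc1", "fc2")) { net[[l]]$weights[] <- 0; net[[l]]$biases[] <- 0 }
    net
  }
  m <- build_fusion_model(zero(bb$ct), zero(bb$xray), fusion_spec(seed = 1L))
  pairs <- tiny_cohort(3L)
  fw <- copdfusion:::fusion_forward_batch(m, pairs)
  expect_equal(fw$cache$f_ct, matrix(0.5, 192, 3), ignore_attr = TRUE)
  # constant features -> identical output for every subject
  expect_equal(fw$probabilities[, 1], fw$probabilities[, 2], tolerance = 1e-12)
  # and it matches the hand-traced head on the fused constant vector
  fused <- randomized_fuse(rep(0.5, 192), rep(0.5, 192), m)
  ref <- softmax_xent(dense_forward(sigmoid(dense_forward(fused, m$head_fc)),
                                    m$head_out), 0L)$probabilities
  expect_equal(fw$probabilities[, 1], ref, tolerance = 1e-12)
})

test_that("frozen backbones are untouched by fusion training", {
  bb <- backbone_pair()
  m <- build_fusion_model(bb$ct, bb$xray, fusion_spec(seed = 7L))
  ds <- tiny_cohort(20L, seed = 3L)
  res <- train_model(m, ds, train_config(100L, 8L, seed = 1L))
  expect_identical(res$model$ct_backbone, m$ct_backbone)
  expect_identical(res$model$xray_backbone, m$xray_backbone)
  expect_identical(res$model$proj, m$proj)        # projections frozen too
  expect_false(identical(res$model$head_fc, m$head_fc))
})

test_that("fine-tuning updates backbones; trainable projections update projections", {
  bb <- backbone_pair()
  ds <- tiny_cohort(12L, seed = 4L)
  m <- build_fusion_model(bb$ct, bb$xray, fusion_spec(seed = 8L),
                          freeze_backbones = FALSE, trainable_projections = TRUE)
  res <- train_model(m, ds, train_config(20L, 6L, seed = 2L,
                                         freeze_backbones = FALSE))
  expect_false(identical(res$model$ct_backbone$conv1$kernels,
                         m$ct_backbone$conv1$kernels))
  expect_false(identical(res$model$proj, m$proj))
})

test_that("fusion gradients pass a finite-difference check on the head", {
  bb <- backbone_pair()
  m <- build_fusion_model(bb$ct, bb$xray, fusion_spec(seed = 10L))
  pairs <- tiny_cohort(4L, seed = 6L)
  y <- vapply(pairs, function(p) p$label, integer(1))
  loss_at <- function(model) copdfusion:::fusion_forward_batch(model, pairs, labels = y)$loss
  fw <- copdfusion:::fusion_forward_batch(m, pairs, labels = y)
  g <- copdfusion:::fusion_backward(m, fw)
  for (slot in c("head_fc", "head_out")) {
    p <- m[[slot]]$weights
    idx <- sample(length(p), 20L)
    num <- vapply(idx, function(i) {
      mp <- m; mp[[slot]]$weights[i] <- p[i] + 1e-5
      mm <- m; mm[[slot]]$weights[i] <- p[i] - 1e-5
      (loss_at(mp) - loss_at(mm)) / 2e-5
    }, numeric(1))
    expect_lt(max(rel_err(num, as.vector(g[[slot]]$weights)[idx])), 1e-4)
  }
})
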