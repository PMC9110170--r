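test_that("similarity implements the four models", {
  expect_equal(similarity(c(1, 2), c(3, 4), attention_config("dot")), 11)
  expect_equal(similarity(c(2, 0), c(5, 0), attention_config("cosine")), 1)
  expect_equal(similarity(rep(1, 4), rep(1, 4), attention_config("scaled_dot")),
               2)  # 4 / sqrt(4)
  # bilinear with identity W equals dot; with a custom W it is k' W q
  expect_equal(similarity(c(1, 2), c(3, 4), attention_config("bilinear")), 11)
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(similarity(c(1, 2), c(3, 4),
                          attention_config("bilinear", bilinear_matrix = W)),
               c(3, 4) %*% W %*% c(1, 2) |> as.numeric())
  expect_error(similarity(c(0, 0), c(1, 1), attention_config("cosine")),
               "zero-norm")
  expect_error(similarity(1:3, 1:4, attention_config("dot")), "mismatch")
})

test_that("attention_weights is a stable softmax", {
  expect_equal(attention_weights(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(attention_weights(c(1, 2, 3)),
               c(0.09003057, 0.24472847, 0.66524096), tolerance = 1e-5)
  w <- attention_weights(c(0, 0, 1000))
  expect_true(all(is.finite(w)))
  expect_equal(w[3], 1, tolerance = 1e-12)
  expect_error(attention_weights(c(1, NA, 2)), "finite")
  expect_error(attention_weights(c(1, 2), temperature = 0), "positive")
})

test_that("weights are positive, sum to 1 and are strictly monotone", {
  cfgs <- lapply(c("dot", "cosine", "bilinear", "scaled_dot"), attention_config)
  qk <- fixture_modal_matrices()
  for (cfg in cfgs) {
    fused <- fuse(qk$F, qk$V, qk$G, cfg)
    expect_true(all(fused$weights > 0))
    expect_equal(sum(fused$weights), 1, tolerance = 1e-12)
  }
  # monotonicity on 1000 random triples at assorted temperatures
  sims <- mindfuse:::with_seed(33, matrix(rnorm(3000, sd = 2), ncol = 3))
  temps <- rep_len(c(0.5, 1, 2), nrow(sims))
  for (i in seq_len(nrow(sims))) {
    w0 <- attention_weights(sims[i, ], temps[i])
    bumped <- sims[i, ] + c(0.3, 0, 0)
    w1 <- attention_weights(bumped, temps[i])
    expect_gt(w1[1], w0[1])
    expect_lt(w1[2], w0[2])
    expect_lt(w1[3], w0[3])
    expect_equal(sum(w1), 1, tolerance = 1e-12)
  }
})

test_that("modality_descriptor is the column mean with optional scaling", {
  m <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(modality_descriptor(m), c(2, 3))
  expect_equal(modality_descriptor(m[1, , drop = FALSE]), c(1, 2))
  expect_equal(modality_descriptor(matrix(0, 3, 2)), c(0, 0))
  sc <- fit_descriptor_scaler(rbind(c(0, 0), c(4, 6)))
  expect_equal(modality_descriptor(m, sc), (c(2, 3) - c(2, 3)) / sc$scale)
  expect_error(modality_descriptor(matrix(numeric(0), 0, 2)), "empty")
})

test_that("fuse stacks weighted blocks in fixed order", {
  qk <- fixture_modal_matrices()
  fused <- fuse(qk$F, qk$V, qk$G)
  expect_equal(nrow(fused$matrix), 103L)
  expect_identical(fused$block_index,
                   rep(c("face", "gait", "voice"), c(68L, 18L, 17L)))
  expect_length(flatten_fused(fused), 412L)
  # row-major flatten: first |S| entries are the first face channel row
  expect_equal(flatten_fused(fused)[1:4], unname(fused$matrix[1, ]))

  # override (1,1,1) reproduces plain concatenation
  plain <- fuse(qk$F, qk$V, qk$G, weight_override = c(1, 1, 1))
  expect_equal(plain$matrix,
               rbind(unclass(qk$F), unclass(qk$G), unclass(qk$V)),
               ignore_attr = TRUE)

  # identical descriptors (equal column means) -> exactly (1/3, 1/3, 1/3)
  mk <- function(mod, k) structure(matrix(rep(c(1, 2, 3, 4), each = k), k),
                                   modality = mod,
                                   class = c("ModalFeatureMatrix", "matrix"))
  f3 <- fuse(mk("face", 68), mk("voice", 17), mk("gait", 18))
  expect_equal(unname(f3$weights), rep(1 / 3, 3), tolerance = 1e-12)

  # zeroing one modality's weight zeroes exactly its rows
  z <- fuse(qk$F, qk$V, qk$G, weight_override = c(1, 0, 1))
  expect_true(all(z$matrix[z$block_index == "voice", ] == 0))
  expect_true(all(z$matrix[z$block_index != "voice", ] != 0))

  # column mismatch is rejected
  bad <- unclass(qk$V)[, 1:3]
  expect_error(fuse(qk$F, bad, qk$G), "statistic columns")
})

test_that("cosine fusion is invariant to a common positive descriptor rescale", {
  qk <- fixture_modal_matrices()
  w1 <- fuse(qk$F, qk$V, qk$G, attention_config("cosine"))$weights
  scale_mat <- function(m, a) structure(unclass(m) * a,
                                        modality = attr(m, "modality"),
                                        class = class(m))
  w2 <- fuse(scale_mat(qk$F, 5), scale_mat(qk$V, 5),
             scale_mat(qk$G, 5), attention_config("cosine"))$weights
  expect_equal(w1, w2, tolerance = 1e-12)

  # dot-mode weights under a common rescale a match temperature a^2
  wd1 <- fuse(qk$F, qk$V, qk$G, attention_config("dot", temperature = 1))$weights
  wd2 <- fuse(scale_mat(qk$F, 2), scale_mat(qk$V, 2), scale_mat(qk$G, 2),
              attention_config("dot", temperature = 4))$weights
  expect_equal(wd1, wd2, tolerance = 1e-9)
})
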