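# Score-level fusion rules, majority voting and paired multimodal fusion.

test_that("fusion rules reproduce the worked arithmetic examples", {
  l1 <- score_matrix(matrix(c(0.6, 0.4), 1), c("a", "b"), "s1")
  l2 <- score_matrix(matrix(c(0.5, 0.5), 1), c("a", "b"), "s1")
  expect_equal(unname(unclass(product_fuse(l1, l2))[1, ]), c(0.30, 0.20))
  expect_equal(unname(unclass(sum_fuse(l1, l2))[1, ]), c(1.1, 0.9))
  expect_equal(unname(unclass(
    weighted_sum_fuse(l1, l2, c(0.7, 0.3)))[1, ]), c(0.57, 0.43))
})

test_that("fusion rules match the brute-force oracle on random matrices", {
  set.seed(20)
  for (rep in 1:250) {
    n <- sample(1:6, 1); L <- sample(2:5, 1)
    a <- random_scores(n, L); b <- random_scores(n, L)
    ids <- paste0("s", 1:n); cls <- paste0("c", 1:L)
    sa <- score_matrix(a, cls, ids); sb <- score_matrix(b, cls, ids)
    w <- runif(2); w <- w / sum(w)
    expect_identical(unname(unclass(product_fuse(sa, sb))),
                     fuse_oracle(a, b, "product"))
    expect_identical(unname(unclass(sum_fuse(sa, sb))),
                     fuse_oracle(a, b, "sum"))
    expect_equal(unname(unclass(weighted_sum_fuse(sa, sb, w))),
                 fuse_oracle(a, b, "weighted", w), tolerance = 1e-15)
    k <- sample(2:4, 1)
    mats <- replicate(k, random_scores(n, L), simplify = FALSE)
    sms <- lapply(mats, score_matrix, class_labels = cls, sample_ids = ids)
    expect_identical(unname(majority_vote(sms)), majority_oracle(mats))
  }
})

test_that("fusion preserves argmax under uniform partners, self-fusion and zero weights", {
  set.seed(21)
  l1 <- score_matrix(random_scores(30, 4))
  unif <- score_matrix(matrix(1 / 4, 30, 4), colnames(l1), rownames(l1))
  expect_equal(max.col(product_fuse(l1, unif)), max.col(l1))
  expect_equal(max.col(sum_fuse(l1, l1)), max.col(l1))
  expect_equal(unclass(weighted_sum_fuse(l1, unif, c(1, 0))), unclass(l1))
  half <- weighted_sum_fuse(l1, l1, c(0.5, 0.5))
  expect_equal(unclass(half), unclass(l1), tolerance = 1e-15)
  # veto: a zero in one model forces a zero product score
  z <- unclass(l1); z[, 2] <- 0
  zs <- score_matrix(z, colnames(l1), rownames(l1))
  expect_true(all(unclass(product_fuse(l1, zs))[, 2] == 0))
})

test_that("fusion rules are row-local (sample permutation equivariance)", {
  set.seed(22)
  a <- random_scores(20, 3); b <- random_scores(20, 3)
  ids <- paste0("s", 1:20)
  perm <- sample(20)
  f_all <- sum_fuse(score_matrix(a, sample_ids = ids),
                    score_matrix(b, sample_ids = ids))
  f_perm <- sum_fuse(score_matrix(a[perm, ], sample_ids = ids[perm]),
                     score_matrix(b[perm, ], sample_ids = ids[perm]))
  expect_identical(unname(unclass(f_perm)), unname(unclass(f_all))[perm, ])
})

test_that("misaligned matrices and invalid weights are rejected", {
  a <- score_matrix(random_scores(4, 3))
  b <- score_matrix(random_scores(5, 3))
  expect_error(sum_fuse(a, b), "alignment error")
  c2 <- score_matrix(random_scores(4, 3), class_labels = c("x", "y", "z"))
  expect_error(product_fuse(a, c2), "alignment error")
  expect_error(weighted_sum_fuse(a, a, c(-0.1, 1.1)), "argument error")
  expect_error(score_matrix(matrix(c(-1, 2), 1)), "nonnegative")
  expect_error(majority_vote(list(a)), "at least two")
})

test_that("choose_weights is accuracy-proportional with the ordering constraint", {
  w <- choose_weights(0.8, 0.6)
  expect_equal(c(w$rho1, w$rho2), c(4 / 7, 3 / 7))
  expect_gt(w$rho1, w$rho2)
  expect_equal(w$rho1 + w$rho2, 1)
  tie <- choose_weights(0.7, 0.7)
  expect_equal(c(tie$rho1, tie$rho2), c(0.5, 0.5))
  degen <- choose_weights(0.9, 0)
  expect_equal(c(degen$rho1, degen$rho2), c(1, 0))
  expect_warning(zero <- choose_weights(0, 0), "equal weights")
  expect_equal(c(zero$rho1, zero$rho2), c(0.5, 0.5))
})

test_that("majority voting resolves ties by summed posterior then class index", {
  ids <- "s1"; cls <- c("a", "b", "c")
  m1 <- score_matrix(matrix(c(0.7, 0.2, 0.1), 1), cls, ids)  # votes a
  m2 <- score_matrix(matrix(c(0.6, 0.3, 0.1), 1), cls, ids)  # votes a
  m3 <- score_matrix(matrix(c(0.1, 0.8, 0.1), 1), cls, ids)  # votes b
  expect_equal(unname(majority_vote(list(m1, m2, m3))), 0L)
  # two-way split: a sums 1.3, b sums 1.1 -> a
  s1 <- score_matrix(matrix(c(0.7, 0.3), 1), c("a", "b"), ids)
  s2 <- score_matrix(matrix(c(0.6, 0.8) / 1.4, 1), c("a", "b"), ids)
  expect_equal(unname(majority_vote(list(s1, s2))), 0L)
  # unanimity equals any single voter's argmax
  expect_equal(unname(majority_vote(list(m1, m1, m1))),
               unname(max.col(m1) - 1L))
})

test_that("paired fusion respects one-hot vetoes and class mappings", {
  set.seed(23)
  n <- 40; L <- 3
  labels <- sample(0:(L - 1), n, replace = TRUE)
  onehot <- diag(L)[labels + 1, ]
  img <- score_matrix(onehot, paste0("class", 0:2), paste0("img", 1:n))
  audio <- score_matrix(random_scores(n, L), paste0("class", 0:2),
                        paste0("aud", 1:n))
  pairing <- data.frame(image_id = paste0("img", 1:n),
                        audio_id = paste0("aud", 1:n), label = labels)
  rep <- pair_and_fuse(img, audio, pairing, method = "product")
  expect_equal(rep$accuracy, 100)  # one-hot image posteriors veto the rest
  # audio classes under different names are translated via the mapping
  audio2 <- score_matrix(unclass(audio), c("low", "moderate", "strong"),
                         rownames(audio))
  map <- c(low = "class0", moderate = "class1", strong = "class2")
  rep2 <- pair_and_fuse(img, audio2, pairing, method = "product",
                        class_map = map)
  expect_equal(rep2$accuracy, 100)
  expect_error(pair_and_fuse(img, audio2, pairing, method = "product",
                             class_map = map[1:2]), "mapping error")
  bad <- pairing; bad$audio_id[1] <- "aud999"
  expect_error(pair_and_fuse(img, audio, bad), "alignment error")
})

test_that("fusing two chance-level modalities stays at chance", {
  set.seed(24)
  n <- 400; L <- 4
  labels <- rep(0:(L - 1), each = n / L)
  img <- score_matrix(random_scores(n, L), paste0("class", 0:3),
                      paste0("img", 1:n))
  audio <- score_matrix(random_scores(n, L), paste0("class", 0:3),
                        paste0("aud", 1:n))
  pairing <- data.frame(image_id = rownames(img), audio_id = rownames(audio),
                        label = labels)
  for (meth in c("majority", "product", "sum")) {
    rep <- pair_and_fuse(img, audio, pairing, method = meth)
    # binomial null: chance 25%, 4 sigma ~ 8.7 points at n = 400
    expect_lt(abs(rep$accuracy - 25), 9)
  }
})
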