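test_that("RBF kernel identities hold", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 5), 1)
  y <- x + c(1, 0, 0)                    # squared distance 1
  expect_equal(rbf_kernel(x, y, 1), exp(-1))
  expect_equal(rbf_kernel(x, y, 0), 1)   # gamma -> 0 limit
  expect_equal(rbf_kernel(x, y, 2), rbf_kernel(y, x, 2))
  expect_error(rbf_kernel(x, c(1, 2), 1), "dimensionality")
})

test_that("well-separated clouds are classified perfectly", {
  toy <- toy_clouds(20, sep = 10, seed = 3)
  m <- train_nu_svm(toy$X, toy$y, nu = 0.5, gamma = 1, scale = "none")
  expect_identical(unname(predict(m, toy$X)), as.character(toy$y))
})

test_that("every trained model satisfies the nu-property", {
  for (seed in 1:4) for (nu in c(0.3, 0.5, 0.8)) {
    toy <- toy_clouds(15, sep = 1.5, seed = seed)   # overlapping classes
    m <- train_nu_svm(toy$X, toy$y, nu = nu, gamma = 1, scale = "none")
    f <- decision_values(m, toy$X)
    ysign <- ifelse(as.character(toy$y) == m$pos_label, 1, -1)
    # free SVs sit at y*f = 1 up to solver tolerance; a 1e-3 cushion keeps
    # them out of the margin-error count
    margin_err <- mean(ysign * f < 1 - 1e-3)
    sv_frac <- length(m$coefs) / m$n_train
    expect_lte(margin_err, nu + 1e-9)
    expect_gte(sv_frac, nu - 1e-9)
  }
})

test_that("duplicating every training point leaves predictions unchanged", {
  toy <- toy_clouds(10, sep = 2, seed = 6)
  m1 <- train_nu_svm(toy$X, toy$y, nu = 0.5, gamma = 1, scale = "none")
  m2 <- train_nu_svm(rbind(toy$X, toy$X), factor(rep(toy$y, 2)),
                     nu = 0.5, gamma = 1, scale = "none")
  grid <- as.matrix(expand.grid(seq(-3, 5, by = 0.5), seq(-3, 5, by = 0.5)))
  expect_identical(predict(m1, grid), predict(m2, grid))
})

test_that("training rejects degenerate inputs with clear messages", {
  X <- matrix(rnorm(20), 10)
  expect_error(train_nu_svm(X, rep("a", 10), gamma = 1),
               "exactly 2 classes")
  y <- c(rep("a", 9), "b")
  expect_error(train_nu_svm(X, y, nu = 0.5, gamma = 1), "infeasible")
  m <- train_nu_svm(X, rep(c("a", "b"), 5), nu = 0.3, gamma = 1)
  expect_error(decision_values(m, matrix(0, 1, 5)), "length mismatch")
  expect_error(decision_values(m, c(0, 0, 0)), "length mismatch")
})

test_that("all-zero decision scores fall back to the first class in order", {
  # craft three binary models whose decision value is exactly 0 everywhere:
  # one support vector at the probe point with coef 1 and rho = K(x, x) = 1
  classes <- c("CS+", "CS-", "scenery")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  probe <- matrix(c(0.5, 0.5), 1)
  mk <- function(p) structure(
    list(sv = probe, coefs = 1, rho = 1, gamma = 1, nu = 0.5, tol = 1e-6,
         pos_label = p[1], neg_label = p[2], levels = p, n_train = 2,
         center = c(0, 0), scale = c(1, 1)), class = "nu_svm")
  ovo <- structure(list(models = lapply(pairs, mk), pairs = pairs,
                        classes = classes, gamma = 1, nu = 0.5),
                   class = "ovo_svm")
  expect_identical(predict(ovo, probe), "CS+")
})

test_that("round-robin CV runs l rounds and is deterministic", {
  set.seed(8)
  X <- matrix(rnorm(36 * 4), 36)
  y <- factor(rep(c("CS+", "CS-", "scenery"), 12),
              levels = c("CS+", "CS-", "scenery"))
  cv1 <- round_robin_cv(X, y, gamma = 0.01)
  cv2 <- round_robin_cv(X, y, gamma = 0.01)
  expect_identical(cv1$rounds, 36L)
  expect_identical(nrow(cv1$predictions), 36L)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_true(all(cv1$per_class >= 0 & cv1$per_class <= 1))

  expect_error(round_robin_cv(X[1:4, ], y[1:4]), "at least 6")
  expect_error(round_robin_cv(X[1:8, ], c(rep("a", 7), "b"), gamma = 1),
               "at least 2 samples")
})

test_that("a huge-margin feature yields perfect leave-one-out accuracy", {
  set.seed(10)
  X <- cbind(rep(c(-10, 0, 10), each = 8) + rnorm(24, sd = 0.1),
             rnorm(24))
  y <- rep(c("CS+", "CS-", "scenery"), each = 8)
  cv <- round_robin_cv(X, y, gamma = 1)
  expect_equal(cv$accuracy, 1)
  expect_true(all(cv$per_class == 1))
})

test_that("the kernel sweep covers the documented gamma grid", {
  set.seed(12)
  X <- matrix(rnorm(18 * 28), 18)
  y <- rep(c("a", "b", "c"), 6)
  sw <- kernel_sweep(X, y, nu = 0.4)
  expect_equal(sw$summary$gamma, c(1e-4, 1e-2, 1, 1 / 28))
  expect_equal(sw$summary$gamma[4], 0.0357142857, tolerance = 1e-6)

  dup <- kernel_sweep(X, y, gammas = c(0.01, 0.01), nu = 0.4)
  expect_identical(dup$summary$accuracy[1], dup$summary$accuracy[2])
  expect_gte(max(sw$summary$accuracy), min(sw$summary$accuracy))
  expect_error(kernel_sweep(X, y, gammas = numeric()), "empty")
})

test_that("decisions agree with an independent dual solver on 2-D toys", {
  grid <- as.matrix(expand.grid(seq(-2.5, 4.5, length.out = 13),
                                seq(-2.5, 4.5, length.out = 13)))
  for (seed in c(2, 5, 9)) {
    toy <- toy_clouds(6, sep = 2, seed = seed)     # 12 points
    m <- train_nu_svm(toy$X, toy$y, nu = 0.5, gamma = 1, scale = "none")
    mine <- ifelse(predict(m, grid) == levels(toy$y)[1], 1, -1)
    ora <- oracle_nu_svm(toy$X, toy$y, nu = 0.5, gamma = 1)$decide(grid)
    agree <- mean(mine == ora | ora == 0)
    expect_gte(agree, 0.95)
  }
})

test_that("label permutation drives accuracy toward chance", {
  set.seed(14)
  X <- matrix(rnorm(24 * 3), 24)
  X[, 1] <- X[, 1] + rep(c(-3, 0, 3), each = 8)    # real signal present
  y <- factor(rep(c("CS+", "CS-", "scenery"), each = 8),
              levels = c("CS+", "CS-", "scenery"))
  expect_gt(round_robin_cv(X, y, gamma = 0.1)$accuracy, 0.8)
  pc <- permutation_chance(X, y, n_perm = 12, gamma = 0.1, seed = 99)
  expect_lt(abs(pc$mean_accuracy - 1 / 3), 0.12)
  expect_error(permutation_chance(X, y, n_perm = 2, gamma = 0.1),
               "seed is mandatory")
})
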