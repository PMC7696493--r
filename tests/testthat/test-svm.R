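test_that("kernels evaluate to their closed forms", {
  u <- c(1, 2, 0, -1, 0.5)
  expect_equal(kernel_eval(kernel_spec("rbf", gamma = 2), u, u), 1.0)
  expect_equal(kernel_eval(kernel_spec("linear"), c(1, 0, 0, 0, 0),
                           c(0, 1, 0, 0, 0)), 0.0)
  # rbf with gamma 1 and squared distance ln 4
  v <- c(sqrt(log(4)), 0)
  expect_equal(kernel_eval(kernel_spec("rbf", gamma = 1), c(0, 0), v), 0.25)
  expect_equal(kernel_eval(kernel_spec("polynomial", gamma = 1, coef0 = 1),
                           c(1, 1), c(1, 1)), 27)   # (1*2 + 1)^3
  expect_equal(kernel_eval(kernel_spec("sigmoid", gamma = 0.5), c(1, 1), c(1, 1)),
               tanh(1))
  expect_error(kernel_eval(kernel_spec("rbf"), c(1, 2), c(1, 2, 3)), "dimension")
  expect_error(kernel_spec("rbf", gamma = 0), "gamma")
})

test_that("kernel matrices agree with pairwise scalar evaluation", {
  set.seed(8)
  U <- matrix(rnorm(15), 3, 5)
  V <- matrix(rnorm(20), 4, 5)
  for (spec in list(kernel_spec("rbf", 0.7), kernel_spec("linear"),
                    kernel_spec("polynomial", 0.5, coef0 = 1),
                    kernel_spec("sigmoid", 0.3, coef0 = 0.2))) {
    K <- kernel_matrix(spec, U, V)
    oracle <- outer(1:3, 1:4, Vectorize(function(i, j)
      kernel_eval(spec, U[i, ], V[j, ])))
    expect_equal(K, oracle, tolerance = 1e-12)
  }
})

test_that("binary training yields a valid dual solution", {
  tb <- toy_binary()
  m <- train_binary(tb$x, tb$y, C = 10, kernel = kernel_spec("rbf", gamma = 1))
  expect_equal(sum(m$coef), 0, tolerance = 1e-8)
  expect_true(all(abs(m$coef) <= 10 + 1e-8))
  expect_identical(predict_binary(m, tb$x)$class, tb$y)
  expect_error(train_binary(tb$x, rep(1L, nrow(tb$x)), C = 1), "both classes")
  expect_error(train_binary(tb$x, tb$y, C = -1), "C must")
})

test_that("the rbf kernel separates an XOR arrangement", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1L, 1L, -1L, -1L)
  m <- train_binary(x, y, C = 10, kernel = kernel_spec("rbf", gamma = 1))
  expect_identical(predict_binary(m, x)$class, y)
})

test_that("flipping training labels negates the decision function", {
  tb <- toy_binary(seed = 9)
  m1 <- train_binary(tb$x, tb$y, C = 2, kernel = kernel_spec("rbf", gamma = 0.5))
  m2 <- train_binary(tb$x, -tb$y, C = 2, kernel = kernel_spec("rbf", gamma = 0.5))
  set.seed(10)
  probe <- matrix(rnorm(25), 5, 5)
  expect_equal(predict_binary(m1, probe)$decision,
               -predict_binary(m2, probe)$decision, tolerance = 1e-8)
})

test_that("decision values match the explicit support-vector sum", {
  tb <- toy_binary(seed = 11)
  for (spec in list(kernel_spec("rbf", 1), kernel_spec("linear"),
                    kernel_spec("polynomial", 0.5, coef0 = 1))) {
    m <- train_binary(tb$x, tb$y, C = 3, kernel = spec)
    set.seed(12)
    probe <- matrix(rnorm(40), 8, 5)
    oracle <- vapply(seq_len(nrow(probe)), function(j) {
      s <- 0
      for (i in seq_len(nrow(m$sv)))
        s <- s + m$coef[i] * kernel_eval(m$kernel, m$sv[i, ], probe[j, ])
      s + m$b
    }, numeric(1))
    expect_equal(predict_binary(m, probe)$decision, oracle, tolerance = 1e-8)
  }
})

test_that("a zero decision value classifies as +1", {
  # crafted node: single pair of support vectors whose contributions cancel
  node <- manual_node(sv = rbind(c(0, 0), c(0, 0)), coef = c(1, -1), b = 0)
  p <- predict_binary(node, c(3, 3))
  expect_equal(p$decision, 0)
  expect_identical(p$class, 1L)
})

test_that("the binary tree peels phases in fixed order", {
  ds <- toy_clusters()
  tree <- train_tree(ds, C = 10, gamma = 1)
  expect_identical(predict_tree(tree, ds$x), ds$y)
  # prediction is deterministic and idempotent
  expect_identical(predict_tree(tree, ds$x), predict_tree(tree, ds$x))
  # totality: crafted always-negative nodes fall through to upper buffer
  never <- manual_node(sv = rbind(c(0, 0, 0, 0, 0), c(1, 1, 1, 1, 1)),
                       coef = c(1, -1), b = -5)
  tree_neg <- structure(list(scheme = "binary_tree",
                             nodes = list(never, never, never)),
                        class = "phase_tree")
  expect_identical(predict_tree(tree_neg, ds$x), rep(4L, length(ds$y)))
  expect_true(all(predict_tree(tree, matrix(rnorm(50), 10, 5)) %in% 1:4))
  # missing class is rejected
  keep <- ds$y != 2
  expect_error(train_tree(labeled_dataset(ds$x[keep, ], ds$y[keep])),
               "all four")
})

test_that("training error never rises with C on separable data", {
  ds <- toy_clusters(sd = 0.3)
  errs <- vapply(c(0.1, 1, 10, 100), function(C) {
    mean(predict_tree(train_tree(ds, C = C, gamma = 1), ds$x) != ds$y)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("the secondary two-stage scheme predicts valid phases", {
  ds <- toy_clusters()
  sec <- train_tree(ds, C = 10, gamma = 1, scheme = "secondary")
  expect_identical(predict_tree(sec, ds$x), ds$y)
})

test_that("kernel grid report sweeps kernels by parameter pair", {
  ds <- toy_clusters(n_per_class = 10)
  rep_ <- kernel_grid_report(ds, ds, params = data.frame(C = c(2, 1),
                                                         gamma = c(1, 1)))
  expect_equal(nrow(rep_), 4 * 2)
  expect_setequal(unique(rep_$kernel),
                  c("polynomial", "rbf", "linear", "sigmoid"))
  expect_true(all(rep_$accuracy[rep_$kernel == "rbf"] == 100))
})

test_that("tree models survive a JSON round trip", {
  ds <- toy_clusters(n_per_class = 10)
  tree <- train_tree(ds, C = 2, gamma = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_model(tree, path)
  back <- read_tree_model(path)
  set.seed(13)
  probe <- matrix(rnorm(100), 20, 5)
  expect_identical(predict_tree(back, probe), predict_tree(tree, probe))
  expect_equal(back$nodes[[1]]$b, tree$nodes[[1]]$b, tolerance = 1e-12)
})
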