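test_that("a planted single predictor is found among noise", {
  set.seed(1)
  n <- 100
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 3 * x1 + rnorm(n, sd = 0.1)
  design <- buildDesign(data.frame(x1 = x1, x2 = x2))
  fit <- stepwiseFit(design, y, c("x1", "x2"))
  expect_equal(fit$terms, "x1")
  expect_equal(unname(fit$coefficients[2]), 3, tolerance = 0.05)
  expect_lt(fit$model_p, 1e-10)
})

test_that("pure noise with a strict entry gate stays intercept-only", {
  set.seed(2)
  n <- 80
  X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  y <- rnorm(n)
  design <- buildDesign(X)
  fit <- stepwiseFit(design, y, colnames(X),
                     params = stepwiseParams(p_enter = 1e-6,
                                             p_remove = 1e-5))
  expect_equal(length(fit$terms), 0)
  expect_equal(fit$model_p, 1)
})

test_that("an irrelevant starting term is removed", {
  set.seed(3)
  n <- 120
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n)
  design <- buildDesign(data.frame(x1 = x1, x2 = x2))
  fit <- stepwiseFit(design, y, c("x1", "x2"),
                     initial_terms = c("x1", "x2"))
  expect_equal(fit$terms, "x1")
})

test_that("stepwise agrees with exhaustive best-subset AIC search", {
  set.seed(4)
  agree <- 0
  cases <- 20
  for (k in seq_len(cases)) {
    n <- 80
    p <- sample(4:6, 1)
    X <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # orthogonal
    colnames(X) <- paste0("v", seq_len(p))
    nsig <- sample(0:p, 1)
    beta <- c(seq(2, 0.8, length.out = max(nsig, 1))[seq_len(nsig)],
              rep(0, p - nsig))
    y <- X %*% beta + rnorm(n)
    design <- buildDesign(as.data.frame(X))
    ## open the F-gates so the AIC criterion alone drives the moves: on an
    ## orthogonal design greedy AIC stepping is then exactly the best
    ## subset, making the exhaustive search a valid oracle
    fit <- stepwiseFit(design, y, colnames(X),
                       params = stepwiseParams(p_enter = 0.5,
                                               p_remove = 0.9))
    best <- bfBestSubsetAIC(X, y)
    if (setequal(fit$terms, colnames(X)[best$cols])) agree <- agree + 1
  }
  expect_equal(agree, cases)
})

test_that("categorical covariates move as whole blocks", {
  set.seed(5)
  n <- 150
  f <- factor(sample(c("a", "b", "c"), n, TRUE))
  y <- 2 * (f == "b") + 3.5 * (f == "c") + rnorm(n)
  design <- buildDesign(data.frame(grp = f, noise = rnorm(n)))
  expect_equal(length(design$terms$grp), 2)       # two dummies, one term
  fit <- stepwiseFit(design, y, c("grp", "noise"))
  expect_equal(fit$terms, "grp")
  expect_equal(length(fit$coefficients), 3)       # intercept + 2 dummies
})

test_that("feature ordering screens and sorts by association strength", {
  set.seed(6)
  n <- 60
  y <- rnorm(n)
  d <- data.frame(strong = y + rnorm(n, sd = 0.2),
                  weak = y + rnorm(n, sd = 2),
                  pure = rnorm(n))
  design <- buildDesign(d)
  ord <- orderFeatures(design, y, screen_p = 0.3, data = d)
  expect_equal(ord[1], "strong")
  expect_true(!"pure" %in% ord || which(ord == "pure") > 1)
  ## under the null, roughly screen_p of features are retained
  set.seed(7)
  k <- 200
  dn <- as.data.frame(matrix(rnorm(n * k), n, k))
  frac <- length(orderFeatures(buildDesign(dn), rnorm(n), 0.3, dn)) / k
  expect_lt(abs(frac - 0.3), 0.12)
})

test_that("AIC accounting is internally consistent", {
  set.seed(8)
  n <- 50
  x <- rnorm(n); y <- x + rnorm(n)
  design <- buildDesign(data.frame(x = x))
  fit <- stepwiseFit(design, y, "x")
  ## aic = 2k - 2 logLik with k = coefficients + sigma
  k <- length(fit$coefficients) + 1
  expect_equal(fit$aic, 2 * k - 2 * fit$log_likelihood, tolerance = 1e-10)
  ## matches lm's AIC
  ref <- AIC(lm(y ~ x))
  expect_equal(fit$aic, ref, tolerance = 1e-8)
})
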