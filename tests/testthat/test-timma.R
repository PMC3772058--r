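# The three-rule prediction engine, checked against hand-traced cases and a
# naive set-scanning oracle.

chain3 <- function() {
  # d1 {A} -> 0.2, d2 {A,B} -> 0.6, d3 {A,B,C} -> 0.9
  list(X = toy_binary(list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
                      c("A", "B", "C")),
       y = c(0.2, 0.6, 0.9))
}

test_that("identical-set rule takes precedence and averages matches", {
  d <- chain3()
  m <- timma_model(d$X, d$y)
  p <- predict_efficacy(m, c("A", "B"))
  expect_equal(p$prediction, 0.6)
  expect_equal(p$identical_estimate, 0.6)
  expect_true(is.na(p$lower_bound) && is.na(p$upper_bound))
  # two equal profiles average
  X2 <- toy_binary(list(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)),
                   c("A", "B", "C"))
  m2 <- timma_model(X2, c(0.2, 0.8, 0.5))
  expect_equal(predict_efficacy(m2, c("A", "B"))$prediction, 0.5)
})

test_that("minimization rule hand-trace: query {B} in the 3-drug chain", {
  d <- chain3()
  m <- timma_model(d$X, d$y)
  p <- predict_efficacy(m, "B")
  # k_min = d2 (0.6); d3 is not a subset of T(d2), no averaging; no subsets
  expect_equal(p$upper_bound, 0.6)
  expect_true(is.na(p$lower_bound))
  expect_equal(p$prediction, 0.6)
})

test_that("maximization rule hand-trace with Eq-5 style averaging", {
  X <- toy_binary(list(c(1, 1, 0, 0), c(1, 1, 1, 0)), c("A", "B", "C", "D"))
  m <- timma_model(X, c(0.6, 0.5))
  p <- predict_efficacy(m, c("A", "B", "C", "D"))
  # k_max = d1 (0.6); d2 contains T(d1) with lower efficacy -> mean(0.6, 0.5)
  expect_equal(p$lower_bound, 0.55)
  expect_true(is.na(p$upper_bound))
  expect_equal(p$prediction, 0.55)
})

test_that("rule exhaustion yields a non-identifiable prediction", {
  X <- toy_binary(list(c(1, 0), c(0, 1)), c("A", "B"))
  m <- timma_model(X, c(0.3, 0.7))
  p <- predict_efficacy(m, "B", exclude = 2L)   # only {A} remains
  expect_false(p$identifiable)
  expect_true(is.na(p$prediction))
})

test_that("queries outside the model target set are rejected", {
  d <- chain3()
  m <- timma_model(d$X, d$y, S = c("A", "B"))
  expect_error(predict_efficacy(m, c("A", "Z")), "outside the model")
  expect_error(timma_model(d$X, d$y[1:2]), "length")
})

test_that("relation cache matches a direct recomputation", {
  set.seed(11)
  inst <- random_instance(7, 5)
  m <- timma_model(inst$X, inst$y)
  for (i in 1:7) for (j in 1:7) {
    expect_identical(m$relations$subset[i, j],
                     set_subset(inst$profiles[[i]], inst$profiles[[j]]))
    expect_identical(m$relations$equal[i, j],
                     set_equal(inst$profiles[[i]], inst$profiles[[j]]))
  }
  expect_identical(m$relations$superset, t(m$relations$subset))
})

test_that("engine agrees with the naive set-scanning oracle everywhere", {
  set.seed(101)
  n_cases <- 300
  for (case in seq_len(n_cases)) {
    nd <- sample(3:8, 1)
    nt <- sample(2:5, 1)
    inst <- random_instance(nd, nt, p = runif(1, 0.2, 0.8))
    m <- timma_model(inst$X, inst$y)
    S <- colnames(inst$X)
    q_set <- S[runif(nt) < 0.5]
    got <- predict_efficacy(m, mask_of(q_set, S))
    want <- naive_timma(inst$profiles, inst$y, q_set)
    expect_equal(got$prediction, want$prediction, info = paste("case", case))
    expect_equal(got$lower_bound, want$lower, info = paste("case", case))
    expect_equal(got$upper_bound, want$upper, info = paste("case", case))
  }
})

test_that("identifiable predictions stay within the training efficacy range", {
  set.seed(21)
  for (case in 1:50) {
    inst <- random_instance(6, 4)
    m <- timma_model(inst$X, inst$y)
    for (q in 0:15) {
      p <- predict_efficacy(m, q)
      if (p$identifiable) {
        expect_gte(p$prediction, min(inst$y))
        expect_lte(p$prediction, max(inst$y))
      }
    }
  }
})

test_that("predictions are invariant to the ordering of training drugs", {
  set.seed(31)
  for (case in 1:25) {
    inst <- random_instance(7, 4)
    y <- sample(seq(0.01, 0.99, length.out = 7))   # distinct efficacies
    m <- timma_model(inst$X, y)
    perm <- sample(7)
    Xp <- inst$X[perm, , drop = FALSE]
    Xp <- affinity_matrix(Xp + 0L, "binary")
    mp <- timma_model(Xp, y[perm])
    for (q in 0:15) {
      expect_equal(predict_efficacy(m, q)$prediction,
                   predict_efficacy(mp, q)$prediction)
    }
  }
})

test_that("noise-free monotone blocking functions are predicted exactly", {
  # efficacy = 1 iff the profile hits both pathways {A} and {B}
  set.seed(41)
  d <- planted_network_dataset(30, list("A", "B"), n_targets = 3, seed = 5)
  m <- timma_model(d$X, d$panel$scaled_efficacy)
  S <- colnames(d$X)
  for (q in 0:7) {
    p <- predict_efficacy(m, q)
    if (p$identifiable) {
      truth <- as.integer(all(c("A", "B") %in% unmask(q, S)))
      expect_equal(p$prediction, truth)
    }
  }
})

test_that("LOO error matches the naive oracle and honours the NA policy", {
  d <- chain3()
  expect_equal(loo_error(d$X, d$y),
               naive_loo(list("A", c("A", "B"), c("A", "B", "C")), d$y,
                         naive_timma))
  # identical profiles, equal efficacies: perfect LOO
  Xi <- toy_binary(list(c(1, 1), c(1, 1)), c("A", "B"))
  expect_equal(loo_error(Xi, c(0.4, 0.4)), 0)
  # identical profiles, opposite efficacies: each predicts the other
  expect_equal(loo_error(Xi, c(0, 1)), 1)
  # no relations at all: policy decides
  Xn <- toy_binary(list(c(1, 0), c(0, 1)), c("A", "B"))
  expect_equal(loo_error(Xn, c(0.1, 0.9)), mean(abs(c(0.1, 0.9) - 0.5)))
  expect_equal(loo_error(Xn, c(0.1, 0.9), na_policy = "worst"), 1)
  expect_true(is.na(loo_error(Xn, c(0.1, 0.9), na_policy = "skip")))
  set.seed(51)
  for (case in 1:30) {
    inst <- random_instance(6, 4)
    expect_equal(loo_error(inst$X, inst$y),
                 naive_loo(inst$profiles, inst$y, naive_timma))
  }
})
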