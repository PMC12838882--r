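test_that("confusion matrix counts reference/prediction pairs", {
  ref <- c("W", "W", "N2")
  prd <- c("W", "N2", "N2")
  cm <- confusion_matrix(ref, prd)
  expect_equal(cm["W", "W"], 1L)
  expect_equal(cm["W", "N2"], 1L)
  expect_equal(cm["N2", "N2"], 1L)
  expect_equal(sum(cm), 3L)

  same <- sample(SLEEP_STAGES, 30, replace = TRUE)
  cmd <- confusion_matrix(same, same)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0L)

  set.seed(1)
  a <- sample(SLEEP_STAGES, 50, replace = TRUE)
  b <- sample(SLEEP_STAGES, 50, replace = TRUE)
  cm2 <- confusion_matrix(a, b)
  expect_equal(unname(colSums(cm2)), as.numeric(table(factor(b, SLEEP_STAGES))))

  expect_error(confusion_matrix(a, b[1:10]), "lengths")
  expect_error(confusion_matrix(c("W", "X"), c("W", "W")), "unknown")
})

test_that("accuracy, F1 and MF1 match a brute-force tally oracle", {
  diagm <- diag(c(5, 3, 7, 2, 4))
  dimnames(diagm) <- list(SLEEP_STAGES, SLEEP_STAGES)
  expect_equal(accuracy(diagm), 1)
  expect_equal(macro_f1(diagm), 1)

  # a class absent from both -> F1 defined as 0 and flagged
  degen <- diag(c(5, 3, 7, 2, 0))
  dimnames(degen) <- list(SLEEP_STAGES, SLEEP_STAGES)
  f <- class_f1(degen, "REM")
  expect_equal(f[["f1"]], 0)
  expect_true(attr(f, "degenerate"))

  set.seed(2)
  for (rep in 1:10) {
    cm <- matrix(rpois(25, 8), 5, 5, dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
    oracle <- oracle_metrics(cm)
    expect_equal(accuracy(cm), oracle$accuracy)
    for (i in 1:5) expect_equal(class_f1(cm, i)[["f1"]], oracle$f1[i])
    expect_equal(macro_f1(cm), oracle$mf1)
    expect_equal(cohens_kappa(cm), oracle$kappa)
  }
})

test_that("Cohen's kappa matches hand computation and an independent implementation", {
  # two-class hand example embedded in the 5-class matrix
  cm <- matrix(0, 5, 5, dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  cm[1:2, 1:2] <- matrix(c(45, 10, 5, 40), 2) # rows ref: (45,5),(10,40)
  expect_equal(accuracy(cm), 0.85)
  # chance agreement from row x column marginal products
  pe <- (55 * 50 + 45 * 50) / 100^2
  expect_equal(pe, 0.50)
  expect_equal(cohens_kappa(cm), (0.85 - 0.50) / (1 - 0.50), tolerance = 1e-12)

  expect_equal(cohens_kappa(diag(c(3, 3, 3, 3, 3))), 1)

  # independent cross-check on random matrices
  skip_if_not_installed("e1071")
  set.seed(3)
  for (rep in 1:5) {
    cmr <- matrix(rpois(25, 6) + 1, 5, 5)
    expect_equal(cohens_kappa(cmr), e1071::classAgreement(cmr)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("kappa is near zero under simulated independence", {
  set.seed(4)
  n <- 100000
  p <- c(0.35, 0.11, 0.35, 0.06, 0.13)
  ref <- sample(SLEEP_STAGES, n, replace = TRUE, prob = p)
  prd <- sample(SLEEP_STAGES, n, replace = TRUE, prob = p)
  expect_lt(abs(cohens_kappa(confusion_matrix(ref, prd))), 0.02)
})

test_that("kappa is undefined when both raters sit on one class", {
  cm <- matrix(0, 5, 5)
  cm[2, 2] <- 10
  expect_warning(k <- cohens_kappa(cm), "undefined")
  expect_true(is.na(k))
})

test_that("class permutation permutes per-class F1 but fixes the global metrics", {
  set.seed(5)
  cm <- matrix(rpois(25, 5) + 1, 5, 5, dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  perm <- c(3, 1, 5, 2, 4)
  cmp <- cm[perm, perm]
  expect_equal(accuracy(cmp), accuracy(cm))
  expect_equal(macro_f1(cmp), macro_f1(cm))
  expect_equal(cohens_kappa(cmp), cohens_kappa(cm))
  for (i in 1:5) {
    expect_equal(class_f1(cmp, i)[["f1"]], class_f1(cm, perm[i])[["f1"]])
  }
})

test_that("the report bundles all metrics and serializes to JSON", {
  set.seed(6)
  ref <- sample(SLEEP_STAGES, 200, replace = TRUE)
  prd <- ifelse(runif(200) < 0.7, ref, sample(SLEEP_STAGES, 200, replace = TRUE))
  rep <- metrics_report(ref, prd)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$n, 200)
  expect_equal(rep$accuracy, mean(ref == prd))
  js <- write_metrics_json(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$accuracy, rep$accuracy)
  expect_equal(parsed$kappa, rep$kappa)
})
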