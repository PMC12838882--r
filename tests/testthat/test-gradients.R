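# Finite-difference verification of the hand-written backward passes. These
# pin the correctness of everything the training loops rely on.

fd_check <- function(loss_fn, model, get, set, analytic, k = 3, h = 1e-5,
                     tol = 1e-5) {
  v <- get(model)
  idx <- sample(length(v), min(k, length(v)))
  for (i in idx) {
    num <- (loss_fn(set(model, replace(v, i, v[i] + h))) -
            loss_fn(set(model, replace(v, i, v[i] - h)))) / (2 * h)
    ana <- analytic[i]
    rel <- abs(num - ana) / max(1, abs(num) + abs(ana))
    expect_lt(rel, tol)
  }
}

test_that("Supcon gradients through the whole network match finite differences", {
  set.seed(42)
  m <- tiny_model(pool_mode = "max", layers = 2, mode = "pyramid")
  X <- matrix(rnorm(4 * 3000), 4, 3000)
  labs <- factor(c("W", "N2", "W", "N2"), levels = SLEEP_STAGES)
  ms <- asNamespace("maxsleep")
  sg <- ms$scl_loss_grads(m, X, labs, tau = 0.07, train = FALSE)
  loss_fn <- function(model) {
    ms$scl_loss_grads(model, X, labs, 0.07, train = FALSE)$loss
  }
  g <- sg$grads
  fd_check(loss_fn, m, function(m) m$params$fe$patch$W,
           function(m, v) { m$params$fe$patch$W[] <- v; m }, g$fe$patch$W)
  fd_check(loss_fn, m, function(m) m$params$fe$pyr2$W,
           function(m, v) { m$params$fe$pyr2$W[] <- v; m }, g$fe$pyr2$W)
  fd_check(loss_fn, m, function(m) m$params$fe$dt$W,
           function(m, v) { m$params$fe$dt$W[] <- v; m }, g$fe$dt$W)
  fd_check(loss_fn, m, function(m) m$params$shared$W,
           function(m, v) { m$params$shared$W[] <- v; m }, g$shared$W)
  fd_check(loss_fn, m, function(m) m$params$tse[[1]]$Wq,
           function(m, v) { m$params$tse[[1]]$Wq[] <- v; m }, g$tse[[1]]$Wq)
  fd_check(loss_fn, m, function(m) m$params$tse[[1]]$Wk,
           function(m, v) { m$params$tse[[1]]$Wk[] <- v; m }, g$tse[[1]]$Wk)
  fd_check(loss_fn, m, function(m) m$params$tse[[2]]$Wv,
           function(m, v) { m$params$tse[[2]]$Wv[] <- v; m }, g$tse[[2]]$Wv)
  fd_check(loss_fn, m, function(m) m$params$tse[[2]]$W1,
           function(m, v) { m$params$tse[[2]]$W1[] <- v; m }, g$tse[[2]]$W1)
  fd_check(loss_fn, m, function(m) m$params$tse[[1]]$ln2_gamma,
           function(m, v) { m$params$tse[[1]]$ln2_gamma[] <- v; m },
           g$tse[[1]]$ln2_gamma)
  fd_check(loss_fn, m, function(m) m$params$projector$W2,
           function(m, v) { m$params$projector$W2[] <- v; m }, g$projector$W2)
})

test_that("avg-pool attention gradients also match finite differences", {
  set.seed(43)
  m <- tiny_model(pool_mode = "avg", layers = 1, mode = "single")
  X <- matrix(rnorm(2 * 3000), 2, 3000)
  labs <- factor(c("N3", "N3"), levels = SLEEP_STAGES)
  ms <- asNamespace("maxsleep")
  sg <- ms$scl_loss_grads(m, X, labs, tau = 0.07, train = FALSE)
  loss_fn <- function(model) {
    ms$scl_loss_grads(model, X, labs, 0.07, train = FALSE)$loss
  }
  fd_check(loss_fn, m, function(m) m$params$tse[[1]]$Wk,
           function(m, v) { m$params$tse[[1]]$Wk[] <- v; m }, sg$grads$tse[[1]]$Wk)
  fd_check(loss_fn, m, function(m) m$params$tse[[1]]$Wv,
           function(m, v) { m$params$tse[[1]]$Wv[] <- v; m }, sg$grads$tse[[1]]$Wv)
})

test_that("classifier cross-entropy gradients match finite differences", {
  set.seed(44)
  ms <- asNamespace("maxsleep")
  w <- init_as2c(8, seed = 2)
  H <- list(matrix(rnorm(8 * 12), 8, 12), matrix(rnorm(8 * 5), 8, 5))
  y <- 3
  cl <- ms$as2c_fwd(H, w)
  ce <- ms$ce_loss_grad(cl$logits, y)
  ab <- ms$as2c_bwd(ce$dlogits, cl, w)
  loss_w <- function(w) ms$ce_loss_grad(ms$as2c_fwd(H, w)$logits, y)$loss
  h <- 1e-6
  for (nm in c("Ws", "bs", "u", "Wa", "ba")) {
    v <- w[[nm]]
    for (i in sample(length(v), min(3, length(v)))) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      num <- (loss_w(wp) - loss_w(wm)) / (2 * h)
      expect_lt(abs(num - ab$grads[[nm]][i]) / max(1, abs(num)), 1e-4)
    }
  }
  # encoder-side gradient (used by full fine-tuning)
  i <- 17
  Hp <- H; Hp[[1]][i] <- Hp[[1]][i] + h
  Hm <- H; Hm[[1]][i] <- Hm[[1]][i] - h
  num <- (ms$ce_loss_grad(ms$as2c_fwd(Hp, w)$logits, y)$loss -
          ms$ce_loss_grad(ms$as2c_fwd(Hm, w)$logits, y)$loss) / (2 * h)
  expect_lt(abs(num - ab$dH[[1]][i]), 1e-5)
})
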