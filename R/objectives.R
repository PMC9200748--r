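#' Loss weights for the two training objectives
#'
#' `lambda1` weights the L1 reconstruction term in the generator objective,
#' `lambda2` weights the gradient penalty in the critic objective, and the
#' adversarial term carries an adaptive weight `lambda_e(epoch) = 1/epoch`
#' (1-based), which decays the unbounded critic score's pull on the generator
#' as training proceeds.
#'
#' @param lambda1 L1 weight (default 100).
#' @param lambda2 Gradient-penalty weight (default 10).
#' @return A `bp_loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 100, lambda2 = 10) {
  if (lambda1 < 0 || lambda2 < 0) abort("loss weights must be >= 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "bp_loss_weights")
}

#' @rdname loss_weights
#' @param epoch 1-based epoch index.
#' @export
lambda_e <- function(epoch) {
  if (any(epoch < 1)) abort("lambda_e: epoch must be >= 1 (1-based indexing)")
  1 / epoch
}

#' Mean absolute error between target and prediction
#'
#' The expectation in the L1 objective is realized as the arithmetic mean
#' over every entry (batch, channels and pixels).
#'
#' @param target,prediction Arrays of identical shape.
#' @return Scalar mean absolute difference.
#' @export
l1_loss <- function(target, prediction) {
  if (!identical(dim(target) %||% length(target),
                 dim(prediction) %||% length(prediction)))
    abort("l1_loss: shape mismatch between target and prediction")
  mean(abs(target - prediction))
}

# Scalar critic scores plus the input-gradient of the per-sample score with
# respect to the fluorescent stack. Supports the full patch critic and the
# analytic linear critic used in tests/diagnostics.
critic_score_and_grad <- function(critic, brightfield, fluorescent) {
  UseMethod("critic_score_and_grad")
}

#' @export
critic_score_and_grad.bp_critic <- function(critic, brightfield, fluorescent) {
  bf <- as_batch(brightfield); fl <- as_batch(fluorescent)
  fw <- critic_forward(critic, abind4(bf, fl), keep = TRUE)
  d <- dim(fw$map)
  score <- colMeans(matrix(fw$map, d[1] * d[2] * d[3], d[4]))
  dmap <- array(1 / (d[1] * d[2] * d[3]), d)
  bw <- critic_backward(critic, fw$cache, dmap, need_dx = TRUE,
                        need_dpar = FALSE)
  nb <- dim(bf)[3]
  g <- bw$dx[, , nb + seq_len(dim(fl)[3]), , drop = FALSE]
  list(score = score, grad = g)
}

# An exactly linear critic D(x, xhat) = <c, xhat> + bias, per sample.
linear_critic <- function(c_arr, bias = 0) {
  structure(list(c = c_arr, bias = bias), class = "bp_linear_critic")
}

#' @export
critic_score_and_grad.bp_linear_critic <- function(critic, brightfield,
                                                   fluorescent) {
  fl <- as_batch(fluorescent)
  n <- dim(fl)[4]
  cv <- as.numeric(critic$c)
  score <- colSums(matrix(fl, length(cv), n) * cv) + critic$bias
  g <- array(rep(cv, n), dim(fl))
  list(score = score, grad = g)
}

#' Gradient penalty of a critic
#'
#' Draws one uniform interpolation coefficient per sample, forms
#' `xhat = t * real + (1 - t) * fake`, and returns the mean over the batch of
#' `(||grad_xhat D(x, xhat)||_2 - 1)^2`, where the gradient of the reduced
#' (mean) critic score is taken with respect to the interpolated fluorescent
#' stack by exact reverse-mode differentiation. The squared form is the
#' standard WGAN-GP penalty enforcing an approximately 1-Lipschitz critic.
#'
#' @param critic A `bp_critic`.
#' @param brightfield `(H, W, 3[, N])` conditioning stack.
#' @param real,fake `(H, W, 5[, N])` real and generated fluorescent stacks of
#'   matching shape.
#' @param seed Optional seed for the interpolation draw.
#' @return Scalar penalty (>= 0).
#' @export
gradient_penalty <- function(critic, brightfield, real, fake, seed = NULL) {
  gp_components(critic, brightfield, real, fake, seed)$value
}

gp_components <- function(critic, brightfield, real, fake, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  real <- as_batch(real); fake <- as_batch(fake)
  if (!identical(dim(real), dim(fake)))
    abort("gradient_penalty: real and fake shapes differ")
  d <- dim(real)
  tcoef <- runif(d[4])
  tb <- rep(tcoef, each = prod(d[1:3]))
  xhat <- real * tb + fake * (1 - tb)
  dim(xhat) <- d
  sg <- critic_score_and_grad(critic, brightfield, xhat)
  norms <- sqrt(colSums(matrix(sg$grad, prod(d[1:3]), d[4])^2))
  list(value = mean((norms - 1)^2), xhat = xhat, grad = sg$grad,
       norms = norms, score = sg$score)
}

#' Generator objective (weighted L1 minus adversarial score)
#'
#' Returns `lambda1 * l1 - lambda_e(epoch) * critic_score_on_fake`, the
#' quantity the generator minimizes: it is rewarded (objective decreases)
#' when the critic scores its output higher.
#'
#' @param l1 Scalar L1 loss of the generated batch.
#' @param critic_score_on_fake Mean critic score of the generated batch.
#' @param weights A [loss_weights()].
#' @param epoch 1-based epoch index (sets the adaptive adversarial weight).
#' @return Scalar objective value.
#' @export
generator_objective <- function(l1, critic_score_on_fake,
                                weights = loss_weights(), epoch = 1) {
  if (epoch < 1) abort("generator_objective: epoch must be >= 1")
  weights$lambda1 * l1 - lambda_e(epoch) * critic_score_on_fake
}

#' Critic objective (negated Wasserstein surrogate plus gradient penalty)
#'
#' Returns the loss the critic minimizes:
#' `-(score_real - score_fake) + lambda2 * gp`. Minimizing it maximizes the
#' real-fake score gap while penalizing deviations of the interpolate
#' gradient norm from 1.
#'
#' @param score_real,score_fake Mean critic scores on real and generated
#'   batches.
#' @param gp Gradient-penalty value (see [gradient_penalty()]).
#' @param weights A [loss_weights()].
#' @return Scalar objective value.
#' @export
critic_objective <- function(score_real, score_fake, gp,
                             weights = loss_weights()) {
  -(score_real - score_fake) + weights$lambda2 * gp
}
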