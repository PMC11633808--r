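# Focal log losses for both networks and the weighted total generator loss.

#' Loss hyper-parameters
#'
#' @param gamma Focusing exponent; 0 recovers the plain negative log
#'   likelihood. Default 2.
#' @param eps Small positive offset inside the logarithm so the loss stays
#'   finite at a target-class probability of exactly 0. Default 1e-7.
#' @param alpha Weight of the generator's supervised focal loss in the total
#'   generator loss. Default 20.
#' @param beta Weight of the adversarial term. Default 1.
#' @return A `loss_params` list.
#' @export
loss_params <- function(gamma = 2, eps = 1e-7, alpha = 20, beta = 1) {
  stopifnot(gamma >= 0, eps > 0, eps < 1, alpha >= 0, beta >= 0)
  structure(list(gamma = gamma, eps = eps, alpha = alpha, beta = beta),
            class = "loss_params")
}

#' Focal log loss on target-class probabilities
#'
#' Per voxel, with target-class probability `p` and label weight fixed at 1:
#' `-(1 - p)^gamma * log(p + eps)`. The `(1 - p)^gamma` factor down-weights
#' voxels the network already classifies confidently, focusing training on
#' hard voxels; `eps` keeps the loss finite at `p = 0`.
#'
#' @param p_target Array/matrix/vector of probabilities of the *target*
#'   class at each voxel, in `[0, 1]`.
#' @param params [loss_params()].
#' @return List with `grid` (per-voxel losses, same shape as `p_target`)
#'   and `mean` (scalar mean over all voxels).
#' @export
focal_log_loss <- function(p_target, params = loss_params()) {
  if (any(p_target < 0) || any(p_target > 1) || any(!is.finite(p_target))) {
    abort("`p_target` must be finite and within [0, 1].")
  }
  grid <- -(1 - p_target)^params$gamma * log(p_target + params$eps)
  list(grid = grid, mean = mean(grid))
}

# d/dp of the per-voxel focal log loss; used by the backward passes.
focal_log_loss_grad <- function(p_target, params = loss_params()) {
  g <- params$gamma
  om <- 1 - p_target
  grad <- -om^g / (p_target + params$eps)
  if (g > 0) grad <- grad + g * om^(g - 1) * log(p_target + params$eps)
  grad
}

#' Total generator loss
#'
#' `alpha * FL_G + beta * (1 - FL_D)`: the supervised focal loss against the
#' gold standard plus an adversarial term that rewards the generator when
#' the discriminator's focal loss on the generated sample is high (i.e. the
#' discriminator is being fooled).
#'
#' @param fl_g Mean generator focal loss (scalar).
#' @param fl_d_on_generated Mean discriminator focal loss evaluated on the
#'   generated sample (scalar).
#' @param params [loss_params()] supplying `alpha` and `beta`.
#' @return Scalar loss.
#' @export
generator_total_loss <- function(fl_g, fl_d_on_generated,
                                 params = loss_params()) {
  if (!is_scalar_number(fl_g) || !is_scalar_number(fl_d_on_generated)) {
    abort("loss terms must be finite scalars.")
  }
  params$alpha * fl_g + params$beta * (1 - fl_d_on_generated)
}
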