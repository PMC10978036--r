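#' Reconstruction configuration
#'
#' Hyper-parameters of the variational objective
#' `F(X) = alpha1 ||A X - Y||^2 + alpha2 CNN(X) + alpha3 TV(X)`
#' and of the steepest-descent iteration that minimizes it.  The default
#' weights (`alpha1 = 1e-8`, `alpha2 = 0.002`, `alpha3 = 1e-11`, 600
#' iterations) suit clinical-range CT intensities; the weights are coupled to
#' the intensity scale of the images the score network was trained on, so
#' unit-intensity synthetic phantoms need larger `alpha1`/`alpha3` (see the
#' methods vignette for the scaling used in this package's experiments).
#'
#' @param alpha1,alpha2,alpha3 Nonnegative weights of the data-fidelity, CNN
#'   score and TV terms.
#' @param n_iter Number of descent iterations.
#' @param step_rule `"backtracking"` (halve the step until the objective
#'   decreases, at most 20 halvings) or `"fixed"`.
#' @param step_size Initial (and, for `"fixed"`, constant) step length.
#' @param init Starting image: `"fbp"` of the measured sinogram, or
#'   `"zeros"`.
#' @param nonnegativity Clamp the image at 0 after every step.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(alpha1 = 1e-8, alpha2 = 0.002, alpha3 = 1e-11,
                         n_iter = 600L, step_rule = c("backtracking", "fixed"),
                         step_size = 1.0, init = c("fbp", "zeros"),
                         nonnegativity = FALSE) {
  step_rule <- match.arg(step_rule)
  init <- match.arg(init)
  n_iter <- as.integer(n_iter)
  stopifnot(alpha1 >= 0, alpha2 >= 0, alpha3 >= 0, n_iter >= 1L,
            step_size > 0, is.logical(nonnegativity))
  structure(
    list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3, n_iter = n_iter,
         step_rule = step_rule, step_size = as.numeric(step_size),
         init = init, nonnegativity = nonnegativity),
    class = "recon_config"
  )
}

#' Recommended reconstruction weights for unit-intensity synthetic phantoms
#'
#' The penalty weights of [recon_config()] are coupled to the intensity scale
#' of the training images.  For the package's synthetic corpora (soft-tissue
#' body at intensity 1, 64 x 64 grid, 45-view scans) the data-fidelity weight
#' is fixed at 1 and the penalty weights were calibrated on reconstruction
#' error over held-out calibration phantoms, preserving the reference weight
#' hierarchy: the TV term is kept weak (it alone must not already solve the
#' piecewise-constant phantoms, or the learned penalty has nothing left to
#' do) and the CNN weight takes the error-optimal value on the calibration
#' set.  See the methods vignette for the calibration.
#'
#' @param n_iter Iteration count (default 200, suited to the 64 x 64 desk
#'   scale).
#' @param alpha2 CNN-score weight; pass 0 to switch the learned penalty off.
#' @param ... Further arguments passed to [recon_config()].
#' @return A [recon_config()].
#' @export
synthetic_recon_config <- function(n_iter = 200L, alpha2 = 2, alpha3 = 0.1,
                                   ...) {
  recon_config(alpha1 = 1, alpha2 = alpha2, alpha3 = alpha3, n_iter = n_iter,
               step_rule = "backtracking", step_size = 1, init = "fbp", ...)
}

#' Reconstruction objective and its components
#'
#' Evaluates `F = alpha1 ||A X - Y||^2 + alpha2 CNN(X) + alpha3 TV(X)`.
#' `F` may be negative, because the CNN score may be negative.  The CNN score
#' is always evaluated and reported (it is the main diagnostic), even when
#' `alpha2 = 0`.
#'
#' @param x Image matrix matching the sinogram's geometry.
#' @param y A [sinogram()].
#' @param model A trained `cnn_prior` in score mode.
#' @param tv A [tv_config()].
#' @param rc A [recon_config()].
#' @return List with `F`, `data_term` (`||AX - Y||^2`), `cnn_score` and
#'   `tv_term`.
#' @export
objective <- function(x, y, model, tv = tv_config(), rc = recon_config()) {
  stopifnot(inherits(y, "tomo_sinogram"), inherits(model, "cnn_prior"),
            inherits(rc, "recon_config"))
  geom <- y$geometry
  x <- .check_image(x, geom)
  resid <- forward_project(x, geom)$values - y$values
  data_term <- sum(resid^2)
  cnn <- cnn_score(model, x)
  tvv <- tv_norm(x, tv)
  list(F = rc$alpha1 * data_term + rc$alpha2 * cnn + rc$alpha3 * tvv,
       data_term = data_term, cnn_score = cnn, tv_term = tvv)
}

#' Gradient of the reconstruction objective
#'
#' `2 alpha1 t(A)(AX - Y) + alpha2 grad CNN(X) + alpha3 grad TV(X)`; matches
#' directional finite differences of [objective()] away from ReLU kinks.
#' Terms with a zero weight are skipped.
#'
#' @inheritParams objective
#' @return Gradient matrix of the same size as `x`.
#' @export
objective_gradient <- function(x, y, model, tv = tv_config(),
                               rc = recon_config()) {
  stopifnot(inherits(y, "tomo_sinogram"), inherits(model, "cnn_prior"),
            inherits(rc, "recon_config"))
  geom <- y$geometry
  x <- .check_image(x, geom)
  g <- matrix(0, nrow(x), ncol(x))
  if (rc$alpha1 > 0) {
    resid <- forward_project(x, geom)$values - y$values
    g <- g + 2 * rc$alpha1 * back_project(resid, geom)
  }
  if (rc$alpha2 > 0) g <- g + rc$alpha2 * cnn_score_gradient(model, x)
  if (rc$alpha3 > 0) g <- g + rc$alpha3 * tv_gradient(x, tv)
  g
}

#' Iterative steepest-descent reconstruction with a learned penalty
#'
#' Minimizes the objective by steepest descent starting from `rc$init`.  With
#' the backtracking rule the step is halved (at most 20 times) until the
#' objective does not increase, which makes the objective trace monotonically
#' non-increasing; if no acceptable step is found the iterate is kept and the
#' failure recorded in the trace.  Every iteration is logged: objective,
#' data-fidelity term, CNN score and TV term (the per-iteration CNN score
#' curve is the main diagnostic of artifact suppression).
#'
#' @param y A [sinogram()] of the measured (typically few-view) data.
#' @param model A trained `cnn_prior`; must be in score mode.
#' @param rc A [recon_config()].
#' @param tv A [tv_config()] with `epsilon > 0`.
#' @return List of class `tomo_recon` with `image` (the final iterate),
#'   `trace` (data frame with `n_iter + 1` rows: iteration 0 is the starting
#'   point) and the configurations used.
#' @export
reconstruct <- function(y, model, rc = recon_config(), tv = tv_config()) {
  stopifnot(inherits(y, "tomo_sinogram"), inherits(model, "cnn_prior"),
            inherits(rc, "recon_config"), inherits(tv, "tv_config"))
  if (model$mode != "score") {
    stop("model must be in score mode (see set_mode); the penalty is the raw logit")
  }
  geom <- y$geometry
  x <- switch(rc$init,
              fbp = fbp(y, geom),
              zeros = matrix(0, geom$image_size, geom$image_size))
  if (rc$nonnegativity) x <- pmax(x, 0)

  n_iter <- rc$n_iter
  trace <- data.frame(
    iteration = 0:n_iter, F = NA_real_, data_term = NA_real_,
    cnn_score = NA_real_, tv_term = NA_real_, step = NA_real_,
    step_accepted = NA
  )
  ob <- objective(x, y, model, tv, rc)
  if (!is.finite(ob$F)) stop("objective is non-finite at iteration 0")
  trace[1, 2:5] <- c(ob$F, ob$data_term, ob$cnn_score, ob$tv_term)

  tau <- rc$step_size
  for (it in seq_len(n_iter)) {
    g <- objective_gradient(x, y, model, tv, rc)
    if (rc$step_rule == "fixed") {
      x_new <- x - rc$step_size * g
      if (rc$nonnegativity) x_new <- pmax(x_new, 0)
      ob_new <- objective(x_new, y, model, tv, rc)
      if (!is.finite(ob_new$F)) {
        stop(sprintf("objective diverged (non-finite) at iteration %d", it))
      }
      x <- x_new; ob <- ob_new
      trace[it + 1, ] <- list(it, ob$F, ob$data_term, ob$cnn_score, ob$tv_term,
                              rc$step_size, TRUE)
    } else {
      tau_try <- min(rc$step_size, 2 * tau)
      accepted <- FALSE
      for (h in 0:20) {
        x_new <- x - tau_try * g
        if (rc$nonnegativity) x_new <- pmax(x_new, 0)
        ob_new <- objective(x_new, y, model, tv, rc)
        if (is.finite(ob_new$F) && ob_new$F <= ob$F) {
          accepted <- TRUE
          break
        }
        tau_try <- tau_try / 2
      }
      if (accepted) {
        x <- x_new; ob <- ob_new; tau <- tau_try
        trace[it + 1, ] <- list(it, ob$F, ob$data_term, ob$cnn_score,
                                ob$tv_term, tau_try, TRUE)
      } else {
        # step underflow: keep the current iterate, note it, carry on
        warning(sprintf("no decreasing step found at iteration %d", it),
                call. = FALSE)
        trace[it + 1, ] <- list(it, ob$F, ob$data_term, ob$cnn_score,
                                ob$tv_term, tau_try, FALSE)
      }
    }
  }
  structure(list(image = x, trace = trace, recon_config = rc, tv_config = tv,
                 geometry = geom),
            class = "tomo_recon")
}

#' @export
#' @method print tomo_recon
print.tomo_recon <- function(x, ...) {
  tr <- x$trace
  cat(sprintf(
    "Reconstruction: %d iterations, F %.6g -> %.6g, CNN score %.4g -> %.4g\n",
    nrow(tr) - 1L, tr$F[1], tr$F[nrow(tr)], tr$cnn_score[1],
    tr$cnn_score[nrow(tr)]))
  invisible(x)
}
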