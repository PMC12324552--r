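# High-level fitting protocol. The EM objective for the full input-driven
# model has local optima in which the sensory transition kernels are
# absorbed into state baselines or emission blocks. The protocol here
# fits the nested sensory-free-transition (HMM) model first, then
# restarts the transition kernels from a small dictionary of smooth
# trend-detector patterns, and arbitrates between the converged candidates
# on a held-out validation split of tracks, where the spurious optima
# lose their in-sample advantage.

#' Fit a model with multiple starts, keeping the best
#'
#' For single-state and sensory-free-transition families this runs
#' [em_fit()] from `n_starts` perturbed initializations and keeps the
#' highest training log-likelihood. For the full input-driven family it
#' applies the two-stage protocol: an HMM pre-fit, transition-kernel
#' restarts from a +/- trend-pattern dictionary, candidate selection on a
#' held-out fraction of tracks (falling back to training likelihood when
#' too few tracks), and a final continuation on all tracks.
#'
#' @param dataset a `stapaw_dataset`.
#' @param spec a [model_spec()].
#' @param n_starts number of initializations / kernel-dictionary
#'   candidates (default 3).
#' @param seed master seed.
#' @param max_iters EM iteration cap per stage.
#' @param select `"validation"` (default) or `"train"`; how candidates
#'   are compared for the input-driven family.
#' @param val_frac fraction of tracks held out for candidate selection.
#' @param ... further arguments to [em_fit()].
#' @return the selected `stapaw_fit`.
#' @export
stapaw_fit <- function(dataset, spec, n_starts = 3, seed = 0,
                       max_iters = 100, select = c("validation", "train"),
                       val_frac = 0.2, ...) {
  select <- match.arg(select)
  if (!(spec$family == "stapaw" && spec$Z > 1)) {
    seeds <- vapply(seq_len(n_starts), function(k)
      sub_seed(seed, 300L + k) %% 100003L, numeric(1))
    inits <- stapaw_inits(dataset, spec, seeds)
    best <- NULL
    for (k in seq_along(inits)) {
      fit <- em_fit(dataset, spec, init = inits[[k]], seed = seeds[k],
                    max_iters = max_iters, ...)
      ll <- utils::tail(fit$loglik_history, 1)
      if (is.null(best) || ll > best$ll) best <- list(fit = fit, ll = ll)
    }
    return(best$fit)
  }

  n_tracks <- length(dataset$tracks)
  use_val <- select == "validation" && n_tracks >= 5
  if (use_val) {
    n_val <- max(1L, round(val_frac * n_tracks))
    val_idx <- with_seed(sub_seed(seed, 41L),
                         sample(n_tracks, n_val))
    train <- stapaw_dataset(dataset$tracks[-val_idx])
    val <- stapaw_dataset(dataset$tracks[val_idx])
  } else {
    train <- dataset
    val <- NULL
  }

  # stage 1: sensory-free transitions
  hspec <- model_spec("hmm", Z = spec$Z, n_basis = spec$n_basis,
                      n_lag = spec$n_lag, opto = spec$opto)
  hinit <- stapaw_init(train, hspec, seed = seed)
  hfit <- em_fit(train, hspec, init = hinit, seed = seed,
                 max_iters = max_iters, ...)

  # stage 2: kernel-dictionary restarts
  basis <- hfit$params$basis
  patt <- trend_pattern(basis)
  Z <- spec$Z
  nb <- basis$n_basis
  variants <- seq_len(max(2L, min(n_starts, 4L)))
  best <- NULL
  for (v in variants) {
    q0 <- hfit$params
    q0 <- with_seed(sub_seed(seed, 500L + v), {
      for (i in seq_len(Z)) for (j in seq_len(Z)) if (i != j) {
        sgn <- if (i < j) 1 else -1
        q0$transition$kernels[[i]][[j]] <- switch(
          as.character(v %% 4L),
          "1" = -20 * sgn * patt,
          "2" = 20 * sgn * patt,
          "3" = 8 * stats::rnorm(nb),
          "0" = rep(0, nb)) + 0.1 * stats::rnorm(nb)
        if (spec$opto && !is.null(q0$transition$opto))
          q0$transition$opto[[i]][[j]] <- 0.5 * stats::rnorm(nb)
      }
      q0
    })
    fit <- em_fit(train, spec, init = q0, seed = seed,
                  max_iters = max_iters, ...)
    score <- if (use_val) test_loglik(fit$params, val)
             else utils::tail(fit$loglik_history, 1)
    if (is.null(best) || score > best$score)
      best <- list(fit = fit, score = score)
  }

  # continuation on all tracks, run to convergence
  if (use_val) {
    em_fit(dataset, spec, init = best$fit$params, seed = seed,
           max_iters = max_iters, ...)
  } else {
    best$fit
  }
}
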