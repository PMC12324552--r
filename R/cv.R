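# Cross-validated model-class comparison: null / dPAW / HMM / staPAW with
# varying state counts, scored by held-out log-likelihood per unit time.

#' Held-out log-likelihood of fitted parameters
#'
#' @param params fitted `stapaw_params`.
#' @param dataset a `stapaw_dataset` (standardization constants from the
#'   training fit are reused).
#' @return total log-likelihood over the dataset.
#' @export
test_loglik <- function(params, dataset) {
  sum(vapply(dataset$tracks,
             function(tr) forward_backward(params, tr)$loglik, numeric(1)))
}

#' Cross-validate a list of model specifications
#'
#' Splits tracks (never steps within a track) into folds; for each spec
#' and fold runs several EM initializations on the training tracks, keeps
#' the one with the highest training log-likelihood, and scores it on the
#' held-out tracks. Test log-likelihoods are reported per second of data,
#' and as differences from the mean of the null model (when a null spec is
#' included).
#'
#' @param dataset a `stapaw_dataset`.
#' @param specs named list of [model_spec()] objects.
#' @param n_folds number of folds (default 3).
#' @param n_inits EM initializations per fold (default 5).
#' @param seed master seed; folds and initializations derive from it.
#' @param max_iters EM iteration cap per fit.
#' @return data frame with one row per spec x fold: `spec`, `fold`,
#'   `train_ll`, `test_ll`, `test_ll_per_s`, `delta_vs_null`.
#' @export
cross_validate <- function(dataset, specs, n_folds = 3, n_inits = 5,
                           seed = 0, max_iters = 40) {
  n_tracks <- length(dataset$tracks)
  if (n_tracks < n_folds)
    stop("fewer tracks than folds", call. = FALSE)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s)
      paste0(s$family, if (s$Z > 1) s$Z else ""), character(1))
  fold_of <- with_seed(sub_seed(seed, 7L),
                       sample(rep(seq_len(n_folds), length.out = n_tracks)))
  rows <- list()
  for (sname in names(specs)) {
    spec <- specs[[sname]]
    for (f in seq_len(n_folds)) {
      if (n_folds == 1) {
        train_tracks <- dataset$tracks
        test_tracks <- dataset$tracks
      } else {
        train_tracks <- dataset$tracks[fold_of != f]
        test_tracks <- dataset$tracks[fold_of == f]
      }
      train <- stapaw_dataset(train_tracks)
      test <- stapaw_dataset(test_tracks)
      fit <- stapaw_fit(train, spec, n_starts = n_inits,
                        seed = sub_seed(seed, 100L + 17L * f) %% 100003L,
                        max_iters = max_iters, select = "train")
      best <- list(fit = fit,
                   ll = utils::tail(fit$loglik_history, 1))
      tll <- test_loglik(best$fit$params, test)
      test_time <- dataset_steps(test) * dataset$dt
      rows[[length(rows) + 1]] <- data.frame(
        spec = sname, fold = f, train_ll = best$ll, test_ll = tll,
        test_ll_per_s = tll / test_time, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  null_rows <- out$spec[vapply(out$spec, function(s)
    specs[[s]]$family == "null", logical(1))]
  if (length(null_rows) > 0) {
    null_mean <- mean(out$test_ll_per_s[out$spec %in% null_rows])
    out$delta_vs_null <- out$test_ll_per_s - null_mean
  } else {
    out$delta_vs_null <- NA_real_
  }
  out
}
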