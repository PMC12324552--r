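# Parameter containers for the state-dependent pirouette-and-weathervane
# (staPAW) model, plus JSON (de)serialization.
#
# A model with Z latent states has, per state, an emission block (turn
# decision, heading-change densities, speed densities) and, between states,
# an input-driven transition block. Sensory inputs C and dCp are z-scored
# with dataset constants stored on the parameter object so that fitting and
# simulation agree.

#' Per-state emission parameters
#'
#' @param M maximum turn probability in (0, 1].
#' @param m minimum turn probability in [0, 1), m <= M.
#' @param alpha uniform-mixture weight of the turn heading density, [0, 1].
#' @param kappa_turn concentration of the turn von Mises (mean pi), > 0.
#' @param kappa_wv concentration of the weathervane von Mises, > 0.
#' @param k_C turn-decision kernel coefficients on concentration history.
#' @param k_h turn-decision kernel coefficients on |dtheta| history.
#' @param k_dCp steering kernel coefficients on dCp history (the
#'   weathervane mean is minus the filtered dCp history).
#' @param gamma_turn,gamma_run Gamma (shape, scale) for step displacement
#'   under the turn and weathervane strategies.
#' @param k_O optional turn-decision kernel on the stimulus history.
#' @return an object of class `stapaw_emission`.
#' @export
emission_params <- function(M, m, alpha, kappa_turn, kappa_wv,
                            k_C, k_h, k_dCp,
                            gamma_turn, gamma_run, k_O = NULL) {
  stopifnot(M > 0, M <= 1, m >= 0, m <= M,
            alpha >= 0, alpha <= 1, kappa_turn > 0, kappa_wv > 0,
            all(gamma_turn > 0), all(gamma_run > 0),
            length(gamma_turn) == 2, length(gamma_run) == 2)
  structure(list(M = M, m = m, alpha = alpha,
                 kappa_turn = kappa_turn, kappa_wv = kappa_wv,
                 k_C = as.numeric(k_C), k_h = as.numeric(k_h),
                 k_dCp = as.numeric(k_dCp),
                 gamma_turn = as.numeric(gamma_turn),
                 gamma_run = as.numeric(gamma_run),
                 k_O = if (is.null(k_O)) NULL else as.numeric(k_O)),
            class = "stapaw_emission")
}

#' Input-driven transition parameters
#'
#' Row i of the per-step transition matrix is the softmax of logits
#' `K[i][j] . C_history` off the diagonal and `baseline[i]` on the diagonal
#' (plus optional stimulus kernels `O[i][j] . I_history`).
#'
#' @param Z number of states.
#' @param baseline length-Z self-transition logit bonuses.
#' @param kernels Z x Z list-matrix of coefficient vectors (entries on the
#'   diagonal are ignored); NULL for a 1-state model.
#' @param opto optional Z x Z list-matrix of stimulus kernels.
#' @return an object of class `stapaw_transition`.
#' @export
transition_params <- function(Z, baseline, kernels = NULL, opto = NULL) {
  stopifnot(Z >= 1, length(baseline) == Z)
  structure(list(Z = Z, baseline = as.numeric(baseline),
                 kernels = kernels, opto = opto),
            class = "stapaw_transition")
}

#' Full staPAW parameter set
#'
#' @param Z number of latent states (Z = 1 is the stateless dPAW model).
#' @param dt seconds per step.
#' @param basis a [stapaw_basis()] shared by all kernels.
#' @param emissions list of Z [emission_params()] objects.
#' @param transition a [transition_params()] object.
#' @param init_dist initial state distribution (length Z, sums to 1).
#' @param standardize list with `C` and `dCp` entries, each `c(mean, sd)`;
#'   inputs are z-scored with these constants before kernels apply.
#' @return an object of class `stapaw_params`.
#' @export
stapaw_params <- function(Z, dt, basis, emissions, transition,
                          init_dist = rep(1 / Z, Z),
                          standardize = list(C = c(mean = 0, sd = 1),
                                             dCp = c(mean = 0, sd = 1))) {
  stopifnot(Z >= 1, length(emissions) == Z, dt > 0,
            length(init_dist) == Z, abs(sum(init_dist) - 1) < 1e-8)
  structure(list(Z = as.integer(Z), dt = dt, basis = basis,
                 emissions = emissions, transition = transition,
                 init_dist = as.numeric(init_dist),
                 standardize = standardize),
            class = "stapaw_params")
}

has_opto <- function(params) {
  !is.null(params$emissions[[1]]$k_O) || !is.null(params$transition$opto)
}

#' @export
print.stapaw_params <- function(x, ...) {
  cat(sprintf(
    "<stapaw parameters: %d state(s), %d-lag/%d-basis kernels%s>\n",
    x$Z, x$basis$n_lag, x$basis$n_basis,
    if (has_opto(x)) ", with stimulus kernels" else ""))
  for (z in seq_len(x$Z)) {
    e <- x$emissions[[z]]
    cat(sprintf(
      "  state %d: turn prob in [%.3f, %.3f], alpha %.2f, kappa (tr %.2f, wv %.2f), speed means (turn %.4g, run %.4g)\n",
      z, e$m, e$M, e$alpha, e$kappa_turn, e$kappa_wv,
      e$gamma_turn[1] * e$gamma_turn[2], e$gamma_run[1] * e$gamma_run[2]))
  }
  invisible(x)
}

#' Serialize parameters to JSON
#'
#' Versioned schema carrying the basis definition, standardization
#' constants and all kernels; round-trips through
#' [read_stapaw_params()] bit-stably for the realized lag weights.
#'
#' @param params a `stapaw_params` object.
#' @param path output file.
#' @export
write_stapaw_params <- function(params, path) {
  doc <- list(
    schema = "stapaw-params-v1",
    Z = params$Z, dt = params$dt,
    basis = list(n_basis = params$basis$n_basis, n_lag = params$basis$n_lag),
    init_dist = params$init_dist,
    standardize = params$standardize,
    emissions = lapply(params$emissions, unclass),
    transition = list(
      Z = params$transition$Z,
      baseline = params$transition$baseline,
      kernels = params$transition$kernels,
      opto = params$transition$opto))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read parameters from JSON
#' @param path file written by [write_stapaw_params()].
#' @return a `stapaw_params` object.
#' @export
read_stapaw_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  sca <- function(x) as.numeric(x[[1]] %||% x)
  basis <- stapaw_basis(sca(doc$basis$n_basis), sca(doc$basis$n_lag))
  Z <- as.integer(sca(doc$Z))
  fix_kernels <- function(k) {
    if (is.null(k)) return(NULL)
    lapply(seq_len(Z), function(i)
      lapply(seq_len(Z), function(j) num(k[[i]][[j]])))
  }
  emissions <- lapply(doc$emissions, function(e)
    emission_params(M = sca(e$M), m = sca(e$m), alpha = sca(e$alpha),
                    kappa_turn = sca(e$kappa_turn),
                    kappa_wv = sca(e$kappa_wv),
                    k_C = num(e$k_C), k_h = num(e$k_h),
                    k_dCp = num(e$k_dCp),
                    gamma_turn = num(e$gamma_turn),
                    gamma_run = num(e$gamma_run),
                    k_O = num(e$k_O)))
  trans <- transition_params(Z = Z,
                             baseline = num(doc$transition$baseline),
                             kernels = fix_kernels(doc$transition$kernels),
                             opto = fix_kernels(doc$transition$opto))
  std <- list(C = num(doc$standardize$C), dCp = num(doc$standardize$dCp))
  names(std$C) <- c("mean", "sd"); names(std$dCp) <- c("mean", "sd")
  stapaw_params(Z = Z, dt = sca(doc$dt), basis = basis,
                emissions = emissions, transition = trans,
                init_dist = num(doc$init_dist), standardize = std)
}
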