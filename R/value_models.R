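# Subjective-value discounting functions, the softmax choice rule, and the
# twelve-model catalog (3 discount shapes x {1,2} kappa x {1,2} beta).
#
# Offer coding follows the task convention: Shock is coded -5..-1 (the number
# of shocks of the work offer, negated), Effort as the level 1..5, and the
# rest offer has a fixed subjective value of -6 (six shocks, no effort).
# Discount rates kappa are negative: more negative means stronger devaluation
# of the shock reduction by the effort required.

REST_SV <- -6
SHAPES <- c("linear", "parabolic", "hyperbolic")

#' Specify one candidate effort-discounting model
#'
#' A model is identified by its discount shape (`linear`, `parabolic`,
#' `hyperbolic`) and by whether the discount rate `kappa` and the softmax
#' inverse-noise `beta` are shared between the self and other conditions
#' (`1k`/`1b`) or separate (`2k`/`2b`). Separate parameters use effect
#' coding: `kappa_other = kappa_self + kappa_effect`.
#'
#' @param name Canonical model name, e.g. `"parabolic_2k1b"`. Alternatively
#'   supply `shape`, `n_kappa`, `n_beta`.
#' @param shape Discount shape, one of `"linear"`, `"parabolic"`,
#'   `"hyperbolic"`.
#' @param n_kappa,n_beta 1 (shared across recipients) or 2 (separate).
#' @return An object of class `ep_model_spec`.
#' @examples
#' model_spec("parabolic_2k1b")
#' model_spec(shape = "linear", n_kappa = 1, n_beta = 2)
#' @export
model_spec <- function(name = NULL, shape = NULL, n_kappa = 1, n_beta = 1) {
  if (!is.null(name)) {
    abort_if(!is.character(name) || length(name) != 1L,
             "model name must be a single string")
    m <- regmatches(name, regexec("^(linear|parabolic|hyperbolic)_([12])k([12])b$", name))[[1]]
    abort_if(length(m) == 0,
             "unknown model name '", name, "'; expected e.g. 'parabolic_2k1b'")
    shape <- m[2]
    n_kappa <- as.integer(m[3])
    n_beta <- as.integer(m[4])
  }
  shape <- match.arg(shape, SHAPES)
  abort_if(!n_kappa %in% 1:2 || !n_beta %in% 1:2,
           "n_kappa and n_beta must each be 1 or 2")
  structure(
    list(shape = shape,
         two_kappa = n_kappa == 2L,
         two_beta = n_beta == 2L,
         name = sprintf("%s_%dk%db", shape, n_kappa, n_beta)),
    class = "ep_model_spec")
}

#' @export
print.ep_model_spec <- function(x, ...) {
  cat("<ep_model_spec>", x$name, "\n")
  invisible(x)
}

#' All twelve candidate model names
#'
#' @return Character vector of the canonical names of the 3 x 2 x 2 model
#'   grid.
#' @export
model_catalog <- function() {
  as.vector(t(outer(SHAPES, c("1k1b", "2k1b", "1k2b", "2k2b"), paste, sep = "_")))
}

# number of distinct free parameter families; used for parsimony tie-breaks
n_param_families <- function(model) {
  2L + model$two_kappa + model$two_beta
}

#' Per-subject model parameters
#'
#' @param kappa_self Discount rate for the self condition, `<= 0`.
#' @param kappa_effect Additive self-to-other offset so that
#'   `kappa_other = kappa_self + kappa_effect`; `kappa_other` must also be
#'   `<= 0`. Default 0 (shared kappa).
#' @param beta_self Softmax inverse-noise for self, `> 0`.
#' @param beta_other Softmax inverse-noise for other; defaults to
#'   `beta_self` (shared beta).
#' @return An object of class `ep_parameter_set` with derived `kappa_other`.
#' @export
parameter_set <- function(kappa_self, kappa_effect = 0, beta_self,
                          beta_other = beta_self) {
  abort_if(!is.numeric(kappa_self) || kappa_self > 0,
           "kappa_self must be <= 0 (aversive-outcome coding)")
  kappa_other <- kappa_self + kappa_effect
  abort_if(kappa_other > 0, "kappa_other = kappa_self + kappa_effect must be <= 0")
  abort_if(beta_self < 0 || beta_other < 0, "beta must be positive")
  structure(
    list(kappa_self = kappa_self, kappa_effect = kappa_effect,
         kappa_other = kappa_other, beta_self = beta_self,
         beta_other = beta_other),
    class = "ep_parameter_set")
}

#' Subjective value of a work offer
#'
#' Computes `SV = Shock + kappa * Effort` (linear),
#' `SV = Shock + kappa * Effort^2` (parabolic) or
#' `SV = Shock * (1 / (1 + kappa * Effort))` (hyperbolic), with Shock coded
#' -5..-1 and Effort coded 1..5. With `kappa = 0` all shapes collapse to
#' `SV = Shock`. For the hyperbolic shape the denominator must stay
#' positive, which restricts `kappa > -1/5` over the effort grid.
#'
#' @param shape Discount shape (see [model_spec()]).
#' @param kappa Discount rate (`<= 0`); scalar or vector recycled with the
#'   offers.
#' @param shock Integer shock coding in -5..-1.
#' @param effort Integer effort level in 1..5.
#' @return Numeric vector of subjective values (shock units).
#' @examples
#' subjective_value("parabolic", -0.19, shock = -1, effort = 5) # -5.75
#' @export
subjective_value <- function(shape, kappa, shock, effort) {
  shape <- match.arg(shape, SHAPES)
  abort_if(any(!shock %in% -5:-1), "shock must be coded in -5..-1")
  abort_if(any(!effort %in% 1:5), "effort must be a level in 1..5")
  switch(shape,
    linear = shock + kappa * effort,
    parabolic = shock + kappa * effort^2,
    hyperbolic = {
      den <- 1 + kappa * effort
      abort_if(any(den <= 0),
               "hyperbolic denominator 1 + kappa*effort must be > 0 ",
               "(requires kappa > -1/5 over the effort grid)")
      shock / den
    })
}

#' Probability of choosing the work offer
#'
#' Two-option softmax (logistic) rule:
#' `p(work) = 1 / (1 + exp(-beta * (sv_work - sv_rest)))`.
#'
#' @param sv_work Subjective value of the work offer.
#' @param beta Inverse-noise parameter, `>= 0`; `beta = 0` is accepted as the
#'   pure-noise limit (p = 0.5).
#' @param sv_rest Subjective value of the rest offer (default -6).
#' @return Probability in (0, 1), overflow-safe.
#' @export
choice_probability <- function(sv_work, beta, sv_rest = REST_SV) {
  abort_if(any(beta < 0), "beta must be non-negative")
  plogis(beta * (sv_work - sv_rest))
}

#' Log-likelihood of observed choices at a fixed parameter point
#'
#' Evaluates, trial by trial, the log softmax probability of the observed
#' choice under a model specification and one subject's parameter set. The
#' recipient column selects which kappa/beta apply under the model's sharing
#' rules (a `1k` model ignores `kappa_effect`, a `1b` model ignores
#' `beta_other`). Non-response trials must be removed upstream.
#'
#' @param params An [parameter_set()] object.
#' @param trials Data frame with columns `recipient` (`"self"`/`"other"`),
#'   `effort_level`, `work_shocks` (1..5) and `choice` (`"work"`/`"rest"`).
#' @param model An [model_spec()] object.
#' @return Numeric vector of per-trial log-probabilities.
#' @export
trial_loglik <- function(params, trials, model) {
  abort_if(!inherits(params, "ep_parameter_set"), "params must be a parameter_set")
  abort_if(!inherits(model, "ep_model_spec"), "model must be a model_spec")
  need <- c("recipient", "effort_level", "work_shocks", "choice")
  abort_if(!all(need %in% names(trials)),
           "trials must have columns: ", paste(need, collapse = ", "))
  abort_if(!all(trials$choice %in% c("work", "rest")),
           "choice must be 'work' or 'rest' (exclude non-responses upstream)")
  other <- trials$recipient == "other"
  kappa <- ifelse(other & model$two_kappa, params$kappa_other, params$kappa_self)
  beta <- ifelse(other & model$two_beta, params$beta_other, params$beta_self)
  sv <- subjective_value(model$shape, kappa, -trials$work_shocks,
                         trials$effort_level)
  p_work <- choice_probability(sv, beta)
  ifelse(trials$choice == "work", log(p_work), log1p(-p_work))
}

#' Dataset log-likelihood
#'
#' Sum of [trial_loglik()] over all trials of one subject.
#'
#' @inheritParams trial_loglik
#' @return Scalar log-likelihood.
#' @export
dataset_loglik <- function(params, trials, model) {
  sum(trial_loglik(params, trials, model))
}
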