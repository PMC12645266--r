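# Model ranking by PSIS-LOO (Pareto-smoothed importance sampling
# leave-one-out cross-validation) and per-subject best-model attribution.
# Lower LOOIC (= -2 * elpd_loo) indicates better expected out-of-sample
# prediction.

# Generalized Pareto fit (Zhang & Stephens 2009 profile-posterior method)
# to exceedances x > 0, with the small-sample shape regularization used by
# modern LOO implementations.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_adj <- 10
  m <- 30 + floor(sqrt(n))
  jhalf <- seq_len(m) - 0.5
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  # saturated log-likelihoods tie at the cutoff and zero the lower quartile;
  # fall back to the smallest positive exceedance to keep the grid finite
  if (xstar <= 0) xstar <- min(x[x > 0])
  theta <- 1 / x[n] + (1 - sqrt(m / jhalf)) / (3 * xstar)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  k <- (n * k + prior_adj * 0.5) / (n + prior_adj)  # weakly-informative pull
  sigma <- k / theta_hat
  list(k = k, sigma = sigma)
}

qgpd <- function(p, mu, sigma, k) {
  if (abs(k) < 1e-12) mu + sigma * (-log1p(-p))
  else mu + sigma * ((1 - p)^(-k) - 1) / k
}

# Pareto-smooth one vector of log importance ratios; returns the smoothed
# log weights (unnormalized) and the tail shape estimate.
psis_smooth <- function(lr) {
  s <- length(lr)
  lr <- lr - max(lr)
  tail_len <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  if (tail_len < 5) return(list(lw = lr, k = NA_real_))
  ord <- order(lr)
  tail_ids <- ord[(s - tail_len + 1):s]
  cutoff_lw <- lr[ord[s - tail_len]]
  exceed <- exp(lr[tail_ids]) - exp(cutoff_lw)
  if (all(exceed == 0)) return(list(lw = lr, k = NA_real_))
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k) || !is.finite(fit$sigma) || fit$sigma <= 0) {
    return(list(lw = lr, k = NA_real_))
  }
  p <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- log(qgpd(p, exp(cutoff_lw), fit$sigma, fit$k))
  lr[tail_ids[order(lr[tail_ids])]] <- pmin(smoothed, 0)  # cap at raw max
  list(lw = lr, k = fit$k)
}

#' PSIS-LOO estimate of out-of-sample predictive accuracy
#'
#' Computes, for each observation, the Pareto-smoothed importance-sampling
#' estimate of its leave-one-out log predictive density from a matrix of
#' pointwise posterior log-likelihoods, and aggregates to
#' `elpd_loo` and `LOOIC = -2 * elpd_loo`. The upper tail of each
#' observation's importance ratios is smoothed by a fitted generalized
#' Pareto distribution; tail-shape diagnostics `k > 0.7` trigger a warning
#' (not an error).
#'
#' @param pointwise_ll Matrix of log-likelihoods, draws x observations
#'   (finite; >= 100 draws).
#' @return An object of class `ep_loo`: `elpd_loo`, `se_elpd`, `looic`,
#'   `se_looic`, per-observation `pointwise` (elpd contributions) and
#'   `pareto_k`.
#' @export
psis_loo <- function(pointwise_ll) {
  abort_if(!is.matrix(pointwise_ll) || !all(is.finite(pointwise_ll)),
           "pointwise_ll must be a finite draws x observations matrix")
  s <- nrow(pointwise_ll)
  abort_if(s < 100, "need at least 100 posterior draws for PSIS-LOO")
  n <- ncol(pointwise_ll)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  for (i in seq_len(n)) {
    ll <- pointwise_ll[, i]
    sm <- psis_smooth(-ll)          # log importance ratios: -loglik
    lw <- sm$lw - log_sum_exp(sm$lw)  # normalized log weights
    elpd_i[i] <- log_sum_exp(lw + ll)
    k_i[i] <- sm$k %||% NA_real_
  }
  n_bad <- sum(k_i > 0.7, na.rm = TRUE)
  if (n_bad > 0) {
    warning(n_bad, " observation(s) with Pareto k > 0.7; ",
            "PSIS-LOO estimates may be unstable", call. = FALSE)
  }
  elpd <- sum(elpd_i)
  se <- sqrt(n * var(elpd_i))
  structure(
    list(elpd_loo = elpd, se_elpd = se, looic = -2 * elpd, se_looic = 2 * se,
         pointwise = elpd_i, pareto_k = k_i, n_obs = n, n_draws = s),
    class = "ep_loo")
}

#' @export
print.ep_loo <- function(x, ...) {
  cat(sprintf("<ep_loo> elpd_loo = %.1f (SE %.1f), LOOIC = %.1f\n",
              x$elpd_loo, x$se_elpd, x$looic))
  invisible(x)
}

same_trial_sets <- function(fits) {
  ref <- fits[[1]]$trials
  key <- function(tr) paste(tr$subject_id, tr$trial %||% seq_len(nrow(tr)),
                            sep = ":")
  all(vapply(fits[-1], function(f) {
    identical(sort(key(f$trials)), sort(key(ref)))
  }, logical(1)))
}

#' Compare fitted models by group and per-subject LOOIC
#'
#' Ranks fits by group-level LOOIC and attributes to each subject the model
#' minimizing that subject's LOOIC contribution (the sum of the subject's
#' pointwise terms from the joint hierarchical fit). Attribution ties go to
#' the model with fewer parameter families. When the top two models differ
#' by less than one standard error of their pointwise difference, the table
#' carries a parsimony note.
#'
#' @param fits List of `ep_fit` objects fitted to identical retained trial
#'   sets.
#' @return An object of class `ep_comparison`: `table` (model, looic, se,
#'   delta vs. best, se_diff), `subject_looic` (subjects x models),
#'   `best_model_per_subject`, `shares`, and `note`.
#' @export
compare_models <- function(fits) {
  abort_if(!is.list(fits) || length(fits) < 1 ||
             !all(vapply(fits, inherits, logical(1), "ep_fit")),
           "fits must be a non-empty list of ep_fit objects")
  names(fits) <- vapply(fits, function(f) f$model$name, character(1))
  abort_if(anyDuplicated(names(fits)) > 0, "duplicate model names in fits")
  abort_if(length(fits) > 1 && !same_trial_sets(fits),
           "fits were computed on different trial sets; refusing to compare")

  loos <- lapply(fits, function(f) psis_loo(f$pointwise_ll))
  looic <- vapply(loos, `[[`, numeric(1), "looic")
  se <- vapply(loos, `[[`, numeric(1), "se_looic")

  # per-subject LOOIC from the pointwise contributions of the joint fit
  subj_ids <- fits[[1]]$subject_ids
  subject_looic <- sapply(names(fits), function(nm) {
    f <- fits[[nm]]
    contrib <- tapply(loos[[nm]]$pointwise, f$trials$subject_id, sum)
    -2 * as.numeric(contrib[as.character(subj_ids)])
  })
  subject_looic <- matrix(subject_looic, nrow = length(subj_ids),
                          dimnames = list(subj_ids, names(fits)))

  nfam <- vapply(fits, function(f) n_param_families(f$model), numeric(1))
  best <- apply(subject_looic, 1, function(row) {
    cand <- which(row <= min(row) + 1e-9)
    cand[which.min(nfam[cand])]      # parsimony tie-break
  })
  best_names <- colnames(subject_looic)[best]
  shares <- table(factor(best_names, levels = names(fits))) /
    length(best_names)

  ord <- order(looic)
  tab <- data.frame(model = names(fits)[ord], looic = looic[ord],
                    se = se[ord], row.names = NULL)
  tab$delta_looic <- tab$looic - tab$looic[1]

  note <- NULL
  if (length(fits) > 1) {
    top2 <- names(fits)[ord[1:2]]
    pd <- -2 * (loos[[top2[1]]]$pointwise - loos[[top2[2]]]$pointwise)
    se_diff <- sqrt(length(pd) * var(pd))
    tab$se_diff_vs_best <- NA_real_
    tab$se_diff_vs_best[2] <- se_diff
    if (abs(diff(looic[ord[1:2]])) <= se_diff + 1e-12) {
      note <- paste0(
        "top models '", top2[1], "' and '", top2[2], "' differ by less than ",
        "one SE of their difference; parsimony favours the one with fewer ",
        "parameters (", top2[which.min(nfam[top2])], ")")
    }
  }

  structure(
    list(table = tab, loos = loos, subject_looic = subject_looic,
         best_model_per_subject = setNames(best_names, subj_ids),
         shares = shares, note = note),
    class = "ep_comparison")
}

#' @export
print.ep_comparison <- function(x, ...) {
  cat("<ep_comparison>\n")
  print(x$table, digits = 5)
  cat("best-model shares:\n")
  print(round(x$shares, 3))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Best-model attribution shares across subjects
#'
#' @param comparison An `ep_comparison` from [compare_models()].
#' @return Named numeric vector: for each model, the share of subjects for
#'   whom it has the lowest subject-level LOOIC (ties to the more
#'   parsimonious model). Shares sum to 1.
#' @export
per_subject_best_model <- function(comparison) {
  abort_if(!inherits(comparison, "ep_comparison"),
           "comparison must come from compare_models()")
  p <- as.numeric(comparison$shares)
  setNames(p, names(comparison$shares))
}
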