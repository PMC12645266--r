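# Descriptive behavioural summaries and default-prior Bayes factors.
#
# BF01 is the Bayes factor for the null over the alternative: BF01 > 1
# favours the null. The paired test uses the JZS (Jeffreys-Zellner-Siow)
# construction: a Cauchy prior on the standardized effect (default r scale
# 0.707); the correlation test uses a uniform (stretched-beta, width 1)
# prior on rho.

#' Per-subject, per-recipient behavioural summary
#'
#' Computes, for every subject x recipient: the work-choice rate (fraction
#' of responded trials choosing work), mean response time, mean force
#' area-under-curve (work trials only) and success rate (work trials only),
#' plus non-response counts. Group means/SDs are computed across subjects.
#' A subject-condition with no responded trials is flagged rather than
#' propagating NaN.
#'
#' @param data Trial-level data frame with the [simulate_dataset()] schema.
#' @return An object of class `ep_behavior`: `per_subject` (one row per
#'   subject x recipient), `group` (mean/SD per recipient per measure) and
#'   `flagged` (subject-conditions with no responded trials).
#' @export
summarize_behavior <- function(data) {
  validate_dataset(data)
  combos <- expand.grid(subject_id = sort(unique(data$subject_id)),
                        recipient = c("self", "other"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- data[data$subject_id == combos$subject_id[i] &
                  data$recipient == combos$recipient[i], , drop = FALSE]
    resp <- sub[sub$choice != "nonresponse", , drop = FALSE]
    work <- resp[resp$choice == "work", , drop = FALSE]
    data.frame(
      subject_id = combos$subject_id[i],
      recipient = combos$recipient[i],
      n_trials = nrow(sub),
      n_nonresponse = sum(sub$choice == "nonresponse"),
      work_choice_rate = if (nrow(resp)) mean(resp$choice == "work") else NA_real_,
      mean_rt_s = if (nrow(resp)) mean(resp$rt_s, na.rm = TRUE) else NA_real_,
      mean_force_auc = if (nrow(work)) mean(work$force_auc, na.rm = TRUE) else NA_real_,
      success_rate = if (nrow(work)) mean(work$success, na.rm = TRUE) else NA_real_)
  })
  per_subject <- do.call(rbind, rows)
  flagged <- per_subject[per_subject$n_trials > 0 &
                           per_subject$n_trials == per_subject$n_nonresponse,
                         c("subject_id", "recipient")]

  measures <- c("work_choice_rate", "mean_rt_s", "mean_force_auc",
                "success_rate")
  group <- do.call(rbind, lapply(c("self", "other"), function(rec) {
    sub <- per_subject[per_subject$recipient == rec, ]
    data.frame(recipient = rec,
               measure = measures,
               mean = vapply(measures, function(m) mean(sub[[m]], na.rm = TRUE),
                             numeric(1)),
               sd = vapply(measures, function(m) sd(sub[[m]], na.rm = TRUE),
                           numeric(1)),
               row.names = NULL)
  }))
  structure(list(per_subject = per_subject, group = group, flagged = flagged),
            class = "ep_behavior")
}

#' @export
print.ep_behavior <- function(x, ...) {
  cat("<ep_behavior>\n")
  print(x$group, digits = 3, row.names = FALSE)
  if (nrow(x$flagged)) {
    cat("flagged (all non-response):",
        paste(x$flagged$subject_id, x$flagged$recipient, collapse = "; "), "\n")
  }
  invisible(x)
}

# JZS marginal likelihood ratio via the g-prior integral
# (Rouder et al. construction: effect-size prior Cauchy(0, rscale) is an
# inverse-gamma(1/2, rscale^2/2) mixture of normals over g).
jzs_bf10 <- function(t, n, rscale) {
  nu <- n - 1
  null_dens <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (rscale^2 / 2)^(1 / 2) / gamma(1 / 2) *
      g^(-3 / 2) * exp(-rscale^2 / (2 * g))
  }
  alt_dens <- integrate(integrand, 0, Inf, rel.tol = 1e-8,
                        abs.tol = 0)$value
  alt_dens / null_dens
}

#' Default-prior (JZS) Bayesian paired t-test
#'
#' One-sample JZS Bayes factor on the paired differences `x - y`, with a
#' Cauchy prior of width `rscale` (default 0.707) on the standardized effect
#' under the alternative. Returns BF01 = 1/BF10, so BF01 > 1 favours the
#' null hypothesis of no difference.
#'
#' @param x,y Paired numeric vectors (same length, n >= 3).
#' @param rscale Cauchy prior scale (default `sqrt(2)/2` = 0.707).
#' @return List: `bf01`, `bf10`, `t`, `df`, `n`, `category` (see
#'   [bf_category()]).
#' @export
jzs_paired_bf <- function(x, y, rscale = 0.707) {
  abort_if(length(x) != length(y), "x and y must be paired (equal length)")
  d <- x - y
  d <- d[is.finite(d)]
  n <- length(d)
  abort_if(n < 3, "need at least 3 complete pairs")
  if (n < 5) warning("fewer than 5 pairs; Bayes factor is fragile",
                     call. = FALSE)
  sd_d <- sd(d)
  t <- if (sd_d == 0) 0 else mean(d) / (sd_d / sqrt(n))
  bf10 <- jzs_bf10(t, n, rscale)
  list(bf01 = 1 / bf10, bf10 = bf10, t = t, df = n - 1, n = n,
       category = bf_category(1 / bf10))
}

# Gauss hypergeometric 2F1(a, b; c; x) by series; converges for |x| < 1 and,
# when c - a - b > 0, at x = 1 as well (always the case here: c - a - b =
# n - 3/2 with n >= 4).
hyp2f1 <- function(a, b, cc, x, max_terms = 5000, tol = 1e-12) {
  term <- 1
  total <- 1
  for (k in 0:(max_terms - 1)) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * x
    total <- total + term
    if (abs(term) < tol * abs(total)) break
  }
  total
}

# exact sampling density of the Pearson correlation r given rho (Fisher)
r_density <- function(r, rho, n) {
  lg <- lgamma(n - 1) - lgamma(n - 0.5)
  (n - 2) * exp(lg) * (1 - rho^2)^((n - 1) / 2) *
    (1 - r^2)^((n - 4) / 2) / (sqrt(2 * pi) * (1 - rho * r)^(n - 1.5)) *
    hyp2f1(0.5, 0.5, (2 * n - 1) / 2, (rho * r + 1) / 2)
}

# r_density with the rho-free factor (1 - r^2)^((n-4)/2) and constants
# stripped: numerically safe as |r| -> 1 because the factor cancels in the
# Bayes-factor ratio
r_kernel <- function(r, rho, n) {
  (1 - rho^2)^((n - 1) / 2) / (1 - rho * r)^(n - 1.5) *
    hyp2f1(0.5, 0.5, (2 * n - 1) / 2, (rho * r + 1) / 2)
}

#' Default-prior Bayesian Pearson correlation test
#'
#' Sample Pearson correlation plus the default Bayes factor contrasting
#' rho = 0 against a uniform prior on rho in (-1, 1) (the stretched-beta
#' prior with width 1), using the exact sampling distribution of r and
#' one-dimensional numerical integration.
#'
#' @param x,y Paired numeric vectors (n >= 4), neither constant.
#' @return List: `r`, `bf01`, `bf10`, `n`, `category`.
#' @export
pearson_bf <- function(x, y) {
  abort_if(length(x) != length(y), "x and y must be paired (equal length)")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  abort_if(n < 4, "need at least 4 complete pairs")
  abort_if(sd(x) == 0 || sd(y) == 0, "constant input has no defined correlation")
  r <- cor(x, y)
  if (1 - r^2 < 1e-12) {
    # degenerate perfect correlation: the alternative dominates entirely
    return(list(r = r, bf01 = 0, bf10 = Inf, n = n,
                category = "strong alternative"))
  }
  null_dens <- r_kernel(r, 0, n)
  alt_dens <- integrate(function(rho) {
    vapply(rho, function(p) r_kernel(r, p, n), numeric(1)) / 2
  }, -1, 1, rel.tol = 1e-8)$value
  bf10 <- alt_dens / null_dens
  list(r = r, bf01 = 1 / bf10, bf10 = bf10, n = n,
       category = bf_category(1 / bf10))
}

#' Evidence category of a BF01 value
#'
#' Interpretive bands: BF01 > 10 strong null, 3-10 moderate null, 0.1-0.3
#' moderate alternative, < 0.1 strong alternative, otherwise anecdotal.
#'
#' @param bf01 Bayes factor in favour of the null.
#' @return Character label.
#' @export
bf_category <- function(bf01) {
  abort_if(!is.numeric(bf01) || length(bf01) != 1 || bf01 < 0,
           "bf01 must be a single non-negative number")
  if (bf01 > 10) "strong null"
  else if (bf01 >= 3) "moderate null"
  else if (bf01 < 0.1) "strong alternative"
  else if (bf01 <= 0.3) "moderate alternative"
  else "anecdotal"
}
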