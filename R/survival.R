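## Survival analysis for baseline ctDNA stratification.
##
## Samples are split into three prognostic groups: plasma-undetectable
## (not_detected), and among detected samples high vs low ctDNA by a cut
## point on copies/mL plasma chosen with a maximally selected rank
## (standardized two-group log-rank) statistic. Groups are compared with
## Kaplan-Meier curves, log-rank tests and a univariate Cox
## proportional-hazards model (Breslow tie handling).
##
## The estimators are implemented here directly — the cut-point scan needs
## the standardized log-rank statistic internally — and are cross-checked
## in the test suite against the survival package.

check_surv <- function(time, event) {
  if (length(time) == 0) stop_input("no survival records")
  if (any(!is.finite(time)) || any(time < 0))
    stop_input("survival times must be finite and non-negative")
  if (!all(event %in% c(0, 1)))
    stop_input("event indicator must be 0 (censored) or 1 (death)")
}

#' Kaplan-Meier product-limit estimate
#'
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over distinct event
#' times. The median is the earliest time at which S(t) drops to 0.5 or
#' below (left-continuous convention when S sits exactly at 0.5), `NA` if
#' S never reaches 0.5.
#'
#' @param time follow-up times (days).
#' @param event 1 = event observed, 0 = censored.
#' @return object of class `km_curve`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `survival`, `median`, `n`, `n_events`.
#' @export
km_estimate <- function(time, event) {
  check_surv(time, event)
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0) {
    out <- list(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                survival = numeric(0), median = NA_real_,
                n = length(time), n_events = 0L)
    return(structure(out, class = "km_curve"))
  }
  ut <- sort(unique(time))
  cnt <- tabulate(match(time, ut), nbins = length(ut))
  at_risk_all <- rev(cumsum(rev(cnt)))          # n at risk at each unique time
  pos <- match(et, ut)
  n_risk <- at_risk_all[pos]
  dcnt <- tabulate(match(time[event == 1], ut), nbins = length(ut))
  n_event <- dcnt[pos]
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) et[which(surv <= 0.5)[1]] else NA_real_
  structure(list(time = et, n_risk = n_risk, n_event = n_event,
                 survival = surv, median = med, n = length(time),
                 n_events = sum(event)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else
                format(x$median, digits = 6)))
  invisible(x)
}

#' @export
summary.km_curve <- function(object, ...) {
  data.frame(time = object$time, n_risk = object$n_risk,
             n_event = object$n_event, survival = object$survival)
}

#' @export
plot.km_curve <- function(x, xlab = "Days", ylab = "Survival probability",
                          col = 1, add = FALSE, ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-2 * length(x$survival)])
  if (!add)
    graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab,
                   ylab = ylab, col = col, ...)
  else graphics::lines(tt, ss, col = col, ...)
  invisible(x)
}

## Log-rank machinery shared by the k-group test and the maxstat scan.
## Vectorized over event times via reverse cumulative risk-set counts.
logrank_core <- function(time, event, group) {
  glev <- sort(unique(group))
  k <- length(glev)
  ut <- sort(unique(time))
  J <- length(ut)
  pos_all <- match(time, ut)
  at_risk <- function(sel) {
    cnt <- tabulate(pos_all[sel], nbins = J)
    rev(cumsum(rev(cnt)))
  }
  n_j <- at_risk(rep(TRUE, length(time)))
  N_g <- matrix(vapply(glev, function(g) at_risk(group == g), numeric(J)),
                nrow = J)
  d_j <- tabulate(pos_all[event == 1], nbins = J)
  D_g <- matrix(vapply(glev, function(g)
    tabulate(pos_all[event == 1 & group == g], nbins = J), numeric(J)),
    nrow = J)
  keep <- d_j > 0
  n_j <- n_j[keep]; d_j <- d_j[keep]
  P <- N_g[keep, , drop = FALSE] / n_j           # J' x k risk fractions
  D <- D_g[keep, , drop = FALSE]
  E <- P * d_j
  cvar <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  V <- diag(colSums(cvar * P), nrow = k) - crossprod(P, cvar * P)
  list(levels = glev, U = colSums(D - E), V = V, O = colSums(D))
}

#' Log-rank test for k groups
#'
#' Observed-minus-expected statistic over pooled event times with the
#' hypergeometric covariance; the chi-square uses k-1 groups (generalized
#' inverse degrees of freedom). For two groups the standardized statistic
#' \eqn{z = U_1/\sqrt{V_{11}}} is also returned.
#'
#' @param time,event survival data.
#' @param group group label per subject (>= 2 non-empty groups).
#' @return list: `chisq`, `df`, `p_value`, `z` (2 groups only), per-group
#'   observed/expected table.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  glev <- unique(group)
  if (length(glev) < 2) stop_input("log-rank test needs at least 2 groups")
  if (any(table(factor(group, levels = glev)) == 0))
    stop_input("every group must be non-empty")
  core <- logrank_core(time, event, group)
  k <- length(core$levels)
  U1 <- core$U[-k]
  V1 <- core$V[-k, -k, drop = FALSE]
  chisq <- if (all(abs(U1) < 1e-12)) 0 else {
    qr_v <- qr(V1)
    if (qr_v$rank < nrow(V1)) {
      as.numeric(U1 %*% MASS_ginv(V1) %*% U1)
    } else as.numeric(U1 %*% solve(V1, U1))
  }
  df <- k - 1
  z <- if (k == 2) {
    if (core$V[1, 1] > 0) unname(core$U[1]) / sqrt(core$V[1, 1]) else 0
  } else NA_real_
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       z = z,
       table = data.frame(group = core$levels, observed = core$O,
                          expected = core$O - core$U,
                          stringsAsFactors = FALSE))
}

## Moore-Penrose inverse via SVD (only needed for degenerate covariance).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Maximally selected log-rank cut point
#'
#' Scans every candidate cut point — midpoints between adjacent sorted
#' unique biomarker values that leave at least `min_group_fraction` of the
#' records on each side — and returns the one maximizing the absolute
#' standardized two-group log-rank statistic. The maximum is a selected
#' statistic; no small-sample p-value correction is applied, so it should
#' be read as a selection criterion, not a test.
#'
#' @param values biomarker values (e.g. ctDNA copies/mL), detected samples
#'   only.
#' @param time,event matching survival data.
#' @param min_group_fraction minimum fraction of records per side.
#' @return object of class `cutpoint_result`: `cutpoint`,
#'   `max_standardized_statistic`, `candidates_evaluated`,
#'   `min_group_fraction`, `reliable` (FALSE when the best statistic is
#'   numerically zero), and the candidate table.
#' @export
maxstat_cutpoint <- function(values, time, event, min_group_fraction = 0.1) {
  check_surv(time, event)
  if (length(values) != length(time))
    stop_input("values and survival data differ in length")
  if (length(values) < 10)
    stop_input("cut-point search needs at least 10 records")
  uv <- sort(unique(values))
  if (length(uv) < 2)
    stop_input("all biomarker values identical: no candidate cut point")
  mids <- (uv[-1] + uv[-length(uv)]) / 2
  n <- length(values)
  min_n <- min_group_fraction * n
  keep <- vapply(mids, function(m)
    sum(values <= m) >= min_n && sum(values > m) >= min_n, TRUE)
  mids <- mids[keep]
  if (length(mids) == 0)
    stop_input("no candidate split respects min_group_fraction = ",
               min_group_fraction)
  zs <- vapply(mids, function(m) {
    g <- ifelse(values > m, "high", "low")
    logrank_test(time, event, g)$z
  }, 0)
  best <- which.max(abs(zs))
  structure(list(cutpoint = mids[best],
                 max_standardized_statistic = abs(zs[best]),
                 z_signed = zs[best],
                 candidates_evaluated = length(mids),
                 min_group_fraction = min_group_fraction,
                 reliable = abs(zs[best]) > 1e-6,
                 candidates = data.frame(cutpoint = mids, z = zs)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "maximally selected cut point: %.4g (|z| = %.4f over %d candidates)%s\n",
    x$cutpoint, x$max_standardized_statistic, x$candidates_evaluated,
    if (!x$reliable) "  [unreliable: statistic ~ 0]" else ""))
  invisible(x)
}

#' Assign ctDNA prognostic groups
#'
#' `not_detected` when the sample has no detected variant; otherwise
#' `high` when the representative ctDNA level exceeds the cut point and
#' `low` at or below it (a sample exactly at the cut point is low).
#'
#' @param quants data frame with `sample_id`, `detected`,
#'   `ctdna_copies_per_ml` (representative per sample).
#' @param cutpoint copies/mL threshold (> 0).
#' @return named character vector sample_id -> group.
#' @export
stratify_ctdna <- function(quants, cutpoint) {
  if (cutpoint <= 0) stop_config("cutpoint must be positive")
  g <- ifelse(!quants$detected, "not_detected",
              ifelse(quants$ctdna_copies_per_ml > cutpoint, "high", "low"))
  stats::setNames(g, quants$sample_id)
}

## Breslow log partial likelihood, gradient and Hessian for covariate
## matrix X (n x p) at beta. Risk-set sums are reverse cumulative sums over
## subjects sorted by decreasing time (ties share the full tied block).
breslow_loglik <- function(beta, time, event, X) {
  p <- length(beta)
  eta <- drop(X %*% beta)
  ord <- order(time, decreasing = TRUE)
  te <- time[ord]
  w <- exp(eta[ord])
  Xo <- X[ord, , drop = FALSE]
  cum0 <- cumsum(w)
  cum1 <- apply(Xo * w, 2, cumsum)
  if (p == 1) cum1 <- matrix(cum1, ncol = 1)
  ## S2 needs the p(p+1)/2 weighted cross-product cumsums
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  cum2 <- sapply(seq_len(nrow(pairs)), function(i)
    cumsum(w * Xo[, pairs[i, 1]] * Xo[, pairs[i, 2]]))
  if (nrow(pairs) == 1) cum2 <- matrix(cum2, ncol = 1)

  et <- sort(unique(time[event == 1]))
  ## risk set of event time t = first m positions of the desc-sorted order
  m <- length(te) - findInterval(et, sort(te), left.open = TRUE)
  d <- as.integer(tabulate(match(time[event == 1], et), nbins = length(et)))
  ev_x <- X[event == 1, , drop = FALSE]

  S0 <- cum0[m]
  S1 <- cum1[m, , drop = FALSE]
  ll <- sum(eta[event == 1]) - sum(d * log(S0))
  grad <- colSums(ev_x) - colSums(d * S1 / S0)
  hess <- matrix(0, p, p)
  Sr <- S1 / S0
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    v <- -sum(d * (cum2[m, i] / S0 - Sr[, a] * Sr[, b]))
    hess[a, b] <- hess[a, b] + v
    if (a != b) hess[b, a] <- hess[b, a] + v
  }
  list(loglik = ll, gradient = grad, hessian = hess)
}

#' Univariate Cox proportional-hazards fit on a group factor
#'
#' Maximizes the Breslow partial likelihood by Newton iteration (to
#' gradient norm < 1e-8) for a categorical covariate, reporting hazard
#' ratios of each group against the reference with Wald 95% confidence
#' intervals on the log scale.
#'
#' @param time,event survival data.
#' @param group group label per subject.
#' @param reference reference level (default `"high"`, falling back to the
#'   first level present).
#' @param max_iter Newton iteration cap.
#' @return object of class `cox_result`: `hazard_ratios`, `ci95` (matrix
#'   with lower/upper), `coef`, `se`, `log_partial_likelihood`,
#'   `converged`, `monotone_likelihood` flag, `iterations`.
#' @export
cox_univariate <- function(time, event, group, reference = "high",
                           max_iter = 50L) {
  check_surv(time, event)
  if (sum(event) == 0) stop_input("no events: Cox model cannot be fitted")
  lev <- unique(group)
  if (length(lev) < 2) stop_input("Cox fit needs at least 2 groups")
  if (!reference %in% lev) reference <- lev[1]
  others <- setdiff(lev, reference)
  ## groups with no events drive their log-HR to -Inf (monotone likelihood)
  no_event_groups <- others[vapply(others, function(g)
    sum(event[group == g]) == 0, TRUE)]
  X <- sapply(others, function(g) as.numeric(group == g))
  X <- matrix(X, ncol = length(others),
              dimnames = list(NULL, others))
  beta <- numeric(length(others))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    bl <- breslow_loglik(beta, time, event, X)
    if (sqrt(sum(bl$gradient^2)) < 1e-8) { converged <- TRUE; break }
    step <- tryCatch(solve(-bl$hessian, bl$gradient), error = function(e) NULL)
    if (is.null(step)) break
    ## step-halving to keep the likelihood ascending
    for (h in 0:10) {
      cand <- beta + step / 2^h
      if (breslow_loglik(cand, time, event, X)$loglik >= bl$loglik - 1e-12) {
        beta <- cand; break
      }
    }
  }
  bl <- breslow_loglik(beta, time, event, X)
  vcov <- tryCatch(solve(-bl$hessian), error = function(e)
    matrix(NA_real_, length(beta), length(beta)))
  se <- sqrt(diag(vcov))
  hr <- exp(beta)
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- others
  names(hr) <- names(beta) <- names(se) <- others
  monotone <- length(no_event_groups) > 0 || any(abs(beta) > 15)
  if (monotone && !converged)
    warning("monotone partial likelihood: group(s) ",
            paste(no_event_groups, collapse = ", "),
            " drive the hazard ratio to a boundary", call. = FALSE)
  structure(list(reference = reference, coef = beta, se = se,
                 hazard_ratios = hr, ci95 = ci,
                 log_partial_likelihood = bl$loglik,
                 converged = converged,
                 monotone_likelihood = monotone,
                 iterations = iter),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (Breslow ties), reference = %s\n",
              x$reference))
  for (g in names(x$hazard_ratios))
    cat(sprintf("  %-14s HR %.4f (95%% CI %.5f-%.4f)\n", g,
                x$hazard_ratios[g], x$ci95[g, "lower"], x$ci95[g, "upper"]))
  cat(sprintf("  log partial likelihood %.4f%s\n", x$log_partial_likelihood,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Three-group survival report
#'
#' Per-group Kaplan-Meier curves and medians, the global log-rank test,
#' pairwise log-rank p-values, median-survival differences against the
#' high-ctDNA group, and the univariate Cox hazard-ratio table.
#'
#' @param records data frame with `sample_id`, `time_days`, `event`,
#'   `group`.
#' @param cutpoint the copies/mL cut point used for the grouping (recorded
#'   in the report).
#' @return object of class `survival_report`.
#' @export
survival_report <- function(records, cutpoint = NA_real_) {
  check_surv(records$time_days, records$event)
  groups <- sort(unique(records$group))
  curves <- lapply(groups, function(g) {
    r <- records[records$group == g, ]
    km_estimate(r$time_days, r$event)
  })
  names(curves) <- groups
  medians <- vapply(curves, `[[`, 0, "median")
  global <- if (length(groups) >= 2)
    logrank_test(records$time_days, records$event, records$group) else NULL
  pairs <- if (length(groups) >= 2) {
    cmb <- utils::combn(groups, 2)
    data.frame(group_a = cmb[1, ], group_b = cmb[2, ],
               p_value = apply(cmb, 2, function(gg) {
                 r <- records[records$group %in% gg, ]
                 logrank_test(r$time_days, r$event, r$group)$p_value
               }), stringsAsFactors = FALSE)
  } else NULL
  median_diff_vs_high <- if ("high" %in% groups)
    medians - medians[["high"]] else NULL
  cox <- if (length(groups) >= 2 && sum(records$event) > 0)
    tryCatch(cox_univariate(records$time_days, records$event, records$group,
                            reference = "high"),
             error = function(e) NULL) else NULL
  structure(list(cutpoint = cutpoint, groups = groups, curves = curves,
                 medians = medians, median_diff_vs_high = median_diff_vs_high,
                 global_logrank = global, pairwise_logrank = pairs,
                 cox = cox, n = nrow(records)),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat("Baseline ctDNA survival stratification\n")
  if (!is.na(x$cutpoint))
    cat(sprintf("  cut point: %.2f copies/mL plasma\n", x$cutpoint))
  for (g in x$groups)
    cat(sprintf("  %-14s n = %3d  median = %s\n", g, x$curves[[g]]$n,
                if (is.na(x$medians[[g]])) "not reached" else
                  paste(format(x$medians[[g]], digits = 6), "days")))
  if (!is.null(x$median_diff_vs_high)) {
    for (g in setdiff(x$groups, "high")) {
      d <- x$median_diff_vs_high[[g]]
      if (!is.na(d))
        cat(sprintf("  survival advantage of %s vs high: %g days\n", g, d))
    }
  }
  if (!is.null(x$global_logrank))
    cat(sprintf("  global log-rank: chi-square %.4f (df %d), p = %.3g\n",
                x$global_logrank$chisq, x$global_logrank$df,
                x$global_logrank$p_value))
  if (!is.null(x$pairwise_logrank))
    for (i in seq_len(nrow(x$pairwise_logrank)))
      cat(sprintf("  log-rank %s vs %s: p = %.3g\n",
                  x$pairwise_logrank$group_a[i], x$pairwise_logrank$group_b[i],
                  x$pairwise_logrank$p_value[i]))
  if (!is.null(x$cox)) print(x$cox)
  invisible(x)
}

#' @export
plot.survival_report <- function(x, col = NULL, ...) {
  if (is.null(col)) col <- seq_along(x$groups)
  first <- TRUE
  for (i in seq_along(x$groups)) {
    plot(x$curves[[i]], col = col[i], add = !first, ...)
    first <- FALSE
  }
  graphics::legend("topright", legend = x$groups, col = col, lty = 1,
                   bty = "n")
  invisible(x)
}
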