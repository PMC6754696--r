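#' Probabilistic cost-effectiveness engine
#'
#' Uncertainty in incremental costs and effects is characterised by a
#' nonparametric bootstrap stratified by trial arm, run across every
#' imputed dataset: for each imputation and each replicate, patients are
#' resampled with replacement within each arm, group summaries (mean
#' societal cost, remission-increase proportion, mean QALY gain) are
#' recomputed, and one incremental draw (delta cost, delta effect) is
#' emitted. The pooled m x B draws feed the ICER percentile summaries, the
#' cost-effectiveness plane quadrant probabilities and the acceptability
#' curves.
#'
#' Random-number discipline: each imputation has its own substream derived
#' from the master seed, and replicates consume that stream sequentially,
#' so increasing `B` extends the draws without reshuffling earlier ones,
#' and rerunning with equal seeds reproduces the draws exactly (this also
#' provides common random numbers across sensitivity scenarios and effect
#' measures).
#'
#' @name bootstrap_cea
NULL

# per-patient quantities the bootstrap averages
.arm_stats <- function(dataset, costs, horizon_years, scenario = NULL) {
  cb <- total_cost(dataset, costs)
  if (!is.null(scenario)) cb <- apply_scenario(cb, scenario)
  ef <- effect_summary(dataset, horizon_years = horizon_years)
  data.frame(arm = cb$arm, total = cb$total,
             rem0 = as.numeric(ef$in_remission_w0),
             rem24 = as.numeric(ef$in_remission_w24),
             qaly = ef$qaly)
}

.as_datasets <- function(x) {
  if (inherits(x, "cea_imputation_set")) x$datasets
  else if (is.data.frame(x)) list(validate_patients(x))
  else stop("expected a cea_imputation_set or a patient data frame",
            call. = FALSE)
}

#' Bootstrap incremental cost and effect draws for one arm contrast
#'
#' @param impsets a `cea_imputation_set` (from [impute()]) or a single
#'   complete `cea_patients` data frame.
#' @param arm_a,arm_b the arms contrasted (A minus B), e.g.
#'   `"telemonitoring"` vs `"control"`.
#' @param B bootstrap replicates per imputation (default 1000).
#' @param seed master seed.
#' @param costs a `cea_unit_costs` table.
#' @param horizon_years QALY horizon.
#' @param scenario optional [sensitivity_scenario()] applied to the cost
#'   breakdowns before resampling (common random numbers across scenarios).
#' @return A data frame of class `cea_draws` with columns `imputation`,
#'   `replicate`, `delta_cost`, `delta_remission` (difference in
#'   remission-increase proportions) and `delta_qaly` (difference in mean
#'   QALY gain); exactly `m * B` rows.
#' @export
bootstrap_contrast <- function(impsets, arm_a, arm_b, B = 1000, seed = 1,
                               costs = default_unit_costs(),
                               horizon_years = 0.5, scenario = NULL) {
  if (B < 1) stop("'B' must be >= 1", call. = FALSE)
  stopifnot(arm_a %in% cea_arms(), arm_b %in% cea_arms())
  datasets <- .as_datasets(impsets)
  m <- length(datasets)
  out <- vector("list", m)
  for (k in seq_len(m)) {
    st <- .arm_stats(datasets[[k]], costs, horizon_years, scenario)
    a <- st[st$arm == arm_a, ]
    b <- st[st$arm == arm_b, ]
    na <- nrow(a)
    nb <- nrow(b)
    if (na < 2 || nb < 2) {
      stop("both arms need at least 2 patients (", arm_a, ": ", na, ", ",
           arm_b, ": ", nb, ")", call. = FALSE)
    }
    set.seed(.subseed(seed, k))
    # one uniform chunk per replicate (arm A then arm B) keeps earlier
    # replicates fixed when B grows
    U <- matrix(stats::runif((na + nb) * B), nrow = na + nb)
    ia <- ceiling(U[seq_len(na), , drop = FALSE] * na)
    ib <- ceiling(U[na + seq_len(nb), , drop = FALSE] * nb)
    mean_at <- function(v, idx) colMeans(matrix(v[idx], nrow = nrow(idx)))
    dc <- mean_at(a$total, ia) - mean_at(b$total, ib)
    drem <- (mean_at(a$rem24, ia) - mean_at(a$rem0, ia)) -
      (mean_at(b$rem24, ib) - mean_at(b$rem0, ib))
    dq <- mean_at(a$qaly, ia) - mean_at(b$qaly, ib)
    out[[k]] <- data.frame(imputation = k, replicate = seq_len(B),
                           delta_cost = dc, delta_remission = drem,
                           delta_qaly = dq)
  }
  res <- do.call(rbind, out)
  attr(res, "contrast") <- c(arm_a, arm_b)
  class(res) <- c("cea_draws", "data.frame")
  res
}

.measure_col <- function(measure = c("remission", "qaly")) {
  measure <- match.arg(measure)
  c(remission = "delta_remission", qaly = "delta_qaly")[[measure]]
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_effect`; undefined (`NA`) when the incremental
#' effect is zero. Undefined ICERs are excluded from ratio summaries but
#' their draws remain in plane and CEAC computations.
#'
#' @param delta_cost,delta_effect numeric vectors.
#' @return Numeric vector of ICERs (EUR per effect unit).
#' @export
#' @examples
#' icer(-211, 0.191) # ~ -1105 EUR per additional patient in remission
icer <- function(delta_cost, delta_effect) {
  ifelse(delta_effect == 0, NA_real_, delta_cost / delta_effect)
}

#' Median ICER and percentile interval over bootstrap draws
#'
#' @param draws a `cea_draws` data frame.
#' @param measure `"remission"` or `"qaly"`.
#' @param min_defined minimum number of defined-ICER draws required.
#' @return A list with `median`, `ci_low`, `ci_high` (2.5th/97.5th
#'   percentiles) and `n_defined`.
#' @export
summarize_icer <- function(draws, measure = "remission",
                           min_defined = 100) {
  r <- icer(draws$delta_cost, draws[[.measure_col(measure)]])
  r <- r[!is.na(r)]
  if (length(r) < min_defined) {
    stop("only ", length(r), " draws with a defined ICER; ",
         "increase the number of bootstrap replicates", call. = FALSE)
  }
  q <- stats::quantile(r, c(0.5, 0.025, 0.975), names = FALSE)
  list(median = q[1], ci_low = q[2], ci_high = q[3], n_defined = length(r))
}

#' Cost-effectiveness plane quadrant probabilities
#'
#' Empirical fractions of draws in each quadrant of the plane (x = delta
#' effect, y = delta cost). The south-east quadrant (more effect, lower
#' cost) is dominant. Boundary draws are resolved by strict inequalities
#' for "more effective" and "cost saving": a draw with `delta_effect = 0`
#' is counted as not more effective, one with `delta_cost = 0` as not cost
#' saving, so the four probabilities always sum to exactly 1.
#'
#' @param draws a `cea_draws` data frame (non-empty).
#' @param measure `"remission"` or `"qaly"`.
#' @return Named numeric vector `c(NE, SE, SW, NW)`; `SE` is dominant.
#' @export
quadrant_probabilities <- function(draws, measure = "remission") {
  if (nrow(draws) == 0) stop("no draws", call. = FALSE)
  de <- draws[[.measure_col(measure)]]
  dc <- draws$delta_cost
  eff <- de > 0
  saving <- dc < 0
  c(NE = mean(eff & !saving), SE = mean(eff & saving),
    SW = mean(!eff & saving), NW = mean(!eff & !saving))
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value `lambda`, the probability that the
#' intervention is cost-effective is the fraction of draws with positive
#' net monetary benefit, `lambda * delta_effect - delta_cost > 0`. The
#' net-benefit criterion (rather than an ICER threshold rule) is used
#' because ICER thresholds are sign-ambiguous when the incremental effect
#' is negative; with draws of negative incremental effect the curve need
#' not be monotone and tends to `P(delta_effect > 0)` as the willingness
#' to pay grows. At `lambda = 0` the curve equals `P(delta_cost < 0)`
#' exactly (probability of cost saving).
#'
#' @param draws a `cea_draws` data frame.
#' @param wtp_grid non-negative willingness-to-pay grid in EUR (default 0
#'   to 20,000 in steps of 500).
#' @param measure `"remission"` or `"qaly"`.
#' @return A data frame of class `cea_ceac` with columns `wtp` and
#'   `probability`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 20000, by = 500),
                 measure = "remission") {
  if (nrow(draws) == 0) stop("no draws", call. = FALSE)
  if (any(wtp_grid < 0)) {
    stop("willingness-to-pay values must be >= 0", call. = FALSE)
  }
  de <- draws[[.measure_col(measure)]]
  dc <- draws$delta_cost
  prob <- vapply(wtp_grid, function(l) mean(l * de - dc > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("cea_ceac", "data.frame"))
}

#' Full contrast analysis: draws, ICERs, plane and CEACs
#'
#' Runs [bootstrap_contrast()] and assembles, for both effect measures,
#' the Rubin-pooled incremental point estimates, the median ICER with its
#' percentile interval, the quadrant probabilities and the acceptability
#' curve.
#'
#' @inheritParams bootstrap_contrast
#' @param wtp_grid willingness-to-pay grid for the CEACs.
#' @return An object of class `cea_contrast`: a list with `contrast`,
#'   `draws`, `pooled` (Rubin-pooled incremental cost/effects with SEs)
#'   and per-measure `icer`, `quadrants`, `ceac`.
#' @export
contrast_analysis <- function(impsets, arm_a, arm_b, B = 1000, seed = 1,
                              costs = default_unit_costs(),
                              horizon_years = 0.5,
                              wtp_grid = seq(0, 20000, by = 500),
                              scenario = NULL) {
  draws <- bootstrap_contrast(impsets, arm_a, arm_b, B = B, seed = seed,
                              costs = costs, horizon_years = horizon_years,
                              scenario = scenario)
  datasets <- .as_datasets(impsets)
  pool_of <- function(stat_fn) {
    ests <- vars <- numeric(length(datasets))
    for (k in seq_along(datasets)) {
      st <- .arm_stats(datasets[[k]], costs, horizon_years, scenario)
      r <- stat_fn(st[st$arm == arm_a, ], st[st$arm == arm_b, ])
      ests[k] <- r[1]
      vars[k] <- r[2]
    }
    if (length(datasets) == 1) {
      list(estimate = ests, variance = vars, se = sqrt(vars), m = 1)
    } else {
      rubin_pool(ests, vars)
    }
  }
  mean_diff <- function(col) {
    function(a, b) {
      c(mean(a[[col]]) - mean(b[[col]]),
        stats::var(a[[col]]) / nrow(a) + stats::var(b[[col]]) / nrow(b))
    }
  }
  rem_incr <- function(a, b) {
    da <- a$rem24 - a$rem0
    db <- b$rem24 - b$rem0
    c(mean(da) - mean(db),
      stats::var(da) / nrow(a) + stats::var(db) / nrow(b))
  }
  pooled <- list(delta_cost = pool_of(mean_diff("total")),
                 delta_remission = pool_of(rem_incr),
                 delta_qaly = pool_of(mean_diff("qaly")))
  per_measure <- function(measure) {
    list(icer = summarize_icer(draws, measure,
                               min_defined = min(100, B)),
         quadrants = quadrant_probabilities(draws, measure),
         ceac = ceac(draws, wtp_grid, measure))
  }
  structure(list(contrast = c(arm_a, arm_b), draws = draws,
                 pooled = pooled,
                 remission = per_measure("remission"),
                 qaly = per_measure("qaly")),
            class = "cea_contrast")
}

#' @export
print.cea_contrast <- function(x, ...) {
  cat("Contrast:", x$contrast[1], "vs", x$contrast[2], "\n")
  cat(sprintf("  pooled incremental cost: %.0f EUR (SE %.0f)\n",
              x$pooled$delta_cost$estimate, x$pooled$delta_cost$se))
  cat(sprintf("  pooled incremental remission increase: %.3f; QALY: %.4f\n",
              x$pooled$delta_remission$estimate,
              x$pooled$delta_qaly$estimate))
  for (ms in c("remission", "qaly")) {
    s <- x[[ms]]
    cat(sprintf(
      "  [%s] median ICER %.0f EUR (95%% CI %.0f to %.0f); P(dominant) %.1f%%; CEAC(0) %.1f%%\n",
      ms, s$icer$median, s$icer$ci_low, s$icer$ci_high,
      100 * s$quadrants["SE"], 100 * s$ceac$probability[1]))
  }
  invisible(x)
}
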