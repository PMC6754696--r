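#' Multiple imputation of missing trial data
#'
#' Week-12/24 activity scores, utilities, WPAI responses and resource
#' counts may be missing (e.g. non-adherent patients). They are completed
#' by multiple imputation in the bootstrap-EM family: for each of the `m`
#' imputations the records are resampled with replacement, the
#' multivariate-normal maximum-likelihood estimate is obtained by EM on the
#' resample, and the original records' missing cells are drawn from the
#' conditional normal given their observed cells. Trial arm, disease, age
#' and employment enter the model as fully observed covariates so that
#' imputations respect the group structure. Counts and hours are modelled
#' on the log1p scale; after the draw, counts are rounded to non-negative
#' integers, percentages clipped to \[0, 100\] and utilities to \[-1, 1\].
#' Disease-specific activity indexes are modelled through a single
#' "activity margin" (score minus its remission threshold) so that one
#' model covers both diseases.
#'
#' @name missing_data
NULL

# ---- model matrix construction ----------------------------------------

.margin <- function(patients, week) {
  w <- paste0("_", week)
  thr <- remission_thresholds()
  uc_score <- pmax(patients[[paste0("sccai", w)]],
                   patients[[paste0("pmayo", w)]])
  uc_score <- ifelse(is.na(uc_score),
                     ifelse(is.na(patients[[paste0("sccai", w)]]),
                            patients[[paste0("pmayo", w)]],
                            patients[[paste0("sccai", w)]]),
                     uc_score)
  ifelse(patients$disease == "CD",
         patients[[paste0("hbi", w)]] - thr["CD"],
         uc_score - thr["UC"])
}

.impute_model_matrix <- function(patients) {
  n <- nrow(patients)
  log_cnt <- function(col) log1p(patients[[col]])
  mm <- data.frame(
    arm_tel = as.numeric(patients$arm == "telephone"),
    arm_tm = as.numeric(patients$arm == "telemonitoring"),
    disease_uc = as.numeric(patients$disease == "UC"),
    age = (patients$age_years - 40) / 12,
    employed = as.numeric(patients$employed),
    margin_w0 = .margin(patients, "w0"),
    margin_w12 = .margin(patients, "w12"),
    margin_w24 = .margin(patients, "w24"),
    eq5d_w0 = patients$eq5d_w0,
    eq5d_w24 = patients$eq5d_w24
  )
  for (w in c("w0", "w12", "w24")) {
    mm[[paste0("hm_", w)]] <- log1p(patients[[paste0("wpai_hours_missed_", w)]])
    mm[[paste0("hw_", w)]] <- log1p(patients[[paste0("wpai_hours_worked_", w)]])
    mm[[paste0("wi_", w)]] <- patients[[paste0("wpai_work_impair_", w)]] / 100
    mm[[paste0("si_", w)]] <- patients[[paste0("wpai_social_impair_", w)]] / 100
  }
  for (col in .count_cols) mm[[paste0("n_", col)]] <- log_cnt(col)
  if (!all(is.na(patients$calpro_w0))) {
    mm$calpro_w0 <- log1p(patients$calpro_w0)
    mm$calpro_w24 <- log1p(patients$calpro_w24)
  }
  as.matrix(mm)
}

# write imputed model-matrix values back into the patient records,
# touching only originally missing cells
.impute_backfill <- function(patients, mm) {
  thr <- remission_thresholds()
  fill <- function(col, value) {
    miss <- is.na(patients[[col]])
    patients[[col]][miss] <<- value[miss]
    invisible(NULL)
  }
  for (w in c("w0", "w12", "w24")) {
    margin <- mm[, paste0("margin_", w)]
    is_cd <- patients$disease == "CD"
    hbi <- pmax(0L, as.integer(round(margin + thr["CD"])))
    uc <- pmax(0L, as.integer(round(margin + thr["UC"])))
    hbi[!is_cd] <- NA_integer_
    uc[is_cd] <- NA_integer_
    fill(paste0("hbi_", w), hbi)
    fill(paste0("sccai_", w), uc)
    fill(paste0("pmayo_", w), pmin(uc, 9L))
    fill(paste0("wpai_hours_missed_", w),
         pmin(168, pmax(0, expm1(mm[, paste0("hm_", w)]))))
    hw <- pmin(168, pmax(0, expm1(mm[, paste0("hw_", w)])))
    nw <- patients[[paste0("wpai_not_working_", w)]]
    nw[is.na(nw)] <- !patients$employed[is.na(nw)]
    patients[[paste0("wpai_not_working_", w)]] <- nw
    hw[nw] <- 0
    fill(paste0("wpai_hours_worked_", w), hw)
    fill(paste0("wpai_work_impair_", w),
         pmin(100, pmax(0, mm[, paste0("wi_", w)] * 100)))
    fill(paste0("wpai_social_impair_", w),
         pmin(100, pmax(0, mm[, paste0("si_", w)] * 100)))
  }
  fill("eq5d_w0", pmin(1, pmax(-1, mm[, "eq5d_w0"])))
  fill("eq5d_w24", pmin(1, pmax(-1, mm[, "eq5d_w24"])))
  not_tm <- patients$arm != "telemonitoring"
  for (col in .count_cols) {
    v <- round(expm1(mm[, paste0("n_", col)]))
    v[!is.finite(v)] <- 0
    # counts capped at a generous per-horizon maximum so extreme draws on
    # the log scale cannot overflow
    v <- as.integer(pmax(0, pmin(v, 999)))
    if (col %in% c("tm_nurse", "tm_physician")) v[not_tm] <- 0L
    fill(col, v)
  }
  miss_tm <- is.na(patients$tm_months)
  patients$tm_months[miss_tm] <-
    ifelse(patients$arm[miss_tm] == "telemonitoring", 6, 0)
  if ("calpro_w0" %in% colnames(mm)) {
    fill("calpro_w0", pmax(0, expm1(mm[, "calpro_w0"])))
    fill("calpro_w24", pmax(0, expm1(mm[, "calpro_w24"])))
  }
  patients
}

# ---- EM for the multivariate normal with missing data -----------------

# Returns list(mu, sigma) on the standardized scale of Y.
.em_mvn <- function(Y, ridge = 0.5, maxit = 100, tol = 1e-4) {
  n <- nrow(Y)
  p <- ncol(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v < 1e-6] <- 1e-6
  prior_diag <- v
  sigma <- diag(v, p)
  lambda <- ridge * p # prior weight, in pseudo-observations
  miss <- is.na(Y)
  pat_key <- apply(miss, 1, function(z) paste(which(z), collapse = ","))
  groups <- split(seq_len(n), pat_key)

  for (iter in seq_len(maxit)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (rows in groups) {
      m <- which(miss[rows[1], ])
      o <- setdiff(seq_len(p), m)
      Yg <- Y[rows, , drop = FALSE]
      if (length(m) == 0) {
        T1 <- T1 + colSums(Yg)
        T2 <- T2 + crossprod(Yg)
        next
      }
      Soo_inv <- solve(sigma[o, o, drop = FALSE])
      B <- sigma[m, o, drop = FALSE] %*% Soo_inv
      resid <- sweep(Yg[, o, drop = FALSE], 2, mu[o])
      Yg[, m] <- matrix(mu[m], nrow(Yg), length(m), byrow = TRUE) +
        resid %*% t(B)
      C <- sigma[m, m, drop = FALSE] -
        B %*% t(sigma[m, o, drop = FALSE])
      T1 <- T1 + colSums(Yg)
      cp <- crossprod(Yg)
      cp[m, m] <- cp[m, m] + length(rows) * C
      T2 <- T2 + cp
    }
    mu_new <- T1 / n
    S <- T2 / n - tcrossprod(mu_new)
    # ridge toward the diagonal prior keeps the estimate positive definite
    sigma_new <- (n * S + lambda * diag(prior_diag, p)) / (n + lambda)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new
    sigma <- sigma_new
    if (delta < tol) break
  }
  list(mu = mu, sigma = sigma)
}

# Draw missing cells of Y from the conditional normal under (mu, sigma).
.draw_conditional <- function(Y, mu, sigma) {
  miss <- is.na(Y)
  for (i in which(rowSums(miss) > 0)) {
    m <- which(miss[i, ])
    o <- which(!miss[i, ])
    if (length(o) == 0) {
      cond_mu <- mu[m]
      C <- sigma[m, m, drop = FALSE]
    } else {
      Soo_inv <- solve(sigma[o, o, drop = FALSE])
      B <- sigma[m, o, drop = FALSE] %*% Soo_inv
      cond_mu <- mu[m] + as.vector(B %*% (Y[i, o] - mu[o]))
      C <- sigma[m, m, drop = FALSE] - B %*% t(sigma[m, o, drop = FALSE])
    }
    C <- (C + t(C)) / 2
    L <- tryCatch(chol(C), error = function(e) {
      chol(C + diag(1e-8 + max(0, -min(eigen(C, only.values = TRUE)$values)),
                    nrow(C)))
    })
    Y[i, m] <- cond_mu + as.vector(t(L) %*% stats::rnorm(length(m)))
  }
  Y
}

#' Multiply impute missing patient data
#'
#' See the module description (`?missing_data`) for the algorithm. With a
#' complete dataset, `m` identical copies are returned. The same seed
#' always yields the same imputation set.
#'
#' @param patients a `cea_patients` data frame, possibly with missing
#'   week-12/24 fields.
#' @param m number of imputations (>= 2; default 5).
#' @param seed integer seed.
#' @param ridge diagonal prior weight per variable (pseudo-observations)
#'   stabilising the EM covariance on small resamples.
#' @param maxit,tol EM iteration controls.
#' @return An object of class `cea_imputation_set`: a list with elements
#'   `m`, `datasets` (list of `m` completed `cea_patients`), `seed` and
#'   `method_tag`.
#' @export
impute <- function(patients, m = 5, seed = 1, ridge = 0.5,
                   maxit = 100, tol = 1e-4) {
  patients <- validate_patients(patients)
  if (m < 2) stop("'m' must be >= 2", call. = FALSE)
  mm <- .impute_model_matrix(patients)
  all_missing <- colSums(!is.na(mm)) == 0
  if (any(all_missing)) {
    stop("variable(s) missing for every patient: ",
         paste(colnames(mm)[all_missing], collapse = ", "), call. = FALSE)
  }
  method_tag <- paste0("bootstrap-em-mvn/log1p-counts/activity-margin",
                       "/ridge=", ridge)
  nw_cols <- paste0("wpai_not_working_", c("w0", "w12", "w24"))
  if (!anyNA(mm) && !anyNA(patients$tm_months) &&
      !anyNA(as.data.frame(patients)[, nw_cols])) {
    datasets <- replicate(m, patients, simplify = FALSE)
    return(structure(list(m = m, datasets = datasets, seed = seed,
                          method_tag = method_tag),
                     class = "cea_imputation_set"))
  }
  n <- nrow(mm)
  # standardize for EM conditioning
  centers <- colMeans(mm, na.rm = TRUE)
  scales <- apply(mm, 2, stats::sd, na.rm = TRUE)
  scales[!is.finite(scales) | scales < 1e-8] <- 1
  Z <- sweep(sweep(mm, 2, centers), 2, scales, "/")

  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    set.seed(.subseed(seed, k))
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      Zb <- Z[idx, , drop = FALSE]
      if (all(colSums(!is.na(Zb)) > 1)) break
    }
    fit <- .em_mvn(Zb, ridge = ridge, maxit = maxit, tol = tol)
    Zk <- .draw_conditional(Z, fit$mu, fit$sigma)
    mmk <- sweep(sweep(Zk, 2, scales, "*"), 2, centers, "+")
    datasets[[k]] <- .impute_backfill(patients, mmk)
  }
  structure(list(m = m, datasets = datasets, seed = seed,
                 method_tag = method_tag),
            class = "cea_imputation_set")
}

# deterministic 32-bit substream seeds derived from a master seed
.subseed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 104729) %% 2147483629 + 1
}

#' @export
print.cea_imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$m, "completed datasets of",
      nrow(x$datasets[[1]]), "patients\n")
  cat("method:", x$method_tag, " seed:", x$seed, "\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled point estimate is the mean of the per-imputation estimates;
#' the total variance is the mean within-imputation variance plus
#' `(1 + 1/m)` times the between-imputation variance. Degrees of freedom
#' follow Rubin's classic formula.
#'
#' @param estimates numeric vector of m point estimates.
#' @param variances numeric vector of m within-imputation variances.
#' @return A list with `estimate`, `variance`, `se`, `within`, `between`,
#'   `m`, `df`, and a 95% interval (`ci_low`, `ci_high`).
#' @export
#' @examples
#' rubin_pool(1:5, rep(0, 5)) # pooled 3, total variance 3.0
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (length(variances) != m) {
    stop("'estimates' and 'variances' must have the same length",
         call. = FALSE)
  }
  if (m < 2) stop("Rubin pooling needs m >= 2 estimates", call. = FALSE)
  qbar <- mean(estimates)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  df <- if (between > 0) {
    (m - 1) * (1 + within / ((1 + 1 / m) * between))^2
  } else {
    Inf
  }
  crit <- stats::qt(0.975, df)
  list(estimate = qbar, variance = total, se = sqrt(total),
       within = within, between = between, m = m, df = df,
       ci_low = qbar - crit * sqrt(total),
       ci_high = qbar + crit * sqrt(total))
}
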