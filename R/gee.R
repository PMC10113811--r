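#' Model specification for the diel presence GEE
#'
#' A binomial (logit link) marginal model for hourly acoustic presence with
#' light regime as a four-level fixed factor and, optionally, the hourly
#' ambient-noise level entered by regime (noise x regime interaction, noise
#' centred within site so regime effects are interpretable at average
#' noise). Observations are clustered by detection day, ordered by hour
#' within the day; within-cluster dependence is handled by the working
#' correlation (AR1 by default) and robust sandwich standard errors.
#'
#' @param working_correlation `"ar1"` or `"independence"`.
#' @param ref_level Reference regime level (default `"dawn"`).
#' @param include_noise Add the per-regime noise slope terms?
#' @param noise_col Column holding the hourly noise level.
#' @param alpha_level Significance level for contrasts and letters.
#' @param max_iter,tol Fisher-scoring iteration cap and relative
#'   coefficient-change tolerance.
#' @return A `model_spec` list.
#' @export
model_spec <- function(working_correlation = c("ar1", "independence"),
                       ref_level = "dawn", include_noise = FALSE,
                       noise_col = "noise_p20_db", alpha_level = 0.05,
                       max_iter = 100, tol = 1e-8) {
  working_correlation <- arg_match(working_correlation)
  structure(list(working_correlation = working_correlation,
                 ref_level = ref_level, include_noise = include_noise,
                 noise_col = noise_col, alpha_level = alpha_level,
                 max_iter = max_iter, tol = tol),
            class = "model_spec")
}

# block-tridiagonal inverse of the AR1 working correlation for contiguous
# clusters: first/last = 1/(1-a^2), interior = (1+a^2)/(1-a^2),
# off-diagonal = -a/(1-a^2) within clusters
ar1_inverse_sparse <- function(cluster, alpha) {
  n <- length(cluster)
  first <- c(TRUE, cluster[-1] != cluster[-n])
  last <- c(first[-1], TRUE)
  singleton <- first & last
  s <- 1 - alpha^2
  d <- ifelse(singleton, 1,
              ifelse(first | last, 1 / s, (1 + alpha^2) / s))
  off <- ifelse(last[-n], 0, -alpha / s)
  Matrix::bandSparse(n, n, k = c(0L, 1L), symmetric = TRUE,
                     diagonals = list(d, off))
}

# dense per-cluster AR1 inverse handling hour gaps: corr = alpha^|h_s - h_t|
ar1_inverse_blocks <- function(cluster, time_index, alpha) {
  idx <- unname(split(seq_along(cluster), cluster))  # ids are in row order
  blocks <- lapply(idx, function(i) {
    h <- time_index[i]
    R <- alpha^abs(outer(h, h, "-"))
    solve(R)
  })
  Matrix::bdiag(blocks)
}

#' Fit a binomial GEE for hourly presence
#'
#' Solves the generalized estimating equations
#' \eqn{\sum_i D_i^T V_i^{-1} (y_i - \mu_i) = 0} for a logit mean model by
#' Fisher scoring, with working covariance
#' \eqn{V_i = \phi A_i^{1/2} R(\alpha) A_i^{1/2}}. Under AR1,
#' \eqn{R_{st} = \alpha^{|h_s - h_t|}} with the hour index advancing across
#' gaps from missing hours; \eqn{\alpha} is re-estimated each iteration from
#' the lag-1 Pearson-residual moment estimator. Model-robust (sandwich)
#' covariance is always reported.
#'
#' @param table Hourly records (typically a [detection_days()] table) with
#'   columns `presence`, `regime`, `site`, `date`, `hour_of_day`, and the
#'   noise column when `include_noise = TRUE`.
#' @param spec A [model_spec()].
#' @return A `findiel_gee` object: coefficients, robust covariance,
#'   estimated `ar1_alpha`, residuals and bookkeeping. Methods: `print()`,
#'   [tidy()], [glance()], `residuals()`.
#' @export
fit_gee <- function(table, spec = model_spec()) {
  stopifnot(all(c("presence", "regime") %in% names(table)))
  if (!"site" %in% names(table)) table$site <- "site"
  if (!"date" %in% names(table)) {
    table <- mutate(table, date = as.Date(.data$utc_hour, tz = "UTC"))
  }
  if (!"hour_of_day" %in% names(table)) {
    table <- mutate(table,
                    hour_of_day = as.integer(format(.data$utc_hour, "%H",
                                                    tz = "UTC")))
  }
  dat <- table
  if (spec$include_noise) {
    if (!spec$noise_col %in% names(dat)) {
      abort(paste0("noise column '", spec$noise_col, "' not found"))
    }
    dat <- filter(dat, !is.na(.data[[spec$noise_col]]))
    dat <- dat %>%
      group_by(.data$site) %>%
      mutate(noise_c = .data[[spec$noise_col]] -
               mean(.data[[spec$noise_col]])) %>%
      ungroup()
  }
  dat <- arrange(dat, .data$site, .data$date, .data$hour_of_day)
  y <- as.numeric(dat$presence)
  if (!all(y %in% c(0, 1))) abort("presence must be binary 0/1")
  if (all(y == y[1])) {
    abort(paste0("separation: all responses are ", y[1],
                 "; the logistic fit does not exist"))
  }
  regime <- factor(as.character(dat$regime),
                   levels = union(spec$ref_level,
                                  c("dawn", "day", "dusk", "night")))
  regime <- droplevels(regime)
  mf <- data.frame(regime = regime)
  form <- ~regime
  if (spec$include_noise) {
    mf$noise_c <- dat$noise_c
    form <- ~ regime + regime:noise_c
  }
  X <- model.matrix(form, mf)
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank deficient; check regime levels and noise")
  }
  key <- paste(dat$site, dat$date)
  cluster <- cumsum(c(TRUE, key[-1] != key[-length(key)]))  # row-order ids
  n <- length(y)
  p <- ncol(X)
  n_clusters <- length(unique(cluster))
  if (n_clusters < 2) abort("need at least 2 clusters (detection days)")
  time_index <- dat$hour_of_day
  contiguous <- {
    same <- cluster[-1] == cluster[-n]
    all(diff(time_index)[same] == 1)
  }

  beta <- numeric(p)
  beta[1] <- qlogis(mean(y))
  alpha <- 0
  phi <- 1
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-10)
    r <- (y - mu) / sqrt(v)
    phi <- sum(r^2) / (n - p)
    if (spec$working_correlation == "ar1") {
      same <- cluster[-1] == cluster[-n] & diff(time_index) == 1
      n1 <- sum(same)
      if (n1 > p) {
        alpha <- sum(r[-n][same] * r[-1][same]) / ((n1 - p) * phi)
        alpha <- min(max(alpha, -0.95), 0.95)
      }
    }
    Rinv <- if (spec$working_correlation == "independence" || alpha == 0) {
      NULL
    } else if (contiguous) {
      ar1_inverse_sparse(cluster, alpha)
    } else {
      ar1_inverse_blocks(cluster, time_index, alpha)
    }
    U <- X * sqrt(v)
    if (is.null(Rinv)) {
      B <- crossprod(U)
      score <- drop(crossprod(U, r))
    } else {
      RU <- as.matrix(Rinv %*% U)
      B <- crossprod(U, RU)
      score <- drop(crossprod(RU, r))
    }
    delta <- tryCatch(solve(B, score), error = function(e) {
      abort(paste0("GEE update failed (singular working information): ",
                   conditionMessage(e)))
    })
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      if (all(is.finite(beta_new)) && max(abs(X %*% beta_new)) < 50) break
      step <- step / 2
      if (step < 1e-4) break
    }
    rel <- max(abs(beta_new - beta)) / max(1, max(abs(beta_new)))
    beta <- beta_new
    if (rel < spec$tol) { converged <- TRUE; break }
    if (iter >= spec$max_iter) break
  }

  # sandwich covariance at the final iterate
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- plogis(eta)
  v <- pmax(mu * (1 - mu), 1e-10)
  r <- (y - mu) / sqrt(v)
  U <- X * sqrt(v)
  Rinv <- if (spec$working_correlation == "independence" || alpha == 0) {
    NULL
  } else if (contiguous) {
    ar1_inverse_sparse(cluster, alpha)
  } else {
    ar1_inverse_blocks(cluster, time_index, alpha)
  }
  RU <- if (is.null(Rinv)) U else as.matrix(Rinv %*% U)
  B <- crossprod(U, RU)
  g <- rowsum(RU * r, cluster)            # per-cluster score contributions
  M <- crossprod(as.matrix(g))
  Binv <- solve(B)
  robust_cov <- Binv %*% M %*% Binv
  robust_cov <- (robust_cov + t(robust_cov)) / 2
  names(beta) <- colnames(X)
  dimnames(robust_cov) <- list(colnames(X), colnames(X))

  structure(list(
    beta = beta, robust_cov = robust_cov, naive_info = B,
    ar1_alpha = if (spec$working_correlation == "ar1") alpha else NA_real_,
    scale = phi, n_obs = n, n_clusters = n_clusters,
    converged = converged, n_iter = iter, spec = spec,
    regime_levels = levels(regime),
    fitted = mu, pearson_residuals = r, y = y,
    cluster = cluster, time_index = time_index
  ), class = "findiel_gee")
}

#' @exportS3Method base::print
print.findiel_gee <- function(x, ...) {
  cat(sprintf(
    "Binomial GEE (logit link, %s working correlation)\n",
    x$spec$working_correlation))
  cat(sprintf("  %d observations in %d detection-day clusters\n",
              x$n_obs, x$n_clusters))
  if (!is.na(x$ar1_alpha)) {
    cat(sprintf("  estimated AR1 alpha = %.3f\n", x$ar1_alpha))
  }
  cat(sprintf("  converged: %s (%d iterations)\n\nCoefficients:\n",
              x$converged, x$n_iter))
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
residuals.findiel_gee <- function(object, type = c("pearson", "response"),
                                  ...) {
  type <- arg_match(type)
  switch(type,
         pearson = object$pearson_residuals,
         response = object$y - object$fitted)
}

#' Tidy a fitted presence GEE
#'
#' @param x A `findiel_gee` fit.
#' @param conf.int Add normal-theory robust confidence intervals?
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error` (robust), `statistic`,
#'   `p.value` (and the interval when requested).
#' @export
tidy.findiel_gee <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$robust_cov))
  z <- x$beta / se
  out <- tibble(term = names(x$beta), estimate = unname(x$beta),
                std.error = unname(se), statistic = unname(z),
                p.value = unname(2 * pnorm(-abs(z))))
  if (conf.int) {
    q <- qnorm(1 - (1 - conf.level) / 2)
    out <- mutate(out, conf.low = .data$estimate - q * .data$std.error,
                  conf.high = .data$estimate + q * .data$std.error)
  }
  out
}

#' @rdname tidy.findiel_gee
#' @return `glance()` returns a one-row tibble of fit-level summaries.
#' @export
glance.findiel_gee <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_clusters = x$n_clusters,
         ar1_alpha = x$ar1_alpha, scale = x$scale,
         converged = x$converged, n_iter = x$n_iter)
}

regime_coef_vector <- function(fit, level) {
  cv <- numeric(length(fit$beta))
  names(cv) <- names(fit$beta)
  if (level != fit$regime_levels[1]) {
    nm <- paste0("regime", level)
    if (!nm %in% names(cv)) {
      abort(paste0("regime level '", level, "' absent from the model"))
    }
    cv[nm] <- 1
  } else if (!level %in% fit$regime_levels) {
    abort(paste0("regime level '", level, "' absent from the model"))
  }
  cv
}

#' Pairwise Wald contrast between regime means
#'
#' Logit-scale difference between two regimes evaluated at average noise
#' (the noise covariate is centred, so per-regime slopes drop out), with
#' robust standard error and two-sided normal p-value.
#'
#' @param fit A [fit_gee()] result.
#' @param pair Character vector of two regime levels.
#' @return One-row tibble: `regime_i`, `regime_j`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
wald_contrast <- function(fit, pair) {
  stopifnot(length(pair) == 2)
  cv <- regime_coef_vector(fit, pair[1]) - regime_coef_vector(fit, pair[2])
  est <- sum(cv * fit$beta)
  se <- sqrt(drop(t(cv) %*% fit$robust_cov %*% cv))
  z <- if (se > 0) est / se else 0
  p <- if (se > 0) 2 * pnorm(-abs(z)) else 1
  tibble(regime_i = pair[1], regime_j = pair[2], estimate = est,
         std.error = se, statistic = z, p.value = p)
}

#' All six pairwise regime contrasts
#'
#' @param fit A [fit_gee()] result.
#' @param adjust P-value adjustment method (`"none"` matches the single
#'   alpha convention; `"holm"` optional).
#' @return Tibble of six contrasts, one per unordered regime pair.
#' @export
regime_contrasts <- function(fit, adjust = c("none", "holm")) {
  adjust <- arg_match(adjust)
  lv <- fit$regime_levels
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- list_rbind(map(pairs, function(pr) wald_contrast(fit, pr)))
  if (adjust != "none") {
    out$p.value <- stats::p.adjust(out$p.value, method = adjust)
  }
  out
}

#' Compact letter display from pairwise contrasts
#'
#' Assigns letters so that two regimes share at least one letter exactly
#' when their pairwise contrast is non-significant at `alpha_level`: letters
#' correspond to the maximal cliques of the non-significance graph
#' (enumerated exactly over the four regimes).
#'
#' @param contrasts Tibble from [regime_contrasts()] (all six pairs).
#' @param alpha_level Significance level.
#' @return Tibble: `regime`, `letters`.
#' @export
letter_display <- function(contrasts, alpha_level = 0.05) {
  lv <- sort(unique(c(contrasts$regime_i, contrasts$regime_j)))
  lv <- intersect(c("dawn", "day", "dusk", "night", lv), lv)
  k <- length(lv)
  adj <- matrix(TRUE, k, k, dimnames = list(lv, lv))
  for (i in seq_len(nrow(contrasts))) {
    ns <- contrasts$p.value[i] >= alpha_level
    adj[contrasts$regime_i[i], contrasts$regime_j[i]] <- ns
    adj[contrasts$regime_j[i], contrasts$regime_i[i]] <- ns
  }
  # enumerate all subsets; keep maximal cliques of the non-significance graph
  subsets <- map(seq_len(2^k - 1), function(b) which(bitwAnd(b, 2^(seq_len(k) - 1)) > 0))
  is_clique <- map_lgl(subsets, function(s) all(adj[s, s]))
  cl <- subsets[is_clique]
  maximal <- map_lgl(seq_along(cl), function(i) {
    !any(map_lgl(seq_along(cl), function(j) {
      j != i && all(cl[[i]] %in% cl[[j]])
    }))
  })
  cl <- cl[maximal]
  cl <- cl[order(map_int(cl, min), -map_int(cl, length))]
  letter_of <- letters[seq_along(cl)]
  lets <- map_chr(seq_len(k), function(i) {
    paste0(letter_of[map_lgl(cl, function(s) i %in% s)], collapse = "")
  })
  tibble(regime = lv, letters = lets)
}

#' Durbin-Watson statistic of within-cluster residual sequences
#'
#' \eqn{d = \sum_{t \ge 2} (e_t - e_{t-1})^2 / \sum_t e_t^2}, with
#' successive differences taken within clusters only and numerators and
#' denominators pooled across clusters. Values near 2 indicate no lag-1
#' serial correlation; near 0, strong positive correlation.
#'
#' @param residuals Numeric residual vector, ordered within cluster.
#' @param cluster Optional cluster id vector; one cluster if omitted.
#' @return The statistic (in \[0, 4\]).
#' @export
durbin_watson <- function(residuals, cluster = NULL) {
  if (length(residuals) < 2) abort("need at least 2 residuals")
  den <- sum(residuals^2)
  if (den == 0) abort("Durbin-Watson undefined for all-zero residuals")
  if (is.null(cluster)) cluster <- rep(1L, length(residuals))
  same <- cluster[-1] == cluster[-length(cluster)]
  d <- diff(residuals)[same]
  sum(d^2) / den
}

#' Sample autocorrelation function of residuals
#'
#' \eqn{r_k = \sum (e_t - \bar e)(e_{t+k} - \bar e) / \sum (e_t - \bar e)^2};
#' lag 0 is exactly 1.
#'
#' @param residuals Numeric vector, `length(residuals) > max_lag`.
#' @param max_lag Largest lag.
#' @return Tibble: `lag` (0..max_lag), `acf`.
#' @export
acf_values <- function(residuals, max_lag = 24) {
  n <- length(residuals)
  if (n <= max_lag) abort("need more residuals than max_lag")
  e <- residuals - mean(residuals)
  den <- sum(e^2)
  if (den == 0) abort("ACF undefined for zero-variance residuals")
  r <- map_dbl(0:max_lag, function(k) {
    sum(e[seq_len(n - k)] * e[seq_len(n - k) + k]) / den
  })
  tibble(lag = 0:max_lag, acf = r)
}

#' Residual diagnostics for a fitted presence GEE
#'
#' @param fit A [fit_gee()] result.
#' @param max_lag Largest ACF lag.
#' @return List with `dw` (pooled within-cluster Durbin-Watson) and `acf`
#'   (tibble of autocorrelations of the Pearson residual sequence).
#' @export
gee_diagnostics <- function(fit, max_lag = 24) {
  r <- fit$pearson_residuals
  list(dw = durbin_watson(r, fit$cluster),
       acf = acf_values(r, max_lag = min(max_lag, length(r) - 1)))
}
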