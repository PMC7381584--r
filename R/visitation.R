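#' Visitation rate: visits per floral unit per minute
#'
#' @param visits non-negative visit count(s).
#' @param floral_units floral units watched (>= 1).
#' @param minutes observation duration (> 0).
#' @return visits / (floral_units * minutes), vectorised.
#' @export
visitation_rate <- function(visits, floral_units, minutes) {
  if (any(floral_units < 1) || any(minutes <= 0)) {
    pn_stop("zero exposure: floral_units must be >= 1 and minutes > 0")
  }
  visits / (floral_units * minutes)
}

#' Long-format model table: one row per observation period x pollinator type
#'
#' Joins filtered observations to site-specific floral abundance and plant
#' native status, stacking honey-bee and wild counts so that the paired
#' rates share an `obs_id`.
#'
#' @param obs filtered observations ([filter_visits()]).
#' @param abundance table from [floral_abundance()].
#' @param plants plant table with native_status.
#' @return Data frame with visits, pollinator_type, abundance,
#'   native_status, floral_units, minutes, obs_id, site, week, plant_id.
#' @export
build_rate_table <- function(obs, abundance, plants) {
  base_cols <- c("obs_id", "site", "week", "plant_id", "floral_units",
                 "minutes")
  long <- rbind(
    data.frame(obs[, base_cols], pollinator_type = "honey_bee",
               visits = obs$honey_bee_visits),
    data.frame(obs[, base_cols], pollinator_type = "wild",
               visits = obs$wild_visits)
  )
  key <- paste(long$site, long$plant_id)
  akey <- paste(abundance$site, abundance$plant_id)
  long$abundance <- abundance$abundance[match(key, akey)]
  long$native_status <- plants$native_status[match(long$plant_id,
                                                   plants$plant_id)]
  drop <- is.na(long$abundance) | !long$native_status %in%
    c("native", "introduced")
  if (any(drop)) {
    pn_warn(sum(drop), " row(s) without abundance or analysable status dropped")
    long <- long[!drop, , drop = FALSE]
  }
  rownames(long) <- NULL
  long
}

.transform_abundance <- function(x, transform) {
  switch(transform,
         identity = x,
         log1p = log1p(x),
         log = log(x),
         pn_stop("unknown abundance transform: ", transform))
}

# cluster-robust covariance for a MASS::glm.nb fit (log link, NB2).
# score_i(beta) = (y_i - mu_i) * theta / (theta + mu_i) * x_i = x_i w_i e_i
# with working weights w_i = mu_i * theta / (theta + mu_i) and working
# residuals e_i = (y_i - mu_i) / mu_i. CR2 deflates each cluster's
# residuals by (I - H_gg)^{-1/2} in the sqrt(W) metric, which removes most
# of the small-G downward bias of the plain (CR1) sandwich.
cluster_vcov_nb <- function(fit, cluster, type = c("CR2", "CR1")) {
  type <- match.arg(type)
  X <- model.matrix(fit)
  y <- fit$y
  mu <- fit$fitted.values
  theta <- fit$theta
  w <- mu * theta / (theta + mu)
  e <- (y - mu) / mu
  g <- as.factor(cluster)
  bread <- vcov(fit)
  if (type == "CR1") {
    sg <- rowsum(X * (w * e), g)
  } else {
    sw <- sqrt(w)
    U <- X * sw
    XtWXinv <- chol2inv(chol(crossprod(U)))
    sg <- matrix(0, nlevels(g), ncol(X))
    for (k in seq_len(nlevels(g))) {
      idx <- which(g == levels(g)[k])
      Ug <- U[idx, , drop = FALSE]
      P <- Ug %*% XtWXinv %*% t(Ug)
      M <- diag(length(idx)) - P
      es <- eigen(M, symmetric = TRUE)
      # Moore-Penrose style: a (near-)singular direction means the cluster
      # fully determines some coefficient; no finite CR2 inflation exists
      # there, so that direction contributes as-is rather than exploding
      lam_is <- ifelse(es$values > 1e-8, 1 / sqrt(es$values), 1)
      Ainv_sqrt <- es$vectors %*% (t(es$vectors) * lam_is)
      sg[k, ] <- crossprod(Ug, Ainv_sqrt %*% (sw[idx] * e[idx]))
    }
  }
  meat <- crossprod(sg)
  G <- nlevels(g)
  adj <- if (type == "CR1") G / max(1, G - 1) else 1
  V <- adj * bread %*% meat %*% bread
  (V + t(V)) / 2
}

#' Fit the negative-binomial visitation-rate model
#'
#' Log-link NB2 model of visit counts with `log(floral_units * minutes)` as
#' exposure offset; fixed effects abundance x native status x pollinator
#' type (or any formula passed via `fixed`); random intercepts for
#' observation period, site, week and plant species.
#'
#' Modes: `"mixed"` fits the crossed random intercepts with
#' [lme4::glmer.nb()]; `"robust"` is the documented approximation — a
#' fixed-effects [MASS::glm.nb()] with cluster-robust covariance (clusters =
#' plant species, which subsume the paired rows of an observation period
#' when a plant is watched once per period); `"auto"` tries mixed and falls
#' back. The mode actually run is recorded in the result.
#'
#' @param table long table from [build_rate_table()].
#' @param fixed right-hand-side formula for the fixed effects; default
#'   `~ abund_x * native_status * pollinator_type` where `abund_x` is the
#'   (optionally transformed) abundance.
#' @param mode `"auto"`, `"mixed"`, or `"robust"`.
#' @param abundance_transform `"identity"` (default), `"log1p"`, or `"log"`.
#' @param cluster column name for robust clustering (default `plant_id`).
#' @return Object of class `rate_model_fit`: list with `fit`, `mode`,
#'   `coefficients`, `vcov` (robust in robust mode), `theta`, `logLik`,
#'   `df`, `converged`, `transform`, `data`.
#' @export
fit_rate_model <- function(table,
                           fixed = ~ abund_x * native_status *
                             pollinator_type,
                           mode = c("auto", "mixed", "robust"),
                           abundance_transform = "identity",
                           cluster = "plant_id") {
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  vars <- intersect(c("native_status", "pollinator_type", "plant_type"),
                    names(df))
  for (v in intersect(vars, all.vars(fixed))) {
    df[[v]] <- factor(df[[v]])
    if (nlevels(df[[v]]) < 2) {
      pn_stop("design is rank deficient: factor '", v,
              "' is constant in the data")
    }
  }
  if ("abundance" %in% names(df)) {
    df$abund_x <- .transform_abundance(df$abundance, abundance_transform)
  }
  df$log_exposure <- log(df$floral_units * df$minutes)
  if (any(!is.finite(df$log_exposure))) pn_stop("non-finite log offset")
  fixed_rhs <- paste(deparse(fixed[[2]]), collapse = " ")
  fit <- NULL
  used_mode <- mode
  if (mode %in% c("auto", "mixed")) {
    mixed_formula <- as.formula(paste(
      "visits ~", fixed_rhs,
      "+ offset(log_exposure) + (1 | obs_id) + (1 | site) + (1 | week)",
      "+ (1 | plant_id)"))
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::glmer.nb(mixed_formula, data = df,
                       control = lme4::glmerControl(
                         check.conv.singular = "ignore",
                         calc.derivs = FALSE)))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      if (mode == "mixed") pn_stop("mixed NB fit failed: ",
                                   conditionMessage(fit))
      fit <- NULL
    } else {
      used_mode <- "mixed"
    }
  }
  if (is.null(fit)) {
    glm_formula <- as.formula(paste("visits ~", fixed_rhs,
                                    "+ offset(log_exposure)"))
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(glm_formula, data = df,
                                    control = stats::glm.control(maxit = 100))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(structure(list(fit = NULL, mode = "robust", converged = FALSE,
                            message = conditionMessage(fit)),
                       class = "rate_model_fit"))
    }
    used_mode <- "robust"
  }
  if (used_mode == "mixed") {
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    theta <- lme4::getME(fit, "glmer.nb.theta")
    conv <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0
    wald_df <- Inf
  } else {
    beta <- coef(fit)
    V <- cluster_vcov_nb(fit, df[[cluster]])
    theta <- fit$theta
    conv <- fit$converged %||% TRUE
    wald_df <- length(unique(df[[cluster]])) - 1L
  }
  structure(list(fit = fit, mode = used_mode, coefficients = beta,
                 vcov = V, theta = theta,
                 logLik = as.numeric(logLik(fit)),
                 df = attr(logLik(fit), "df"),
                 wald_df = wald_df,
                 converged = isTRUE(conv),
                 transform = abundance_transform,
                 fixed = fixed, data = df),
            class = "rate_model_fit")
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat("Negative-binomial visitation-rate model (mode:", x$mode, ")\n")
  cat("theta =", format(x$theta, digits = 4),
      " logLik =", format(x$logLik, digits = 6),
      " converged:", x$converged, "\n")
  print(round(cbind(estimate = x$coefficients,
                    se = sqrt(diag(x$vcov))), 4))
  invisible(x)
}

.loglik_of <- function(fit) {
  if (inherits(fit, "rate_model_fit")) {
    list(ll = fit$logLik, df = fit$df)
  } else {
    ll <- logLik(fit)
    list(ll = as.numeric(ll), df = attr(ll, "df"))
  }
}

#' Likelihood-ratio test of two nested fits
#'
#' `chi2 = max(0, 2 * (ll_full - ll_reduced))` with degrees of freedom equal
#' to the parameter-count difference. Accepts `rate_model_fit` objects or
#' anything with a [logLik()] method.
#'
#' @param fit_full,fit_reduced nested fits on the same rows.
#' @param label optional term label for the output row.
#' @return Data frame: term, chisq, df, p.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced, label = NA_character_) {
  a <- .loglik_of(fit_full); b <- .loglik_of(fit_reduced)
  df <- a$df - b$df
  if (df < 0) pn_stop("reduced model has more parameters than full model; ",
                      "models are not nested as given")
  chi2 <- max(0, 2 * (a$ll - b$ll))
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  data.frame(term = label, chisq = chi2, df = df, p = p)
}

# restore-on-exit fixed-seed evaluation so the quasi-MC Tukey integral is
# deterministic without perturbing the caller's RNG stream
.with_fixed_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Tukey-style multiplicity adjustment over a set of contrasts
#'
#' Adjusted p-value for contrast k is `P(max_j |Z_j| > |z_k|)` where `Z` is
#' multivariate normal with the correlation of the contrast estimates — the
#' max-|t| construction underlying Tukey's method, evaluated with a fixed
#' quasi-Monte-Carlo seed when more than two contrasts are involved.
#'
#' @param estimates contrast estimates.
#' @param vcmat their covariance matrix.
#' @param df reference degrees of freedom: `Inf` (default) for a normal
#'   reference, finite for a multivariate-t / t reference (used with
#'   cluster-robust covariances, df = clusters - 1).
#' @return Vector of adjusted p-values.
#' @export
adjust_tukey <- function(estimates, vcmat, df = Inf) {
  vcmat <- as.matrix(vcmat)
  se <- sqrt(diag(vcmat))
  z <- estimates / se
  k <- length(z)
  if (k == 1L) return(2 * .pt_abs(abs(z), df))
  R <- suppressWarnings(stats::cov2cor(vcmat))
  if (!all(is.finite(R)) || !all(is.finite(z))) {
    pn_warn("degenerate contrast covariance; returning unadjusted p-values")
    return(2 * .pt_abs(abs(z), df))
  }
  vapply(seq_len(k), function(i) {
    q <- abs(z[i])
    prob <- .with_fixed_seed(20200617L, {
      if (is.finite(df)) {
        mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k), corr = R,
                      df = as.integer(df),
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-7,
                                                     maxpts = 1e5))
      } else {
        mvtnorm::pmvnorm(lower = rep(-q, k), upper = rep(q, k), corr = R,
                         algorithm = mvtnorm::GenzBretz(abseps = 1e-7,
                                                        maxpts = 1e5))
      }
    })
    min(1, max(0, 1 - as.numeric(prob)))
  }, numeric(1))
}

# two-sided tail with a t or normal reference
.pt_abs <- function(q, df) {
  if (is.finite(df)) stats::pt(-q, df) else pnorm(-q)
}

# model-matrix rows for prototype group combinations (offset-free)
.group_rows <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(
    as.formula(paste("visits ~", paste(deparse(fit$fixed[[2]]),
                                       collapse = " ")))))
  for (v in names(newdata)) {
    if (is.factor(fit$data[[v]])) {
      newdata[[v]] <- factor(newdata[[v]], levels = levels(fit$data[[v]]))
    }
  }
  mf <- stats::model.frame(tt, newdata)
  X <- model.matrix(tt, mf)
  X[, names(fit$coefficients), drop = FALSE]
}

#' Abundance slopes per native status x pollinator type
#'
#' Extracts the four slopes of (transformed) abundance from a three-way
#' interaction fit as linear combinations of coefficients, tests each with
#' a Wald z-test, and compares the two slopes within each pollinator type
#' with the max-|t| (Tukey) adjustment. When the slopes within a type do not
#' differ at `alpha`, the native-status main-effect contrast evaluated at
#' the mean abundance is reported for that type as well.
#'
#' @param fit converged [fit_rate_model()] result containing the three-way
#'   interaction.
#' @param alpha threshold used only to decide whether the at-mean status
#'   contrast is appended.
#' @return List with `slopes`, `slope_differences`, `status_at_mean`
#'   (possibly empty) — data frames of class-`ContrastResult` columns:
#'   label, estimate, se, statistic, p_adj, adjustment.
#' @export
abundance_slopes <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "rate_model_fit"))
  if (!isTRUE(fit$converged)) pn_stop("fit did not converge")
  statuses <- levels(fit$data$native_status)
  types <- levels(fit$data$pollinator_type)
  beta <- fit$coefficients
  V <- fit$vcov
  proto <- expand.grid(native_status = statuses, pollinator_type = types,
                       stringsAsFactors = FALSE)
  L <- t(vapply(seq_len(nrow(proto)), function(i) {
    nd0 <- data.frame(abund_x = 0, proto[i, , drop = FALSE])
    nd1 <- data.frame(abund_x = 1, proto[i, , drop = FALSE])
    as.numeric(.group_rows(fit, nd1) - .group_rows(fit, nd0))
  }, numeric(length(beta))))
  if (qr(L)$rank < nrow(L)) {
    pn_stop("rank-deficient contrast: the abundance x status x type ",
            "interaction terms are missing from the fit")
  }
  est <- as.numeric(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  wdf <- fit$wald_df %||% Inf
  slopes <- data.frame(
    label = paste(proto$native_status, proto$pollinator_type, sep = ":"),
    native_status = proto$native_status,
    pollinator_type = proto$pollinator_type,
    estimate = est, se = se, statistic = est / se,
    p_adj = 2 * .pt_abs(abs(est / se), wdf), adjustment = "none")
  diffs <- lapply(types, function(tp) {
    i1 <- which(proto$pollinator_type == tp & proto$native_status ==
                  statuses[1])
    i2 <- which(proto$pollinator_type == tp & proto$native_status ==
                  statuses[2])
    D <- L[i2, , drop = FALSE] - L[i1, , drop = FALSE]
    dest <- as.numeric(D %*% beta)
    dv <- D %*% V %*% t(D)
    data.frame(label = paste0(tp, ": ", statuses[2], " - ", statuses[1]),
               pollinator_type = tp, estimate = dest,
               se = sqrt(diag(dv)), statistic = dest / sqrt(diag(dv)),
               p_adj = adjust_tukey(dest, dv, df = wdf),
               adjustment = "tukey")
  })
  diffs <- do.call(rbind, diffs)
  at_mean <- list()
  abar <- mean(fit$data$abund_x)
  for (tp in types) {
    if (diffs$p_adj[diffs$pollinator_type == tp] > alpha) {
      nd1 <- data.frame(abund_x = abar, native_status = statuses[2],
                        pollinator_type = tp)
      nd0 <- data.frame(abund_x = abar, native_status = statuses[1],
                        pollinator_type = tp)
      D <- .group_rows(fit, nd1) - .group_rows(fit, nd0)
      dest <- as.numeric(D %*% beta)
      dv <- D %*% V %*% t(D)
      at_mean[[tp]] <- data.frame(
        label = paste0(tp, ": status main effect at mean abundance"),
        pollinator_type = tp, estimate = dest, se = sqrt(diag(dv)),
        statistic = dest / sqrt(diag(dv)),
        p_adj = 2 * .pt_abs(abs(dest / sqrt(diag(dv))), wdf),
        adjustment = "none")
    }
  }
  list(slopes = slopes, slope_differences = diffs,
       status_at_mean = if (length(at_mean)) do.call(rbind, at_mean)
       else data.frame())
}

#' Knapweed versus coflowering plants contrast
#'
#' Restricts nothing itself (pass the table for the knapweed flowering
#' window), derives `plant_type` from the knapweed id set, fits the same NB
#' offset model with pollinator type x plant type fixed effects, and
#' returns Tukey-adjusted pairwise comparisons of the four group means on
#' the visitation-rate scale, plus the interaction LRT.
#'
#' @param table long table ([build_rate_table()]) for the flowering window.
#' @param knapweed_ids plant ids counted as knapweed.
#' @inheritParams fit_rate_model
#' @return List: `fit`, `means` (group means on the rate scale),
#'   `pairwise` (Tukey-adjusted), `interaction_lrt`.
#' @export
knapweed_contrast <- function(table, knapweed_ids = "CENTAUREA",
                              mode = c("auto", "mixed", "robust")) {
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  df$plant_type <- ifelse(df$plant_id %in% knapweed_ids, "knapweed",
                          "coflowering")
  if (!any(df$plant_type == "knapweed")) pn_stop("no knapweed rows in table")
  df$plant_type <- factor(df$plant_type,
                          levels = c("coflowering", "knapweed"))
  # robust clustering by plant would leave the knapweed indicator identified
  # from a single cluster; the observation-period pairing is the right unit
  fit <- fit_rate_model(df, fixed = ~ pollinator_type * plant_type,
                        mode = mode, cluster = "obs_id")
  if (!isTRUE(fit$converged)) return(list(fit = fit, means = NULL,
                                          pairwise = NULL,
                                          interaction_lrt = NULL))
  red <- fit_rate_model(df, fixed = ~ pollinator_type + plant_type,
                        mode = fit$mode, cluster = "obs_id")
  lrt <- likelihood_ratio_test(fit, red, label = "pollinator_type:plant_type")
  proto <- expand.grid(pollinator_type = levels(fit$data$pollinator_type),
                       plant_type = levels(fit$data$plant_type),
                       stringsAsFactors = FALSE)
  X <- t(vapply(seq_len(nrow(proto)), function(i) {
    as.numeric(.group_rows(fit, proto[i, , drop = FALSE]))
  }, numeric(length(fit$coefficients))))
  eta <- as.numeric(X %*% fit$coefficients)
  means <- data.frame(proto,
                      rate = exp(eta),
                      se_log = sqrt(diag(X %*% fit$vcov %*% t(X))))
  cmb <- utils::combn(nrow(proto), 2)
  D <- t(apply(cmb, 2, function(ix) X[ix[1], ] - X[ix[2], ]))
  dest <- as.numeric(D %*% fit$coefficients)
  dv <- D %*% fit$vcov %*% t(D)
  pairwise <- data.frame(
    label = apply(cmb, 2, function(ix) {
      paste(paste(proto[ix[1], ], collapse = "/"), "-",
            paste(proto[ix[2], ], collapse = "/"))
    }),
    estimate = dest, se = sqrt(diag(dv)), statistic = dest / sqrt(diag(dv)),
    p_adj = adjust_tukey(dest, dv, df = fit$wald_df %||% Inf),
    adjustment = "tukey")
  list(fit = fit, means = means, pairwise = pairwise, interaction_lrt = lrt)
}
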