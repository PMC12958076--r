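#' Prior specification for the factorial logistic models
#'
#' Independent zero-mean normal priors on the log-odds scale. Defaults are
#' weakly informative: SD 1 on reminder framing/timing/interaction effects
#' (an OR of about 0.14-7 within 2 SD), SD 2.5 on the intercept and on age
#' and calendar-epoch adjustments, and scale 1 for clinic and parent
#' effects. These keep estimates finite under separation (an arm cell with
#' all-0 or all-1 outcomes) while remaining dominated by data at trial
#' sample sizes.
#'
#' @param sd_intercept,sd_effects,sd_age,sd_epoch Prior SDs for the
#'   corresponding coefficient blocks.
#' @param sd_clinic_scale,sd_parent_scale Scale of clinic / parent random
#'   effects. Both engines use this as a fixed prior SD on the effects by
#'   default; the MCMC engine can instead sample the SD under a half-Normal
#'   with this scale (`hierarchical = TRUE` in [model_spec()]).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(sd_intercept = 2.5, sd_effects = 1, sd_age = 2.5,
                       sd_epoch = 2.5, sd_clinic_scale = 1,
                       sd_parent_scale = 1) {
  x <- list(sd_intercept = sd_intercept, sd_effects = sd_effects,
            sd_age = sd_age, sd_epoch = sd_epoch,
            sd_clinic_scale = sd_clinic_scale,
            sd_parent_scale = sd_parent_scale)
  if (any(unlist(x) <= 0)) stop("prior SDs must be positive", call. = FALSE)
  structure(x, class = "prior_spec")
}

#' Specify one of the five pre-specified model structures
#'
#' The primary analysis fits a logistic model for on-time vaccination with
#' a full timing-by-framing interaction structure; four reduced models drop
#' the interactions, keep only framing, keep only timing, or pool all 12
#' reminder combinations into a single shared effect. Every structure
#' adjusts for child age (schedule point), calendar epoch of the due date
#' (4-week intervals) and source clinic; all-occasion (secondary) analyses
#' add parent effects.
#'
#' @param structure One of `"full"`, `"no_interaction"`, `"framing_only"`,
#'   `"timing_only"`, `"shared"`.
#' @param unit `"index"` (one row per parent: the primary analysis) or
#'   `"all_occasions"` (secondary; includes parent effects).
#' @param heterogeneity Logical; model the reminder effect separately per
#'   schedule point (secondary heterogeneity analysis; `shared` structure
#'   only).
#' @param engine `"laplace"` (posterior mode of the penalised model plus a
#'   multivariate-normal approximation — fast, used inside replicate
#'   simulations) or `"mcmc"` (JAGS, for one-shot analyses).
#' @param n_draws Number of retained joint posterior draws (default 10000).
#' @param priors A [prior_spec()].
#' @param hierarchical MCMC only: sample the clinic (and parent) effect SD
#'   under a half-Normal prior instead of fixing the prior scale.
#' @param min_epoch_n Epochs with fewer observations are pooled with their
#'   neighbour before encoding (default 10).
#' @param seed Optional seed for the posterior draws.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(structure = c("full", "no_interaction",
                                     "framing_only", "timing_only",
                                     "shared"),
                       unit = c("index", "all_occasions"),
                       heterogeneity = FALSE,
                       engine = c("laplace", "mcmc"),
                       n_draws = 10000L,
                       priors = prior_spec(),
                       hierarchical = FALSE,
                       min_epoch_n = 10L,
                       seed = NULL) {
  structure <- match.arg(structure)
  unit <- match.arg(unit)
  engine <- match.arg(engine)
  if (heterogeneity && structure != "shared")
    stop("heterogeneity by schedule point is defined for the shared ",
         "structure", call. = FALSE)
  stopifnot(inherits(priors, "prior_spec"), n_draws >= 1)
  structure(list(structure = structure, unit = unit,
                 heterogeneity = heterogeneity, engine = engine,
                 n_draws = as.integer(n_draws), priors = priors,
                 hierarchical = hierarchical,
                 min_epoch_n = as.integer(min_epoch_n), seed = seed),
            class = "model_spec")
}

# pool factor levels (ordered numerically) with < min_n observations into
# their left neighbour (first level pools rightward)
pool_sparse_levels <- function(x, min_n) {
  lev <- sort(unique(x))
  if (length(lev) <= 1L) return(match(x, lev))
  cnt <- tabulate(match(x, lev))
  grp <- seq_along(lev)
  for (i in seq_along(lev)) {
    if (cnt[i] < min_n) {
      j <- if (i == 1L) 2L else i - 1L
      tgt <- grp[j]
      cnt[tgt] <- cnt[tgt] + cnt[i]
      cnt[i] <- 0L
      grp[grp == grp[i]] <- tgt
    }
  }
  match(grp, sort(unique(grp)))[match(x, lev)]
}

#' Build the design for a factorial logistic model
#'
#' Produces the response vector, a sparse indicator design matrix, the
#' per-column prior SDs, and the 13 x p map from model coefficients to
#' per-arm log odds ratios versus control. Occasions must have complete
#' follow-up with status `ontime`/`not_ontime`; `excluded_early` and
#' pending rows are dropped. For the index unit only `is_index` rows are
#' kept (one per parent). Reference levels: control arm, day-14 timing and
#' neutral framing for interactions, first observed schedule point, first
#' observed epoch. Epochs thinner than `min_epoch_n` are pooled with a
#' neighbour; clinic (and parent) indicators enter without a reference and
#' are shrunk by their prior scale.
#'
#' @param occasions Occasion-level data with columns `arm`,
#'   `schedule_point`, `epoch`, `clinic_id`, `parent_id`, `status`, and
#'   `is_index` when `spec$unit == "index"`.
#' @param spec A [model_spec()].
#' @return A list of class `sms_design`: `y`, `X` (dgCMatrix), `prior_sd`,
#'   `arm_map`, `blocks` (named column index list), `age_levels`,
#'   `epoch_levels`, `n_by_arm`, `spec`.
#' @export
build_design <- function(occasions, spec) {
  at <- arm_table()
  occ <- occasions[!is.na(occasions$status) &
                     occasions$status %in% c("ontime", "not_ontime"), ,
                   drop = FALSE]
  if (spec$unit == "index") {
    if (!"is_index" %in% names(occ))
      stop("index unit requires an is_index column", call. = FALSE)
    occ <- occ[occ$is_index %in% TRUE, , drop = FALSE]
  }
  if (nrow(occ) == 0L) stop("no analysable occasions", call. = FALSE)
  k <- match(occ$arm, at$arm)
  if (anyNA(k)) stop("unknown arm label in data", call. = FALSE)

  n <- nrow(occ)
  y <- as.integer(occ$status == "ontime")
  pr <- spec$priors

  cols <- list()   # each: list(name, sd, i (row idx), j always 1 col)
  add_dummy <- function(name, rows, sd) {
    cols[[length(cols) + 1L]] <<- list(name = name, rows = rows, sd = sd)
  }
  add_dummy("(Intercept)", seq_len(n), pr$sd_intercept)

  framing <- as.character(at$framing[k])
  timing <- as.character(at$timing[k])
  framings <- c("neutral", "positive", "risk", "social")
  timings <- c("day-14", "day0", "day+7")

  st <- spec$structure
  if (st %in% c("full", "no_interaction", "framing_only")) {
    for (f in framings)
      add_dummy(paste0("framing:", f), which(framing == f), pr$sd_effects)
  }
  if (st %in% c("full", "no_interaction")) {
    for (t in c("day0", "day+7"))
      add_dummy(paste0("timing:", t), which(timing == t), pr$sd_effects)
  }
  if (st == "timing_only") {
    for (t in timings)
      add_dummy(paste0("timing:", t), which(timing == t), pr$sd_effects)
  }
  if (st == "full") {
    for (f in c("positive", "risk", "social"))
      for (t in c("day0", "day+7"))
        add_dummy(paste0("ix:", f, ":", t),
                  which(framing == f & timing == t), pr$sd_effects)
  }
  if (st == "shared" && !spec$heterogeneity)
    add_dummy("any_sms", which(framing != "control"), pr$sd_effects)
  if (st == "shared" && spec$heterogeneity) {
    for (s in sort(unique(occ$schedule_point)))
      add_dummy(paste0("any_sms:", s),
                which(framing != "control" & occ$schedule_point == s),
                pr$sd_effects)
  }

  age_levels <- sort(unique(occ$schedule_point))
  if (length(age_levels) > 1L)
    for (s in age_levels[-1L])
      add_dummy(paste0("age:", s), which(occ$schedule_point == s), pr$sd_age)

  ep_grp <- pool_sparse_levels(occ$epoch, spec$min_epoch_n)
  ep_lab <- vapply(seq_len(max(ep_grp)), function(g)
    as.character(min(occ$epoch[ep_grp == g])), character(1))
  if (max(ep_grp) > 1L)
    for (g in 2:max(ep_grp))
      add_dummy(paste0("epoch:", ep_lab[g]), which(ep_grp == g), pr$sd_epoch)

  clinics <- sort(unique(occ$clinic_id))
  for (cl in clinics)
    add_dummy(paste0("clinic:", cl), which(occ$clinic_id == cl),
              pr$sd_clinic_scale)
  if (spec$unit == "all_occasions") {
    for (p_ in sort(unique(occ$parent_id)))
      add_dummy(paste0("parent:", p_), which(occ$parent_id == p_),
                pr$sd_parent_scale)
  }

  nm <- vapply(cols, `[[`, character(1), "name")
  sd <- vapply(cols, `[[`, numeric(1), "sd")
  ii <- unlist(lapply(cols, `[[`, "rows"))
  jj <- rep.int(seq_along(cols), vapply(cols, function(c) length(c$rows),
                                        integer(1)))
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, length(cols)),
                            dimnames = list(NULL, nm))

  # 13 x p map: coefficient combination giving each arm's log-OR vs control
  A <- matrix(0, 13L, length(cols), dimnames = list(at$arm, nm))
  for (a in 2:13) {
    f <- as.character(at$framing[a]); t <- as.character(at$timing[a])
    pick <- function(col) if (col %in% nm) A[a, col] <<- 1
    if (st %in% c("full", "no_interaction", "framing_only"))
      pick(paste0("framing:", f))
    if (st %in% c("full", "no_interaction", "timing_only"))
      pick(paste0("timing:", t))
    if (st == "full") pick(paste0("ix:", f, ":", t))
    if (st == "shared" && !spec$heterogeneity) pick("any_sms")
    if (st == "shared" && spec$heterogeneity) {
      # equal-weight average over observed schedule points
      sc <- grep("^any_sms:", nm)
      A[a, sc] <- 1 / length(sc)
    }
  }

  blocks <- split(seq_along(nm),
                  sub("^(framing|timing|ix|age|epoch|clinic|parent|any_sms).*",
                      "\\1", nm))
  n_by_arm <- stats::setNames(tabulate(k, 13L), at$arm)

  structure(list(y = y, X = X, prior_sd = sd, arm_map = A, blocks = blocks,
                 age_levels = age_levels,
                 epoch_levels = as.integer(ep_lab),
                 n_by_arm = n_by_arm, spec = spec),
            class = "sms_design")
}

# ridge-penalised IRLS for Bernoulli-logit; returns mode and upper Cholesky
# of the negative log-posterior Hessian
penalised_logistic_mode <- function(X, y, prior_prec, start = NULL,
                                    max_iter = 50L, tol = 1e-9) {
  p <- ncol(X)
  b <- if (is.null(start)) numeric(p) else start
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- as.matrix(Matrix::crossprod(sqrt(w) * X))
    diag(H) <- diag(H) + prior_prec
    g <- as.numeric(Matrix::crossprod(X, y - mu)) - prior_prec * b
    R <- chol(H)
    d <- backsolve(R, forwardsolve(t(R), g))
    # step-halving safeguard
    step <- 1
    repeat {
      bn <- b + step * d
      if (max(abs(bn)) < 50 || step < 1e-4) break
      step <- step / 2
    }
    b <- bn
    if (max(abs(step * d)) < tol) { converged <- TRUE; break }
  }
  eta <- as.numeric(X %*% b)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- as.matrix(Matrix::crossprod(sqrt(w) * X))
  diag(H) <- diag(H) + prior_prec
  list(mode = stats::setNames(b, colnames(X)), chol_H = chol(H),
       converged = converged, iterations = it)
}

#' Fit the posterior of a factorial logistic model
#'
#' `engine = "laplace"`: finds the posterior mode of the penalised model by
#' iteratively reweighted least squares and samples `n_draws` coefficient
#' vectors from the multivariate-normal approximation with covariance equal
#' to the inverse Hessian at the mode. `engine = "mcmc"`: samples the same
#' posterior by Gibbs/Metropolis via JAGS (package \pkg{rjags}), optionally
#' with a hierarchical half-Normal prior on the clinic/parent effect SD.
#' Separation is handled by the proper priors; non-convergence is flagged
#' on the returned object (and warned about), never silent.
#'
#' @param design An [build_design()] result.
#' @param spec Optional [model_spec()] override (defaults to the one the
#'   design was built with).
#' @param start Optional coefficient start values (warm start across
#'   interim analyses).
#' @return An object of class `sms_fit`: `draws` (n_draws x p matrix),
#'   `mode`, `design`, `spec`, `diagnostics`.
#' @export
fit_posterior <- function(design, spec = design$spec, start = NULL) {
  stopifnot(inherits(design, "sms_design"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  prior_prec <- 1 / design$prior_sd^2
  p <- ncol(design$X)

  # a treatment cell with all-0 or all-1 outcomes has no finite MLE; the
  # proper priors keep the posterior well defined, but say so
  arm_cols <- unlist(design$blocks[intersect(
    c("framing", "timing", "ix", "any_sms"), names(design$blocks))],
    use.names = FALSE)
  for (j in arm_cols) {
    yj <- design$y[design$X[, j] == 1]
    if (length(yj) && (all(yj == 1L) || all(yj == 0L))) {
      warning("complete separation in a treatment cell; ",
              "estimates rely on the priors")
      break
    }
  }

  if (spec$engine == "laplace") {
    fit <- penalised_logistic_mode(design$X, design$y, prior_prec,
                                   start = start)
    if (!fit$converged)
      warning("Laplace engine did not converge; result is flagged")
    if (max(abs(fit$mode)) > 10)
      warning("extreme coefficient at the posterior mode; ",
              "possible separation held in check by the priors")
    z <- matrix(stats::rnorm(spec$n_draws * p), p, spec$n_draws)
    draws <- t(fit$mode + backsolve(fit$chol_H, z))
    colnames(draws) <- colnames(design$X)
    diag <- list(engine = "laplace", converged = fit$converged,
                 iterations = fit$iterations)
    chol_H <- fit$chol_H
  } else {
    dm <- fit_posterior_jags(design, spec)
    draws <- dm$draws
    fit <- list(mode = colMeans(draws))
    diag <- dm$diagnostics
    chol_H <- NULL
    if (!diag$converged)
      warning("MCMC diagnostics exceeded threshold; result is flagged")
  }

  structure(list(draws = draws, mode = fit$mode, chol_H = chol_H,
                 design = design, spec = spec, diagnostics = diag),
            class = "sms_fit")
}

fit_posterior_jags <- function(design, spec) {
  if (!requireNamespace("rjags", quietly = TRUE))
    stop("engine = \"mcmc\" requires the rjags package", call. = FALSE)
  X <- as.matrix(design$X)
  p <- ncol(X)
  re_cols <- unlist(design$blocks[intersect(c("clinic", "parent"),
                                            names(design$blocks))],
                    use.names = FALSE)
  hier <- isTRUE(spec$hierarchical) && length(re_cols) > 0L
  prior_prec <- 1 / design$prior_sd^2

  if (!hier) {
    model <- "
model {
  for (i in 1:n) {
    y[i] ~ dbern(ilogit(inprod(X[i, ], beta[])))
  }
  for (j in 1:p) { beta[j] ~ dnorm(0, prec[j]) }
}"
    data <- list(y = design$y, X = X, n = nrow(X), p = p, prec = prior_prec)
    monitor <- "beta"
  } else {
    fe <- setdiff(seq_len(p), re_cols)
    model <- "
model {
  for (i in 1:n) {
    y[i] ~ dbern(ilogit(inprod(Xf[i, ], beta[]) + inprod(Xr[i, ], u[])))
  }
  for (j in 1:pf) { beta[j] ~ dnorm(0, prec[j]) }
  for (j in 1:pr) { u[j] ~ dnorm(0, pow(sigma_re, -2)) }
  sigma_re ~ dnorm(0, pow(re_scale, -2)) T(0, )
}"
    data <- list(y = design$y, Xf = X[, fe, drop = FALSE],
                 Xr = X[, re_cols, drop = FALSE], n = nrow(X),
                 pf = length(fe), pr = length(re_cols),
                 prec = prior_prec[fe],
                 re_scale = spec$priors$sd_clinic_scale)
    monitor <- c("beta", "u", "sigma_re")
  }

  jm <- rjags::jags.model(textConnection(model), data = data, n.chains = 1L,
                          quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = if (is.null(spec$seed))
                                         sample.int(1e6, 1) else spec$seed))
  stats::update(jm, 1000L, progress.bar = "none")
  sm <- rjags::coda.samples(jm, monitor, n.iter = spec$n_draws,
                            progress.bar = "none")
  draws <- as.matrix(sm[[1L]])
  if (!hier) {
    colnames(draws) <- colnames(X)
  } else {
    fe <- setdiff(seq_len(p), re_cols)
    sigma_draws <- draws[, "sigma_re"]
    out <- matrix(0, nrow(draws), p, dimnames = list(NULL, colnames(X)))
    out[, fe] <- draws[, grep("^beta", colnames(draws)), drop = FALSE]
    out[, re_cols] <- draws[, grep("^u", colnames(draws)), drop = FALSE]
    attr(out, "sigma_re") <- sigma_draws
    draws <- out
  }
  ess <- tryCatch(
    if (requireNamespace("coda", quietly = TRUE))
      min(coda::effectiveSize(sm[[1L]][, seq_len(min(5L, p))])) else NA_real_,
    error = function(e) NA_real_)
  list(draws = draws,
       diagnostics = list(engine = "mcmc",
                          converged = is.na(ess) || ess > 100,
                          min_ess = ess))
}

#' Per-arm posterior summaries
#'
#' Maps coefficient draws to per-arm conditional log odds ratios versus
#' control (via the structure's arm map), then summarises each reminder
#' arm: posterior median OR, central 95% credible interval, `Pr(OR > 1)`,
#' `Pr(best)` (the fraction of draws in which the arm's conditional
#' log-odds is maximal among *active* reminder arms; ties share their draw
#' equally; control is excluded, matching the response-adaptive weighting),
#' the variance of the arm's log-OR draws, and the arm's sample size.
#'
#' @param fit An [fit_posterior()] result.
#' @param active_arms Character vector of active SMS arms for `Pr(best)`
#'   (default: all 12).
#' @return Data frame of class `sms_arm_summary`, one row per SMS arm.
#' @export
summarise_arms <- function(fit, active_arms = sms_arms()) {
  stopifnot(inherits(fit, "sms_fit"))
  at <- arm_table()
  A <- fit$design$arm_map[-1L, , drop = FALSE]  # 12 x p
  lor <- fit$draws %*% t(A)                     # n_draws x 12

  act <- colnames(lor) %in% active_arms
  if (!any(act)) stop("no active arms", call. = FALSE)
  sub <- lor[, act, drop = FALSE]
  mx <- do.call(pmax, as.data.frame(sub))
  is_best <- sub == mx
  pb_act <- colMeans(is_best / rowSums(is_best))
  pr_best <- stats::setNames(numeric(ncol(lor)), colnames(lor))
  pr_best[act] <- pb_act

  q <- apply(lor, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  out <- data.frame(
    arm = colnames(lor),
    framing = as.character(at$framing[match(colnames(lor), at$arm)]),
    timing = as.character(at$timing[match(colnames(lor), at$arm)]),
    median_or = exp(q[2L, ]),
    cri_low = exp(q[1L, ]),
    cri_high = exp(q[3L, ]),
    pr_gt_1 = colMeans(lor > 0),
    pr_best = unname(pr_best),
    var_logodds = apply(lor, 2L, stats::var),
    n = unname(fit$design$n_by_arm[colnames(lor)]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("sms_arm_summary", "data.frame")
  out
}

#' Posterior probability that a log-odds contrast is positive
#'
#' For a Laplace fit the posterior of any linear contrast `a' beta` is
#' exactly normal, so its tail probability `Pr(a' beta > 0)` is available
#' in closed form — free of Monte Carlo granularity, which matters when
#' interim stopping rules compare it against thresholds like 0.9995. For
#' an MCMC fit it falls back to the fraction of positive draws.
#'
#' @param fit An [fit_posterior()] result.
#' @param contrasts Numeric vector (one contrast) or matrix (one row per
#'   contrast, columns matching the design coefficients).
#' @return Numeric vector of probabilities.
#' @export
pr_positive <- function(fit, contrasts) {
  if (is.null(dim(contrasts))) contrasts <- rbind(contrasts)
  if (!is.null(fit$chol_H)) {
    m <- as.numeric(contrasts %*% fit$mode)
    # var(a'beta) = ||R^-T a||^2 where H = R'R
    s <- sqrt(colSums(forwardsolve(t(fit$chol_H), t(contrasts))^2))
    stats::pnorm(m / s)
  } else {
    as.numeric(colMeans(fit$draws %*% t(contrasts) > 0))
  }
}

#' Marginal standardised differences in on-time proportion
#'
#' For each posterior draw, predicts the on-time probability at the most
#' recent calendar epoch for a "typical" clinic (and parent), i.e. random
#' effects set to zero, separately at every schedule point; takes the
#' simple average over schedule points; and differences each arm against
#' control. Summarised as posterior median and central 95% interval.
#'
#' @param fit An [fit_posterior()] result.
#' @param arms Arms to report (default all 12 SMS arms).
#' @return Data frame `arm`, `median`, `cri_low`, `cri_high` of the
#'   absolute difference in proportion vaccinated on time.
#' @export
marginal_difference <- function(fit, arms = sms_arms()) {
  stopifnot(inherits(fit, "sms_fit"))
  des <- fit$design
  if (is.null(des$epoch_levels) || !length(des$epoch_levels))
    stop("design lacks an epoch encoding", call. = FALSE)
  draws <- fit$draws
  nd <- nrow(draws)

  b0 <- draws[, "(Intercept)"]
  latest <- max(des$epoch_levels)
  ep_col <- paste0("epoch:", latest)
  ep <- if (ep_col %in% colnames(draws)) draws[, ep_col] else 0

  # n_draws x n_points matrix of control linear predictors
  eta0 <- vapply(des$age_levels, function(s) {
    ac <- paste0("age:", s)
    b0 + ep + if (ac %in% colnames(draws)) draws[, ac] else 0
  }, numeric(nd))
  p_control <- rowMeans(stats::plogis(eta0))

  A <- des$arm_map[arms, , drop = FALSE]
  out <- lapply(arms, function(a) {
    lor <- as.numeric(draws %*% A[a, ])
    diff <- rowMeans(stats::plogis(eta0 + lor)) - p_control
    qq <- stats::quantile(diff, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(arm = a, median = qq[2L], cri_low = qq[1L], cri_high = qq[3L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
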