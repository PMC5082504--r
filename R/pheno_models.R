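#' Aggregate fly-level records into vial phenotypes
#'
#' For the DCV survival assay, flies dying within 24 h (death day <= 1) are
#' excluded as injection casualties; flies alive at the end of the 15-day
#' observation window enter at the window bound (configurable); the vial
#' value is the mean death day of the remaining flies. For the sigma assay
#' the vial value is the proportion of infected flies. Vials with no
#' remaining flies are dropped with a warning.
#'
#' @param records data.frame of single-fly records with columns `ril_id`,
#'   `vial_id`, `date`, `assay` and, for `dcv`, `day` (death day, 1..15) plus
#'   optional logical `censored` (alive at day 15); for `sigma`, `infected`
#'   (0/1).
#' @param censor_day end of the observation window (default 15).
#' @param include_censored include survivors at `censor_day` (default TRUE);
#'   if FALSE they are dropped from the vial mean.
#' @return A data.frame of vials: `ril_id`, `vial_id`, `date`, `assay`,
#'   `n_flies`, `value`.
#' @export
build_vial_phenotypes <- function(records, censor_day = 15,
                                  include_censored = TRUE) {
  stopifnot(is.data.frame(records))
  assay <- unique(records$assay)
  if (length(assay) != 1)
    stop("records mix assays: ", paste(assay, collapse = ", "))
  vials_in <- unique(paste(records$ril_id, records$vial_id, records$date,
                           sep = "\r"))
  if (assay == "dcv") {
    cens <- if ("censored" %in% names(records)) as.logical(records$censored)
            else rep(FALSE, nrow(records))
    day <- ifelse(cens, censor_day, records$day)
    keep <- day > 1 & (include_censored | !cens)
    records <- records[keep, , drop = FALSE]
    val <- day[keep]
  } else if (assay == "sigma") {
    val <- records$infected
    if (any(!val %in% c(0, 1))) stop("sigma `infected` must be 0/1")
  } else stop("unknown assay: ", assay)

  if (nrow(records) == 0) {
    warning("all flies excluded; no vials remain")
    return(data.frame(ril_id = character(), vial_id = character(),
                      date = character(), assay = character(),
                      n_flies = integer(), value = numeric()))
  }
  key <- paste(records$ril_id, records$vial_id, records$date, sep = "\r")
  lost <- setdiff(vials_in, unique(key))
  if (length(lost))
    warning(length(lost), " vial(s) dropped: no flies left after exclusions")
  agg <- rowsum(cbind(value = val, n = 1), key)
  meta <- records[!duplicated(key), c("ril_id", "vial_id", "date")]
  meta <- meta[match(rownames(agg), unique(key)), , drop = FALSE]
  out <- data.frame(meta,
                    assay = assay,
                    n_flies = as.integer(agg[, "n"]),
                    value = agg[, "value"] / agg[, "n"],
                    stringsAsFactors = FALSE)
  # report vials that disappeared entirely (all flies excluded)
  rownames(out) <- NULL
  out
}

#' Fit the baseline vial mixed model
#'
#' REML fit of `value ~ 1 + (1 | date) + (1 | ril)`: the vial phenotype is
#' the grand mean plus random injection-date and RIL deviations plus residual
#' error. This is the variance-decomposition model underlying repeatability
#' and the date-corrected RIL BLUPs.
#'
#' @param vials vial data.frame (see [build_vial_phenotypes()] /
#'   [simulate_vials()]); needs columns `ril_id`, `date`, `value`.
#' @return An object of class `model_fit`: grand mean `beta`, variance
#'   components `sigma2_date`, `sigma2_ril`, `sigma2_resid`, the random-effect
#'   deviations, the REML criterion, and the underlying `lmer` fit (or NULL
#'   for degenerate data).
#' @export
fit_baseline <- function(vials) {
  check_vials(vials)
  fit_lmm(vials, fixed = NULL, corrected_for = "none")
}

check_vials <- function(vials) {
  stopifnot(is.data.frame(vials),
            all(c("ril_id", "date", "value") %in% names(vials)))
  if (any(!is.finite(vials$value))) stop("non-finite vial values")
  if (length(unique(vials$ril_id)) < 2) stop("need vials from >= 2 RILs")
  invisible(vials)
}

# Shared REML fitting path for the baseline and QTL-covariate models.
# `fixed` is NULL, a 2-level factor per vial, or a numeric matrix per vial.
fit_lmm <- function(vials, fixed = NULL, corrected_for = "none") {
  vials$date <- factor(vials$date)
  vials$ril_id <- factor(vials$ril_id)
  has_date <- nlevels(vials$date) > 1
  if (!has_date && nlevels(vials$date) == 1)
    warning("single injection date: sigma2_date fixed at 0")

  if (var(vials$value) == 0 && is.null(fixed)) {
    return(structure(list(
      beta = vials$value[1], sigma2_date = 0, sigma2_ril = 0,
      sigma2_resid = 0,
      date_dev = setNames(rep(0, nlevels(vials$date)), levels(vials$date)),
      ril_dev = setNames(rep(0, nlevels(vials$ril_id)), levels(vials$ril_id)),
      logLik = NA_real_, method = "degenerate", fit = NULL, vials = vials,
      has_date = has_date, corrected_for = corrected_for
    ), class = "model_fit"))
  }

  dat <- vials
  fix_txt <- "1"
  if (!is.null(fixed)) {
    if (is.matrix(fixed)) {
      # founder-probability covariate: drop one column for identifiability
      dat <- cbind(dat, as.data.frame(fixed[, -1, drop = FALSE]))
      fix_txt <- paste(c("1", colnames(fixed)[-1]), collapse = " + ")
    } else {
      dat$qtl_class <- factor(fixed)
      fix_txt <- "1 + qtl_class"
    }
  }
  re_txt <- if (has_date) "(1 | date) + (1 | ril_id)" else "(1 | ril_id)"
  form <- as.formula(paste("value ~", fix_txt, "+", re_txt))
  # tight optimizer tolerances: REML estimates on balanced designs should
  # agree with their closed forms well beyond reporting precision
  fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE,
                                     control = lme4::lmerControl(
                                       check.conv.singular = "ignore",
                                       optimizer = "bobyqa",
                                       optCtrl = list(rhobeg = 0.2,
                                                      rhoend = 1e-8))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    i <- which(vc$grp == g)
    if (length(i)) vc$vcov[i] else 0
  }
  re <- lme4::ranef(fit)
  structure(list(
    beta = unname(lme4::fixef(fit)[1]),
    sigma2_date = getv("date"),
    sigma2_ril = getv("ril_id"),
    sigma2_resid = getv("Residual"),
    date_dev = if (has_date) setNames(re$date[[1]], rownames(re$date))
               else setNames(rep(0, nlevels(dat$date)), levels(dat$date)),
    ril_dev = setNames(re$ril_id[[1]], rownames(re$ril_id)),
    logLik = as.numeric(logLik(fit)),
    method = "REML", fit = fit, vials = vials, has_date = has_date,
    corrected_for = corrected_for
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Vial mixed model (", x$method, ")\n", sep = "")
  cat(sprintf("  grand mean      %.4g\n", x$beta))
  cat(sprintf("  sigma2_date     %.4g\n", x$sigma2_date))
  cat(sprintf("  sigma2_ril      %.4g\n", x$sigma2_ril))
  cat(sprintf("  sigma2_resid    %.4g\n", x$sigma2_resid))
  cat(sprintf("  repeatability R %.3f\n",
              x$sigma2_ril / (x$sigma2_ril + x$sigma2_resid)))
  invisible(x)
}

#' Repeatability of the assay with a profile-likelihood interval
#'
#' Repeatability is the fraction of between-vial variance attributable to
#' RIL identity, `R = sigma2_ril / (sigma2_ril + sigma2_resid)` — the
#' single-day repeatability, excluding the between-date variance. The
#' confidence interval profiles the REML criterion over R (re-optimising the
#' date component), falling back to a parametric bootstrap when the profile
#' is uninformative.
#'
#' @param fit a `model_fit` from [fit_baseline()].
#' @param level confidence level (default 0.95).
#' @param nboot bootstrap replicates for the fallback (default 1000).
#' @return An object of class `variance_decomposition`: `R`, `R_ci_95`,
#'   the variance components, and the CI method used.
#' @export
repeatability <- function(fit, level = 0.95, nboot = 1000) {
  stopifnot(inherits(fit, "model_fit"))
  tot <- fit$sigma2_ril + fit$sigma2_resid
  if (tot == 0)
    stop("repeatability undefined: sigma2_ril and sigma2_resid are both 0",
         call. = FALSE)
  R <- fit$sigma2_ril / tot
  ci <- c(NA_real_, NA_real_)
  method <- "none"
  if (!is.null(fit$fit)) {
    ci <- tryCatch(profile_ci_R(fit, level), error = function(e) NULL)
    method <- "profile"
    if (is.null(ci)) {
      ci <- boot_ci_R(fit, level, nboot)
      method <- "bootstrap"
    }
  }
  structure(list(R = R, R_ci_95 = ci, level = level, ci_method = method,
                 sigma2_ril = fit$sigma2_ril, sigma2_resid = fit$sigma2_resid,
                 sigma2_date = fit$sigma2_date),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f (%d%% CI %.3f-%.3f, %s)\n", x$R,
              round(100 * x$level), x$R_ci_95[1], x$R_ci_95[2], x$ci_method))
  invisible(x)
}

# Profile REML criterion over R = t^2/(1+t^2) where t = sd_ril/sd_resid.
profile_ci_R <- function(fit, level = 0.95) {
  m <- fit$fit
  devfun <- lme4::lmer(formula(m), data = m@frame, REML = TRUE,
                       devFunOnly = TRUE,
                       control = lme4::lmerControl(
                         check.conv.singular = "ignore"))
  tn <- names(getME_theta(m))
  i_ril <- grep("^ril_id", tn)
  i_date <- grep("^date", tn)
  th_hat <- getME_theta(m)
  pdev <- function(R) {
    th_r <- sqrt(R / (1 - R))
    if (length(i_date)) {
      th <- th_hat
      th[i_ril] <- th_r
      o <- optimize(function(td) {
        th[i_date] <- td
        devfun(th)
      }, interval = c(0, max(10 * th_hat[i_date], 5)))
      o$objective
    } else {
      th <- th_hat
      th[i_ril] <- th_r
      devfun(th)
    }
  }
  Rhat <- fit$sigma2_ril / (fit$sigma2_ril + fit$sigma2_resid)
  Rhat <- min(max(Rhat, 1e-8), 1 - 1e-8)
  d0 <- pdev(Rhat)
  cut <- d0 + qchisq(level, 1)
  eps <- 1e-6
  # flat profile -> signal for the bootstrap fallback
  if (max(pdev(eps), pdev(1 - eps)) - d0 < 0.05) stop("flat profile")
  lo <- if (pdev(eps) < cut) 0 else
    uniroot(function(R) pdev(R) - cut, c(eps, Rhat), tol = 1e-6)$root
  hi <- if (pdev(1 - eps) < cut) 1 else
    uniroot(function(R) pdev(R) - cut, c(Rhat, 1 - eps), tol = 1e-6)$root
  c(lo, hi)
}

getME_theta <- function(m) lme4::getME(m, "theta")

boot_ci_R <- function(fit, level = 0.95, nboot = 1000) {
  m <- fit$fit
  Rs <- vapply(seq_len(nboot), function(b) {
    y <- unlist(stats::simulate(m, 1))
    v <- fit$vials
    v$value <- y
    f <- tryCatch(fit_lmm(v), error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    tot <- f$sigma2_ril + f$sigma2_resid
    if (tot == 0) NA_real_ else f$sigma2_ril / tot
  }, numeric(1))
  quantile(Rs, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE,
           names = FALSE)
}

#' Best linear unbiased predictors of RIL phenotypic deviations
#'
#' The BLUP is each RIL's shrunken deviation from the grand mean, net of
#' injection-date effects — the phenotype used by the genome scans.
#'
#' @param fit a `model_fit`.
#' @return A data.frame `ril_id`, `blup`, `corrected_for`.
#' @export
ril_blups <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  data.frame(ril_id = names(fit$ril_dev), blup = unname(fit$ril_dev),
             corrected_for = fit$corrected_for, stringsAsFactors = FALSE)
}

#' RIL BLUPs corrected for a QTL
#'
#' Adds the QTL as a fixed effect to the baseline model (either a two-level
#' allele class per RIL, or the eight founder genotype probabilities at the
#' QTL) and returns the RIL deviations net of that fixed effect. Used to
#' rescan the genome for additional QTL after accounting for a major locus.
#'
#' @param vials vial data.frame.
#' @param qtl_covariate either a named character/factor vector (RIL ->
#'   allele class) or a numeric matrix with 8 columns and RIL ids as
#'   rownames (founder probabilities at the QTL).
#' @param label name recorded in `corrected_for`.
#' @return A data.frame `ril_id`, `blup`, `corrected_for`, with the
#'   underlying `model_fit` as attribute `fit`.
#' @export
blups_corrected <- function(vials, qtl_covariate, label = "qtl") {
  check_vials(vials)
  fx <- covariate_for_vials(vials, qtl_covariate)
  if (any(fx$missing)) {
    warning(sum(fx$missing), " RIL(s) lack the covariate; dropped")
    vials <- vials[!fx$missing, , drop = FALSE]
    fx$value <- if (is.matrix(fx$value))
      fx$value[!fx$missing, , drop = FALSE] else fx$value[!fx$missing]
  }
  fixed <- fx$value
  if (!is.matrix(fixed) && length(unique(fixed)) < 2) fixed <- NULL
  fit <- fit_lmm(vials, fixed = fixed, corrected_for = label)
  out <- ril_blups(fit)
  attr(out, "fit") <- fit
  out
}

# Expand a per-RIL covariate to vial rows; returns value + missing flags.
covariate_for_vials <- function(vials, qtl_covariate) {
  if (is.matrix(qtl_covariate)) {
    idx <- match(vials$ril_id, rownames(qtl_covariate))
    v <- qtl_covariate[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    colnames(v) <- paste0("qtl_p", seq_len(ncol(v)))
    list(value = v, missing = is.na(idx))
  } else {
    v <- qtl_covariate[match(vials$ril_id, names(qtl_covariate))]
    list(value = v, missing = is.na(v))
  }
}

# ---- Bayesian variance decomposition ---------------------------------------

#' MCMC settings for the Gibbs sampler
#'
#' @param nitt total iterations (default 13000).
#' @param burnin discarded initial iterations (default 3000).
#' @param thin thinning interval (default 10).
#' @param ess_min effective-sample-size threshold below which results are
#'   flagged as unconverged (default 100).
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(nitt = 13000, burnin = 3000, thin = 10,
                         ess_min = 100) {
  stopifnot(nitt > burnin, thin >= 1)
  structure(list(nitt = nitt, burnin = burnin, thin = thin,
                 ess_min = ess_min), class = "mcmc_control")
}

# Gibbs sampler for y = X b + u_date + u_ril + e with weak inverse-gamma
# (0.001, 0.001) priors on the variances and a flat prior on b.
# Returns a matrix of posterior draws.
gibbs_lmm <- function(y, X, date, ril, control = mcmc_control()) {
  n <- length(y)
  date <- factor(date)
  ril <- factor(ril)
  has_date <- nlevels(date) > 1
  id <- as.integer(date)
  ir <- as.integer(ril)
  nd <- tabulate(id, nlevels(date))
  nr <- tabulate(ir, nlevels(ril))
  p <- ncol(X)
  XtX <- crossprod(X)
  cXtX <- tryCatch(chol(XtX), error = function(e) {
    # collinear fixed effects: ridge-stabilize so the sampler can proceed
    # (the offending covariates are flagged upstream)
    chol(XtX + diag(1e-8 * mean(diag(XtX)), p))
  })
  a0 <- b0 <- 0.001

  vy <- var(y)
  if (vy == 0) vy <- 1e-8
  s2d <- if (has_date) vy / 3 else 0
  s2r <- vy / 3
  s2e <- vy / 3
  ud <- rep(0, nlevels(date))
  ur <- rep(0, nlevels(ril))
  b <- drop(backsolve(cXtX, forwardsolve(t(cXtX), crossprod(X, y))))

  keep <- seq(control$burnin + 1, control$nitt, by = control$thin)
  out <- matrix(NA_real_, length(keep), p + 3,
                dimnames = list(NULL, c(paste0("b", seq_len(p) - 1),
                                        "s2_date", "s2_ril", "s2_e")))
  k <- 0L
  for (it in seq_len(control$nitt)) {
    # fixed effects
    yr <- y - ud[id] - ur[ir]
    mu_b <- backsolve(cXtX, forwardsolve(t(cXtX), crossprod(X, yr)))
    b <- drop(mu_b + backsolve(cXtX, rnorm(p)) * sqrt(s2e))
    xb <- drop(X %*% b)
    # date deviations
    if (has_date) {
      rs <- rowsum(y - xb - ur[ir], id, reorder = TRUE)
      prec <- nd + s2e / s2d
      ud <- rnorm(length(nd), drop(rs) / prec, sqrt(s2e / prec))
      s2d <- 1 / rgamma(1, a0 + length(ud) / 2, b0 + sum(ud^2) / 2)
    }
    # RIL deviations
    rs <- rowsum(y - xb - ud[id], ir, reorder = TRUE)
    prec <- nr + s2e / s2r
    ur <- rnorm(length(nr), drop(rs) / prec, sqrt(s2e / prec))
    s2r <- 1 / rgamma(1, a0 + length(ur) / 2, b0 + sum(ur^2) / 2)
    # residual
    e <- y - xb - ud[id] - ur[ir]
    s2e <- 1 / rgamma(1, a0 + n / 2, b0 + sum(e^2) / 2)
    if (it > control$burnin && (it - control$burnin - 1) %% control$thin == 0) {
      k <- k + 1L
      out[k, ] <- c(b, s2d, s2r, s2e)
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Effective sample size via the initial positive autocorrelation sum.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Proportion of genetic variance explained by a QTL
#'
#' Fits the baseline vial model and the model with the QTL as a fixed effect
#' using a Gibbs sampler, and reports how much the posterior between-RIL
#' variance shrinks: `(median sigma2_ril[baseline] - median sigma2_ril[QTL])
#' / median sigma2_ril[baseline]`. A negative value (sampling noise around a
#' null effect) is reported as-is and flagged.
#'
#' @param vials vial data.frame.
#' @param qtl_covariate as in [blups_corrected()].
#' @param mcmc a [mcmc_control()].
#' @param seed optional integer seed for the sampler.
#' @return A list: `proportion`, `p` (two-sided posterior probability of no
#'   shrinkage), `negative` flag, `ess` (smallest effective sample size of
#'   the monitored variances), `converged`, posterior medians.
#' @export
variance_explained <- function(vials, qtl_covariate, mcmc = mcmc_control(),
                               seed = NULL) {
  check_vials(vials)
  if (!is.null(seed)) set.seed(seed)
  fx <- covariate_for_vials(vials, qtl_covariate)
  if (any(fx$missing)) {
    warning(sum(fx$missing), " RIL(s) lack the covariate; dropped")
    vials <- vials[!fx$missing, , drop = FALSE]
    fx$value <- if (is.matrix(fx$value))
      fx$value[!fx$missing, , drop = FALSE] else fx$value[!fx$missing]
  }
  n <- nrow(vials)
  X1 <- matrix(1, n, 1)
  X3 <- if (is.matrix(fx$value)) {
    cbind(1, fx$value[, -1, drop = FALSE])  # rows sum to 1; drop one column
  } else {
    stats::model.matrix(~ factor(fx$value))
  }
  s1 <- gibbs_lmm(vials$value, X1, vials$date, vials$ril_id, mcmc)
  s3 <- gibbs_lmm(vials$value, X3, vials$date, vials$ril_id, mcmc)
  m1 <- median(s1[, "s2_ril"])
  m3 <- median(s3[, "s2_ril"])
  prop <- (m1 - m3) / m1
  d <- s1[, "s2_ril"] - s3[, "s2_ril"]
  ns <- length(d)
  p <- 2 * min((sum(d <= 0) + 1) / (ns + 1), (sum(d >= 0) + 1) / (ns + 1))
  e <- min(ess(s1[, "s2_ril"]), ess(s3[, "s2_ril"]))
  list(proportion = prop, p = min(p, 1), negative = prop < 0,
       ess = e, converged = e >= mcmc$ess_min,
       sigma2_ril_baseline = m1, sigma2_ril_qtl = m3)
}

#' Joint Bayesian effect sizes of mapped QTL
#'
#' All mapped QTL enter one mixed model simultaneously, each as the per-RIL
#' probability of carrying its resistant allele; a coefficient is the trait
#' change from certainly-susceptible to certainly-resistant. Posterior
#' medians, 95% quantile intervals and two-sided posterior p-values come from
#' the Gibbs sampler; Wald type II tests from the corresponding REML fit are
#' attached so each QTL is also judged net of all others.
#'
#' @param vials vial data.frame.
#' @param resistant_probs named list (one element per QTL) of named numeric
#'   vectors (RIL -> probability of carrying the resistant allele), or a
#'   matrix with RIL rownames and one column per QTL.
#' @param mcmc a [mcmc_control()].
#' @param seed optional integer seed.
#' @param units unit label stored with the estimates (e.g. `"days"`).
#' @return A data.frame of class `effect_estimates`: `qtl_id`, `effect`,
#'   `ci_lo`, `ci_hi`, `p`, `wald_p`, `units`, with attribute `collinear`
#'   naming any covariate pair with |r| > 0.99.
#' @export
effect_sizes_joint <- function(vials, resistant_probs, mcmc = mcmc_control(),
                               seed = NULL, units = "") {
  check_vials(vials)
  if (!is.null(seed)) set.seed(seed)
  if (is.list(resistant_probs)) {
    ids <- Reduce(intersect, lapply(resistant_probs, names))
    rp <- do.call(cbind, lapply(resistant_probs, function(v) v[ids]))
    colnames(rp) <- names(resistant_probs)
    rownames(rp) <- ids
  } else rp <- as.matrix(resistant_probs)
  if (is.null(colnames(rp)))
    colnames(rp) <- paste0("qtl", seq_len(ncol(rp)))

  keep <- vials$ril_id %in% rownames(rp)
  if (!all(keep)) {
    warning(sum(!keep), " vial(s) from RILs without resistant probabilities; dropped")
    vials <- vials[keep, , drop = FALSE]
  }
  Z <- rp[match(vials$ril_id, rownames(rp)), , drop = FALSE]

  collinear <- character()
  if (ncol(Z) > 1) {
    cc <- cor(Z)
    bad <- which(abs(cc) > 0.99 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(bad))
      collinear <- apply(bad, 1, function(i)
        paste(colnames(Z)[i[1]], colnames(Z)[i[2]], sep = "~"))
  }
  if (length(collinear))
    warning("collinear QTL covariates (|r| > 0.99): ",
            paste(collinear, collapse = ", "))

  X <- cbind(`(Intercept)` = 1, Z)
  s <- gibbs_lmm(vials$value, X, vials$date, vials$ril_id, mcmc)
  bcols <- seq_len(ncol(Z)) + 1  # skip intercept
  eff <- apply(s[, bcols, drop = FALSE], 2, median)
  ci <- apply(s[, bcols, drop = FALSE], 2, quantile, c(0.025, 0.975))
  ns <- nrow(s)
  pp <- apply(s[, bcols, drop = FALSE], 2, function(x)
    min(1, 2 * min((sum(x <= 0) + 1) / (ns + 1), (sum(x >= 0) + 1) / (ns + 1))))

  # Wald type II tests (each 1-df QTL term given all others) from REML
  dat <- data.frame(vials, Z, check.names = FALSE)
  has_date <- length(unique(dat$date)) > 1
  re_txt <- if (has_date) "(1 | date) + (1 | ril_id)" else "(1 | ril_id)"
  form <- as.formula(paste("value ~",
                           paste(sprintf("`%s`", colnames(Z)), collapse = " + "),
                           "+", re_txt))
  wald_p <- rep(NA_real_, ncol(Z))
  fitW <- tryCatch(suppressMessages(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore", optimizer = "bobyqa",
                 optCtrl = list(rhobeg = 0.2, rhoend = 1e-9)))),
    error = function(e) NULL)
  if (!is.null(fitW)) {
    bw <- lme4::fixef(fitW)[-1]
    se <- sqrt(diag(as.matrix(vcov(fitW)))[-1])
    wald_p <- 2 * stats::pnorm(-abs(bw / se))
  }

  out <- data.frame(qtl_id = colnames(Z), effect = unname(eff),
                    ci_lo = ci[1, ], ci_hi = ci[2, ], p = unname(pp),
                    wald_p = unname(wald_p), units = units,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "collinear") <- collinear
  attr(out, "ess") <- min(apply(s[, bcols, drop = FALSE], 2, ess))
  class(out) <- c("effect_estimates", "data.frame")
  out
}
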