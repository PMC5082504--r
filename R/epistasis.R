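# Pairwise epistasis between mapped QTL and genomewide modifier-interaction
# scans.

#' Pairwise epistasis test between two mapped QTL
#'
#' Maximum-likelihood fits of the vial mixed model with both QTL allele
#' classes, their interaction, and random injection-date and RIL effects; the
#' interaction is judged by a 1-df likelihood-ratio test against the
#' additive model. The test is skipped when any of the four joint genotype
#' classes has fewer than `min_class_n` RILs (rare or missing genotype
#' combinations make the interaction inestimable).
#'
#' @param vials vial data.frame.
#' @param class_a,class_b named character vectors (RIL -> allele class, two
#'   levels each).
#' @param min_class_n minimum RILs per joint genotype class (default 10).
#' @return An object of class `epistasis_test`: main-effect and interaction
#'   estimates, LRT statistic and p, per-class RIL counts; or, when skipped,
#'   the counts and the reason.
#' @export
pairwise_epistasis <- function(vials, class_a, class_b, min_class_n = 10) {
  check_vials(vials)
  a <- class_a[match(vials$ril_id, names(class_a))]
  b <- class_b[match(vials$ril_id, names(class_b))]
  ok <- !is.na(a) & !is.na(b)
  if (!all(ok)) {
    warning(sum(!ok), " vial(s) without both allele classes; dropped")
    vials <- vials[ok, , drop = FALSE]
    a <- a[ok]
    b <- b[ok]
  }
  rils <- !duplicated(vials$ril_id)
  counts <- table(factor(a[rils]), factor(b[rils]))
  if (length(counts) != 4 || any(counts < min_class_n)) {
    return(structure(list(
      skipped = TRUE, counts = counts,
      reason = sprintf(
        "joint genotype class below min_class_n = %d (counts: %s)",
        min_class_n, paste(as.vector(counts), collapse = "/"))),
      class = "epistasis_test"))
  }
  dat <- data.frame(vials, qa = factor(a), qb = factor(b))
  has_date <- length(unique(dat$date)) > 1
  re <- if (has_date) "(1 | date) + (1 | ril_id)" else "(1 | ril_id)"
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            optimizer = "bobyqa",
                            optCtrl = list(rhobeg = 0.2, rhoend = 1e-9))
  full <- suppressMessages(lme4::lmer(
    as.formula(paste("value ~ qa * qb +", re)), dat, REML = FALSE,
    control = ctrl))
  red <- suppressMessages(lme4::lmer(
    as.formula(paste("value ~ qa + qb +", re)), dat, REML = FALSE,
    control = ctrl))
  lrt <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
  fe <- lme4::fixef(full)
  structure(list(
    skipped = FALSE, counts = counts,
    main_a = unname(fe[2]), main_b = unname(fe[3]),
    interaction = unname(fe[4]),
    lrt = lrt, df = 1, p = stats::pchisq(lrt, 1, lower.tail = FALSE),
    logLik_full = as.numeric(logLik(full)),
    logLik_reduced = as.numeric(logLik(red))),
    class = "epistasis_test")
}

#' @export
print.epistasis_test <- function(x, ...) {
  if (x$skipped) {
    cat("Epistasis test skipped:", x$reason, "\n")
  } else {
    cat(sprintf(
      "Epistasis LRT = %.3f (1 df), p = %.4g; interaction = %.3g\n",
      x$lrt, x$p, x$interaction))
  }
  invisible(x)
}

# Per-position designs for the interaction scan: reduced = [1, q, locus],
# full adds q x locus products. Founder columns with total probability mass
# below min_mass are pooled; one locus column is dropped for identifiability.
modifier_designs <- function(P, q, min_mass) {
  mass <- colSums(P)
  keep <- mass >= min_mass
  M <- P[, keep, drop = FALSE]
  if (any(!keep)) {
    pooled <- rowSums(P[, !keep, drop = FALSE])
    if (sum(pooled) > 0) M <- cbind(M, pooled)
  }
  if (ncol(M) < 2) return(NULL)  # no locus contrast left
  L <- M[, -1, drop = FALSE]
  Xr <- cbind(1, q, L)
  Xf <- cbind(Xr, q * L)
  list(Xr = Xr, Xf = Xf)
}

#' Genome scan for loci that modify a QTL's effect
#'
#' At every grid position, ordinary least-squares fits of
#' `blup ~ qtl + locus + qtl:locus` and of the main-effects-only model are
#' compared; the interaction LOD is the log10 likelihood ratio,
#' `(n/2) log10(RSS_reduced / RSS_full)`. The QTL enters as the per-RIL
#' resistant-allele probability; the locus as its founder probability
#' columns, with founders carrying total probability mass below `min_mass`
#' pooled (degrees of freedom adjusted).
#'
#' @param blups named numeric vector or [ril_blups()] data.frame (corrected
#'   for major QTL as appropriate).
#' @param panel a `ril_panel`.
#' @param qtl_resistant_prob named per-RIL probability of carrying the QTL's
#'   resistant allele (see [resistant_probability()]).
#' @param min_mass minimum founder probability mass (in effective RILs) for a
#'   founder to keep its own column (default 5).
#' @param rows optional subset of grid rows.
#' @return A data.frame of class `interaction_scan`: `arm`, `pos_kb`, `lod`,
#'   `df`; degenerate positions carry NA and are reported.
#' @export
modifier_scan <- function(blups, panel, qtl_resistant_prob, min_mass = 5,
                          rows = NULL) {
  al <- align_to_panel(blups, panel, qtl_resistant_prob)
  if (is.null(rows)) rows <- seq_len(nrow(panel$grid))
  sc <- interaction_core(matrix(al$y, ncol = 1), panel, al$sel,
                         drop(al$C), min_mass, rows)
  out <- data.frame(arm = panel$grid$arm[rows],
                    pos_kb = panel$grid$pos_kb[rows],
                    lod = sc$lod[, 1], df = sc$df, stringsAsFactors = FALSE)
  class(out) <- c("interaction_scan", "data.frame")
  out
}

interaction_core <- function(Y, panel, sel, q, min_mass,
                             rows = seq_len(nrow(panel$grid))) {
  n <- nrow(Y)
  m <- ncol(Y)
  lod <- matrix(NA_real_, length(rows), m)
  df <- rep(NA_integer_, length(rows))
  n_skip <- 0
  for (k in seq_along(rows)) {
    P <- prob_rows(panel, rows[k])[sel, , drop = FALSE]
    if (anyNA(P)) {
      n_skip <- n_skip + 1
      next
    }
    d <- modifier_designs(P, q, min_mass)
    if (is.null(d)) {
      n_skip <- n_skip + 1
      next
    }
    qr_r <- qr(d$Xr)
    qr_f <- qr(d$Xf)
    ddf <- qr_f$rank - qr_r$rank
    if (ddf < 1) {
      # interaction columns are linear combinations of the main effects:
      # the interaction adds nothing, so its LOD is exactly zero
      lod[k, ] <- 0
      df[k] <- 0L
      next
    }
    rss_r <- colSums(qr.resid(qr_r, Y)^2)
    rss_f <- colSums(qr.resid(qr_f, Y)^2)
    lod[k, ] <- safe_lod(n, rss_r, rss_f, colSums(Y^2))
    df[k] <- ddf
  }
  if (n_skip > 0)
    message(n_skip, " position(s) skipped in interaction scan (degenerate design)")
  list(lod = lod, df = df)
}

#' Permutation threshold for the modifier-interaction scan
#'
#' BLUPs are permuted across RILs (the QTL probability stays attached to the
#' genotypes), the interaction scan is rerun in full, and the genomewide
#' maximum interaction LOD is recorded per permutation.
#'
#' @inheritParams modifier_scan
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param alpha genomewide type-I error rate (default 0.05).
#' @param chunk permutations per block.
#' @return The LOD threshold, with the full `permutation_null` attached as
#'   attribute `"null"`.
#' @export
modifier_threshold <- function(blups, panel, qtl_resistant_prob, n_perm = 1000,
                               seed = NULL, alpha = 0.05, min_mass = 5,
                               rows = NULL, chunk = 250) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  al <- align_to_panel(blups, panel, qtl_resistant_prob)
  if (is.null(rows)) rows <- seq_len(nrow(panel$grid))
  n <- length(al$y)
  max_lod <- numeric(0)
  done <- 0
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    Y <- vapply(seq_len(m), function(j) al$y[sample.int(n)], numeric(n))
    sc <- suppressMessages(
      interaction_core(Y, panel, al$sel, drop(al$C), min_mass, rows))
    max_lod <- c(max_lod, apply(sc$lod, 2, max, na.rm = TRUE))
    done <- done + m
  }
  null <- structure(list(n_perm = n_perm, max_lod = max_lod, seed = seed),
                    class = "permutation_null")
  thr <- genomewide_threshold(null, alpha)
  attr(thr, "null") <- null
  thr
}
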