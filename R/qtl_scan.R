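# Founder-haplotype genome scans with permutation genomewide significance.
#
# The scan regresses each RIL's BLUP on the eight founder genotype
# probabilities at a position (intercept + founders 2..8: rows sum to one, so
# one column is dropped; fitted values do not depend on which). The
# F-statistic is converted to a LOD score as (n/2) * log10(RSS0/RSS1).

# Accept either a named numeric vector or the data.frame from ril_blups().
as_blup_vector <- function(blups) {
  if (is.data.frame(blups)) return(setNames(blups$blup, blups$ril_id))
  if (is.null(names(blups))) stop("BLUPs must be named by RIL id")
  blups
}

# Align BLUPs (and an optional genotype-linked covariate) with panel RILs.
align_to_panel <- function(blups, panel, covariate = NULL) {
  y <- as_blup_vector(blups)
  sel <- match(names(y), panel$ril_ids)
  if (anyNA(sel)) {
    warning(sum(is.na(sel)), " BLUP(s) not in panel; dropped")
    y <- y[!is.na(sel)]
    sel <- sel[!is.na(sel)]
  }
  C <- NULL
  if (!is.null(covariate)) {
    if (is.matrix(covariate)) {
      C <- covariate[match(names(y), rownames(covariate)), , drop = FALSE]
    } else {
      C <- matrix(covariate[match(names(y), names(covariate))], ncol = 1)
    }
    if (anyNA(C)) stop("covariate missing for some scanned RILs")
  }
  list(y = y, sel = sel, C = C)
}

safe_lod <- function(n, rss0, rss1, scale = rss0) {
  # a numerically-zero null RSS means a constant response: no signal, LOD 0
  eps <- 1e-300
  l <- (n / 2) * log10(pmax(rss0, eps) / pmax(rss1, eps))
  l[rss0 <= 1e-10 * (scale + eps)] <- 0
  pmax(l, 0)
}

# RSS of Y's columns under the designs [1, C] and [1, C, P(-1)] at given grid
# rows. Y: n x m matrix. Returns per-row LOD matrix plus F statistics for the
# first column.
scan_core <- function(Y, panel, sel, C = NULL, rows = seq_len(nrow(panel$grid))) {
  n <- nrow(Y)
  X0 <- cbind(rep(1, n), C)
  q0 <- qr(X0)
  r0 <- qr.resid(q0, Y)
  rss0 <- colSums(r0^2)
  y_scale <- colSums(Y^2) + 1e-300
  m <- ncol(Y)
  lod <- matrix(NA_real_, length(rows), m)
  Fv <- rep(NA_real_, length(rows))
  dfn <- dfd <- rep(NA_integer_, length(rows))
  skipped <- logical(length(rows))
  for (k in seq_along(rows)) {
    P <- prob_rows(panel, rows[k])[sel, , drop = FALSE]
    if (anyNA(P)) {
      skipped[k] <- TRUE
      next
    }
    q1 <- qr(cbind(X0, P[, -1, drop = FALSE]))
    rss1 <- colSums(qr.resid(q1, Y)^2)
    lod[k, ] <- safe_lod(n, rss0, rss1, y_scale)
    d1 <- q1$rank - q0$rank
    d2 <- n - q1$rank
    dfn[k] <- d1
    dfd[k] <- d2
    Fv[k] <- if (d1 > 0 && d2 > 0 && rss1[1] > 1e-10 * y_scale[1] &&
                 rss0[1] > 1e-10 * y_scale[1])
      ((rss0[1] - rss1[1]) / d1) / (rss1[1] / d2) else 0
  }
  if (any(skipped))
    warning(sum(skipped), " position(s) skipped: missing probability rows")
  list(lod = lod, F = Fv, df_num = dfn, df_den = dfd, skipped = skipped)
}

#' Single-position founder-haplotype association
#'
#' Least-squares fit of RIL BLUPs on the eight founder genotype probabilities
#' at one position; the F statistic (7 numerator df when all founders are
#' represented) is converted to `LOD = (n/2) log10(RSS0/RSS1)`, RSS0 being the
#' about-the-mean (or covariate-only) residual sum of squares.
#'
#' @param blups named numeric vector or [ril_blups()] data.frame.
#' @param probs numeric matrix, one 8-founder probability row per RIL,
#'   rownames = RIL ids (aligned to `blups` by name when present).
#' @param covariate optional per-RIL covariate (named vector or matrix with
#'   RIL rownames) included in both the null and full models.
#' @return A one-row data.frame: `F`, `df_num`, `df_den`, `lod`. A founder
#'   absent from the sample reduces `df_num` below 7.
#' @export
position_lod <- function(blups, probs, covariate = NULL) {
  y <- as_blup_vector(blups)
  if (!is.null(rownames(probs)) && !is.null(names(y)))
    probs <- probs[match(names(y), rownames(probs)), , drop = FALSE]
  n <- length(y)
  C <- NULL
  if (!is.null(covariate)) {
    C <- if (is.matrix(covariate))
      covariate[match(names(y), rownames(covariate)), , drop = FALSE]
    else matrix(covariate[match(names(y), names(covariate))], ncol = 1)
  }
  X0 <- cbind(rep(1, n), C)
  q0 <- qr(X0)
  rss0 <- sum(qr.resid(q0, y)^2)
  q1 <- qr(cbind(X0, probs[, -1, drop = FALSE]))
  rss1 <- sum(qr.resid(q1, y)^2)
  d1 <- q1$rank - q0$rank
  d2 <- n - q1$rank
  y_scale <- sum(y^2) + 1e-300
  degen <- rss0 <= 1e-10 * y_scale || d1 < 1 || d2 < 1 ||
    rss1 <= 1e-10 * y_scale
  Fv <- if (degen) 0 else ((rss0 - rss1) / d1) / (rss1 / d2)
  data.frame(F = Fv, df_num = d1, df_den = d2,
             lod = safe_lod(n, rss0, rss1, y_scale))
}

#' Genome scan of BLUPs on founder probabilities
#'
#' One [position_lod()] fit at every grid position. With a covariate, both
#' the null and full models include it, so the LOD measures each position's
#' increment over the covariate — the device used to find secondary QTL after
#' controlling a major locus.
#'
#' @param blups named numeric vector or [ril_blups()] data.frame.
#' @param panel a `ril_panel`.
#' @param covariate optional named vector (e.g. resistant-allele probability
#'   of a mapped QTL) or matrix with RIL rownames.
#' @param rows optional subset of grid rows to scan.
#' @return A data.frame of class `qtl_scan`: `arm`, `pos_kb`, `F`, `df_num`,
#'   `df_den`, `lod`.
#' @export
genome_scan <- function(blups, panel, covariate = NULL, rows = NULL) {
  al <- align_to_panel(blups, panel, covariate)
  if (is.null(rows)) rows <- seq_len(nrow(panel$grid))
  sc <- scan_core(matrix(al$y, ncol = 1), panel, al$sel, al$C, rows)
  out <- data.frame(arm = panel$grid$arm[rows], pos_kb = panel$grid$pos_kb[rows],
                    F = sc$F, df_num = sc$df_num, df_den = sc$df_den,
                    lod = sc$lod[, 1], stringsAsFactors = FALSE)
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Peak of a genome scan
#'
#' Ties in the maximum LOD break deterministically toward the lowest
#' (arm order, position).
#'
#' @param scan a `qtl_scan` data.frame.
#' @return The one-row data.frame at the peak.
#' @export
scan_peak <- function(scan) {
  scan <- scan[!is.na(scan$lod), , drop = FALSE]
  scan[which.max(scan$lod), , drop = FALSE]
}

#' Permutation null distribution of the genomewide maximum LOD
#'
#' BLUPs are permuted across RIL labels while the genotypes — and any
#' genotype-linked covariate, which stays attached to its genome — are left
#' in place, preserving the panel's linkage structure under the null. The
#' genomewide maximum LOD is recorded for each permutation.
#'
#' @inheritParams genome_scan
#' @param n_perm number of permutations (the study-scale setting is 2000).
#' @param seed integer seed.
#' @param chunk permutations processed per block (memory/speed trade-off).
#' @return An object of class `permutation_null`: `n_perm`, `max_lod`
#'   (length `n_perm`), `seed`.
#' @export
permutation_null <- function(blups, panel, n_perm, seed = NULL,
                             covariate = NULL, rows = NULL, chunk = 250) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  al <- align_to_panel(blups, panel, covariate)
  if (is.null(rows)) rows <- seq_len(nrow(panel$grid))
  n <- length(al$y)
  max_lod <- numeric(0)
  done <- 0
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    Y <- vapply(seq_len(m), function(j) al$y[sample.int(n)], numeric(n))
    sc <- scan_core(Y, panel, al$sel, al$C, rows)
    max_lod <- c(max_lod, apply(sc$lod, 2, max, na.rm = TRUE))
    done <- done + m
  }
  structure(list(n_perm = n_perm, max_lod = max_lod, seed = seed),
            class = "permutation_null")
}

#' Genomewide significance threshold from a permutation null
#'
#' The threshold is the `ceiling(alpha * n_perm)`-th largest null maximum
#' LOD — the (1 - alpha) quantile of the permutation distribution.
#'
#' @param null a `permutation_null`.
#' @param alpha genomewide type-I error rate.
#' @return LOD threshold (numeric scalar).
#' @export
genomewide_threshold <- function(null, alpha) {
  stopifnot(inherits(null, "permutation_null"), alpha > 0, alpha <= 1)
  if (alpha * null$n_perm < 1)
    stop("alpha * n_perm < 1: permutation resolution insufficient")
  k <- ceiling(alpha * null$n_perm)
  sort(null$max_lod, decreasing = TRUE)[k]
}

#' Genomewide permutation p-value of an observed maximum LOD
#'
#' Uses the add-one convention `p = (r + 1) / (n_perm + 1)` with `r` the
#' number of null maxima at or above the observed value, so the smallest
#' attainable p with 2000 permutations is 1/2001 (< 0.0005).
#'
#' @param null a `permutation_null`.
#' @param observed_max_lod observed genomewide maximum LOD.
#' @return p-value (numeric scalar).
#' @export
genomewide_pvalue <- function(null, observed_max_lod) {
  stopifnot(inherits(null, "permutation_null"), length(null$max_lod) > 0)
  (sum(null$max_lod >= observed_max_lod) + 1) / (null$n_perm + 1)
}

#' Local interval refinement around a QTL peak
#'
#' Recomputes the LOD profile in a window around a peak and reports two
#' location intervals: the smallest contiguous grid interval, grown outward
#' from the peak, containing at least `cover` of the normalized 10^LOD mass
#' (a Bayesian credible interval), and the outermost positions whose LOD is
#' within `lod_drop` of the peak (a LOD-drop support interval).
#'
#' @inheritParams genome_scan
#' @param arm chromosome arm of the peak.
#' @param window numeric `c(lo_kb, hi_kb)` or NULL for the whole arm.
#' @param cover credible-interval mass (default 0.95).
#' @param lod_drop LOD units for the support interval (default 2).
#' @param null optional `permutation_null` for a genomewide p-value.
#' @return An object of class `qtl_interval`: `arm`, `peak_kb`, `peak_lod`,
#'   `bayes_ci`, `lod_drop_ci`, `p_genomewide` (NA without a null).
#' @export
refine_interval <- function(blups, panel, arm, window = NULL, cover = 0.95,
                            lod_drop = 2, covariate = NULL, null = NULL) {
  rows <- which(panel$grid$arm == arm)
  if (!is.null(window))
    rows <- rows[panel$grid$pos_kb[rows] >= window[1] &
                 panel$grid$pos_kb[rows] <= window[2]]
  if (length(rows) == 0) stop("empty window on arm ", arm)
  sc <- genome_scan(blups, panel, covariate = covariate, rows = rows)
  iv <- interval_from_profile(sc$pos_kb, sc$lod, cover, lod_drop)
  if (iv$peak_i == 1 || iv$peak_i == length(sc$lod))
    warning("peak lies on the window edge; consider widening the window")
  if (iv$n_modes > 1)
    message(iv$n_modes, " local modes within ", lod_drop,
            " LOD of the peak; credible interval grown from the highest")
  structure(list(arm = arm, peak_kb = iv$peak_kb, peak_lod = iv$peak_lod,
                 bayes_ci = iv$bayes_ci, lod_drop_ci = iv$lod_drop_ci,
                 p_genomewide = if (is.null(null)) NA_real_ else
                   genomewide_pvalue(null, iv$peak_lod),
                 scan = sc, n_modes = iv$n_modes),
            class = "qtl_interval")
}

# Interval arithmetic on a LOD profile: credible interval grown outward from
# the peak on normalized 10^LOD mass, and the outermost positions within
# lod_drop of the peak. Positions must be ordered.
interval_from_profile <- function(pos_kb, lod, cover = 0.95, lod_drop = 2) {
  pk <- which.max(lod)  # first maximum: lowest position wins ties
  w <- 10^(lod - max(lod, na.rm = TRUE))
  w[is.na(w)] <- 0
  w <- w / sum(w)
  lo <- hi <- pk
  mass <- w[pk]
  while (mass < cover && (lo > 1 || hi < length(w))) {
    wl <- if (lo > 1) w[lo - 1] else -Inf
    wr <- if (hi < length(w)) w[hi + 1] else -Inf
    if (wl >= wr) {
      lo <- lo - 1
      mass <- mass + w[lo]
    } else {
      hi <- hi + 1
      mass <- mass + w[hi]
    }
  }
  keep <- which(!is.na(lod) & lod >= lod[pk] - lod_drop)
  is_mode <- which(diff(sign(diff(c(-Inf, lod, -Inf)))) == -2)
  list(peak_i = pk, peak_kb = pos_kb[pk], peak_lod = lod[pk],
       bayes_ci = c(pos_kb[lo], pos_kb[hi]),
       lod_drop_ci = c(pos_kb[min(keep)], pos_kb[max(keep)]),
       n_modes = sum(lod[is_mode] > lod[pk] - lod_drop))
}

#' @export
print.qtl_interval <- function(x, ...) {
  cat(sprintf("QTL %s:%g  LOD %.2f  Bayes 95%% CI %g-%g kb  LOD-drop CI %g-%g kb",
              x$arm, x$peak_kb, x$peak_lod, x$bayes_ci[1], x$bayes_ci[2],
              x$lod_drop_ci[1], x$lod_drop_ci[2]))
  if (!is.na(x$p_genomewide)) cat(sprintf("  p(gw) %.4g", x$p_genomewide))
  cat("\n")
  invisible(x)
}
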