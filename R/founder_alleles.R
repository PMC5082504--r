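# Partitioning founder alleles at a QTL into resistant/susceptible classes,
# per-RIL resistant probabilities, and linkage-disequilibrium tests.

#' Per-founder phenotype means at a QTL
#'
#' RILs are hard-assigned to the founder whose genotype probability at the
#' peak is at least `assign_threshold`; ambiguous RILs are excluded (the
#' computable analogue of genotyping ambiguous lines by PCR). Founders with
#' no assigned RIL are flagged absent.
#'
#' @param blups named numeric vector or [ril_blups()] data.frame.
#' @param probs matrix of founder probabilities at the peak, one row per RIL,
#'   rownames = RIL ids.
#' @param assign_threshold minimum probability for a hard assignment
#'   (default 0.95).
#' @return A list: `means` (length 8, NA where absent), `counts` (length 8),
#'   `assignments` (named founder index per used RIL), `blups` (the used
#'   BLUPs).
#' @export
founder_means <- function(blups, probs, assign_threshold = 0.95) {
  y <- as_blup_vector(blups)
  if (!is.null(rownames(probs)))
    probs <- probs[match(names(y), rownames(probs)), , drop = FALSE]
  stopifnot(nrow(probs) == length(y), ncol(probs) == 8)
  f <- max.col(probs, ties.method = "first")
  ok <- probs[cbind(seq_along(f), f)] >= assign_threshold
  f <- f[ok]
  y <- y[ok]
  counts <- tabulate(f, 8)
  means <- rep(NA_real_, 8)
  for (j in which(counts > 0)) means[j] <- mean(y[f == j])
  if (sum(counts > 0) < 2)
    stop("partition impossible: fewer than 2 founders represented at this position",
         call. = FALSE)
  list(means = means, counts = counts,
       assignments = setNames(f, names(y)), blups = y)
}

one_way_F <- function(y, g) {
  # one-way ANOVA F between two groups
  n <- length(y)
  k <- length(unique(g))
  if (k < 2) return(0)
  gm <- mean(y)
  mg <- tapply(y, g, mean)
  ng <- tapply(y, g, length)
  ssb <- sum(ng * (mg - gm)^2)
  ssw <- sum((y - mg[as.character(g)])^2)
  if (ssw <= 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Best two-class partition of founder alleles
#'
#' Founders are ranked by their mean phenotype and every ranked cut-point is
#' evaluated by a one-way ANOVA of BLUPs between the two classes; the split
#' with the highest F wins (ties broken toward the smaller resistant class).
#' Only ranked cuts are searched — a maximum-likelihood two-class partition
#' of a one-dimensional mean always occurs at a ranked cut.
#'
#' @param fm result of [founder_means()].
#' @param direction `"high"` if larger phenotype values indicate resistance
#'   (DCV survival days), `"low"` if smaller values do (sigma infection
#'   proportion).
#' @param qtl_id optional identifier stored with the partition.
#' @return An object of class `founder_partition`: `class_of` (length-8
#'   character, `"resistant"`/`"susceptible"`; absent founders are placed in
#'   the susceptible class and listed in `absent`), `founder_means`,
#'   `counts`, `best_F`, `n_rils_used`, `cut_F` (F of every evaluated cut).
#' @export
best_two_class_partition <- function(fm, direction = c("high", "low"),
                                     qtl_id = NULL) {
  direction <- match.arg(direction)
  present <- which(fm$counts > 0)
  k <- length(present)
  if (k < 2) stop("partition impossible: fewer than 2 founders represented",
                  call. = FALSE)
  ord <- present[order(fm$means[present])]  # ascending mean
  f <- fm$assignments
  y <- fm$blups
  cut_F <- numeric(k - 1)
  cut_sizes <- integer(k - 1)
  for (j in seq_len(k - 1)) {
    upper <- ord[(j + 1):k]  # founders with larger means
    res_set <- if (direction == "high") upper else ord[1:j]
    cut_F[j] <- one_way_F(y, as.integer(f %in% res_set))
    cut_sizes[j] <- length(res_set)
  }
  best <- which(cut_F == max(cut_F))
  if (length(best) > 1) best <- best[which.min(cut_sizes[best])]
  res_set <- if (direction == "high") ord[(best + 1):k] else ord[1:best]
  class_of <- rep("susceptible", 8)
  class_of[res_set] <- "resistant"
  structure(list(qtl_id = qtl_id, class_of = class_of,
                 founder_means = fm$means, counts = fm$counts,
                 best_F = max(cut_F), cut_F = cut_F,
                 n_rils_used = length(y), direction = direction,
                 absent = which(fm$counts == 0)),
            class = "founder_partition")
}

#' @export
print.founder_partition <- function(x, ...) {
  cat("Founder partition", if (!is.null(x$qtl_id)) paste0("(", x$qtl_id, ")"),
      "\n  resistant:  ", paste(which(x$class_of == "resistant"), collapse = " "),
      "\n  susceptible:", paste(setdiff(which(x$class_of == "susceptible"),
                                        x$absent), collapse = " "))
  if (length(x$absent))
    cat("\n  absent:     ", paste(x$absent, collapse = " "))
  cat(sprintf("\n  best F = %.2f over %d RILs\n", x$best_F, x$n_rils_used))
  invisible(x)
}

#' Per-RIL probability of carrying the resistant allele
#'
#' The sum of a RIL's founder genotype probabilities over the resistant-class
#' founders; the susceptible-class probability is its complement.
#'
#' @param partition a `founder_partition`.
#' @param probs matrix of founder probabilities at the same position, one row
#'   per RIL, rownames = RIL ids.
#' @return Named numeric vector in `[0, 1]`.
#' @export
resistant_probability <- function(partition, probs) {
  stopifnot(inherits(partition, "founder_partition"), ncol(probs) == 8)
  rowSums(probs[, partition$class_of == "resistant", drop = FALSE])
}

#' Linkage disequilibrium between two QTL (Fisher's exact test)
#'
#' RILs are hard-assigned a resistant or susceptible allele at each locus
#' (resistant probability at least `assign_threshold`, susceptible at most
#' `1 - assign_threshold`; others dropped) and cross-classified in a 2x2
#' table tested by Fisher's exact test, two-sided.
#'
#' @param partition_a,partition_b `founder_partition`s at the two loci.
#' @param probs_a,probs_b founder-probability matrices at the two loci
#'   (shared RIL rownames).
#' @param assign_threshold hard-assignment threshold (default 0.95).
#' @return A list: `odds_ratio`, `p`, `table`, `n_used`, `degenerate` (TRUE
#'   with p = 1 when a margin is empty).
#' @export
ld_fisher <- function(partition_a, partition_b, probs_a, probs_b,
                      assign_threshold = 0.95) {
  ids <- intersect(rownames(probs_a), rownames(probs_b))
  rpa <- resistant_probability(partition_a, probs_a[ids, , drop = FALSE])
  rpb <- resistant_probability(partition_b, probs_b[ids, , drop = FALSE])
  cls <- function(rp) ifelse(rp >= assign_threshold, "resistant",
                      ifelse(rp <= 1 - assign_threshold, "susceptible", NA))
  a <- cls(rpa)
  b <- cls(rpb)
  ok <- !is.na(a) & !is.na(b)
  tab <- table(factor(a[ok], c("resistant", "susceptible")),
               factor(b[ok], c("resistant", "susceptible")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1, table = tab,
                n_used = sum(ok), degenerate = TRUE))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab,
       n_used = sum(ok), degenerate = FALSE)
}
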