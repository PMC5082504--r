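#' Default Drosophila melanogaster chromosome arms
#'
#' Physical lengths (kb, reference v5) and genetic map lengths (cM) of the
#' five major arms. The X is treated like the autosomes for mosaic purposes.
#'
#' @return A data.frame with columns `arm`, `len_kb`, `len_cM`.
#' @export
dmel_arms <- function() {
  data.frame(
    arm = c("X", "2L", "2R", "3L", "3R"),
    len_kb = c(22422, 23011, 21146, 24543, 27905),
    len_cM = c(66, 55, 52, 47, 59),
    stringsAsFactors = FALSE
  )
}

#' Build a genome grid of evenly spaced positions
#'
#' Positions are 1-based kb multiples of `step_kb` covering each arm once,
#' the spacing at which founder genotype probabilities are tabulated.
#'
#' @param arms data.frame with columns `arm`, `len_kb`, `len_cM`.
#' @param step_kb grid spacing in kb (default 10).
#' @return An object of class `genome_grid`: a data.frame with columns
#'   `arm`, `pos_kb`, carrying the arm table as attribute `arms`.
#' @export
genome_grid <- function(arms = dmel_arms(), step_kb = 10) {
  stopifnot(is.data.frame(arms), all(c("arm", "len_kb", "len_cM") %in% names(arms)))
  if (any(arms$len_kb <= 0) || any(arms$len_cM <= 0))
    stop("arm lengths must be positive")
  if (step_kb <= 0) stop("step_kb must be positive")
  pos <- lapply(seq_len(nrow(arms)), function(i) {
    p <- seq(step_kb, arms$len_kb[i], by = step_kb)
    data.frame(arm = arms$arm[i], pos_kb = p, stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, pos)
  rownames(g) <- NULL
  attr(g, "arms") <- arms
  attr(g, "step_kb") <- step_kb
  class(g) <- c("genome_grid", "data.frame")
  g
}

#' Describe a planted QTL for simulation
#'
#' @param arm chromosome arm name (must exist in the grid).
#' @param pos_kb position in kb; must lie on the grid.
#' @param founder_class character vector of length 8 with entries
#'   `"resistant"` / `"susceptible"` assigning each founder allele to a class.
#' @param effect phenotypic effect of carrying a resistant-class allele, in
#'   trait units (days for the DCV survival assay, probability points for the
#'   sigma infection assay). Sign convention: the effect is *added* to the
#'   trait of resistant-allele carriers.
#' @param id optional identifier (defaults to `arm:pos`).
#' @param interaction optional `list(partner = <qtl id>, coef = <numeric>)`
#'   adding `coef` to the trait of RILs carrying the resistant allele at both
#'   this QTL and the partner. A coefficient of `-2 * effect` reverses the
#'   QTL's effect in the resistant background of the partner.
#' @return An object of class `planted_qtl`.
#' @export
planted_qtl <- function(arm, pos_kb, founder_class, effect, id = NULL,
                        interaction = NULL) {
  founder_class <- match.arg(founder_class, c("resistant", "susceptible"),
                             several.ok = TRUE)
  if (length(founder_class) != 8)
    stop("founder_class must have one entry per founder (8)")
  structure(list(
    id = if (is.null(id)) paste0(arm, ":", pos_kb) else id,
    arm = arm, pos_kb = pos_kb, founder_class = founder_class,
    effect = effect, interaction = interaction
  ), class = "planted_qtl")
}

#' Configuration for a synthetic multiparent RIL study
#'
#' Defaults emulate the design of a DSPR-style virus-resistance study: eight
#' founders intercrossed for 50 generations, RILs derived by full-sib
#' inbreeding, 20 flies per vial, about 50 vials injected per day, and
#' variance components giving a repeatability near 0.77 for the survival
#' (dcv) assay.
#'
#' @param n_ril number of recombinant inbred lines (>= 2).
#' @param n_generations intercross generations before inbreeding (default 50).
#' @param grid a [genome_grid()].
#' @param qtl list of [planted_qtl()] objects.
#' @param assay `"dcv"` (vial mean survival days) or `"sigma"` (vial
#'   proportion infected).
#' @param beta grand mean on the trait scale (days or probability).
#' @param sigma2_ril,sigma2_date,sigma2_resid polygenic between-RIL,
#'   between-injection-day and residual vial variances on the trait scale.
#' @param n_vials_per_ril replicate vials per RIL (default 2).
#' @param flies_per_vial flies injected per vial (default 20).
#' @param vials_per_day injection batch size (default 50).
#' @param n_pairs intercross census in mating pairs (default 10000, i.e. a
#'   20000-fly cage population). Multiparent panels are intercrossed at large
#'   census precisely to limit drift of founder proportions away from 1/8;
#'   the exact census used in panel construction is not a published quantity,
#'   so it is exposed here. Replicated small simulations (e.g. permutation
#'   calibration experiments) can pass a much smaller census.
#' @param blur optional emission noise in `[0,1)`: genotype-probability rows
#'   are `(1-blur)` on the true founder mixed with `blur` uniform.
#' @param het_target inbreeding stops when genomewide heterozygosity falls
#'   below this fraction (default 0.01).
#' @param seed integer seed making the whole simulation reproducible.
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(n_ril, n_generations = 50, grid = genome_grid(),
                       qtl = list(), assay = c("dcv", "sigma"),
                       beta = if (assay == "dcv") 8 else 0.45,
                       sigma2_ril = if (assay == "dcv") 3.35 else 0.031,
                       sigma2_date = if (assay == "dcv") 1 else 0.002,
                       sigma2_resid = if (assay == "dcv") 1 else 0.011,
                       n_vials_per_ril = 2, flies_per_vial = 20,
                       vials_per_day = 50, n_pairs = 10000, blur = 0,
                       het_target = 0.01, seed = NULL) {
  assay <- match.arg(assay)
  if (n_ril < 1) stop("invalid config: n_ril must be >= 1")
  if (n_ril < 2) warning("n_ril < 2: phenotype models require at least 2 RILs")
  if (any(c(sigma2_ril, sigma2_date, sigma2_resid) < 0))
    stop("invalid config: variances must be >= 0")
  if (flies_per_vial < 1) stop("invalid config: flies_per_vial must be >= 1")
  if (blur < 0 || blur >= 1) stop("invalid config: blur must be in [0, 1)")
  if (inherits(qtl, "planted_qtl")) qtl <- list(qtl)
  structure(list(
    n_founders = 8L, n_ril = as.integer(n_ril),
    n_generations = as.integer(n_generations), grid = grid, qtl = qtl,
    assay = assay, beta = beta, sigma2_ril = sigma2_ril,
    sigma2_date = sigma2_date, sigma2_resid = sigma2_resid,
    n_vials_per_ril = as.integer(n_vials_per_ril),
    flies_per_vial = as.integer(flies_per_vial),
    vials_per_day = as.integer(vials_per_day),
    n_pairs = as.integer(n_pairs), blur = blur, het_target = het_target,
    seed = seed
  ), class = "sim_config")
}

#' Simulate a multiparent RIL panel
#'
#' Simulates `n_generations` of random-mating intercross among eight inbred
#' founder lines in a finite pedigree (`n_pairs` monogamous pairs, two
#' offspring each), then derives each RIL by full-sib inbreeding of a random
#' founding pair until genomewide heterozygosity drops below `het_target`,
#' retaining one haplotype. Crossovers per arm per meiosis are Poisson with
#' mean the arm's genetic length in Morgans, positions uniform on the genetic
#' map; genetic and physical coordinates are related by linear interpolation.
#' With `n_generations = 0` no intercrossing has occurred, so each RIL is an
#' intact founder line.
#'
#' @param config a [sim_config()].
#' @return An object of class `ril_panel` with elements `grid`, `ril_ids`,
#'   `mosaics` (per RIL, per arm `data.frame(start_kb, end_kb, founder)`),
#'   `founder_idx` (integer matrix, grid positions x RILs, the true founder
#'   at each position) and `blur`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_ril < 1) stop("invalid config: n_ril must be >= 1")
  if (!is.null(config$seed)) set.seed(config$seed)
  arms <- attr(config$grid, "arms")
  n_arm <- nrow(arms)
  n_ril <- config$n_ril

  if (config$n_generations == 0) {
    fdr <- sample.int(8, n_ril, replace = TRUE)
    mosaics <- lapply(fdr, function(f) {
      lapply(seq_len(n_arm), function(a) {
        data.frame(start_kb = 0, end_kb = arms$len_kb[a], founder = f)
      })
    })
  } else {
    n_ind <- 2L * config$n_pairs
    if (n_ind < 2) stop("invalid config: need at least one mating pair")
    # balanced founder representation at generation 0
    init <- sample(rep_len(1:8, n_ind))
    ped <- lapply(seq_len(config$n_generations), function(g) {
      pairs <- matrix(sample.int(n_ind), ncol = 2)
      ped_g <- pairs[rep(seq_len(nrow(pairs)), each = 2), , drop = FALSE]
      storage.mode(ped_g) <- "integer"
      ped_g
    })
    ril_pairs <- t(vapply(seq_len(n_ril), function(r) sample.int(n_ind, 2),
                          integer(2)))
    raw <- sim_panel_cpp(ped, arms$len_cM, as.integer(init), ril_pairs,
                         config$het_target, 60L)
    mosaics <- lapply(raw, function(ril) {
      lapply(seq_len(n_arm), function(a) {
        end_kb <- ril[[a]]$brk / arms$len_cM[a] * arms$len_kb[a]
        end_kb[length(end_kb)] <- arms$len_kb[a]  # guard rounding
        data.frame(start_kb = c(0, head(end_kb, -1)), end_kb = end_kb,
                   founder = ril[[a]]$fdr)
      })
    })
  }
  ril_ids <- sprintf("RIL%04d", seq_len(n_ril))
  names(mosaics) <- ril_ids

  founder_idx <- matrix(NA_integer_, nrow(config$grid), n_ril,
                        dimnames = list(NULL, ril_ids))
  for (a in seq_len(n_arm)) {
    rows <- which(config$grid$arm == arms$arm[a])
    pos <- config$grid$pos_kb[rows]
    for (r in seq_len(n_ril)) {
      ends <- mosaics[[r]][[a]]$end_kb
      i <- findInterval(pos - 1e-9, ends) + 1L
      i[i > length(ends)] <- length(ends)
      founder_idx[rows, r] <- mosaics[[r]][[a]]$founder[i]
    }
  }
  structure(list(grid = config$grid, ril_ids = ril_ids, mosaics = mosaics,
                 founder_idx = founder_idx, blur = config$blur),
            class = c("sim_panel", "ril_panel"))
}

# ---- panel accessors (shared by simulated and file-backed panels) ----------

#' Number of RILs in a panel
#' @param panel a `ril_panel`.
#' @return Integer.
#' @export
n_rils <- function(panel) length(panel$ril_ids)

#' Founder genotype probability rows at one grid position
#'
#' @param panel a `ril_panel`.
#' @param i row index into `panel$grid`.
#' @return A numeric matrix, RILs x 8 founders; each row sums to 1.
#' @export
prob_rows <- function(panel, i) UseMethod("prob_rows")

#' @export
prob_rows.sim_panel <- function(panel, i) {
  stopifnot(length(i) == 1, i >= 1, i <= nrow(panel$grid))
  n <- n_rils(panel)
  p <- matrix(panel$blur / 8, n, 8, dimnames = list(panel$ril_ids, NULL))
  p[cbind(seq_len(n), panel$founder_idx[i, ])] <-
    p[cbind(seq_len(n), panel$founder_idx[i, ])] + (1 - panel$blur)
  p
}

#' @export
prob_rows.dense_panel <- function(panel, i) {
  stopifnot(length(i) == 1, i >= 1, i <= nrow(panel$grid))
  p <- t(panel$probs[i, , ])
  dimnames(p) <- list(panel$ril_ids, NULL)
  p
}

#' Full founder probability matrix for one RIL
#'
#' @param panel a `ril_panel`.
#' @param ril a RIL id or index.
#' @return A numeric matrix, grid positions x 8 founders.
#' @export
founder_probs <- function(panel, ril) UseMethod("founder_probs")

#' @export
founder_probs.sim_panel <- function(panel, ril) {
  r <- if (is.character(ril)) match(ril, panel$ril_ids) else ril
  if (is.na(r) || r < 1 || r > n_rils(panel)) stop("unknown RIL: ", ril)
  np <- nrow(panel$grid)
  p <- matrix(panel$blur / 8, np, 8,
              dimnames = list(NULL, paste0("p_F", 1:8)))
  p[cbind(seq_len(np), panel$founder_idx[, r])] <-
    p[cbind(seq_len(np), panel$founder_idx[, r])] + (1 - panel$blur)
  p
}

#' @export
founder_probs.dense_panel <- function(panel, ril) {
  r <- if (is.character(ril)) match(ril, panel$ril_ids) else ril
  if (is.na(r) || r < 1 || r > n_rils(panel)) stop("unknown RIL: ", ril)
  m <- panel$probs[, , r]
  dimnames(m) <- list(NULL, paste0("p_F", 1:8))
  m
}

#' Genomewide founder-share summary of a panel
#'
#' Mean share of the genome contributed by each founder, averaged over RILs
#' and grid positions.
#'
#' @param panel a `ril_panel`.
#' @return Named numeric vector of length 8 summing to 1.
#' @export
founder_shares <- function(panel) {
  tot <- numeric(8)
  for (i in seq_len(nrow(panel$grid))) {
    tot <- tot + colSums(prob_rows(panel, i))
  }
  p <- tot / (nrow(panel$grid) * n_rils(panel))
  names(p) <- paste0("F", 1:8)
  p
}

#' Count recombination breakpoints in simulated mosaics
#'
#' @param panel a simulated `ril_panel`.
#' @return A data.frame with one row per RIL x arm: `ril_id`, `arm`,
#'   `n_breakpoints` (segment transitions between different founders).
#' @export
count_breakpoints <- function(panel) {
  stopifnot(inherits(panel, "sim_panel"))
  arms <- attr(panel$grid, "arms")
  out <- lapply(seq_along(panel$mosaics), function(r) {
    nb <- vapply(panel$mosaics[[r]], function(m) nrow(m) - 1L, integer(1))
    data.frame(ril_id = panel$ril_ids[r], arm = arms$arm,
               n_breakpoints = nb, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- phenotype simulation ---------------------------------------------------

#' Genetic values implied by planted QTL
#'
#' Uses the true founder mosaic (not the emitted probabilities): a RIL's
#' genetic value is the sum over planted QTL of `effect` when its founder at
#' the QTL position belongs to the resistant class, plus any interaction
#' coefficient when it carries the resistant allele at both members of an
#' interacting pair.
#'
#' @param panel a simulated `ril_panel`.
#' @param qtl_list list of [planted_qtl()].
#' @return Named numeric vector of genetic values (trait units), one per RIL.
#' @export
plant_genetic_values <- function(panel, qtl_list) {
  if (inherits(qtl_list, "planted_qtl")) qtl_list <- list(qtl_list)
  n <- n_rils(panel)
  g <- setNames(numeric(n), panel$ril_ids)
  if (length(qtl_list) == 0) return(g)
  z <- list()  # resistant indicator per QTL
  for (q in qtl_list) {
    row <- which(panel$grid$arm == q$arm & panel$grid$pos_kb == q$pos_kb)
    if (length(row) != 1)
      stop("QTL position off the grid: ", q$arm, ":", q$pos_kb)
    z[[q$id]] <- as.numeric(q$founder_class[panel$founder_idx[row, ]] == "resistant")
    g <- g + q$effect * z[[q$id]]
  }
  for (q in qtl_list) {
    if (!is.null(q$interaction)) {
      zp <- z[[q$interaction$partner]]
      if (is.null(zp)) stop("unknown interaction partner: ", q$interaction$partner)
      g <- g + q$interaction$coef * z[[q$id]] * zp
    }
  }
  g
}

#' Simulate vial-level phenotypes
#'
#' Applies the study's vial model: a vial's expectation is the grand mean
#' plus the RIL's planted genetic value, a polygenic RIL deviation
#' (Normal, `sigma2_ril`), an injection-day deviation (Normal, `sigma2_date`)
#' and a residual (Normal, `sigma2_resid`). Vials are injected in batches of
#' `vials_per_day`, with replicate vials of a RIL always on different days.
#' For the `sigma` assay the latent vial infection probability is clipped to
#' `[0, 1]` and the observed value is a binomial proportion over
#' `flies_per_vial` flies.
#'
#' @param genetic_values named numeric vector from [plant_genetic_values()]
#'   (one value per RIL).
#' @param config a [sim_config()].
#' @return A data.frame of vials: `ril_id`, `vial_id`, `date`, `assay`,
#'   `n_flies`, `value`.
#' @export
simulate_vials <- function(genetic_values, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(c(config$sigma2_ril, config$sigma2_date, config$sigma2_resid) < 0))
    stop("invalid config: variances must be >= 0")
  rils <- names(genetic_values)
  if (is.null(rils)) stop("genetic_values must be named by RIL")
  n <- length(rils)
  u_ril <- rnorm(n, 0, sqrt(config$sigma2_ril))
  vials <- list()
  day0 <- 0L
  for (rep_i in seq_len(config$n_vials_per_ril)) {
    ord <- sample.int(n)
    day <- day0 + (seq_len(n) - 1L) %/% config$vials_per_day + 1L
    vials[[rep_i]] <- data.frame(
      ril = ord, rep = rep_i, day = day, stringsAsFactors = FALSE)
    day0 <- max(day)
  }
  v <- do.call(rbind, vials)
  days <- sort(unique(v$day))
  u_date <- setNames(rnorm(length(days), 0, sqrt(config$sigma2_date)),
                     as.character(days))
  mu <- config$beta + genetic_values[v$ril] + u_ril[v$ril] +
    u_date[as.character(v$day)] + rnorm(nrow(v), 0, sqrt(config$sigma2_resid))
  if (config$assay == "sigma") {
    p <- pmin(pmax(mu, 0), 1)
    value <- rbinom(nrow(v), config$flies_per_vial, p) / config$flies_per_vial
  } else {
    value <- mu
  }
  out <- data.frame(
    ril_id = rils[v$ril],
    vial_id = sprintf("%s_v%d", rils[v$ril], v$rep),
    date = sprintf("day%03d", v$day),
    assay = config$assay,
    n_flies = config$flies_per_vial,
    value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  out[order(out$date, out$ril_id), , drop = FALSE]
}

#' Simulate a complete study (panel, genetic values, vials, truth)
#'
#' Convenience wrapper running [simulate_panel()], [plant_genetic_values()]
#' and [simulate_vials()] under the config's seed, returning the pieces
#' together with the planted truth.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel`, `genetic_values`, `vials`, `truth`
#'   (planted QTL, variance components, seed).
#' @export
simulate_study <- function(config) {
  panel <- simulate_panel(config)  # sets seed from config
  g <- plant_genetic_values(panel, config$qtl)
  vials <- simulate_vials(g, config)
  truth <- list(
    qtl = config$qtl, beta = config$beta,
    sigma2_ril = config$sigma2_ril, sigma2_date = config$sigma2_date,
    sigma2_resid = config$sigma2_resid, assay = config$assay,
    seed = config$seed
  )
  list(panel = panel, genetic_values = g, vials = vials, truth = truth)
}
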