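# Synthetic-data generators: every input the pipeline consumes can be
# produced here with the statistical structure the analysis assumes, so the
# whole chain is testable without instrument data.

#' Describe an in vitro exposure design
#'
#' Captures the layout of a plate-based cytotoxicity screen: which nanoforms
#' (particles) are applied to which cell lines, which endpoints are read out,
#' the dose series, and the replication structure. The conventional layout is
#' three independent experiments with two technical replicates each, over a
#' two-fold dose series spanning 0--100 ug/cm^2, with a single higher
#' "mechanistic" dose used for redox, cytokine and proteomic endpoints.
#'
#' @param particles character vector of particle (nanoform) labels.
#' @param cell_lines character vector of cell line labels.
#' @param assays cytotoxicity endpoints, a subset of `c("LDH","ATP","CTB")`.
#' @param doses strictly increasing numeric dose series in ug/cm^2; must
#'   include 0 (the vehicle control).
#' @param n_experiments number of independent experiments (>= 1).
#' @param n_technical technical replicates per experiment (>= 1).
#' @param mechanistic_dose single positive dose (ug/cm^2) at which
#'   single-dose mechanistic endpoints (markers, proteomics) are measured.
#'   It need not belong to `doses`: mechanistic endpoints are separate
#'   single-dose exposures, not rows of the dose-response plate.
#' @return an object of class `exposure_design`.
#' @export
exposure_design <- function(particles,
                            cell_lines = c("A549", "J774A.1"),
                            assays = c("LDH", "ATP", "CTB"),
                            doses = c(0, 3.125, 6.25, 12.5, 25, 50, 100),
                            n_experiments = 3L,
                            n_technical = 2L,
                            mechanistic_dose = 30) {
  if (length(particles) < 1L) .np_stop("at least one particle is required")
  assays <- match.arg(assays, c("LDH", "ATP", "CTB"), several.ok = TRUE)
  if (length(doses) < 2L || !0 %in% doses) {
    .np_stop("`doses` must contain 0 and at least one positive dose")
  }
  if (is.unsorted(doses, strictly = TRUE)) {
    .np_stop("`doses` must be strictly increasing")
  }
  if (any(doses < 0)) .np_stop("doses must be non-negative")
  if (n_experiments < 1L || n_technical < 1L) {
    .np_stop("n_experiments and n_technical must be >= 1")
  }
  if (length(mechanistic_dose) != 1L || mechanistic_dose <= 0) {
    .np_stop("`mechanistic_dose` must be a single positive dose")
  }
  structure(
    list(particles = as.character(particles),
         cell_lines = as.character(cell_lines),
         assays = assays,
         doses = as.numeric(doses),
         n_experiments = as.integer(n_experiments),
         n_technical = as.integer(n_technical),
         mechanistic_dose = as.numeric(mechanistic_dose)),
    class = "exposure_design")
}

#' Ground-truth potency parameters for simulation
#'
#' Builds the per particle x cell line x assay table of true power-law slopes
#' used by [generate_cytotox_plate()]. By default the membrane-damage endpoint
#' (LDH release) increases with dose (positive slope) while the viability
#' endpoints (ATP, CTB) decrease (negative slope), matching assay
#' directionality; the reported potency is the slope magnitude either way.
#'
#' @param design an [exposure_design()].
#' @param beta either a single non-negative slope magnitude applied to every
#'   particle/cell line, or a numeric vector named by particle.
#' @param noise_cv multiplicative coefficient of variation of well-level
#'   noise (>= 0).
#' @return data frame of class `potency_truth` with columns
#'   `particle`, `cell_line`, `assay`, `true_beta` (signed), `noise_cv`.
#' @export
potency_truth <- function(design, beta = 0.03, noise_cv = 0.1) {
  stopifnot(inherits(design, "exposure_design"))
  if (any(noise_cv < 0)) .np_stop("noise_cv must be >= 0")
  if (is.null(names(beta))) {
    if (length(beta) == 1L) {
      beta <- stats::setNames(rep(beta, length(design$particles)),
                              design$particles)
    } else if (length(beta) == length(design$particles)) {
      names(beta) <- design$particles
    } else {
      .np_stop("`beta` must be scalar or one value per particle")
    }
  }
  miss <- setdiff(design$particles, names(beta))
  if (length(miss)) .np_stop("no true beta for particle(s): %s",
                             paste(miss, collapse = ", "))
  direction <- c(LDH = 1, ATP = -1, CTB = -1)
  grid <- expand.grid(particle = design$particles,
                      cell_line = design$cell_lines,
                      assay = design$assays,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$true_beta <- unname(beta[grid$particle]) * direction[grid$assay]
  grid$noise_cv <- noise_cv
  class(grid) <- c("potency_truth", "data.frame")
  grid
}

#' Simulate a cytotoxicity plate
#'
#' Generates replicate-level raw signals under the power-law dose-response
#' model: `signal = baseline * scale_e * (dose + 1)^true_beta * noise`, where
#' `scale_e` is an experiment-level lognormal plate effect and `noise` is
#' well-level lognormal with the coefficient of variation stated in `truth`.
#' Particle interference is modelled as a dose-independent additive offset
#' (per particle) present in both cell wells and matched cell-free wells, so
#' the cell-free correction in [compute_fold_effect()] can remove it exactly.
#'
#' @param design an [exposure_design()].
#' @param truth a [potency_truth()] table.
#' @param seed integer RNG seed; the same (design, truth, seed) triple always
#'   yields an identical table.
#' @param baseline named numeric of assay baselines at dose zero (arbitrary
#'   units, all positive).
#' @param plate_sd SD of the log experiment-level scale (default 0.05, i.e.
#'   ~5% plate-to-plate variation).
#' @param cellfree_offset additive particle-interference signal, a scalar or
#'   a numeric named by particle (default 0 = no interference).
#' @return data frame of class `plate_measurements` with columns `particle`,
#'   `cell_line`, `assay`, `dose`, `experiment`, `technical_rep`,
#'   `cell_free`, `signal`.
#' @export
generate_cytotox_plate <- function(design, truth, seed,
                                   baseline = c(LDH = 2000, ATP = 50000,
                                                CTB = 30000),
                                   plate_sd = 0.05,
                                   cellfree_offset = 0) {
  stopifnot(inherits(design, "exposure_design"),
            inherits(truth, "potency_truth"))
  if (any(baseline[design$assays] <= 0) || anyNA(baseline[design$assays])) {
    .np_stop("`baseline` must give a positive value for every assay")
  }
  if (is.null(names(cellfree_offset))) {
    cellfree_offset <- stats::setNames(
      rep_len(cellfree_offset, length(design$particles)), design$particles)
  }
  key <- function(p, cl, a) paste(p, cl, a, sep = "\r")
  tb <- stats::setNames(truth$true_beta,
                        key(truth$particle, truth$cell_line, truth$assay))
  cv <- stats::setNames(truth$noise_cv,
                        key(truth$particle, truth$cell_line, truth$assay))

  .np_with_seed(seed, {
    grid <- expand.grid(
      technical_rep = seq_len(design$n_technical),
      dose = design$doses,
      experiment = seq_len(design$n_experiments),
      assay = design$assays,
      cell_line = design$cell_lines,
      particle = design$particles,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    k <- key(grid$particle, grid$cell_line, grid$assay)
    if (anyNA(tb[k])) {
      .np_stop("`truth` does not cover every particle x cell line x assay")
    }
    # experiment-level plate scale, shared by all wells of one
    # particle x cell_line x assay x experiment group
    ek <- paste(k, grid$experiment, sep = "\r")
    uek <- unique(ek)
    esc <- stats::setNames(exp(stats::rnorm(length(uek), 0, plate_sd)), uek)
    mu <- baseline[grid$assay] * esc[ek] * (grid$dose + 1)^tb[k]
    noise <- exp(stats::rnorm(nrow(grid), 0,
                              .np_sdlog(cv[k])) - .np_sdlog(cv[k])^2 / 2)
    off <- unname(cellfree_offset[grid$particle])
    grid$cell_free <- FALSE
    grid$signal <- as.numeric(mu * noise + off)

    # one cell-free well per particle x assay x dose x experiment; its signal
    # is the interference offset (floored to stay positive) so that
    # subtracting the matched cell-free mean restores the biological signal
    cf <- expand.grid(
      technical_rep = 1L,
      dose = design$doses,
      experiment = seq_len(design$n_experiments),
      assay = design$assays,
      cell_line = design$cell_lines,
      particle = design$particles,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cf$cell_free <- TRUE
    cf$signal <- pmax(unname(cellfree_offset[cf$particle]), 1e-3)

    out <- rbind(grid, cf)
    out <- out[, c("particle", "cell_line", "assay", "dose", "experiment",
                   "technical_rep", "cell_free", "signal")]
    rownames(out) <- NULL
    class(out) <- c("plate_measurements", "data.frame")
    out
  })
}

# property -> (mean, sd) on its natural scale; chosen to resemble published
# characterization tables for silica/titania nanoforms
.physchem_scales <- list(
  tem_size = c(45, 30), bet_sa = c(60, 40), dls_size = c(450, 250),
  pdi = c(0.35, 0.15), zeta_potential = c(-15, 15),
  tga_groups = c(500, 300), total_metals = c(600, 250),
  transition_metals = c(520, 220), transition_metals_no_ti = c(80, 40))

#' Simulate a physicochemical characterization table
#'
#' One row per particle with the descriptor columns of a standard nanoform
#' characterization panel (TEM size, BET surface area, DLS size, PDI,
#' zeta-potential, TGA surface groups, metal contents) plus subset labels.
#' Optionally one property is "planted" to correlate with a supplied
#' consensus-potency vector at an exact sample correlation, so determinant
#' recovery by the association screen can be tested; all other properties are
#' independent noise.
#'
#' @param particles character vector of particle labels.
#' @param seed integer RNG seed.
#' @param planted_property name of the descriptor column to plant, or `NULL`
#'   for a fully null table.
#' @param target_r desired Pearson correlation (in `[-1, 1]`) between the
#'   planted column and `beta_avg`; achieved exactly by construction.
#' @param beta_avg numeric vector of consensus potencies, one per particle;
#'   required when `planted_property` is set.
#' @param coating,crystal optional label vectors recycled across particles
#'   (subset masks for the correlation screen are explicit configuration, so
#'   these are carried as plain columns).
#' @return data frame of class `physchem_table`.
#' @export
generate_physchem_table <- function(particles, seed,
                                    planted_property = NULL,
                                    target_r = 0, beta_avg = NULL,
                                    coating = c("pristine", "coated"),
                                    crystal = "mixed") {
  n <- length(particles)
  if (n < 1L) .np_stop("at least one particle is required")
  props <- names(.physchem_scales)
  if (!is.null(planted_property)) {
    planted_property <- match.arg(planted_property, props)
    if (is.null(beta_avg) || length(beta_avg) != n) {
      .np_stop("`beta_avg` must supply one value per particle")
    }
    if (abs(target_r) > 1) .np_stop("|target_r| must be <= 1")
  }
  .np_with_seed(seed, {
    tab <- data.frame(particle = as.character(particles),
                      stringsAsFactors = FALSE)
    for (p in props) {
      sc <- .physchem_scales[[p]]
      tab[[p]] <- stats::rnorm(n, sc[1], sc[2])
      if (p != "zeta_potential") tab[[p]] <- abs(tab[[p]])
      if (p == "pdi") tab[[p]] <- pmin(pmax(tab[[p]], 0.05), 0.95)
    }
    if (!is.null(planted_property)) {
      sc <- .physchem_scales[[planted_property]]
      z <- .np_correlated_vector(as.numeric(beta_avg), target_r)
      x <- sc[1] + sc[2] * z
      if (planted_property != "zeta_potential") {
        x <- x - min(x, 0) + 0.05 * sc[1]  # shift keeps r, restores positivity
      }
      tab[[planted_property]] <- x
    }
    tab$coating <- rep_len(coating, n)
    tab$crystal <- rep_len(crystal, n)
    class(tab) <- c("physchem_table", "data.frame")
    tab
  })
}

#' Simulate replicate protein quantification matrices
#'
#' Log-normal protein abundances for a treated and a control condition over a
#' shared universe. Members of perturbed gene sets are shifted in the treated
#' condition by the requested log2 effect; every other protein is null, so a
#' correct enrichment stage should flag exactly the perturbed sets.
#'
#' @param universe_size total number of proteins; must cover all set members.
#' @param sets a gene-set collection (named list of member id vectors), e.g.
#'   from [read_gmt()].
#' @param perturbed named numeric: set name -> log2 effect in treated samples.
#' @param n_reps replicates per condition (>= 2).
#' @param seed integer RNG seed.
#' @param cv well-level coefficient of variation of abundances.
#' @return list with elements `treated` and `control`, each a numeric matrix
#'   (proteins x replicates) with protein ids as row names.
#' @export
generate_protein_matrix <- function(universe_size, sets, perturbed = list(),
                                    n_reps = 3L, seed, cv = 0.25) {
  if (n_reps < 2L) .np_stop("n_reps must be >= 2")
  perturbed <- unlist(perturbed)
  if (length(perturbed) > 0) {
    unknown <- setdiff(names(perturbed), names(sets))
    if (length(unknown)) .np_stop("unknown set name(s) in `perturbed`: %s",
                                  paste(unknown, collapse = ", "))
  }
  members <- unique(unlist(sets, use.names = FALSE))
  if (length(members) > universe_size) {
    .np_stop("universe_size (%d) smaller than the union of set members (%d)",
             universe_size, length(members))
  }
  filler <- sprintf("P%05d", seq_len(universe_size - length(members)))
  universe <- c(members, filler)
  .np_with_seed(seed, {
    mu <- stats::rnorm(universe_size, 10, 2)      # per-protein log2 baseline
    sdlog2 <- .np_sdlog(cv) / log(2)
    shift <- stats::setNames(numeric(universe_size), universe)
    for (s in names(perturbed)) shift[sets[[s]]] <- shift[sets[[s]]] + perturbed[[s]]
    draw <- function(m) {
      x <- matrix(2^(stats::rnorm(universe_size * n_reps, mean = rep(m, n_reps),
                                  sd = sdlog2)),
                  nrow = universe_size,
                  dimnames = list(universe, sprintf("rep%d", seq_len(n_reps))))
      x
    }
    list(treated = draw(mu + shift), control = draw(mu))
  })
}

#' Simulate a single-dose mechanistic marker panel
#'
#' Per-particle oxidative-stress (GSH/GSSG ratio fold change) and
#' proinflammatory cytokine fold changes measured at the mechanistic dose
#' only. `target_r` is applied to the GSH/GSSG column; the cytokine column
#' receives `-target_r`, reflecting that potency tracks depleted glutathione
#' (oxidative stress) and elevated cytokine secretion. Correlations are exact
#' by construction.
#'
#' @param particles particle labels.
#' @param beta_avg consensus potency per particle.
#' @param target_r Pearson correlation between `beta_avg` and the GSH/GSSG
#'   fold change, in `[-1, 1]` (typically negative).
#' @param seed integer RNG seed.
#' @param mechanistic_dose dose (ug/cm^2) recorded on every row.
#' @return data frame of class `marker_panel` with columns `particle`,
#'   `dose`, `gsh_gssg_fold`, `cytokine_fold`.
#' @export
generate_marker_panel <- function(particles, beta_avg, target_r = -0.8,
                                  seed, mechanistic_dose = 30) {
  n <- length(particles)
  if (length(beta_avg) != n) .np_stop("`beta_avg` must match `particles`")
  if (abs(target_r) > 1) .np_stop("|target_r| must be <= 1")
  .np_with_seed(seed, {
    gsh <- 1 + 0.25 * .np_correlated_vector(as.numeric(beta_avg), target_r)
    cyt <- 2 + 0.60 * .np_correlated_vector(as.numeric(beta_avg), -target_r)
    out <- data.frame(particle = as.character(particles),
                      dose = mechanistic_dose,
                      gsh_gssg_fold = gsh, cytokine_fold = cyt,
                      stringsAsFactors = FALSE)
    class(out) <- c("marker_panel", "data.frame")
    out
  })
}
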