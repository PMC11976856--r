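# Potency stage: fold-effect normalization, power-law fitting, consensus
# potency and dense ranking.

#' Normalize raw plate signals to fold effects
#'
#' Each signal is divided by the mean dose-zero signal of its own
#' particle x cell line x assay x experiment group, giving the dimensionless
#' fold effect FE. With `subtract_cell_free = TRUE` the mean cell-free signal
#' at the matching particle x dose x assay (pooled over experiments) is first
#' subtracted from both numerator and denominator, removing additive particle
#' interference; corrected signals that are not positive are dropped with a
#' warning.
#'
#' @param raw a `plate_measurements` data frame (see
#'   [generate_cytotox_plate()] or [read_plate_csv()]); a `cell_free` logical
#'   column is optional and defaults to all-`FALSE`.
#' @param subtract_cell_free apply the cell-free interference correction?
#' @return data frame of class `dose_response` with columns `particle`,
#'   `cell_line`, `assay`, `dose`, `experiment`, `technical_rep`, `FE`.
#'   Attribute `drop_report` reconciles input, retained and dropped counts.
#' @export
compute_fold_effect <- function(raw, subtract_cell_free = FALSE) {
  .np_check_cols(raw, c("particle", "cell_line", "assay", "dose",
                        "experiment", "signal"), "plate table")
  if (is.null(raw$cell_free)) raw$cell_free <- FALSE
  if (is.null(raw$technical_rep)) raw$technical_rep <- 1L
  cells <- raw[!raw$cell_free, , drop = FALSE]
  cf <- raw[raw$cell_free, , drop = FALSE]
  n_input <- nrow(cells)
  if (n_input == 0L) .np_stop("no cell wells in input")

  sig <- cells$signal
  if (subtract_cell_free) {
    if (nrow(cf) == 0L) {
      .np_warn("subtract_cell_free = TRUE but no cell-free records; no correction applied")
    } else {
      k <- paste(cf$particle, cf$assay, cf$dose, sep = "\r")
      cfm <- tapply(cf$signal, k, mean)
      kk <- paste(cells$particle, cells$assay, cells$dose, sep = "\r")
      adj <- cfm[kk]
      adj[is.na(adj)] <- 0
      sig <- sig - as.numeric(adj)
    }
  }
  keep <- sig > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    .np_warn("dropped %d record(s) with non-positive corrected signal", n_dropped)
  }
  cells <- cells[keep, , drop = FALSE]
  sig <- sig[keep]
  if (nrow(cells) == 0L) .np_stop("all records dropped after correction")

  grp <- paste(cells$particle, cells$cell_line, cells$assay,
               cells$experiment, sep = "\r")
  is0 <- cells$dose == 0
  if (any(!unique(grp) %in% grp[is0])) {
    bad <- setdiff(unique(grp), grp[is0])[1L]
    .np_stop("group '%s' has no dose-0 record to normalize against",
             gsub("\r", " / ", bad))
  }
  base <- tapply(sig[is0], grp[is0], mean)
  fe <- sig / as.numeric(base[grp])

  out <- data.frame(particle = cells$particle, cell_line = cells$cell_line,
                    assay = cells$assay, dose = cells$dose,
                    experiment = cells$experiment,
                    technical_rep = cells$technical_rep,
                    FE = fe, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "drop_report") <- list(input = n_input, retained = nrow(out),
                                   dropped_nonpositive = n_dropped,
                                   cell_free_excluded = nrow(cf))
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Fit the power-law potency model for one endpoint
#'
#' Fits `FE = (dose + 1)^beta` by least squares through the origin on the
#' log-log scale: `ln FE = beta * ln(dose + 1)`, using every replicate-level
#' record (or per-dose mean FE with `on_dose_means = TRUE`). The zero
#' intercept is forced by the model itself, which pins FE(0) = 1; dose-zero
#' records sit at the origin and carry no leverage. The reported potency is
#' the slope magnitude (assays that decline with dose give negative slopes);
#' the signed slope is kept for diagnostics.
#'
#' @param dr a `dose_response` table from [compute_fold_effect()].
#' @param particle,cell_line,endpoint the group to fit; `endpoint` is one of
#'   `"LDH"`, `"ATP"`, `"CTB"`.
#' @param on_dose_means fit per-dose mean FE instead of replicate-level FE.
#' @return one-row data frame of class `potency_estimate`: `particle`,
#'   `cell_line`, `endpoint`, `beta` (= |signed_slope|), `signed_slope`,
#'   `se_beta`, `r_squared`, `n_points`.
#' @export
fit_potency <- function(dr, particle, cell_line, endpoint,
                        on_dose_means = FALSE) {
  .np_check_cols(dr, c("particle", "cell_line", "assay", "dose", "FE"),
                 "dose-response table")
  sub <- dr[dr$particle == particle & dr$cell_line == cell_line &
              dr$assay == endpoint, , drop = FALSE]
  if (nrow(sub) == 0L) {
    .np_stop("no records for %s / %s / %s", particle, cell_line, endpoint)
  }
  bad <- !is.finite(sub$FE) | sub$FE <= 0
  if (any(bad)) {
    .np_warn("excluded %d record(s) with non-positive FE from the fit", sum(bad))
    sub <- sub[!bad, , drop = FALSE]
  }
  if (on_dose_means) {
    fe <- tapply(sub$FE, sub$dose, mean)
    sub <- data.frame(dose = as.numeric(names(fe)), FE = as.numeric(fe))
  }
  if (sum(sub$dose > 0) < 1L) {
    .np_stop("fit for %s / %s / %s needs at least one positive-dose record",
             particle, cell_line, endpoint)
  }
  x <- log(sub$dose + 1)
  y <- log(sub$FE)
  fit <- stats::lm(y ~ x + 0)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[["x"]])
  se <- unname(sm$coefficients["x", "Std. Error"])
  out <- data.frame(particle = particle, cell_line = cell_line,
                    endpoint = endpoint,
                    beta = abs(slope), signed_slope = slope,
                    se_beta = se, r_squared = sm$r.squared,
                    n_points = nrow(sub), stringsAsFactors = FALSE)
  class(out) <- c("potency_estimate", "data.frame")
  out
}

#' Fit every particle x cell line x endpoint group of a dose-response table
#'
#' @inheritParams fit_potency
#' @return data frame of stacked [fit_potency()] rows.
#' @export
fit_potency_all <- function(dr, on_dose_means = FALSE) {
  groups <- unique(dr[, c("particle", "cell_line", "assay")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    fit_potency(dr, groups$particle[i], groups$cell_line[i], groups$assay[i],
                on_dose_means = on_dose_means)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("potency_estimate", "data.frame")
  out
}

#' Consensus potency across the three cytotoxicity endpoints
#'
#' `beta_avg` is the arithmetic mean of the LDH, ATP and CTB potency
#' magnitudes for one particle and cell line. Exactly those three endpoints
#' must be present; the mean is symmetric in its arguments.
#'
#' @param betas either a numeric vector named `LDH`, `ATP`, `CTB`, or a
#'   `potency_estimate` data frame holding exactly one row per endpoint for a
#'   single particle/cell line.
#' @return one-row data frame of class `consensus_potency` with the component
#'   betas and `beta_avg`.
#' @export
consensus_potency <- function(betas) {
  need <- c("LDH", "ATP", "CTB")
  if (is.data.frame(betas)) {
    .np_check_cols(betas, c("endpoint", "beta"), "potency estimates")
    if (length(unique(paste(betas$particle, betas$cell_line))) > 1L) {
      .np_stop("consensus_potency() takes a single particle/cell line group")
    }
    v <- stats::setNames(betas$beta, betas$endpoint)
    particle <- betas$particle[1] %||% NA_character_
    cell_line <- betas$cell_line[1] %||% NA_character_
  } else {
    v <- betas
    particle <- NA_character_
    cell_line <- NA_character_
  }
  if (!setequal(names(v), need) || length(v) != 3L) {
    .np_stop("exactly the three endpoints %s are required (got: %s)",
             paste(need, collapse = "/"),
             paste(names(v), collapse = "/"))
  }
  if (any(v < 0) || anyNA(v)) .np_stop("component betas must be non-negative")
  out <- data.frame(particle = particle, cell_line = cell_line,
                    beta_LDH = unname(v["LDH"]), beta_ATP = unname(v["ATP"]),
                    beta_CTB = unname(v["CTB"]),
                    beta_avg = unname(mean(v[need])),
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_potency", "data.frame")
  out
}

#' Consensus potencies for a whole estimates table
#'
#' @param estimates a `potency_estimate` data frame covering all three
#'   endpoints for each particle x cell line group.
#' @return data frame of class `consensus_potency`, one row per group.
#' @export
consensus_table <- function(estimates) {
  groups <- unique(estimates[, c("particle", "cell_line")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- estimates[estimates$particle == groups$particle[i] &
                       estimates$cell_line == groups$cell_line[i], ]
    consensus_potency(sub)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("consensus_potency", "data.frame")
  out
}

#' Dense potency ranking within one cell line
#'
#' Consensus potencies are rounded to `precision` decimals and ranked in
#' descending order with dense tie handling: the most potent particle is rank
#' 1, equal rounded values share a rank, and the next distinct value takes
#' the next consecutive integer (so the ranks used are exactly
#' `1..k` for `k` distinct rounded values). Rounding before ranking is what
#' produces the shared ranks seen in published potency tables.
#'
#' @param consensus a `consensus_potency` data frame (a single cell line), or
#'   a numeric vector of beta_avg values named by particle.
#' @param precision decimals to round to before ranking (default 3).
#' @return data frame of class `rank_table`: `particle`, `beta_avg`,
#'   `rounded_beta_avg`, `rank`.
#' @export
rank_particles <- function(consensus, precision = 3L) {
  if (is.data.frame(consensus)) {
    .np_check_cols(consensus, c("particle", "beta_avg"), "consensus table")
    if (!is.null(consensus$cell_line) &&
        length(unique(consensus$cell_line[!is.na(consensus$cell_line)])) > 1L) {
      .np_stop("rank_particles() ranks a single cell line per call")
    }
    particle <- consensus$particle
    beta_avg <- consensus$beta_avg
  } else {
    particle <- names(consensus) %||% as.character(seq_along(consensus))
    beta_avg <- as.numeric(consensus)
  }
  if (length(beta_avg) == 0L) .np_stop("empty consensus input")
  rounded <- round(beta_avg, precision)
  lev <- sort(unique(rounded), decreasing = TRUE)
  out <- data.frame(particle = particle, beta_avg = beta_avg,
                    rounded_beta_avg = rounded,
                    rank = match(rounded, lev), stringsAsFactors = FALSE)
  class(out) <- c("rank_table", "data.frame")
  out
}
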