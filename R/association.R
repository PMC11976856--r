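# Association stage: factorial hypothesis tests on FE data and correlation
# screening of consensus potency against descriptors and markers.

#' Fixed-effects factorial ANOVA on fold-effect data
#'
#' Fits all main effects plus (by default) all two-way interactions of the
#' requested factors and reports a per-term ANOVA table. With
#' `rank_transform = TRUE` the entire response vector is replaced by
#' mid-ranks before fitting -- the standard rank-transform device used when
#' fold effects violate normality/equal-variance assumptions, and invariant
#' to any strictly monotone transform of the response. Sums of squares are
#' Type II (each term adjusted for every term that does not contain it),
#' which reduces to the usual sequential decomposition on balanced designs.
#'
#' @param data data frame holding the response and factor columns.
#' @param response name of the numeric response column (e.g. `"FE"`).
#' @param factors character vector of >= 2-level factor columns (e.g.
#'   `c("size", "dose", "mod")` for a three-way layout).
#' @param rank_transform replace the response by mid-ranks before fitting?
#' @param max_order highest interaction order to include (default 2; use
#'   `length(factors)` for the saturated factorial).
#' @return data frame of class `anova_table` with columns `term`, `df`,
#'   `sum_sq`, `mean_sq`, `statistic`, `p_value` (residual row last);
#'   attribute `rank_transformed` records the transform flag.
#' @export
anova_factorial <- function(data, response, factors, rank_transform = FALSE,
                            max_order = 2L) {
  .np_check_cols(data, c(response, factors), "ANOVA input")
  if (length(factors) < 1L) .np_stop("at least one factor is required")
  d <- data[, c(response, factors)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  for (f in factors) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) < 2L) {
      .np_stop("factor '%s' has fewer than 2 levels", f)
    }
  }
  y <- d[[response]]
  if (!is.numeric(y)) .np_stop("response '%s' must be numeric", response)
  if (rank_transform) y <- rank(y)          # mid-ranks for ties
  d$.y <- y

  max_order <- min(max_order, length(factors))
  rhs <- unlist(lapply(seq_len(max_order), function(k) {
    utils::combn(factors, k, paste, collapse = ":")
  }))
  full_formula <- stats::reformulate(rhs, response = ".y")
  full <- stats::lm(full_formula, data = d)
  rdf <- stats::df.residual(full)
  if (rdf < 1L) {
    top <- rhs[which.max(lengths(strsplit(rhs, ":", fixed = TRUE)))]
    .np_stop("no residual degrees of freedom: term '%s' is not estimable %s",
             top, "without replication")
  }
  rss_full <- sum(stats::residuals(full)^2)
  mse <- rss_full / rdf

  rss_of <- function(terms) {
    if (length(terms) == 0L) {
      sum((d$.y - mean(d$.y))^2)
    } else {
      sum(stats::residuals(stats::lm(stats::reformulate(terms, ".y"), d))^2)
    }
  }
  contains <- function(a, b) {  # does term a contain term b?
    all(strsplit(b, ":")[[1]] %in% strsplit(a, ":")[[1]])
  }
  rows <- lapply(rhs, function(tm) {
    others <- rhs[!vapply(rhs, contains, logical(1), b = tm)]
    ss <- rss_of(others) - rss_of(c(others, tm))
    df <- prod(vapply(strsplit(tm, ":")[[1]],
                      function(f) nlevels(d[[f]]) - 1L, integer(1)))
    ss <- max(ss, 0)
    tot <- sum((d$.y - mean(d$.y))^2)
    if (ss <= 1e-12 * max(tot, 1)) ss <- 0    # constant response -> F = 0
    f_stat <- if (ss == 0) 0 else (ss / df) / mse
    data.frame(term = tm, df = df, sum_sq = ss, mean_sq = ss / df,
               statistic = f_stat,
               p_value = stats::pf(f_stat, df, rdf, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(term = "Residuals", df = rdf, sum_sq = rss_full,
                               mean_sq = mse, statistic = NA_real_,
                               p_value = NA_real_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "rank_transformed") <- rank_transform
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak procedure: with the p-values sorted ascending, the i-th
#' smallest is adjusted to `1 - (1 - p_(i))^(m - i + 1)`, adjusted values are
#' made monotone non-decreasing along the sorted order, capped at 1, and
#' returned in the original input order. At `m = 1` the p-value is returned
#' unchanged.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as the input.
#' @export
holm_sidak <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    .np_stop("p-values must lie in [0, 1] with no NAs")
  }
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Shared correlation engine: x against each column of `ytab`, pairwise
# deletion, t-distributed p (df = n - 2); Spearman runs Pearson on mid-ranks.
.cor_screen <- function(x, x_name, ytab, method, subset_label = NA_character_) {
  method <- match.arg(method, c("pearson", "spearman"))
  rows <- lapply(names(ytab), function(nm) {
    y <- ytab[[nm]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    res <- data.frame(x_name = x_name, y_name = nm, method = method,
                      n = n, r = NA_real_, p = NA_real_,
                      subset = subset_label, skipped = TRUE,
                      stringsAsFactors = FALSE)
    if (n < 3L) {
      .np_warn("correlation with '%s' skipped: n = %d < 3", nm, n)
      return(res)
    }
    xi <- x[ok]; yi <- y[ok]
    if (method == "spearman") { xi <- rank(xi); yi <- rank(yi) }
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) {
      .np_warn("correlation with '%s' skipped: zero variance", nm)
      return(res)
    }
    r <- stats::cor(xi, yi)
    if (abs(r) >= 1) {
      p <- 0
    } else {
      t <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
    res$r <- r; res$p <- p; res$skipped <- FALSE
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_screen", "data.frame")
  out
}

#' Correlate consensus potency with physicochemical descriptors
#'
#' Screens `beta_avg` against every numeric descriptor column of the
#' characterization table, with pairwise deletion of missing values and the
#' per-correlation `n` reported. Subsets (e.g. pristine-only, anatase-only)
#' are explicit masks supplied by the caller -- membership is configuration,
#' never inferred from particle names. Correlations with fewer than 3
#' complete pairs or a zero-variance side are reported as skipped (with a
#' warning), never silently omitted.
#'
#' @param consensus a `consensus_potency` data frame (or any data frame with
#'   `particle` and `beta_avg`).
#' @param physchem a `physchem_table` (one row per particle).
#' @param properties descriptor columns to screen; default: every numeric
#'   column of `physchem` except the potency join key.
#' @param subset optional logical mask on the rows of `physchem` (or a
#'   character vector of particle labels) selecting the subset to screen.
#' @param subset_label free-text label recorded on each result row.
#' @param method `"pearson"` (product-moment) or `"spearman"` (mid-ranks).
#' @return data frame of class `correlation_screen`.
#' @export
correlate_potency_physchem <- function(consensus, physchem,
                                       properties = NULL, subset = NULL,
                                       subset_label = "all",
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  .np_check_cols(consensus, c("particle", "beta_avg"), "consensus table")
  .np_check_cols(physchem, "particle", "physchem table")
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- physchem$particle %in% subset
    physchem <- physchem[subset, , drop = FALSE]
  }
  if (nrow(physchem) == 0L) {
    .np_warn("subset excludes every particle; empty screen returned")
    out <- data.frame(x_name = character(0), y_name = character(0),
                      method = character(0), n = integer(0), r = numeric(0),
                      p = numeric(0), subset = character(0),
                      skipped = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("correlation_screen", "data.frame")
    return(out)
  }
  m <- merge(physchem, consensus[, c("particle", "beta_avg")], by = "particle")
  if (is.null(properties)) {
    properties <- setdiff(names(m)[vapply(m, is.numeric, logical(1))],
                          "beta_avg")
  }
  .cor_screen(m$beta_avg, "beta_avg", m[, properties, drop = FALSE],
              method, subset_label)
}

#' Correlate consensus potency with mechanistic markers
#'
#' Same engine as [correlate_potency_physchem()], applied to single-dose
#' marker panels (GSH/GSSG ratio fold change, cytokine fold change).
#'
#' @param consensus a `consensus_potency` data frame.
#' @param markers a `marker_panel` data frame (one row per particle).
#' @param markers_cols marker columns to screen; default: every numeric
#'   column except `dose`.
#' @inheritParams correlate_potency_physchem
#' @return data frame of class `correlation_screen`.
#' @export
correlate_potency_markers <- function(consensus, markers, markers_cols = NULL,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  .np_check_cols(consensus, c("particle", "beta_avg"), "consensus table")
  .np_check_cols(markers, "particle", "marker panel")
  m <- merge(markers, consensus[, c("particle", "beta_avg")], by = "particle")
  if (is.null(markers_cols)) {
    markers_cols <- setdiff(names(m)[vapply(m, is.numeric, logical(1))],
                            c("beta_avg", "dose"))
  }
  .cor_screen(m$beta_avg, "beta_avg", m[, markers_cols, drop = FALSE], method)
}
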