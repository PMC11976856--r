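# Proteomic enrichment stage: protein fold changes, preranked GSEA
# (running-sum ES, permutation NES/p, sign-stratified FDR), NES clustering,
# and threshold over-representation. The GSEA core is implemented here from
# first principles -- it is the analytical heart of the proteomic stage.

#' Protein fold changes ranked against control
#'
#' Per-protein fold change = mean treated abundance / mean control abundance
#' over the shared protein universe. Proteins observed (finite, positive
#' replicate count) fewer than `min_obs` times in either condition are
#' dropped, with the count reported via `message()`. The result is strictly
#' sorted by descending score with ties broken by protein id, as preranked
#' GSEA requires a deterministic order.
#'
#' @param treated,control numeric matrices (proteins x replicates) with
#'   protein ids as row names; `NA` marks a missed observation.
#' @param min_obs minimum finite observations per condition to retain a
#'   protein (default 2).
#' @return data frame of class `ranked_proteins` with columns `protein`,
#'   `score`, sorted descending.
#' @export
compute_protein_fold_change <- function(treated, control, min_obs = 2L) {
  if (is.null(rownames(treated)) || is.null(rownames(control))) {
    .np_stop("both matrices need protein ids as row names")
  }
  shared <- intersect(rownames(treated), rownames(control))
  if (length(shared) == 0L) .np_stop("no shared proteins between conditions")
  tr <- treated[shared, , drop = FALSE]
  ct <- control[shared, , drop = FALSE]
  nt <- rowSums(is.finite(tr))
  nc <- rowSums(is.finite(ct))
  keep <- nt >= min_obs & nc >= min_obs
  if (any(!keep)) {
    message(sprintf("compute_protein_fold_change: dropped %d of %d proteins below min_obs = %d",
                    sum(!keep), length(shared), min_obs))
  }
  if (!any(keep)) .np_stop("no protein passes min_obs = %d", min_obs)
  score <- rowMeans(tr[keep, , drop = FALSE], na.rm = TRUE) /
    rowMeans(ct[keep, , drop = FALSE], na.rm = TRUE)
  out <- data.frame(protein = shared[keep], score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_proteins", "data.frame")
  out
}

#' Per-protein two-sample p-values on the log2 scale
#'
#' Welch t-test of log2 treated vs log2 control replicate abundances per
#' protein, the companion to [compute_protein_fold_change()] for the
#' threshold over-representation stage. Proteins with fewer than 2 finite
#' observations on either side get `NA`.
#'
#' @inheritParams compute_protein_fold_change
#' @return named numeric vector of p-values over the shared universe.
#' @export
protein_pvalues <- function(treated, control) {
  shared <- intersect(rownames(treated), rownames(control))
  if (length(shared) == 0L) .np_stop("no shared proteins between conditions")
  vapply(shared, function(p) {
    x <- log2(treated[p, ]); y <- log2(control[p, ])
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    stats::t.test(x, y)$p.value
  }, numeric(1))
}

# Running-sum core shared by the public API and the permutation null.
# hit: logical vector along the ranked list; absw: |score|^weight.
# Extremum rule: largest |deviation|; when the positive and negative
# extremes agree to within 1e-9 (a floating-point tie), the earlier
# position wins, making the result independent of summation order.
.es_core <- function(hit, absw) {
  n <- length(hit)
  nh <- sum(hit)
  denom <- sum(absw[hit])
  inc <- numeric(n)
  if (denom > 0) inc[hit] <- absw[hit] / denom else inc[hit] <- 1 / nh
  inc[!hit] <- -1 / (n - nh)
  run <- cumsum(inc)
  i_up <- which.max(run)
  i_dn <- which.min(run)
  up <- run[i_up]
  dn <- run[i_dn]
  i <- if (abs(abs(up) - abs(dn)) <= 1e-9) {
    min(i_up, i_dn)
  } else if (abs(up) > abs(dn)) i_up else i_dn
  list(es = run[i], run = run, extremum = i)
}

#' GSEA running-sum enrichment score for one gene set
#'
#' Walking the ranked list from top to bottom, set members ("hits")
#' increment a running sum by `|score|^weight / sum_set |score|^weight` and
#' non-members decrement it by `1 / (N - n_set)`. The enrichment score ES is
#' the running-sum value of maximum absolute deviation from zero (first such
#' position on ties), so ES is in `[-1, 1]`; at `weight = 0` it reduces to
#' the classic Kolmogorov-Smirnov statistic between hit and miss positions.
#' The leading edge is the hit members at or before the extremum for
#' positive ES, and strictly after it for negative ES.
#'
#' @param ranked a `ranked_proteins` data frame (see
#'   [compute_protein_fold_change()]), or a named numeric score vector
#'   already sorted descending.
#' @param members character vector of set member ids.
#' @param weight exponent on |score| for hit increments (default 1, the
#'   classic weighted statistic; 0 gives the unweighted KS form).
#' @return list with `es`, `running_sum` (length-N profile) and
#'   `leading_edge` (character vector of member ids).
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  if (is.data.frame(ranked)) {
    ids <- ranked$protein
    scores <- ranked$score
  } else {
    ids <- names(ranked)
    scores <- as.numeric(ranked)
  }
  n <- length(ids)
  hit <- ids %in% members
  nh <- sum(hit)
  if (nh == 0L) .np_stop("gene set has no overlap with the ranked list")
  if (nh == n) .np_stop("gene set covers the whole ranked universe")
  absw <- abs(scores)^weight
  res <- .es_core(hit, absw)
  le <- if (res$es >= 0) {
    ids[hit & seq_len(n) <= res$extremum]
  } else {
    ids[hit & seq_len(n) > res$extremum]
  }
  list(es = res$es, running_sum = res$run, leading_edge = le)
}

#' Preranked gene set enrichment analysis
#'
#' From-scratch preranked GSEA. Because only a ranked fold-change list exists
#' (no per-sample phenotype labels), the null is gene-label sampling: for
#' each set, `n_perm` random draws of the same size from the ranked universe
#' give a null ES distribution. NES = ES divided by the mean |null ES| of
#' matching sign; the nominal p-value is the fraction of same-sign null ES at
#' least as extreme as the observed; the FDR q-value compares the observed
#' NES against the pooled sign-stratified null NES distribution (the standard
#' preranked GSEA scheme). Fully deterministic given `seed`.
#'
#' @inheritParams enrichment_score
#' @param sets named list of member-id vectors (see [read_gmt()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return data frame of class `gsea_results`, one row per scored set:
#'   `set`, `n_hits`, `es`, `nes`, `p_value`, `fdr_q`, plus a list-column
#'   `leading_edge`. Sets with no overlap (or full overlap) are skipped with
#'   a warning. A set whose null contains no same-sign ES gets `NA` NES and
#'   is flagged in `nes_defined`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000L, weight = 1, seed) {
  if (n_perm < 100L) .np_stop("n_perm must be >= 100")
  if (length(sets) == 0L) .np_stop("empty gene set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    .np_stop("gene sets must have unique names")
  }
  if (is.data.frame(ranked)) {
    ids <- ranked$protein; scores <- ranked$score
  } else {
    ids <- names(ranked); scores <- as.numeric(ranked)
  }
  n <- length(ids)
  absw <- abs(scores)^weight

  usable <- vapply(sets, function(m) {
    k <- sum(ids %in% m); k > 0L && k < n
  }, logical(1))
  if (any(!usable)) {
    .np_warn("skipped %d set(s) with no usable overlap: %s", sum(!usable),
             paste(names(sets)[!usable], collapse = ", "))
  }
  sets <- sets[usable]
  if (length(sets) == 0L) {
    out <- data.frame(set = character(0), n_hits = integer(0),
                      es = numeric(0), nes = numeric(0),
                      p_value = numeric(0), fdr_q = numeric(0),
                      nes_defined = logical(0))
    out$leading_edge <- list()
    class(out) <- c("gsea_results", "data.frame")
    return(out)
  }

  .np_with_seed(seed, {
    m <- length(sets)
    es_obs <- numeric(m)
    nes_obs <- rep(NA_real_, m)
    pval <- rep(NA_real_, m)
    nes_def <- logical(m)
    le <- vector("list", m)
    ksz <- integer(m)
    null_nes <- vector("list", m)

    for (j in seq_len(m)) {
      r <- enrichment_score(if (is.data.frame(ranked)) ranked else
        stats::setNames(scores, ids), sets[[j]], weight)
      es_obs[j] <- r$es
      le[[j]] <- r$leading_edge
      k <- sum(ids %in% sets[[j]])
      ksz[j] <- k
      null_es <- vapply(seq_len(n_perm), function(i) {
        hit <- logical(n)
        hit[sample.int(n, k)] <- TRUE
        .es_core(hit, absw)$es
      }, numeric(1))
      mean_pos <- mean(null_es[null_es > 0])
      mean_neg <- mean(abs(null_es[null_es < 0]))
      same <- if (r$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      if (length(same) > 0L) {
        pval[j] <- mean(abs(same) >= abs(r$es))
      }
      norm <- if (r$es >= 0) mean_pos else mean_neg
      if (is.finite(norm) && norm > 0) {
        nes_obs[j] <- r$es / norm
        nes_def[j] <- TRUE
      }
      # normalize the null the same way, for the FDR comparison
      nn <- null_es
      nn[null_es > 0] <- if (is.finite(mean_pos) && mean_pos > 0)
        null_es[null_es > 0] / mean_pos else NA_real_
      nn[null_es < 0] <- if (is.finite(mean_neg) && mean_neg > 0)
        null_es[null_es < 0] / mean_neg else NA_real_
      null_nes[[j]] <- nn[is.finite(nn)]
    }

    pool <- unlist(null_nes, use.names = FALSE)
    fdr <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      if (!nes_def[j]) next
      v <- nes_obs[j]
      if (v >= 0) {
        num_den <- sum(pool >= 0)
        num <- if (num_den > 0) sum(pool >= v) / num_den else NA_real_
        obs <- nes_obs[nes_def & nes_obs >= 0]
        den <- sum(obs >= v) / length(obs)
      } else {
        num_den <- sum(pool < 0)
        num <- if (num_den > 0) sum(pool <= v) / num_den else NA_real_
        obs <- nes_obs[nes_def & nes_obs < 0]
        den <- sum(obs <= v) / length(obs)
      }
      fdr[j] <- if (is.na(num) || den == 0) NA_real_ else min(1, num / den)
    }

    out <- data.frame(set = names(sets), n_hits = ksz, es = es_obs,
                      nes = nes_obs, p_value = pval, fdr_q = fdr,
                      nes_defined = nes_def, stringsAsFactors = FALSE)
    out$leading_edge <- le
    rownames(out) <- NULL
    class(out) <- c("gsea_results", "data.frame")
    out
  })
}

# hclust merge tree -> nested-parenthesis (newick-like) string with heights
.tree_to_newick <- function(hc) {
  lab <- hc$labels %||% as.character(seq_along(hc$order))
  node <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%g", lab[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%g", node(hc$merge[i, 1], h), node(hc$merge[i, 2], h),
              parent_h - h)
    }
  }
  n <- nrow(hc$merge)
  h <- hc$height[n]
  sprintf("(%s,%s);", node(hc$merge[n, 1], h), node(hc$merge[n, 2], h))
}

# pairwise-complete distance matrices; errors name the offending item/pair
.nes_dist <- function(mat, distance) {
  if (distance == "correlation") {
    cc <- suppressWarnings(stats::cor(t(mat), use = "pairwise.complete.obs"))
    if (anyNA(cc)) {
      bad <- which(is.na(cc), arr.ind = TRUE)[1, ]
      .np_stop("no complete pairs between '%s' and '%s'",
               rownames(mat)[bad[1]], rownames(mat)[bad[2]])
    }
    stats::as.dist(1 - cc)
  } else {
    d <- stats::dist(mat)  # NAs handled pairwise with rescaling
    if (anyNA(d)) .np_stop("Euclidean distance undefined for some row pair")
    d
  }
}

#' Hierarchically cluster a condition x set NES matrix
#'
#' Agglomerative clustering of the normalized-enrichment-score grid along
#' rows (conditions), columns (sets) or both, for heatmap-style display.
#' Distances are 1 - Pearson correlation (pairwise-complete; the customary
#' choice for enrichment heatmaps) or Euclidean; linkage is average or
#' complete, so merge heights are non-decreasing along the agglomeration.
#' Agglomeration is deterministic; equal merge distances are resolved by
#' original index order.
#'
#' @param mat numeric matrix (conditions x sets) of NES values; `NA`
#'   allowed. Dimnames are carried into the trees.
#' @param axis `"both"`, `"rows"` or `"columns"`.
#' @param distance `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return list with (per clustered axis) an `hclust` tree, the leaf order,
#'   a nested-parenthesis `newick` string, and `matrix`, the input reordered
#'   by the leaf orders.
#' @export
cluster_nes <- function(mat, axis = c("both", "rows", "columns"),
                        distance = c("correlation", "euclidean"),
                        linkage = c("average", "complete")) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("row%d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("col%d", seq_len(ncol(mat)))
  all_na_row <- rowSums(is.finite(mat)) == 0
  all_na_col <- colSums(is.finite(mat)) == 0
  if (any(all_na_row)) .np_stop("row '%s' is entirely missing",
                                rownames(mat)[which(all_na_row)[1]])
  if (any(all_na_col)) .np_stop("column '%s' is entirely missing",
                                colnames(mat)[which(all_na_col)[1]])
  out <- list(matrix = mat, axis = axis, distance = distance,
              linkage = linkage)
  if (axis %in% c("both", "rows")) {
    if (nrow(mat) < 2L) .np_stop("need >= 2 rows to cluster rows")
    hr <- stats::hclust(.nes_dist(mat, distance), method = linkage)
    out$row_tree <- hr
    out$row_order <- hr$order
    out$row_newick <- .tree_to_newick(hr)
  }
  if (axis %in% c("both", "columns")) {
    if (ncol(mat) < 2L) .np_stop("need >= 2 columns to cluster columns")
    hcl <- stats::hclust(.nes_dist(t(mat), distance), method = linkage)
    out$col_tree <- hcl
    out$col_order <- hcl$order
    out$col_newick <- .tree_to_newick(hcl)
  }
  out$matrix <- mat[out$row_order %||% seq_len(nrow(mat)),
                    out$col_order %||% seq_len(ncol(mat)), drop = FALSE]
  out
}

#' Threshold-based over-representation of gene sets
#'
#' Selects the proteins with fold change at or beyond a symmetric cutoff
#' (`score >= fc_cutoff` or `score <= 1/fc_cutoff`) and `p < p_cutoff`, then
#' asks, per set, whether the selection overlaps the set more than the
#' hypergeometric expectation: `z = (k - E) / sd_hypergeom` with
#' `E = n_sel * n_set / N`, plus the hypergeometric upper-tail p-value
#' `P(X >= k)`. A set is "identified" when `|z| >= z_cutoff`.
#'
#' @param scores a `ranked_proteins` data frame; its proteins define the
#'   universe.
#' @param pvalues named numeric vector (or 2-column data frame) of
#'   per-protein p-values; proteins without a p-value are never selected.
#' @param sets named list of member-id vectors.
#' @param fc_cutoff symmetric fold-change cutoff (default 1.5).
#' @param p_cutoff per-protein p-value cutoff (default 0.05).
#' @param z_cutoff identification threshold on |z| (default 2).
#' @return data frame of class `ora_results`: `set`, `n_set`, `overlap`,
#'   `expected`, `z`, `p_hyper`, `identified`; attribute `n_selected` gives
#'   the selection size. An empty selection is flagged with a warning and
#'   all-zero overlaps.
#' @export
overrepresentation_test <- function(scores, pvalues, sets, fc_cutoff = 1.5,
                                    p_cutoff = 0.05, z_cutoff = 2) {
  .np_check_cols(scores, c("protein", "score"), "ranked protein list")
  if (is.data.frame(pvalues)) {
    pvalues <- stats::setNames(pvalues[[2]], pvalues[[1]])
  }
  if (fc_cutoff < 1) .np_stop("fc_cutoff must be >= 1")
  universe <- scores$protein
  N <- length(universe)
  pv <- pvalues[universe]
  extreme <- scores$score >= fc_cutoff | scores$score <= 1 / fc_cutoff
  selected <- universe[extreme & !is.na(pv) & pv < p_cutoff]
  n_sel <- length(selected)
  if (n_sel == 0L) .np_warn("no protein passes the selection thresholds")
  rows <- lapply(names(sets), function(nm) {
    mem <- intersect(sets[[nm]], universe)
    n_set <- length(mem)
    k <- length(intersect(mem, selected))
    expected <- n_sel * n_set / N
    v <- n_sel * (n_set / N) * (1 - n_set / N) * (N - n_sel) / (N - 1)
    z <- if (v > 0) (k - expected) / sqrt(v) else 0
    p <- stats::phyper(k - 1, n_set, N - n_set, n_sel, lower.tail = FALSE)
    data.frame(set = nm, n_set = n_set, overlap = k, expected = expected,
               z = z, p_hyper = p, identified = abs(z) >= z_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_selected") <- n_sel
  class(out) <- c("ora_results", "data.frame")
  out
}
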