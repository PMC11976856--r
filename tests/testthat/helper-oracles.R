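# Independent oracles and tiny fixture builders used across the suite.

# Brute-force GSEA running sum: plain loop over the ranked list, kept
# deliberately naive and separate from the package's vectorized path.
bf_enrichment_score <- function(scores, hit, weight) {
  n <- length(scores)
  nh <- sum(hit)
  denom <- sum(abs(scores[hit])^weight)
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + if (denom > 0) abs(scores[i])^weight / denom else 1 / nh
    } else {
      cur <- cur - 1 / (n - nh)
    }
    run[i] <- cur
  }
  i_up <- which.max(run)
  i_dn <- which.min(run)
  best <- if (abs(abs(run[i_up]) - abs(run[i_dn])) <= 1e-9) {
    min(i_up, i_dn)            # near-tie: earlier position wins
  } else if (abs(run[i_up]) > abs(run[i_dn])) i_up else i_dn
  list(es = run[best], run = run)
}

# Exhaustive gene-label permutation null for tiny universes.
bf_exhaustive_null <- function(scores, k, weight) {
  n <- length(scores)
  combos <- utils::combn(n, k)
  apply(combos, 2, function(idx) {
    hit <- logical(n)
    hit[idx] <- TRUE
    bf_enrichment_score(scores, hit, weight)$es
  })
}

# Minimal hand-built plate: one particle/cell line/assay, explicit signals.
tiny_plate <- function(doses, signals, cell_free_signal = NULL,
                       assay = "LDH") {
  stopifnot(length(doses) == length(signals))
  d <- data.frame(particle = "NP", cell_line = "CL", assay = assay,
                  dose = doses, experiment = 1L,
                  technical_rep = seq_along(doses), cell_free = FALSE,
                  signal = signals, stringsAsFactors = FALSE)
  if (!is.null(cell_free_signal)) {
    cf <- data.frame(particle = "NP", cell_line = "CL", assay = assay,
                     dose = unique(doses), experiment = 1L,
                     technical_rep = 1L, cell_free = TRUE,
                     signal = cell_free_signal, stringsAsFactors = FALSE)
    d <- rbind(d, cf)
  }
  class(d) <- c("plate_measurements", "data.frame")
  d
}

ranked_from <- function(ids, scores) {
  d <- data.frame(protein = ids, score = scores, stringsAsFactors = FALSE)
  d <- d[order(-d$score, d$protein), ]
  rownames(d) <- NULL
  class(d) <- c("ranked_proteins", "data.frame")
  d
}

# Small synthetic gene-set collection over a P%05d universe.
toy_sets <- function(n_sets = 10L, set_size = 15L) {
  sets <- lapply(seq_len(n_sets), function(i) {
    sprintf("P%05d", ((i - 1L) * set_size + 1L):(i * set_size))
  })
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  sets
}
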