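# shared fixture builders and independent oracle implementations

make_samples <- function(groups, months = NULL) {
  data.frame(sample_id = sprintf("S%02d", seq_along(groups)),
             group = groups,
             months_since_event = months %||% rep(NA_real_, length(groups)),
             stringsAsFactors = FALSE)
}

make_expr <- function(values, groups, unit = "counts", months = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("TX%06d", seq_len(nrow(values)))
  }
  s <- make_samples(groups, months)
  colnames(values) <- s$sample_id
  expr_matrix(values, s, unit)
}

tiny_annotation <- function(n, exonic = NULL, intronic = NULL,
                            biotype = "protein_coding") {
  ann <- data.frame(
    transcript_id = sprintf("TX%06d", seq_len(n)),
    gene_id = sprintf("GN%06d", seq_len(n)),
    gene_symbol = sprintf("GN%06d", seq_len(n)),
    biotype = rep_len(biotype, n),
    exonic_length = as.integer(exonic %||% rep(1000L, n)),
    intronic_length = as.integer(intronic %||% rep(5000L, n)),
    marker_of = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("transcript_annotation", "data.frame")
  ann
}

# --- independent oracles -------------------------------------------------

# BH step-up straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)  # position of p[i] in the sorted order
    cand <- vapply(seq(rank_i, m), function(j) m * p[ord[j]] / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

fpkm_oracle <- function(counts, lengths, totals) {
  out <- counts
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      out[i, j] <- counts[i, j] / (lengths[i] / 1e3) / (totals[j] / 1e6)
    }
  }
  out
}

welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Spearman rho via Pearson on ranks; p via the t approximation
spearman_oracle <- function(x, y) {
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t), n - 2))
}

# expected bulk means of the mixture design, written independently of the
# package internals: group proportions from base proportions x multipliers,
# per-cell expression = baseline x regulation, library renormalization
mixture_oracle <- function(annotation, signatures, design) {
  cts <- design$cell_types
  B <- unclass(signatures)[annotation$transcript_id, cts, drop = FALSE]
  groups <- c("RAA", "RAC", "C")
  mu <- matrix(NA_real_, nrow(B), 3, dimnames = list(rownames(B), groups))
  for (g in groups) {
    p <- design$base_proportions * design$cellcount_multiplier[g, ]
    p <- p / sum(p)
    R <- matrix(1, nrow(B), length(cts), dimnames = dimnames(B))
    reg <- design$regulation[design$regulation$group == g, , drop = FALSE]
    for (k in seq_len(nrow(reg))) {
      R[reg$transcript_id[k], reg$cell_type[k]] <- reg$multiplier[k]
    }
    w <- as.numeric((B * R) %*% p)
    mu[, g] <- design$library_size * w / sum(w)
  }
  mu
}
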