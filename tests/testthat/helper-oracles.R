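# Independent brute-force oracles used to cross-check the package's
# vectorized metrics and the beam-search decoder.

# Plain-loop multi-label metrics over explicit label slots.
ref_metrics <- function(pred, gold, labels) {
  n <- length(pred)
  L <- length(labels)
  xor_count <- 0
  tp <- fp <- fn <- 0
  cls <- matrix(0, L, 3, dimnames = list(labels, c("tp", "fp", "fn")))
  doc_rows <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- labels %in% pred[[i]]
    g <- labels %in% gold[[i]]
    for (j in seq_len(L)) {
      if (p[j] != g[j]) xor_count <- xor_count + 1
      if (p[j] && g[j]) { tp <- tp + 1; cls[j, 1] <- cls[j, 1] + 1 }
      if (p[j] && !g[j]) { fp <- fp + 1; cls[j, 2] <- cls[j, 2] + 1 }
      if (!p[j] && g[j]) { fn <- fn + 1; cls[j, 3] <- cls[j, 3] + 1 }
    }
    dtp <- sum(p & g)
    dp <- if (sum(p) > 0) dtp / sum(p) else if (sum(g) == 0) 1 else 0
    dr <- if (sum(g) > 0) dtp / sum(g) else if (sum(p) == 0) 1 else 0
    df <- if (dp + dr > 0) 2 * dp * dr / (dp + dr) else if (sum(p) + sum(g) == 0) 1 else 0
    doc_rows[i, ] <- c(dp, dr, df)
  }
  f1_of <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  list(hamming = xor_count / (n * L),
       micro_f1 = f1_of(tp, fp, fn),
       macro_f1 = mean(vapply(seq_len(L), function(j)
         f1_of(cls[j, 1], cls[j, 2], cls[j, 3]), 0)),
       per_doc = colMeans(doc_rows))
}

# Score one explicit no-repeat label sequence (EOS appended) by stepping
# the decoder and accumulating masked log-probabilities.
score_seq <- function(model, enc, labels_idx) {
  m <- model$label_vocab$size
  state <- NULL; prev <- NULL; lp <- 0
  for (k in c(labels_idx, m + 1L)) {
    st <- decoder_step(model, enc, state, prev)
    if (st$dist[[k]] <= 0) return(-Inf)
    lp <- lp + log(st$dist[[k]])
    state <- seqspecies:::state_emit(st$state, k, m)
    prev <- if (k <= m) k else NULL
  }
  lp
}

# all permutations of a vector (tiny n)
all_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], all_perms(v[-i])))
  out
}

# Brute-force best decoding: enumerate every ordered no-repeat label
# subset terminated by EOS and take the highest-scoring one.
enumerate_best <- function(model, enc) {
  m <- model$label_vocab$size
  best <- NULL
  seqs <- list(integer())
  for (len in seq_len(m)) {
    perms <- do.call(rbind, lapply(utils::combn(m, len, simplify = FALSE),
                                   all_perms))
    seqs <- c(seqs, lapply(seq_len(nrow(perms)), function(r) perms[r, ]))
  }
  for (s in seqs) {
    lp <- score_seq(model, enc, s)
    if (is.null(best) || lp > best$lp + 1e-12) best <- list(seq = s, lp = lp)
  }
  best
}
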