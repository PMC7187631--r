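# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape records nodes (environments holding a value, an accumulated
# gradient and a backward closure) in creation order; ad_backward() seeds
# the loss gradient and replays the tape in reverse. Only the operations
# the encoder/decoder needs are provided, plus one fused operation running
# a whole (masked, batched) LSTM sequence with hand-written backpropagation
# through time — the hot loop of training.
#
# All values are base-R double matrices; correctness is pinned down by a
# finite-difference test.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_push <- function(tape, value, backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  node$id <- tape$n
  tape$nodes[[tape$n]] <- node
  node
}

ad_leaf <- function(tape, value) ad_push(tape, value)

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Run the backward pass from a scalar (1x1) node.
ad_backward <- function(tape, node) {
  node$grad <- matrix(1, 1, 1)
  for (i in seq(node$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# ---- elementary operations -------------------------------------------------

ad_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_push(tape, av %*% bv, function(g) {
    ad_accum(a, g %*% t(bv))
    ad_accum(b, t(av) %*% g)
  })
}

# a + b; b may be a 1 x ncol(a) row vector broadcast over rows of a.
ad_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  bcast <- nrow(bv) == 1L && nrow(av) > 1L
  val <- if (bcast) sweep(av, 2L, as.vector(bv), "+") else av + bv
  ad_push(tape, val, function(g) {
    ad_accum(a, g)
    ad_accum(b, if (bcast) matrix(colSums(g), 1L) else g)
  })
}

ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_push(tape, av * bv, function(g) {
    ad_accum(a, g * bv)
    ad_accum(b, g * av)
  })
}

ad_scale <- function(tape, a, k) {
  ad_push(tape, a$value * k, function(g) ad_accum(a, g * k))
}

ad_tanh <- function(tape, a) {
  val <- tanh(a$value)
  ad_push(tape, val, function(g) ad_accum(a, g * (1 - val^2)))
}

ad_sigmoid <- function(tape, a) {
  val <- 1 / (1 + exp(-a$value))
  ad_push(tape, val, function(g) ad_accum(a, g * val * (1 - val)))
}

# Row gather, duplicates allowed; backward is scatter-add.
ad_rows <- function(tape, a, idx) {
  av <- a$value
  idx <- as.integer(idx)
  ad_push(tape, av[idx, , drop = FALSE], function(g) {
    acc <- rowsum(g, group = idx)
    full <- matrix(0, nrow(av), ncol(av))
    full[as.integer(rownames(acc)), ] <- acc
    ad_accum(a, full)
  })
}

ad_cols <- function(tape, a, idx) {
  av <- a$value
  idx <- as.integer(idx)
  ad_push(tape, av[, idx, drop = FALSE], function(g) {
    full <- matrix(0, nrow(av), ncol(av))
    full[, idx] <- g
    ad_accum(a, full)
  })
}

ad_vcat <- function(tape, nodes) {
  vals <- lapply(nodes, `[[`, "value")
  rows <- vapply(vals, nrow, 1L)
  ad_push(tape, do.call(rbind, vals), function(g) {
    at <- 0L
    for (k in seq_along(nodes)) {
      ad_accum(nodes[[k]], g[at + seq_len(rows[k]), , drop = FALSE])
      at <- at + rows[k]
    }
  })
}

ad_hcat <- function(tape, a, b) {
  na <- ncol(a$value)
  ad_push(tape, cbind(a$value, b$value), function(g) {
    ad_accum(a, g[, seq_len(na), drop = FALSE])
    ad_accum(b, g[, -seq_len(na), drop = FALSE])
  })
}

ad_transpose <- function(tape, a) {
  ad_push(tape, t(a$value), function(g) ad_accum(a, t(g)))
}

ad_sum <- function(tape, a) {
  av <- a$value
  ad_push(tape, matrix(sum(av), 1L, 1L), function(g)
    ad_accum(a, matrix(g[1L], nrow(av), ncol(av))))
}

# Softmax of a column vector (n x 1).
ad_softmax_col <- function(tape, a) {
  z <- as.vector(a$value)
  e <- exp(z - max(z))
  s <- e / sum(e)
  val <- matrix(s, ncol = 1L)
  ad_push(tape, val, function(g) {
    gv <- as.vector(g)
    ad_accum(a, matrix(s * (gv - sum(gv * s)), ncol = 1L))
  })
}

# Column-wise max over rows -> 1 x m; gradient flows to the (first) argmax.
ad_colmax <- function(tape, a) {
  av <- a$value
  which_max <- apply(av, 2L, which.max)
  ad_push(tape, matrix(apply(av, 2L, max), 1L), function(g) {
    full <- matrix(0, nrow(av), ncol(av))
    full[cbind(which_max, seq_len(ncol(av)))] <- as.vector(g)
    ad_accum(a, full)
  })
}

# Inverted dropout: active only when training and p > 0.
ad_dropout <- function(tape, a, p, training) {
  if (!training || p <= 0) return(a)
  keep <- matrix(stats::rbinom(length(a$value), 1L, 1 - p), nrow(a$value)) / (1 - p)
  ad_push(tape, a$value * keep, function(g) ad_accum(a, g * keep))
}

# Numerically safe masked softmax on a numeric vector; masked entries are
# exactly zero (they are dropped before exponentiation).
masked_softmax <- function(z, mask) {
  keep <- which(!mask)
  e <- numeric(length(z))
  zk <- z[keep]
  ek <- exp(zk - max(zk))
  e[keep] <- ek / sum(ek)
  e
}

# Masked cross-entropy over a single logit row (1 x K).
# `mask` is logical length K: TRUE entries are excluded (probability exactly
# 0). Returns the loss node; the probability row is kept in `$probs`.
ad_masked_ce <- function(tape, logits, target, mask) {
  z <- as.vector(logits$value)
  p <- masked_softmax(z, mask)
  if (mask[target])
    seqc_abort("state", "cross-entropy target is masked out")
  node <- ad_push(tape, matrix(-log(p[target]), 1L, 1L), function(g) {
    dz <- p
    dz[target] <- dz[target] - 1
    ad_accum(logits, matrix(dz * g[1L], 1L))
  })
  node$probs <- p
  node
}

# ---- fused LSTM sequence ---------------------------------------------------
#
# Runs a unidirectional LSTM over B variable-length sequences in parallel.
#   X       node, (N x d): stacked real-token inputs (no padding rows).
#   idx     B x Tmax integer matrix: idx[b, t] is the row of X holding
#           sequence b's t-th input, or 0 past the end of sequence b.
#   Wx (d x 4h), Wh (h x 4h), b (1 x 4h): gate order [input, forget,
#           candidate, output].
#   reverse process positions Tmax..1 (the backward half of a BiLSTM).
# Output node value: rbind(H, h_final), size (N + B) x h. H[r, ] is the
# hidden state emitted at X row r; h_final stacks each sequence's state
# after its last processed position. Sequences shorter than Tmax pass their
# state through inactive steps unchanged.
ad_lstm_seq <- function(tape, X, idx, Wx, Wh, b, reverse = FALSE) {
  Xv <- X$value; Wxv <- Wx$value; Whv <- Wh$value; bv <- as.vector(b$value)
  B <- nrow(idx); Tmax <- ncol(idx)
  h <- ncol(Whv) / 4L
  d <- ncol(Xv)
  N <- nrow(Xv)
  steps <- if (reverse) rev(seq_len(Tmax)) else seq_len(Tmax)

  hs <- matrix(0, B, h); cs <- matrix(0, B, h)
  H_out <- matrix(0, N, h)
  cache <- vector("list", Tmax)
  for (t in steps) {
    rows <- idx[, t]
    active <- rows > 0L
    if (!any(active)) next
    xt <- matrix(0, B, d)
    xt[active, ] <- Xv[rows[active], , drop = FALSE]
    z <- sweep(xt %*% Wxv + hs %*% Whv, 2L, bv, "+")
    ii <- 1 / (1 + exp(-z[, seq_len(h), drop = FALSE]))
    ff <- 1 / (1 + exp(-z[, h + seq_len(h), drop = FALSE]))
    gg <- tanh(z[, 2L * h + seq_len(h), drop = FALSE])
    oo <- 1 / (1 + exp(-z[, 3L * h + seq_len(h), drop = FALSE]))
    c_prev <- cs; h_prev <- hs
    c_new <- ff * c_prev + ii * gg
    tc <- tanh(c_new)
    h_new <- oo * tc
    hs[active, ] <- h_new[active, , drop = FALSE]
    cs[active, ] <- c_new[active, , drop = FALSE]
    H_out[rows[active], ] <- hs[active, , drop = FALSE]
    cache[[t]] <- list(xt = xt, i = ii, f = ff, g = gg, o = oo,
                       c_prev = c_prev, h_prev = h_prev, tc = tc,
                       active = active, rows = rows)
  }

  ad_push(tape, rbind(H_out, hs), function(G) {
    dH <- G[seq_len(N), , drop = FALSE]
    dh_after <- G[N + seq_len(B), , drop = FALSE]
    dc_after <- matrix(0, B, h)
    dWx <- matrix(0, d, 4L * h); dWh <- matrix(0, h, 4L * h)
    db <- numeric(4L * h)
    dX <- matrix(0, N, d)
    for (t in rev(steps)) {
      cc <- cache[[t]]
      if (is.null(cc)) next
      act <- cc$active
      dh <- dh_after
      dh[act, ] <- dh[act, , drop = FALSE] + dH[cc$rows[act], , drop = FALSE]
      do_ <- dh * cc$tc
      dc <- dc_after + dh * cc$o * (1 - cc$tc^2)
      dc_prev <- dc * cc$f
      dz <- cbind((dc * cc$g) * cc$i * (1 - cc$i),
                  (dc * cc$c_prev) * cc$f * (1 - cc$f),
                  (dc * cc$i) * (1 - cc$g^2),
                  do_ * cc$o * (1 - cc$o))
      dz[!act, ] <- 0
      dWx <- dWx + crossprod(cc$xt, dz)
      dWh <- dWh + crossprod(cc$h_prev, dz)
      db <- db + colSums(dz)
      dxt <- dz %*% t(Wxv)
      r <- cc$rows[act]
      dX[r, ] <- dX[r, , drop = FALSE] + dxt[act, , drop = FALSE]
      dh_before <- dz %*% t(Whv)
      dh_before[!act, ] <- dh[!act, , drop = FALSE]       # state pass-through
      dc_before <- dc_prev
      dc_before[!act, ] <- dc_after[!act, , drop = FALSE]
      dh_after <- dh_before
      dc_after <- dc_before
    }
    ad_accum(X, dX)
    ad_accum(Wx, dWx)
    ad_accum(Wh, dWh)
    ad_accum(b, matrix(db, 1L))
  })
}
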