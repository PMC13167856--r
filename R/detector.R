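#' Detector configuration
#'
#' Architecture, optimization, and event-decoding parameters of the
#' hybrid convolutional-recurrent wheeze detector. The network maps a
#' per-frame input of stacked log-mel and Sobel-mel channels through two
#' temporal convolution blocks, concatenates the handcrafted feature
#' vector, runs an LSTM over the frame sequence, and emits one wheeze
#' probability per frame.
#'
#' @param conv_channels Integer vector of channel widths, one per
#'   convolution block.
#' @param conv_kernel Temporal kernel width (frames).
#' @param recurrent_hidden LSTM hidden size.
#' @param dropout Dropout probability applied after the convolutional
#'   stage and before the output layer (training only).
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Windows per minibatch.
#' @param class_weight Positive-frame loss weight; `"balanced"` uses the
#'   inverse frame-label frequency of the training set (capped at
#'   `class_weight_cap`).
#' @param class_weight_cap Upper bound for the balanced weight.
#' @param patience Early-stopping patience (epochs without improvement of
#'   validation frame-level F1).
#' @param seed Integer seed for initialization, batching and dropout.
#' @param decode_threshold Posterior threshold for event decoding.
#' @param min_event_s Minimum decoded event duration, seconds. Runs more
#'   than one hop shorter than this are dropped (the one-hop tolerance
#'   keeps the label/decode round trip exact at the minimum duration).
#' @param merge_gap_s Sub-threshold gaps shorter than this are merged.
#' @return List of class `detector_config`.
#' @export
detector_config <- function(conv_channels = c(16, 16), conv_kernel = 5,
                            recurrent_hidden = 24, dropout = 0.1,
                            lr = 0.005, epochs = 12, batch_size = 8,
                            class_weight = "balanced", class_weight_cap = 20,
                            patience = 4, seed = 1L,
                            decode_threshold = 0.5, min_event_s = 0.1,
                            merge_gap_s = 0.05) {
  stopifnot(decode_threshold > 0, decode_threshold < 1,
            min_event_s > 0, merge_gap_s >= 0, conv_kernel %% 2 == 1)
  structure(as.list(environment()), class = "detector_config")
}

#' Frame posterior container
#'
#' @param probs Per-frame wheeze probabilities in `[0, 1]`.
#' @param frame_starts_s Frame start times, seconds.
#' @param frame_hop_s Frame hop, seconds.
#' @return Object of class `frame_posterior`.
#' @export
frame_posterior <- function(probs, frame_starts_s, frame_hop_s) {
  stopifnot(length(probs) == length(frame_starts_s),
            all(probs >= 0 & probs <= 1))
  structure(list(probs = as.numeric(probs),
                 frame_starts_s = as.numeric(frame_starts_s),
                 frame_times_s = as.numeric(frame_starts_s) + frame_hop_s / 2,
                 frame_hop_s = frame_hop_s),
            class = "frame_posterior")
}

#' Frame labels from event annotations
#'
#' A frame is labeled positive iff at least half of its interval overlaps
#' an annotated event. Consequently an event shorter than half a frame
#' that sits between frame centers yields no positive frame.
#'
#' @param events data.frame with `onset_s`/`offset_s` (or
#'   `begin_s`/`end_s`) columns.
#' @param frame_starts_s Frame start times.
#' @param frame_hop_s Frame hop, seconds.
#' @param frame_len_s Frame interval length, seconds (defaults to twice
#'   the hop, the package's framing default).
#' @return Integer vector of 0/1 labels, one per frame.
#' @export
frame_labels_from_events <- function(events, frame_starts_s, frame_hop_s,
                                     frame_len_s = 2 * frame_hop_s) {
  if (!is.null(events) && nrow(events) > 0) {
    on <- if ("onset_s" %in% names(events)) events$onset_s else events$begin_s
    off <- if ("offset_s" %in% names(events)) events$offset_s else events$end_s
    if (any(off <= on)) stop("malformed event: offset_s <= onset_s")
  } else {
    return(integer(length(frame_starts_s)))
  }
  y <- integer(length(frame_starts_s))
  a <- frame_starts_s
  b <- frame_starts_s + frame_len_s
  for (j in seq_along(on)) {
    ov <- pmax(0, pmin(b, off[j]) - pmax(a, on[j]))
    y[ov >= frame_len_s / 2] <- 1L
  }
  y
}

#' Decode frame posteriors into timed wheeze events
#'
#' Threshold at `decode_threshold`, merge sub-threshold gaps shorter than
#' `merge_gap_s`, drop runs shorter than `min_event_s` (with a one-hop
#' tolerance), and emit each surviving run as an event spanning from the
#' first frame's start to one hop past the last frame's start.
#'
#' @param post [frame_posterior()].
#' @param cfg [detector_config()] (only the three decoding fields are
#'   used).
#' @return data.frame with columns `onset_s`, `offset_s`, sorted and
#'   non-overlapping.
#' @export
decode_events <- function(post, cfg = detector_config()) {
  stopifnot(inherits(post, "frame_posterior"))
  hop <- post$frame_hop_s
  mask <- post$probs >= cfg$decode_threshold
  if (!any(mask))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by gaps shorter than merge_gap_s
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap_frames <- runs[i, 1] - merged[nrow(merged), 2] - 1L
      if (gap_frames * hop < cfg$merge_gap_s) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  dur <- (runs[, 2] - runs[, 1] + 1L) * hop
  runs <- runs[dur >= cfg$min_event_s - hop - 1e-9, , drop = FALSE]
  if (nrow(runs) == 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  data.frame(onset_s = post$frame_starts_s[runs[, 1]],
             offset_s = post$frame_starts_s[runs[, 2]] + hop)
}

# ---------------------------------------------------------------------------
# network internals: temporal convolution (im2col) + LSTM, base-R matrices

relu <- function(x) pmax(x, 0)
sigm <- function(x) 1 / (1 + exp(-x))

# stack of B sequences of T rows -> (B*T) x (D*k) context matrix
im2col_time <- function(Xstack, B, T_, k) {
  D <- ncol(Xstack)
  half <- (k - 1L) %/% 2L
  zrow <- B * T_ + 1L
  Xp <- rbind(Xstack, matrix(0, 1, D))
  out <- matrix(0, B * T_, D * k)
  t_idx <- rep(seq_len(T_), times = B)
  base <- rep((seq_len(B) - 1L) * T_, each = T_)
  for (s in seq_len(k)) {
    sh <- s - 1L - half
    tt <- t_idx + sh
    idx <- ifelse(tt >= 1L & tt <= T_, base + tt, zrow)
    out[, ((s - 1L) * D + 1L):(s * D)] <- Xp[idx, , drop = FALSE]
  }
  out
}

# scatter gradient of the context matrix back onto the sequence stack
col2im_time <- function(dXc, B, T_, k, D) {
  half <- (k - 1L) %/% 2L
  dX <- matrix(0, B * T_, D)
  t_idx <- rep(seq_len(T_), times = B)
  base <- rep((seq_len(B) - 1L) * T_, each = T_)
  for (s in seq_len(k)) {
    sh <- s - 1L - half
    tt <- t_idx + sh
    valid <- tt >= 1L & tt <= T_
    idx <- base[valid] + tt[valid]
    dX[idx, ] <- dX[idx, ] +
      dXc[valid, ((s - 1L) * D + 1L):(s * D), drop = FALSE]
  }
  dX
}

init_params <- function(d0, p_hc, cfg) {
  glorot <- function(nin, nout) {
    r <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -r, r), nin, nout)
  }
  k <- cfg$conv_kernel
  c1 <- cfg$conv_channels[1]
  c2 <- if (length(cfg$conv_channels) >= 2) cfg$conv_channels[2] else c1
  H <- cfg$recurrent_hidden
  dz <- c2 + p_hc
  list(W1 = glorot(d0 * k, c1), b1 = numeric(c1),
       W2 = glorot(c1 * k, c2), b2 = numeric(c2),
       Wx = glorot(dz, 4 * H), Wh = glorot(H, 4 * H),
       bg = c(numeric(H), rep(1, H), numeric(2 * H)),  # forget-gate bias 1
       Wo = glorot(H, 1), bo = 0)
}

# forward pass over a batch of windows; returns probs and (optionally) the
# cache needed for backpropagation
nn_forward <- function(params, Xs, Hs, cfg, training = FALSE) {
  B <- length(Xs)
  T_ <- nrow(Xs[[1]])
  k <- cfg$conv_kernel
  H <- cfg$recurrent_hidden
  Xstack <- do.call(rbind, Xs)
  Hstack <- do.call(rbind, Hs)

  C1in <- im2col_time(Xstack, B, T_, k)
  A1p <- sweep(C1in %*% params$W1, 2, params$b1, `+`)
  A1 <- relu(A1p)
  C2in <- im2col_time(A1, B, T_, k)
  A2p <- sweep(C2in %*% params$W2, 2, params$b2, `+`)
  A2 <- relu(A2p)

  drop1 <- NULL
  if (training && cfg$dropout > 0) {
    drop1 <- matrix(rbinom(length(A2), 1, 1 - cfg$dropout), nrow(A2)) /
      (1 - cfg$dropout)
    A2 <- A2 * drop1
  }
  Z <- cbind(A2, Hstack)

  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache_t <- if (training) vector("list", T_) else NULL
  Hout <- matrix(0, B * T_, H)
  row_of_t <- function(t) t + (seq_len(B) - 1L) * T_
  for (t in seq_len(T_)) {
    rt <- row_of_t(t)
    Zt <- Z[rt, , drop = FALSE]
    g <- Zt %*% params$Wx + h %*% params$Wh
    g <- sweep(g, 2, params$bg, `+`)
    i_g <- sigm(g[, 1:H, drop = FALSE])
    f_g <- sigm(g[, (H + 1):(2 * H), drop = FALSE])
    o_g <- sigm(g[, (2 * H + 1):(3 * H), drop = FALSE])
    c_g <- tanh(g[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * c_g
    tc <- tanh(cc)
    h <- o_g * tc
    Hout[rt, ] <- h
    if (training)
      cache_t[[t]] <- list(i = i_g, f = f_g, o = o_g, g = c_g,
                           c = cc, tc = tc, c_prev = c_prev, Zt = Zt)
  }
  drop2 <- NULL
  Hd <- Hout
  if (training && cfg$dropout > 0) {
    drop2 <- matrix(rbinom(length(Hout), 1, 1 - cfg$dropout), nrow(Hout)) /
      (1 - cfg$dropout)
    Hd <- Hout * drop2
  }
  logits <- as.vector(Hd %*% params$Wo) + params$bo
  probs <- sigm(logits)
  res <- list(probs = probs, B = B, T_ = T_)
  if (training)
    res$cache <- list(C1in = C1in, A1p = A1p, A1 = A1, C2in = C2in,
                      A2p = A2p, Z = Z, Hd = Hd, cache_t = cache_t,
                      drop1 = drop1, drop2 = drop2)
  res
}

# gradient of the weighted BCE loss wrt every parameter
nn_backward <- function(params, fw, y, w, cfg) {
  B <- fw$B; T_ <- fw$T_
  k <- cfg$conv_kernel
  H <- cfg$recurrent_hidden
  ca <- fw$cache
  c2 <- ncol(ca$A2p)

  u <- (fw$probs - y) * w / length(y)        # d loss / d logit
  gWo <- crossprod(ca$Hd, u)
  gbo <- sum(u)
  dHout <- outer(u, as.vector(params$Wo))    # (B*T) x H
  if (!is.null(ca$drop2)) dHout <- dHout * ca$drop2

  gWx <- matrix(0, nrow(params$Wx), ncol(params$Wx))
  gWh <- matrix(0, H, 4 * H)
  gbg <- numeric(4 * H)
  dZ <- matrix(0, B * T_, ncol(ca$Z))
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  row_of_t <- function(t) t + (seq_len(B) - 1L) * T_
  for (t in rev(seq_len(T_))) {
    st <- ca$cache_t[[t]]
    rt <- row_of_t(t)
    dh <- dHout[rt, , drop = FALSE] + dh_next
    do_ <- dh * st$tc
    dct <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dct * st$g
    dg <- dct * st$i
    df <- dct * st$c_prev
    dc_next <- dct * st$f
    G <- cbind(di * st$i * (1 - st$i),
               df * st$f * (1 - st$f),
               do_ * st$o * (1 - st$o),
               dg * (1 - st$g^2))
    gWx <- gWx + crossprod(st$Zt, G)
    # h_{t-1} equals o_{t-1} * tanh(c_{t-1}); recover it from the cache
    h_prev <- if (t > 1) {
      sp <- ca$cache_t[[t - 1]]
      sp$o * sp$tc
    } else matrix(0, B, H)
    gWh <- gWh + crossprod(h_prev, G)
    gbg <- gbg + colSums(G)
    dZ[rt, ] <- tcrossprod(G, params$Wx)
    dh_next <- tcrossprod(G, params$Wh)
  }

  dA2 <- dZ[, seq_len(c2), drop = FALSE]
  if (!is.null(ca$drop1)) dA2 <- dA2 * ca$drop1
  dA2p <- dA2 * (ca$A2p > 0)
  gW2 <- crossprod(ca$C2in, dA2p)
  gb2 <- colSums(dA2p)
  dC2in <- tcrossprod(dA2p, params$W2)
  dA1 <- col2im_time(dC2in, B, T_, k, ncol(ca$A1))
  dA1p <- dA1 * (ca$A1p > 0)
  gW1 <- crossprod(ca$C1in, dA1p)
  gb1 <- colSums(dA1p)

  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       Wx = gWx, Wh = gWh, bg = gbg, Wo = gWo, bo = gbo)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

frame_f1 <- function(probs, y, thr = 0.5) {
  pred <- probs >= thr
  tp <- sum(pred & y == 1)
  fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# scale raw feature bundles to network inputs; hc normalization stats come
# from the training split only
bundle_to_input <- function(fb, cfg_feat, hc_stats = NULL) {
  dr <- cfg_feat$dynamic_range_db
  mel01 <- (fb$mel$values + dr) / dr
  sob01 <- fb$sobel_mel / (4 * dr)
  X <- cbind(mel01, sob01)
  Hc <- fb$handcrafted
  if (!is.null(hc_stats))
    Hc <- sweep(sweep(Hc, 2, hc_stats$mean), 2, hc_stats$sd, `/`)
  list(X = X, Hc = Hc)
}

#' Prepare labeled training windows from recordings and annotations
#'
#' Segments each recording into 10-s analysis windows, extracts the
#' feature bundle per window, and builds frame labels from the
#' ground-truth events (shifted onto the window timeline and clipped).
#'
#' @param recordings List of [audio_recording].
#' @param annotations data.frame of events with `recording_id`,
#'   `onset_s`, `offset_s`.
#' @param feature_cfg [feature_config()].
#' @param window_s Analysis window length (seconds).
#' @return List of class `window_set`; each element holds the raw feature
#'   bundle, label vector, and identifiers.
#' @export
prepare_training_windows <- function(recordings, annotations,
                                     feature_cfg = feature_config(),
                                     window_s = 10) {
  out <- list()
  for (rec in recordings) {
    ev <- annotations[annotations$recording_id == rec$recording_id, ,
                      drop = FALSE]
    for (w in segment_windows(rec, window_s)) {
      fb <- feature_bundle(w, feature_cfg)
      evw <- ev
      if (nrow(evw) > 0) {
        evw$onset_s <- evw$onset_s - w$offset_s
        evw$offset_s <- evw$offset_s - w$offset_s
        keep <- evw$offset_s > 0 & evw$onset_s < w$window_s
        evw <- evw[keep, , drop = FALSE]
        evw$onset_s <- pmax(evw$onset_s, 0)
        evw$offset_s <- pmin(evw$offset_s, w$window_s)
      }
      y <- frame_labels_from_events(evw, fb$frame_starts_s, fb$frame_hop_s,
                                    fb$frame_len_s)
      out[[length(out) + 1]] <- list(
        recording_id = rec$recording_id,
        patient_id = rec$patient_id,
        window_index = w$window_index,
        bundle = fb, y = y)
    }
  }
  structure(out, class = "window_set")
}

#' @export
`[.window_set` <- function(x, i) {
  structure(unclass(x)[i], class = "window_set")
}

#' Fit the CNN+LSTM wheeze detector
#'
#' The main fitting function. Takes a labeled window set (from
#' [prepare_training_windows()]) or a simulated cohort (from
#' [simulate_cohort()]), splits it at the patient level, and trains the
#' hybrid network with class-weighted binary cross-entropy per frame,
#' Adam, and early stopping on validation frame-level F1.
#'
#' @param x A `window_set`, or the list returned by [simulate_cohort()]
#'   (its recordings and annotations are windowed automatically).
#' @param val A held-out `window_set` for early stopping; if `NULL`, a
#'   patient-level fraction of `x` is held out.
#' @param config [detector_config()].
#' @param feature_cfg [feature_config()] used when `x` is a cohort.
#' @param val_fraction Fraction of patients held out when `val` is
#'   `NULL`.
#' @param verbose Print per-epoch progress.
#' @return Object of class `wheeze_detector` with components `params`
#'   (network weights), `config`, `feature_cfg`, `hc_stats`
#'   (normalization statistics of the handcrafted features, training
#'   split only), `history` (per-epoch loss and validation F1), `dims`,
#'   and `n_parameters`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(n_patients = 6, seed = 7,
#'   wheeze_prevalence = 0.5, quality_proportion = 1))
#' fit <- wheeze_detector(cohort, config = detector_config(epochs = 2))
#' print(fit)
#' }
#' @export
wheeze_detector <- function(x, val = NULL, config = detector_config(),
                            feature_cfg = feature_config(),
                            val_fraction = 0.25, verbose = FALSE) {
  cl <- match.call()
  if (!inherits(x, "window_set")) {
    stopifnot(is.list(x), !is.null(x$recordings), !is.null(x$annotations))
    x <- prepare_training_windows(x$recordings, x$annotations, feature_cfg)
  }
  cfg <- config

  with_seed(cfg$seed, {
    patients <- vapply(x, function(w) w$patient_id %||% w$recording_id, "")
    if (is.null(val)) {
      up <- unique(patients)
      n_val <- max(1L, round(length(up) * val_fraction))
      val_pat <- sample(up, n_val)
      val <- x[patients %in% val_pat]
      x <- x[!patients %in% val_pat]
      patients <- patients[!patients %in% val_pat]
    } else {
      vp <- vapply(val, function(w) w$patient_id %||% w$recording_id, "")
      if (length(intersect(unique(patients), unique(vp))) > 0)
        stop("train and validation sets share patients; ",
             "splits must be disjoint at the patient level")
    }
    if (length(x) == 0 || length(val) == 0)
      stop("empty training or validation split")
    y_all <- unlist(lapply(x, `[[`, "y"))
    if (sum(y_all) == 0) stop("training split has no positive frames")

    # handcrafted-feature normalization from the training split only
    hc_all <- do.call(rbind, lapply(x, function(w) w$bundle$handcrafted))
    hc_stats <- list(mean = colMeans(hc_all),
                     sd = pmax(apply(hc_all, 2, sd), 1e-6))
    tr_in <- lapply(x, function(w) bundle_to_input(w$bundle, feature_cfg, hc_stats))
    va_in <- lapply(val, function(w) bundle_to_input(w$bundle, feature_cfg, hc_stats))
    va_y <- unlist(lapply(val, `[[`, "y"))

    d0 <- ncol(tr_in[[1]]$X)
    p_hc <- ncol(tr_in[[1]]$Hc)
    params <- init_params(d0, p_hc, cfg)

    w_pos <- if (identical(cfg$class_weight, "balanced")) {
      min(cfg$class_weight_cap, sum(y_all == 0) / max(sum(y_all == 1), 1))
    } else as.numeric(cfg$class_weight)

    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_f1 = numeric(0))
    best <- list(f1 = -Inf, params = params, epoch = 0L)
    step <- 0L
    n_tr <- length(tr_in)

    if (cfg$epochs > 0) for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; n_chunks <- 0
      for (b0 in seq(1, n_tr, by = cfg$batch_size)) {
        ids <- ord[b0:min(b0 + cfg$batch_size - 1, n_tr)]
        Xs <- lapply(tr_in[ids], `[[`, "X")
        Hs <- lapply(tr_in[ids], `[[`, "Hc")
        # stacked window-major: labels follow the same ordering
        yb <- unlist(lapply(x[ids], `[[`, "y"))
        wb <- ifelse(yb == 1, w_pos, 1)
        fw <- nn_forward(params, Xs, Hs, cfg, training = TRUE)
        p_ <- pmin(pmax(fw$probs, 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss +
          sum(wb * -(yb * log(p_) + (1 - yb) * log(1 - p_))) / length(yb)
        n_chunks <- n_chunks + 1
        grads <- nn_backward(params, fw, yb, wb, cfg)
        step <- step + 1L
        upd <- adam_step(params, grads, state, cfg$lr, step)
        params <- upd$params
        state <- upd$state
      }
      va_p <- predict_probs_set(params, va_in, cfg)
      f1 <- frame_f1(va_p, va_y)
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = ep_loss / n_chunks,
                                           val_f1 = f1))
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val frame-F1 %.3f", ep,
                        ep_loss / n_chunks, f1))
      if (f1 > best$f1 + 1e-6) {
        best <- list(f1 = f1, params = params, epoch = ep)
      } else if (ep - best$epoch >= cfg$patience) break
    }
    if (best$f1 > -Inf && cfg$epochs > 0) params <- best$params

    fb1 <- x[[1]]$bundle
    structure(list(params = params, config = cfg, feature_cfg = feature_cfg,
                   hc_stats = hc_stats, history = history,
                   dims = list(d0 = d0, p_hc = p_hc,
                               frame_hop_s = fb1$frame_hop_s,
                               frame_len_s = fb1$frame_len_s),
                   n_parameters = sum(vapply(params, length, 1L)),
                   best_val_f1 = if (nrow(history)) best$f1 else NA_real_,
                   call = cl),
              class = "wheeze_detector")
  })
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

predict_probs_set <- function(params, inputs, cfg) {
  unlist(lapply(inputs, function(z)
    nn_forward(params, list(z$X), list(z$Hc), cfg)$probs))
}

#' Frame-wise posterior for one window
#'
#' @param fit A fitted [wheeze_detector].
#' @param features A `feature_bundle` for one analysis window.
#' @return [frame_posterior()].
#' @export
predict_frames <- function(fit, features) {
  stopifnot(inherits(fit, "wheeze_detector"),
            inherits(features, "feature_bundle"))
  z <- bundle_to_input(features, fit$feature_cfg, fit$hc_stats)
  if (ncol(z$X) != fit$dims$d0 || ncol(z$Hc) != fit$dims$p_hc)
    stop("feature shape mismatch: model expects ", fit$dims$d0, "+",
         fit$dims$p_hc, " columns, got ", ncol(z$X), "+", ncol(z$Hc))
  p <- nn_forward(fit$params, list(z$X), list(z$Hc), fit$config)$probs
  frame_posterior(p, features$frame_starts_s, features$frame_hop_s)
}

#' @export
print.wheeze_detector <- function(x, ...) {
  cat("CNN+LSTM wheeze event detector\n")
  cat(sprintf("  input: %d spectral columns (mel + Sobel-mel) + %d handcrafted\n",
              x$dims$d0, x$dims$p_hc))
  cat(sprintf("  conv channels: %s (kernel %d) | LSTM hidden: %d | %d parameters\n",
              paste(x$config$conv_channels, collapse = ", "),
              x$config$conv_kernel, x$config$recurrent_hidden, x$n_parameters))
  if (nrow(x$history) > 0)
    cat(sprintf("  trained %d epochs; best validation frame-F1 %.3f\n",
                nrow(x$history), x$best_val_f1))
  else cat("  untrained (initialized weights)\n")
  invisible(x)
}

#' @export
summary.wheeze_detector <- function(object, ...) {
  s <- list(n_parameters = object$n_parameters,
            config = object$config,
            history = object$history,
            best_val_f1 = object$best_val_f1)
  class(s) <- "summary.wheeze_detector"
  s
}

#' @export
print.summary.wheeze_detector <- function(x, ...) {
  cat("CNN+LSTM wheeze detector —", x$n_parameters, "parameters\n")
  cat(sprintf("decode: threshold %.2f, min event %.2f s, merge gap %.2f s\n",
              x$config$decode_threshold, x$config$min_event_s,
              x$config$merge_gap_s))
  if (nrow(x$history) > 0) {
    cat("training history:\n")
    print(x$history, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.wheeze_detector <- function(object, ...) {
  unlist(lapply(object$params, as.vector))
}

#' @export
plot.wheeze_detector <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    message("no training history to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
       ylab = "weighted BCE", main = "training loss", ...)
  plot(h$epoch, h$val_f1, type = "b", xlab = "epoch",
       ylab = "frame-level F1", main = "validation F1", ylim = c(0, 1), ...)
  invisible(x)
}

#' Predict wheezes for new recordings
#'
#' Runs the full inference pipeline on each recording: 10-s windowing,
#' feature extraction, frame posteriors, event decoding, mapping of
#' events onto the recording timeline (pad-region events discarded), and
#' the any-window recording-level label.
#'
#' @param object Fitted [wheeze_detector].
#' @param newdata An [audio_recording], a list of them, or a cohort list
#'   from [simulate_cohort()].
#' @param type `"recording"` (default) returns one `detection_result`
#'   per recording; `"events"` returns a combined event table;
#'   `"frames"` returns per-window [frame_posterior] lists.
#' @param window_s Analysis window length.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.wheeze_detector <- function(object, newdata,
                                    type = c("recording", "events", "frames"),
                                    window_s = 10, ...) {
  type <- match.arg(type)
  recs <- if (inherits(newdata, "audio_recording")) list(newdata)
          else if (is.list(newdata) && !is.null(newdata$recordings))
            newdata$recordings
          else newdata
  res <- lapply(recs, function(rec) {
    wins <- segment_windows(rec, window_s)
    posts <- lapply(wins, function(w)
      predict_frames(object, feature_bundle(w, object$feature_cfg)))
    ev_by_win <- lapply(posts, decode_events, cfg = object$config)
    dr <- classify_recording(ev_by_win, wins, rec$duration_s,
                             min_event_s = object$config$min_event_s)
    dr$posteriors <- posts
    dr
  })
  names(res) <- vapply(recs, `[[`, "", "recording_id")
  if (type == "recording") return(res)
  if (type == "frames") return(lapply(res, `[[`, "posteriors"))
  ev <- do.call(rbind, lapply(res, function(d) {
    if (nrow(d$events) == 0) return(NULL)
    cbind(recording_id = d$recording_id, d$events)
  }))
  if (is.null(ev))
    ev <- data.frame(recording_id = character(0), onset_s = numeric(0),
                     offset_s = numeric(0))
  rownames(ev) <- NULL
  ev
}

#' Save / load a detector checkpoint
#'
#' The checkpoint is a single JSON file holding the configuration header,
#' normalization statistics, and the network weights.
#'
#' @param fit Fitted [wheeze_detector].
#' @param path Checkpoint path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `wheeze_detector`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "wheeze_detector"))
  obj <- list(
    config = unclass(fit$config),
    feature_cfg = unclass(fit$feature_cfg),
    hc_stats = fit$hc_stats,
    dims = fit$dims,
    n_parameters = fit$n_parameters,
    history = fit$history,
    params = lapply(fit$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = NULL, data = as.vector(p)))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  cfg <- obj$config
  class(cfg) <- "detector_config"
  fcfg <- obj$feature_cfg
  class(fcfg) <- "feature_config"
  structure(list(params = params, config = cfg, feature_cfg = fcfg,
                 hc_stats = list(mean = obj$hc_stats$mean,
                                 sd = obj$hc_stats$sd),
                 history = as.data.frame(obj$history),
                 dims = obj$dims, n_parameters = obj$n_parameters,
                 best_val_f1 = NA_real_, call = NULL),
            class = "wheeze_detector")
}
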