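# Identity assignment: shape/change histograms, the ordered-label hidden
# Markov model, and confidence-ordered propagation across frames.

FEATURE_NAMES <- c("angle", "curvature", "score", "length", "follicle", "tip")

#' Scalar features of a traced curve
#'
#' The six features the linker models: angle near the face, average
#' absolute curvature, average tracing score, arc length, and the
#' anterior-posterior positions of the two endpoints (face-side
#' "follicle" end and distal "tip" end).  Angle and curvature come from
#' a parametric degree-3 polynomial fit; curves with fewer than 4 points
#' fall back to the chord angle and zero curvature.
#'
#' @param curve a \code{\link{wt_curve}}.
#' @param face a \code{\link{wt_face_config}} defining the
#'   anterior-posterior axis.
#' @param image_size optional \code{c(width, height)}.
#' @return named numeric vector of the six features.
#' @export
compute_features <- function(curve, face = wt_face_config(),
                             image_size = NULL) {
  wdt <- if (is.null(image_size)) NULL else image_size[1L]
  hgt <- if (is.null(image_size)) NULL else image_size[2L]
  pts <- orient_face_first(curve$points, face, wdt, hgt)
  n <- nrow(pts)
  len <- curve_arc_length(curve)
  if (n >= 4L) {
    fit <- fit_parametric(pts, 3L)
    tan0 <- polyfit_eval(fit, 0, 1L)[1L, ]
    if (sum(tan0 * (pts[n, ] - pts[1L, ])) < 0) tan0 <- -tan0
    ang <- face_angle(tan0, face)
    kgrid <- seq(0.02, 0.98, length.out = 33L)
    curv <- mean(abs(curvature_at(fit, kgrid)))
  } else {
    ang <- face_angle(pts[n, ] - pts[1L, ], face)
    curv <- 0
  }
  ax <- face_axes(face)
  ap <- function(p) sum(p * ax$anterior)
  c(angle = ang, curvature = curv, score = mean(curve$scores),
    length = len, follicle = ap(pts[1L, ]), tip = ap(pts[n, ]))
}

# features for every curve in a frame, sorted posterior -> anterior by
# the face-side endpoint; keeps the original curve index in `curve`
frame_features <- function(curves, face, image_size = NULL) {
  if (!length(curves))
    return(data.frame(curve = integer(0),
                      matrix(numeric(0), 0, 6,
                             dimnames = list(NULL, FEATURE_NAMES))))
  f <- t(vapply(curves, compute_features, numeric(6), face = face,
                image_size = image_size))
  df <- data.frame(curve = seq_along(curves), f)
  df[order(df$follicle), , drop = FALSE]   # ascending AP = posterior first
}

#' Estimate the length threshold and whisker count
#'
#' For a length threshold lambda, let F_n(lambda) be the set of frames
#' with exactly n curves longer than lambda.  Given N, the estimate
#' lambda-hat maximizes |F_N(lambda)| (the frames of F_N are then the
#' training set: their long curves are true whiskers).  With N unknown,
#' |F_n(lambda)| is maximized jointly over (n, lambda); among tied
#' counts the n whose maximizing lambda-interval (the plateau between
#' consecutive observed lengths) is widest wins -- the most robust
#' length gap.  Candidate lambdas are midpoints between consecutive
#' distinct observed lengths plus 0 and max + 1; ties in the sweep break
#' toward larger lambda.
#'
#' @param lengths list (one element per frame) of curve arc lengths.
#' @param N known whisker count, or NULL to estimate.
#' @return list with \code{N}, \code{lambda_px},
#'   \code{training_frames} (indices into \code{lengths}) and
#'   \code{n_training}.
#' @export
estimate_threshold <- function(lengths, N = NULL) {
  if (!length(lengths)) stop("need at least one frame")
  all_len <- sort(unique(unlist(lengths)))
  if (!length(all_len))
    stop("no curves in any frame; supply N manually")
  if (length(all_len) > 1200L)   # quantize candidates for very large inputs
    all_len <- sort(unique(round(all_len)))
  cand <- c(0, (head(all_len, -1L) + tail(all_len, -1L)) / 2,
            max(all_len) + 1)
  sorted <- lapply(lengths, sort)
  counts <- vapply(sorted, function(s)
    length(s) - findInterval(cand, s), integer(length(cand)))
  counts <- matrix(counts, nrow = length(cand))   # candidates x frames
  max_n <- max(counts)
  if (is.null(N)) {
    if (max_n < 1L) stop("no frame has any curve; supply N manually")
    best <- NULL
    for (n in seq_len(max_n)) {
      freq <- rowSums(counts == n)
      top <- max(freq)
      if (top == 0L) next
      hit <- which(freq == top)
      # widest maximal plateau: bracket runs of maximizing candidates
      # by the observed lengths around them
      runs <- split(hit, cumsum(c(1L, diff(hit) != 1L)))
      width <- 0; pick <- hit[length(hit)]
      for (r in runs) {
        lo <- max(c(0, all_len[all_len < cand[r[1L]]]))
        hi <- min(c(max(all_len) + 1, all_len[all_len > cand[r[length(r)]]]))
        if (hi - lo > width) { width <- hi - lo; pick <- r[length(r)] }
      }
      cndd <- list(n = n, count = top, width = width, lambda = cand[pick])
      if (is.null(best) || cndd$count > best$count ||
          (cndd$count == best$count && cndd$width > best$width))
        best <- cndd
    }
    if (is.null(best)) stop("threshold heuristic failed; supply N manually")
    N <- best$n; lambda <- best$lambda
  } else {
    N <- as.integer(N)
    freq <- rowSums(counts == N)
    if (max(freq) == 0L)
      stop(sprintf("no frame has exactly %d long curves for any threshold; check N", N))
    lambda <- cand[max(which(freq == max(freq)))]
  }
  lamcounts <- vapply(sorted, function(s) length(s) - findInterval(lambda, s), 0L)
  training <- which(lamcounts == N)
  list(N = N, lambda_px = lambda, training_frames = training,
       n_training = length(training))
}

# ---- histogram machinery ----------------------------------------------

# add-one-smoothed histogram over nbins uniform bins spanning rng
smoothed_hist <- function(values, rng, nbins = 32L) {
  if (!is.finite(rng[1L]) || rng[1L] >= rng[2L])
    rng <- c(rng[1L] - 0.5, rng[1L] + 0.5)
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  idx <- findInterval(values, br, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > nbins] <- nbins     # clamp out-of-range
  cnt <- tabulate(idx, nbins)
  mass <- (cnt + 1) / (sum(cnt) + nbins)             # a count of one per bin
  list(breaks = br, mass = mass)
}

hist_logmass <- function(h, x) {
  nb <- length(h$mass)
  idx <- findInterval(x, h$breaks, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > nb] <- nb
  log(h$mass[idx])
}

#' Build the shape model from heuristically classified training curves
#'
#' One add-one-smoothed 32-bin histogram per feature and per kind
#' (whisker W, false positive FP), all spanning the feature range
#' observed in training.  The log-likelihood of a curve under a kind is
#' the sum of its per-feature log bin masses (features treated as
#' conditionally independent).
#'
#' @param features data.frame with the six feature columns (one row per
#'   training curve).
#' @param kind character vector, "W" or "FP" per row.
#' @param nbins histogram bins per feature (default 32).
#' @return object of class \code{wt_shape_model}.
#' @export
build_shape_model <- function(features, kind, nbins = 32L) {
  stopifnot(nrow(features) == length(kind))
  if (!any(kind == "W")) stop("training set has no whisker curves")
  if (!any(kind == "FP"))
    message("no false-positive curves in training; FP histograms are uniform")
  hists <- list()
  for (f in FEATURE_NAMES) {
    rng <- range(features[[f]])
    hists[[f]] <- list(
      W = smoothed_hist(features[[f]][kind == "W"], rng, nbins),
      FP = smoothed_hist(if (any(kind == "FP")) features[[f]][kind == "FP"]
                         else numeric(0), rng, nbins))
  }
  structure(list(hists = hists, nbins = nbins), class = "wt_shape_model")
}

# sum over features of log mass for each row of `features` under kind
shape_loglik <- function(model, features, kind) {
  ll <- rep(0, nrow(features))
  for (f in FEATURE_NAMES)
    ll <- ll + hist_logmass(model$hists[[f]][[kind]], features[[f]])
  ll
}

#' Build the change model from corresponding curves in successive frames
#'
#' Histograms of per-feature changes between successive frames, one set
#' for whiskers and one for false positives, with the same smoothing as
#' the shape model.  Labels with no correspondent (an absent whisker, or
#' any F label, which has no unique correspondent) later use a neutral
#' constant: the mean log bin mass of these histograms.
#'
#' @param deltas_w,deltas_fp data.frames of feature changes (six
#'   columns; zero rows allowed).
#' @param nbins bins per feature.
#' @return object of class \code{wt_change_model}.
#' @export
build_change_model <- function(deltas_w, deltas_fp = NULL, nbins = 32L) {
  hists <- list(); const <- c(W = 0, FP = 0)
  for (f in FEATURE_NAMES) {
    vw <- if (nrow(deltas_w)) deltas_w[[f]] else numeric(0)
    vf <- if (!is.null(deltas_fp) && nrow(deltas_fp)) deltas_fp[[f]] else numeric(0)
    rng <- range(c(vw, vf, 0))
    rng <- rng + c(-1, 1) * max(1e-6, 0.05 * diff(rng))
    hists[[f]] <- list(W = smoothed_hist(vw, rng, nbins),
                       FP = smoothed_hist(vf, rng, nbins))
    const["W"] <- const[["W"]] + mean(log(hists[[f]]$W$mass))
    const["FP"] <- const[["FP"]] + mean(log(hists[[f]]$FP$mass))
  }
  structure(list(hists = hists, const = const, nbins = nbins),
            class = "wt_change_model")
}

change_loglik <- function(model, delta, kind) {
  ll <- 0
  for (f in FEATURE_NAMES)
    ll <- ll + hist_logmass(model$hists[[f]][[kind]], delta[[f]])
  ll
}

# ---- label alphabet and transitions -----------------------------------

# states in anterior-posterior scan order: F0, W1, F1, W2, ..., WN, FN
label_states <- function(N) {
  s <- "F0"
  for (i in seq_len(N)) s <- c(s, paste0("W", i), paste0("F", i))
  s
}
state_index <- function(states) as.integer(sub("^[WF]", "", states))
state_kind <- function(states) ifelse(grepl("^W", states), "W", "FP")

# legality: labels are consumed posterior -> anterior; the index may
# never decrease, W_i may not repeat, and F_i may not precede W_i
legal_transition <- function(states) {
  idx <- state_index(states); knd <- state_kind(states)
  S <- length(states)
  m <- matrix(FALSE, S, S, dimnames = list(states, states))
  for (a in seq_len(S)) for (b in seq_len(S))
    m[a, b] <- idx[b] > idx[a] || (idx[b] == idx[a] && knd[b] == "FP")
  m
}

#' Build the label transition model from training labelings
#'
#' Start and pair counts over the 2N+1 label alphabet, add-one smoothed
#' and normalized.  Transitions that violate the anterior-posterior
#' ordering rules have probability zero before smoothing and are never
#' smoothed into legality.
#'
#' @param labelings list of character vectors (labels of each frame's
#'   curves in posterior-to-anterior order).
#' @param N whisker count.
#' @return object of class \code{wt_transition_model} with
#'   \code{log_start} and \code{log_trans}.
#' @export
build_transition_model <- function(labelings, N) {
  states <- label_states(N)
  S <- length(states)
  legal <- legal_transition(states)
  start_cnt <- setNames(rep(0, S), states)
  pair_cnt <- matrix(0, S, S, dimnames = list(states, states))
  for (lab in labelings) {
    if (!length(lab)) next
    start_cnt[lab[1L]] <- start_cnt[lab[1L]] + 1
    if (length(lab) > 1L)
      for (i in seq_len(length(lab) - 1L))
        pair_cnt[lab[i], lab[i + 1L]] <- pair_cnt[lab[i], lab[i + 1L]] + 1
  }
  log_start <- log((start_cnt + 1) / sum(start_cnt + 1))
  log_trans <- matrix(-Inf, S, S, dimnames = list(states, states))
  for (a in seq_len(S)) {
    leg <- which(legal[a, ])
    log_trans[a, leg] <- log((pair_cnt[a, leg] + 1) /
                             sum(pair_cnt[a, leg] + 1))
  }
  structure(list(states = states, N = N, log_start = log_start,
                 log_trans = log_trans, legal = legal),
            class = "wt_transition_model")
}

# emission log-likelihood matrix (curves x states)
emission_matrix <- function(features, shape, trans, change = NULL,
                            neighbor = NULL, forward_delta = TRUE) {
  states <- trans$states
  knd <- state_kind(states)
  n <- nrow(features)
  e <- matrix(0, n, length(states))
  llW <- shape_loglik(shape, features, "W")
  llF <- shape_loglik(shape, features, "FP")
  for (s in seq_along(states)) e[, s] <- if (knd[s] == "W") llW else llF
  if (!is.null(change)) {
    for (s in seq_along(states)) {
      if (knd[s] == "W") {
        j <- if (!is.null(neighbor)) which(neighbor$labels == states[s]) else integer(0)
        if (length(j) == 1L) {
          for (i in seq_len(n)) {
            delta <- lapply(FEATURE_NAMES, function(f)
              if (forward_delta) features[[f]][i] - neighbor$features[[f]][j]
              else neighbor$features[[f]][j] - features[[f]][i])
            names(delta) <- FEATURE_NAMES
            e[i, s] <- e[i, s] + change_loglik(change, delta, "W")
          }
        } else e[, s] <- e[, s] + change$const[["W"]]
      } else e[, s] <- e[, s] + change$const[["FP"]]
    }
  }
  e
}

#' Optimal labeling of one frame
#'
#' Exact maximization, by the Viterbi recursion over the 2N+1-state
#' chain, of the product of transition priors and per-curve likelihoods
#' over all label sequences satisfying the ordering rules.  With a
#' change model and a neighbouring frame's labeling, each W_i term is
#' multiplied by the likelihood of its feature changes relative to the
#' correspondingly labeled neighbour curve (a neutral constant when
#' absent); F terms use a constant, as false positives have no unique
#' correspondent.
#'
#' @param features frame features (rows in posterior-to-anterior
#'   order), e.g. from \code{\link{compute_features}}.
#' @param shape a \code{\link{build_shape_model}} object.
#' @param trans a \code{\link{build_transition_model}} object.
#' @param change optional \code{\link{build_change_model}} object.
#' @param neighbor optional \code{list(labels, features)} of an adjacent
#'   frame (labels aligned to its feature rows).
#' @param forward_delta TRUE if the neighbour precedes this frame in
#'   time (changes are taken later minus earlier).
#' @return list with \code{labels} (per feature row), \code{log_score}
#'   (joint log probability) and \code{score} (log probability per
#'   curve, the frame's confidence).
#' @export
label_frame <- function(features, shape, trans, change = NULL,
                        neighbor = NULL, forward_delta = TRUE) {
  n <- nrow(features)
  if (n == 0L)
    return(list(labels = character(0), log_score = 0, score = 0))
  states <- trans$states
  S <- length(states)
  e <- emission_matrix(features, shape, trans, change, neighbor, forward_delta)
  dp <- matrix(-Inf, n, S)
  bk <- matrix(0L, n, S)
  dp[1L, ] <- trans$log_start + e[1L, ]
  if (n > 1L) for (i in 2:n) for (s in seq_len(S)) {
    cand <- dp[i - 1L, ] + trans$log_trans[, s]
    b <- which.max(cand)
    dp[i, s] <- cand[b] + e[i, s]
    bk[i, s] <- b
  }
  s_end <- which.max(dp[n, ])
  lab <- integer(n); lab[n] <- s_end
  if (n > 1L) for (i in (n - 1L):1L) lab[i] <- bk[i + 1L, lab[i + 1L]]
  total <- dp[n, s_end]
  list(labels = states[lab], log_score = total, score = total / n)
}

#' Link traced curves into whisker identities across a video
#'
#' The full linking pipeline: (1) estimate the length threshold and
#' whisker count; (2) from the heuristically labeled training frames,
#' build the shape histograms and the label transition model; (3) label
#' every frame with shape features alone; (4) build the change model
#' from the shape-only labelings of successive training frames;
#' (5) propagate in confidence order -- repeatedly visit the
#' highest-scoring unvisited frame and relabel its unvisited neighbours
#' with the full model conditioned on it, updating their scores --
#' until every frame has been visited.  Deterministic; queue ties break
#' toward the lower frame index.
#'
#' @param curves_by_frame list (one element per frame, in time order)
#'   of lists of \code{\link{wt_curve}}.
#' @param config a \code{\link{wt_config}} (face geometry, optional
#'   known N).
#' @param image_size optional \code{c(width, height)}.
#' @return object of class \code{wt_linking}: per-frame \code{labels}
#'   (aligned to the input curve order; NULL frames allowed), the
#'   estimated \code{N}, \code{lambda_px}, training-frame count, and
#'   the fitted models.
#' @export
link_video <- function(curves_by_frame, config = wt_config(),
                       image_size = NULL) {
  T_ <- length(curves_by_frame)
  if (T_ < 1L) stop("need at least one frame")
  face <- config$face
  feats <- lapply(curves_by_frame, frame_features, face = face,
                  image_size = image_size)
  thr <- estimate_threshold(lapply(feats, function(f) f$length),
                            config$n_whiskers)
  N <- thr$N; lambda <- thr$lambda_px
  states <- label_states(N)

  # heuristic labeling of training frames: the N long curves are
  # W1..WN posterior-to-anterior, everything else F_i
  heur <- vector("list", T_)
  for (t in thr$training_frames) {
    f <- feats[[t]]
    lab <- character(nrow(f))
    wi <- 0L
    for (i in seq_len(nrow(f))) {
      if (f$length[i] > lambda) { wi <- wi + 1L; lab[i] <- paste0("W", wi) }
      else lab[i] <- paste0("F", wi)
    }
    heur[[t]] <- lab
  }
  train_feats <- do.call(rbind, feats[thr$training_frames])
  train_kind <- state_kind(unlist(heur[thr$training_frames]))
  shape <- build_shape_model(train_feats, train_kind)
  trans <- build_transition_model(heur[thr$training_frames], N)

  # shape-only pass over every frame
  lab0 <- lapply(feats, label_frame, shape = shape, trans = trans)

  # change histograms from successive training-frame pairs, using the
  # shape-only labelings as the correspondence
  dW <- list(); dF <- list()
  tset <- intersect(thr$training_frames, thr$training_frames - 1L)
  for (t in tset) {   # t and t+1 both in training
    la <- lab0[[t]]$labels; lb <- lab0[[t + 1L]]$labels
    fa <- feats[[t]]; fb <- feats[[t + 1L]]
    for (s in states) {
      ia <- which(la == s); ib <- which(lb == s)
      if (!length(ia) || !length(ib)) next
      if (startsWith(s, "W")) {
        if (length(ia) == 1L && length(ib) == 1L)
          dW[[length(dW) + 1L]] <- fb[ib, FEATURE_NAMES] - fa[ia, FEATURE_NAMES]
      } else {
        k <- min(length(ia), length(ib))   # zip same-label FPs in AP order
        for (q in seq_len(k))
          dF[[length(dF) + 1L]] <- fb[ib[q], FEATURE_NAMES] - fa[ia[q], FEATURE_NAMES]
      }
    }
  }
  bind0 <- function(l) if (length(l)) do.call(rbind, l) else
    as.data.frame(matrix(numeric(0), 0, 6, dimnames = list(NULL, FEATURE_NAMES)))
  change <- build_change_model(bind0(dW), bind0(dF))

  # confidence-ordered propagation
  labelings <- lab0
  scores <- vapply(lab0, `[[`, 0, "score")
  visited <- rep(FALSE, T_)
  for (step in seq_len(T_)) {
    t <- which(!visited)[which.max(scores[!visited])]
    visited[t] <- TRUE
    nb_t <- list(labels = labelings[[t]]$labels, features = feats[[t]])
    for (nb in c(t - 1L, t + 1L)) {
      if (nb < 1L || nb > T_ || visited[nb]) next
      rel <- label_frame(feats[[nb]], shape, trans, change,
                         neighbor = nb_t, forward_delta = nb > t)
      labelings[[nb]] <- rel
      scores[nb] <- rel$score
    }
  }

  # map labels back to input curve order
  out <- vector("list", T_)
  for (t in seq_len(T_)) {
    lab <- character(length(curves_by_frame[[t]]))
    if (length(lab)) lab[feats[[t]]$curve] <- labelings[[t]]$labels
    out[[t]] <- list(labels = lab, score = labelings[[t]]$score)
  }
  structure(list(frames = out, N = N, lambda_px = lambda,
                 n_training = thr$n_training,
                 shape_model = shape, transition_model = trans,
                 change_model = change),
            class = "wt_linking")
}

#' @export
print.wt_linking <- function(x, ...) {
  cat(sprintf("<wt_linking  %d frames, N = %d, lambda = %.1f px, %d training frames>\n",
              length(x$frames), x$N, x$lambda_px, x$n_training))
  invisible(x)
}
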