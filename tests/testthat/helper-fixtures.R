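# Shared fixtures: everything is generated in code at test time.

# Small, fast render settings used by most simulator/tracker unit tests
# (study-scale 224 px frames are exercised in test-acceptance.R).
tiny_protocol <- function(...) {
  args <- list(duration_s = 0.5, repeats = 1, fps = 200,
               frame_size = 64, field_size = 128,
               gain_px_per_urad = 0.5, pupil_fraction = 0.25,
               read_noise_dn = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(recording_protocol, args)
}

# A displacement trace fabricated directly (no rendering) for feature and
# pipeline tests.
fake_trace <- function(n = 200, fps = 200, f_x = 10, amp_x = 1,
                       f_y = 0, amp_y = 0, tag = "v1", noise = 0) {
  t <- (0:(n - 1)) / fps
  px <- amp_x * sin(2 * pi * f_x * t)
  py <- if (f_y > 0) amp_y * sin(2 * pi * f_y * t) else rep(0, n)
  if (noise > 0) {
    px <- px + rnorm(n, 0, noise)
    py <- py + rnorm(n, 0, noise)
  }
  structure(list(pos_x = px, pos_y = py, dpos_x = diff(px),
                 dpos_y = diff(py), fps = fps, video_tag = tag,
                 mode = "sequential"),
            class = "displacement_trace")
}

# A labelled feature table fabricated from per-class tone traces; classes
# occupy disjoint frequency bands so band-power features separate them.
fake_feature_table <- function(classes = c("a", "b"),
                               freqs = c(a = 10, b = 40),
                               dogs = "dog1", videos_per_class = 4,
                               frames_per_video = 200, noise = 0.05,
                               seed = 1) {
  set.seed(seed)
  rows <- list()
  for (dog in dogs) for (cl in classes) {
    for (v in seq_len(videos_per_class)) {
      tag <- sprintf("%s_%s_v%d", dog, cl, v)
      tr <- fake_trace(frames_per_video, f_x = freqs[[cl]], amp_x = 1,
                       tag = tag, noise = noise)
      chunks <- chunk_trace(tr)
      feats <- do.call(rbind, lapply(chunks, extract_features))
      rows[[tag]] <- cbind(
        data.frame(dog_id = dog, region = "amygdala", smell = cl,
                   distance_m = 0.1, video_tag = tag,
                   chunk_idx = seq_along(chunks),
                   stringsAsFactors = FALSE),
        as.data.frame(feats))
    }
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(tab, "schema") <- feature_schema()
  tab
}

# Independent exhaustive split oracle: enumerates every (feature,
# midpoint-threshold) pair and scores it directly from the structure-score
# formula. Deliberately written as plain loops, independent of the
# package's vectorized split search.
oracle_best_split <- function(X, g, h, lambda = 0, gamma = 0,
                              min_child_hessian = 0) {
  score_leaf <- function(idx) {
    -0.5 * sum(g[idx])^2 / (sum(h[idx]) + lambda) + gamma
  }
  parent <- score_leaf(seq_len(nrow(X)))
  best <- list(gain = 0, feature = NA, threshold = NA)
  for (f in seq_len(ncol(X))) {
    vals <- sort(unique(X[, f]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      left <- which(X[, f] < thr)
      right <- which(X[, f] >= thr)
      if (sum(h[left]) < min_child_hessian ||
          sum(h[right]) < min_child_hessian) next
      gain <- parent - (score_leaf(left) + score_leaf(right))
      if (gain > best$gain) {
        best <- list(gain = gain, feature = f, threshold = thr)
      }
    }
  }
  best
}

# Count leaves of a gbt tree.
n_leaves <- function(tree) attr(tree, "n_leaves")

`%||%` <- function(a, b) if (is.null(a)) b else a
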