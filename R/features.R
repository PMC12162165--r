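#' Segment a displacement trace into fixed-length chunks
#'
#' Cuts the positional channels into windows of `chunk_len` frames
#' (default 40, i.e. 200 ms at 200 FPS). Windows never span two videos;
#' the trailing partial window is dropped. Within each chunk the
#' differential channels (`dpos`) are the first differences of that
#' chunk's own `pos` samples (length `chunk_len - 1`), so chunks are
#' self-contained.
#'
#' @param trace A [track()] result.
#' @param chunk_len Window length in frames (>= 2).
#' @param stride Window start increment; default `chunk_len`
#'   (non-overlapping). Smaller strides give overlapping windows.
#' @return List of objects of class `"speckle_chunk"`, each with `pos_x`,
#'   `pos_y` (length `chunk_len`), `dpos_x`, `dpos_y` (length
#'   `chunk_len - 1`), `fps`, `video_tag`, `chunk_idx`. A trace shorter
#'   than one window yields an empty list.
#' @examples
#' tr <- structure(list(pos_x = sin(1:200), pos_y = cos(1:200),
#'                      fps = 200, video_tag = "v1"),
#'                 class = "displacement_trace")
#' length(chunk_trace(tr))  # 5
#' @export
chunk_trace <- function(trace, chunk_len = 40, stride = chunk_len) {
  if (chunk_len < 2) stop("chunk_len must be >= 2", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  n <- length(trace$pos_x)
  if (n < chunk_len) return(list())
  starts <- seq(1, n - chunk_len + 1, by = stride)
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:(starts[i] + chunk_len - 1)
    structure(list(pos_x = trace$pos_x[idx], pos_y = trace$pos_y[idx],
                   dpos_x = diff(trace$pos_x[idx]),
                   dpos_y = diff(trace$pos_y[idx]),
                   fps = trace$fps, video_tag = trace$video_tag,
                   chunk_idx = i),
              class = "speckle_chunk")
  })
}

#' Spectral centroid of a time series
#'
#' Amplitude-weighted mean frequency `sum(f_k |X_k|) / sum(|X_k|)` over the
#' one-sided, non-DC bins of the mean-removed series. Returns 0 when all
#' magnitudes vanish (degenerate input contract).
#'
#' @param x Numeric series (length >= 4).
#' @param fps Sampling rate in Hz.
#' @return Centroid frequency in Hz.
#' @examples
#' t <- (0:39) / 200
#' spectral_centroid(sin(2 * pi * 10 * t), 200)  # ~10
#' @export
spectral_centroid <- function(x, fps) {
  if (length(x) < 4) stop("series too short", call. = FALSE)
  sp <- .one_sided_spectrum(x - mean(x), fps)
  mag <- sp$magnitude[-1]
  f <- sp$freqs[-1]
  s <- sum(mag)
  if (s < .Machine$double.eps * length(mag)) return(0)
  sum(f * mag) / s
}

.dominant_frequency <- function(x, fps) {
  sp <- .one_sided_spectrum(x - mean(x), fps)
  mag <- sp$magnitude[-1]
  if (max(mag) < .Machine$double.eps * length(mag)) return(0)
  sp$freqs[-1][which.max(mag)]
}

.band_power <- function(x, fps, lo, hi) {
  sp <- .one_sided_spectrum(x - mean(x), fps)
  nyq <- fps / 2
  # [lo, hi), except the top band closes at Nyquist
  sel <- sp$freqs >= lo & (if (hi >= nyq) sp$freqs <= hi else sp$freqs < hi)
  sel[1] <- FALSE
  sum(sp$magnitude[sel]^2)
}

.feature_bands <- list(c(0, 10), c(10, 30), c(30, 60), c(60, 100))

.channel_features <- function(x, fps, hann = TRUE) {
  m <- mean(x)
  xs <- x - m
  xw <- if (hann) xs * .hann(length(xs)) else xs
  bands <- vapply(.feature_bands,
                  function(b) .band_power(xw, fps, b[1], b[2]), 0)
  c(mean = m,
    sd = stats::sd(x),
    rms = sqrt(mean(x^2)),
    min = min(x),
    max = max(x),
    range = max(x) - min(x),
    energy = sum(x^2),
    dom_freq = .dominant_frequency(xw, fps),
    spec_centroid = spectral_centroid(xw, fps),
    bp_0_10 = bands[1], bp_10_30 = bands[2],
    bp_30_60 = bands[3], bp_60_100 = bands[4])
}

#' Extract the fixed 52-feature vector from a chunk
#'
#' For each of the four channels (`pos_x`, `pos_y`, `dpos_x`, `dpos_y`)
#' computes 13 features in a fixed, documented order: mean, standard
#' deviation, RMS, min, max, range, energy, dominant frequency, spectral
#' centroid, and band powers over 0-10, 10-30, 30-60 and 60-100 Hz.
#' Spectral features are computed on the mean-removed, Hann-windowed
#' samples (frequency resolution 5 Hz for 40-frame chunks at 200 FPS).
#' The result is fully deterministic.
#'
#' @param chunk A `speckle_chunk` from [chunk_trace()].
#' @param fps Sampling rate; defaults to the chunk's own.
#' @return Named numeric vector of length 52, names
#'   `<channel>.<feature>`.
#' @export
extract_features <- function(chunk, fps = chunk$fps) {
  chans <- c("pos_x", "pos_y", "dpos_x", "dpos_y")
  out <- unlist(lapply(chans, function(ch) {
    x <- chunk[[ch]]
    if (anyNA(x) || any(!is.finite(x))) {
      stop("non-finite values in channel ", ch, call. = FALSE)
    }
    f <- .channel_features(x, fps)
    names(f) <- paste(ch, names(f), sep = ".")
    f
  }))
  out
}

#' @rdname extract_features
#' @return `feature_schema()` returns the 52 feature column names in their
#'   fixed order.
#' @export
feature_schema <- function() {
  feats <- c("mean", "sd", "rms", "min", "max", "range", "energy",
             "dom_freq", "spec_centroid",
             "bp_0_10", "bp_10_30", "bp_30_60", "bp_60_100")
  as.vector(vapply(c("pos_x", "pos_y", "dpos_x", "dpos_y"),
                   function(ch) paste(ch, feats, sep = "."),
                   character(length(feats))))
}

.group_cols <- c("dog_id", "region", "smell", "distance_m",
                 "video_tag", "chunk_idx")

#' Build the labelled feature table for a dataset
#'
#' Chunks every trace, extracts the fixed 52-feature vector per chunk and
#' attaches the label (`smell`) and grouping keys from the manifest. The
#' schema (column order) is fixed; an MD5 schema hash is recorded as an
#' attribute for reproducibility.
#'
#' @param manifest Manifest data frame from [generate_dataset()].
#' @param traces Named list of [track()] results, keyed by `video_tag`;
#'   every manifest row must have one.
#' @param chunk_len,stride Passed to [chunk_trace()].
#' @return Data frame with columns `dog_id, region, smell, distance_m,
#'   video_tag, chunk_idx` followed by the 52 features; one row per chunk.
#'   Attributes: `schema` (feature names), `schema_hash`.
#' @export
build_feature_table <- function(manifest, traces, chunk_len = 40,
                                stride = chunk_len) {
  missing_tags <- setdiff(manifest$video_tag, names(traces))
  if (length(missing_tags)) {
    stop("manifest rows without traces: ",
         paste(utils::head(missing_tags, 5), collapse = ", "), call. = FALSE)
  }
  schema <- feature_schema()
  blocks <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    chunks <- chunk_trace(traces[[row$video_tag]], chunk_len, stride)
    if (!length(chunks)) return(NULL)
    feats <- do.call(rbind, lapply(chunks, extract_features))
    cbind(data.frame(dog_id = row$dog_id, region = row$region,
                     smell = row$smell, distance_m = row$distance_m,
                     video_tag = row$video_tag,
                     chunk_idx = seq_along(chunks),
                     stringsAsFactors = FALSE),
          as.data.frame(feats))
  })
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  tab <- if (length(blocks)) {
    do.call(rbind, c(blocks, make.row.names = FALSE))
  } else {
    empty <- c(.group_cols, schema)
    as.data.frame(stats::setNames(
      c(list(character(0), character(0), character(0), numeric(0),
             character(0), integer(0)),
        rep(list(numeric(0)), length(schema))), empty))
  }
  # order is manifest-independent: sort by (video_tag, chunk_idx)
  tab <- tab[order(tab$video_tag, tab$chunk_idx), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "schema") <- schema
  attr(tab, "schema_hash") <- .schema_hash(schema)
  tab
}

.schema_hash <- function(schema) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(schema, f)
  unname(tools::md5sum(f))
}
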