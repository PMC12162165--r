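#' Confusion matrix
#'
#' Counts of true class (rows) against predicted class (columns) over a
#' fixed class order.
#'
#' @param y_true,y_pred Vectors (factor or character) of equal length with
#'   labels drawn from `classes`.
#' @param classes Class order; defaults to the sorted union of labels.
#' @return Object of class `"confusion_matrix"`: a C x C integer matrix
#'   with `dimnames` `list(true = classes, predicted = classes)`.
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown)) {
    stop("labels outside class order: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- table(factor(y_true, levels = classes),
             factor(y_pred, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Row-normalized confusion matrix
#'
#' Divides every nonzero row by its sum, so that each true class "has 1.00
#' samples". All-zero rows are left at zero and flagged in the
#' `zero_rows` attribute.
#'
#' @param m A [confusion_matrix()].
#' @return Numeric matrix with (nonzero) rows summing to 1, attribute
#'   `zero_rows` naming any all-zero rows.
#' @export
normalize_rows <- function(m) {
  rs <- rowSums(m)
  out <- m / ifelse(rs == 0, 1, rs)
  out <- matrix(as.numeric(out), nrow = nrow(m), dimnames = dimnames(m))
  attr(out, "zero_rows") <- rownames(m)[rs == 0]
  out
}

#' One-vs-rest collapse of a confusion matrix
#'
#' @param m A [confusion_matrix()].
#' @param positive_class The class treated as positive.
#' @return Object of class `"binary_counts"`: list with `TP`, `FN`, `FP`,
#'   `TN` (summing to the total instance count).
#' @export
binary_counts <- function(m, positive_class) {
  classes <- rownames(m)
  if (!positive_class %in% classes) {
    stop("unknown class: ", positive_class, call. = FALSE)
  }
  i <- match(positive_class, classes)
  TP <- m[i, i]
  FN <- sum(m[i, -i])
  FP <- sum(m[-i, i])
  TN <- sum(m[-i, -i])
  structure(list(TP = TP, FN = FN, FP = FP, TN = TN,
                 positive_class = positive_class),
            class = "binary_counts")
}

#' Classification metrics from binary counts
#'
#' Computes accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, sensitivity
#' (recall) `TP/(TP+FN)`, specificity `TN/(FP+TN)` and
#' `F1 = 2*P*R/(P+R)`. A metric with a zero denominator is flagged
#' undefined (`NA` value, named in the `undefined` attribute) rather than
#' silently set to 0.
#'
#' @param counts A [binary_counts()] object.
#' @return Object of class `"class_metrics"`: named numeric vector
#'   `accuracy, precision, sensitivity, specificity, f1` with attribute
#'   `undefined`.
#' @examples
#' cm <- confusion_matrix(rep(c("p", "n"), c(10, 10)),
#'                        rep(c("p", "n", "p", "n"), c(8, 2, 1, 9)))
#' classification_metrics(binary_counts(cm, "p"))
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "binary_counts"))
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0) stop("no instances", call. = FALSE)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- (counts$TP + counts$TN) / n
  prec <- safe(counts$TP, counts$TP + counts$FP)
  sens <- safe(counts$TP, counts$TP + counts$FN)
  spec <- safe(counts$TN, counts$FP + counts$TN)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  out <- c(accuracy = acc, precision = prec, sensitivity = sens,
           specificity = spec, f1 = f1)
  structure(out, undefined = names(out)[is.na(out)],
            class = c("class_metrics", "numeric"))
}

#' @export
print.class_metrics <- function(x, digits = 4, ...) {
  v <- unclass(x)
  attr(v, "undefined") <- NULL
  print(round(v, digits))
  und <- attr(x, "undefined")
  if (length(und)) cat("undefined (zero denominator):",
                       paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' Macro-averaged multi-class metrics
#'
#' Unweighted mean of the per-class one-vs-rest metrics
#' ([classification_metrics()] over every class as positive). Per-class
#' undefined entries are skipped; the number skipped per metric is
#' recorded in the `n_undefined` attribute and reported with a warning.
#' A metric undefined for every class is itself `NA`.
#'
#' @param m A [confusion_matrix()] with >= 2 classes.
#' @return A `class_metrics` vector of macro averages with attributes
#'   `n_undefined` and `per_class` (the per-class metric matrix).
#' @export
macro_metrics <- function(m) {
  classes <- rownames(m)
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  per <- vapply(classes,
                function(cl) unclass(classification_metrics(
                  binary_counts(m, cl))),
                numeric(5))
  rownames(per) <- c("accuracy", "precision", "sensitivity",
                     "specificity", "f1")
  n_und <- rowSums(is.na(per))
  if (any(n_und > 0)) {
    warning(sum(n_und), " undefined per-class metric value(s) skipped in ",
            "macro average", call. = FALSE)
  }
  avg <- rowMeans(per, na.rm = TRUE)
  avg[n_und == length(classes)] <- NA_real_
  structure(avg, undefined = names(avg)[is.na(avg)],
            n_undefined = n_und, per_class = per,
            class = c("class_metrics", "numeric"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(matrix(as.integer(x), nrow(x), dimnames = dimnames(x)))
  invisible(x)
}
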