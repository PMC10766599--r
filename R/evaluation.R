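# Open-set verification protocol: disjoint train/test class splits,
# genuine/impostor pair construction, FAR/FRR curves, equal error rate and
# maximum accuracy. Scores are similarities: a pair is accepted at threshold
# t when its score is >= t.

#' Split classes into disjoint train/test halves
#'
#' Open-set protocol: for each fold seed, half of the classes (rounded down)
#' are drawn at random for training and the remainder are reserved for
#' testing, so verification is always scored on classes the model never saw.
#' The four default folds are independent seeded repetitions whose metrics
#' are averaged.
#'
#' @param classes Vector of class identifiers (length >= 2).
#' @param fold_seeds Integer seed per fold.
#' @return A list with one `list(train, test)` per fold.
#' @export
split_open_set <- function(classes, fold_seeds = 1:4) {
  if (length(classes) < 2) stop("need at least 2 classes to split")
  lapply(fold_seeds, function(s) {
    idx <- withr::with_seed(s, sample.int(length(classes)))
    k <- length(classes) %/% 2
    list(train = sort(classes[idx[seq_len(k)]]),
         test = sort(classes[idx[-seq_len(k)]]))
  })
}

#' Construct genuine and impostor pair indices
#'
#' Genuine pairs are all within-class sample pairs, giving
#' `N_g = sum_c choose(n_c, 2)` (equal to `N_c * N_f * (N_f - 1) / 2` on a
#' balanced set). Impostor pairs follow the one-representative convention:
#' one cross-class pair per unordered class pair, `N_i = choose(N_c, 2)`,
#' using the first sample of each class under a seeded within-class ordering.
#' `impostor = "exhaustive"` instead enumerates all cross-class sample pairs.
#'
#' @param x A `vein_dataset` or an integer/factor label vector.
#' @param impostor `"representative"` (default) or `"exhaustive"`.
#' @param seed Seed for the representative ordering.
#' @return A list with integer index matrices `genuine` and `impostor` (two
#'   columns, rows are pairs) and counts `n_genuine`, `n_impostor`.
#' @examples
#' p <- make_pairs(rep(1:2, each = 2))
#' p$n_genuine  # 2
#' p$n_impostor # 1
#' @export
make_pairs <- function(x, impostor = c("representative", "exhaustive"),
                       seed = 1L) {
  impostor <- match.arg(impostor)
  labels <- if (inherits(x, "vein_dataset")) x$labels else x
  labels <- as.integer(factor(labels))
  by_class <- split(seq_along(labels), labels)
  genuine <- do.call(rbind, lapply(by_class, function(idx) {
    if (length(idx) < 2) return(NULL)
    t(utils::combn(idx, 2))
  }))
  if (is.null(genuine)) genuine <- matrix(integer(), ncol = 2)
  nc <- length(by_class)
  if (nc < 2) {
    imp <- matrix(integer(), ncol = 2)
  } else if (impostor == "representative") {
    reps <- withr::with_seed(seed, vapply(by_class, function(idx)
      idx[sample.int(length(idx), 1L)], integer(1)))
    imp <- t(utils::combn(unname(reps), 2))
  } else {
    cp <- t(utils::combn(nc, 2))
    imp <- do.call(rbind, lapply(seq_len(nrow(cp)), function(r)
      as.matrix(expand.grid(by_class[[cp[r, 1]]], by_class[[cp[r, 2]]]))))
    imp <- unname(imp)
  }
  list(genuine = unname(genuine), impostor = imp,
       n_genuine = nrow(genuine), n_impostor = nrow(imp))
}

#' Bundle genuine and impostor scores
#'
#' @param genuine,impostor Numeric similarity scores of genuine (same-class)
#'   and impostor (cross-class) pairs.
#' @return An object of class `pair_set`.
#' @export
pair_set <- function(genuine, impostor) {
  stopifnot(all(is.finite(genuine)), all(is.finite(impostor)))
  structure(list(genuine = as.numeric(genuine),
                 impostor = as.numeric(impostor),
                 n_genuine = length(genuine), n_impostor = length(impostor)),
            class = "pair_set")
}

#' Score pairs of embeddings
#'
#' @param embeddings `N x D` matrix of (unit-norm) embeddings.
#' @param pairs A [make_pairs()] result.
#' @param metric `"cosine"` similarity (default) or negated Euclidean
#'   distance, so that larger is always more similar.
#' @return A [pair_set()].
#' @export
score_pairs <- function(embeddings, pairs, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  sc <- function(ix) {
    if (nrow(ix) == 0) return(numeric())
    a <- embeddings[ix[, 1], , drop = FALSE]
    b <- embeddings[ix[, 2], , drop = FALSE]
    if (metric == "cosine") {
      rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
    } else {
      -sqrt(rowSums((a - b)^2))
    }
  }
  pair_set(sc(pairs$genuine), sc(pairs$impostor))
}

# counts of genuine < t and impostor < t for a vector of thresholds
count_below <- function(scores, t) {
  findInterval(t, sort(scores), left.open = TRUE)
}

#' FAR/FRR curves over thresholds
#'
#' At threshold `t` (accept when score >= t): the false acceptance rate is
#' the fraction of impostor scores at or above `t`, the false rejection rate
#' the fraction of genuine scores below `t`. FAR is non-increasing and FRR
#' non-decreasing in `t`.
#'
#' @param pairs A [pair_set()].
#' @param thresholds Thresholds to evaluate; defaults to the sorted union of
#'   all scores flanked by `-Inf` and `+Inf`.
#' @return A data frame with columns `threshold`, `far`, `frr`.
#' @export
compute_far_frr <- function(pairs, thresholds = NULL) {
  stopifnot(inherits(pairs, "pair_set"))
  if (pairs$n_genuine < 1 || pairs$n_impostor < 1)
    stop("need at least one genuine and one impostor score")
  if (is.null(thresholds))
    thresholds <- c(-Inf, sort(unique(c(pairs$genuine, pairs$impostor))), Inf)
  data.frame(
    threshold = thresholds,
    far = 1 - count_below(pairs$impostor, thresholds) / pairs$n_impostor,
    frr = count_below(pairs$genuine, thresholds) / pairs$n_genuine)
}

#' Equal error rate
#'
#' Finds the operating point where the false acceptance and false rejection
#' rates cross. The crossing is located over the sorted union of observed
#' scores; when FAR and FRR are never exactly equal at an evaluated
#' threshold, the EER is linearly interpolated between the two bracketing
#' thresholds. Ties are broken toward the lower threshold.
#'
#' @param pairs A [pair_set()].
#' @return A list with `eer` in `[0, 1]` and `threshold`.
#' @export
compute_eer <- function(pairs) {
  curves <- compute_far_frr(pairs)
  d <- curves$far - curves$frr        # non-increasing, starts at 1
  i <- which(d <= 0)[1]
  if (is.na(i)) i <- nrow(curves)     # cannot happen with both sets non-empty
  if (d[i] == 0)
    return(list(eer = curves$far[i], threshold = curves$threshold[i]))
  # bracket: d[i-1] > 0 >= d[i]
  f1 <- curves$far[i - 1]; f2 <- curves$far[i]
  r1 <- curves$frr[i - 1]; r2 <- curves$frr[i]
  alpha <- (f1 - r1) / ((f1 - r1) - (f2 - r2))
  t1 <- curves$threshold[i - 1]; t2 <- curves$threshold[i]
  list(eer = f1 + alpha * (f2 - f1),
       threshold = if (is.finite(t1) && is.finite(t2))
         t1 + alpha * (t2 - t1) else t2)
}

#' Maximum verification accuracy
#'
#' `Acc = max_t (genuine accepts at t + impostor rejects at t) / (N_g + N_i)`
#' over all thresholds (the decision-threshold rule is a documented
#' convention; the curve-level quantities do not depend on it).
#'
#' @param pairs A [pair_set()].
#' @return Scalar accuracy in `[0, 1]`.
#' @export
compute_accuracy <- function(pairs) {
  stopifnot(inherits(pairs, "pair_set"))
  cand <- c(sort(unique(c(pairs$genuine, pairs$impostor))), Inf)
  correct <- (pairs$n_genuine - count_below(pairs$genuine, cand)) +
    count_below(pairs$impostor, cand)
  max(correct) / (pairs$n_genuine + pairs$n_impostor)
}

#' Full verification result for a score set
#'
#' @param pairs A [pair_set()].
#' @return An object of class `verification_result`: FAR/FRR curves plus
#'   `eer`, `eer_threshold` and `acc`.
#' @export
verification_result <- function(pairs) {
  curves <- compute_far_frr(pairs)
  e <- compute_eer(pairs)
  structure(list(curves = curves, eer = e$eer, eer_threshold = e$threshold,
                 acc = compute_accuracy(pairs),
                 n_genuine = pairs$n_genuine, n_impostor = pairs$n_impostor),
            class = "verification_result")
}

#' @export
print.verification_result <- function(x, ...) {
  cat(sprintf("Verification result: EER %.2f%% (threshold %.4f), Acc %.2f%%\n",
              100 * x$eer, x$eer_threshold, 100 * x$acc))
  cat(sprintf("  %d genuine pairs, %d impostor pairs\n",
              x$n_genuine, x$n_impostor))
  invisible(x)
}

#' @export
as.data.frame.verification_result <- function(x, ...) x$curves

#' Plot FAR/FRR curves of a verification result
#'
#' @param object A [verification_result()].
#' @param ... Unused.
#' @return A ggplot object showing FAR and FRR against the decision
#'   threshold, with the EER operating point marked.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.verification_result <- function(object, ...) {
  cv <- object$curves[is.finite(object$curves$threshold), ]
  df <- data.frame(
    threshold = rep(cv$threshold, 2),
    rate = c(cv$far, cv$frr),
    which = rep(c("FAR", "FRR"), each = nrow(cv)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$rate,
                                   colour = .data$which)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = data.frame(threshold = object$eer_threshold,
                                          rate = object$eer, which = "EER"),
                        colour = "black") +
    ggplot2::labs(x = "decision threshold", y = "error rate", colour = NULL,
                  title = sprintf("EER = %.2f%%", 100 * object$eer)) +
    ggplot2::theme_minimal()
}
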