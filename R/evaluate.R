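#' Score a predicted assignment against ground truth
#'
#' Computes accuracy, macro F1 (mean of one-vs-rest F1 over the classes
#' present in the truth; a class with zero precision + recall contributes 0)
#' and the multiclass Matthews correlation coefficient in its covariance
#' (Gorodkin) form, with the zero-denominator convention MCC = 0.
#'
#' Labels may be integers, characters or factors; the two vectors share one
#' label space. SPAN predicts named types directly, so no cluster matching
#' is needed; for unsupervised baselines or ablations with anonymous
#' clusters, relabel first with [match_labels()].
#'
#' @param z_true,z_pred Equal-length label vectors.
#' @return A one-row tibble with columns `accuracy`, `macro_f1`, `mcc`.
#' @export
score_assignment <- function(z_true, z_pred) {
  if (length(z_true) != length(z_pred)) {
    abort("z_true and z_pred must have equal length", class = "spanr_invalid_input")
  }
  levels <- union(unique(as.character(z_true)), unique(as.character(z_pred)))
  zt <- factor(as.character(z_true), levels = levels)
  zp <- factor(as.character(z_pred), levels = levels)
  cm <- table(truth = zt, pred = zp)
  n <- sum(cm)

  accuracy <- sum(diag(cm)) / n

  # macro F1 over classes present in the truth; predicted-only classes still
  # contribute through their false positives
  truth_classes <- levels[rowSums(cm) > 0]
  f1 <- vapply(truth_classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  macro_f1 <- mean(f1)

  # Gorodkin covariance form of the multiclass MCC
  t_k <- rowSums(cm); p_k <- colSums(cm); c_ <- sum(diag(cm))
  num <- c_ * n - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den

  tibble::tibble(accuracy = accuracy, macro_f1 = macro_f1, mcc = mcc)
}

#' Optimally relabel anonymous clusters
#'
#' Finds the one-to-one mapping from predicted cluster labels to truth
#' labels that maximises agreement (an assignment problem on the confusion
#' matrix, solved exactly for up to 9 classes by enumeration). Surplus
#' predicted clusters stay unmatched, keep a label outside the truth space,
#' and therefore score as errors.
#'
#' @param z_true,z_pred Equal-length label vectors.
#' @return `z_pred` relabelled into the truth label space where matched.
#' @export
match_labels <- function(z_true, z_pred) {
  if (length(z_true) != length(z_pred)) {
    abort("z_true and z_pred must have equal length", class = "spanr_invalid_input")
  }
  tl <- unique(as.character(z_true))
  pl <- unique(as.character(z_pred))
  cm <- table(factor(as.character(z_true), levels = tl),
              factor(as.character(z_pred), levels = pl))
  if (length(pl) > 9 || length(tl) > 9) {
    abort("label matching by enumeration supports at most 9 classes",
          class = "spanr_invalid_input")
  }
  # enumerate injective maps pred -> truth, maximising matched agreement
  best <- NULL; best_score <- -1
  assign_rec <- function(map, used, score) {
    p <- length(map) + 1L
    if (p > length(pl)) {
      if (score > best_score) { best_score <<- score; best <<- map }
      return(invisible())
    }
    cand <- seq_along(tl)[!used]
    if (!length(cand)) {
      # no truth label left: surplus predicted cluster stays unmatched
      assign_rec(c(map, NA_integer_), used, score)
    } else {
      for (t in cand) {
        used2 <- used
        used2[t] <- TRUE
        assign_rec(c(map, t), used2, score + cm[t, p])
      }
    }
  }
  assign_rec(integer(0), rep(FALSE, length(tl)), 0)

  out <- as.character(z_pred)
  for (p in seq_along(pl)) {
    if (!is.na(best[p])) {
      out[as.character(z_pred) == pl[p]] <- tl[best[p]]
    } else {
      out[as.character(z_pred) == pl[p]] <- paste0(".unmatched_", pl[p])
    }
  }
  if (is.numeric(z_true) && !any(grepl("^\\.unmatched_", out))) {
    out <- as.numeric(out)
    if (is.integer(z_true)) out <- as.integer(out)
  }
  out
}
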