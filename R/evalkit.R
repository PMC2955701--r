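# Evaluation statistics: ROC with the unscored-gene convention, precision
# among top-k, cumulative fold-change curves and their integrated area
# M(n), the consistency sum C(n), and the binding-probability logo.

#' ROC curve and AUC with the unscored-gene convention
#'
#' Scored genes are ranked by descending score (ties grouped); genes without
#' a score are assumed to be ranked by a random predictor, i.e. they
#' contribute the expected diagonal continuation of the curve from the end
#' of the scored segment to (1, 1). AUC by the trapezoid rule.
#'
#' @param scores named numeric vector of prediction scores.
#' @param labels named 0/1 (or logical) truth for every gene, scored or not.
#' @param unscored_ids ids of genes without scores (must appear in
#'   `labels`).
#' @return list with `fpr`, `tpr` (curve points) and `auc`.
#' @export
roc_with_unscored <- function(scores, labels, unscored_ids = character(0)) {
  labels <- setNames(as.integer(as.logical(labels)), names(labels))
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  scored_ids <- setdiff(names(labels), unscored_ids)
  stopifnot(all(scored_ids %in% names(scores)))
  Tt <- sum(labels); Ft <- sum(1 - labels)
  s <- scores[scored_ids]
  l <- labels[scored_ids]
  o <- order(-s)
  s <- s[o]; l <- l[o]
  tp <- fp <- 0
  fpr <- 0; tpr <- 0
  i <- 1
  while (i <= length(s)) {
    j <- i
    while (j < length(s) && s[j + 1] == s[i]) j <- j + 1
    tp <- tp + sum(l[i:j]); fp <- fp + sum(1 - l[i:j])
    fpr <- c(fpr, fp / Ft); tpr <- c(tpr, tp / Tt)
    i <- j + 1
  }
  # unscored genes: expected diagonal continuation to (1,1)
  if (utils::tail(fpr, 1) < 1 || utils::tail(tpr, 1) < 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' True positives among top-ranked predictions
#'
#' @param ranked character vector of gene ids, best first.
#' @param truth character vector of true-target ids.
#' @param ks cutoffs; each must not exceed the ranked-list length.
#' @return named integer vector: number of true targets among the top k.
#' @export
precision_at_k <- function(ranked, truth, ks) {
  if (any(ks > length(ranked)))
    stop("k exceeds the ranked list length")
  out <- vapply(ks, function(k) sum(ranked[seq_len(k)] %in% truth), 0L)
  names(out) <- as.character(ks)
  out
}

#' Cumulative fold-change curve over ranked predictions
#'
#' Orders fold changes by descending prediction score (ties keep input
#' order) and accumulates them; the returned curve vector is sampled at
#' x = 0..K with c(0) = 0.
#'
#' @param scores prediction scores.
#' @param fold_changes (log) fold changes aligned with `scores`.
#' @return object of class `CfcCurve`: numeric vector `c` of length K+1 and
#'   the ranking order.
#' @export
cfc_curve <- function(scores, fold_changes) {
  stopifnot(length(scores) == length(fold_changes))
  o <- order(-scores)                  # stable: ties keep input order
  structure(list(c = c(0, cumsum(fold_changes[o])), order = o),
            class = "CfcCurve")
}

#' Integrated cumulative fold change M(n)
#'
#' \eqn{M(n) = (1/n) \int_0^n c(x) dx} by the trapezoid rule on the
#' piecewise-linear interpolation of the curve samples.
#'
#' @param cfc a `CfcCurve`, or a raw numeric vector of curve values at
#'   x = 0, 1, ..., K.
#' @param n upper integration limit (may be fractional, <= K).
#' @return the average area M(n); more negative = better.
#' @export
m_score <- function(cfc, n) {
  cvals <- if (inherits(cfc, "CfcCurve")) cfc$c else as.numeric(cfc)
  K <- length(cvals) - 1
  if (n > K) stop("n = ", n, " exceeds the curve length ", K)
  if (n <= 0) stop("n must be positive")
  x <- 0:K
  full <- floor(n)
  area <- if (full >= 1)
    sum((cvals[1:full] + cvals[2:(full + 1)]) / 2) else 0
  if (n > full) {
    frac <- n - full
    c_at_n <- cvals[full + 1] + frac * (cvals[full + 2] - cvals[full + 1])
    area <- area + frac * (cvals[full + 1] + c_at_n) / 2
  }
  area / n
}

#' Consistency measure C(n) across miRNAs
#'
#' The sum (default, as defined) or mean of the per-miRNA M(n) values.
#'
#' @param m_scores numeric vector of M(n) values, one per miRNA.
#' @param mode "sum" or "mean".
#' @return C(n).
#' @export
consistency <- function(m_scores, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (mode == "sum") sum(m_scores) else mean(m_scores)
}

#' Binding matrix and binding-probability logo
#'
#' Builds the sites x miRNA-position 0/1 binding matrix from duplex
#' statuses (an element is 1 when that miRNA nucleotide is paired at that
#' site) and the per-position empirical pairing probability; G:U wobbles
#' count as paired by default.
#'
#' @param duplexes list of `DuplexStructure` for the predicted sites.
#' @param mirna_length number of miRNA positions in the logo (positions past
#'   the duplex window count as unpaired).
#' @param count_gu count G:U pairs as bound.
#' @return object of class `BindingLogo`: `matrix` (sites x positions),
#'   `probability` (column means), `n_sites`.
#' @export
tarlogo <- function(duplexes, mirna_length = NULL, count_gu = TRUE) {
  if (!length(duplexes)) stop("empty site list")
  if (is.null(mirna_length))
    mirna_length <- max(vapply(duplexes, function(d) length(d$status), 0L))
  B <- matrix(0L, length(duplexes), mirna_length)
  for (i in seq_along(duplexes)) {
    st <- duplexes[[i]]$status
    paired <- if (count_gu) st <= 2L else st == 1L
    B[i, seq_along(st)] <- as.integer(paired)
  }
  structure(list(matrix = B, probability = colMeans(B),
                 n_sites = length(duplexes)),
            class = "BindingLogo")
}

#' @export
print.BindingLogo <- function(x, ...) {
  cat("<BindingLogo> ", x$n_sites, " site(s); per-position P(bound):\n",
      paste(sprintf("%.2f", x$probability), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write a binding logo as a position-probability table
#'
#' @param logo a `BindingLogo`.
#' @param mirna the `MirnaSeq` the logo describes (provides letters).
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_logo_ppm <- function(logo, mirna, path) {
  n <- length(logo$probability)
  nt <- strsplit(mirna$seq, "")[[1]]
  df <- data.frame(position = seq_len(n),
                   nucleotide = c(nt, rep("-", max(0, n - length(nt))))[1:n],
                   p_bound = logo$probability)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a binding logo with base graphics
#'
#' Letter heights are proportional to the per-position binding probability.
#'
#' @param x a `BindingLogo`.
#' @param mirna the `MirnaSeq`.
#' @param ... passed to `plot`.
#' @export
plot_logo <- function(x, mirna, ...) {
  p <- x$probability
  n <- length(p)
  nt <- strsplit(mirna$seq, "")[[1]]
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(0, 1.05),
                 xlab = "miRNA position (5' to 3')",
                 ylab = "P(bound)", ...)
  cols <- c(A = "#33a02c", C = "#1f78b4", G = "#ff7f00", U = "#e31a1c")
  for (i in seq_len(n)) {
    ch <- if (i <= length(nt)) nt[i] else "-"
    graphics::text(i, p[i] / 2, ch, cex = 0.6 + 2.2 * p[i],
                   col = if (ch %in% names(cols)) cols[[ch]] else "grey40")
  }
  invisible(x)
}
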