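# Independent oracles used across the suite. These re-derive expected values
# by literal enumeration of the stated rules and definitions, never by
# calling the implementation under test.

# grade-group table from the grouping definitions: GG1 = GS <= 6,
# GG2 = 3+4, GG3 = 4+3, GG4 = GS 8, GG5 = GS 9-10
oracle_score_table <- function() {
  tibble::tribble(
    ~primary, ~secondary, ~gg,
    3, 3, 1,
    3, 4, 2,
    3, 5, 4,
    4, 3, 3,
    4, 4, 4,
    4, 5, 5,
    5, 3, 4,
    5, 4, 5,
    5, 5, 5
  )
}

# step-by-step enumeration of the composition rules: 1% total-area floor,
# worst-pattern-any-amount secondary, 5% of-cancer-area rule for lower-grade
# secondaries, worse-pattern tie-break for the primary
oracle_composition_gg <- function(fr, floor = 0.01, sec_min = 0.05) {
  pat_no <- c(gp3 = 3, gp4 = 4, gp5 = 5)
  a <- c(gp3 = 0, gp4 = 0, gp5 = 0)
  a[intersect(names(fr), names(a))] <- fr[intersect(names(fr), names(a))]
  a[a < floor] <- 0
  if (sum(a) == 0) return(0L)
  present <- names(a)[a > 0]
  mx <- max(a)
  tied <- names(a)[a == mx]
  primary <- tied[which.max(pat_no[tied])]
  higher <- present[pat_no[present] > pat_no[primary]]
  if (length(higher)) {
    secondary <- higher[which.max(pat_no[higher])]
  } else {
    lower <- setdiff(present, primary)
    lower <- lower[a[lower] / sum(a) > sec_min]
    secondary <- if (length(lower)) lower[which.max(pat_no[lower])] else primary
  }
  tab <- oracle_score_table()
  tab$gg[tab$primary == pat_no[[primary]] & tab$secondary == pat_no[[secondary]]]
}

# random composition generator biased toward rule boundaries (values near
# the 1% floor and the 5% secondary share)
random_composition <- function() {
  k <- sample(1:4, 1)
  cls <- c("benign", sample(c("gp3", "gp4", "gp5"), k - 1))
  w <- stats::runif(k)
  if (stats::runif(1) < 0.5 && k > 1) {
    # push one cancer pattern near a threshold
    w[k] <- sample(c(stats::runif(1, 0.001, 0.02),
                     stats::runif(1, 0.02, 0.06)), 1)
  }
  stats::setNames(w / sum(w), cls)
}

# pairwise-concordance ROC AUC: enumerate all positive x negative pairs
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# average-precision PR AUC: full recount of precision at each distinct
# threshold
oracle_pr_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  prev_tp <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    ap <- ap + (tp - prev_tp) / n_pos * prec
    prev_tp <- tp
  }
  ap
}

# direct-formula Cohen's kappa with optional quadratic weights
oracle_kappa <- function(cm, quadratic = FALSE) {
  K <- nrow(cm)
  p <- cm / sum(cm)
  w <- if (quadratic) 1 - (outer(1:K, 1:K, "-"))^2 / (K - 1)^2 else diag(K)
  po <- sum(w * p)
  pe <- sum(w * (rowSums(p) %o% colSums(p)))
  (po - pe) / (1 - pe)
}

# exhaustive-threshold best-F1 scan
oracle_best_f1 <- function(scores, labels) {
  best <- -1; best_t <- NA
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred & labels); fp <- sum(pred & !labels); fn <- sum(!pred & labels)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best) { best <- f1; best_t <- t }
  }
  list(f1 = best, threshold = best_t)
}
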