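# Independent brute-force oracles used to cross-check the vectorized
# implementations. Deliberately naive: loops and exhaustive enumeration.

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

oracle_ap <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_rec <- 0
  for (c_ in thr) {
    call_pos <- scores >= c_
    tp <- sum(call_pos & labels == 1)
    prec <- tp / sum(call_pos)
    rec <- tp / n_pos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

oracle_spec_at_sens <- function(scores, labels, target = 0.9) {
  cands <- sort(unique(scores), decreasing = TRUE)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  best <- NULL
  for (c_ in cands) {
    if (mean(pos >= c_) >= target) { best <- c_; break }
  }
  if (is.null(best)) best <- min(scores)
  list(threshold = best, specificity = mean(neg < best))
}

oracle_nri <- function(p_new, p_old, labels) {
  up_e <- dn_e <- up_n <- dn_n <- 0
  for (i in seq_along(labels)) {
    d <- p_new[i] - p_old[i]
    if (labels[i] == 1) {
      if (d > 0) up_e <- up_e + 1
      if (d < 0) dn_e <- dn_e + 1
    } else {
      if (d > 0) up_n <- up_n + 1
      if (d < 0) dn_n <- dn_n + 1
    }
  }
  ne <- sum(labels == 1); nn <- sum(labels == 0)
  (up_e - dn_e) / ne + (dn_n - up_n) / nn
}

oracle_idi <- function(p_new, p_old, labels) {
  ev <- labels == 1
  (mean(p_new[ev]) - mean(p_new[!ev])) - (mean(p_old[ev]) - mean(p_old[!ev]))
}

oracle_net_benefit <- function(prob, labels, pt) {
  tp <- fp <- 0
  for (i in seq_along(labels)) {
    if (prob[i] >= pt) {
      if (labels[i] == 1) tp <- tp + 1 else fp <- fp + 1
    }
  }
  n <- length(labels)
  tp / n - (fp / n) * pt / (1 - pt)
}

oracle_confusion <- function(scores, labels, thr) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(labels)) {
    called <- scores[i] >= thr
    if (called && labels[i] == 1) tp <- tp + 1
    if (called && labels[i] == 0) fp <- fp + 1
    if (!called && labels[i] == 0) tn <- tn + 1
    if (!called && labels[i] == 1) fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# random small prediction tables (<= 10 rows, both classes, ties possible)
make_small_tables <- function(n_tables = 30, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n_tables), function(i) {
    n <- sample(4:10, 1)
    repeat {
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) == 2) break
    }
    scores <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) / 5 else runif(n)
    probs_new <- pmin(pmax(scores + rnorm(n, sd = 0.2), 0.01), 0.99)
    data.frame(scores = scores, probs_new = probs_new,
               cspca_label = labels)
  })
}

# small noiseless study for biomarker tests
tiny_cohort_config <- function(n = 4, prevalence = 0.5, noise_sigma = 0,
                               seed = 1, grid = c(14L, 14L, 10L)) {
  cohort_config(
    sites = list(site_profile("t", n, prevalence, 0.5,
                              noise_sigma = noise_sigma)),
    grid_shape = grid, voxel_spacing = c(2, 2, 3),
    lesion_radius_range = c(3, 5), seed = seed)
}
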