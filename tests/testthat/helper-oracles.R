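# Shared fixtures and independently-coded oracles used across the suite.

NTS <- c("A", "C", "G", "U")

rand_rna <- function(n) paste(sample(NTS, n, replace = TRUE), collapse = "")

rand_mirna <- function(id = "m", n = 22) mirna_seq(id, rand_rna(n))

# --- independent seed-rule oracle ------------------------------------------
# Literal transcription of the five filter rules for an ungapped seed window;
# inputs are character vectors: mseed[k] = miRNA nt at p_k, siteq[k] = UTR nt
# at q_k.  Runs are computed from mismatch breakpoints, not rle.
oracle_rules <- function(mseed, siteq, rule5_strict = TRUE) {
  pairs <- paste0(mseed, siteq)
  is_wc <- pairs %in% c("AU", "UA", "CG", "GC")
  is_gu <- pairs %in% c("GU", "UG")
  is_m <- is_wc | is_gu
  maxrun <- function(v) {
    breaks <- c(0, which(!v), length(v) + 1)
    max(diff(breaks)) - 1
  }
  out <- integer(0)
  if (maxrun(is_wc) > 4) out <- c(out, 1L)
  if (maxrun(is_m) > 5 && maxrun(is_wc) > 2) out <- c(out, 2L)
  if (sum(is_m) > 6 && maxrun(is_wc) > 3) out <- c(out, 3L)
  if (all(is_wc[2:4]) && sum(is_wc) > 3 && sum(is_m) > 4) out <- c(out, 4L)
  wc_need <- if (rule5_strict) 5 else 4
  if (sum(is_m) > 5 && sum(is_wc) > wc_need) out <- c(out, 5L)
  out
}

# --- independent duplex-region oracle --------------------------------------
# Enumerates every strictly increasing pair chain of the 3' region and scores
# it directly from the energy parameters; returns the minimum of (junction +
# interior costs), trailing ends free, empty chain = 0.
oracle_three_prime <- function(mcod, ucod, start, t0, params, Mc, Kr) {
  pt <- function(a, b) {
    key <- paste(a, b)
    switch(key, "1 4" = 1L, "2 3" = 2L, "3 2" = 3L, "4 1" = 4L,
           "3 4" = 5L, "4 3" = 6L, 0L)
  }
  stk <- function(t1, t2) {
    if (t1 == 0 || t2 == 0) return(0)
    ngu <- (t1 >= 5) + (t2 >= 5)
    if (ngu == 0) {
      top <- c(1L, 2L, 3L, 4L, 3L, 4L)
      params$stack_wc[top[t1], top[t2]]
    } else if (ngu == 1) params$stack_gu1 else params$stack_gu2
  }
  gapcost <- function(dm, dj, tp, tn) {
    if (dm == 0 && dj == 0) return(if (tp > 0) stk(tp, tn) else 0)
    k <- min(dm, dj); ex <- max(dm, dj) - k
    params$mismatch * k + if (ex > 0) params$bulge_open +
      params$bulge_ext * ex else 0
  }
  n_m <- Mc - 8L
  pairs <- list()
  for (a in seq_len(n_m)) for (j in seq_len(Kr)) {
    cc <- start - j
    if (cc < 0) next
    t <- pt(mcod[8 + a], ucod[cc + 1])
    if (t > 0) pairs[[length(pairs) + 1]] <- c(a, j, t)
  }
  best <- 0
  recurse <- function(prev, cost) {
    best <<- min(best, cost)
    for (p in pairs) {
      if (p[1] > prev[1] && p[2] > prev[2]) {
        add <- if (prev[1] == 0)
          (if (p[1] == 1 && p[2] == 1 && t0 > 0) stk(t0, p[3]) else 0)
        else gapcost(p[1] - prev[1] - 1, p[2] - prev[2] - 1, prev[3], p[3])
        recurse(p, cost + add)
      }
    }
  }
  recurse(c(0, 0, 0), 0)
  best
}

# --- independent nested-structure fold oracle -------------------------------
# Enumerates every nested pairing (min hairpin loop 3) on a short sequence
# and scores stacked pairs only; returns min(0, best).
oracle_fold <- function(codes, can = rep(TRUE, length(codes)),
                        params = default_energy_params()) {
  n <- length(codes)
  ptab <- matrix(0L, 4, 4)
  ptab[1, 4] <- 1L; ptab[2, 3] <- 2L; ptab[3, 2] <- 3L; ptab[4, 1] <- 4L
  ptab[3, 4] <- 5L; ptab[4, 3] <- 6L
  pairable <- function(i, j) can[i] && can[j] && ptab[codes[i], codes[j]] > 0
  structs <- function(i, j) {
    if (j - i < 4) return(list(list()))
    res <- structs(i + 1, j)
    for (k in (i + 4):j) {
      if (!pairable(i, k)) next
      inner <- structs(i + 1, k - 1)
      outer <- if (k + 1 <= j) structs(k + 1, j) else list(list())
      for (s1 in inner) for (s2 in outer)
        res[[length(res) + 1]] <- c(list(c(i, k)), s1, s2)
    }
    res
  }
  score <- function(s) {
    if (!length(s)) return(0)
    key <- vapply(s, function(p) p[1] * 1000 + p[2], 0)
    e <- 0
    top <- c(1L, 2L, 3L, 4L, 3L, 4L)
    for (p in s) {
      inner <- (p[1] + 1) * 1000 + (p[2] - 1)
      if (inner %in% key) {
        t1 <- ptab[codes[p[1]], codes[p[2]]]
        t2 <- ptab[codes[p[1] + 1], codes[p[2] - 1]]
        ngu <- (t1 >= 5) + (t2 >= 5)
        e <- e + if (ngu == 0) params$stack_wc[top[t1], top[t2]]
        else if (ngu == 1) params$stack_gu1 else params$stack_gu2
      }
    }
    e
  }
  min(0, min(vapply(structs(1, n), score, 0)))
}

# --- independent greedy mRMR -----------------------------------------------
# Recomputes D and R from scratch for every candidate at every step.
oracle_mrmr <- function(X, y) {
  d <- ncol(X)
  yn <- as.numeric(as.factor(y))
  sel <- integer(0)
  avail <- seq_len(d)
  while (length(avail)) {
    phis <- vapply(avail, function(j) {
      S <- c(sel, j)
      D <- mean(vapply(S, function(i) mutual_information(X[, i], yn), 0))
      R <- mean(outer(S, S, Vectorize(function(a, b)
        mutual_information(X[, a], X[, b]))))
      D - R
    }, 0)
    pick <- avail[which.max(phis)]
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  sel
}

# plant the exact reverse complement of p1..p8 at a given q1 coordinate
plant_rc_seed <- function(codes, mcod, q1) {
  comp <- c(4L, 3L, 2L, 1L)
  for (k in 1:8) codes[q1 + 1L - (k - 1L)] <- comp[mcod[k]]
  codes
}

# a small trained two-stage model on a tiny synthetic corpus (cached per
# session; used by pipeline-level tests)
tiny_model_env <- new.env()
get_tiny_setup <- function() {
  if (!is.null(tiny_model_env$setup)) return(tiny_model_env$setup)
  spec <- synthetic_spec(n_mirnas = 1, n_pos_utrs = 10, n_neg_utrs = 10,
                         utr_len_range = c(300L, 500L), seed = 11)
  corpus <- generate_synthetic(spec)
  parts <- split_corpus(corpus, 0.7, seed = 11)
  cfg <- train_config(c_grid = 4^(0:2), gamma_grid = 4^(-3:0),
                      sfs_max = 8, seed = 11, max_neg_sites = 200)
  model <- suppressMessages(train_two_stage(parts$train, cfg))
  tiny_model_env$setup <- list(spec = spec, corpus = corpus, parts = parts,
                               cfg = cfg, model = model)
  tiny_model_env$setup
}
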